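#' Multi-method candidate genes for one phenotype group
#'
#' A gene is "identified by" an annotation engine (GO / KEGG / MGI) iff it is
#' a contributing gene of at least one significant enrichment from that
#' engine, and by the co-expression engine iff it is a contributing gene of a
#' significant network clustering test. Candidate genes are those identified
#' by at least \code{minMethods} distinct engines — method granularity is the
#' engine, not the individual annotation term, so two significant GO terms
#' still count as one method.
#'
#' @param enrichments named list of per-engine enrichment tables
#'   ([S4Vectors::DataFrame] as from [enrichGroup()]), e.g.
#'   \code{list(GO = ..., KEGG = ..., MGI = ...)}.
#' @param clusterResults list of [clusterTest()] results attributed to the
#'   co-expression engine (empty list if none).
#' @param minMethods minimum number of distinct engines (default 2).
#' @param alpha significance threshold for cluster-test p-values (default
#'   0.05; enrichment tables carry their own significance flag).
#' @return list with \code{genes} (character candidates), \code{methods}
#'   (named list: candidate gene -> engines that identified it) and
#'   \code{perEngine} (named list: engine -> all genes it identified).
#'   Raising \code{minMethods} can only shrink the candidate set.
#' @export
multiMethodCandidates <- function(enrichments, clusterResults = list(),
                                  minMethods = 2L, alpha = 0.05) {
  perEngine <- lapply(enrichments, function(res) {
    if (is.null(res) || !nrow(res)) return(character())
    sig <- res[res$significant, , drop = FALSE]
    sort(unique(unlist(sig$contributing, use.names = FALSE)))
  })
  coexpr <- character()
  for (cr in clusterResults) {
    if (isTRUE(cr$testable) && !is.na(cr$p) && cr$p < alpha) {
      coexpr <- union(coexpr, cr$contributing)
    }
  }
  perEngine$coexpression <- sort(coexpr)
  counts <- table(unlist(perEngine, use.names = FALSE))
  genes <- sort(names(counts)[counts >= minMethods])
  methods <- lapply(stats::setNames(genes, genes), function(g)
    names(perEngine)[vapply(perEngine, function(x) g %in% x, logical(1L))])
  list(genes = genes, methods = methods, perEngine = perEngine)
}

#' Validate a candidate set by protein-interaction clustering
#'
#' Tests whether a group's multi-method candidate genes interact more than
#' degree-matched random gene sets do, delegating to [clusterTest()] with the
#' edge-count statistic on the PPI network.
#'
#' @param candidates character vector of candidate genes (or the list from
#'   [multiMethodCandidates()]).
#' @param ppi a unit-weight [GeneNetwork-class].
#' @param nSamples degree-matched null sets (default 1000; the analysis cap
#'   is 10,000).
#' @param alpha significance threshold on the empirical p (default 0.05).
#' @return a [clusterTest()] result with an added \code{significant} flag;
#'   untestable when fewer than two candidates are in the network.
#' @export
validateCandidatesPpi <- function(candidates, ppi, nSamples = 1000L,
                                  alpha = 0.05) {
  if (is.list(candidates)) candidates <- candidates$genes
  res <- clusterTest(ppi, candidates, statistic = "edge-count",
                     nSamples = nSamples)
  res$significant <- isTRUE(res$testable) && !is.na(res$p) && res$p < alpha
  res
}
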
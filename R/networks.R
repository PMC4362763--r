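#' Construct a GeneNetwork
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{weight} (defaults to 1); one row per undirected edge.
#' @param weighted logical; set FALSE for unit-weight interaction networks.
#' @param nodes optional character vector of additional isolated nodes to
#'   include (normally edges define the node set).
#' @return A [GeneNetwork-class]. Self-edges are an error; duplicate edges are
#'   collapsed keeping the first weight.
#' @export
geneNetwork <- function(edges, weighted = TRUE, nodes = NULL) {
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  edges <- edges[!duplicated(key), , drop = FALSE]
  vs <- unique(c(edges$gene_a, edges$gene_b, nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b, weight = edges$weight),
    directed = FALSE, vertices = vs)
  new("GeneNetwork", graph = g, weighted = weighted)
}

#' @describeIn geneNetwork Gene (node) names of a network.
#' @param net a [GeneNetwork-class].
#' @export
networkGenes <- function(net) igraph::V(net@graph)$name

#' @describeIn geneNetwork Named node degrees (number of incident edges).
#' @export
networkDegree <- function(net) igraph::degree(net@graph)

#' @describeIn geneNetwork Edge table (gene_a, gene_b, weight).
#' @export
networkEdges <- function(net) {
  e <- igraph::as_data_frame(net@graph, what = "edges")
  names(e)[1:2] <- c("gene_a", "gene_b")
  e
}

## weighted (or unit) adjacency as a sparse symmetric matrix
.adjacency <- function(net, weighted = TRUE) {
  igraph::as_adjacency_matrix(net@graph,
    attr = if (weighted) "weight" else NULL, sparse = TRUE)
}

#' Read a network from an edge-list TSV
#'
#' Three tab-separated header columns \code{gene_a}, \code{gene_b},
#' \code{weight}; a two-column file is accepted with weights defaulting to 1.
#'
#' @param path input file path.
#' @param weighted logical, stored on the returned network.
#' @return A [GeneNetwork-class].
#' @export
readEdgeList <- function(path, weighted = TRUE) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  if (is.null(d$weight)) d$weight <- 1
  geneNetwork(d, weighted = weighted)
}

#' Write a network as an edge-list TSV
#'
#' @param net a [GeneNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a co-expression network from an expression matrix
#'
#' Genes expressed below \code{rpkmMin} in more than \code{lowFracMax} of the
#' samples are excluded, pairwise Pearson correlation is computed on the
#' remaining genes, and an edge is kept for every pair with signed correlation
#' \code{r >= rMin} (positive correlations only, not absolute values). Genes
#' left without any edge are dropped from the node set.
#'
#' @param expr numeric matrix, genes (rows, named) x samples; RPKM-like scale.
#' @param rpkmMin expression floor (default 1).
#' @param lowFracMax maximum tolerated fraction of below-floor samples
#'   (default 0.95, i.e. exclude genes low in more than 95\% of samples).
#' @param rMin correlation threshold for edges (default 0.7).
#' @return A weighted [GeneNetwork-class] whose edge weights are the
#'   correlation coefficients.
#' @export
buildCoexpressionNetwork <- function(expr, rpkmMin = 1, lowFracMax = 0.95,
                                     rMin = 0.7) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  lowFrac <- rowMeans(expr < rpkmMin)
  expr <- expr[lowFrac <= lowFracMax, , drop = FALSE]
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from correlation")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  r[lower.tri(r, diag = TRUE)] <- NA
  hit <- which(r >= rMin, arr.ind = TRUE)
  geneNetwork(data.frame(gene_a = rownames(r)[hit[, 1L]],
                         gene_b = rownames(r)[hit[, 2L]],
                         weight = r[hit]),
              weighted = TRUE)
}

#' Degree-matched random gene sets
#'
#' Draws random gene sets equal in size to the seed set and matching its node
#' degree distribution: for each seed gene a gene of identical degree is
#' sampled where the degree class allows, falling back to the nearest degrees
#' (smallest absolute degree difference) when a class is exhausted; the
#' maximum degree deviation used is recorded in the \code{"tolerance"}
#' attribute. Sampling within a set is without replacement; duplicate sets may
#' occur across draws.
#'
#' @param net a [GeneNetwork-class].
#' @param seedGenes character vector of seed genes, all present in the
#'   network.
#' @param nSamples number of sets to draw (the analysis default caps this at
#'   10,000).
#' @return list of character vectors, each of length
#'   \code{length(seedGenes)}; attribute \code{"tolerance"} gives the largest
#'   degree deviation accepted (0 when matching was exact throughout).
#' @export
degreeMatchedSamples <- function(net, seedGenes, nSamples = 1000L) {
  nodes <- networkGenes(net)
  seedGenes <- unique(seedGenes)
  if (!all(seedGenes %in% nodes)) stop("seed genes must all be network nodes")
  if (length(seedGenes) > length(nodes)) stop("seed set larger than node set")
  deg <- networkDegree(net)
  classNodes <- split(names(deg), deg)
  seedDeg <- deg[seedGenes]
  profile <- table(seedDeg)           # degree -> how many to draw
  dVals <- as.integer(names(profile))
  cnts <- as.integer(profile)
  exactOK <- all(vapply(seq_along(dVals), function(i)
    length(classNodes[[as.character(dVals[i])]]) >= cnts[i], logical(1L)))
  tol <- 0L
  samples <- vector("list", nSamples)
  if (exactOK) {
    pools <- lapply(as.character(dVals), function(d) classNodes[[d]])
    for (s in seq_len(nSamples)) {
      samples[[s]] <- unlist(lapply(seq_along(pools), function(i) {
        p <- pools[[i]]
        p[sample.int(length(p), cnts[i])]
      }), use.names = FALSE)
    }
  } else {
    ## some exact degree class is exhausted: widen to nearest degrees,
    ## excluding genes already drawn into this set
    for (s in seq_len(nSamples)) {
      chosen <- character()
      for (i in seq_along(dVals)) {
        avail <- setdiff(nodes, chosen)
        dd <- abs(deg[avail] - dVals[i])
        take <- cnts[i]
        picked <- character()
        for (t in sort(unique(dd))) {
          tier <- avail[dd == t]
          need <- take - length(picked)
          picked <- c(picked,
                      if (length(tier) <= need) tier
                      else tier[sample.int(length(tier), need)])
          tol <- max(tol, t)
          if (length(picked) == take) break
        }
        chosen <- c(chosen, picked)
      }
      samples[[s]] <- chosen
    }
  }
  attr(samples, "tolerance") <- tol
  samples
}

## the (1 + more-extreme) / (1 + draws) empirical p estimator; never zero
.empiricalP <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Network clustering test with a degree-matched null
#'
#' Measures how strongly a test gene set clusters in a network: the observed
#' statistic over the induced subgraph (sum of edge correlation weights, or
#' the number of edges for interaction networks) is compared against
#' degree-matched random gene sets, giving the empirical p-value
#' \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{samples})}.
#'
#' @param net a [GeneNetwork-class].
#' @param testGenes character vector of genes; genes absent from the network
#'   are silently dropped (their number is reported in the result).
#' @param statistic "weight-sum" (default) or "edge-count"; on a unit-weight
#'   network the two coincide.
#' @param nSamples number of degree-matched null sets (default 1000; the
#'   analysis cap is 10,000).
#' @return list with elements \code{testable}, \code{statistic},
#'   \code{observed}, \code{p}, \code{nSamples}, \code{genes} (in-network test
#'   genes), \code{contributing} (test genes with at least one induced edge),
#'   \code{nDropped} and \code{tolerance} (degree-matching tolerance used).
#'   Fewer than two in-network genes gives \code{testable = FALSE}.
#' @export
clusterTest <- function(net, testGenes,
                        statistic = c("weight-sum", "edge-count"),
                        nSamples = 1000L) {
  statistic <- match.arg(statistic)
  testGenes <- unique(testGenes)
  nodes <- networkGenes(net)
  present <- intersect(testGenes, nodes)
  nDropped <- length(testGenes) - length(present)
  if (length(present) < 2L) {
    return(list(testable = FALSE, statistic = statistic, observed = NA_real_,
                p = NA_real_, nSamples = 0L, genes = present,
                contributing = character(), nDropped = nDropped,
                tolerance = NA_integer_))
  }
  A <- .adjacency(net, weighted = statistic == "weight-sum")
  idx <- match(present, nodes)
  sub <- A[idx, idx, drop = FALSE]
  observed <- sum(sub) / 2
  contributing <- present[Matrix::rowSums(sub != 0) > 0]
  samples <- degreeMatchedSamples(net, present, nSamples)
  lookup <- stats::setNames(seq_along(nodes), nodes)
  null <- vapply(samples, function(g) {
    j <- lookup[g]
    sum(A[j, j]) / 2
  }, numeric(1L))
  list(testable = TRUE, statistic = statistic, observed = observed,
       p = .empiricalP(observed, null), nSamples = length(null),
       genes = present, contributing = contributing, nDropped = nDropped,
       tolerance = attr(samples, "tolerance"))
}

#' Bait-network extension test with randomised CNV regions
#'
#' Asks whether the genes hit by a set of CNV regions (CNVRs) from an
#' independent cohort interact with a phenotype-associated "bait" gene set
#' more often than expected. CNVRs containing a bait gene are removed first,
#' as are CNVRs hitting no gene present in the interaction network (both
#' counts are reported). The observed statistic is the number of network edges
#' between bait genes and CNVR-hit genes; the null re-places each CNVR as a
#' random run of consecutive genes (genomic order) containing the same number
#' of in-network genes, prohibited from containing any bait gene, with the
#' chromosome chosen proportionally to its count of feasible anchor positions.
#'
#' @param baitGenes character vector of bait genes.
#' @param cnvrs GRanges of merged CNV regions (see [mergeCnvrs()]).
#' @param ppi a unit-weight [GeneNetwork-class].
#' @param models a [GeneModelSet-class] defining gene content and genomic
#'   order.
#' @param nRand number of randomised CNVR sets (default 500).
#' @param maxTries placement retries per CNVR before a hard error.
#' @return list with \code{testable}, \code{observed}, \code{p},
#'   \code{nRand}, \code{extension} (CNVR genes with at least one edge to a
#'   bait gene), \code{nBaitCnvrsDropped}, \code{nNoPpiCnvrsDropped} and
#'   \code{nCnvrsUsed}.
#' @export
baitExtensionTest <- function(baitGenes, cnvrs, ppi, models, nRand = 500L,
                              maxTries = 1000L) {
  baitGenes <- unique(baitGenes)
  nodes <- networkGenes(ppi)
  cnvrGenes <- as.list(genesAffected(cnvrs, models))
  hasBait <- vapply(cnvrGenes, function(g) any(baitGenes %in% g), logical(1L))
  nBaitDropped <- sum(hasBait)
  cnvrGenes <- cnvrGenes[!hasBait]
  inPpi <- lapply(cnvrGenes, intersect, y = nodes)
  noPpi <- lengths(inPpi) == 0L
  nNoPpiDropped <- sum(noPpi)
  inPpi <- inPpi[!noPpi]
  message(nBaitDropped, " CNVR(s) dropped for containing bait genes; ",
          nNoPpiDropped, " CNVR(s) dropped with no in-network genes")
  baitIn <- intersect(baitGenes, nodes)
  if (!length(inPpi) || !length(baitIn)) {
    return(list(testable = FALSE, observed = NA_real_, p = NA_real_,
                nRand = 0L, extension = character(),
                nBaitCnvrsDropped = nBaitDropped,
                nNoPpiCnvrsDropped = nNoPpiDropped, nCnvrsUsed = length(inPpi)))
  }
  A <- .adjacency(ppi, weighted = FALSE)
  lookup <- stats::setNames(seq_along(nodes), nodes)
  countEdges <- function(targets) {
    targets <- setdiff(targets, baitIn)
    if (!length(targets)) return(0)
    sum(A[lookup[baitIn], lookup[targets], drop = FALSE])
  }
  targetGenes <- unique(unlist(inPpi, use.names = FALSE))
  observed <- countEdges(targetGenes)
  ## genomic order of in-network genes per chromosome
  genes <- models@genes
  ord <- order(as.character(seqnames(genes)), start(genes))
  genesOrd <- names(genes)[ord]
  chromOrd <- as.character(seqnames(genes))[ord]
  keep <- genesOrd %in% nodes
  runSeq <- split(genesOrd[keep], chromOrd[keep])
  sizes <- lengths(inPpi)
  null <- numeric(nRand)
  for (r in seq_len(nRand)) {
    hit <- character()
    for (ci in seq_along(sizes)) {
      m <- sizes[[ci]]
      anchors <- pmax(lengths(runSeq) - m + 1L, 0L)
      if (sum(anchors) == 0L) {
        stop("no feasible matched run for CNVR #", ci, " (", m,
             " in-network genes)")
      }
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        chrom <- sample(names(runSeq), 1L, prob = anchors)
        a <- sample.int(anchors[[chrom]], 1L)
        win <- runSeq[[chrom]][a:(a + m - 1L)]
        if (!any(baitGenes %in% win)) {
          hit <- c(hit, win)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("no bait-free matched run found for CNVR #", ci,
             " after ", maxTries, " tries")
      }
    }
    null[[r]] <- countEdges(unique(hit))
  }
  edgeToBait <- Matrix::colSums(
    A[lookup[baitIn], lookup[setdiff(targetGenes, baitIn)], drop = FALSE]) > 0
  list(testable = TRUE, observed = observed,
       p = .empiricalP(observed, null), nRand = nRand,
       extension = sort(names(edgeToBait)[edgeToBait]),
       nBaitCnvrsDropped = nBaitDropped,
       nNoPpiCnvrsDropped = nNoPpiDropped, nCnvrsUsed = length(inPpi))
}
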
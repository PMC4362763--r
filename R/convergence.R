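#' Phenotype frequencies over a patient population
#'
#' For every ontology term carried (after propagation) by at least one patient
#' in the population, the fraction of patients carrying it. The named terms
#' form the phenotype universe used by the Goodall3 similarity: all phenotypes
#' annotated to any of the patients considered.
#'
#' @param termsList named list of (propagated) term sets, one per patient.
#' @return named numeric vector of frequencies in (0, 1].
#' @export
phenotypeFrequencies <- function(termsList) {
  if (!length(termsList)) stop("empty cohort")
  tab <- table(unlist(termsList, use.names = FALSE))
  stats::setNames(as.numeric(tab) / length(termsList), names(tab))
}

#' Goodall3 phenotypic similarity between two patients
#'
#' Frequency-weighted categorical similarity over a fixed phenotype universe:
#' a phenotype of population frequency \eqn{f_i} contributes
#' \eqn{1 - f_i^2} when present in both patients, \eqn{1 - (1 - f_i)^2} when
#' present in neither, and 0 when present in only one. Shared rare presences
#' and shared common absences thus weigh most; a ubiquitous phenotype
#' (\eqn{f_i = 1}) carries no information. Requires systematic phenotyping, so
#' that absence of a term is evidence of absence.
#'
#' @param a,b character vectors of (propagated) term ids for the two patients.
#' @param freqs named numeric of term frequencies defining the universe (see
#'   [phenotypeFrequencies()]); terms outside the universe are ignored.
#' @return the similarity score, symmetric in its arguments.
#' @examples
#' f <- c(A = 0.5, B = 0.25, C = 0.75)
#' goodall3(c("A", "B"), "A", f)  # 0.75 + 0 + 0.9375
#' @export
goodall3 <- function(a, b, freqs) {
  f <- unname(freqs)
  u <- names(freqs)
  inA <- u %in% a
  inB <- u %in% b
  sum((1 - f^2)[inA & inB]) + sum((1 - (1 - f)^2)[!inA & !inB])
}

#' Pairwise Goodall3 similarity matrix
#'
#' Computes all pairwise Goodall3 scores for a set of patients at once via the
#' presence-matrix identity
#' \eqn{S = P \, \mathrm{diag}(1 - f^2) \, P^\top +
#'      (1-P) \, \mathrm{diag}(1 - (1-f)^2) \, (1-P)^\top}.
#'
#' @param termsList named list of (propagated) term sets per patient.
#' @param freqs named numeric term frequencies defining the universe.
#' @return symmetric numeric matrix with patient ids as dimnames.
#' @export
goodall3Matrix <- function(termsList, freqs) {
  u <- names(freqs)
  f <- unname(freqs)
  P <- vapply(termsList, function(t) as.numeric(u %in% t),
              numeric(length(u)))
  if (length(u) == 1L) P <- matrix(P, nrow = 1L,
                                   dimnames = list(u, names(termsList)))
  Q <- 1 - P
  S <- t(P * (1 - f^2)) %*% P + t(Q * (1 - (1 - f)^2)) %*% Q
  dimnames(S) <- list(names(termsList), names(termsList))
  S
}

#' Split a phenotype group into contributing and non-contributing patients
#'
#' A group member is "contributing" to a functional enrichment iff at least
#' one of its filtered de novo CNV genes belongs to the enrichment's
#' contributing gene set.
#'
#' @param members character vector of the group's patient ids.
#' @param geneSets named list of per-patient pooled gene sets (see
#'   [patientGeneSets()]).
#' @param contributingGenes character vector, the enrichment's contributing
#'   genes.
#' @return list with character elements \code{contributing} and
#'   \code{nonContributing}, a partition of \code{members}.
#' @export
contributingSplit <- function(members, geneSets, contributingGenes) {
  hit <- vapply(members, function(p)
    any(geneSets[[p]] %in% contributingGenes), logical(1L))
  list(contributing = members[hit], nonContributing = members[!hit])
}

.pairValues <- function(sim, contrib, noncontrib) {
  intra <- sim[contrib, contrib, drop = FALSE][upper.tri(diag(length(contrib)))]
  inter <- as.vector(sim[contrib, noncontrib, drop = FALSE])
  list(intra = intra, inter = inter)
}

#' Phenotypic convergence test for one enrichment split
#'
#' Compares the Goodall3 similarity amongst contributing patients (all
#' contributing pairs, "intra") against the similarity between contributing
#' and non-contributing patients ("inter") with a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction for large pair sets, exact
#' enumeration automatically for tiny tie-free ones). Tested only when both
#' sides of the split have at least \code{minEach} patients. Note the pair
#' values share patients and are not independent; p-values are reported as
#' descriptive indices of convergence.
#'
#' @param contrib,noncontrib character vectors of patient ids.
#' @param termsList named list of propagated term sets (used with
#'   \code{freqs} to compute similarities when \code{sim} is not given).
#' @param freqs named numeric term frequencies.
#' @param sim optional precomputed similarity matrix covering all patients.
#' @param minEach minimum patients on each side (default 10).
#' @return list with \code{testable}, \code{p}, \code{W}, \code{direction}
#'   (+1 when the intra median exceeds the inter median, -1 below, 0 tie),
#'   \code{medianIntra}, \code{medianInter}, \code{nContributing},
#'   \code{nNonContributing}, \code{nIntra}, \code{nInter}.
#' @export
convergenceTest <- function(contrib, noncontrib, termsList = NULL,
                            freqs = NULL, sim = NULL, minEach = 10L) {
  if (length(contrib) < minEach || length(noncontrib) < minEach) {
    return(list(testable = FALSE, p = NA_real_, W = NA_real_,
                direction = NA_real_, medianIntra = NA_real_,
                medianInter = NA_real_,
                nContributing = length(contrib),
                nNonContributing = length(noncontrib),
                nIntra = NA_integer_, nInter = NA_integer_))
  }
  if (is.null(sim)) {
    if (is.null(termsList) || is.null(freqs)) {
      stop("either sim or both termsList and freqs must be supplied")
    }
    sim <- goodall3Matrix(termsList[c(contrib, noncontrib)], freqs)
  }
  pv <- .pairValues(sim, contrib, noncontrib)
  wt <- suppressWarnings(
    stats::wilcox.test(pv$intra, pv$inter, alternative = "two.sided"))
  mi <- stats::median(pv$intra)
  mo <- stats::median(pv$inter)
  list(testable = TRUE, p = wt$p.value, W = unname(wt$statistic),
       direction = sign(mi - mo), medianIntra = mi, medianInter = mo,
       nContributing = length(contrib), nNonContributing = length(noncontrib),
       nIntra = length(pv$intra), nInter = length(pv$inter))
}

#' Subterm-restricted convergence test
#'
#' Repeats the convergence test using only the proper descendants (subterms)
#' of the group's phenotype term as the phenotype universe, with frequencies
#' recomputed over the comparison patients. A significant full-universe test
#' together with a null subterm test indicates convergence through distinct
#' co-morbid phenotypes (pleiotropy) rather than a finer subtype of the group
#' phenotype.
#'
#' @param groupTerm the group's ontology term id.
#' @param contrib,noncontrib character vectors of patient ids.
#' @param termsList named list of propagated term sets.
#' @param dag an [OntologyDAG-class].
#' @param minEach minimum patients on each side (default 10).
#' @return as [convergenceTest()], with an extra element
#'   \code{nUniverseTerms}; untestable when no subterm of the group term is
#'   carried by any comparison patient.
#' @export
subtermConvergence <- function(groupTerm, contrib, noncontrib, termsList,
                               dag, minEach = 10L) {
  patients <- c(contrib, noncontrib)
  sub <- properDescendants(dag, groupTerm)
  carried <- unique(unlist(termsList[patients], use.names = FALSE))
  universe <- intersect(sub, carried)
  if (!length(universe)) {
    out <- convergenceTest(character(), character(), minEach = minEach)
    out$testable <- FALSE
    out$nUniverseTerms <- 0L
    return(out)
  }
  restricted <- lapply(termsList[patients], intersect, y = universe)
  freqs <- stats::setNames(
    vapply(universe, function(t)
      mean(vapply(restricted, function(x) t %in% x, logical(1L))),
    numeric(1L)), universe)
  out <- convergenceTest(contrib, noncontrib, restricted, freqs,
                         minEach = minEach)
  out$nUniverseTerms <- length(universe)
  out
}

#' Binomial excess test over convergence directions
#'
#' Counts, across testable convergence results, how often the contributing
#' patients' intra-group median similarity exceeds the inter-group median, and
#' tests the excess against a fair coin with a one-sided binomial test.
#' Results with exactly tied medians are dropped from the denominator.
#'
#' @param results list of results from [convergenceTest()] (untestable entries
#'   are ignored), or a numeric vector of directions (+1/-1/0).
#' @return list with \code{p}, \code{nGreater}, \code{nLess}, \code{nTies},
#'   \code{testable}; all-tied input is reported untestable.
#' @export
excessBinomial <- function(results) {
  dirs <- if (is.numeric(results)) results
          else vapply(Filter(function(r) isTRUE(r$testable), results),
                      `[[`, numeric(1L), "direction")
  nG <- sum(dirs > 0)
  nL <- sum(dirs < 0)
  nT <- sum(dirs == 0)
  if (nG + nL == 0L) {
    return(list(p = NA_real_, nGreater = nG, nLess = nL, nTies = nT,
                testable = FALSE))
  }
  bt <- stats::binom.test(nG, nG + nL, p = 0.5, alternative = "greater")
  list(p = bt$p.value, nGreater = nG, nLess = nL, nTies = nT, testable = TRUE)
}

#' Combine phenotype groups sharing a significant annotation
#'
#' Where the same annotation term is significantly enriched in several
#' patient-phenotype groups, pools the patients: contributing patients are the
#' union of each group's contributing patients and non-contributing patients
#' are the pooled group members contributing nowhere for that term, then the
#' convergence test is applied to the pooled split. The number of associated
#' phenotype groups is reported alongside, since annotations driving many
#' phenotype groups tend to identify less phenotypically-coherent subsets.
#'
#' @param enrichments [S4Vectors::DataFrame] of per-group enrichment rows
#'   (columns \code{group_term}, \code{resource}, \code{term},
#'   \code{significant}, \code{contributing}), as produced by the pipeline.
#' @param groups [S4Vectors::DataFrame] from [buildGroups()].
#' @param geneSets named list of per-patient gene sets.
#' @param termsList named list of propagated term sets.
#' @param freqs cohort-wide term frequencies.
#' @param minEach minimum patients on each side (default 10).
#' @return list of results keyed by "resource|term", each a
#'   [convergenceTest()] result plus \code{resource}, \code{term},
#'   \code{nGroups}; entries where every pooled patient contributes are
#'   untestable by the size rule.
#' @export
combineByAnnotation <- function(enrichments, groups, geneSets, termsList,
                                freqs, minEach = 10L) {
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  if (!nrow(sig)) return(list())
  keys <- paste(sig$resource, sig$term, sep = "|")
  memberOf <- stats::setNames(as.list(groups$members), groups$term)
  out <- list()
  for (key in unique(keys)) {
    rows <- which(keys == key)
    contrib <- character()
    pooled <- character()
    for (i in rows) {
      m <- memberOf[[sig$group_term[i]]]
      pooled <- union(pooled, m)
      sp <- contributingSplit(m, geneSets, sig$contributing[[i]])
      contrib <- union(contrib, sp$contributing)
    }
    noncontrib <- setdiff(pooled, contrib)
    res <- convergenceTest(contrib, noncontrib, termsList, freqs,
                           minEach = minEach)
    res$resource <- sig$resource[rows[1L]]
    res$term <- sig$term[rows[1L]]
    res$nGroups <- length(rows)
    out[[key]] <- res
  }
  out
}

#' Extended gene set of a candidate pathway
#'
#' Genes functionally related to a candidate set: genes sharing the enriched
#' annotation and/or genes with a direct network edge (co-expression or
#' protein interaction) to a candidate gene, excluding the candidates
#' themselves.
#'
#' @param candidates character vector of candidate pathway genes.
#' @param annotGenes character vector of genes carrying the same annotation
#'   (may be empty).
#' @param networks list of [GeneNetwork-class] objects whose direct neighbours
#'   of candidates are included.
#' @return character vector of extended genes.
#' @export
extendedGeneSet <- function(candidates, annotGenes = character(),
                            networks = list()) {
  ext <- annotGenes
  for (net in networks) {
    present <- intersect(candidates, networkGenes(net))
    if (length(present)) {
      nb <- unique(unlist(lapply(
        igraph::adjacent_vertices(net@graph, present), igraph::as_ids)))
      ext <- union(ext, nb)
    }
  }
  sort(setdiff(unique(ext), candidates))
}

#' Replication grouping on patients without de novo CNVs
#'
#' Assigns each replication-pool patient, on the basis of the genes affected
#' by their inherited/unknown-inheritance CNVs, to exactly one of three
#' mutually exclusive groups: \code{candidate} (a CNV hits a candidate pathway
#' gene; candidate wins over extended), \code{extended} (no candidate gene but
#' a gene of the extended pathway), or \code{none} (no CNVs, or neither).
#' Two convergence comparisons are run: candidate vs (extended + none), and
#' extended vs none.
#'
#' @param repCohort a [PatientCohort-class] of the replication pool, gene
#'   annotated.
#' @param candidateGenes character vector from the de novo analysis.
#' @param extendedGenes character vector (see [extendedGeneSet()]).
#' @param minEach minimum group sizes for the tests (default 10).
#' @return list with \code{assignment} (named character:
#'   candidate/extended/none), \code{candidateTest} and \code{extendedTest}
#'   ([convergenceTest()] results, frequencies computed over the replication
#'   pool).
#' @export
replicationGrouping <- function(repCohort, candidateGenes, extendedGenes,
                                minEach = 10L) {
  geneSets <- patientGeneSets(repCohort,
                              inheritance = c("inherited", "unknown"))
  ids <- patientIds(repCohort)
  assignment <- vapply(ids, function(p) {
    g <- geneSets[[p]]
    if (any(g %in% candidateGenes)) "candidate"
    else if (any(g %in% extendedGenes)) "extended"
    else "none"
  }, character(1L))
  termsList <- propagatedTerms(repCohort)
  freqs <- phenotypeFrequencies(termsList)
  cand <- ids[assignment == "candidate"]
  ext <- ids[assignment == "extended"]
  none <- ids[assignment == "none"]
  list(assignment = assignment,
       candidateTest = convergenceTest(cand, c(ext, none), termsList, freqs,
                                       minEach = minEach),
       extendedTest = convergenceTest(ext, none, termsList, freqs,
                                      minEach = minEach))
}
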
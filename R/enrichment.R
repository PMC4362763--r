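#' Construct an AnnotationCollection
#'
#' @param name resource name (e.g. "GO", "KEGG", "MGI").
#' @param sets named list of gene id vectors, one per annotation term.
#' @param universe background gene universe; defaults to the union of all
#'   annotated genes (the resource's own gene coverage approximates the
#'   whole-genome background, and can be overridden).
#' @param categories optional named character, annotation term -> overarching
#'   category.
#' @param orthologs optional named character, human gene -> model gene,
#'   strictly 1:1 (genes with ambiguous orthology must be omitted upstream).
#' @return An [AnnotationCollection-class].
#' @export
annotationCollection <- function(name, sets, universe = NULL,
                                 categories = character(),
                                 orthologs = character()) {
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  new("AnnotationCollection", name = name, sets = sets,
      universe = sort(unique(universe)), categories = categories,
      orthologs = orthologs)
}

#' @describeIn annotationCollection Term -> gene-set map.
#' @param annot an [AnnotationCollection-class].
#' @export
annotationSets <- function(annot) annot@sets

#' @describeIn annotationCollection Background gene universe.
#' @export
annotationUniverse <- function(annot) annot@universe

#' @describeIn annotationCollection Resource name.
#' @export
annotationName <- function(annot) annot@name

#' Read gene sets in GMT format
#'
#' GMT lines are tab-separated: term id, description, then member genes.
#'
#' @param path input file path.
#' @param name resource name for the returned collection.
#' @param ... further arguments to [annotationCollection()].
#' @return An [AnnotationCollection-class].
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path, name = basename(path), ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-c(1L, 2L)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  annotationCollection(name, sets, ...)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene vectors.
#' @param path output file path.
#' @param descriptions optional named character of term descriptions.
#' @return invisibly, the path.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(t) {
    d <- if (!is.null(descriptions) && t %in% names(descriptions))
      descriptions[[t]] else "na"
    paste(c(t, d, sets[[t]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 1:1 ortholog map
#'
#' Two tab-separated columns without header: human gene, model-organism gene.
#' Rows participating in any many-to-one or one-to-many relationship are
#' dropped, keeping only simple, unambiguous 1:1 pairs.
#'
#' @param path input file path.
#' @return named character vector, human gene -> model gene (a bijection).
#' @export
readOrthologMap <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "")
  dupH <- d[[1L]] %in% d[[1L]][duplicated(d[[1L]])]
  dupM <- d[[2L]] %in% d[[2L]][duplicated(d[[2L]])]
  d <- d[!dupH & !dupM, ]
  stats::setNames(d[[2L]], d[[1L]])
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least \code{k} annotated genes when drawing
#' \code{n} genes without replacement from a universe of \code{N} genes of
#' which \code{K} are annotated: \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}, computed as an exact tail sum.
#'
#' @param k observed overlap (test genes that are annotated).
#' @param n number of test genes in the universe.
#' @param K number of annotated genes in the universe.
#' @param N universe size.
#' @return the exact upper-tail probability.
#' @examples
#' hypergeomUpperTail(3, 6, 5, 20)
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("invalid hypergeometric counts (need 0 <= k <= min(n, K); n, K <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH step-up: \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j},
#' capped at 1; order-preserving in p.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment of one phenotype group
#'
#' Tests the pooled CNV gene set of a patient-phenotype group against every
#' term of an annotation collection with the upper-tail hypergeometric test,
#' applying BH-FDR within the (group x resource) family. Terms annotating no
#' universe gene are skipped.
#'
#' @param genes character vector, the group's pooled gene set.
#' @param annot an [AnnotationCollection-class].
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return [S4Vectors::DataFrame] with one row per testable term: columns
#'   \code{resource}, \code{term}, \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{fold} ((k/n)/(K/N); 0 when k = 0), \code{p}, \code{q},
#'   \code{significant} and \code{contributing} (CharacterList, the test genes
#'   annotated to the term). Zero rows (with a warning) when no test gene is
#'   in the universe.
#' @export
enrichGroup <- function(genes, annot, alpha = 0.05) {
  test <- intersect(genes, annot@universe)
  empty <- DataFrame(resource = character(), term = character(),
                     k = integer(), n = integer(), K = integer(),
                     N = integer(), fold = numeric(), p = numeric(),
                     q = numeric(), significant = logical(),
                     contributing = IRanges::CharacterList())
  if (!length(test)) {
    warning("no test gene present in the '", annot@name, "' universe")
    return(empty)
  }
  sets <- annot@sets[lengths(annot@sets) > 0L]
  if (!length(sets)) return(empty)
  N <- length(annot@universe)
  n <- length(test)
  K <- lengths(sets)
  contrib <- lapply(sets, intersect, x = test)
  k <- lengths(contrib)
  p <- vapply(seq_along(sets), function(i)
    hypergeomUpperTail(k[[i]], n, K[[i]], N), numeric(1L))
  q <- bhFdr(p)
  DataFrame(resource = annot@name, term = names(sets),
            k = unname(k), n = n, K = unname(K), N = N,
            fold = unname(ifelse(k == 0, 0, (k / n) / (K / N))),
            p = p, q = q, significant = q < alpha,
            contributing = IRanges::CharacterList(unname(contrib)))
}

#' Mouse-knockout phenotype enrichment with ortholog and category rules
#'
#' The model-organism engine: test genes are mapped through strictly 1:1
#' orthologs, only annotation terms belonging to the overarching category most
#' relevant to the group's human phenotype are tested, and terms annotating
#' fewer than \code{minFrac} of the genes in that category are excluded before
#' FDR (removing underpowered, uninformative terms). The background is the set
#' of resource genes reachable through the 1:1 ortholog map.
#'
#' @param genes character vector of human gene ids (the group's pooled set).
#' @param annot an [AnnotationCollection-class] carrying \code{orthologs} and
#'   \code{categories}.
#' @param category the overarching category for the group's phenotype (from
#'   [hpoToMpoCategory()]); \code{NA} skips the group with a warning.
#' @param alpha FDR threshold (default 0.05).
#' @param minFrac minimum fraction of the category's gene pool a term must
#'   annotate (default 0.01).
#' @return as [enrichGroup()], with \code{contributing} reported as human gene
#'   ids (mapped back through the ortholog map).
#' @export
enrichGroupMgi <- function(genes, annot, category, alpha = 0.05,
                           minFrac = 0.01) {
  empty <- DataFrame(resource = character(), term = character(),
                     k = integer(), n = integer(), K = integer(),
                     N = integer(), fold = numeric(), p = numeric(),
                     q = numeric(), significant = logical(),
                     contributing = IRanges::CharacterList())
  if (is.na(category)) {
    warning("phenotype has no mapped overarching category; group skipped")
    return(empty)
  }
  if (!length(annot@orthologs)) stop("annotation collection has no ortholog map")
  if (!length(annot@categories)) stop("annotation collection has no categories")
  ## human -> model space through 1:1 orthologs only
  mapped <- annot@orthologs[intersect(genes, names(annot@orthologs))]
  universe <- intersect(unname(annot@orthologs), annot@universe)
  catTerms <- names(annot@categories)[annot@categories == category]
  sets <- lapply(annot@sets[intersect(names(annot@sets), catTerms)],
                 intersect, x = universe)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) return(empty)
  pool <- unique(unlist(sets, use.names = FALSE))
  sets <- sets[lengths(sets) >= minFrac * length(pool)]
  if (!length(sets)) return(empty)
  sub <- annotationCollection(annot@name, sets, universe = universe)
  res <- enrichGroup(unname(mapped), sub, alpha = alpha)
  ## report contributing genes as human ids
  back <- stats::setNames(names(annot@orthologs), unname(annot@orthologs))
  res$contributing <- IRanges::CharacterList(
    lapply(res$contributing, function(g) sort(unname(back[g]))))
  res
}
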
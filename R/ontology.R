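#' Construct an OntologyDAG
#'
#' @param edges two-column character matrix or data.frame of (child, parent)
#'   is_a pairs.
#' @param terms character vector of all term ids (defaults to those appearing
#'   in \code{edges}).
#' @param labels optional named character vector of term names.
#' @param altIds optional named character vector mapping alias ids to
#'   canonical ids.
#' @return An [OntologyDAG-class] object. Construction fails with an error if
#'   the edge relation is cyclic or references unknown terms.
#' @examples
#' dag <- ontologyDAG(data.frame(child = "T2", parent = "T1"))
#' ontologyRoots(dag)
#' @export
ontologyDAG <- function(edges, terms = NULL, labels = NULL, altIds = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) && ncol(edges) != 2L) {
    stop("edges must have two columns (child, parent)")
  }
  mode(edges) <- "character"
  if (is.null(terms)) terms <- unique(as.vector(edges))
  terms <- unique(as.character(terms))
  parents <- rep(list(character()), length(terms))
  names(parents) <- terms
  for (i in seq_len(nrow(edges))) {
    child <- edges[i, 1L]
    parents[[child]] <- union(parents[[child]], edges[i, 2L])
  }
  children <- .invertParents(terms, parents)
  lab <- structure(rep("", length(terms)), names = terms)
  if (!is.null(labels)) lab[names(labels)[names(labels) %in% terms]] <-
      labels[names(labels) %in% terms]
  new("OntologyDAG",
      terms = terms, labels = lab, parents = parents, children = children,
      roots = terms[lengths(parents) == 0L],
      altIds = if (is.null(altIds)) stats::setNames(character(), character())
               else altIds)
}

.invertParents <- function(terms, parents) {
  children <- rep(list(character()), length(terms))
  names(children) <- terms
  for (child in terms) {
    for (p in parents[[child]]) children[[p]] <- c(children[[p]], child)
  }
  children
}

#' @describeIn ontologyDAG All term identifiers of a DAG.
#' @param dag an [OntologyDAG-class].
#' @export
ontologyTerms <- function(dag) dag@terms

#' @describeIn ontologyDAG Root terms (terms with no parent).
#' @export
ontologyRoots <- function(dag) dag@roots

#' @describeIn ontologyDAG Direct is_a parents of a term.
#' @param term a single term id.
#' @export
termParents <- function(dag, term) {
  .checkTerms(dag, term)
  dag@parents[[term]]
}

.checkTerms <- function(dag, terms) {
  bad <- setdiff(terms, dag@terms)
  if (length(bad)) {
    stop("unknown ontology term id(s): ", paste(bad, collapse = ", "))
  }
  invisible(terms)
}

#' Resolve alias term ids to canonical ids
#'
#' @param dag an [OntologyDAG-class].
#' @param terms character vector of term ids, possibly containing alt_id
#'   aliases.
#' @return character vector with aliases replaced by their canonical ids;
#'   unknown ids pass through unchanged (callers validate).
#' @export
resolveAltIds <- function(dag, terms) {
  hit <- terms %in% names(dag@altIds)
  terms[hit] <- dag@altIds[terms[hit]]
  terms
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads the stanza-based OBO flat-file format used to distribute the human
#' and mammalian phenotype ontologies. Only \code{is_a} relationships are
#' honoured; terms flagged obsolete are dropped (together with edges touching
#' them) and \code{alt_id} aliases are recorded so they can be resolved to
#' canonical ids.
#'
#' @param path path to an OBO file.
#' @return An [OntologyDAG-class]. A cyclic is_a relation or an is_a reference
#'   to a missing term id is a hard error.
#' @seealso [writeOBO()]
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  stanzaStarts <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  ends <- c(stanzaStarts[-1L] - 1L, length(lines))
  names(ends) <- stanzaStarts
  ids <- character()
  labels <- character()
  obsolete <- character()
  altIds <- character()
  edges <- list()
  for (s in termStarts) {
    block <- lines[(s + 1L):ends[[as.character(s)]]]
    getVals <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing OBO comments
    }
    id <- getVals("id")
    if (length(id) != 1L) stop("OBO stanza without a single id line")
    if (any(grepl("true", getVals("is_obsolete")))) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    nm <- getVals("name")
    labels[id] <- if (length(nm)) nm[[1L]] else ""
    for (a in getVals("alt_id")) altIds[a] <- id
    isa <- sub("\\s.*$", "", getVals("is_a"))
    if (length(isa)) edges[[id]] <- isa
  }
  edgeChild <- rep(names(edges), lengths(edges))
  edgeParent <- unlist(edges, use.names = FALSE)
  ## edges to obsolete parents are dropped with the obsolete term
  keep <- !(edgeParent %in% obsolete)
  edgeChild <- edgeChild[keep]
  edgeParent <- edgeParent[keep]
  missingParent <- setdiff(edgeParent, ids)
  if (length(missingParent)) {
    stop("is_a references missing term id(s): ",
         paste(utils::head(missingParent, 5L), collapse = ", "))
  }
  ontologyDAG(cbind(edgeChild, edgeParent), terms = ids, labels = labels,
              altIds = altIds)
}

#' Propagate term sets up the ontology
#'
#' Imputes the general terms implied by specific ones: returns the input terms
#' together with all their ancestors, i.e. the closure of \code{direct} under
#' the parent relation. The operation is idempotent and monotone.
#'
#' @param dag an [OntologyDAG-class].
#' @param direct character vector of term ids.
#' @return character vector (sorted) of \code{direct} plus all ancestors.
#'   Unknown term ids are a hard error listing the offenders.
#' @examples
#' dag <- ontologyDAG(data.frame(child = c("B", "C"), parent = c("A", "B")))
#' propagateAncestors(dag, "C")
#' @export
propagateAncestors <- function(dag, direct) {
  direct <- unique(as.character(direct))
  .checkTerms(dag, direct)
  out <- character()
  frontier <- direct
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(unlist(dag@parents[frontier], use.names = FALSE)), out)
  }
  sort(unique(out))
}

#' Proper descendants (subterms) of a term
#'
#' All terms whose ancestor closure contains \code{term}, excluding the term
#' itself. These are the "subterms" used to ask whether phenotypic convergence
#' reflects finer subtypes of a phenotype rather than distinct co-morbidities.
#'
#' @param dag an [OntologyDAG-class].
#' @param term a single term id.
#' @return character vector (sorted), empty for leaves.
#' @export
properDescendants <- function(dag, term) {
  stopifnot(length(term) == 1L)
  .checkTerms(dag, term)
  out <- character()
  frontier <- dag@children[[term]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(unlist(dag@children[frontier], use.names = FALSE)), out)
  }
  sort(unique(out))
}

#' Construct a CategoryMap
#'
#' @param mpoCategory named character vector: model-organism phenotype term ->
#'   overarching category.
#' @param hpoCategory named character vector: human phenotype term -> its most
#'   relevant overarching category (supplied as configuration; there is no
#'   algorithm for "most relevant").
#' @return A [CategoryMap-class].
#' @export
categoryMap <- function(mpoCategory = character(), hpoCategory = character()) {
  new("CategoryMap", mpoCategory = mpoCategory, hpoCategory = hpoCategory)
}

#' Read a CategoryMap from two-column TSV files
#'
#' Each file has two tab-separated columns, term id and category, no header.
#'
#' @param mpoPath path of the MPO term -> category table.
#' @param hpoPath path of the HPO term -> category table.
#' @return A [CategoryMap-class].
#' @export
readCategoryMap <- function(mpoPath, hpoPath) {
  readOne <- function(p) {
    if (is.null(p)) return(stats::setNames(character(), character()))
    d <- utils::read.table(p, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
    stats::setNames(d[[2L]], d[[1L]])
  }
  categoryMap(readOne(mpoPath), readOne(hpoPath))
}

#' Overarching category for a human phenotype term
#'
#' Looks up the configured model-organism category most relevant to a human
#' phenotype term. Absence is a legal outcome (the caller then skips the
#' mouse-knockout engine for that phenotype group).
#'
#' @param term a single human phenotype term id.
#' @param map a [CategoryMap-class].
#' @return the category as a single character, or \code{NA_character_} when
#'   the term is unmapped.
#' @export
hpoToMpoCategory <- function(term, map) {
  stopifnot(length(term) == 1L)
  if (term %in% names(map@hpoCategory)) unname(map@hpoCategory[[term]])
  else NA_character_
}

#' Categories of model-organism annotation terms
#'
#' @param map a [CategoryMap-class].
#' @return named character vector, MPO term -> category.
#' @export
mpoCategories <- function(map) map@mpoCategory

#' Write an OntologyDAG as an OBO 1.2 file
#'
#' Emits a minimal OBO file (format-version header, one [Term] stanza per term
#' with id, name and is_a lines) that [parseOBO()] round-trips exactly.
#'
#' @param dag an [OntologyDAG-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag@terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    if (nzchar(dag@labels[[t]])) writeLines(paste0("name: ", dag@labels[[t]]), con)
    for (p in dag@parents[[t]]) {
      writeLines(paste0("is_a: ", p, " ! ", dag@labels[[p]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
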
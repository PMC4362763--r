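#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Ontology DAG of phenotype terms
#'
#' A directed acyclic graph of ontology terms connected by is_a edges, as used
#' by the Human and Mammalian Phenotype Ontologies: specific child terms sit
#' underneath broader parent terms, and a patient annotated with a specific
#' term implicitly carries every ancestor term. Multi-parent terms are fully
#' supported; only is_a edges are represented.
#'
#' @slot terms character vector of term identifiers.
#' @slot labels named character vector of human-readable term names (may be
#'   empty strings).
#' @slot parents named list; for each term, the character vector of its direct
#'   is_a parents (empty for roots).
#' @slot children named list; inverse of \code{parents}.
#' @slot roots character vector of terms with no parent.
#' @slot altIds named character vector mapping alias identifiers to canonical
#'   term identifiers.
#'
#' @seealso [ontologyDAG()], [parseOBO()], [propagateAncestors()],
#'   [properDescendants()]
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    labels = "character",
    parents = "list",
    children = "list",
    roots = "character",
    altIds = "character"
  )
)

.topoSort <- function(terms, parents) {
  ## Kahn's algorithm over child -> parent edges; returns NULL on success,
  ## otherwise a term participating in a cycle.
  nParents <- lengths(parents)[terms]
  childrenOf <- vector("list", length(terms))
  names(childrenOf) <- terms
  for (child in terms) {
    for (p in parents[[child]]) {
      childrenOf[[p]] <- c(childrenOf[[p]], child)
    }
  }
  queue <- terms[nParents == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in childrenOf[[t]]) {
      nParents[[ch]] <- nParents[[ch]] - 1L
      if (nParents[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    return(names(nParents)[nParents > 0L][1L])
  }
  NULL
}

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  trm <- object@terms
  if (anyDuplicated(trm)) msgs <- c(msgs, "duplicated term identifiers")
  if (!setequal(names(object@parents), trm)) {
    msgs <- c(msgs, "parents list must be named by exactly the term set")
  }
  unknownParents <- setdiff(unlist(object@parents, use.names = FALSE), trm)
  if (length(unknownParents)) {
    msgs <- c(msgs, paste0("unknown parent id(s): ",
                           paste(utils::head(unknownParents, 5L), collapse = ", ")))
  }
  if (!length(msgs)) {
    cyc <- .topoSort(trm, object@parents)
    if (!is.null(cyc)) {
      msgs <- c(msgs, paste0("cycle detected in is_a relation involving term '",
                             cyc, "'"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Map of ontology terms to overarching categories
#'
#' Holds the assignment of model-organism phenotype terms to a fixed set of
#' overarching categories (33 in the mammalian phenotype ontology), together
#' with the configured "most relevant" category for each human phenotype term.
#' The human-term assignment is an input table, not computed.
#'
#' @slot mpoCategory named character; model-organism term -> category.
#' @slot hpoCategory named character; human term -> category.
#'
#' @seealso [categoryMap()], [readCategoryMap()], [hpoToMpoCategory()]
#' @export
setClass("CategoryMap",
  representation(mpoCategory = "character", hpoCategory = "character")
)

setValidity("CategoryMap", function(object) {
  msgs <- character()
  if (length(object@mpoCategory) && anyDuplicated(names(object@mpoCategory))) {
    msgs <- c(msgs, "each MPO term must map to exactly one category")
  }
  if (length(object@hpoCategory) && anyDuplicated(names(object@hpoCategory))) {
    msgs <- c(msgs, "each HPO term must map to exactly one category")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene models with transcripts and exons
#'
#' Gene structures used by the exon-aware CNV overlap rule: each gene spans all
#' of its transcripts, and each transcript is a set of exon intervals.
#' Coordinates are held as GRanges (1-based, closed).
#'
#' @slot genes GRanges named by gene id, one range per gene.
#' @slot exons GRanges of exon intervals with metadata columns
#'   \code{transcript_id} and \code{gene_id}.
#' @slot transcripts data.frame with columns \code{transcript_id} and
#'   \code{gene_id}.
#'
#' @seealso [geneModelSet()], [readGeneModels()], [genesAffected()]
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    exons = "GRanges",
    transcripts = "data.frame"
  )
)

setValidity("GeneModelSet", function(object) {
  msgs <- character()
  if (is.null(names(object@genes)) || anyDuplicated(names(object@genes))) {
    msgs <- c(msgs, "genes must be uniquely named by gene id")
  }
  if (!all(c("transcript_id", "gene_id") %in% colnames(object@transcripts))) {
    msgs <- c(msgs, "transcripts needs transcript_id and gene_id columns")
  } else {
    if (anyDuplicated(object@transcripts$transcript_id)) {
      msgs <- c(msgs, "duplicated transcript ids")
    }
    if (!all(object@transcripts$gene_id %in% names(object@genes))) {
      msgs <- c(msgs, "transcript references unknown gene id")
    }
    if (!all(names(object@genes) %in% object@transcripts$gene_id)) {
      msgs <- c(msgs, "every gene needs at least one transcript")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Cohort of phenotyped patients with CNV calls
#'
#' The central patient container: direct ontology term assignments, their
#' ancestor-propagated closure, and CNV calls as a GRanges with per-call
#' metadata (patient, dosage gain/loss, inheritance, and, once annotated, the
#' affected gene set).
#'
#' @slot patientIds character vector of patient identifiers.
#' @slot directTerms named list (by patient) of directly assigned term ids.
#' @slot propagatedTerms named list (by patient) of ancestor-closed term sets.
#' @slot cnvs GRanges with metadata columns \code{cnv_id}, \code{patient_id},
#'   \code{dosage} ("gain"/"loss") and \code{inheritance}
#'   ("de_novo"/"inherited"/"unknown"); after [annotateCnvGenes()] also a
#'   \code{genes} CharacterList.
#'
#' @seealso [patientCohort()], [filterCohort()], [buildGroups()]
#' @export
setClass("PatientCohort",
  representation(
    patientIds = "character",
    directTerms = "list",
    propagatedTerms = "list",
    cnvs = "GRanges"
  )
)

setValidity("PatientCohort", function(object) {
  msgs <- character()
  ids <- object@patientIds
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated patient ids")
  if (!setequal(names(object@directTerms), ids) ||
      !setequal(names(object@propagatedTerms), ids)) {
    msgs <- c(msgs, "term lists must be named by exactly the patient ids")
  } else {
    notSub <- vapply(ids, function(p) {
      !all(object@directTerms[[p]] %in% object@propagatedTerms[[p]])
    }, logical(1L))
    if (any(notSub)) {
      msgs <- c(msgs, "direct terms must be a subset of propagated terms")
    }
  }
  mc <- S4Vectors::mcols(object@cnvs)
  need <- c("cnv_id", "patient_id", "dosage", "inheritance")
  if (!all(need %in% colnames(mc))) {
    msgs <- c(msgs, paste0("cnvs need metadata columns: ",
                           paste(need, collapse = ", ")))
  } else {
    if (!all(mc$patient_id %in% ids)) {
      msgs <- c(msgs, "CNV call references unknown patient id")
    }
    if (!all(mc$dosage %in% c("gain", "loss"))) {
      msgs <- c(msgs, "dosage must be 'gain' or 'loss'")
    }
    if (!all(mc$inheritance %in% c("de_novo", "inherited", "unknown"))) {
      msgs <- c(msgs, "inheritance must be de_novo/inherited/unknown")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Annotation collection for gene-set enrichment
#'
#' A named resource (GO-, KEGG- or MPO-like) of term -> gene-set annotations
#' over a background gene universe, optionally carrying a term -> overarching
#' category map and a strictly 1:1 ortholog map (human gene <-> model-organism
#' gene) for the mouse-knockout engine.
#'
#' @slot name resource name, e.g. "GO".
#' @slot sets named list of character gene vectors, one per annotation term.
#' @slot universe character vector, the background gene universe.
#' @slot categories named character, annotation term -> category (may be empty).
#' @slot orthologs named character, human gene -> model gene, a bijection on
#'   its domain (may be empty).
#'
#' @seealso [annotationCollection()], [readGmt()], [enrichGroup()],
#'   [enrichGroupMgi()]
#' @export
setClass("AnnotationCollection",
  representation(
    name = "character",
    sets = "list",
    universe = "character",
    categories = "character",
    orthologs = "character"
  )
)

setValidity("AnnotationCollection", function(object) {
  msgs <- character()
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (length(object@sets) && is.null(names(object@sets))) {
    msgs <- c(msgs, "sets must be named by annotation term")
  }
  annotated <- unique(unlist(object@sets, use.names = FALSE))
  if (!all(annotated %in% object@universe)) {
    msgs <- c(msgs, "every annotated gene must belong to the universe")
  }
  if (length(object@orthologs)) {
    if (anyDuplicated(names(object@orthologs)) ||
        anyDuplicated(object@orthologs)) {
      msgs <- c(msgs, "ortholog map must be a bijection on its domain")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Undirected gene network
#'
#' A weighted (co-expression, edge weight = Pearson r) or unit-weight (PPI)
#' undirected simple graph over genes, wrapping an igraph object.
#'
#' @slot graph an igraph undirected simple graph with a \code{weight} edge
#'   attribute.
#' @slot weighted logical; FALSE for unit-weight interaction networks.
#'
#' @seealso [geneNetwork()], [buildCoexpressionNetwork()], [clusterTest()]
#' @export
setClass("GeneNetwork",
  representation(graph = "ANY", weighted = "logical")
)

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) {
    msgs <- c(msgs, "graph must be an igraph object")
  } else {
    if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
    if (igraph::any_loop(g)) msgs <- c(msgs, "self-edges are not allowed")
    if (igraph::any_multiple(g)) msgs <- c(msgs, "multi-edges are not allowed")
    if (is.null(igraph::V(g)$name)) msgs <- c(msgs, "nodes must be named genes")
    if (igraph::gsize(g) > 0L && is.null(igraph::E(g)$weight)) {
      msgs <- c(msgs, "edges must carry a weight attribute")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms,",
      sum(lengths(object@parents)), "is_a edges,",
      length(object@roots), "root(s)\n")
})

setMethod("show", "CategoryMap", function(object) {
  cat("CategoryMap:", length(object@mpoCategory), "MPO terms,",
      length(object@hpoCategory), "HPO terms,",
      length(unique(object@mpoCategory)), "categories\n")
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "genes,",
      nrow(object@transcripts), "transcripts,",
      length(object@exons), "exons on",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      "chromosome(s)\n")
})

setMethod("show", "PatientCohort", function(object) {
  dn <- sum(S4Vectors::mcols(object@cnvs)$inheritance == "de_novo")
  cat("PatientCohort with", length(object@patientIds), "patients,",
      length(object@cnvs), "CNV calls (", dn, "de novo )\n")
})

setMethod("show", "AnnotationCollection", function(object) {
  cat("AnnotationCollection '", object@name, "': ", length(object@sets),
      " terms over ", length(object@universe), " genes",
      if (length(object@orthologs)) " (with 1:1 ortholog map)" else "",
      "\n", sep = "")
})

setMethod("show", "GeneNetwork", function(object) {
  cat(if (object@weighted) "Weighted" else "Unit-weight",
      "GeneNetwork with", igraph::gorder(object@graph), "genes and",
      igraph::gsize(object@graph), "edges\n")
})
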
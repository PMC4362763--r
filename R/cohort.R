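#' @importFrom GenomicRanges GRanges seqnames findOverlaps reduce width start end
#' @importFrom IRanges IRanges CharacterList
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
NULL

#' Construct a GeneModelSet
#'
#' @param genes GRanges named by gene id (1-based, closed coordinates),
#'   spanning all transcripts of each gene.
#' @param exons GRanges of exons with metadata columns \code{transcript_id}
#'   and \code{gene_id}.
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}; derived from \code{exons} when omitted.
#' @return A [GeneModelSet-class].
#' @export
geneModelSet <- function(genes, exons, transcripts = NULL) {
  if (is.null(transcripts)) {
    transcripts <- unique(data.frame(
      transcript_id = mcols(exons)$transcript_id,
      gene_id = mcols(exons)$gene_id, stringsAsFactors = FALSE))
  }
  new("GeneModelSet", genes = genes, exons = exons, transcripts = transcripts)
}

#' @describeIn geneModelSet Gene ranges of a model set.
#' @param models a [GeneModelSet-class].
#' @export
modelGenes <- function(models) models@genes

#' Read gene models from a GTF-like TSV
#'
#' Expects a tab-separated file with header columns \code{type} ("gene" or
#' "exon"), \code{gene_id}, \code{transcript_id} (empty for gene rows),
#' \code{chrom}, \code{start}, \code{end} in the 1-based inclusive GTF dialect.
#'
#' @param path input file path.
#' @return A [GeneModelSet-class].
#' @seealso [writeGeneModels()]
#' @export
readGeneModels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = c(type = "character",
                                        gene_id = "character",
                                        transcript_id = "character",
                                        chrom = "character",
                                        start = "integer", end = "integer"))
  g <- d[d$type == "gene", ]
  e <- d[d$type == "exon", ]
  genes <- GRanges(g$chrom, IRanges(g$start, g$end))
  names(genes) <- g$gene_id
  exons <- GRanges(e$chrom, IRanges(e$start, e$end),
                   transcript_id = e$transcript_id, gene_id = e$gene_id)
  geneModelSet(genes, exons)
}

#' Write gene models as a GTF-like TSV
#'
#' @param models a [GeneModelSet-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGeneModels <- function(models, path) {
  g <- data.frame(type = "gene", gene_id = names(models@genes),
                  transcript_id = "",
                  chrom = as.character(seqnames(models@genes)),
                  start = start(models@genes), end = end(models@genes))
  e <- data.frame(type = "exon", gene_id = mcols(models@exons)$gene_id,
                  transcript_id = mcols(models@exons)$transcript_id,
                  chrom = as.character(seqnames(models@exons)),
                  start = start(models@exons), end = end(models@exons))
  utils::write.table(rbind(g, e), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read CNV calls from a BED-like TSV
#'
#' Expects a tab-separated file with header columns \code{chrom}, \code{start},
#' \code{end} (0-based half-open, BED convention), \code{dosage}
#' ("gain"/"loss"), \code{inheritance} ("de_novo"/"inherited"/"unknown") and
#' \code{patient_id}. Coordinates are converted to the internal 1-based closed
#' convention at this boundary.
#'
#' @param path input file path.
#' @return GRanges with metadata columns \code{cnv_id}, \code{patient_id},
#'   \code{dosage}, \code{inheritance}.
#' @seealso [writeCnvCalls()]
#' @export
readCnvCalls <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = c(chrom = "character",
                                        start = "integer", end = "integer",
                                        dosage = "character",
                                        inheritance = "character",
                                        patient_id = "character"))
  if (any(d$end <= d$start)) stop("CNV with non-positive length")
  GRanges(d$chrom, IRanges(d$start + 1L, d$end),
          cnv_id = sprintf("cnv%05d", seq_len(nrow(d))),
          patient_id = d$patient_id, dosage = d$dosage,
          inheritance = d$inheritance)
}

#' Write CNV calls as a BED-like TSV (0-based half-open)
#'
#' @param cnvs GRanges as produced by [readCnvCalls()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeCnvCalls <- function(cnvs, path) {
  d <- data.frame(chrom = as.character(seqnames(cnvs)),
                  start = start(cnvs) - 1L, end = end(cnvs),
                  dosage = mcols(cnvs)$dosage,
                  inheritance = mcols(cnvs)$inheritance,
                  patient_id = mcols(cnvs)$patient_id)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read direct phenotype assignments
#'
#' Two tab-separated header columns \code{patient_id}, \code{term_id}; one row
#' per direct assignment.
#'
#' @param path input file path.
#' @return named list of character term vectors, one per patient.
#' @export
readPhenotypes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = "character")
  split(d$term_id, d$patient_id)
}

#' Write direct phenotype assignments
#'
#' @param directTerms named list of term vectors per patient.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePhenotypes <- function(directTerms, path) {
  d <- data.frame(patient_id = rep(names(directTerms), lengths(directTerms)),
                  term_id = unlist(directTerms, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PatientCohort
#'
#' Builds the central cohort object from direct phenotype assignments and CNV
#' calls, propagating each patient's terms up the ontology so that every
#' broader term implied by a specific assignment is carried too.
#'
#' @param directTerms named list of direct term id vectors per patient.
#' @param cnvs GRanges of CNV calls (see [readCnvCalls()]); patients without
#'   any CNV call are allowed at this stage.
#' @param dag an [OntologyDAG-class] used for propagation; alias ids are
#'   resolved first.
#' @return A [PatientCohort-class].
#' @export
patientCohort <- function(directTerms, cnvs, dag) {
  ids <- union(names(directTerms), mcols(cnvs)$patient_id)
  direct <- lapply(stats::setNames(ids, ids), function(p) {
    t <- directTerms[[p]]
    if (is.null(t)) character() else sort(unique(resolveAltIds(dag, t)))
  })
  prop <- lapply(direct, function(t) {
    if (length(t)) propagateAncestors(dag, t) else character()
  })
  new("PatientCohort", patientIds = ids, directTerms = direct,
      propagatedTerms = prop, cnvs = cnvs)
}

#' @describeIn patientCohort Patient identifiers.
#' @param cohort a [PatientCohort-class].
#' @export
patientIds <- function(cohort) cohort@patientIds

#' @describeIn patientCohort CNV calls as GRanges.
#' @export
cnvCalls <- function(cohort) cohort@cnvs

#' @describeIn patientCohort Ancestor-propagated term sets per patient.
#' @export
propagatedTerms <- function(cohort) cohort@propagatedTerms

#' @describeIn patientCohort Directly assigned term sets per patient.
#' @export
directTerms <- function(cohort) cohort@directTerms

.subsetCohort <- function(cohort, ids) {
  keep <- mcols(cohort@cnvs)$patient_id %in% ids
  new("PatientCohort", patientIds = ids,
      directTerms = cohort@directTerms[ids],
      propagatedTerms = cohort@propagatedTerms[ids],
      cnvs = cohort@cnvs[keep])
}

#' Apply the de novo CNV cohort filter
#'
#' Splits a cohort into the analysis set (patients possessing at least one de
#' novo CNV, all of whose de novo CNVs are shorter than \code{maxCnvLen}) and
#' the replication pool (patients without any de novo CNV, analysed later via
#' their inherited/unknown-inheritance CNVs). Patients with a de novo CNV at
#' or above the length cap are excluded from both pools, as are patients with
#' no CNV records at all (with a warning).
#'
#' @param cohort a [PatientCohort-class].
#' @param maxCnvLen length cap in base pairs; a CNV is retained iff
#'   \code{end - start < maxCnvLen} (strictly less; default 5 Mb).
#' @return list with elements \code{retained} and \code{replication} (both
#'   [PatientCohort-class]) and \code{excluded} (character ids dropped for an
#'   over-length de novo CNV).
#' @export
filterCohort <- function(cohort, maxCnvLen = 5e6) {
  mc <- mcols(cohort@cnvs)
  noCnv <- setdiff(cohort@patientIds, mc$patient_id)
  if (length(noCnv)) {
    warning(length(noCnv), " patient(s) with zero CNV records excluded")
  }
  dn <- mc$inheritance == "de_novo"
  dnPatients <- unique(mc$patient_id[dn])
  ## width(gr) == end - start under the half-open input convention
  tooLong <- unique(mc$patient_id[dn & width(cohort@cnvs) >= maxCnvLen])
  retainedIds <- setdiff(dnPatients, tooLong)
  replicationIds <- setdiff(unique(mc$patient_id), dnPatients)
  if (length(tooLong)) {
    message(length(tooLong), " patient(s) excluded for a de novo CNV >= ",
            maxCnvLen, " bp")
  }
  list(retained = .subsetCohort(cohort, retainedIds),
       replication = .subsetCohort(cohort, replicationIds),
       excluded = tooLong)
}

#' Genes affected by CNVs under the exon-aware rule
#'
#' A gene is affected by a CNV iff (a) the entire gene lies within the CNV
#' boundaries, or (b) the CNV intersects at least one exon in \emph{every}
#' transcript of the gene, ensuring all coding transcripts are affected rather
#' than a fraction of very long transcripts. Chromosome mismatches simply
#' exclude the gene.
#'
#' @param cnvs GRanges of CNV intervals.
#' @param models a [GeneModelSet-class] sharing the CNVs' coordinate system.
#' @return A [IRanges::CharacterList] of affected gene ids, one element per
#'   CNV.
#' @export
genesAffected <- function(cnvs, models) {
  res <- vector("list", length(cnvs))
  for (i in seq_along(res)) res[[i]] <- character()
  ## rule (a): whole gene within the CNV (disjoint seqlevels are a legal
  ## mismatch, not a warning-worthy condition)
  wv <- suppressWarnings(
    findOverlaps(models@genes, cnvs, type = "within", ignore.strand = TRUE))
  for (j in seq_along(wv)) {
    i <- subjectHits(wv)[j]
    res[[i]] <- c(res[[i]], names(models@genes)[queryHits(wv)[j]])
  }
  ## rule (b): >=1 exon hit in every transcript
  nTx <- table(models@transcripts$gene_id)
  txGene <- stats::setNames(models@transcripts$gene_id,
                            models@transcripts$transcript_id)
  ex <- suppressWarnings(findOverlaps(models@exons, cnvs,
                                      ignore.strand = TRUE))
  if (length(ex)) {
    hitTx <- mcols(models@exons)$transcript_id[queryHits(ex)]
    hitCnv <- subjectHits(ex)
    pair <- !duplicated(paste(hitTx, hitCnv))
    hitTx <- hitTx[pair]
    hitCnv <- hitCnv[pair]
    hitGene <- unname(txGene[hitTx])
    cnt <- rowsum(rep(1L, length(hitTx)), paste(hitGene, hitCnv))
    full <- rownames(cnt)[cnt[, 1L] ==
                            as.integer(nTx[sub(" .*$", "", rownames(cnt))])]
    for (key in full) {
      sp <- strsplit(key, " ", fixed = TRUE)[[1L]]
      i <- as.integer(sp[[2L]])
      res[[i]] <- c(res[[i]], sp[[1L]])
    }
  }
  CharacterList(lapply(res, function(g) sort(unique(g))))
}

#' Remove control-cohort genes in a dosage-aware manner
#'
#' Genes observed copy-number changed in the same direction in an unaffected
#' control cohort are removed from each CNV's gene set: control gains only
#' strip genes from gain CNVs, control losses only from loss CNVs.
#'
#' @param genesByCnv [IRanges::CharacterList] of gene ids per CNV.
#' @param dosage character vector ("gain"/"loss") parallel to
#'   \code{genesByCnv}.
#' @param controlGains,controlLosses character vectors of control genes
#'   (possibly empty).
#' @return filtered [IRanges::CharacterList].
#' @export
filterControlGenes <- function(genesByCnv, dosage,
                               controlGains = character(),
                               controlLosses = character()) {
  stopifnot(length(genesByCnv) == length(dosage))
  out <- as.list(genesByCnv)
  for (i in seq_along(out)) {
    ctrl <- if (dosage[[i]] == "gain") controlGains else controlLosses
    out[[i]] <- setdiff(out[[i]], ctrl)
  }
  CharacterList(out)
}

#' Annotate a cohort's CNVs with their affected gene sets
#'
#' Runs [genesAffected()] on every CNV call and applies the direction-aware
#' control-gene filter, storing the result as a \code{genes} metadata column.
#' Control filtering is applied before any enrichment.
#'
#' @param cohort a [PatientCohort-class].
#' @param models a [GeneModelSet-class].
#' @param controlGains,controlLosses control gene sets (see
#'   [filterControlGenes()]).
#' @return the cohort with \code{mcols(cnvCalls(cohort))$genes} filled in.
#' @export
annotateCnvGenes <- function(cohort, models, controlGains = character(),
                             controlLosses = character()) {
  g <- genesAffected(cohort@cnvs, models)
  g <- filterControlGenes(g, mcols(cohort@cnvs)$dosage,
                          controlGains, controlLosses)
  mcols(cohort@cnvs)$genes <- g
  cohort
}

#' Per-patient pooled de novo CNV gene sets
#'
#' @param cohort an annotated [PatientCohort-class] (see
#'   [annotateCnvGenes()]).
#' @param inheritance which calls to pool (default de novo only).
#' @return named list of gene id vectors per patient; a patient's genes across
#'   multiple CNVs are pooled as a union.
#' @export
patientGeneSets <- function(cohort, inheritance = "de_novo") {
  mc <- mcols(cohort@cnvs)
  if (is.null(mc$genes)) stop("cohort CNVs are not gene-annotated")
  keep <- mc$inheritance %in% inheritance
  out <- lapply(stats::setNames(cohort@patientIds, cohort@patientIds),
                function(p) character())
  gl <- as.list(mc$genes[keep])
  pid <- mc$patient_id[keep]
  for (i in seq_along(gl)) {
    out[[pid[[i]]]] <- union(out[[pid[[i]]]], gl[[i]])
  }
  lapply(out, sort)
}

#' Merge CNVs into CNV regions (CNVRs)
#'
#' Merges CNVs that overlap by at least 1 bp or are bookended (directly
#' adjacent), gains and losses combined; regions are the connected components
#' of that relation and span the union of their members.
#'
#' @param cnvs GRanges of CNV calls with \code{cnv_id} and \code{patient_id}
#'   metadata columns.
#' @return GRanges of regions with CharacterList metadata columns
#'   \code{cnv_ids} and \code{patient_ids}.
#' @export
mergeCnvrs <- function(cnvs) {
  ## adjacent 1-based closed ranges (gap 0) are exactly the bookended pairs
  ## under the half-open input convention; reduce() merges gap < min.gapwidth
  red <- reduce(cnvs, min.gapwidth = 1L, with.revmap = TRUE,
                ignore.strand = TRUE)
  revmap <- mcols(red)$revmap
  mcols(red) <- NULL
  mcols(red)$cnv_ids <- CharacterList(lapply(revmap, function(i)
    sort(unique(mcols(cnvs)$cnv_id[i]))))
  mcols(red)$patient_ids <- CharacterList(lapply(revmap, function(i)
    sort(unique(mcols(cnvs)$patient_id[i]))))
  red
}

#' Build patient-phenotype groups
#'
#' One non-exclusive group per ontology term carried (after propagation) by at
#' least \code{minSize} retained patients; each group pools the union of its
#' members' filtered de novo CNV genes.
#'
#' @param cohort an annotated, filtered [PatientCohort-class].
#' @param minSize minimum number of member patients (default 3).
#' @return [S4Vectors::DataFrame] with columns \code{term},
#'   \code{n_patients}, \code{members} (CharacterList) and \code{genes}
#'   (CharacterList), sorted by term.
#' @export
buildGroups <- function(cohort, minSize = 3L) {
  geneSets <- patientGeneSets(cohort)
  termList <- cohort@propagatedTerms
  allTerms <- sort(unique(unlist(termList, use.names = FALSE)))
  carriers <- lapply(stats::setNames(allTerms, allTerms), function(t) {
    names(termList)[vapply(termList, function(x) t %in% x, logical(1L))]
  })
  keep <- lengths(carriers) >= minSize
  terms <- allTerms[keep]
  members <- carriers[keep]
  genes <- lapply(members, function(m)
    sort(unique(unlist(geneSets[m], use.names = FALSE))))
  DataFrame(term = terms,
            n_patients = lengths(members),
            members = CharacterList(members),
            genes = CharacterList(genes))
}
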
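.joinSet <- function(x) vapply(x, paste, character(1L), collapse = ";")

#' Pipeline configuration
#'
#' Collects the input file paths and every analysis threshold of the
#' end-to-end pipeline. Defaults follow the analysis constants: de novo CNVs
#' under 5 Mb, phenotype groups of 3 or more patients, FDR below 5\%,
#' co-expression edges at r >= 0.7, candidate genes recurrent across >= 2
#' engines, convergence tests at >= 10 patients per side, and 500 randomised
#' CNVR sets for the bait-extension test.
#'
#' @param inputs named list/vector of input paths, with the names used by
#'   [simulateStudy()]: ontology, genes, cnvs, phenotypes, go, kegg, mpo,
#'   orthologs, mpoCategories, hpoCategories, expression, ppi, controlGains,
#'   controlLosses (the last four annotation/control entries optional).
#' @param outdir output directory.
#' @param seed RNG seed for all resampling.
#' @param maxCnvLen,minGroupSize,alpha,rMin,rpkmMin,lowFracMax,minMethods,minEach,nSamples,nRand
#'   analysis thresholds (see description; \code{nSamples} is the
#'   degree-matched null size per clustering test, capped in the underlying
#'   analysis at 10,000).
#' @param runReplication run the inherited-CNV replication analysis.
#' @param baitGenes optional character vector; when given, the bait-extension
#'   test runs against CNVRs merged from the replication pool's CNVs.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(inputs, outdir, seed = 1L,
                           maxCnvLen = 5e6, minGroupSize = 3L, alpha = 0.05,
                           rMin = 0.7, rpkmMin = 1, lowFracMax = 0.95,
                           minMethods = 2L, minEach = 10L,
                           nSamples = 1000L, nRand = 500L,
                           runReplication = TRUE, baitGenes = NULL) {
  cfg <- as.list(environment())
  stopifnot(maxCnvLen > 0, minGroupSize > 0, alpha > 0, rMin > 0,
            minMethods > 0, minEach > 0, nSamples > 0, nRand > 0)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file carries an \code{inputs} mapping plus any of the
#' [pipelineConfig()] threshold fields.
#'
#' @param path YAML file path.
#' @param outdir output directory (overrides any value in the file when
#'   given).
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outdir = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(pipelineConfig, y)
}

.readInputs <- function(cfg) {
  paths <- cfg$inputs
  need <- c("ontology", "genes", "cnvs", "phenotypes", "go", "kegg",
            "expression", "ppi")
  missing <- setdiff(need, names(paths))
  if (length(missing)) stop("missing input path(s): ",
                            paste(missing, collapse = ", "))
  for (p in unlist(paths)) if (!file.exists(p)) stop("input not found: ", p)
  dag <- parseOBO(paths[["ontology"]])
  models <- readGeneModels(paths[["genes"]])
  cnvs <- readCnvCalls(paths[["cnvs"]])
  phen <- readPhenotypes(paths[["phenotypes"]])
  go <- readGmt(paths[["go"]], name = "GO")
  kegg <- readGmt(paths[["kegg"]], name = "KEGG")
  mgi <- NULL
  categories <- NULL
  if (!is.null(paths[["mpo"]]) && !is.null(paths[["orthologs"]])) {
    orth <- readOrthologMap(paths[["orthologs"]])
    categories <- readCategoryMap(paths[["mpoCategories"]],
                                  paths[["hpoCategories"]])
    sets <- annotationSets(readGmt(paths[["mpo"]]))
    mgi <- annotationCollection("MGI", sets, categories =
                                  mpoCategories(categories),
                                orthologs = orth)
  }
  expr <- as.matrix(utils::read.table(paths[["expression"]], sep = "\t",
                                      header = TRUE, row.names = 1L,
                                      check.names = FALSE))
  ppi <- readEdgeList(paths[["ppi"]], weighted = FALSE)
  ctrlG <- if (!is.null(paths[["controlGains"]]))
    readLines(paths[["controlGains"]]) else character()
  ctrlL <- if (!is.null(paths[["controlLosses"]]))
    readLines(paths[["controlLosses"]]) else character()
  list(dag = dag, models = models, cnvs = cnvs, phen = phen, go = go,
       kegg = kegg, mgi = mgi, categories = categories, expr = expr,
       ppi = ppi, controlGains = ctrlG, controlLosses = ctrlL)
}

.convRow <- function(groupTerm, engine, term, res) {
  data.frame(group_term = groupTerm, engine = engine, term = term,
             testable = res$testable,
             n_contributing = res$nContributing,
             n_noncontributing = res$nNonContributing,
             direction = res$direction, p = res$p,
             median_intra = res$medianIntra, median_inter = res$medianInter)
}

#' Run the full CNV-to-pathway convergence pipeline
#'
#' Executes every stage in order on one set of inputs: cohort filter (de novo
#' CNVs under the length cap), exon-aware gene annotation with control-gene
#' removal, patient-phenotype grouping, the four enrichment engines (GO,
#' KEGG, mouse-knockout MGI, co-expression clustering), multi-method candidate
#' intersection with PPI validation, the Goodall3 convergence suite (per
#' enrichment, subterm-restricted for nominally convergent enrichments,
#' binomial excess meta-test, combined-annotation pooling), the optional
#' inherited-CNV replication analysis, and the optional bait-extension test.
#' All stage outputs are written as TSV under the configured output directory
#' together with a JSON summary; a re-run with identical inputs and seed is
#' byte-identical.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results
#'   (\code{cohort}, \code{groups}, \code{enrichments}, \code{clusterTests},
#'   \code{candidates}, \code{ppiValidation}, \code{convergence},
#'   \code{subterm}, \code{excess}, \code{combined}, \code{replication},
#'   \code{bait}, \code{summary}, \code{outdir}).
#' @export
runPipeline <- function(cfg) {
  set.seed(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  inp <- .readInputs(cfg)
  ## analysis parameters only: paths do not affect results
  jsonlite::write_json(
    cfg[setdiff(names(cfg), c("inputs", "outdir"))],
    file.path(cfg$outdir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)
  cfgHash <- unname(tools::md5sum(file.path(cfg$outdir, "run_config.json")))

  ## stage 1: cohort filter + gene annotation + groups
  cohort <- patientCohort(inp$phen, inp$cnvs, inp$dag)
  filt <- filterCohort(cohort, maxCnvLen = cfg$maxCnvLen)
  retained <- annotateCnvGenes(filt$retained, inp$models,
                               inp$controlGains, inp$controlLosses)
  groups <- buildGroups(retained, minSize = cfg$minGroupSize)
  message("pipeline: ", length(patientIds(retained)), " patients retained, ",
          nrow(groups), " patient-phenotype groups")
  geneSets <- patientGeneSets(retained)

  ## stage 2: networks
  coex <- buildCoexpressionNetwork(inp$expr, rpkmMin = cfg$rpkmMin,
                                   lowFracMax = cfg$lowFracMax,
                                   rMin = cfg$rMin)
  ppi <- inp$ppi

  ## stage 3: four enrichment engines per group
  enrichRows <- list()
  clusterTests <- list()
  for (gi in seq_len(nrow(groups))) {
    term <- groups$term[gi]
    genes <- groups$genes[[gi]]
    for (engine in c("GO", "KEGG")) {
      annot <- if (engine == "GO") inp$go else inp$kegg
      res <- suppressWarnings(enrichGroup(genes, annot, alpha = cfg$alpha))
      if (nrow(res)) {
        res$group_term <- term
        enrichRows[[length(enrichRows) + 1L]] <- res
      }
    }
    if (!is.null(inp$mgi)) {
      cat33 <- hpoToMpoCategory(term, inp$categories)
      res <- suppressWarnings(enrichGroupMgi(genes, inp$mgi, cat33,
                                             alpha = cfg$alpha))
      if (nrow(res)) {
        res$group_term <- term
        enrichRows[[length(enrichRows) + 1L]] <- res
      }
    }
    clusterTests[[term]] <- clusterTest(coex, genes,
                                        statistic = "weight-sum",
                                        nSamples = cfg$nSamples)
  }
  enrichments <- if (length(enrichRows)) do.call(rbind, enrichRows) else
    DataFrame(resource = character(), term = character(), k = integer(),
              n = integer(), K = integer(), N = integer(), fold = numeric(),
              p = numeric(), q = numeric(), significant = logical(),
              contributing = IRanges::CharacterList(),
              group_term = character())

  ## stage 4: multi-method candidates + PPI validation
  candRows <- list()
  ppiRows <- list()
  candSets <- list()
  for (gi in seq_len(nrow(groups))) {
    term <- groups$term[gi]
    sub <- enrichments[enrichments$group_term == term, , drop = FALSE]
    byEngine <- lapply(c(GO = "GO", KEGG = "KEGG", MGI = "MGI"),
                       function(e) sub[sub$resource == e, , drop = FALSE])
    cand <- multiMethodCandidates(byEngine, clusterTests[term],
                                  minMethods = cfg$minMethods,
                                  alpha = cfg$alpha)
    candSets[[term]] <- cand
    if (length(cand$genes)) {
      candRows[[term]] <- data.frame(
        group_term = term, gene = cand$genes,
        methods = .joinSet(cand$methods))
      val <- validateCandidatesPpi(cand, ppi, nSamples = cfg$nSamples,
                                   alpha = cfg$alpha)
      ppiRows[[term]] <- data.frame(
        group_term = term, n_candidates = length(cand$genes),
        n_in_ppi = length(val$genes), observed = val$observed,
        p = val$p, significant = val$significant,
        contributing = paste(val$contributing, collapse = ";"))
      candSets[[term]]$ppi <- val
    }
  }

  ## stage 5: convergence suite
  termsList <- propagatedTerms(retained)
  freqs <- phenotypeFrequencies(termsList)
  sim <- goodall3Matrix(termsList, freqs)
  memberOf <- stats::setNames(as.list(groups$members), groups$term)
  convRows <- list()
  subtermRows <- list()
  convResults <- list()
  addConv <- function(groupTerm, engine, annotTerm, contributingGenes) {
    sp <- contributingSplit(memberOf[[groupTerm]], geneSets,
                            contributingGenes)
    res <- convergenceTest(sp$contributing, sp$nonContributing,
                           sim = sim, minEach = cfg$minEach)
    convRows[[length(convRows) + 1L]] <<-
      .convRow(groupTerm, engine, annotTerm, res)
    convResults[[length(convResults) + 1L]] <<- res
    if (isTRUE(res$testable) && !is.na(res$p) && res$p < 0.05) {
      st <- subtermConvergence(groupTerm, sp$contributing,
                               sp$nonContributing, termsList, inp$dag,
                               minEach = cfg$minEach)
      subtermRows[[length(subtermRows) + 1L]] <<-
        cbind(.convRow(groupTerm, engine, annotTerm, st),
              n_subterms = st$nUniverseTerms)
    }
    invisible(res)
  }
  sigEnrich <- enrichments[enrichments$significant, , drop = FALSE]
  for (i in seq_len(nrow(sigEnrich))) {
    addConv(sigEnrich$group_term[i], sigEnrich$resource[i],
            sigEnrich$term[i], sigEnrich$contributing[[i]])
  }
  for (term in names(clusterTests)) {
    ct <- clusterTests[[term]]
    if (isTRUE(ct$testable) && !is.na(ct$p) && ct$p < cfg$alpha) {
      addConv(term, "coexpression", "coexpression-cluster", ct$contributing)
    }
  }
  for (term in names(candSets)) {
    val <- candSets[[term]]$ppi
    if (!is.null(val) && isTRUE(val$significant)) {
      addConv(term, "PPI", "ppi-cluster", val$contributing)
    }
  }
  excess <- excessBinomial(convResults)
  combined <- combineByAnnotation(enrichments, groups, geneSets, termsList,
                                  freqs, minEach = cfg$minEach)

  ## stage 6: replication on the no-de-novo pool
  replicationRows <- list()
  if (isTRUE(cfg$runReplication) &&
      length(patientIds(filt$replication)) > 0L && nrow(sigEnrich)) {
    repCohort <- annotateCnvGenes(filt$replication, inp$models,
                                  inp$controlGains, inp$controlLosses)
    for (i in seq_len(nrow(sigEnrich))) {
      candidates <- sigEnrich$contributing[[i]]
      annotGenes <- {
        annot <- switch(sigEnrich$resource[i], GO = inp$go,
                        KEGG = inp$kegg, NULL)
        if (!is.null(annot)) annotationSets(annot)[[sigEnrich$term[i]]]
        else character()
      }
      ext <- extendedGeneSet(candidates, annotGenes,
                             networks = list(coex, ppi))
      rg <- replicationGrouping(repCohort, candidates, ext,
                                minEach = cfg$minEach)
      replicationRows[[length(replicationRows) + 1L]] <- data.frame(
        group_term = sigEnrich$group_term[i],
        engine = sigEnrich$resource[i], term = sigEnrich$term[i],
        n_candidate = sum(rg$assignment == "candidate"),
        n_extended = sum(rg$assignment == "extended"),
        n_none = sum(rg$assignment == "none"),
        candidate_p = rg$candidateTest$p,
        candidate_direction = rg$candidateTest$direction,
        extended_p = rg$extendedTest$p,
        extended_direction = rg$extendedTest$direction)
    }
  }

  ## stage 7: optional bait-extension test
  bait <- NULL
  if (!is.null(cfg$baitGenes) && length(patientIds(filt$replication))) {
    cnvrs <- mergeCnvrs(cnvCalls(filt$replication))
    bait <- baitExtensionTest(cfg$baitGenes, cnvrs, ppi, inp$models,
                              nRand = cfg$nRand)
  }

  ## write stage outputs
  out <- function(f) file.path(cfg$outdir, f)
  utils::write.table(
    data.frame(term = groups$term, n_patients = groups$n_patients,
               members = .joinSet(groups$members),
               genes = .joinSet(groups$genes)),
    out("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- as.data.frame(enrichments[, setdiff(colnames(enrichments),
                                            "contributing")])
  ed$contributing <- .joinSet(enrichments$contributing)
  utils::write.table(ed, out("enrichments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    do.call(rbind, lapply(names(clusterTests), function(t) {
      ct <- clusterTests[[t]]
      data.frame(group_term = t, testable = ct$testable,
                 statistic = ct$statistic, observed = ct$observed,
                 p = ct$p, n_samples = ct$nSamples,
                 n_genes = length(ct$genes),
                 contributing = paste(ct$contributing, collapse = ";"))
    })),
    out("cluster_tests.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    if (length(candRows)) do.call(rbind, candRows) else
      data.frame(group_term = character(), gene = character(),
                 methods = character()),
    out("candidates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    if (length(ppiRows)) do.call(rbind, ppiRows) else
      data.frame(group_term = character(), n_candidates = integer(),
                 n_in_ppi = integer(), observed = numeric(), p = numeric(),
                 significant = logical(), contributing = character()),
    out("ppi_validation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    if (length(convRows)) do.call(rbind, convRows) else
      .convRow(character(), character(), character(),
               convergenceTest(character(), character()))[0L, ],
    out("convergence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    if (length(subtermRows)) do.call(rbind, subtermRows) else
      cbind(.convRow(character(), character(), character(),
                     convergenceTest(character(), character())),
            n_subterms = integer())[0L, ],
    out("subterm_convergence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    if (length(combined)) do.call(rbind, lapply(combined, function(r)
      data.frame(resource = r$resource, term = r$term, n_groups = r$nGroups,
                 testable = r$testable, direction = r$direction, p = r$p,
                 n_contributing = r$nContributing,
                 n_noncontributing = r$nNonContributing))) else
      data.frame(resource = character(), term = character(),
                 n_groups = integer(), testable = logical(),
                 direction = numeric(), p = numeric(),
                 n_contributing = integer(), n_noncontributing = integer()),
    out("combined_annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    if (length(replicationRows)) do.call(rbind, replicationRows) else
      data.frame(group_term = character(), engine = character(),
                 term = character(), n_candidate = integer(),
                 n_extended = integer(), n_none = integer(),
                 candidate_p = numeric(), candidate_direction = numeric(),
                 extended_p = numeric(), extended_direction = numeric()),
    out("replication.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bait)) {
    jsonlite::write_json(bait[c("testable", "observed", "p", "nRand",
                                "extension", "nBaitCnvrsDropped",
                                "nNoPpiCnvrsDropped", "nCnvrsUsed")],
                         out("bait_extension.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  summary <- summarizePipeline(cfg$outdir)
  summary$seed <- cfg$seed
  summary$config_hash <- cfgHash
  summary$n_patients_retained <- length(patientIds(retained))
  summary$n_patients_replication <- length(patientIds(filt$replication))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(cohort = retained, replication = filt$replication,
                 groups = groups, enrichments = enrichments,
                 clusterTests = clusterTests, candidates = candSets,
                 convergence = if (length(convRows)) do.call(rbind, convRows)
                               else NULL,
                 subterm = if (length(subtermRows))
                   do.call(rbind, subtermRows) else NULL,
                 excess = excess, combined = combined,
                 replicationTable = if (length(replicationRows))
                   do.call(rbind, replicationRows) else NULL,
                 bait = bait, coexpression = coex, ppi = ppi,
                 geneSets = geneSets, freqs = freqs, sim = sim,
                 summary = summary, outdir = cfg$outdir))
}

#' Summarise a pipeline output directory
#'
#' Recounts the stage output tables of a completed run: groups formed, groups
#' with significant associations from 1/2/3/4 engines, candidate and
#' PPI-validated sets, testable and significant convergence results, and the
#' binomial excess test over convergence directions. A missing stage file is
#' a hard error.
#'
#' @param outdir the pipeline output directory.
#' @return named list of counts (the content of the run's summary JSON,
#'   except the seed/hash fields added by [runPipeline()]).
#' @export
summarizePipeline <- function(outdir) {
  readTsv <- function(f) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) stop("missing stage output: ", f)
    utils::read.table(p, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE,
                      colClasses = NA, comment.char = "")
  }
  groups <- readTsv("groups.tsv")
  enrich <- readTsv("enrichments.tsv")
  clust <- readTsv("cluster_tests.tsv")
  cands <- readTsv("candidates.tsv")
  ppiVal <- readTsv("ppi_validation.tsv")
  conv <- readTsv("convergence.tsv")
  engineCount <- vapply(groups$term, function(t) {
    sub <- enrich[enrich$group_term == t & enrich$significant, , drop = FALSE]
    n <- length(unique(sub$resource))
    cl <- clust[clust$group_term == t, , drop = FALSE]
    if (nrow(cl) && any(cl$testable & !is.na(cl$p) & cl$p < 0.05)) n <- n + 1L
    n
  }, integer(1L))
  testable <- conv[conv$testable & !is.na(conv$p), , drop = FALSE]
  excess <- excessBinomial(testable$direction)
  list(n_groups = nrow(groups),
       n_groups_assoc1 = sum(engineCount >= 1L),
       n_groups_assoc2 = sum(engineCount >= 2L),
       n_groups_assoc3 = sum(engineCount >= 3L),
       n_groups_assoc4 = sum(engineCount >= 4L),
       n_enrichments_significant = sum(enrich$significant),
       n_cluster_significant = sum(clust$testable & !is.na(clust$p) &
                                     clust$p < 0.05),
       n_candidate_groups = length(unique(cands$group_term)),
       n_candidate_genes = length(unique(cands$gene)),
       n_ppi_validated = sum(ppiVal$significant),
       n_convergence_testable = nrow(testable),
       n_convergence_significant = sum(testable$p < 0.05),
       excess_binomial = excess[c("p", "nGreater", "nLess", "nTies")])
}
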
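#' Simulation configuration for synthetic study data
#'
#' Bundles every tunable of the synthetic-data generator: an HPO-like DAG, a
#' multi-chromosome genome with transcript/exon structure, a phenotyped cohort
#' carrying de novo and inherited CNVs, GO/KEGG/MPO-like annotation resources
#' with a 1:1 ortholog map and overarching categories, a block-structured
#' co-expression matrix and a degree-heterogeneous PPI network — together with
#' planted pathway -> phenotype causal structure (penetrant target phenotype
#' plus pleiotropic co-morbid terms in pathway carriers).
#'
#' @param nTerms,dagDepth,multiParentFrac ontology shape: number of terms,
#'   maximum depth, fraction of terms given a second parent.
#' @param nGenes,nChromosomes,geneLenRange,geneGapRange,maxTranscripts,maxExons
#'   genome shape (lengths in bp; genes are laid non-overlapping).
#' @param nPatients patients receiving de novo CNVs.
#' @param nReplicationPatients patients receiving only inherited/unknown CNVs.
#' @param secondCnvProb probability a de novo patient carries a second CNV.
#' @param inheritedCnvProb probability a de novo patient also carries an
#'   inherited CNV.
#' @param gainFrac fraction of CNVs that are gains (the cohort emulated is
#'   loss-dominated).
#' @param cnvLenRange CNV lengths are drawn log-uniform on this interval; the
#'   default upper end of 5 Mb respects the cohort filter by construction.
#' @param backgroundTermRate per-term probability of a direct background
#'   phenotype assignment.
#' @param targetBackgroundFreq frequency of each planted target phenotype
#'   among non-carriers (so that phenotype groups contain non-contributing
#'   patients).
#' @param comorbidBackgroundFreq background frequency of the pleiotropy terms
#'   in non-carriers.
#' @param plantedPathways list of planted pathways; each a list with
#'   \code{nGenes}, \code{nCarriers}, \code{penetrance},
#'   \code{nPleiotropyTerms}, \code{comorbidFreq} and \code{mode}
#'   ("comorbid": distinct-branch co-morbid terms are elevated in carriers,
#'   the pleiotropy signature; "subtype": child terms of the target phenotype
#'   are elevated instead, a finer-subtype signature). An empty list gives a
#'   null cohort used for calibration.
#' @param nReplicationCarriers replication-pool patients given inherited CNVs
#'   over planted genes with the same phenotype signature.
#' @param orthologFrac fraction of genes with a 1:1 model-organism ortholog.
#' @param nCategories number of overarching model-phenotype categories.
#' @param nGoTerms,nKeggTerms,nMpoTerms,annotSizeRange decoy annotation
#'   resource sizes.
#' @param controlFrac fraction of (non-planted) genes placed on each control
#'   CNV gene list.
#' @param nExprSamples,exprBlockSize,backgroundR,moduleR,nLowExprGenes
#'   expression model: samples, size of background co-expression blocks
#'   (block membership is assigned by random permutation, deliberately
#'   independent of genomic position), target within-block and within-module
#'   correlations, and number of below-floor genes exercising the expression
#'   filter.
#' @param ppiFrac,ppiM fraction of genes present in the PPI network and
#'   edges-per-step of its preferential-attachment backbone.
#' @param plantPpiClique whether planted pathway genes are fully
#'   interconnected in the PPI network.
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nTerms = 300L, dagDepth = 6L,
                             multiParentFrac = 0.1,
                             nGenes = 1500L, nChromosomes = 10L,
                             geneLenRange = c(5e3, 1.5e5),
                             geneGapRange = c(2e4, 8e4),
                             maxTranscripts = 3L, maxExons = 6L,
                             nPatients = 120L, nReplicationPatients = 80L,
                             secondCnvProb = 0.3, inheritedCnvProb = 0.3,
                             gainFrac = 0.4, cnvLenRange = c(5e4, 5e6),
                             backgroundTermRate = 0.015,
                             targetBackgroundFreq = 0.2,
                             comorbidBackgroundFreq = 0.1,
                             plantedPathways = list(
                               list(nGenes = 12L, nCarriers = 20L,
                                    penetrance = 1.0, nPleiotropyTerms = 5L,
                                    comorbidFreq = 0.8, mode = "comorbid")),
                             nReplicationCarriers = 15L,
                             orthologFrac = 0.7, nCategories = 33L,
                             nGoTerms = 60L, nKeggTerms = 30L,
                             nMpoTerms = 40L, annotSizeRange = c(10L, 80L),
                             controlFrac = 0.05,
                             nExprSamples = 50L, exprBlockSize = 20L,
                             backgroundR = 0.75, moduleR = 0.88,
                             nLowExprGenes = 5L,
                             ppiFrac = 0.6, ppiM = 2L,
                             plantPpiClique = TRUE) {
  cfg <- as.list(environment())
  probs <- c(cfg$multiParentFrac, cfg$secondCnvProb, cfg$inheritedCnvProb,
             cfg$gainFrac, cfg$backgroundTermRate, cfg$targetBackgroundFreq,
             cfg$comorbidBackgroundFreq, cfg$orthologFrac, cfg$controlFrac,
             cfg$ppiFrac,
             unlist(lapply(cfg$plantedPathways, function(p)
               c(p$penetrance, p$comorbidFreq))))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$nTerms < cfg$dagDepth) stop("nTerms must be at least dagDepth")
  if (cfg$backgroundR < 0 || cfg$backgroundR >= 1 ||
      cfg$moduleR < 0 || cfg$moduleR >= 1) stop("correlations must be in [0, 1)")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate a synthetic rooted ontology DAG
#'
#' Builds a single-rooted DAG of the configured depth: every term at level
#' \eqn{l} has one parent at level \eqn{l - 1}, and a configured fraction of
#' terms gain a second parent from a strictly shallower level (so the result
#' is a true multi-parent DAG, never cyclic). With depth 1 the DAG is a star
#' of leaves under the root. Draws from the current RNG stream.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{dag} (an [OntologyDAG-class]) and \code{levels}
#'   (named integer, term depth with the root at 0).
#' @export
generateOntology <- function(config) {
  n <- config$nTerms
  depth <- config$dagDepth
  ids <- sprintf("T%04d", seq_len(n))
  levels <- integer(n)
  names(levels) <- ids
  levels[1L] <- 0L
  ## seed each level with one term, then place the rest at random depths
  if (n > 1L) {
    spine <- seq_len(min(depth, n - 1L)) + 1L
    levels[spine] <- seq_along(spine)
    rest <- setdiff(seq_len(n), c(1L, spine))
    if (length(rest)) {
      levels[rest] <- sample(seq_len(depth), length(rest), replace = TRUE,
                             prob = 2^seq_len(depth))
    }
  }
  edges <- NULL
  for (i in seq_len(n)[-1L]) {
    l <- levels[i]
    cand <- ids[levels == l - 1L]  # parents strictly shallower: acyclic
    p1 <- cand[[sample.int(length(cand), 1L)]]
    edges <- rbind(edges, c(ids[i], p1))
    if (stats::runif(1L) < config$multiParentFrac && l > 1L) {
      shallower <- ids[levels[ids] < l & ids != p1]
      p2 <- shallower[[sample.int(length(shallower), 1L)]]
      if (p2 != p1) edges <- rbind(edges, c(ids[i], p2))
    }
  }
  labels <- stats::setNames(paste("Synthetic phenotype", seq_len(n)), ids)
  dag <- ontologyDAG(edges, terms = ids, labels = labels)
  list(dag = dag, levels = levels)
}

#' Generate a synthetic genome of gene models
#'
#' Lays non-overlapping genes with random lengths and spacing across the
#' configured chromosomes; each gene receives 1 or more transcripts whose
#' exons are alternating sub-intervals of the gene span, so that partial CNV
#' overlaps can hit exons of some transcripts but not others.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{models} (a [GeneModelSet-class]) and
#'   \code{chromEnds} (named numeric, usable length per chromosome).
#' @export
generateGenome <- function(config) {
  n <- config$nGenes
  chroms <- sprintf("chr%d", seq_len(config$nChromosomes))
  perChrom <- diff(round(seq(0, n, length.out = config$nChromosomes + 1L)))
  geneRows <- list()
  exonRows <- list()
  chromEnds <- stats::setNames(numeric(length(chroms)), chroms)
  gi <- 0L
  for (ci in seq_along(chroms)) {
    pos <- 1
    for (k in seq_len(perChrom[ci])) {
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      len <- round(stats::runif(1L, config$geneLenRange[1L],
                                config$geneLenRange[2L]))
      gap <- round(stats::runif(1L, config$geneGapRange[1L],
                                config$geneGapRange[2L]))
      gStart <- pos + gap
      gEnd <- gStart + len - 1
      pos <- gEnd
      geneRows[[gi]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                   start = gStart, end = gEnd)
      nTx <- sample.int(config$maxTranscripts, 1L)
      for (t in seq_len(nTx)) {
        tid <- sprintf("%s.t%d", gid, t)
        nEx <- sample.int(config$maxExons, 1L)
        ## alternating exon/gap partition of the gene span
        cuts <- sort(sample.int(len - 1L, min(2L * nEx - 1L, len - 2L)))
        bounds <- c(0L, cuts, len)
        starts <- gStart + bounds[seq(1L, length(bounds) - 1L, by = 2L)]
        ends <- gStart + bounds[seq(2L, length(bounds), by = 2L)] - 1L
        ends[length(ends)] <- min(ends[length(ends)], gEnd)
        keep <- ends >= starts
        exonRows[[length(exonRows) + 1L]] <-
          data.frame(transcript_id = tid, gene_id = gid, chrom = chroms[ci],
                     start = starts[keep], end = ends[keep])
      }
    }
    chromEnds[ci] <- pos + 1e6
  }
  g <- do.call(rbind, geneRows)
  e <- do.call(rbind, exonRows)
  genes <- GRanges(g$chrom, IRanges(g$start, g$end))
  names(genes) <- g$gene_id
  exons <- GRanges(e$chrom, IRanges(e$start, e$end),
                   transcript_id = e$transcript_id, gene_id = e$gene_id)
  list(models = geneModelSet(genes, exons), chromEnds = chromEnds)
}

## pick pathway genes spread across chromosomes so one CNV hits one of them
.choosePlantedGenes <- function(models, nGenes, exclude = character()) {
  genes <- models@genes
  pool <- setdiff(names(genes), exclude)
  chromOf <- stats::setNames(as.character(seqnames(genes)), names(genes))
  picked <- character()
  chromCycle <- rep_len(unique(chromOf), nGenes * 4L)
  ci <- 1L
  while (length(picked) < nGenes && ci <= length(chromCycle)) {
    onChrom <- pool[chromOf[pool] == chromCycle[ci]]
    ci <- ci + 1L
    if (!length(onChrom)) next
    g <- onChrom[[sample.int(length(onChrom), 1L)]]
    ## keep picks >5 Mb apart on the same chromosome
    same <- picked[chromOf[picked] == chromOf[g]]
    if (length(same) &&
        any(abs(start(genes[same]) - start(genes[g])) < 5e6)) next
    picked <- c(picked, g)
    pool <- setdiff(pool, g)
  }
  if (length(picked) < nGenes) stop("could not place planted genes far enough apart")
  sort(picked)
}

#' Generate annotation resources with planted terms
#'
#' Builds GO-, KEGG- and MPO-like collections: one planted term per planted
#' pathway whose gene set exactly covers the pathway genes (the MPO version
#' through the 1:1 ortholog map), plus decoy terms drawn as random gene sets.
#' Planted MPO terms are assigned to one overarching category and each
#' planted target phenotype is mapped to that category; remaining terms and
#' phenotypes receive random categories.
#'
#' @param config a [simulationConfig()].
#' @param models a [GeneModelSet-class].
#' @param plantedSets list of planted pathway gene vectors (possibly empty).
#' @param dag the ontology (its terms receive category mappings).
#' @param targetTerms character vector of planted target phenotype term ids,
#'   parallel to \code{plantedSets}.
#' @return list with [AnnotationCollection-class] elements \code{go},
#'   \code{kegg}, \code{mgi}, plus \code{orthologs} (named character) and
#'   \code{categories} (a [CategoryMap-class]).
#' @export
generateAnnotations <- function(config, models, plantedSets, dag,
                                targetTerms = character()) {
  geneIds <- names(models@genes)
  randomSet <- function() {
    sz <- sample(seq(config$annotSizeRange[1L], config$annotSizeRange[2L]), 1L)
    sort(sample(geneIds, min(sz, length(geneIds))))
  }
  mkSets <- function(prefix, nDecoy, planted) {
    sets <- list()
    for (i in seq_along(planted)) {
      sets[[sprintf("%s:P%03d", prefix, i)]] <- planted[[i]]
    }
    for (i in seq_len(nDecoy)) {
      sets[[sprintf("%s:%04d", prefix, i)]] <- randomSet()
    }
    sets
  }
  go <- annotationCollection("GO",
    mkSets("GO", config$nGoTerms, plantedSets), universe = geneIds)
  kegg <- annotationCollection("KEGG",
    mkSets("KEGG", config$nKeggTerms, plantedSets), universe = geneIds)
  ## 1:1 ortholog map over a fraction of the genome
  orthoHuman <- sort(sample(geneIds, round(config$orthologFrac *
                                             length(geneIds))))
  orthologs <- stats::setNames(paste0("M", orthoHuman), orthoHuman)
  toMouse <- function(g) unname(orthologs[intersect(g, names(orthologs))])
  mouseIds <- unname(orthologs)
  randomMouseSet <- function() {
    sz <- sample(seq(config$annotSizeRange[1L], config$annotSizeRange[2L]), 1L)
    sort(sample(mouseIds, min(sz, length(mouseIds))))
  }
  mpoSets <- list()
  for (i in seq_along(plantedSets)) {
    mpoSets[[sprintf("MP:P%03d", i)]] <- sort(toMouse(plantedSets[[i]]))
  }
  for (i in seq_len(config$nMpoTerms)) {
    mpoSets[[sprintf("MP:%04d", i)]] <- randomMouseSet()
  }
  mpoSets <- mpoSets[lengths(mpoSets) > 0L]
  cats <- sprintf("CAT%02d", seq_len(config$nCategories))
  mpoCat <- stats::setNames(sample(cats, length(mpoSets), replace = TRUE),
                            names(mpoSets))
  ## planted MPO terms all live in the first category
  mpoCat[grepl(":P", names(mpoCat))] <- cats[1L]
  hpoCat <- stats::setNames(sample(cats, length(ontologyTerms(dag)),
                                   replace = TRUE), ontologyTerms(dag))
  hpoCat[intersect(targetTerms, names(hpoCat))] <- cats[1L]
  mgi <- annotationCollection("MGI", mpoSets, universe = mouseIds,
                              categories = mpoCat, orthologs = orthologs)
  list(go = go, kegg = kegg, mgi = mgi, orthologs = orthologs,
       categories = categoryMap(mpoCat, hpoCat))
}

## one CNV interval covering gene `gid`, shorter than the configured cap
.cnvCovering <- function(models, chromEnds, gid, lenRange, maxTries = 50L) {
  g <- models@genes[gid]
  chrom <- as.character(seqnames(g))
  gLen <- width(g)
  for (try in seq_len(maxTries)) {
    len <- round(exp(stats::runif(1L, log(max(lenRange[1L], gLen + 2)),
                                  log(lenRange[2L]))))
    pad <- len - gLen
    if (pad < 1) next
    s <- start(g) - round(stats::runif(1L, 0, pad))
    e <- s + len - 1
    if (s < 1) { s <- 1; e <- s + len - 1 }
    if (e > chromEnds[[chrom]]) { e <- chromEnds[[chrom]]; s <- e - len + 1 }
    if (s >= 1 && s <= start(g) && e >= end(g) && (e - s + 1) < lenRange[2L]) {
      return(GRanges(chrom, IRanges(s, e)))
    }
  }
  stop("CNV placement infeasible around gene ", gid)
}

## a random background CNV avoiding all planted genes
.randomCnv <- function(models, chromEnds, avoid, lenRange, maxTries = 100L) {
  for (try in seq_len(maxTries)) {
    chrom <- sample(names(chromEnds), 1L)
    len <- round(exp(stats::runif(1L, log(lenRange[1L]), log(lenRange[2L]))))
    len <- min(len, chromEnds[[chrom]] - 1)
    s <- round(stats::runif(1L, 1, chromEnds[[chrom]] - len))
    cnv <- GRanges(chrom, IRanges(s, s + len - 1))
    if (!length(avoid) ||
        !length(findOverlaps(models@genes[avoid], cnv))) return(cnv)
  }
  stop("could not place a background CNV avoiding planted genes")
}

#' Generate a synthetic phenotyped cohort with planted causal structure
#'
#' Every de novo patient draws background phenotypes; pathway carriers
#' additionally receive a de novo CNV covering one planted pathway gene, the
#' target phenotype with the configured penetrance, and (mode "comorbid") each
#' pleiotropy phenotype with the co-morbidity frequency or (mode "subtype")
#' elevated child terms of the target phenotype. Non-carriers receive
#' background CNVs that avoid planted genes, and express the target and
#' co-morbid phenotypes at their background frequencies. Replication-pool
#' patients carry only inherited/unknown CNVs; a configured number of them are
#' replication carriers with inherited CNVs over planted genes and the same
#' phenotype signature.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [generateGenome()].
#' @param dagInfo output of [generateOntology()].
#' @param plantedSets list of planted pathway gene vectors.
#' @return list with \code{cohort} (a [PatientCohort-class], not yet gene
#'   annotated) and \code{truth} (planted pathway memberships, per-patient
#'   carrier labels, target and pleiotropy terms, replication carriers).
#' @export
generateCohort <- function(config, genome, dagInfo, plantedSets) {
  dag <- dagInfo$dag
  levels <- dagInfo$levels
  models <- genome$models
  terms <- ontologyTerms(dag)
  nP <- config$nPatients
  pids <- sprintf("P%04d", seq_len(nP))
  rids <- sprintf("R%04d", seq_len(config$nReplicationPatients))
  ## choose target + pleiotropy terms per pathway
  pathTruth <- list()
  usedTerms <- character()
  for (i in seq_along(plantedSets)) {
    pw <- config$plantedPathways[[i]]
    ## a target needs subterms (for the subtype mode and subterm analyses)
    ## but not so many that background propagation floods its patient group
    need <- max(2L, pw$nPleiotropyTerms)
    cap <- need + max(6L, round(0.05 * length(terms)))
    cand <- setdiff(terms[levels[terms] %in% c(2L, 3L)], usedTerms)
    nd <- vapply(cand, function(t)
      length(properDescendants(dag, t)), integer(1L))
    ok <- cand[nd >= need & nd <= cap]
    if (!length(ok)) ok <- cand[nd >= need]   # relax the cap if needed
    cand <- ok
    if (!length(cand)) stop("no eligible target term for pathway ", i)
    target <- cand[[sample.int(length(cand), 1L)]]
    related <- c(target, properDescendants(dag, target),
                 propagateAncestors(dag, target))
    usedTerms <- c(usedTerms, related)
    if (identical(pw$mode, "subtype")) {
      kids <- properDescendants(dag, target)
      pleio <- kids[sample.int(length(kids),
                               min(pw$nPleiotropyTerms, length(kids)))]
    } else {
      distinct <- setdiff(terms, c(related, usedTerms))
      pleio <- distinct[sample.int(length(distinct), pw$nPleiotropyTerms)]
    }
    usedTerms <- c(usedTerms, pleio)
    pathTruth[[i]] <- list(genes = plantedSets[[i]], targetTerm = target,
                           pleiotropyTerms = sort(pleio), mode = pw$mode)
  }
  ## carrier assignment (disjoint across pathways)
  carrierOf <- stats::setNames(rep(NA_integer_, nP), pids)
  free <- pids
  for (i in seq_along(plantedSets)) {
    nC <- min(config$plantedPathways[[i]]$nCarriers, length(free))
    chosen <- free[sample.int(length(free), nC)]
    carrierOf[chosen] <- i
    free <- setdiff(free, chosen)
    pathTruth[[i]]$carriers <- sort(chosen)
  }
  plantedAll <- unique(unlist(plantedSets, use.names = FALSE))
  drawDosage <- function() if (stats::runif(1L) < config$gainFrac) "gain" else "loss"
  cnvRows <- list()
  addCnv <- function(gr, pid, inh) {
    cnvRows[[length(cnvRows) + 1L]] <<- data.frame(
      chrom = as.character(seqnames(gr)), start = start(gr), end = end(gr),
      patient_id = pid, dosage = drawDosage(), inheritance = inh)
  }
  directTerms <- list()
  drawPhenotypes <- function(pathwayIdx) {
    mine <- terms[stats::runif(length(terms)) < config$backgroundTermRate]
    for (i in seq_along(pathTruth)) {
      pt <- pathTruth[[i]]
      pw <- config$plantedPathways[[i]]
      if (!is.na(pathwayIdx) && pathwayIdx == i) {
        if (stats::runif(1L) < pw$penetrance) mine <- c(mine, pt$targetTerm)
        keep <- stats::runif(length(pt$pleiotropyTerms)) < pw$comorbidFreq
        mine <- c(mine, pt$pleiotropyTerms[keep])
      } else {
        if (stats::runif(1L) < config$targetBackgroundFreq) {
          mine <- c(mine, pt$targetTerm)
        }
        keep <- stats::runif(length(pt$pleiotropyTerms)) <
          config$comorbidBackgroundFreq
        mine <- c(mine, pt$pleiotropyTerms[keep])
      }
    }
    sort(unique(mine))
  }
  geneCycle <- function(i) {
    g <- pathTruth[[i]]$genes
    g[[sample.int(length(g), 1L)]]
  }
  for (p in pids) {
    ci <- carrierOf[[p]]
    if (!is.na(ci)) {
      addCnv(.cnvCovering(models, genome$chromEnds, geneCycle(ci),
                          config$cnvLenRange), p, "de_novo")
      if (stats::runif(1L) < config$secondCnvProb) {
        addCnv(.randomCnv(models, genome$chromEnds, plantedAll,
                          config$cnvLenRange), p, "de_novo")
      }
    } else {
      addCnv(.randomCnv(models, genome$chromEnds, plantedAll,
                        config$cnvLenRange), p, "de_novo")
      if (stats::runif(1L) < config$secondCnvProb) {
        addCnv(.randomCnv(models, genome$chromEnds, plantedAll,
                          config$cnvLenRange), p, "de_novo")
      }
    }
    if (stats::runif(1L) < config$inheritedCnvProb) {
      addCnv(.randomCnv(models, genome$chromEnds, plantedAll,
                        config$cnvLenRange), p, "inherited")
    }
    directTerms[[p]] <- drawPhenotypes(ci)
  }
  ## replication pool: inherited/unknown CNVs only
  repCarriers <- character()
  if (length(plantedSets) && config$nReplicationCarriers > 0L) {
    repCarriers <- rids[sample.int(length(rids),
                                   min(config$nReplicationCarriers,
                                       length(rids)))]
  }
  for (p in rids) {
    inh <- sample(c("inherited", "unknown"), 1L, prob = c(0.8, 0.2))
    if (p %in% repCarriers) {
      i <- sample.int(length(plantedSets), 1L)
      addCnv(.cnvCovering(models, genome$chromEnds, geneCycle(i),
                          config$cnvLenRange), p, inh)
      directTerms[[p]] <- drawPhenotypes(i)
    } else {
      addCnv(.randomCnv(models, genome$chromEnds, plantedAll,
                        config$cnvLenRange), p, inh)
      directTerms[[p]] <- drawPhenotypes(NA_integer_)
    }
  }
  cd <- do.call(rbind, cnvRows)
  cnvs <- GRanges(cd$chrom, IRanges(cd$start, cd$end),
                  cnv_id = sprintf("cnv%05d", seq_len(nrow(cd))),
                  patient_id = cd$patient_id, dosage = cd$dosage,
                  inheritance = cd$inheritance)
  cohort <- patientCohort(directTerms, cnvs, dag)
  truth <- list(pathways = pathTruth,
                carrierOf = carrierOf,
                replicationCarriers = sort(repCarriers))
  list(cohort = cohort, truth = truth)
}

#' Generate expression and PPI networks with planted modules
#'
#' Expression follows a latent one-factor-per-block model: each gene loads on
#' its block factor with weight \eqn{\sqrt{\rho}} so within-block pairs
#' correlate near \eqn{\rho}; background block membership is a random
#' permutation of the genome (independent of genomic position), while each
#' planted module forms its own block at the higher module correlation. A few
#' genes are generated below the expression floor to exercise the filter. The
#' PPI network is a preferential-attachment (degree-heterogeneous) random
#' graph over a random subset of genes, with planted modules fully
#' interconnected and optional extra planted edges.
#'
#' @param config a [simulationConfig()].
#' @param models a [GeneModelSet-class].
#' @param plantedSets list of planted module gene vectors.
#' @param extraPpiEdges optional data.frame (gene_a, gene_b) of planted edges,
#'   e.g. bait-to-CNVR-gene links.
#' @return list with \code{expr} (genes x samples matrix) and \code{ppi}
#'   (a unit-weight [GeneNetwork-class]).
#' @export
generateNetworks <- function(config, models, plantedSets,
                             extraPpiEdges = NULL) {
  geneIds <- names(models@genes)
  nS <- config$nExprSamples
  plantedAll <- unique(unlist(plantedSets, use.names = FALSE))
  lowGenes <- utils::head(setdiff(geneIds, plantedAll), config$nLowExprGenes)
  bg <- setdiff(geneIds, c(plantedAll, lowGenes))
  ## random-permutation block assignment
  blockOf <- stats::setNames(
    sample(rep(seq_len(ceiling(length(bg) / config$exprBlockSize)),
               length.out = length(bg))), bg)
  for (i in seq_along(plantedSets)) {
    blockOf[plantedSets[[i]]] <- max(blockOf, 0L) + i
  }
  rhoOf <- ifelse(names(blockOf) %in% plantedAll,
                  config$moduleR, config$backgroundR)
  names(rhoOf) <- names(blockOf)
  nBlocks <- max(blockOf)
  factors <- matrix(stats::rnorm(nBlocks * nS), nBlocks, nS)
  expr <- matrix(0, length(geneIds), nS,
                 dimnames = list(geneIds,
                                 sprintf("S%03d", seq_len(nS))))
  for (g in names(blockOf)) {
    rho <- rhoOf[[g]]
    expr[g, ] <- 5 + sqrt(rho) * factors[blockOf[[g]], ] +
      sqrt(1 - rho) * stats::rnorm(nS)
  }
  for (g in lowGenes) {
    expr[g, ] <- abs(stats::rnorm(nS, mean = 0.3, sd = 0.1))
  }
  ## PPI backbone: preferential attachment over a random gene subset
  ppiGenes <- sort(unique(c(sample(geneIds, round(config$ppiFrac *
                                                    length(geneIds))),
                            plantedAll)))
  g <- igraph::sample_pa(length(ppiGenes), m = config$ppiM, directed = FALSE)
  igraph::V(g)$name <- sample(ppiGenes)
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges) <- c("gene_a", "gene_b")
  if (config$plantPpiClique) {
    for (set in plantedSets) {
      pairs <- utils::combn(sort(set), 2L)
      edges <- rbind(edges, data.frame(gene_a = pairs[1L, ],
                                       gene_b = pairs[2L, ]))
    }
  }
  if (!is.null(extraPpiEdges)) {
    edges <- rbind(edges, extraPpiEdges[, c("gene_a", "gene_b")])
  }
  edges$weight <- 1
  ppi <- geneNetwork(edges, weighted = FALSE,
                     nodes = ppiGenes)
  list(expr = expr, ppi = ppi)
}

#' Simulate a complete synthetic study and write its files
#'
#' Runs the full generator under one seed — ontology, genome, annotations,
#' cohort, networks — checks the truth record against the emitted objects, and
#' writes every format the pipeline reads (OBO ontology, gene-model TSV, CNV
#' TSV, phenotype TSV, GMT annotation files, ortholog and category TSVs,
#' expression TSV, PPI edge list, control gene lists) plus the truth record as
#' JSON. Identical config and seed give byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @return invisibly, a list with the in-memory objects (\code{dag},
#'   \code{models}, \code{cohort}, \code{annotations}, \code{expr},
#'   \code{ppi}, \code{controlGains}, \code{controlLosses}, \code{truth}) and
#'   \code{paths} (named character of written files).
#' @export
simulateStudy <- function(config, dir, seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onto <- generateOntology(config)
  genome <- generateGenome(config)
  plantedSets <- lapply(config$plantedPathways, function(pw)
    .choosePlantedGenes(genome$models, pw$nGenes))
  ## keep pathways gene-disjoint
  if (length(plantedSets) > 1L) {
    for (i in seq_along(plantedSets)[-1L]) {
      plantedSets[[i]] <- .choosePlantedGenes(
        genome$models, config$plantedPathways[[i]]$nGenes,
        exclude = unlist(plantedSets[seq_len(i - 1L)]))
    }
  }
  coh <- generateCohort(config, genome, onto, plantedSets)
  annots <- generateAnnotations(
    config, genome$models, plantedSets, onto$dag,
    targetTerms = vapply(coh$truth$pathways, `[[`, character(1L),
                         "targetTerm"))
  nets <- generateNetworks(config, genome$models, plantedSets)
  plantedAll <- unique(unlist(plantedSets, use.names = FALSE))
  ctrlPool <- setdiff(names(genome$models@genes), plantedAll)
  nCtrl <- round(config$controlFrac * length(ctrlPool))
  controlGains <- sort(sample(ctrlPool, nCtrl))
  controlLosses <- sort(sample(ctrlPool, nCtrl))
  truth <- coh$truth
  truth$plantedModules <- plantedSets
  truth$seed <- seed
  ## truth consistency: every carrier's de novo CNVs hit >=1 planted gene
  gsets <- genesAffected(cnvCalls(coh$cohort), genome$models)
  mc <- mcols(cnvCalls(coh$cohort))
  for (i in seq_along(truth$pathways)) {
    pg <- truth$pathways[[i]]$genes
    for (p in truth$pathways[[i]]$carriers) {
      rows <- which(mc$patient_id == p & mc$inheritance == "de_novo")
      if (!any(vapply(rows, function(r)
        any(pg %in% gsets[[r]]), logical(1L)))) {
        stop("truth record inconsistent: carrier ", p,
             " has no de novo CNV over pathway ", i)
      }
    }
  }
  paths <- c(
    ontology = file.path(dir, "ontology.obo"),
    genes = file.path(dir, "gene_models.tsv"),
    cnvs = file.path(dir, "cnv_calls.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    go = file.path(dir, "go.gmt"),
    kegg = file.path(dir, "kegg.gmt"),
    mpo = file.path(dir, "mpo.gmt"),
    orthologs = file.path(dir, "orthologs.tsv"),
    mpoCategories = file.path(dir, "mpo_categories.tsv"),
    hpoCategories = file.path(dir, "hpo_categories.tsv"),
    expression = file.path(dir, "expression.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    controlGains = file.path(dir, "control_gains.txt"),
    controlLosses = file.path(dir, "control_losses.txt"),
    truth = file.path(dir, "truth.json"))
  writeOBO(onto$dag, paths[["ontology"]])
  writeGeneModels(genome$models, paths[["genes"]])
  writeCnvCalls(cnvCalls(coh$cohort), paths[["cnvs"]])
  writePhenotypes(directTerms(coh$cohort), paths[["phenotypes"]])
  writeGmt(annotationSets(annots$go), paths[["go"]])
  writeGmt(annotationSets(annots$kegg), paths[["kegg"]])
  writeGmt(annotationSets(annots$mgi), paths[["mpo"]])
  utils::write.table(
    data.frame(human = names(annots$orthologs),
               mouse = unname(annots$orthologs)),
    paths[["orthologs"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(term = names(mpoCategories(annots$categories)),
               category = unname(mpoCategories(annots$categories))),
    paths[["mpoCategories"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(term = names(annots$categories@hpoCategory),
               category = unname(annots$categories@hpoCategory)),
    paths[["hpoCategories"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(round(nets$expr, 6L), paths[["expression"]],
                     sep = "\t", quote = FALSE, col.names = NA)
  writeEdgeList(nets$ppi, paths[["ppi"]])
  writeLines(controlGains, paths[["controlGains"]])
  writeLines(controlLosses, paths[["controlLosses"]])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(dag = onto$dag, levels = onto$levels,
                 models = genome$models, chromEnds = genome$chromEnds,
                 cohort = coh$cohort, annotations = annots,
                 expr = nets$expr, ppi = nets$ppi,
                 controlGains = controlGains, controlLosses = controlLosses,
                 truth = truth, paths = paths))
}
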
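simpleDag <- ontologyDAG(data.frame(child = c("B", "C"), parent = c("A", "B")))

mkCnvs <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         cnv_id = sprintf("c%02d", seq_len(nrow(df))),
                         patient_id = df$patient, dosage = df$dosage,
                         inheritance = df$inh)
}

test_that("cohort filter keeps short de novo carriers and pools the rest", {
  cnvs <- mkCnvs(data.frame(
    chrom = "chr1",
    start = c(1, 1, 1, 1, 1),
    end = c(6e6, 1e6, 2e6, 1e6, 4e6),
    patient = c("pLong", "pKeep", "pKeep", "pInh", "pBoth"),
    dosage = "loss",
    inh = c("de_novo", "de_novo", "inherited", "inherited", "de_novo")))
  coh <- patientCohort(list(pLong = "A", pKeep = "A", pInh = "A",
                            pBoth = "A", pNone = "A"), cnvs, simpleDag)
  expect_warning(f <- filterCohort(coh), "zero CNV")
  expect_setequal(patientIds(f$retained), c("pKeep", "pBoth"))
  expect_setequal(patientIds(f$replication), "pInh")
  expect_identical(f$excluded, "pLong")
})

test_that("a de novo CNV of exactly the cap length excludes its patient", {
  cnvs <- mkCnvs(data.frame(chrom = "chr1", start = c(1, 1),
                            end = c(5e6, 4999999),
                            patient = c("pAt", "pUnder"), dosage = "loss",
                            inh = "de_novo"))
  ## widths are exactly 5e6 and 5e6 - 1
  coh <- patientCohort(list(pAt = "A", pUnder = "A"), cnvs, simpleDag)
  f <- filterCohort(coh, maxCnvLen = 5e6)
  expect_setequal(patientIds(f$retained), "pUnder")
  expect_identical(f$excluded, "pAt")
})

test_that("only de novo CNV genes enter a retained patient's pooled set", {
  models <- tinyModels()
  cnvs <- mkCnvs(data.frame(chrom = "chr1", start = c(900, 4000),
                            end = c(2100, 9500), patient = "p1",
                            dosage = "loss",
                            inh = c("de_novo", "inherited")))
  coh <- patientCohort(list(p1 = "A"), cnvs, simpleDag)
  coh <- annotateCnvGenes(coh, models)
  gs <- patientGeneSets(coh)
  expect_identical(gs$p1, "gA")  # gB is hit only by the inherited call
  gsAll <- patientGeneSets(coh, inheritance = c("de_novo", "inherited"))
  expect_identical(gsAll$p1, c("gA", "gB"))
})

test_that("exon-aware overlap needs every transcript hit", {
  models <- tinyModels()
  hit <- function(s, e, chrom = "chr1") {
    genesAffected(GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e)),
                  models)[[1L]]
  }
  expect_identical(hit(500, 2500), "gA")         # whole gene inside
  ## gB: left exon block only belongs to transcript 1 -> excluded
  expect_length(hit(5000, 5300), 0L)
  ## a window hitting exons of both transcripts -> included
  expect_identical(hit(8100, 8600), "gB")
  ## chromosome mismatch is a silent skip
  expect_length(hit(2000, 2999, chrom = "chr9"), 0L)
})

test_that("overlap rule agrees with the interval oracle and is monotone", {
  set.seed(42)
  gt <- randomGenomeTables(nGenes = 120L)
  for (i in 1:300) {
    chrom <- sample(unique(gt$geneTab$chrom), 1L)
    s <- sample.int(3e5, 1L)
    e <- s + sample.int(3e4, 1L)
    got <- genesAffected(GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e)),
                         gt$models)[[1L]]
    gene <- gt$geneTab[sample.int(nrow(gt$geneTab), 1L), ]
    expect_identical(gene$gene_id %in% got,
                     oracleGeneHit(chrom, s, e, gene, gt$exonTab))
    ## enlarging the CNV never removes genes
    wider <- genesAffected(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(max(1L, s - 5000L), e + 5000L)), gt$models)[[1L]]
    expect_true(all(got %in% wider))
  }
})

test_that("control-gene removal is direction aware", {
  g <- IRanges::CharacterList(list(c("g1", "g2"), c("g1", "g3")))
  out <- filterControlGenes(g, dosage = c("gain", "loss"),
                            controlGains = "g1", controlLosses = "g3")
  expect_identical(as.list(out), list("g2", "g1"))
  idt <- filterControlGenes(g, dosage = c("gain", "loss"))
  expect_identical(as.list(idt), as.list(g))
})

test_that("CNVR merging joins overlapping or bookended calls only", {
  ## half-open [1000,2000) and [2000,3000) are bookended -> one region
  cnvs <- mkCnvs(data.frame(chrom = "chr1", start = c(1001, 2001),
                            end = c(2000, 3000), patient = c("p1", "p2"),
                            dosage = "loss", inh = "de_novo"))
  r <- mergeCnvrs(cnvs)
  expect_length(r, 1L)
  expect_identical(c(GenomicRanges::start(r), GenomicRanges::end(r)),
                   c(1001L, 3000L))
  expect_identical(as.list(r$patient_ids)[[1L]], c("p1", "p2"))
  ## a 1 bp gap keeps two regions
  cnvs2 <- mkCnvs(data.frame(chrom = "chr1", start = c(1001, 2002),
                             end = c(2000, 3000), patient = c("p1", "p2"),
                             dosage = "loss", inh = "de_novo"))
  expect_length(mergeCnvrs(cnvs2), 2L)
})

test_that("CNVR components match an independent union-find oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 60L
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = sample.int(5e4, n), patient = "p", dosage = "loss",
                     inh = "de_novo")
    df$end <- df$start + sample.int(3e3, n)
    cnvs <- mkCnvs(df)
    r <- mergeCnvrs(cnvs)
    ## oracle: connected components of the overlap-or-bookend graph
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      df$chrom[i] == df$chrom[j] &&
        max(df$start[i], df$start[j]) <= min(df$end[i], df$end[j]) + 1L
    }))
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$no
    expect_identical(length(r), as.integer(comp))
    ## regions are pairwise non-overlapping and non-bookended
    if (length(r) > 1L) {
      byChrom <- split(r, as.character(GenomicRanges::seqnames(r)))
      for (rr in byChrom) {
        if (length(rr) < 2L) next
        ss <- sort(GenomicRanges::start(rr))
        ee <- sort(GenomicRanges::end(rr))
        expect_true(all(ss[-1L] > ee[-length(ee)] + 1L))
      }
    }
    expect_identical(sum(GenomicRanges::width(GenomicRanges::reduce(cnvs))),
                     sum(GenomicRanges::width(r)))
  }
})

test_that("phenotype groups respect the minimum size and pool gene unions", {
  models <- tinyModels()
  cnvs <- mkCnvs(data.frame(chrom = c("chr1", "chr1", "chr2"),
                            start = c(900, 4500, 1900),
                            end = c(2100, 9200, 3100),
                            patient = c("p1", "p2", "p3"), dosage = "loss",
                            inh = "de_novo"))
  coh <- patientCohort(list(p1 = "C", p2 = "C", p3 = "B"), cnvs, simpleDag)
  coh <- annotateCnvGenes(coh, models)
  g2 <- buildGroups(coh, minSize = 3L)
  ## A is shared by all three after propagation; B by all; C only by two
  expect_setequal(g2$term, c("A", "B"))
  expect_identical(as.list(g2[g2$term == "A", "genes"])[[1L]],
                   c("gA", "gB", "gC"))
  g3 <- buildGroups(coh, minSize = 2L)
  expect_setequal(g3$term, c("A", "B", "C"))
  ## parent groups are at least as large as any child's group
  nOf <- setNames(g3$n_patients, g3$term)
  expect_gte(nOf[["A"]], nOf[["B"]])
  expect_gte(nOf[["B"]], nOf[["C"]])
  ## counting identity: sum of member counts = patient-term incidences
  termsList <- propagatedTerms(coh)
  inc <- sum(vapply(g3$term, function(t)
    sum(vapply(termsList, function(x) t %in% x, logical(1L))), numeric(1L)))
  expect_identical(sum(g3$n_patients), as.integer(inc))
})
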
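test_that("phenotype frequencies satisfy the counting identity", {
  tl <- list(p1 = c("A", "B"), p2 = "A", p3 = c("A", "C"), p4 = "A")
  f <- phenotypeFrequencies(tl)
  expect_equal(unname(f["A"]), 1)
  expect_equal(unname(f["B"]), 0.25)
  expect_equal(sum(lengths(tl)), sum(f) * length(tl))
  expect_error(phenotypeFrequencies(list()), "empty")
})

test_that("Goodall3 follows the piecewise formula and its invariants", {
  ## ubiquitous phenotype carries no information
  expect_equal(goodall3("A", "A", c(A = 1)), 0)
  ## worked example: shared A, discordant B, shared-absent C
  f <- c(A = 0.5, B = 0.25, C = 0.75)
  expect_equal(goodall3(c("A", "B"), "A", f), 1.6875)
  expect_equal(goodall3("A", c("A", "B"), f), 1.6875)  # symmetry
  ## self-similarity dominates, scores within analytic bounds
  set.seed(1)
  u <- sprintf("T%02d", 1:30)
  fr <- setNames(runif(30, 0.05, 0.95), u)
  for (i in 1:50) {
    a <- u[runif(30) < 0.4]
    b <- u[runif(30) < 0.4]
    s <- goodall3(a, b, fr)
    expect_identical(s, goodall3(b, a, fr))
    expect_gte(goodall3(a, a, fr), s)
    expect_gte(s, 0)
    expect_lte(s, sum(pmax(1 - fr^2, 1 - (1 - fr)^2)))
  }
  ## shared presence of a non-ubiquitous term strictly increases the score;
  ## a discordant term never increases it
  a <- u[1:5]; b <- u[3:8]
  base <- goodall3(a, b, fr)
  shared <- u[10]
  expect_gt(goodall3(c(a, shared), c(b, shared), fr), base)
  expect_lte(goodall3(c(a, u[11]), b, fr), base)
})

test_that("matrix similarity equals the scalar formula", {
  set.seed(2)
  u <- sprintf("T%02d", 1:25)
  fr <- setNames(runif(25, 0.05, 0.95), u)
  tl <- lapply(setNames(sprintf("p%02d", 1:12), sprintf("p%02d", 1:12)),
               function(p) u[runif(25) < 0.3])
  S <- goodall3Matrix(tl, fr)
  for (i in 1:12) for (j in 1:12) {
    expect_equal(S[i, j], goodall3(tl[[i]], tl[[j]], fr))
  }
})

test_that("contributing split partitions members by gene overlap", {
  gs <- list(p1 = c("g1", "g2"), p2 = "g3", p3 = character())
  sp <- contributingSplit(c("p1", "p2", "p3"), gs, "g1")
  expect_identical(sp$contributing, "p1")
  expect_setequal(sp$nonContributing, c("p2", "p3"))
  spAll <- contributingSplit(c("p1", "p2"), gs, c("g1", "g3"))
  expect_length(spAll$nonContributing, 0L)
  spNone <- contributingSplit(c("p1", "p2"), gs, "zz")
  expect_length(spNone$contributing, 0L)
})

test_that("convergence test enforces the 10/10 rule and matches exact ranks", {
  tl <- lapply(setNames(sprintf("p%02d", 1:19), sprintf("p%02d", 1:19)),
               function(p) "A")
  f <- c(A = 1)
  r <- convergenceTest(sprintf("p%02d", 1:9), sprintf("p%02d", 10:19),
                       tl, f)
  expect_false(r$testable)
  ## exact rank-sum enumeration: 3 contributing (3 intra pairs) vs
  ## 3 non-contributing (9 inter pairs) on a tie-free similarity matrix
  set.seed(3)
  for (i in 1:5) {
    ids <- sprintf("q%d", 1:6)
    S <- matrix(0, 6, 6, dimnames = list(ids, ids))
    S[upper.tri(S)] <- sample(seq(0.01, 0.99, by = 0.01), 15)
    S <- S + t(S)
    r2 <- convergenceTest(ids[1:3], ids[4:6], sim = S, minEach = 2L)
    intra <- S[ids[1:3], ids[1:3]][upper.tri(diag(3))]
    inter <- as.vector(S[ids[1:3], ids[4:6]])
    expect_equal(r2$p, oracleWilcox(intra, inter), tolerance = 1e-12)
    expect_identical(r2$direction, sign(median(intra) - median(inter)))
  }
})

test_that("subterm restriction is untestable for leaves", {
  dag <- ontologyDAG(data.frame(child = c("B", "C"), parent = c("A", "B")))
  tl <- lapply(setNames(sprintf("p%02d", 1:24), sprintf("p%02d", 1:24)),
               function(p) c("A", "B", "C"))
  r <- subtermConvergence("C", sprintf("p%02d", 1:12), sprintf("p%02d", 13:24),
                          tl, dag)
  expect_false(r$testable)
  expect_identical(r$nUniverseTerms, 0L)
})

test_that("binomial excess counts median directions with ties dropped", {
  mk <- function(d) list(testable = TRUE, direction = d)
  r <- excessBinomial(lapply(rep(1, 10), mk))
  expect_equal(r$p, 2^-10, tolerance = 1e-12)
  r2 <- excessBinomial(c(rep(1, 5), rep(-1, 5)))
  expect_gt(r2$p, 0.5)
  r3 <- excessBinomial(c(1, 1, -1, 0, 0))
  expect_identical(r3$nTies, 2L)
  expect_equal(r3$p, binom.test(2, 3, alternative = "greater")$p.value)
  expect_false(excessBinomial(c(0, 0))$testable)
})

test_that("pooling groups by annotation unions the splits", {
  set.seed(4)
  u <- sprintf("T%02d", 1:20)
  pts <- sprintf("p%02d", 1:48)
  tl <- lapply(setNames(pts, pts), function(p) u[runif(20) < 0.3])
  fr <- phenotypeFrequencies(tl)
  gs <- lapply(setNames(pts, pts), function(p) character())
  for (p in pts[c(1:12, 25:36)]) gs[[p]] <- "gHit"
  groups <- S4Vectors::DataFrame(
    term = c("grpA", "grpB"),
    n_patients = c(24L, 24L),
    members = IRanges::CharacterList(list(pts[1:24], pts[25:48])),
    genes = IRanges::CharacterList(list("gHit", "gHit")))
  enr <- S4Vectors::DataFrame(
    resource = "GO", term = "ann1", significant = TRUE,
    contributing = IRanges::CharacterList(list("gHit", "gHit")),
    group_term = c("grpA", "grpB"))
  out <- combineByAnnotation(enr, groups, gs, tl, fr)
  expect_length(out, 1L)
  res <- out[["GO|ann1"]]
  expect_identical(res$nGroups, 2L)
  expect_identical(res$nContributing, 24L)
  ## intra pair count over the pooled contributing set
  expect_identical(res$nIntra, as.integer(choose(24L, 2L)))
  ## with a single group the pooled result equals the single-group result
  out1 <- combineByAnnotation(enr[1L, ], groups, gs, tl, fr)
  single <- convergenceTest(pts[1:12], pts[13:24], tl, fr)
  expect_equal(out1[["GO|ann1"]]$p, single$p)
})

test_that("replication grouping is mutually exclusive with candidate priority", {
  dag <- ontologyDAG(data.frame(child = "B", parent = "A"))
  gt <- randomGenomeTables(nGenes = 40L, nChrom = 2L)
  genes <- names(modelGenes(gt$models))
  gr <- modelGenes(gt$models)
  mk <- function(pid, gid) {
    g <- gr[gid]
    GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                           IRanges::IRanges(GenomicRanges::start(g) - 5,
                                            GenomicRanges::end(g) + 5),
                           cnv_id = paste0("c", pid), patient_id = pid,
                           dosage = "loss", inheritance = "inherited")
  }
  cnvs <- suppressWarnings(c(mk("r1", genes[1L]), mk("r2", genes[2L]),
                             mk("r3", genes[10L])))
  coh <- patientCohort(list(r1 = "B", r2 = "B", r3 = "B", r4 = "B"),
                       cnvs, dag)
  coh <- annotateCnvGenes(coh, gt$models)
  ## r1 hits a candidate gene (and would also hit extended): candidate wins
  rg <- replicationGrouping(coh, candidateGenes = genes[1:2],
                            extendedGenes = genes[c(1L, 10L)], minEach = 2L)
  expect_identical(unname(rg$assignment[c("r1", "r2", "r3", "r4")]),
                   c("candidate", "candidate", "extended", "none"))
})
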
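smallWeightedNet <- function() {
  geneNetwork(data.frame(
    gene_a = c("a", "a", "b", "c", "d"),
    gene_b = c("b", "c", "c", "d", "e"),
    weight = c(0.9, 0.8, 0.85, 0.75, 0.95)))
}

test_that("co-expression construction filters, thresholds and drops isolates", {
  set.seed(1)
  n <- 30L
  f <- rnorm(n)
  expr <- rbind(
    hi1 = 5 + 0.95 * f + 0.2 * rnorm(n),
    hi2 = 5 + 0.95 * f + 0.2 * rnorm(n),
    same1 = 5 + f,
    same2 = 5 + f,              # identical profile -> r = 1
    lone = rnorm(n, mean = 5),  # uncorrelated -> isolated, dropped
    low = rep(0.5, n) + abs(rnorm(n, sd = 0.01)))  # below floor everywhere
  net <- buildCoexpressionNetwork(expr, rMin = 0.7)
  expect_false("low" %in% networkGenes(net))
  expect_false("lone" %in% networkGenes(net))
  e <- networkEdges(net)
  pair <- e[(e$gene_a == "same1" & e$gene_b == "same2") |
              (e$gene_a == "same2" & e$gene_b == "same1"), ]
  expect_equal(pair$weight, 1)
  ## zero-variance genes are excluded with a warning
  expect_warning(buildCoexpressionNetwork(rbind(expr, flat = rep(5, n))),
                 "zero-variance")
})

test_that("r threshold sweep yields nested edge sets", {
  set.seed(2)
  cfg <- simulationConfig(nGenes = 200L, nChromosomes = 2L,
                          plantedPathways = list(), nExprSamples = 40L)
  g <- generateGenome(cfg)
  expr <- generateNetworks(cfg, g$models, list())$expr
  key <- function(net) {
    e <- networkEdges(net)
    paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  }
  e6 <- key(buildCoexpressionNetwork(expr, rMin = 0.6))
  e7 <- key(buildCoexpressionNetwork(expr, rMin = 0.7))
  e8 <- key(buildCoexpressionNetwork(expr, rMin = 0.8))
  expect_true(all(e8 %in% e7))
  expect_true(all(e7 %in% e6))
  expect_gt(length(e6), length(e7))
})

test_that("degree-matched samples preserve the seed degree profile", {
  net <- smallWeightedNet()
  deg <- networkDegree(net)
  ## seed set = all nodes: the only admissible sample is the node set
  s <- degreeMatchedSamples(net, networkGenes(net), nSamples = 5L)
  for (x in s) expect_setequal(x, networkGenes(net))
  ## regular graph: degree constraint is vacuous, samples are plain subsets
  ring <- geneNetwork(data.frame(gene_a = letters[1:6],
                                 gene_b = letters[c(2:6, 1)]))
  set.seed(3)
  s2 <- degreeMatchedSamples(ring, c("a", "d"), nSamples = 50L)
  expect_true(all(vapply(s2, function(x)
    length(unique(x)) == 2L, logical(1L))))
  expect_identical(attr(s2, "tolerance"), 0L)
  ## larger random graph: exact degree multisets when classes are large enough
  set.seed(4)
  cfg <- simulationConfig(nGenes = 300L, nChromosomes = 2L,
                          plantedPathways = list(), nExprSamples = 40L)
  g <- generateGenome(cfg)
  net2 <- buildCoexpressionNetwork(generateNetworks(cfg, g$models,
                                                    list())$expr)
  deg2 <- networkDegree(net2)
  seed <- sample(networkGenes(net2), 6L)
  classSizes <- table(deg2)[as.character(deg2[seed])]
  s3 <- degreeMatchedSamples(net2, seed, nSamples = 100L)
  if (all(classSizes >= table(deg2[seed])[names(classSizes)])) {
    for (x in s3) {
      expect_identical(sort(unname(deg2[x])), sort(unname(deg2[seed])))
    }
  }
  expect_error(degreeMatchedSamples(net, "nope"), "network nodes")
})

test_that("cluster test statistics, contributing genes and p behave", {
  net <- smallWeightedNet()
  set.seed(5)
  ## disconnected pair: observed 0, p of 1 under the +1/+1 estimator
  res0 <- clusterTest(net, c("a", "e"), nSamples = 100L)
  expect_equal(res0$observed, 0)
  expect_gt(res0$p, 0.5)
  expect_length(res0$contributing, 0L)
  ## untestable below two in-network genes
  expect_false(clusterTest(net, c("a", "zz"))$testable)
  ## edge-count equals weight-sum on a unit-weight network
  unit <- geneNetwork(networkEdges(net)[, 1:2], weighted = FALSE)
  set.seed(6)
  r1 <- clusterTest(unit, c("a", "b", "c"), statistic = "weight-sum",
                    nSamples = 50L)
  set.seed(6)
  r2 <- clusterTest(unit, c("a", "b", "c"), statistic = "edge-count",
                    nSamples = 50L)
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)  # empirical p is never zero
})

test_that("empirical p approaches the exact degree-class enumeration", {
  ## 8-node graph, seed pairs: enumerate all degree-feasible pairs exactly
  set.seed(7)
  edges <- data.frame(gene_a = c("a", "a", "b", "c", "d", "e", "f"),
                      gene_b = c("b", "c", "c", "d", "e", "f", "g"),
                      weight = round(runif(7, 0.7, 1), 3))
  net <- geneNetwork(edges, nodes = letters[1:8])
  deg <- networkDegree(net)
  A <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  for (i in seq_len(nrow(edges))) {
    A[edges$gene_a[i], edges$gene_b[i]] <- edges$weight[i]
    A[edges$gene_b[i], edges$gene_a[i]] <- edges$weight[i]
  }
  seedPair <- c("a", "b")  # connected pair, non-trivial tail
  obs <- A["a", "b"]
  ## exact null: all ordered picks of distinct genes from the two classes
  c1 <- names(deg)[deg == deg[["a"]]]
  c2 <- names(deg)[deg == deg[["b"]]]
  vals <- c()
  for (x in c1) for (y in c2) if (x != y) vals <- c(vals, A[x, y])
  exactTail <- mean(vals >= obs)
  set.seed(8)
  res <- clusterTest(net, seedPair, nSamples = 4000L)
  expect_lt(abs(res$p - exactTail),
            3 * sqrt(exactTail * (1 - exactTail) / 4000) + 1e-3)
})

test_that("bait extension handles edgeless baits and reports drop counts", {
  set.seed(9)
  gt <- randomGenomeTables(nGenes = 80L, nChrom = 2L)
  genes <- names(modelGenes(gt$models))
  ppi <- geneNetwork(data.frame(gene_a = genes[1:20], gene_b = genes[21:40]),
                     weighted = FALSE, nodes = genes[1:60])
  ## baits present in the network but with no edges at all
  baits <- genes[41:45]
  gr <- modelGenes(gt$models)[genes[50:55]]
  cnvrs <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(GenomicRanges::start(gr) - 10,
                                                   GenomicRanges::end(gr) + 10))
  res <- suppressMessages(
    baitExtensionTest(baits, cnvrs, ppi, gt$models, nRand = 30L))
  expect_true(res$testable)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
  expect_length(res$extension, 0L)
  ## CNVRs containing bait genes are dropped before testing
  grB <- modelGenes(gt$models)[c(baits[1L], genes[52])]
  cnvrsB <- GenomicRanges::GRanges(GenomicRanges::seqnames(grB),
                                   IRanges::IRanges(GenomicRanges::start(grB) - 10,
                                                    GenomicRanges::end(grB) + 10))
  resB <- suppressMessages(
    baitExtensionTest(baits, cnvrsB, ppi, gt$models, nRand = 10L))
  expect_identical(resB$nBaitCnvrsDropped, 1L)
})
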
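test_that("hypergeometric upper tail matches enumeration and edge cases", {
  expect_identical(hypergeomUpperTail(0, 6, 5, 20), 1)
  expect_identical(hypergeomUpperTail(4, 4, 4, 4), 1)
  expect_error(hypergeomUpperTail(5, 4, 4, 20), "invalid")
  expect_error(hypergeomUpperTail(2, 4, 4, 3), "invalid")
  expect_lt(abs(hypergeomUpperTail(3, 6, 5, 20) - oracleHyperTail(3, 6, 5, 20)),
            1e-12)
})

test_that("BH q-values follow the step-up definition", {
  expect_identical(bhFdr(0.037), 0.037)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_error(bhFdr(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1L))
    q <- bhFdr(p)
    expect_equal(q, oracleBH(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(order(p) == order(q) | q[order(p)] ==
                      cummax(q[order(p)])))  # order preserving
  }
})

test_that("group enrichment recovers planted terms and behaves at the edges", {
  universe <- sprintf("g%03d", 1:100)
  annot <- annotationCollection("GO", list(
    planted = universe[1:10],
    decoy1 = universe[11:40],
    decoy2 = universe[30:90]), universe = universe)
  ## whole test set inside one term: maximal enrichment with fold N/K
  res <- enrichGroup(universe[1:10], annot)
  row <- res[res$term == "planted", ]
  expect_true(row$significant)
  expect_equal(row$fold, 100 / 10)
  expect_true(all(res$q >= res$p))
  ## test set = universe: all folds 1, nothing significant
  resAll <- enrichGroup(universe, annot)
  expect_true(all(resAll$fold == 1))
  expect_false(any(resAll$significant))
  ## BH rejections always contain the Bonferroni rejections
  set.seed(2)
  for (i in 1:20) {
    sets <- lapply(1:20, function(j) sample(universe, sample(5:50, 1L)))
    names(sets) <- paste0("t", 1:20)
    a <- annotationCollection("X", sets, universe = universe)
    r <- enrichGroup(sample(universe, 30), a, alpha = 0.05)
    bonf <- r$p < 0.05 / nrow(r)
    expect_true(all(which(bonf) %in% which(r$significant)))
  }
  expect_warning(enrichGroup("absent", annot), "no test gene")
})

test_that("ortholog reading keeps only unambiguous 1:1 pairs", {
  f <- tempfile()
  writeLines(c("h1\tm1", "h2\tm2", "h2\tm3", "h4\tm4", "h5\tm4"), f)
  orth <- readOrthologMap(f)
  expect_identical(orth, c(h1 = "m1"))
})

test_that("mouse-phenotype engine applies category and 1% rules", {
  humans <- sprintf("h%03d", 1:200)
  orth <- setNames(paste0("m", humans), humans)
  ## category CAT01 pool: 100 mouse genes; planted term = 20 of them;
  ## tiny term annotates <1% of a padded pool via a large pool term
  mice <- unname(orth)
  sets <- list(
    planted = mice[1:20],
    pool = mice[1:150],
    tiny = mice[1:1],        # < 1% of the 150-gene pool -> dropped
    otherCat = mice[1:20])   # identical signal, different category
  cats <- c(planted = "CAT01", pool = "CAT01", tiny = "CAT01",
            otherCat = "CAT02")
  annot <- annotationCollection("MGI", sets, universe = mice,
                                categories = cats, orthologs = orth)
  res <- enrichGroupMgi(humans[1:20], annot, "CAT01")
  expect_false("tiny" %in% res$term)
  expect_false("otherCat" %in% res$term)
  row <- res[res$term == "planted", ]
  expect_true(row$significant)
  ## contributing genes are reported in human id space
  expect_true(all(row$contributing[[1L]] %in% humans))
  ## the same signal planted in another category is never tested
  res2 <- enrichGroupMgi(humans[1:20], annot, "CAT02")
  expect_identical(res2$term, "otherCat")
  expect_warning(enrichGroupMgi(humans[1:5], annot, NA_character_),
                 "no mapped overarching category")
})
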
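test_that("OBO parsing handles chains, obsolete terms and aliases", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T1", "name: root", "",
    "[Term]", "id: T2", "name: child", "alt_id: T2alt", "is_a: T1 ! root", "",
    "[Term]", "id: T9", "name: gone", "is_obsolete: true", ""), obo)
  dag <- parseOBO(obo)
  expect_setequal(ontologyTerms(dag), c("T1", "T2"))
  expect_identical(ontologyRoots(dag), "T1")
  expect_identical(termParents(dag, "T2"), "T1")
  expect_identical(resolveAltIds(dag, c("T2alt", "T1")), c("T2", "T1"))
})

test_that("cyclic and dangling is_a relations are hard errors", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: T1", "is_a: T2", "",
    "[Term]", "id: T2", "is_a: T1", ""), obo)
  expect_error(parseOBO(obo), "cycle")
  writeLines(c("[Term]", "id: T1", "is_a: TX", ""), obo)
  expect_error(parseOBO(obo), "missing term")
})

test_that("ancestor propagation matches brute-force closure on random DAGs", {
  for (s in 1:20) {
    set.seed(1000 + s)
    parents <- randomDagParents(200L)
    dag <- dagFromParents(parents)
    direct <- sample(names(parents), sample(1:8, 1L))
    expect_identical(propagateAncestors(dag, direct),
                     oracleClosure(parents, direct))
  }
})

test_that("propagation is idempotent, monotone and grows the input", {
  set.seed(7)
  parents <- randomDagParents(80L)
  dag <- dagFromParents(parents)
  d1 <- sample(names(parents), 3L)
  d2 <- union(d1, sample(names(parents), 4L))
  c1 <- propagateAncestors(dag, d1)
  c2 <- propagateAncestors(dag, d2)
  expect_identical(propagateAncestors(dag, c1), c1)
  expect_true(all(c1 %in% c2))
  expect_gte(length(c1), length(d1))
  expect_identical(propagateAncestors(dag, ontologyRoots(dag)),
                   ontologyRoots(dag))
})

test_that("descendants are the dual of ancestors over all term pairs", {
  set.seed(11)
  parents <- randomDagParents(40L)
  dag <- dagFromParents(parents)
  terms <- ontologyTerms(dag)
  chain <- ontologyDAG(data.frame(child = c("A", "B"), parent = c("B", "C")))
  expect_identical(properDescendants(chain, "C"), c("A", "B"))
  expect_length(properDescendants(chain, "A"), 0L)
  for (t in terms) {
    desc <- properDescendants(dag, t)
    for (x in terms) {
      inAnc <- t %in% setdiff(propagateAncestors(dag, x), x)
      expect_identical(x %in% desc, inAnc)
    }
  }
})

test_that("category lookup returns the configured category or NA", {
  map <- categoryMap(
    mpoCategory = c(MP1 = "CAT01", MP2 = "CAT02"),
    hpoCategory = c(T1 = "CAT01"))
  expect_identical(hpoToMpoCategory("T1", map), "CAT01")
  expect_true(is.na(hpoToMpoCategory("T2", map)))
  expect_error(categoryMap(mpoCategory = c(MP1 = "a", MP1 = "b")),
               "exactly one")
  ## every mapped term resolves to one of the configured categories
  set.seed(3)
  cats <- sprintf("CAT%02d", 1:33)
  hmap <- setNames(sample(cats, 100, replace = TRUE), sprintf("T%03d", 1:100))
  cm <- categoryMap(hpoCategory = hmap)
  got <- vapply(names(hmap), hpoToMpoCategory, character(1L), map = cm)
  expect_true(all(got %in% cats))
})
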
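test_that("generated ontologies have the configured shape and round-trip", {
  set.seed(20)
  star <- generateOntology(simulationConfig(nTerms = 12L, dagDepth = 1L,
                                            plantedPathways = list()))
  expect_length(ontologyRoots(star$dag), 1L)
  expect_true(all(star$levels[setdiff(ontologyTerms(star$dag),
                                      ontologyRoots(star$dag))] == 1L))
  set.seed(21)
  o <- generateOntology(simulationConfig(nTerms = 150L,
                                         plantedPathways = list()))
  f <- tempfile(fileext = ".obo")
  writeOBO(o$dag, f)
  dag2 <- parseOBO(f)
  expect_setequal(ontologyTerms(dag2), ontologyTerms(o$dag))
  for (t in ontologyTerms(o$dag)) {
    expect_setequal(termParents(dag2, t), termParents(o$dag, t))
  }
})

test_that("the full study generator is deterministic under a seed", {
  cfg <- simulationConfig(nTerms = 80L, nGenes = 250L, nChromosomes = 3L,
                          nPatients = 25L, nReplicationPatients = 10L,
                          nExprSamples = 20L,
                          plantedPathways = list(
                            list(nGenes = 5L, nCarriers = 8L, penetrance = 1,
                                 nPleiotropyTerms = 3L, comorbidFreq = 0.8,
                                 mode = "comorbid")),
                          nReplicationCarriers = 4L)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulateStudy(cfg, d1, seed = 123L)
  s2 <- simulateStudy(cfg, d2, seed = 123L)
  for (nm in names(s1$paths)) {
    expect_identical(unname(tools::md5sum(s1$paths[[nm]])),
                     unname(tools::md5sum(s2$paths[[nm]])),
                     info = nm)
  }
  ## planted annotation terms cover exactly the planted pathway genes
  expect_identical(annotationSets(s1$annotations$go)[["GO:P001"]],
                   s1$truth$pathways[[1L]]$genes)
  ## the ortholog map is a bijection
  orth <- s1$annotations$orthologs
  expect_false(anyDuplicated(names(orth)) > 0L)
  expect_false(anyDuplicated(unname(orth)) > 0L)
  ## full penetrance: every carrier expresses the target phenotype
  tgt <- s1$truth$pathways[[1L]]$targetTerm
  for (p in s1$truth$pathways[[1L]]$carriers) {
    expect_true(tgt %in% propagatedTerms(s1$cohort)[[p]])
  }
  ## all generated CNVs respect the 5 Mb cap by construction
  expect_true(all(GenomicRanges::width(cnvCalls(s1$cohort)) < 5e6))
  ## replication carriers sit in the no-de-novo pool
  inh <- S4Vectors::mcols(cnvCalls(s1$cohort))
  for (p in s1$truth$replicationCarriers) {
    expect_false(any(inh$inheritance[inh$patient_id == p] == "de_novo"))
  }
})

test_that("planted co-expression modules survive the r threshold", {
  set.seed(22)
  cfg <- simulationConfig(nGenes = 400L, nChromosomes = 3L,
                          nExprSamples = 50L, moduleR = 0.9,
                          plantedPathways = list())
  g <- generateGenome(cfg)
  mod <- sample(names(modelGenes(g$models)), 10L)
  nets <- generateNetworks(cfg, g$models, list(mod))
  r <- cor(t(nets$expr[mod, ]))
  passFrac <- mean(r[upper.tri(r)] >= 0.7)
  expect_gte(passFrac, 0.99)
  ## within-module edge density beats cross-block density in the built network
  net <- buildCoexpressionNetwork(nets$expr)
  e <- networkEdges(net)
  inMod <- e$gene_a %in% mod & e$gene_b %in% mod
  dens <- sum(inMod) / choose(length(mod), 2)
  cross <- sum(xor(e$gene_a %in% mod, e$gene_b %in% mod)) /
    (length(mod) * (length(networkGenes(net)) - length(mod)))
  expect_gt(dens, cross)
})

test_that("null configurations carry no planted structure", {
  set.seed(23)
  cfg <- simulationConfig(nTerms = 60L, nGenes = 200L, nChromosomes = 2L,
                          nPatients = 15L, nReplicationPatients = 5L,
                          nExprSamples = 15L, plantedPathways = list(),
                          nReplicationCarriers = 0L)
  s <- simulateStudy(cfg, file.path(tempdir(), "sim_null"), seed = 9L)
  expect_length(s$truth$pathways, 0L)
  expect_length(s$truth$replicationCarriers, 0L)
  expect_false(any(grepl(":P", names(annotationSets(s$annotations$go)))))
})
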
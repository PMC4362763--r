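## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths: plain loops and arithmetic only.

## transitive closure by repeated parent lookup
oracleClosure <- function(parents, direct) {
  out <- unique(direct)
  repeat {
    more <- unique(unlist(lapply(out, function(t) parents[[t]])))
    new <- setdiff(more, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}

## upper-tail hypergeometric by exhaustive enumeration over all C(N, n) draws
oracleHyperTail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

## BH step-up from its definition: q_i = min over j with p_(j) >= p_i of
## m * p_(j) / j, capped at 1
oracleBH <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(m * sp[js] / js))
  }, numeric(1L))
}

## Goodall3 from the piecewise definition, one term at a time
oracleGoodall <- function(a, b, freqs) {
  s <- 0
  for (t in names(freqs)) {
    f <- freqs[[t]]
    inA <- t %in% a
    inB <- t %in% b
    if (inA && inB) {
      s <- s + (1 - f^2)
    } else if (!inA && !inB) {
      s <- s + (1 - (1 - f)^2)
    }
  }
  s
}

## exon-aware CNV/gene overlap rule by direct interval arithmetic on a plain
## table of exons (1-based closed coordinates)
oracleGeneHit <- function(cnvChrom, cnvStart, cnvEnd, geneRow, exonTable) {
  if (geneRow$chrom != cnvChrom) return(FALSE)
  if (geneRow$start >= cnvStart && geneRow$end <= cnvEnd) return(TRUE)
  ex <- exonTable[exonTable$gene_id == geneRow$gene_id, , drop = FALSE]
  for (tid in unique(ex$transcript_id)) {
    te <- ex[ex$transcript_id == tid, , drop = FALSE]
    anyHit <- any(pmax(te$start, cnvStart) <= pmin(te$end, cnvEnd))
    if (!anyHit) return(FALSE)
  }
  TRUE
}

## exact two-sided rank-sum p by enumerating all group assignments,
## reproducing the Mann-Whitney U convention
oracleWilcox <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  all <- c(x, y)
  r <- rank(all)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  ws <- apply(idx, 2L, function(i) sum(rank(all)[i]) - nx * (nx + 1) / 2)
  if (obs > nx * ny / 2) {
    p <- mean(ws >= obs)
  } else {
    p <- mean(ws <= obs)
  }
  min(1, 2 * p)
}

## small random DAG (child -> parents) for property tests
randomDagParents <- function(nTerms, pEdge = 0.15) {
  ids <- sprintf("T%03d", seq_len(nTerms))
  parents <- vector("list", nTerms)
  names(parents) <- ids
  for (i in seq_len(nTerms)[-1L]) {
    anc <- ids[seq_len(i - 1L)]
    pick <- anc[stats::runif(length(anc)) < pEdge]
    if (!length(pick)) pick <- anc[sample.int(length(anc), 1L)]
    parents[[ids[i]]] <- pick
  }
  parents
}

dagFromParents <- function(parents) {
  edges <- do.call(rbind, lapply(names(parents), function(ch) {
    if (length(parents[[ch]])) cbind(ch, parents[[ch]]) else NULL
  }))
  ontologyDAG(edges, terms = names(parents))
}

## tiny two-transcript gene model fixture
tinyModels <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1000, 5000, 2000), c(1999, 8999, 2999)))
  names(genes) <- c("gA", "gB", "gC")
  exons <- GenomicRanges::GRanges(
    c("chr1", "chr1",               # gA single transcript, two exons
      "chr1", "chr1", "chr1",       # gB.t1 exons left+right, gB.t2 right only
      "chr2"),
    IRanges::IRanges(c(1000, 1800, 5000, 8000, 8500, 2000),
                     c(1099, 1999, 5199, 8199, 8999, 2999)),
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1", "gB.t2", "gC.t1"),
    gene_id = c("gA", "gA", "gB", "gB", "gB", "gC"))
  geneModelSet(genes, exons)
}

## random single-exon-per-transcript genome as plain tables + GeneModelSet,
## for the interval-oracle comparison
randomGenomeTables <- function(nGenes = 200L, nChrom = 4L) {
  rows <- list()
  exRows <- list()
  gi <- 0L
  for (c in seq_len(nChrom)) {
    pos <- 1L
    for (k in seq_len(nGenes %/% nChrom)) {
      gi <- gi + 1L
      gid <- sprintf("g%03d", gi)
      len <- sample(500:5000, 1L)
      start <- pos + sample(200:2000, 1L)
      end <- start + len - 1L
      pos <- end
      rows[[gi]] <- data.frame(gene_id = gid, chrom = paste0("chr", c),
                               start = start, end = end)
      nTx <- sample(1:3, 1L)
      for (t in seq_len(nTx)) {
        nEx <- sample(1:3, 1L)
        bounds <- sort(sample(seq(start, end), 2L * nEx))
        exRows[[length(exRows) + 1L]] <- data.frame(
          transcript_id = sprintf("%s.t%d", gid, t), gene_id = gid,
          chrom = paste0("chr", c),
          start = bounds[seq(1L, 2L * nEx, by = 2L)],
          end = bounds[seq(2L, 2L * nEx, by = 2L)])
      }
    }
  }
  geneTab <- do.call(rbind, rows)
  exonTab <- do.call(rbind, exRows)
  genes <- GenomicRanges::GRanges(geneTab$chrom,
                                  IRanges::IRanges(geneTab$start, geneTab$end))
  names(genes) <- geneTab$gene_id
  exons <- GenomicRanges::GRanges(exonTab$chrom,
                                  IRanges::IRanges(exonTab$start, exonTab$end),
                                  transcript_id = exonTab$transcript_id,
                                  gene_id = exonTab$gene_id)
  list(geneTab = geneTab, exonTab = exonTab,
       models = geneModelSet(genes, exons))
}
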
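test_that("block and gene scores follow the closed forms", {
  expect_equal(blockScore(c(0.10, 0.25)), 0.35)
  expect_equal(blockScore(numeric(0)), 0)
  expect_warning(expect_equal(blockScore(c(0.7, 0.7)), 1), "clamped")
  expect_equal(geneScore(c(0.2, 0.5)), 0.6)
  expect_equal(geneScore(numeric(0)), 0)
  expect_equal(geneScore(c(0.3, 1, 0.1)), 1)
  expect_error(geneScore(c(0.5, 1.2)), class = "cogsr_data_error")
})

test_that("variants deduplicate within a gene but propagate across genes", {
  # GA has the variant in both an exon and an interacting fragment; GB shares
  # the interacting fragment
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 50, 50), c(200, 400, 400)),
    gene_id = c("GA", "GA", "GB"),
    category = c("coding", "interacting", "interacting"),
    provenance = "x")
  rs <- new("GeneRegions", regions = gr)
  fmTab <- data.frame(variant_id = "v1", chrom = "chr1", pos = 150,
                      block_id = "b1", ppi = 0.4)
  ov <- overlapVariants(fmTab, rs)
  expect_equal(nrow(ov), 2)
  expect_setequal(ov$gene_id, c("GA", "GB"))
  # precedence attributes GA's mass to coding
  expect_equal(ov$category[ov$gene_id == "GA"], "coding")
  res <- scoreGenes(fmTab, rs)
  gs <- as.data.frame(geneScores(res))
  expect_equal(gs$score, c(0.4, 0.4))  # counted once per gene
})

test_that("gene scores equal exhaustive enumeration over causal placements", {
  # oracle: each block independently places its causal at variant i with
  # probability ppi_i (residual mass = no causal); enumerate all placements
  enumScore <- function(ppis, inGene) {
    opts <- lapply(ppis, function(p) seq(0, length(p)))  # 0 = no causal
    grid <- expand.grid(opts)
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      pr <- 1; hit <- FALSE
      for (b in seq_along(ppis)) {
        ch <- grid[r, b]
        pr <- pr * if (ch == 0) max(0, 1 - sum(ppis[[b]])) else ppis[[b]][ch]
        if (ch > 0 && inGene[[b]][ch]) hit <- TRUE
      }
      if (hit) tot <- tot + pr
    }
    tot
  }
  set.seed(99)
  for (i in 1:40) {
    nb <- sample(1:5, 1)
    ppis <- list(); inGene <- list()
    for (b in seq_len(nb)) {
      m <- sample(1:4, 1)
      w <- runif(m); w <- w / sum(w) * runif(1)  # block mass <= 1
      ppis[[b]] <- w
      inGene[[b]] <- runif(m) < 0.5
    }
    sb <- vapply(seq_len(nb), function(b) blockScore(ppis[[b]][inGene[[b]]]), 0)
    expect_equal(geneScore(sb), enumScore(ppis, inGene), tolerance = 1e-12)
  }
})

test_that("scores are monotone in region size and invariant to region splits", {
  fmTab <- data.frame(variant_id = paste0("v", 1:4), chrom = "chr1",
                      pos = c(100, 300, 500, 700),
                      block_id = c("b1", "b1", "b2", "b2"),
                      ppi = c(0.3, 0.4, 0.2, 0.5))
  mk <- function(ints) new("GeneRegions", regions = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(vapply(ints, `[`, 0, 1), vapply(ints, `[`, 0, 2)),
    gene_id = "G", category = "interacting", provenance = "x"))
  small <- scoreGenes(fmTab, mk(list(c(90, 110))))
  big <- scoreGenes(fmTab, mk(list(c(90, 110), c(290, 310), c(490, 510))))
  expect_gte(as.data.frame(geneScores(big))$score,
             as.data.frame(geneScores(small))$score)
  # splitting one covering region into two adjacent halves changes nothing
  whole <- scoreGenes(fmTab, mk(list(c(50, 750))))
  halves <- scoreGenes(fmTab, mk(list(c(50, 400), c(401, 750))))
  expect_equal(as.data.frame(geneScores(whole))$score,
               as.data.frame(geneScores(halves))$score, tolerance = 1e-12)
  # G >= 1 - exp(-sum s_b)
  bs <- as.data.frame(blockScores(big))
  expect_gte(as.data.frame(geneScores(big))$score + 1e-12,
             1 - exp(-sum(bs$score)))
})

test_that("removing interactions changes scores only via the interacting category", {
  sim <- cachedSim()
  fmp <- suppressMessages(runFinemap(sim$gwas, sim$blocks))
  withI <- scoreGenes(fmp, suppressMessages(
    assembleGeneRegions(sim$genes, sim$fmap, sim$interactions)), sim$genes)
  noI <- scoreGenes(fmp, suppressMessages(
    assembleGeneRegions(sim$genes, sim$fmap, NULL)), sim$genes)
  a <- as.data.frame(geneScores(withI)); b <- as.data.frame(geneScores(noI))
  untouched <- a$gene_id[a$interacting_share == 0]
  expect_gt(length(untouched), 0)
  expect_equal(b$score[match(untouched, b$gene_id)],
               a$score[match(untouched, a$gene_id)], tolerance = 1e-12)
  expect_true(all(b$score <= a$score + 1e-12))  # regions only shrink
})

test_that("runs combine by primary-key join with max and union", {
  mkRes <- function(ids, scores, trait) {
    n <- length(ids)
    new("CogsResult",
        geneScores = S4Vectors::DataFrame(gene_id = ids, score = scores,
          n_blocks = rep(1L, n), coding_share = rep(1, n),
          promoter_share = rep(0, n), interacting_share = rep(0, n)),
        blockScores = S4Vectors::DataFrame(gene_id = character(0),
          block_id = character(0), score = numeric(0)),
        trait = trait, dataset = "d")
  }
  r1 <- mkRes(c("GA", "GB"), c(0.2, 0.35), "t1")
  r2 <- mkRes(c("GA", "GC"), c(0.5, 0.1), "t2")
  cmb <- combineRuns(list(t1 = r1, t2 = r2), threshold = 0.3)
  expect_equal(cmb$scores$max_score[cmb$scores$gene_id == "GA"], 0.5)
  expect_setequal(cmb$prioritised, c("GA", "GB"))
  empty <- combineRuns(list())
  expect_equal(nrow(empty$scores), 0)
  expect_equal(empty$prioritised, character(0))
})

test_that("Manhattan tables label strictly above threshold and suppress non-coding", {
  genes <- toyGenes(list(
    GA = list(tss = 1000, exons = list(c(1000, 2000))),
    GB = list(tss = 5000, exons = list(c(5000, 6000)), biotype = "lincRNA"),
    GC = list(tss = 2e6 + 5000, exons = list(c(2e6 + 5000, 2e6 + 6000)),
              biotype = "lincRNA")))
  res <- new("CogsResult",
    geneScores = S4Vectors::DataFrame(gene_id = c("GA", "GB", "GC"),
      score = c(0.8, 0.5, 0.3), n_blocks = 1L, coding_share = 1,
      promoter_share = 0, interacting_share = 0),
    blockScores = S4Vectors::DataFrame(gene_id = character(0),
      block_id = character(0), score = numeric(0)),
    trait = "t", dataset = "d")
  tab <- manhattanTable(res, genes, threshold = 0.3, locusWindow = 1e6)
  # GB suppressed by the prioritised protein-coding GA in the same locus;
  # GC sits exactly at the threshold: strict > means unlabelled
  expect_equal(tab$label, c(TRUE, FALSE, FALSE))
  expect_equal(tab$gene_id, c("GA", "GB", "GC"))  # genome order
  expect_identical(tab, manhattanTable(res, genes, threshold = 0.3, locusWindow = 1e6))
})

test_that("a strongly planted interacting variant drives its gene to the top", {
  sim <- cachedSim()
  res <- suppressMessages(runCogs(sim$gwas, sim$fmap, sim$interactions,
                                  sim$blocks, sim$genes))
  gs <- as.data.frame(geneScores(res))
  te <- as.data.frame(truthEntries(sim$truth))
  expect_equal(gs$gene_id[which.max(gs$score)], te$gene_id)
  expect_gt(max(gs$score), 0.5)
  expect_gt(gs$interacting_share[gs$gene_id == te$gene_id], 0.5)
})
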
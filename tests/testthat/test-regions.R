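test_that("positions map to fragments with half-open boundary semantics", {
  fm <- toyFragmentMap(c(0, 4000, 8000, 12000))
  pos <- data.frame(chrom = "chr1", pos = c(1, 4000, 4001, 12000))
  expect_equal(mapToFragments(pos, fm), c(1, 1, 2, 3))
  # a file-coordinate fragment end (0-based 4000 == 1-based 4001) opens frag 2
  expect_message(
    expect_equal(mapToFragments(data.frame(chrom = "chr1", pos = 12001), fm),
                 NA_integer_), "beyond the fragment map")
})

test_that("fragment lookup agrees with a linear-scan oracle on random positions", {
  sim <- cachedSim()
  fr <- fragments(sim$fmap)
  df <- as.data.frame(fr)
  set.seed(42)
  idx <- sample(nrow(df), 1000, replace = TRUE)
  pos <- data.frame(chrom = df$seqnames[idx],
                    pos = floor(runif(1000, df$start[idx], df$end[idx] + 1)))
  oracle <- vapply(seq_len(1000), function(i) {
    hit <- which(df$seqnames == pos$chrom[i] & df$start <= pos$pos[i] &
                 df$end >= pos$pos[i])
    df$frag_id[hit]
  }, 0L)
  expect_equal(mapToFragments(pos, sim$fmap), oracle)
})

test_that("promoter-proximal regions are the bait plus its flanks", {
  fm <- toyFragmentMap(c(0, 4000, 8000, 12000, 16000))
  expect_equal(S4Vectors::mcols(promoterProximal(3, fm, 1))$frag_id, c(2, 3, 4))
  expect_equal(S4Vectors::mcols(promoterProximal(1, fm, 1))$frag_id, c(1, 2))
  expect_equal(S4Vectors::mcols(promoterProximal(3, fm, 0))$frag_id, 3)
  expect_error(promoterProximal(99, fm), class = "cogsr_data_error")
})

test_that("virtual baits appear exactly where promoters are unassayed", {
  fm <- toyFragmentMap(c(0, 4000, 8000, 12000), baits = 1, baitGenes = "GA")
  genes <- toyGenes(list(
    GA = list(tss = 100, exons = list(c(100, 500))),       # already baited
    GB = list(tss = 4500, exons = list(c(4500, 5000))),    # unbaited frag 2
    GC = list(tss = 8500, exons = list(c(8500, 9000),      # two TSSs, 2 frags
                                       c(11000, 11500)))))
  gr <- tssSites(genes)
  # add a second TSS for GC on fragment 1 (shared with GA's bait)
  genes@tss <- suppressWarnings(c(gr, GenomicRanges::GRanges("chr1",
    IRanges::IRanges(300, width = 1), gene_id = "GC")))
  fm2 <- buildVirtualBaits(genes, fm)
  fr <- fragments(fm2)
  expect_equal(S4Vectors::mcols(fr)$virtual, c(FALSE, TRUE, TRUE))
  expect_equal(S4Vectors::mcols(fr)$bait, c(TRUE, TRUE, TRUE))
  # GA untouched; GC appended to the shared real bait's annotation
  expect_equal(S4Vectors::mcols(fr)$bait_genes, c("GA;GC", "GB", "GC"))
  # idempotent
  expect_equal(fragments(buildVirtualBaits(genes, fm2)), fr)
})

test_that("interacting regions obey the strict CHiCAGO threshold and shared baits", {
  links <- data.frame(frag_id = c(1, 1), gene_id = c("GA", "GB"), virtual = FALSE)
  it <- toyInteractions(
    data.frame(bait_id = c(1, 1, 1), oe_chrom = "chr1",
               oe_start = c(10001, 20001, 30001), oe_end = c(12000, 22000, 32000),
               oe_id = c(10, 20, 30)),
    scores = cbind(c(3.1, 2.0, 5.0), c(5.2, 4.9, 5.0), c(0.0, 1.0, 5.0)))
  out <- interactingRegions(it, links)
  # row 1 passes (5.2 > 5), row 2 fails, row 3 fails (5.0 is not > 5)
  expect_equal(GenomicRanges::start(out), c(10001, 10001))
  expect_setequal(S4Vectors::mcols(out)$gene_id, c("GA", "GB"))
  # raising the threshold never adds regions
  for (thr in c(0, 2, 5, 8)) {
    n1 <- length(interactingRegions(it, links, RegionConfig(chicagoMin = thr)))
    n2 <- length(interactingRegions(it, links, RegionConfig(chicagoMin = thr + 1)))
    expect_lte(n2, n1)
  }
})

test_that("binning snaps other ends, keeps baits intact and max-pools scores", {
  it <- toyInteractions(
    data.frame(bait_id = c(1, 1, 2), oe_chrom = "chr1",
               oe_start = c(12346, 13001, 12346), oe_end = c(12999, 14000, 12999),
               oe_id = c(10, 11, 10)),
    scores = cbind(c(4, 6, 2)))
  b <- binOtherEnds(it, 5000)
  tab <- interactions(b)
  # 0-based 12345 falls in bin [10000, 15000)
  expect_equal(tab$oe_start, c(10001, 10001))
  expect_equal(tab$oe_end, c(15000, 15000))
  expect_equal(tab$bait_id, c(1, 2))          # bait ids untouched, not binned
  expect_equal(chicagoScores(b)[, 1], c(6, 2))  # max rule within a bin
  expect_equal(b@design, "bin")
})

test_that("coding regions merge exons strand-agnostically", {
  genes <- toyGenes(list(
    GA = list(exons = list(c(100, 200), c(150, 300))),
    GB = list(strand = "-", exons = list(c(1000, 1100), c(2000, 2100), c(3000, 3100)))))
  cr <- codingRegions(genes)
  ga <- cr[S4Vectors::mcols(cr)$gene_id == "GA"]
  expect_equal(length(ga), 1)
  expect_equal(c(GenomicRanges::start(ga), GenomicRanges::end(ga)), c(100, 300))
  expect_equal(length(cr[S4Vectors::mcols(cr)$gene_id == "GB"]), 3)
})

test_that("assembled region sets honour bait status and are idempotent", {
  fm <- toyFragmentMap(c(0, 4000, 8000, 12000, 16000, 20000),
                       baits = 2, baitGenes = "GA")
  genes <- toyGenes(list(
    GA = list(tss = 4500, exons = list(c(4500, 5000))),
    GB = list(tss = 16500, exons = list(c(16500, 17000)))))  # unbaited -> virtual
  it <- toyInteractions(
    data.frame(bait_id = 2, oe_chrom = "chr1", oe_start = 16001,
               oe_end = 20000, oe_id = 5),
    scores = cbind(7))
  rs <- suppressMessages(assembleGeneRegions(genes, fm, it))
  df <- regionsTable(rs)
  expect_setequal(df$category[df$gene_id == "GA"],
                  c("coding", "promoter", "interacting"))
  # virtual-baited gene: promoter (+flanks) and coding only
  expect_setequal(df$category[df$gene_id == "GB"], c("coding", "promoter"))
  # promoter-proximal = bait +/- 1 fragment
  pa <- df[df$gene_id == "GA" & df$category == "promoter", ]
  expect_equal(c(min(pa$start), max(pa$end)), c(0, 12000))
  # assembling again from the same inputs is the identity
  rs2 <- suppressMessages(assembleGeneRegions(genes, fm, it))
  expect_equal(regionsTable(rs2), df)
  # within a gene and category, merged intervals are disjoint
  gr <- regions(rs)
  for (g in unique(df$gene_id)) for (cat in unique(df$category)) {
    sub <- gr[S4Vectors::mcols(gr)$gene_id == g & S4Vectors::mcols(gr)$category == cat]
    expect_equal(length(GenomicRanges::reduce(sub)), length(sub))
  }
})

test_that("raising the CHiCAGO threshold never adds assembled regions", {
  sim <- cachedSim()
  sizes <- vapply(c(0, 3, 5, 10, 20), function(thr) {
    rs <- suppressMessages(assembleGeneRegions(sim$genes, sim$fmap, sim$interactions,
                                               RegionConfig(chicagoMin = thr)))
    sum(GenomicRanges::width(regions(rs)))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("binned and fragment designs agree on which genes gain interactions", {
  # other-end fragments nested inside single bins: gene-level presence matches
  fm <- toyFragmentMap(c(0, 4000, 5000, 10000, 15000, 20000), baits = 1,
                       baitGenes = "GA")
  genes <- toyGenes(list(GA = list(tss = 100, exons = list(c(100, 500)))))
  it <- toyInteractions(
    data.frame(bait_id = 1, oe_chrom = "chr1", oe_start = 10001,
               oe_end = 15000, oe_id = 4),
    scores = cbind(8))
  cfg <- RegionConfig()
  frag <- suppressMessages(assembleGeneRegions(genes, fm, it, cfg))
  binned <- suppressMessages(assembleGeneRegions(genes, fm, binOtherEnds(it, 5000), cfg))
  gFrag <- unique(regionsTable(frag)$gene_id[regionsTable(frag)$category == "interacting"])
  gBin <- unique(regionsTable(binned)$gene_id[regionsTable(binned)$category == "interacting"])
  expect_equal(gFrag, gBin)
})

test_that("planted interacting truth intervals appear in the target's regions", {
  sim <- cachedSim()
  te <- as.data.frame(truthEntries(sim$truth))
  rs <- suppressMessages(assembleGeneRegions(sim$genes, sim$fmap, sim$interactions))
  gr <- regions(rs)
  tgt <- gr[S4Vectors::mcols(gr)$gene_id == te$gene_id &
            S4Vectors::mcols(gr)$category == "interacting"]
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$pos, width = 1)), tgt)
  expect_gt(length(hit), 0)
})
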
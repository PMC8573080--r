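## In-code fixtures shared across test files.

# fragment map from explicit 0-based half-open boundaries on one chromosome
toyFragmentMap <- function(cuts = c(0, 4000, 8000, 12000), chrom = "chr1",
                           baits = integer(0), baitGenes = character(0)) {
  n <- length(cuts) - 1
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(head(cuts, -1) + 1, cuts[-1]))
  S4Vectors::mcols(gr)$frag_id <- seq_len(n)
  S4Vectors::mcols(gr)$bait <- seq_len(n) %in% baits
  S4Vectors::mcols(gr)$bait_genes <- NA_character_
  S4Vectors::mcols(gr)$bait_genes[baits] <- baitGenes
  S4Vectors::mcols(gr)$virtual <- FALSE
  new("FragmentMap", fragments = gr)
}

toyBlocks <- function(bounds = c(0, 1000), chrom = "chr1",
                      ids = paste0("b", seq_len(length(bounds) - 1))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(head(bounds, -1) + 1, bounds[-1]),
                               block_id = ids)
  new("LdBlockSet", blocks = gr)
}

# minimal gene model set; exons as list of 1-based closed (start, end) pairs
toyGenes <- function(spec) {
  rows <- list(); tss <- list(); ex <- list()
  for (i in seq_along(spec)) {
    g <- spec[[i]]
    gid <- names(spec)[i]
    strand <- if (is.null(g$strand)) "+" else g$strand
    biotype <- if (is.null(g$biotype)) "protein_coding" else g$biotype
    chrom <- if (is.null(g$chrom)) "chr1" else g$chrom
    rows[[i]] <- data.frame(gene_id = gid, name = gid, chrom = chrom,
                            strand = strand, biotype = biotype)
    tssPos <- if (is.null(g$tss)) g$exons[[1]][1] else g$tss
    tss[[i]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tssPos, width = 1),
                                       gene_id = gid)
    for (e in g$exons)
      ex[[length(ex) + 1]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(e[1], e[2]),
                                                     gene_id = gid)
  }
  new("GeneModelSet",
      genes = S4Vectors::DataFrame(do.call(rbind, rows)),
      tss = suppressWarnings(do.call(c, tss)),
      exons = suppressWarnings(do.call(c, ex)))
}

toyInteractions <- function(df, cellTypes = paste0("ct", seq_len(ncol(scores))),
                            scores) {
  it <- S4Vectors::DataFrame(bait_id = as.integer(df$bait_id),
                             oe_chrom = df$oe_chrom,
                             oe_start = as.integer(df$oe_start),
                             oe_end = as.integer(df$oe_end),
                             oe_id = as.integer(df$oe_id))
  new("InteractionTable", interactions = it,
      scores = matrix(scores, nrow = nrow(df)), cellTypes = cellTypes,
      design = "fragment")
}

# small-but-real synthetic world reused across tests (cached per session)
.simCache <- new.env()
cachedSim <- function(seed = 11, planted = list(plantedEffect(3, "interacting", zMean = 8))) {
  key <- paste0("s", seed, "_", length(planted))
  if (is.null(.simCache[[key]])) {
    cfg <- SyntheticConfig(plantedEffects = planted, seed = seed)
    .simCache[[key]] <- suppressMessages(simulateCogsData(cfg))
  }
  .simCache[[key]]
}
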
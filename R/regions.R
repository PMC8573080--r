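## Assembly of per-gene gene-associated regions: coding exons,
## promoter-proximal fragments (bait + immediate flanks, with virtual baits
## for unassayed promoters) and PCHi-C promoter-interacting regions passing
## the CHiCAGO threshold in at least one cell type.

#' Map genomic positions to restriction fragments
#'
#' Each position maps to the unique fragment containing it (fragments tile
#' the chromosome; half-open file coordinates mean a position at a fragment's
#' end boundary belongs to the next fragment). Positions beyond the map are
#' unmapped (`NA`) with a reported count.
#'
#' @param positions data.frame with columns `chrom` and `pos` (1-based).
#' @param fmap a [FragmentMap-class].
#' @return integer vector of fragment ids (`NA` if unmapped).
#' @export
mapToFragments <- function(positions, fmap) {
  fr <- fragments(fmap)
  gr <- GRanges(normChrom(positions$chrom), IRanges(positions$pos, width = 1L))
  hits <- findOverlaps(gr, fr)
  out <- rep(NA_integer_, nrow(positions))
  out[S4Vectors::queryHits(hits)] <- mcols(fr)$frag_id[S4Vectors::subjectHits(hits)]
  if (anyNA(out)) message(sum(is.na(out)), " position(s) beyond the fragment map")
  out
}

#' Promoter-proximal fragments: the bait and its flanking fragments
#'
#' @param baitId fragment id of the baited fragment.
#' @param fmap a [FragmentMap-class].
#' @param flankCount fragments added on each side (default 1, the immediate
#'   flanks); truncated at chromosome ends.
#' @return `GRanges` of the bait plus up to `flankCount` neighbours per side.
#' @export
promoterProximal <- function(baitId, fmap, flankCount = 1L) {
  fr <- fragments(fmap)
  i <- match(baitId, mcols(fr)$frag_id)
  if (is.na(i)) dataError(paste0("bait fragment not in map: ", baitId))
  chrom <- as.character(seqnames(fr))
  same <- which(chrom == chrom[i])
  pos <- match(i, same)
  take <- same[max(1, pos - flankCount):min(length(same), pos + flankCount)]
  fr[take]
}

#' Add virtual baits for promoters absent from the capture design
#'
#' Every gene promoter (TSS) whose fragment carries no bait gains a virtual
#' bait on that fragment. Virtual baits contribute promoter-proximal regions
#' only — no interactions exist for them. A TSS on an already-baited fragment
#' leaves the map unchanged, except that the gene is appended to the bait's
#' annotation if missing (promoters sharing a captured fragment share its
#' interactions).
#'
#' @param genes a [GeneModelSet-class].
#' @param fmap a [FragmentMap-class].
#' @return an updated [FragmentMap-class].
#' @export
buildVirtualBaits <- function(genes, fmap) {
  fr <- fragments(fmap)
  tss <- tssSites(genes)
  fid <- mapToFragments(data.frame(chrom = as.character(seqnames(tss)),
                                   pos = start(tss)), fmap)
  for (j in which(!is.na(fid))) {
    i <- match(fid[j], mcols(fr)$frag_id)
    gid <- mcols(tss)$gene_id[j]
    if (!mcols(fr)$bait[i]) {
      mcols(fr)$bait[i] <- TRUE
      mcols(fr)$virtual[i] <- TRUE
      mcols(fr)$bait_genes[i] <- gid
    } else {
      have <- strsplit(mcols(fr)$bait_genes[i], ";", fixed = TRUE)[[1]]
      if (is.na(mcols(fr)$bait_genes[i])) have <- character(0)
      if (!gid %in% have)
        mcols(fr)$bait_genes[i] <- paste(c(have, gid), collapse = ";")
    }
  }
  new("FragmentMap", fragments = fr)
}

#' Promoter-interacting regions per gene
#'
#' An other-end interval is attached to gene G iff some bait of G interacts
#' with it with a CHiCAGO score above `chicagoMin` in at least one cell type
#' (the pooled-across-cell-types rule). Baits shared by several genes
#' propagate the region to all of them. Baits without a gene link are
#' ignored with a reported count.
#'
#' @param pchic an [InteractionTable-class].
#' @param baitLinks data.frame from [baitGeneLinks()] (`frag_id`, `gene_id`,
#'   `virtual`).
#' @param config a [RegionConfig].
#' @return `GRanges` with mcols `gene_id`, `category = "interacting"`,
#'   `provenance`.
#' @export
interactingRegions <- function(pchic, baitLinks, config = RegionConfig()) {
  it <- interactions(pchic)
  pooled <- apply(chicagoScores(pchic), 1, max)
  keep <- which(pooled > config@chicagoMin)
  links <- baitLinks[!baitLinks$virtual, , drop = FALSE]
  orphan <- setdiff(unique(it$bait_id), links$frag_id)
  if (length(orphan) > 0)
    message(length(orphan), " bait(s) without a gene link ignored")
  kept <- as.data.frame(it[keep, , drop = FALSE])
  kept$prov <- ifelse(is.na(kept$oe_id),
                      sprintf("bin:%s:%d", kept$oe_chrom, kept$oe_start - 1L),
                      sprintf("oe:%d", kept$oe_id))
  joined <- merge(kept, links[, c("frag_id", "gene_id")],
                  by.x = "bait_id", by.y = "frag_id")
  if (nrow(joined) == 0)
    return(GRanges(gene_id = character(0), category = character(0),
                   provenance = character(0)))
  GRanges(joined$oe_chrom, IRanges(joined$oe_start, joined$oe_end),
          gene_id = joined$gene_id, category = "interacting",
          provenance = joined$prov)
}

#' Snap interaction other ends to fixed-width bins
#'
#' Other-end coordinates are snapped to `[k binBp, (k+1) binBp)` bins (bin
#' chosen by the other end's start); baited fragments are left unbinned, as
#' in DpnII-style designs. Other ends of one bait falling in the same bin are
#' combined, per cell type, by max score.
#'
#' @param pchic an [InteractionTable-class] (fragment design).
#' @param binBp bin width, default 5000.
#' @return an [InteractionTable-class] with `design = "bin"`.
#' @export
binOtherEnds <- function(pchic, binBp = 5000L) {
  if (binBp <= 0) configError("binBp must be > 0")
  it <- interactions(pchic)
  sc <- chicagoScores(pchic)
  bin0 <- (it$oe_start - 1L) %/% as.integer(binBp) * as.integer(binBp)
  key <- paste(it$bait_id, it$oe_chrom, bin0)
  grp <- match(key, unique(key))
  n <- max(grp, 0L)
  newSc <- matrix(0, n, ncol(sc))
  for (ct in seq_len(ncol(sc)))
    newSc[, ct] <- vapply(split(sc[, ct], grp), max, 0)[as.character(seq_len(n))]
  first <- !duplicated(grp)
  out <- DataFrame(bait_id = it$bait_id[first], oe_chrom = it$oe_chrom[first],
                   oe_start = bin0[first] + 1L,
                   oe_end = bin0[first] + as.integer(binBp),
                   oe_id = NA_integer_)
  metadata(out) <- metadata(it)
  new("InteractionTable", interactions = out, scores = newSc,
      cellTypes = cellTypes(pchic), design = "bin")
}

#' Coding regions: merged exons per gene
#'
#' Strand-agnostic union of all annotated exons (all transcripts) per gene;
#' genes without exons contribute nothing, with a reported count.
#'
#' @param genes a [GeneModelSet-class].
#' @return `GRanges` with mcols `gene_id`, `category = "coding"`, `provenance`.
#' @export
codingRegions <- function(genes) {
  ex <- exonRanges(genes)
  missing <- setdiff(geneTable(genes)$gene_id, unique(mcols(ex)$gene_id))
  if (length(missing) > 0)
    message(length(missing), " gene(s) without exons have no coding regions")
  if (length(ex) == 0)
    return(GRanges(gene_id = character(0), category = character(0),
                   provenance = character(0)))
  sp <- GenomicRanges::reduce(GenomicRanges::split(ex, mcols(ex)$gene_id))
  merged <- unlist(sp)
  GRanges(seqnames(merged), IRanges(start(merged), end(merged)),
          gene_id = names(merged), category = "coding", provenance = "exons")
}

## merge intervals per gene within one category, collapsing provenance tags
mergeByGene <- function(gr) {
  if (length(gr) == 0) return(gr)
  key <- mcols(gr)$gene_id
  sp <- GenomicRanges::split(gr, key)
  red <- GenomicRanges::reduce(sp, with.revmap = TRUE)
  flat <- unlist(red, use.names = FALSE)
  geneOf <- rep(names(red), lengths(red))
  provSplit <- split(mcols(gr)$provenance, key)[names(red)]
  rv <- mcols(flat)$revmap
  grpOf <- rep(seq_along(red), lengths(red))
  prov <- character(length(flat))
  for (i in seq_along(flat))
    prov[i] <- paste(sort(unique(provSplit[[grpOf[i]]][rv[[i]]])), collapse = ";")
  GRanges(seqnames(flat), IRanges(start(flat), end(flat)), gene_id = geneOf,
          category = mcols(gr)$category[1], provenance = prov)
}

#' Assemble the full per-gene region sets
#'
#' Combines, for every gene: merged coding exons; promoter-proximal regions
#' (each linked bait fragment — real or virtual — plus `flankCount` flanking
#' fragments per side); and promoter-interacting other ends passing the
#' CHiCAGO threshold. Each category is merged to a disjoint union per gene,
#' with provenance tags preserved.
#'
#' @param genes a [GeneModelSet-class].
#' @param fmap a [FragmentMap-class].
#' @param pchic an [InteractionTable-class] (or `NULL` for no interaction data).
#' @param config a [RegionConfig].
#' @return a [GeneRegions-class].
#' @export
assembleGeneRegions <- function(genes, fmap, pchic = NULL, config = RegionConfig()) {
  if (config@useVirtualBaits) fmap <- buildVirtualBaits(genes, fmap)
  links <- baitGeneLinks(fmap)
  links <- links[links$gene_id %in% geneTable(genes)$gene_id, , drop = FALSE]

  # bait +/- flankCount fragments per link, vectorised over the sorted map
  fr <- fragments(fmap)
  frChrom <- as.character(seqnames(fr))
  idx <- match(links$frag_id, mcols(fr)$frag_id)
  fc <- config@flankCount
  offs <- seq(-fc, fc)
  cand <- rep(idx, each = length(offs)) + offs
  linkOf <- rep(seq_len(nrow(links)), each = length(offs))
  ok <- cand >= 1 & cand <= length(fr)
  ok[ok] <- frChrom[cand[ok]] == frChrom[idx[linkOf[ok]]]
  promoter <- if (any(ok))
    GRanges(frChrom[cand[ok]],
            IRanges(start(fr)[cand[ok]], end(fr)[cand[ok]]),
            gene_id = links$gene_id[linkOf[ok]], category = "promoter",
            provenance = sprintf("bait:%d", links$frag_id[linkOf[ok]]))
  else GRanges(gene_id = character(0), category = character(0),
               provenance = character(0))

  interacting <- if (is.null(pchic))
    GRanges(gene_id = character(0), category = character(0), provenance = character(0))
  else interactingRegions(pchic, links, config)

  all <- suppressWarnings(c(mergeByGene(codingRegions(genes)), mergeByGene(promoter),
                            mergeByGene(interacting)))
  new("GeneRegions", regions = GenomicRanges::sort(all, ignore.strand = TRUE))
}

#' Export gene regions as a BED-like table
#'
#' @param x a [GeneRegions-class].
#' @param path optional TSV output path.
#' @return data.frame: `chrom, start, end, gene_id, category, provenance`
#'   (0-based half-open, BED convention).
#' @export
regionsTable <- function(x, path = NULL) {
  gr <- regions(x)
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), gene_id = mcols(gr)$gene_id,
                   category = mcols(gr)$category, provenance = mcols(gr)$provenance,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) writeTsv(df, path)
  df
}
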
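## Readers/writers for the standard formats the pipeline touches.
##
## Conventions: files carrying BED-like coordinates (rmap/baitmap, BED3/12,
## peak-matrix other ends) are 0-based half-open on disk; GWAS positions are
## 1-based as in their sources. In memory everything is 1-based closed
## (GRanges convention); the conversions happen exactly once, at load/save.

#' Column dialects for GWAS summary-statistic files
#'
#' A dialect maps the pipeline's canonical field names to the column headers
#' of a concrete file layout. `"hgi_r5"` matches the COVID-19 HGI release-5
#' meta-analysis files; `"simple"` is the plain layout written by
#' [writeGwas()] and the synthetic generator manifest.
#'
#' @param name dialect name, or a named character vector/list giving a custom
#'   mapping with fields `chrom, pos, ref, alt, p, beta, se, af, n_cases,
#'   n_controls` (and optionally `id`).
#' @return named list mapping canonical fields to file column names.
#' @export
gwasDialect <- function(name = "hgi_r5") {
  if (is.list(name) || (is.character(name) && length(name) > 1)) return(as.list(name))
  switch(name,
    hgi_r5 = list(chrom = "#CHR", pos = "POS", ref = "REF", alt = "ALT",
                  id = "SNP", p = "all_inv_var_meta_p",
                  beta = "all_inv_var_meta_beta", se = "all_inv_var_meta_sebeta",
                  af = "all_meta_AF", n_cases = "all_inv_var_meta_cases",
                  n_controls = "all_inv_var_meta_controls"),
    simple = list(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                  id = "id", p = "p", beta = "beta", se = "se", af = "af",
                  n_cases = "n_cases", n_controls = "n_controls"),
    formatError(paste0("unknown GWAS dialect: ", name)))
}

#' Read GWAS summary statistics
#'
#' Loads a summary-statistics TSV in a given column dialect and applies the
#' pipeline's validation rules: rows with p outside (0, 1], missing allele
#' frequency or missing sample sizes are dropped (with a message reporting
#' the count); allele frequencies above 0.5 are folded to minor allele
#' frequency; duplicated (chrom, pos, ref, alt) rows keep the smallest p;
#' sex-chromosome variants are loaded but flagged (`sex_chrom`), since
#' ldetect LD blocks cover autosomes only and such variants are excluded at
#' block assignment.
#'
#' @param path TSV(.gz) file.
#' @param dialect see [gwasDialect()].
#' @return a `data.frame` with columns `variant_id, chrom, pos, ref, alt, p,
#'   beta, se, maf, n_cases, n_controls, sex_chrom` (pos 1-based).
#' @export
readGwas <- function(path, dialect = "hgi_r5") {
  map <- gwasDialect(dialect)
  raw <- readTsv(path)
  mandatory <- c("chrom", "pos", "ref", "alt", "af", "n_cases", "n_controls")
  for (f in mandatory) {
    if (is.null(map[[f]]) || !map[[f]] %in% names(raw))
      formatError(paste0("GWAS file missing mandatory column: ",
                         if (is.null(map[[f]])) f else map[[f]]))
  }
  hasP  <- !is.null(map$p) && map$p %in% names(raw)
  hasBS <- !is.null(map$beta) && map$beta %in% names(raw) &&
           !is.null(map$se) && map$se %in% names(raw)
  if (!hasP && !hasBS)
    formatError("GWAS file must provide a p-value column or beta+se columns")

  df <- data.frame(
    chrom = normChrom(raw[[map$chrom]]),
    pos = as.integer(raw[[map$pos]]),
    ref = as.character(raw[[map$ref]]),
    alt = as.character(raw[[map$alt]]),
    p = if (hasP) as.numeric(raw[[map$p]]) else NA_real_,
    beta = if (hasBS) as.numeric(raw[[map$beta]]) else NA_real_,
    se = if (hasBS) as.numeric(raw[[map$se]]) else NA_real_,
    af = as.numeric(raw[[map$af]]),
    n_cases = as.numeric(raw[[map$n_cases]]),
    n_controls = as.numeric(raw[[map$n_controls]]),
    stringsAsFactors = FALSE)
  df$variant_id <- if (!is.null(map$id) && map$id %in% names(raw))
    as.character(raw[[map$id]]) else paste0(df$chrom, ":", df$pos, "_", df$ref, "_", df$alt)

  # Invariants: p in (0, 1]; af in (0, 1); maf and N needed by the variance
  # formula; at least one of {p, beta+se} per row. Violations drop the row.
  n0 <- nrow(df)
  badP <- !is.na(df$p) & (df$p <= 0 | df$p > 1)   # out of range: drop always
  noBS <- is.na(df$beta) | is.na(df$se)
  bad <- badP | (is.na(df$p) & noBS) |
         is.na(df$af) | df$af <= 0 | df$af >= 1 |
         is.na(df$n_cases) | is.na(df$n_controls) | is.na(df$pos)
  df <- df[!bad, , drop = FALSE]
  if (n0 - nrow(df) > 0)
    message(n0 - nrow(df), " GWAS row(s) dropped (invalid p/af/N)")

  df$maf <- pmin(df$af, 1 - df$af)
  df$af <- NULL
  # duplicates: deterministic, conservative — keep the smallest p
  key <- paste(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    ord <- order(key, df$p, na.last = TRUE)
    df <- df[ord, ][!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  df$sex_chrom <- isSexChrom(df$chrom)
  rownames(df) <- NULL
  df[, c("variant_id", "chrom", "pos", "ref", "alt", "p", "beta", "se",
         "maf", "n_cases", "n_controls", "sex_chrom")]
}

#' Write GWAS summary statistics
#'
#' Inverse of [readGwas()]; writes the canonical in-memory table in the given
#' dialect so that read -> write -> read is the identity.
#'
#' @param gwas data.frame as returned by [readGwas()] or [simulateGwas()].
#' @param path output TSV(.gz).
#' @inheritParams readGwas
#' @export
writeGwas <- function(gwas, path, dialect = "hgi_r5") {
  map <- gwasDialect(dialect)
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = sub("^chr", "", gwas$chrom), b = gwas$pos, c = gwas$ref, d = gwas$alt)
  names(out) <- unlist(map[c("chrom", "pos", "ref", "alt")])
  if (!is.null(map$id)) out[[map$id]] <- gwas$variant_id
  out[[map$beta]] <- gwas$beta
  out[[map$se]] <- gwas$se
  out[[map$p]] <- gwas$p
  out[[map$af]] <- gwas$maf  # already folded; MAF is the stored frequency
  out[[map$n_cases]] <- gwas$n_cases
  out[[map$n_controls]] <- gwas$n_controls
  writeTsv(out, path)
}

#' Read a CHiCAGO-style rmap/baitmap pair into a FragmentMap
#'
#' The rmap lists every restriction fragment (chrom, start, end, id;
#' coordinates 0-based half-open, no header); the baitmap lists the captured
#' subset with a fifth column of ";"-separated gene annotations. Bait ids must
#' be a subset of rmap ids. Fragments are returned coordinate-sorted with
#' their original ids preserved.
#'
#' @param rmapPath,baitmapPath TSV(.gz) files.
#' @return a [FragmentMap-class].
#' @export
readRmapBaitmap <- function(rmapPath, baitmapPath) {
  rm <- readTsv(rmapPath, header = FALSE)
  if (ncol(rm) < 4) formatError("rmap needs 4 columns: chrom, start, end, id")
  names(rm)[1:4] <- c("chrom", "start", "end", "id")
  bm <- readTsv(baitmapPath, header = FALSE)
  if (ncol(bm) < 5) formatError("baitmap needs 5 columns: chrom, start, end, id, genes")
  names(bm)[1:5] <- c("chrom", "start", "end", "id", "genes")
  if (!all(bm$id %in% rm$id))
    consistencyError(paste0("baitmap ids absent from rmap: ",
                            paste(utils::head(setdiff(bm$id, rm$id), 5), collapse = ", ")))
  gr <- GRanges(normChrom(rm$chrom), IRanges(rm$start + 1L, rm$end))
  mcols(gr)$frag_id <- as.integer(rm$id)
  mcols(gr)$bait <- rm$id %in% bm$id
  mcols(gr)$bait_genes <- as.character(bm$genes[match(rm$id, bm$id)])
  mcols(gr)$virtual <- FALSE
  gr <- GenomicRanges::sort(gr)
  new("FragmentMap", fragments = gr)
}

#' @rdname readRmapBaitmap
#' @param fmap a [FragmentMap-class] to serialise.
#' @export
writeRmapBaitmap <- function(fmap, rmapPath, baitmapPath) {
  gr <- fragments(fmap)
  rm <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), id = mcols(gr)$frag_id)
  con <- file(rmapPath, "wb")
  write.table(rm, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  isb <- mcols(gr)$bait & !mcols(gr)$virtual
  bm <- cbind(rm[isb, ], genes = mcols(gr)$bait_genes[isb])
  con <- file(baitmapPath, "wb")
  write.table(bm, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(fmap)
}

#' Split baitmap gene annotations into bait-to-gene links
#'
#' A bait annotated `"GENE1;GENE2"` (two promoters sharing one captured
#' fragment) yields one link per gene.
#'
#' @param fmap a [FragmentMap-class].
#' @return data.frame with columns `frag_id`, `gene_id`, `virtual`.
#' @export
baitGeneLinks <- function(fmap) {
  gr <- fragments(fmap)
  isb <- mcols(gr)$bait & !is.na(mcols(gr)$bait_genes)
  if (!any(isb)) return(data.frame(frag_id = integer(), gene_id = character(),
                                   virtual = logical()))
  genes <- strsplit(mcols(gr)$bait_genes[isb], ";", fixed = TRUE)
  data.frame(frag_id = rep(mcols(gr)$frag_id[isb], lengths(genes)),
             gene_id = unlist(genes),
             virtual = rep(mcols(gr)$virtual[isb], lengths(genes)),
             stringsAsFactors = FALSE)
}

#' Read a peak-matrix-like PCHi-C interaction table
#'
#' Layout: `bait_chrom bait_start bait_end bait_id oe_chrom oe_start oe_end
#' oe_id` followed by one CHiCAGO score column per cell type (header row
#' carries the cell-type names). Coordinates 0-based half-open on disk.
#' `oe_id` is `NA` for binned (DpnII-style) designs in which other ends are
#' fixed-width bins rather than restriction fragments.
#'
#' @param path TSV(.gz).
#' @param cellTypeColumns optional character vector naming the score columns
#'   to load; default: every column after the first eight.
#' @return an [InteractionTable-class].
#' @export
readInteractions <- function(path, cellTypeColumns = NULL) {
  raw <- readTsv(path)
  fixed <- c("bait_chrom", "bait_start", "bait_end", "bait_id",
             "oe_chrom", "oe_start", "oe_end", "oe_id")
  if (!all(fixed %in% names(raw)))
    formatError(paste0("interaction table missing column(s): ",
                       paste(setdiff(fixed, names(raw)), collapse = ", ")))
  if (is.null(cellTypeColumns)) cellTypeColumns <- setdiff(names(raw), fixed)
  if (length(cellTypeColumns) == 0) formatError("interaction table has no score columns")
  scores <- as.matrix(raw[, cellTypeColumns, drop = FALSE])
  storage.mode(scores) <- "double"
  bad <- which(apply(is.na(scores), 1, any) | is.na(raw$bait_id) | is.na(raw$oe_start))
  if (length(bad) > 0)
    formatError(paste0("malformed interaction row at line ", bad[1] + 1L))
  it <- DataFrame(bait_id = as.integer(raw$bait_id),
                  oe_chrom = normChrom(raw$oe_chrom),
                  oe_start = as.integer(raw$oe_start) + 1L,
                  oe_end = as.integer(raw$oe_end),
                  oe_id = suppressWarnings(as.integer(raw$oe_id)))
  design <- if (all(is.na(it$oe_id)) && nrow(it) > 0) "bin" else "fragment"
  new("InteractionTable", interactions = it, scores = unname(scores),
      cellTypes = cellTypeColumns, design = design)
}

#' @rdname readInteractions
#' @param x an [InteractionTable-class] to serialise.
#' @export
writeInteractions <- function(x, path) {
  it <- interactions(x)
  df <- data.frame(bait_chrom = NA_character_, bait_start = NA_integer_,
                   bait_end = NA_integer_, bait_id = it$bait_id,
                   oe_chrom = it$oe_chrom, oe_start = it$oe_start - 1L,
                   oe_end = it$oe_end, oe_id = it$oe_id, stringsAsFactors = FALSE)
  bc <- metadata(it)$bait_coords
  if (!is.null(bc)) {
    idx <- match(it$bait_id, bc$frag_id)
    df$bait_chrom <- bc$chrom[idx]; df$bait_start <- bc$start[idx] - 1L
    df$bait_end <- bc$end[idx]
  }
  sc <- chicagoScores(x)
  colnames(sc) <- cellTypes(x)
  writeTsv(cbind(df, sc), path)
}

#' Read a BED3/BED4 file of LD blocks
#'
#' @param path BED(.gz); 0-based half-open. A 4th column, when present, gives
#'   block ids; otherwise ids are generated as `chrom:start-end`.
#' @return an [LdBlockSet-class].
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) formatError(paste0("malformed BED line ", which(nf < 3)[1]))
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    formatError(paste0("malformed BED line ", which(is.na(start) | is.na(end))[1]))
  id <- ifelse(nf >= 4, vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
               paste0(normChrom(chrom), ":", start, "-", end))
  gr <- GenomicRanges::sort(GRanges(normChrom(chrom), IRanges(start + 1L, end),
                                    block_id = id))
  new("LdBlockSet", blocks = gr)
}

#' @rdname readBed
#' @param x an [LdBlockSet-class] to serialise (BED4).
#' @export
writeBed <- function(x, path) {
  gr <- ldBlocks(x)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   mcols(gr)$block_id)
  con <- file(path, "wb")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF parsing goes through [rtracklayer::import()] with `gene_id` as the
#' primary key (`gene`/`transcript`/`exon` features used for the gene table,
#' TSSs and exons respectively). BED12 uses the name field as gene id, the
#' strand-aware interval start as the single TSS, and the blocks as exons.
#'
#' @param path `.gtf(.gz)` or `.bed(.gz)` file.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$|\\.gff[23]?(\\.gz)?$", path)) readGeneModelsGtf(path)
  else readGeneModelsBed12(path)
}

readGeneModelsGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(mcols(gr))) formatError("GTF lacks gene_id attribute")
  GenomeInfoDb::seqlevels(gr) <- normChrom(GenomeInfoDb::seqlevels(gr))
  ex <- gr[mcols(gr)$type == "exon"]
  txs <- gr[mcols(gr)$type == "transcript"]
  if (length(txs) == 0) txs <- gr[mcols(gr)$type == "gene"]
  gfeat <- gr[mcols(gr)$type == "gene"]
  if (length(gfeat) == 0) { # derive per-gene summary from exons
    sp <- split(ex, mcols(ex)$gene_id)
    gfeat <- unlist(range(sp))
    mcols(gfeat)$gene_id <- names(sp)
    mcols(gfeat)$gene_name <- NA_character_
    mcols(gfeat)$gene_biotype <- NA_character_
  }
  biotype <- if ("gene_biotype" %in% names(mcols(gfeat))) mcols(gfeat)$gene_biotype
             else rep(NA_character_, length(gfeat))
  gname <- if ("gene_name" %in% names(mcols(gfeat))) mcols(gfeat)$gene_name
           else mcols(gfeat)$gene_id
  genes <- DataFrame(gene_id = mcols(gfeat)$gene_id,
                     name = ifelse(is.na(gname), mcols(gfeat)$gene_id, gname),
                     chrom = as.character(seqnames(gfeat)),
                     strand = as.character(GenomicRanges::strand(gfeat)),
                     biotype = ifelse(is.na(biotype), "unknown", biotype))
  tssPos <- ifelse(as.character(GenomicRanges::strand(txs)) == "-", end(txs), start(txs))
  tss <- GRanges(seqnames(txs), IRanges(tssPos, width = 1L),
                 gene_id = mcols(txs)$gene_id)
  tss <- unique(tss)
  exons <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)), gene_id = mcols(ex)$gene_id)
  new("GeneModelSet", genes = genes, tss = GenomicRanges::sort(tss),
      exons = GenomicRanges::sort(exons))
}

readGeneModelsBed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12)
  if (length(bad) > 0) formatError(paste0("malformed BED12 line ", bad[1]))
  m <- do.call(rbind, parts)
  chrom <- normChrom(m[, 1]); start0 <- as.integer(m[, 2]); end0 <- as.integer(m[, 3])
  gid <- m[, 4]; strand <- m[, 6]
  nblock <- as.integer(m[, 10])
  sizes <- lapply(strsplit(m[, 11], ",", fixed = TRUE), as.integer)
  offs <- lapply(strsplit(m[, 12], ",", fixed = TRUE), as.integer)
  if (any(lengths(sizes) != nblock) || any(lengths(offs) != nblock))
    formatError(paste0("malformed BED12 blocks at line ",
                       which(lengths(sizes) != nblock | lengths(offs) != nblock)[1]))
  genes <- DataFrame(gene_id = gid, name = gid, chrom = chrom, strand = strand,
                     biotype = if (ncol(m) >= 13) m[, 13] else rep("protein_coding", nrow(m)))
  tssPos <- ifelse(strand == "-", end0, start0 + 1L)
  tss <- GRanges(chrom, IRanges(tssPos, width = 1L), gene_id = gid)
  exChrom <- rep(chrom, nblock); exGid <- rep(gid, nblock)
  exStart <- rep(start0, nblock) + unlist(offs) + 1L
  exEnd <- exStart + unlist(sizes) - 1L
  exons <- GRanges(exChrom, IRanges(exStart, exEnd), gene_id = exGid)
  new("GeneModelSet", genes = genes, tss = GenomicRanges::sort(tss),
      exons = GenomicRanges::sort(exons))
}

#' @rdname readGeneModels
#' @param genes a [GeneModelSet-class] to serialise as BED12 (one row per
#'   gene; first TSS-consistent interval; exons as blocks; biotype in a 13th
#'   column — read back by [readGeneModels()]).
#' @export
writeGeneModelsBed12 <- function(genes, path) {
  gt <- as.data.frame(geneTable(genes))
  ex <- exonRanges(genes)
  rows <- character(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    gid <- gt$gene_id[i]
    e <- reduce(ex[mcols(ex)$gene_id == gid])
    e <- e[order(start(e))]
    gstart <- min(start(e)) - 1L; gend <- max(end(e))
    rows[i] <- paste(gt$chrom[i], gstart, gend, gid, 0L, gt$strand[i],
                     gstart, gend, "0", length(e),
                     paste0(paste(width(e), collapse = ","), ","),
                     paste0(paste(start(e) - 1L - gstart, collapse = ","), ","),
                     gt$biotype[i], sep = "\t")
  }
  writeLines(rows, path)
  invisible(genes)
}

#' Read a GMT gene-set file
#'
#' @param path GMT(.gz): per line, set name, description, then member genes.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) formatError(paste0("malformed GMT line ", bad[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write a per-gene results table
#'
#' Serialises the gene-score table of a [CogsResult-class] (or any data
#' frame) as TSV with scores at 6 decimals.
#'
#' @param x a `CogsResult` or data.frame.
#' @param path output TSV(.gz).
#' @export
writeResults <- function(x, path) {
  if (is(x, "CogsResult")) x <- as.data.frame(geneScores(x))
  writeTsv(x, path)
}

#' Read/write a gene-by-sample expression matrix
#'
#' TSV with gene ids in the first column, sample labels in the header.
#'
#' @param path TSV(.gz).
#' @return numeric matrix (genes x samples).
#' @export
readExpression <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (anyNA(m) || any(m < 0)) formatError("expression values must be numeric and >= 0")
  m
}

#' @rdname readExpression
#' @param expr numeric matrix with gene rownames.
#' @export
writeExpression <- function(expr, path) {
  writeTsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE), path)
}
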
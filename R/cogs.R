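## COGS score aggregation: per-variant posteriors -> per-(gene, block) block
## scores -> per-gene score G = 1 - prod_b (1 - s_b), the posterior
## probability that at least one causal variant falls in at least one
## gene-associated region, under at most one causal variant per LD block and
## independence across blocks.

#' Overlap fine-mapped variants with gene regions
#'
#' A variant contributes at most once per gene per block even if it falls in
#' several categories or regions of that gene; when it does, its posterior is
#' attributed to one category by the precedence coding > promoter >
#' interacting (decomposition reporting only — the score is unaffected).
#' A variant inside regions of several genes contributes to each of them.
#'
#' @param finemap data.frame from [runFinemap()] (needs `chrom`, `pos`,
#'   `block_id`, `ppi`).
#' @param regionSet a [GeneRegions-class].
#' @return data.frame: `gene_id, block_id, variant_id, ppi, category`, one
#'   row per (gene, variant).
#' @export
overlapVariants <- function(finemap, regionSet) {
  gr <- regions(regionSet)
  vr <- GRanges(finemap$chrom, IRanges(finemap$pos, width = 1L))
  hits <- findOverlaps(vr, gr, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(gene_id = character(0), block_id = character(0),
                      variant_id = character(0), ppi = numeric(0),
                      category = character(0)))
  df <- data.frame(
    gene_id = mcols(gr)$gene_id[S4Vectors::subjectHits(hits)],
    block_id = finemap$block_id[S4Vectors::queryHits(hits)],
    variant_id = finemap$variant_id[S4Vectors::queryHits(hits)],
    ppi = finemap$ppi[S4Vectors::queryHits(hits)],
    category = mcols(gr)$category[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = REGION_CATEGORIES)
  df <- df[order(df$gene_id, df$variant_id, df$category), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_id, df$variant_id)), , drop = FALSE]
  df$category <- as.character(df$category)
  rownames(df) <- NULL
  df
}

#' Block score: summed posterior mass of a gene's variants in one LD block
#'
#' Under the single-causal-variant model the events "variant i is causal"
#' are mutually exclusive within a block, so the probability that the causal
#' variant falls in the gene's regions is the plain sum of posteriors,
#' clamped to 1 (with a warning) if floating-point overshoot occurs.
#'
#' @param ppi posteriors of the gene's (deduplicated) variants in one block.
#' @return block score `s_b` in \[0, 1\].
#' @examples
#' blockScore(c(0.10, 0.25))  # 0.35
#' @export
blockScore <- function(ppi) {
  s <- sum(ppi)
  if (s > 1) {
    if (s > 1 + 1e-6) warning("block posterior mass ", s, " clamped to 1")
    s <- 1
  }
  s
}

#' Gene score from block scores
#'
#' `G = 1 - prod_b (1 - s_b)`: the probability of at least one causal
#' variant in at least one gene-associated region, blocks independent.
#'
#' @param blockScores numeric vector of per-block scores in \[0, 1\].
#' @return `G` in \[0, 1\]; 0 for an empty vector.
#' @examples
#' geneScore(c(0.2, 0.5))  # 0.6
#' @export
geneScore <- function(blockScores) {
  if (any(blockScores < 0 | blockScores > 1)) dataError("block scores must lie in [0, 1]")
  1 - prod(1 - blockScores)
}

#' Score all genes from fine-mapped posteriors and assembled regions
#'
#' @param finemap data.frame from [runFinemap()].
#' @param regionSet a [GeneRegions-class].
#' @param genes optional [GeneModelSet-class]; genes without any overlapping
#'   variant are then reported with score 0.
#' @param trait,dataset tags recorded in the result.
#' @return a [CogsResult-class].
#' @export
scoreGenes <- function(finemap, regionSet, genes = NULL,
                       trait = "trait", dataset = "dataset") {
  ov <- overlapVariants(finemap, regionSet)
  gb <- split(ov$ppi, paste(ov$gene_id, ov$block_id, sep = "\r"))
  if (length(gb) > 0) {
    keys <- strsplit(names(gb), "\r", fixed = TRUE)
    bs <- DataFrame(gene_id = vapply(keys, `[`, "", 1),
                    block_id = vapply(keys, `[`, "", 2),
                    score = vapply(gb, blockScore, 0))
  } else {
    bs <- DataFrame(gene_id = character(0), block_id = character(0), score = numeric(0))
  }
  allGenes <- if (is.null(genes)) sort(unique(ov$gene_id))
              else sort(geneTable(genes)$gene_id)
  catMass <- matrix(0, length(allGenes), 3,
                    dimnames = list(allGenes, REGION_CATEGORIES))
  if (nrow(ov) > 0) {
    agg <- stats::aggregate(ppi ~ gene_id + category, data = ov, FUN = sum)
    catMass[cbind(agg$gene_id, agg$category)] <- agg$ppi
  }
  tot <- rowSums(catMass)
  shares <- catMass / ifelse(tot > 0, tot, 1)
  score <- vapply(allGenes, function(g) geneScore(bs$score[bs$gene_id == g]), 0)
  nb <- vapply(allGenes, function(g) sum(bs$gene_id == g), 0L)
  gs <- DataFrame(gene_id = allGenes, score = unname(score), n_blocks = unname(nb),
                  coding_share = unname(shares[, "coding"]),
                  promoter_share = unname(shares[, "promoter"]),
                  interacting_share = unname(shares[, "interacting"]))
  ord <- order(bs$gene_id, bs$block_id)
  new("CogsResult", geneScores = gs, blockScores = bs[ord, , drop = FALSE],
      trait = trait, dataset = dataset)
}

#' Run the full COGS pipeline on one GWAS and one PCHi-C dataset
#'
#' Fine-maps the GWAS within LD blocks, assembles gene-associated regions
#' (with virtual baits), and aggregates posteriors into per-gene scores.
#' Deterministic given its inputs.
#'
#' @param gwas data.frame from [readGwas()] or [simulateGwas()].
#' @param fmap a [FragmentMap-class].
#' @param pchic an [InteractionTable-class] (or `NULL`).
#' @param blocks an [LdBlockSet-class].
#' @param genes a [GeneModelSet-class].
#' @param finemapConfig a [FinemapConfig].
#' @param regionConfig a [RegionConfig].
#' @param trait,dataset tags recorded in the result.
#' @return a [CogsResult-class].
#' @export
runCogs <- function(gwas, fmap, pchic, blocks, genes,
                    finemapConfig = FinemapConfig(), regionConfig = RegionConfig(),
                    trait = "trait", dataset = "dataset") {
  fm <- runFinemap(gwas, blocks, finemapConfig)
  rs <- assembleGeneRegions(genes, fmap, pchic, regionConfig)
  scoreGenes(fm, rs, genes, trait = trait, dataset = dataset)
}

#' Combine COGS results across traits and PCHi-C datasets
#'
#' Joins per-run gene scores on gene id (primary key), reports the per-gene
#' max across runs, and the union set of genes exceeding the threshold in
#' any run.
#'
#' @param results named list of [CogsResult-class] objects.
#' @param threshold prioritisation cut-off (strict `>`), default 0.3.
#' @return list: `scores` (data.frame gene_id, one column per run,
#'   `max_score`) and `prioritised` (character vector, the union set).
#' @export
combineRuns <- function(results, threshold = 0.3) {
  if (length(results) == 0)
    return(list(scores = data.frame(gene_id = character(0), max_score = numeric(0)),
                prioritised = character(0)))
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("run", seq_along(results))
  ids <- sort(Reduce(union, lapply(results, function(r) geneScores(r)$gene_id)))
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    gs <- geneScores(results[[nm]])
    out[[nm]] <- gs$score[match(ids, gs$gene_id)]
  }
  runCols <- as.matrix(out[, names(results), drop = FALSE])
  out$max_score <- apply(runCols, 1, max, na.rm = TRUE)
  list(scores = out,
       prioritised = out$gene_id[apply(runCols > threshold, 1, any, na.rm = TRUE)])
}

#' Gene-level Manhattan plotting table
#'
#' One row per scored gene with model coordinates, ordered along the genome.
#' Genes above the threshold (strict `>`) are flagged for labelling;
#' non-coding genes are label-suppressed when a protein-coding gene within
#' `locusWindow` of them is also prioritised. Genes without model
#' coordinates are dropped with a reported count.
#'
#' @param result a [CogsResult-class].
#' @param genes a [GeneModelSet-class].
#' @param threshold label threshold, default 0.3.
#' @param locusWindow bp window defining a locus for label suppression.
#' @return data.frame: `chrom, pos, gene_id, name, biotype, score, label`.
#' @export
manhattanTable <- function(result, genes, threshold = 0.3, locusWindow = 1e6) {
  gs <- as.data.frame(geneScores(result))
  gt <- as.data.frame(geneTable(genes))
  tss <- tssSites(genes)
  firstTss <- tss[!duplicated(mcols(tss)$gene_id)]
  gt$pos <- start(firstTss)[match(gt$gene_id, mcols(firstTss)$gene_id)]
  df <- merge(gs, gt[, c("gene_id", "name", "chrom", "biotype", "pos")], by = "gene_id")
  dropped <- nrow(gs) - nrow(df)
  if (dropped > 0) message(dropped, " scored gene(s) without model coordinates dropped")
  df <- df[order(df$chrom, df$pos, df$gene_id), , drop = FALSE]
  df$label <- df$score > threshold
  hot <- df$label & df$biotype == "protein_coding"
  for (i in which(df$label & df$biotype != "protein_coding")) {
    near <- hot & df$chrom == df$chrom[i] & abs(df$pos - df$pos[i]) <= locusWindow
    if (any(near)) df$label[i] <- FALSE
  }
  rownames(df) <- NULL
  df[, c("chrom", "pos", "gene_id", "name", "biotype", "score", "label")]
}

#' Plot a gene-level Manhattan table
#'
#' @param tab output of [manhattanTable()].
#' @param path optional file to save to (via [ggplot2::ggsave()]).
#' @return a ggplot object.
#' @export
plotManhattan <- function(tab, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab$x <- seq_len(nrow(tab))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$score,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0.3, linetype = "dashed") +
    ggplot2::geom_text(data = tab[tab$label, , drop = FALSE],
                       ggplot2::aes(label = .data$name), vjust = -0.6, size = 2.6,
                       show.legend = FALSE) +
    ggplot2::labs(x = "genes (genome order)", y = "COGS score") +
    ggplot2::ylim(0, 1.05) + ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 3.5)
  p
}
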
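## Comparison and characterisation analyses downstream of COGS scoring:
## naive nearest-exon prioritisation, set comparisons, precision-recall
## threshold calibration, preranked GSEA (weighted Kolmogorov-Smirnov running
## sum with gene-label permutations), hypergeometric over-representation and
## expression k-means clustering with silhouette-based k selection.

#' Prioritise genes above a COGS score threshold
#'
#' @param result a [CogsResult-class] or a data.frame with `gene_id`, `score`.
#' @param threshold cut-off, strict `>` (default 0.3).
#' @return character vector of gene ids.
#' @export
prioritise <- function(result, threshold = 0.3) {
  df <- if (is(result, "CogsResult")) as.data.frame(geneScores(result)) else result
  df$gene_id[df$score > threshold]
}

#' Naive nearest-exon variant-to-gene assignment
#'
#' Variants with nominal p below `pThreshold` (default 1e-8, genome-wide
#' significance) are assigned to the gene owning the nearest exon (distance 0
#' inside an exon); equidistant ties report all tied genes, flagged. Variants
#' on chromosomes without exons stay unassigned, with a reported count.
#'
#' @param gwas data.frame from [readGwas()] or [simulateGwas()].
#' @param genes a [GeneModelSet-class].
#' @param pThreshold significance cut-off on the nominal p-value.
#' @return list: `genes` (the prioritised union set), `assignments`
#'   (data.frame `variant_id, gene_id, distance, tie`).
#' @export
nearestExonAssign <- function(gwas, genes, pThreshold = 1e-8) {
  hitRows <- which(!is.na(gwas$p) & gwas$p < pThreshold)
  ex <- exonRanges(genes)
  if (length(hitRows) == 0 || length(ex) == 0)
    return(list(genes = character(0),
                assignments = data.frame(variant_id = character(0),
                                         gene_id = character(0),
                                         distance = integer(0), tie = logical(0))))
  vr <- GRanges(gwas$chrom[hitRows], IRanges(gwas$pos[hitRows], width = 1L))
  exChrom <- as.character(seqnames(ex))
  rows <- list(); unassigned <- 0L
  for (i in seq_along(vr)) {
    onChrom <- which(exChrom == as.character(seqnames(vr))[i])
    if (length(onChrom) == 0) { unassigned <- unassigned + 1L; next }
    d <- GenomicRanges::distance(rep(vr[i], length(onChrom)), ex[onChrom],
                                 ignore.strand = TRUE)
    best <- onChrom[d == min(d)]  # equidistant ties: report all tied genes
    gids <- unique(mcols(ex)$gene_id[best])
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = gwas$variant_id[hitRows][i], gene_id = gids,
      distance = min(d), tie = length(gids) > 1, stringsAsFactors = FALSE)
  }
  if (unassigned > 0)
    message(unassigned, " significant variant(s) with no exon on their chromosome")
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(variant_id = character(0), gene_id = character(0),
                     distance = integer(0), tie = logical(0))
  rownames(df) <- NULL
  list(genes = sort(unique(df$gene_id)), assignments = df)
}

#' Compare two gene sets over a universe
#'
#' @param a,b character vectors of gene ids.
#' @param universe optional universe (defaults to `union(a, b)`).
#' @return data.frame: `n_a, n_b, n_intersect, n_union, jaccard, n_universe`.
#' @export
compareSets <- function(a, b, universe = union(a, b)) {
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b)); uni <- length(union(a, b))
  data.frame(n_a = length(a), n_b = length(b), n_intersect = inter,
             n_union = uni, jaccard = if (uni == 0) NA_real_ else inter / uni,
             n_universe = length(unique(universe)))
}

#' Precision-recall curve of COGS prioritisation against a reference set
#'
#' At each threshold t, the prioritised set P(t) = genes with score > t;
#' precision = |P n R| / |P| (`NA` when P is empty), recall = |P n R| / |R|,
#' and fold-enrichment = precision / (|R| / |universe|), the lift of the
#' reference rate among prioritised genes over the background rate. By
#' default the reference is restricted to genes that received a non-zero
#' COGS score, mirroring how differential-expression references are compared
#' against scored genes only.
#'
#' @param result a [CogsResult-class] or data.frame with `gene_id`, `score`.
#' @param reference character vector of reference gene ids (e.g. DE genes).
#' @param thresholds grid over \[0, 1\].
#' @param restrictToScored restrict reference (and universe) to genes with a
#'   non-zero score (default TRUE).
#' @return data.frame: `threshold, n_prioritised, precision, recall,
#'   fold_enrichment`.
#' @export
precisionRecall <- function(result, reference, thresholds = seq(0, 1, by = 0.05),
                            restrictToScored = TRUE) {
  df <- if (is(result, "CogsResult")) as.data.frame(geneScores(result)) else result
  universe <- if (restrictToScored) df$gene_id[df$score > 0] else df$gene_id
  ref <- intersect(unique(reference), universe)
  if (length(ref) == 0) dataError("no reference genes with a COGS score")
  bg <- length(ref) / length(universe)
  rows <- lapply(thresholds, function(t) {
    p <- df$gene_id[df$score > t & df$gene_id %in% universe]
    hit <- length(intersect(p, ref))
    prec <- if (length(p) == 0) NA_real_ else hit / length(p)
    data.frame(threshold = t, n_prioritised = length(p), precision = prec,
               recall = hit / length(ref), fold_enrichment = prec / bg)
  })
  do.call(rbind, rows)
}

## weighted KS running-sum enrichment score for one set (indices into the
## ranked list); exponent 0 reduces to the classic unweighted KS statistic
esScore <- function(scores, hitIdx, exponent = 1) {
  n <- length(scores)
  hits <- logical(n); hits[hitIdx] <- TRUE
  w <- abs(scores)^exponent
  nr <- sum(w[hits])
  if (nr == 0) w[hits] <- 1 / sum(hits) else w[hits] <- w[hits] / nr
  miss <- 1 / (n - sum(hits))
  run <- cumsum(ifelse(hits, w, -miss))
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' The classic weighted Kolmogorov-Smirnov running-sum statistic on a ranked
#' gene list: walking down the ranking, hits increment the running sum
#' proportionally to |score|^exponent (normalised over the set) and misses
#' decrement it by 1/(N - Nhit); the enrichment score ES is the maximum
#' deviation. Significance comes from gene-label permutations (the only
#' scheme available for preranked input): NES = ES / mean(|permuted ES| of
#' the same sign), nominal p is the same-sign permutation tail, and FDR q
#' follows the positive/negative pool convention (the pooled permuted NES
#' tail rate divided by the observed NES tail rate, capped at 1).
#'
#' @param ranked data.frame with `gene_id` and `score`, or a named numeric
#'   vector; ranked by decreasing score internally.
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param nPerm number of gene-label permutations (default 1000).
#' @param exponent weight on |score| (default 1; 0 gives the unweighted KS).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param minSize,maxSize set-size filter after intersection with the list;
#'   a set covering the whole list is degenerate and rejected.
#' @return data.frame: `set, size, es, nes, p, fdr`.
#' @export
gseaPreranked <- function(ranked, geneSets, nPerm = 1000, exponent = 1,
                          seed = 1, minSize = 1, maxSize = Inf) {
  if (is.numeric(ranked)) ranked <- data.frame(gene_id = names(ranked), score = ranked)
  if (anyDuplicated(ranked$gene_id)) dataError("ranked list has duplicate gene ids")
  ranked <- ranked[order(-ranked$score), , drop = FALSE]
  n <- nrow(ranked)
  if (n < 2) dataError("ranked list needs at least 2 genes")
  idxSets <- lapply(geneSets, function(s) which(ranked$gene_id %in% s))
  sizes <- lengths(idxSets)
  if (any(sizes == n)) dataError("gene set covers the whole ranked list")
  keep <- sizes >= minSize & sizes <= maxSize & sizes > 0
  idxSets <- idxSets[keep]
  if (length(idxSets) == 0) dataError("no gene set passes the size filter")
  sizes <- lengths(idxSets)

  es <- vapply(idxSets, function(ix) esScore(ranked$score, ix, exponent), 0)
  set.seed(seed)
  uniqSizes <- sort(unique(sizes))
  permEs <- matrix(NA_real_, nPerm, length(uniqSizes),
                   dimnames = list(NULL, as.character(uniqSizes)))
  for (p in seq_len(nPerm)) {
    for (sz in uniqSizes)
      permEs[p, as.character(sz)] <- esScore(ranked$score, sample.int(n, sz), exponent)
  }
  nes <- numeric(length(es)); pval <- numeric(length(es))
  permNes <- matrix(NA_real_, nPerm, length(es))
  for (k in seq_along(es)) {
    pe <- permEs[, as.character(sizes[k])]
    same <- pe[sign(pe) == sign(es[k]) | es[k] == 0]
    denom <- mean(abs(same))
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(pe))
    nes[k] <- es[k] / denom
    pval[k] <- (1 + sum(abs(same) >= abs(es[k]))) / (1 + length(same))
    pos <- pe > 0; neg <- pe < 0
    permNes[pos, k] <- pe[pos] / mean(pe[pos])
    permNes[neg, k] <- pe[neg] / -mean(-pe[neg])
  }
  pool <- permNes[!is.na(permNes)]
  fdr <- vapply(seq_along(nes), function(k) {
    if (nes[k] >= 0) {
      num <- mean(pool >= nes[k]); den <- mean(nes >= nes[k])
    } else {
      num <- mean(pool <= nes[k]); den <- mean(nes <= nes[k])
    }
    min(1, num / max(den, 1 / length(nes)))
  }, 0)
  data.frame(set = names(idxSets), size = sizes, es = es, nes = nes,
             p = pval, fdr = fdr, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each annotation set's overlap with the
#' prioritised set, Benjamini-Hochberg adjusted across sets.
#'
#' @param prioritised character vector of gene ids (must lie in `universe`).
#' @param annotationSets named list of character vectors.
#' @param universe character vector of all scored genes.
#' @param alpha significance cut-off on the adjusted p (default 0.05).
#' @return data.frame: `set, n_set, n_overlap, expected, p, p_adjust,
#'   significant`, ordered by p.
#' @export
oraHypergeometric <- function(prioritised, annotationSets, universe, alpha = 0.05) {
  universe <- unique(universe)
  prioritised <- unique(prioritised)
  if (!all(prioritised %in% universe))
    dataError("prioritised genes must be a subset of the universe")
  k <- length(prioritised); N <- length(universe)
  rows <- lapply(names(annotationSets), function(nm) {
    s <- intersect(unique(annotationSets[[nm]]), universe)
    ov <- length(intersect(s, prioritised))
    p <- stats::phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_overlap = ov,
               expected = k * length(s) / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjust < alpha
  out[order(out$p), , drop = FALSE]
}

## mean silhouette width from a precomputed distance matrix
meanSilhouette <- function(d, cluster) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(cluster))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster[i]
    sizes <- table(factor(cluster, levels = ks))
    a <- if (sizes[as.character(own)] > 1)
      sum(d[i, cluster == own]) / (sizes[as.character(own)] - 1) else 0
    b <- min(vapply(setdiff(ks, own), function(kk) mean(d[i, cluster == kk]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster a gene expression matrix with silhouette-guided k-means
#'
#' Expression is z-scaled per gene across samples (constant-expression genes
#' are dropped with a reported count); k-means (25 restarts, fixed seed) is
#' run for every k in `kRange`, the returned k maximises the mean silhouette
#' width, and the elbow curve (total within-cluster sum of squares) is
#' reported alongside for inspection.
#'
#' @param expr numeric matrix, genes x samples (TPM/FPKM scale).
#' @param kRange candidate cluster counts (values >= n(genes) are skipped).
#' @param seed RNG seed.
#' @return list: `k`, `cluster` (named assignments), `silhouette` and
#'   `elbow` (data.frames over `kRange`), `scaled` (the matrix clustered).
#' @export
clusterExpression <- function(expr, kRange = 2:8, seed = 1) {
  if (nrow(expr) < 2 || ncol(expr) < 2)
    dataError("expression matrix needs at least 2 genes and 2 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant-expression gene(s) dropped from scaling")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(expr)))
  kRange <- kRange[kRange >= 2 & kRange < nrow(z)]
  if (length(kRange) == 0) dataError("no admissible k in kRange")
  d <- stats::dist(z)
  fits <- list(); sil <- numeric(length(kRange)); wss <- numeric(length(kRange))
  for (j in seq_along(kRange)) {
    set.seed(seed + kRange[j])
    fits[[j]] <- stats::kmeans(z, centers = kRange[j], nstart = 25, iter.max = 100)
    sil[j] <- meanSilhouette(d, fits[[j]]$cluster)
    wss[j] <- fits[[j]]$tot.withinss
  }
  best <- which.max(sil)
  list(k = kRange[best], cluster = fits[[best]]$cluster,
       silhouette = data.frame(k = kRange, mean_silhouette = sil),
       elbow = data.frame(k = kRange, tot_withinss = wss),
       scaled = z)
}

#' Keep genes in the top expression quantile
#'
#' @param expr numeric matrix, genes x samples.
#' @param quantile keep genes whose per-gene summary reaches at least the
#'   given quantile of summaries (default 0.75: the top 25%); boundary ties
#'   are kept, so the subset never falls below the nominal size.
#' @param summary per-gene summary statistic: `"max"` (default) or `"mean"`.
#' @return character vector of gene ids.
#' @export
topExpressionFilter <- function(expr, quantile = 0.75, summary = c("max", "mean")) {
  if (is.null(dim(expr)) || nrow(expr) == 0) dataError("empty expression matrix")
  summary <- match.arg(summary)
  s <- apply(expr, 1, summary)
  rownames(expr)[s >= stats::quantile(s, quantile)]
}
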
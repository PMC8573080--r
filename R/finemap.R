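## Wakefield approximate-Bayes-factor fine-mapping within LD blocks.
##
## For a case-control GWAS, the sampling variance of the log odds ratio at a
## variant with minor allele frequency f in N individuals of whom a fraction
## s are cases is approximately V = 1 / (2 N f (1-f) s (1-s)). With a
## Normal(0, W) prior on the true log OR, the log approximate Bayes factor
## for association is labf = [log(1 - r) + r z^2] / 2 with shrinkage
## r = W / (V + W). Under at most one causal variant per LD block, the
## posterior probability that variant i is the causal one is the
## labf-softmax within its block.

#' Sampling variance of a case-control log odds ratio
#'
#' @param maf minor allele frequency, in (0, 1).
#' @param nTotal total sample size (cases + controls).
#' @param propCases fraction of samples that are cases, in (0, 1).
#' @return `V = 1 / (2 nTotal maf (1-maf) propCases (1-propCases))`;
#'   symmetric in `maf <-> 1-maf` and `propCases <-> 1-propCases`.
#' @examples
#' caseControlVariance(0.5, 10000, 0.5)  # 8e-4
#' @export
caseControlVariance <- function(maf, nTotal, propCases) {
  if (any(maf <= 0 | maf >= 1)) dataError("maf must lie strictly in (0, 1)")
  if (any(propCases <= 0 | propCases >= 1)) dataError("propCases must lie strictly in (0, 1)")
  if (any(nTotal <= 0)) dataError("nTotal must be > 0")
  1 / (2 * nTotal * maf * (1 - maf) * propCases * (1 - propCases))
}

#' Absolute z-score from a two-sided p-value
#'
#' @param p two-sided p-value(s) in (0, 1]. A p of exactly 0 (underflow in
#'   the source file) is capped at `zMax` with a warning.
#' @param zMax cap for underflowing p.
#' @return `|z|`, the upper-tail standard-normal quantile of `p/2`.
#' @export
zFromP <- function(p, zMax = 40) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) dataError("p must lie in [0, 1]")
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 capped at |z| = ", zMax)
    z[!is.na(p) & p == 0] <- zMax
  }
  z
}

#' Wakefield log approximate Bayes factor
#'
#' @param z z-score (only |z| matters).
#' @param V sampling variance of the effect estimate (> 0), e.g. from
#'   [caseControlVariance()].
#' @param W prior variance of the true effect size (>= 0); `W = 0` is the
#'   degenerate point-null prior, giving `labf = 0`.
#' @return natural-log Bayes factor in favour of association.
#' @examples
#' wakefieldLabf(4, 0.04, 0.04)  # (log 0.5 + 0.5 * 16) / 2
#' @export
wakefieldLabf <- function(z, V, W) {
  if (any(V <= 0)) dataError("V must be > 0")
  if (any(W < 0)) dataError("W must be >= 0")
  r <- W / (V + W)
  0.5 * (log1p(-r) + r * z^2)
}

#' Per-variant posterior probabilities of causality within one LD block
#'
#' In `exactly_one_causal` mode, `ppi_i = exp(labf_i) / sum_j exp(labf_j)`
#' (log-sum-exp stabilised), so block posteriors sum to 1. In `null_model`
#' mode an additional no-causal-variant term joins the denominator with
#' prior weight `1 - m * pi0Prior` against per-variant prior `pi0Prior`
#' (m variants in the block), so posteriors sum to at most 1.
#'
#' @param labf log approximate Bayes factors of the block's variants.
#' @param config a [FinemapConfig].
#' @return numeric vector of posteriors, same length as `labf`.
#' @export
finemapBlock <- function(labf, config = FinemapConfig()) {
  if (length(labf) == 0) dataError("empty LD block")
  m <- max(labf)
  w <- exp(labf - m)
  if (config@mode == "exactly_one_causal") return(w / sum(w))
  pi0 <- config@pi0Prior
  if (length(labf) * pi0 >= 1)
    configError("pi0Prior * block size must be < 1 in null_model mode")
  pi0 * w / ((1 - length(labf) * pi0) * exp(-m) + pi0 * sum(w))
}

#' Assign variants to LD blocks
#'
#' Each variant is assigned to the unique block containing its position.
#' Variants falling in no block — including all sex-chromosome variants when
#' the block set covers autosomes only, as ldetect output does — are excluded
#' with a reported count.
#'
#' @param gwas data.frame as from [readGwas()] (1-based `pos`).
#' @param blocks an [LdBlockSet-class].
#' @return character vector of block ids, `NA` for excluded variants.
#' @export
assignBlocks <- function(gwas, blocks) {
  bl <- ldBlocks(blocks)
  vr <- GRanges(gwas$chrom, IRanges(gwas$pos, width = 1L))
  hits <- findOverlaps(vr, bl)
  if (anyDuplicated(S4Vectors::queryHits(hits)) > 0)
    dataError("LD blocks overlap: a variant maps to more than one block")
  out <- rep(NA_character_, nrow(gwas))
  out[S4Vectors::queryHits(hits)] <- mcols(bl)$block_id[S4Vectors::subjectHits(hits)]
  if (anyNA(out))
    message(sum(is.na(out)), " variant(s) outside LD blocks excluded (",
            sum(is.na(out) & gwas$sex_chrom), " on sex chromosomes)")
  out
}

#' Fine-map a GWAS across all LD blocks
#'
#' Applies, in order: the MAF filter (`mafMin`), LD-block assignment (which
#' drops variants outside blocks, notably sex chromosomes), the case-control
#' variance formula, z-scores (`beta/se` where present, else from p), the
#' Wakefield log ABF, and per-block posterior normalisation.
#'
#' @param gwas data.frame as from [readGwas()] or [simulateGwas()].
#' @param blocks an [LdBlockSet-class].
#' @param config a [FinemapConfig].
#' @return data.frame: `variant_id, chrom, pos, block_id, maf, z, V, labf, ppi`.
#' @export
runFinemap <- function(gwas, blocks, config = FinemapConfig()) {
  lowMaf <- gwas$maf < config@mafMin
  if (any(lowMaf)) {
    message(sum(lowMaf), " variant(s) below MAF ", config@mafMin, " excluded")
    gwas <- gwas[!lowMaf, , drop = FALSE]
  }
  gwas$block_id <- assignBlocks(gwas, blocks)
  gwas <- gwas[!is.na(gwas$block_id), , drop = FALSE]
  if (nrow(gwas) == 0) dataError("no variants left after filtering")
  n <- gwas$n_cases + gwas$n_controls
  if (any(gwas$n_cases <= 0 | gwas$n_controls <= 0))
    configError("case-control variance needs n_cases > 0 and n_controls > 0")
  V <- caseControlVariance(gwas$maf, n, gwas$n_cases / n)
  # effect direction is irrelevant to the ABF; beta/se takes precedence
  z <- ifelse(!is.na(gwas$beta) & !is.na(gwas$se), abs(gwas$beta / gwas$se),
              zFromP(gwas$p, config@zMax))
  labf <- wakefieldLabf(z, V, config@W)
  out <- data.frame(variant_id = gwas$variant_id, chrom = gwas$chrom,
                    pos = gwas$pos, block_id = gwas$block_id, maf = gwas$maf,
                    z = z, V = V, labf = labf, ppi = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in split(seq_len(nrow(out)), out$block_id))
    out$ppi[b] <- finemapBlock(out$labf[b], config)
  rownames(out) <- NULL
  out
}
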
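#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps reduce
#' @importFrom IRanges IRanges
NULL

REGION_CATEGORIES <- c("coding", "promoter", "interacting")

#' FragmentMap: a restriction-fragment (or bin) map with bait annotation
#'
#' Wraps a sorted, disjoint [GenomicRanges::GRanges] of restriction fragments
#' (HindIII-like) or fixed-width bins. Metadata columns: `frag_id` (stable
#' integer id), `bait` (logical: captured in the PCHi-C design), `bait_genes`
#' (";"-separated gene ids annotated on a bait, `NA` otherwise) and `virtual`
#' (logical: bait added in silico for an unassayed promoter).
#'
#' @slot fragments a `GRanges` with the metadata columns described above.
#' @export
setClass("FragmentMap", slots = c(fragments = "GRanges"))

setValidity("FragmentMap", function(object) {
  gr <- object@fragments
  need <- c("frag_id", "bait", "bait_genes", "virtual")
  if (!all(need %in% names(mcols(gr))))
    return(paste("missing mcols:", paste(setdiff(need, names(mcols(gr))), collapse = ", ")))
  if (anyDuplicated(mcols(gr)$frag_id)) return("frag_id values must be unique")
  if (length(gr) > 1) {
    if (is.unsorted(order(as.factor(seqnames(gr)), start(gr))) &&
        !identical(gr, GenomicRanges::sort(gr)))
      return("fragments must be coordinate-sorted")
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0) return("fragments must not overlap")
  }
  TRUE
})

#' LdBlockSet: an ldetect-style partition of the genome into LD blocks
#'
#' @slot blocks a `GRanges` with metadata column `block_id` (unique character).
#' @export
setClass("LdBlockSet", slots = c(blocks = "GRanges"))

setValidity("LdBlockSet", function(object) {
  gr <- object@blocks
  if (!"block_id" %in% names(mcols(gr))) return("missing mcols: block_id")
  if (anyDuplicated(mcols(gr)$block_id)) return("block_id values must be unique")
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0) return("LD blocks must not overlap")
  TRUE
})

#' GeneModelSet: gene models keyed by stable gene id
#'
#' @slot genes a `DataFrame` with columns `gene_id` (primary key), `name`,
#'   `chrom`, `strand`, `biotype`.
#' @slot tss a `GRanges` of width-1 transcription start sites, mcol `gene_id`
#'   (a gene may have several TSSs).
#' @slot exons a `GRanges` of exons, mcol `gene_id`.
#' @export
setClass("GeneModelSet", slots = c(genes = "DataFrame", tss = "GRanges", exons = "GRanges"))

setValidity("GeneModelSet", function(object) {
  need <- c("gene_id", "name", "chrom", "strand", "biotype")
  if (!all(need %in% colnames(object@genes)))
    return(paste("genes table missing:", paste(setdiff(need, colnames(object@genes)), collapse = ", ")))
  if (anyDuplicated(object@genes$gene_id)) return("gene ids must be unique")
  for (slotname in c("tss", "exons")) {
    gr <- slot(object, slotname)
    if (!"gene_id" %in% names(mcols(gr))) return(paste(slotname, "missing mcol gene_id"))
    if (!all(mcols(gr)$gene_id %in% object@genes$gene_id))
      return(paste(slotname, "refer to unknown gene ids"))
  }
  TRUE
})

#' InteractionTable: PCHi-C interaction calls with per-cell-type CHiCAGO scores
#'
#' One row per (bait, other end) pair. `scores` holds one column per cell
#' type; the conventional CHiCAGO significance cut-off is a score above 5 in
#' at least one cell type. `design` records whether other ends are restriction
#' fragments or fixed-width bins (baits are never binned).
#'
#' @slot interactions a `DataFrame` with columns `bait_id`, `oe_chrom`,
#'   `oe_start`, `oe_end` (1-based closed), `oe_id` (fragment id, `NA` for bins).
#' @slot scores numeric matrix, rows matching `interactions`, one column per cell type.
#' @slot cellTypes character vector of cell-type labels.
#' @slot design `"fragment"` or `"bin"`.
#' @export
setClass("InteractionTable",
         slots = c(interactions = "DataFrame", scores = "matrix",
                   cellTypes = "character", design = "character"))

setValidity("InteractionTable", function(object) {
  need <- c("bait_id", "oe_chrom", "oe_start", "oe_end", "oe_id")
  if (!all(need %in% colnames(object@interactions)))
    return(paste("interactions missing:", paste(setdiff(need, colnames(object@interactions)), collapse = ", ")))
  if (nrow(object@interactions) != nrow(object@scores))
    return("scores rows must match interaction rows")
  if (ncol(object@scores) != length(object@cellTypes))
    return("one score column per cell type required")
  if (nrow(object@scores) > 0 && any(object@scores < 0)) return("CHiCAGO scores must be >= 0")
  if (!object@design %in% c("fragment", "bin")) return("design must be 'fragment' or 'bin'")
  TRUE
})

#' GeneRegions: per-gene gene-associated regions with category and provenance
#'
#' Holds, for every gene, the merged intervals over which variant posteriors
#' are aggregated, in three categories: `coding` (exons), `promoter`
#' (baited fragment plus flanking fragments, including virtual baits) and
#' `interacting` (PCHi-C other ends passing the CHiCAGO threshold).
#'
#' @slot regions a `GRanges` with mcols `gene_id`, `category`, `provenance`.
#' @export
setClass("GeneRegions", slots = c(regions = "GRanges"))

setValidity("GeneRegions", function(object) {
  gr <- object@regions
  need <- c("gene_id", "category", "provenance")
  if (!all(need %in% names(mcols(gr))))
    return(paste("missing mcols:", paste(setdiff(need, names(mcols(gr))), collapse = ", ")))
  if (length(gr) > 0 && !all(mcols(gr)$category %in% REGION_CATEGORIES))
    return(paste("category must be one of", paste(REGION_CATEGORIES, collapse = "/")))
  TRUE
})

#' CogsResult: per-gene COGS scores with block and category decomposition
#'
#' The overall score `G = 1 - prod_b (1 - s_b)` over LD blocks `b`, where the
#' block score `s_b` is the summed posterior probability of causality of the
#' gene's variants in that block. `G` is the posterior probability that at
#' least one causal variant falls in at least one gene-associated region,
#' under at most one causal variant per LD block.
#'
#' @slot geneScores `DataFrame`: `gene_id`, `score`, `n_blocks`, and the share
#'   of summed posterior mass attributed to each region category
#'   (`coding_share`, `promoter_share`, `interacting_share`).
#' @slot blockScores `DataFrame`: `gene_id`, `block_id`, `score` (`s_b`).
#' @slot trait character tag for the GWAS trait scored.
#' @slot dataset character tag for the PCHi-C dataset used.
#' @export
setClass("CogsResult",
         slots = c(geneScores = "DataFrame", blockScores = "DataFrame",
                   trait = "character", dataset = "character"))

setValidity("CogsResult", function(object) {
  gs <- object@geneScores
  need <- c("gene_id", "score", "n_blocks", "coding_share", "promoter_share", "interacting_share")
  if (!all(need %in% colnames(gs)))
    return(paste("geneScores missing:", paste(setdiff(need, colnames(gs)), collapse = ", ")))
  if (nrow(gs) > 0 && (any(gs$score < 0) || any(gs$score > 1 + 1e-9)))
    return("COGS scores must lie in [0, 1]")
  bs <- object@blockScores
  if (!all(c("gene_id", "block_id", "score") %in% colnames(bs)))
    return("blockScores must have gene_id, block_id, score")
  if (nrow(bs) > 0 && (any(bs$score < 0) || any(bs$score > 1 + 1e-9)))
    return("block scores must lie in [0, 1]")
  TRUE
})

#' TruthSet: planted causal variants and their intended target genes
#'
#' @slot entries `DataFrame`: `variant_id`, `block_id`, `gene_id`, `category`
#'   (placement of the causal variant: coding/promoter/interacting/none), `beta`.
#' @export
setClass("TruthSet", slots = c(entries = "DataFrame"))

setValidity("TruthSet", function(object) {
  need <- c("variant_id", "block_id", "gene_id", "category", "beta")
  if (!all(need %in% colnames(object@entries)))
    return(paste("entries missing:", paste(setdiff(need, colnames(object@entries)), collapse = ", ")))
  ok <- c(REGION_CATEGORIES, "none")
  if (nrow(object@entries) > 0 && !all(object@entries$category %in% ok))
    return(paste("category must be one of", paste(ok, collapse = "/")))
  TRUE
})

#' FinemapConfig: priors and filters for Wakefield fine-mapping
#'
#' `W` is the prior variance of the log odds ratio at a causal variant
#' (default 0.2^2 = 0.04, the conventional prior sd 0.2). `mode` selects how
#' per-variant posteriors are normalised within an LD block:
#' `"exactly_one_causal"` renormalises Bayes factors so block posteriors sum
#' to 1; `"null_model"` adds a no-causal-variant term with per-variant prior
#' `pi0Prior`, so posteriors sum to at most 1.
#'
#' @slot W prior effect-size variance (> 0).
#' @slot mafMin minimum minor allele frequency kept before fine-mapping.
#' @slot mode `"exactly_one_causal"` or `"null_model"`.
#' @slot pi0Prior per-variant prior probability of causality (null_model mode).
#' @slot zMax cap applied to |z| when p underflows to 0.
#' @export
setClass("FinemapConfig",
         slots = c(W = "numeric", mafMin = "numeric", mode = "character",
                   pi0Prior = "numeric", zMax = "numeric"))

setValidity("FinemapConfig", function(object) {
  if (object@W <= 0) return("W must be > 0")
  if (object@mafMin < 0 || object@mafMin >= 0.5) return("mafMin must lie in [0, 0.5)")
  if (!object@mode %in% c("exactly_one_causal", "null_model"))
    return("mode must be 'exactly_one_causal' or 'null_model'")
  if (object@pi0Prior <= 0 || object@pi0Prior >= 1) return("pi0Prior must lie in (0, 1)")
  if (object@zMax <= 0) return("zMax must be > 0")
  TRUE
})

#' @rdname FinemapConfig-class
#' @param W,mafMin,mode,pi0Prior,zMax see slot documentation.
#' @export
FinemapConfig <- function(W = 0.04, mafMin = 0.01, mode = "exactly_one_causal",
                          pi0Prior = 1e-4, zMax = 40) {
  new("FinemapConfig", W = W, mafMin = mafMin, mode = mode,
      pi0Prior = pi0Prior, zMax = zMax)
}

#' RegionConfig: thresholds and options for gene-region assembly
#'
#' @slot chicagoMin CHiCAGO score an interaction must exceed in at least one
#'   cell type to contribute an interacting region (default 5, the
#'   conventional significance cut-off).
#' @slot flankCount fragments (or bins) added each side of a baited fragment
#'   for the promoter-proximal category (default 1: the immediate flanks).
#' @slot binBp bin width for binned (DpnII-style) designs, default 5000.
#' @slot useVirtualBaits add in-silico baits for promoters absent from the
#'   capture design, so their promoter-proximal variants can be scored.
#' @export
setClass("RegionConfig",
         slots = c(chicagoMin = "numeric", flankCount = "integer",
                   binBp = "integer", useVirtualBaits = "logical"))

setValidity("RegionConfig", function(object) {
  if (object@chicagoMin < 0) return("chicagoMin must be >= 0")
  if (object@flankCount < 0) return("flankCount must be >= 0")
  if (object@binBp <= 0) return("binBp must be > 0")
  TRUE
})

#' @rdname RegionConfig-class
#' @param chicagoMin,flankCount,binBp,useVirtualBaits see slot documentation.
#' @export
RegionConfig <- function(chicagoMin = 5, flankCount = 1L, binBp = 5000L,
                         useVirtualBaits = TRUE) {
  new("RegionConfig", chicagoMin = chicagoMin, flankCount = as.integer(flankCount),
      binBp = as.integer(binBp), useVirtualBaits = useVirtualBaits)
}

## ---- show methods -----------------------------------------------------------

setMethod("show", "FragmentMap", function(object) {
  gr <- object@fragments
  cat("FragmentMap with", length(gr), "fragments on",
      length(unique(as.character(seqnames(gr)))), "chromosome(s);",
      sum(mcols(gr)$bait), "baited (", sum(mcols(gr)$virtual), "virtual )\n")
})

setMethod("show", "LdBlockSet", function(object) {
  cat("LdBlockSet with", length(object@blocks), "blocks, mean width",
      round(mean(width(object@blocks))), "bp\n")
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", nrow(object@genes), "genes,",
      length(object@tss), "TSSs,", length(object@exons), "exons\n")
})

setMethod("show", "InteractionTable", function(object) {
  cat("InteractionTable (", object@design, "design):",
      nrow(object@interactions), "interactions x",
      length(object@cellTypes), "cell types\n")
})

setMethod("show", "GeneRegions", function(object) {
  tab <- table(factor(mcols(object@regions)$category, levels = REGION_CATEGORIES))
  cat("GeneRegions:", length(object@regions), "intervals for",
      length(unique(mcols(object@regions)$gene_id)), "genes (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

setMethod("show", "CogsResult", function(object) {
  gs <- object@geneScores
  cat("CogsResult [trait=", object@trait, ", dataset=", object@dataset, "]: ",
      nrow(gs), " genes, ", sum(gs$score > 0.3), " with score > 0.3\n", sep = "")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet with", nrow(object@entries), "planted effects\n")
})
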
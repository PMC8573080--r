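## Seeded synthetic genomes, PCHi-C designs and GWAS summary statistics with
## planted causal variants, so every pipeline stage is testable offline.
##
## The stated world the defaults emulate: a HindIII capture design (~4 kb
## fragments), ldetect-scale LD blocks (~2 Mb), HGI-scale case-control sizes,
## distance-decaying CHiCAGO scores, and LD modelled directly at the z-score
## level (correlation ld_decay^rank-distance to the causal variant) — COGS
## consumes summary statistics only, so no haplotypes are simulated.

#' SyntheticConfig: the generative model for synthetic pipeline inputs
#'
#' @slot nChromosomes,chromLengthBp chromosome count and common length.
#' @slot meanFragmentBp mean restriction-fragment size (HindIII-like 4000).
#' @slot binBp bin width for the binned interaction dialect (5000).
#' @slot nGenes,nCellTypes,nVariantsPerBlock,nBlocks counts; `nBlocks` is
#'   per chromosome.
#' @slot nCases,nControls GWAS sample sizes.
#' @slot plantedEffects list of [plantedEffect()] entries.
#' @slot ldDecay z-score correlation decay per rank step, in \[0, 1\].
#' @slot unbaitedFraction fraction of gene promoters left out of the capture
#'   design (default 0.2), exercising virtual-bait logic.
#' @slot maxCausalPerBlock 1 (the pipeline's own assumption) or 2 (to probe
#'   model misspecification).
#' @slot seed integer; all randomness flows from it via per-table sub-streams.
#' @export
setClass("SyntheticConfig",
  slots = c(nChromosomes = "integer", chromLengthBp = "integer",
            meanFragmentBp = "integer", binBp = "integer", nGenes = "integer",
            nCellTypes = "integer", nVariantsPerBlock = "integer",
            nBlocks = "integer", nCases = "integer", nControls = "integer",
            plantedEffects = "list", ldDecay = "numeric",
            unbaitedFraction = "numeric", maxCausalPerBlock = "integer",
            seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  counts <- c(object@nChromosomes, object@chromLengthBp, object@meanFragmentBp,
              object@binBp, object@nGenes, object@nCellTypes,
              object@nVariantsPerBlock, object@nBlocks, object@nCases,
              object@nControls)
  if (any(counts <= 0)) return("all counts and lengths must be > 0")
  if (object@ldDecay < 0 || object@ldDecay > 1) return("ldDecay must lie in [0, 1]")
  if (object@unbaitedFraction < 0 || object@unbaitedFraction > 1)
    return("unbaitedFraction must lie in [0, 1]")
  if (!object@maxCausalPerBlock %in% 1:2) return("maxCausalPerBlock must be 1 or 2")
  for (pe in object@plantedEffects) {
    if (!is.list(pe) || is.null(pe$gene) || is.null(pe$category))
      return("plantedEffects entries must come from plantedEffect()")
    if (!pe$category %in% c(REGION_CATEGORIES, "none"))
      return("planted category must be coding/promoter/interacting/none")
    if (pe$category != "none" && is.null(pe$beta) && is.null(pe$zMean))
      return("planted effect needs beta or zMean")
  }
  TRUE
})

#' @rdname SyntheticConfig-class
#' @param nChromosomes,chromLengthBp,meanFragmentBp,binBp,nGenes,nCellTypes,nVariantsPerBlock,nBlocks,nCases,nControls,plantedEffects,ldDecay,unbaitedFraction,maxCausalPerBlock,seed
#'   see slots.
#' @export
SyntheticConfig <- function(nChromosomes = 2, chromLengthBp = 4e6,
                            meanFragmentBp = 4000, binBp = 5000, nGenes = 20,
                            nCellTypes = 3, nVariantsPerBlock = 20, nBlocks = 2,
                            nCases = 49000, nControls = 2000000,
                            plantedEffects = list(), ldDecay = 0.5,
                            unbaitedFraction = 0.2, maxCausalPerBlock = 1,
                            seed = 1) {
  new("SyntheticConfig",
      nChromosomes = as.integer(nChromosomes), chromLengthBp = as.integer(chromLengthBp),
      meanFragmentBp = as.integer(meanFragmentBp), binBp = as.integer(binBp),
      nGenes = as.integer(nGenes), nCellTypes = as.integer(nCellTypes),
      nVariantsPerBlock = as.integer(nVariantsPerBlock), nBlocks = as.integer(nBlocks),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      plantedEffects = plantedEffects, ldDecay = ldDecay,
      unbaitedFraction = unbaitedFraction,
      maxCausalPerBlock = as.integer(maxCausalPerBlock), seed = as.integer(seed))
}

#' Declare a planted causal effect
#'
#' @param gene target gene: an id like `"G0003"` or a 1-based gene index.
#' @param category where the causal variant is placed relative to the target:
#'   `"coding"` (inside an exon), `"promoter"` (inside the baited promoter
#'   fragment), `"interacting"` (inside a PCHi-C other-end fragment of the
#'   target's bait, wired with a CHiCAGO score above 5), or `"none"`.
#' @param beta true log odds ratio of the causal variant.
#' @param zMean alternative to `beta`: the intended mean of the causal
#'   z-score; converted to `beta = zMean * sqrt(V)` using the planted
#'   variant's own sampling variance, so `z ~ Normal(zMean, 1)` exactly.
#' @export
plantedEffect <- function(gene, category = "interacting", beta = NULL, zMean = NULL) {
  list(gene = gene, category = category, beta = beta, zMean = zMean)
}

syntheticGeneId <- function(i) sprintf("G%04d", i)

resolvePlantedGene <- function(pe, geneIds) {
  gid <- if (is.numeric(pe$gene)) geneIds[pe$gene] else as.character(pe$gene)
  if (is.na(gid) || !gid %in% geneIds)
    dataError(paste0("planted effect targets unknown gene: ", pe$gene))
  gid
}

#' Simulate the reference layer: fragment map, LD blocks and gene models
#'
#' Restriction fragments tile each chromosome without gaps or overlaps
#' (lengths exponential around `meanFragmentBp`); `nBlocks` equal-width LD
#' blocks partition each chromosome; genes are laid out in disjoint slots
#' with a TSS, 1-6 exons and a strand. A fraction `1 - unbaitedFraction` of
#' gene promoters is flagged baited (promoters of planted promoter/
#' interacting target genes are always baited, since their effects require a
#' captured promoter); the rest are left unbaited to exercise virtual-bait
#' logic.
#'
#' @param config a [SyntheticConfig].
#' @return list with elements `fmap` ([FragmentMap-class]),
#'   `blocks` ([LdBlockSet-class]), `genes` ([GeneModelSet-class]).
#' @export
simulateReference <- function(config) {
  validObject(config)
  set.seed(subSeed(config@seed, 1))
  L <- config@chromLengthBp
  chroms <- paste0("chr", seq_len(config@nChromosomes))

  ## fragments: exponential lengths, truncated to partition [1, L]
  fragGr <- list()
  for (ci in seq_along(chroms)) {
    cuts <- integer(0); pos <- 0L
    while (pos < L) {
      len <- max(200L, as.integer(round(stats::rexp(1, 1 / config@meanFragmentBp))))
      pos <- min(pos + len, L)
      cuts <- c(cuts, pos)
    }
    starts <- c(1L, utils::head(cuts, -1) + 1L)
    fragGr[[ci]] <- GRanges(chroms[ci], IRanges(starts, cuts))
  }
  fragGr <- suppressWarnings(do.call(c, fragGr))
  mcols(fragGr)$frag_id <- seq_along(fragGr)
  mcols(fragGr)$bait <- FALSE
  mcols(fragGr)$bait_genes <- NA_character_
  mcols(fragGr)$virtual <- FALSE

  ## LD blocks: equal-width partition per chromosome
  bounds <- round(L * seq_len(config@nBlocks) / config@nBlocks)
  blkGr <- list()
  for (ci in seq_along(chroms)) {
    starts <- c(1L, utils::head(bounds, -1) + 1L)
    blkGr[[ci]] <- GRanges(chroms[ci], IRanges(starts, bounds),
                           block_id = sprintf("%s_b%02d", chroms[ci], seq_len(config@nBlocks)))
  }
  blocks <- new("LdBlockSet", blocks = suppressWarnings(do.call(c, blkGr)))

  ## genes: round-robin over chromosomes, one disjoint slot per gene
  perChrom <- table(factor(rep(seq_along(chroms), length.out = config@nGenes),
                           levels = seq_along(chroms)))
  geneRows <- list(); tssList <- list(); exonList <- list(); gi <- 0L
  for (ci in seq_along(chroms)) {
    g <- as.integer(perChrom[ci])
    if (g == 0) next
    slot <- floor((L - 100000) / g)
    for (si in seq_len(g)) {
      gi <- gi + 1L
      gid <- syntheticGeneId(gi)
      strand <- sample(c("+", "-"), 1)
      nEx <- 1L + stats::rpois(1, 2)
      widths <- as.integer(round(stats::runif(nEx, 120, 1200)))
      gaps <- if (nEx > 1) as.integer(round(stats::runif(nEx - 1, 500, 8000))) else integer(0)
      span <- sum(widths) + sum(gaps)
      slotStart <- 50000L + (si - 1L) * slot
      gstart <- slotStart + as.integer(floor(stats::runif(1, 0, max(1, slot - span - 1000))))
      exStart <- gstart + cumsum(c(0L, widths[-nEx] + gaps))
      exEnd <- exStart + widths - 1L
      tssPos <- if (strand == "+") exStart[1] else exEnd[nEx]
      biotype <- if (stats::runif(1) < 0.85) "protein_coding" else "lincRNA"
      geneRows[[gi]] <- data.frame(gene_id = gid, name = gid, chrom = chroms[ci],
                                   strand = strand, biotype = biotype)
      tssList[[gi]] <- GRanges(chroms[ci], IRanges(tssPos, width = 1L), gene_id = gid)
      exonList[[gi]] <- GRanges(chroms[ci], IRanges(exStart, exEnd), gene_id = gid)
    }
  }
  genes <- new("GeneModelSet",
               genes = DataFrame(do.call(rbind, geneRows)),
               tss = GenomicRanges::sort(suppressWarnings(do.call(c, tssList))),
               exons = GenomicRanges::sort(suppressWarnings(do.call(c, exonList))))

  ## bait assignment: per gene, keep with prob 1 - unbaitedFraction; planted
  ## promoter/interacting targets are part of the stated world and always baited
  geneIds <- genes@genes$gene_id
  for (pe in config@plantedEffects) resolvePlantedGene(pe, geneIds)
  mustBait <- vapply(Filter(function(pe) pe$category %in% c("promoter", "interacting"),
                            config@plantedEffects),
                     resolvePlantedGene, "", geneIds = geneIds)
  baited <- stats::runif(length(geneIds)) >= config@unbaitedFraction
  baited[geneIds %in% mustBait] <- TRUE
  tss <- genes@tss
  tssFrag <- mapToFragments(data.frame(chrom = as.character(seqnames(tss)),
                                       pos = start(tss)),
                            new("FragmentMap", fragments = fragGr))
  baitFrags <- unique(tssFrag[mcols(tss)$gene_id %in% geneIds[baited]])
  idx <- match(baitFrags, mcols(fragGr)$frag_id)
  mcols(fragGr)$bait[idx] <- TRUE
  # annotate each baited fragment with every gene whose TSS it contains
  ann <- vapply(baitFrags, function(f)
    paste(sort(unique(mcols(tss)$gene_id[tssFrag == f & !is.na(tssFrag)])), collapse = ";"), "")
  mcols(fragGr)$bait_genes[idx] <- ann
  fmap <- new("FragmentMap", fragments = fragGr)

  list(fmap = fmap, blocks = blocks, genes = genes)
}

## mean CHiCAGO score at distance d (bp): strong decay over ~0.5 Mb
chicagoMeanAt <- function(d) 8 * exp(-d / 5e5) + 0.5

#' Simulate PCHi-C interaction calls over a synthetic reference
#'
#' Every real baited fragment receives a Poisson number of other-end
#' fragments at exponentially distributed distances (mean 300 kb); each
#' interaction carries one CHiCAGO score per cell type, exponentially
#' distributed with mean decaying in distance, so nearby other ends score
#' systematically higher than distal ones. Interactions wired to planted
#' `interacting` target genes are guaranteed a score above 5 in at least one
#' cell type; the planted other-end fragment id per target gene is recorded
#' in `metadata(interactions(x))$planted`.
#'
#' @param config a [SyntheticConfig].
#' @param reference output of [simulateReference()].
#' @return an [InteractionTable-class] (fragment design).
#' @export
simulatePchic <- function(config, reference) {
  set.seed(subSeed(config@seed, 2))
  fr <- fragments(reference$fmap)
  geneIds <- reference$genes@genes$gene_id
  links <- baitGeneLinks(reference$fmap)
  baitIds <- unique(links$frag_id[!links$virtual])
  fmid <- (start(fr) + end(fr)) / 2
  fidx <- match(baitIds, mcols(fr)$frag_id)
  cts <- paste0("celltype_", seq_len(config@nCellTypes))

  plantedGenes <- vapply(Filter(function(pe) pe$category == "interacting",
                                config@plantedEffects),
                         resolvePlantedGene, "", geneIds = geneIds)
  for (g in plantedGenes) {
    if (!g %in% links$gene_id[!links$virtual])
      dataError(paste0("planted target gene has no baited promoter: ", g))
  }

  rows <- list(); scoreRows <- list(); k <- 0L
  planted <- data.frame(gene_id = character(0), oe_id = integer(0))
  for (bi in seq_along(baitIds)) {
    bFrag <- fidx[bi]
    chrom <- as.character(seqnames(fr))[bFrag]
    sameChrom <- which(as.character(seqnames(fr)) == chrom)
    nOE <- 1L + stats::rpois(1, 4)
    dist <- (1e4 + stats::rexp(nOE, 1 / 3e5)) * sample(c(-1, 1), nOE, replace = TRUE)
    target <- fmid[bFrag] + dist
    idx <- findInterval(target, start(fr)[sameChrom])
    ok <- idx >= 1 & target <= max(end(fr)[sameChrom])
    oe <- setdiff(unique(sameChrom[idx[ok]]), bFrag)
    baitGenes <- links$gene_id[links$frag_id == baitIds[bi] & !links$virtual]
    needPlant <- intersect(baitGenes, plantedGenes)
    for (g in needPlant) {
      # guaranteed passing interaction at 200-500 kb from the bait
      d <- stats::runif(1, 2e5, 5e5) * (if (fmid[bFrag] > 1e6) -1 else 1)
      poe <- sameChrom[findInterval(fmid[bFrag] + d, start(fr)[sameChrom])]
      oe <- setdiff(oe, poe)
      k <- k + 1L
      sc <- stats::rexp(config@nCellTypes, 1 / chicagoMeanAt(abs(d)))
      sc[sample(config@nCellTypes, 1)] <- 5.5 + stats::rexp(1, 1 / 3)
      rows[[k]] <- data.frame(bait_id = baitIds[bi], oe = poe)
      scoreRows[[k]] <- sc
      planted <- rbind(planted, data.frame(gene_id = g, oe_id = mcols(fr)$frag_id[poe]))
    }
    for (o in oe) {
      k <- k + 1L
      d <- abs(fmid[o] - fmid[bFrag])
      rows[[k]] <- data.frame(bait_id = baitIds[bi], oe = o)
      scoreRows[[k]] <- stats::rexp(config@nCellTypes, 1 / chicagoMeanAt(d))
    }
  }
  tab <- do.call(rbind, rows)
  scores <- do.call(rbind, scoreRows)
  it <- DataFrame(bait_id = tab$bait_id,
                  oe_chrom = as.character(seqnames(fr))[tab$oe],
                  oe_start = start(fr)[tab$oe], oe_end = end(fr)[tab$oe],
                  oe_id = mcols(fr)$frag_id[tab$oe])
  metadata(it)$planted <- planted
  metadata(it)$bait_coords <- data.frame(
    frag_id = mcols(fr)$frag_id, chrom = as.character(seqnames(fr)),
    start = start(fr), end = end(fr))[mcols(fr)$bait & !mcols(fr)$virtual, ]
  new("InteractionTable", interactions = it, scores = unname(scores),
      cellTypes = cts, design = "fragment")
}

#' Plan the planted truth: causal positions, blocks and effect sizes
#'
#' Chooses one causal position per planted effect inside its stated placement
#' category for the target gene (an exon for `coding`, the baited promoter
#' fragment for `promoter`, the guaranteed PCHi-C other-end fragment for
#' `interacting`), draws the causal variant's MAF, and resolves `zMean` into
#' `beta` through the case-control variance at that MAF. With
#' `maxCausalPerBlock = 1`, two planted effects falling in one LD block are
#' rejected.
#'
#' @param config a [SyntheticConfig].
#' @param reference output of [simulateReference()].
#' @param pchic output of [simulatePchic()] (needed for `interacting` placements).
#' @return a [TruthSet-class]; extra columns `chrom`, `pos`, `maf` record the
#'   planted variant itself.
#' @export
simulateTruth <- function(config, reference, pchic = NULL) {
  set.seed(subSeed(config@seed, 3))
  geneIds <- reference$genes@genes$gene_id
  fr <- fragments(reference$fmap)
  entries <- list()
  for (pe in config@plantedEffects) {
    gid <- resolvePlantedGene(pe, geneIds)
    if (pe$category == "none") next
    if (pe$category == "coding") {
      ex <- reference$genes@exons
      ex <- ex[mcols(ex)$gene_id == gid]
      pick <- ex[sample(length(ex), 1)]
      pos <- as.integer(round(stats::runif(1, start(pick), end(pick))))
      chrom <- as.character(seqnames(pick))
    } else if (pe$category == "promoter") {
      tss <- reference$genes@tss
      tss <- tss[mcols(tss)$gene_id == gid][1]
      fid <- mapToFragments(data.frame(chrom = as.character(seqnames(tss)),
                                       pos = start(tss)), reference$fmap)
      frag <- fr[match(fid, mcols(fr)$frag_id)]
      pos <- as.integer(round(stats::runif(1, start(frag), end(frag))))
      chrom <- as.character(seqnames(frag))
    } else { # interacting
      if (is.null(pchic)) configError("interacting placements need the PCHi-C table")
      pl <- metadata(interactions(pchic))$planted
      oe <- pl$oe_id[pl$gene_id == gid]
      if (length(oe) == 0)
        dataError(paste0("no planted interaction recorded for gene: ", gid))
      frag <- fr[match(oe[1], mcols(fr)$frag_id)]
      pos <- as.integer(round(stats::runif(1, start(frag), end(frag))))
      chrom <- as.character(seqnames(frag))
    }
    bl <- ldBlocks(reference$blocks)
    hit <- findOverlaps(GRanges(chrom, IRanges(pos, width = 1L)), bl)
    blockId <- mcols(bl)$block_id[S4Vectors::subjectHits(hit)][1]
    maf <- stats::runif(1, 0.05, 0.5)
    beta <- pe$beta
    if (is.null(beta)) {
      V <- caseControlVariance(maf, config@nCases + config@nControls,
                               config@nCases / (config@nCases + config@nControls))
      beta <- pe$zMean * sqrt(V)
    }
    entries[[length(entries) + 1]] <- data.frame(
      variant_id = sprintf("rs_%s_%d", chrom, pos), block_id = blockId,
      gene_id = gid, category = pe$category, beta = beta,
      chrom = chrom, pos = pos, maf = maf, stringsAsFactors = FALSE)
  }
  entries <- if (length(entries)) do.call(rbind, entries)
             else data.frame(variant_id = character(0), block_id = character(0),
                             gene_id = character(0), category = character(0),
                             beta = numeric(0), chrom = character(0),
                             pos = integer(0), maf = numeric(0))
  dup <- table(entries$block_id)
  if (config@maxCausalPerBlock == 1L && any(dup > 1))
    configError(paste0("two planted causals in one LD block (",
                       names(dup)[dup > 1][1], "); set maxCausalPerBlock = 2"))
  if (any(dup > 2)) configError("at most two causals per block are supported")
  new("TruthSet", entries = DataFrame(entries))
}

#' Simulate GWAS summary statistics with planted causal variants
#'
#' Per LD block, `nVariantsPerBlock` variants at uniform positions (one is
#' moved onto each planted causal position). The causal variant's z-score is
#' drawn as `z ~ Normal(beta / sqrt(V), 1)` with `V` from the case-control
#' variance formula at its MAF; a non-causal variant at rank distance `k`
#' from the causal gets `z ~ Normal(ldDecay^k * beta / sqrt(V_causal), 1)`.
#' Blocks without a planted causal are pure null (`z ~ Normal(0, 1)`). MAF is
#' Uniform(0.05, 0.5); the two-sided p comes from `|z|`; `beta_hat = z
#' sqrt(V)` and `se = sqrt(V)` are emitted so either column route can be
#' exercised downstream.
#'
#' @param config a [SyntheticConfig].
#' @param reference output of [simulateReference()].
#' @param truth a [TruthSet-class] from [simulateTruth()].
#' @return data.frame in the canonical GWAS layout of [readGwas()].
#' @export
simulateGwas <- function(config, reference, truth = NULL) {
  if (length(config@plantedEffects) > 0 &&
      any(vapply(config@plantedEffects, function(pe) pe$category != "none", TRUE)) &&
      is.null(truth))
    configError("planted effects require a TruthSet (simulateTruth)")
  if (config@nCases == 0 && length(config@plantedEffects) > 0)
    configError("planted beta given with n_cases = 0")
  set.seed(subSeed(config@seed, 4))
  te <- if (is.null(truth)) NULL else as.data.frame(truthEntries(truth))
  bl <- ldBlocks(reference$blocks)
  nTot <- config@nCases + config@nControls
  propCases <- config@nCases / nTot
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(bl))
  for (i in seq_along(bl)) {
    blockId <- mcols(bl)$block_id[i]
    chrom <- as.character(seqnames(bl))[i]
    m <- config@nVariantsPerBlock
    pos <- sort(as.integer(round(stats::runif(m, start(bl)[i], end(bl)[i]))))
    maf <- stats::runif(m, 0.05, 0.5)
    causalRows <- integer(0); betas <- numeric(0)
    if (!is.null(te)) {
      tb <- te[te$block_id == blockId, , drop = FALSE]
      for (j in seq_len(nrow(tb))) {
        free <- setdiff(seq_len(m), causalRows)
        row <- free[which.min(abs(pos[free] - tb$pos[j]))]
        pos[row] <- tb$pos[j]
        maf[row] <- tb$maf[j]
        causalRows <- c(causalRows, row); betas <- c(betas, tb$beta[j])
      }
      # restore position order so rank distance reflects physical order
      ord <- order(pos)
      causalRows <- match(causalRows, ord)
      pos <- pos[ord]; maf <- maf[ord]
    }
    V <- caseControlVariance(maf, nTot, propCases)
    zMean <- numeric(m)
    for (j in seq_along(causalRows)) {
      mu <- betas[j] / sqrt(V[causalRows[j]])
      zMean <- zMean + config@ldDecay^abs(seq_len(m) - causalRows[j]) * mu
    }
    z <- stats::rnorm(m, zMean, 1)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    out[[i]] <- data.frame(
      variant_id = sprintf("rs_%s_%d", chrom, pos), chrom = chrom, pos = pos,
      ref = ref, alt = alt, p = 2 * stats::pnorm(-abs(z)),
      beta = z * sqrt(V), se = sqrt(V), maf = maf,
      n_cases = as.numeric(config@nCases), n_controls = as.numeric(config@nControls),
      stringsAsFactors = FALSE)
  }
  gwas <- do.call(rbind, out)
  # duplicate positions can arise from uniform draws; keep planted rows,
  # otherwise the row with the smallest p (deterministic, conservative)
  key <- paste(gwas$chrom, gwas$pos)
  if (anyDuplicated(key)) {
    planted <- gwas$variant_id %in% te$variant_id
    ord <- order(key, !planted, gwas$p)
    gwas <- gwas[ord, ][!duplicated(key[ord]), , drop = FALSE]
    gwas <- gwas[order(gwas$chrom, gwas$pos), , drop = FALSE]
  }
  gwas$sex_chrom <- isSexChrom(gwas$chrom)
  rownames(gwas) <- NULL
  gwas
}

#' Simulate a complete, self-consistent synthetic dataset
#'
#' Runs [simulateReference()], [simulatePchic()], [simulateTruth()] and
#' [simulateGwas()] off one seed (per-table sub-streams), plus a synthetic
#' expression matrix with planted cluster structure for the downstream
#' analyses.
#'
#' @param config a [SyntheticConfig].
#' @return list: `fmap`, `blocks`, `genes`, `interactions`, `truth`, `gwas`,
#'   `expression`, and the `config` used.
#' @export
simulateCogsData <- function(config = SyntheticConfig()) {
  reference <- simulateReference(config)
  pchic <- simulatePchic(config, reference)
  truth <- simulateTruth(config, reference, pchic)
  gwas <- simulateGwas(config, reference, truth)
  expr <- simulateExpression(config, reference)
  c(reference, list(interactions = pchic, truth = truth, gwas = gwas,
                    expression = expr, config = config))
}

#' Simulate a gene-by-sample expression matrix with cluster structure
#'
#' Genes are split into `nClusters` groups; each group is highly expressed
#' (TPM-scale lognormal around `highTpm`) in its own subset of samples and at
#' baseline elsewhere, emulating the tissue-restricted expression blocks seen
#' in consortium data.
#'
#' @param config a [SyntheticConfig].
#' @param reference output of [simulateReference()].
#' @param nSamples,nClusters,highTpm,baselineTpm generator knobs.
#' @return numeric matrix (genes x samples), TPM-like units.
#' @export
simulateExpression <- function(config, reference, nSamples = 12, nClusters = 3,
                               highTpm = 100, baselineTpm = 2) {
  set.seed(subSeed(config@seed, 5))
  gid <- reference$genes@genes$gene_id
  cl <- rep_len(seq_len(nClusters), length(gid))
  sampleCl <- rep_len(seq_len(nClusters), nSamples)
  mu <- matrix(baselineTpm, length(gid), nSamples)
  mu[outer(cl, sampleCl, "==")] <- highTpm
  m <- matrix(stats::rlnorm(length(mu), log(mu), 0.4), nrow(mu), ncol(mu))
  dimnames(m) <- list(gid, paste0("sample_", seq_len(nSamples)))
  m
}

#' Write a simulated dataset to disk in its native file dialects
#'
#' Emits: GWAS TSV (HGI release-5 dialect), rmap/baitmap, interaction table
#' (peak-matrix-like TSV, fragment dialect, plus a binned version), LD-block
#' BED, gene models BED12, expression TSV, truth TSV and a JSON run manifest.
#'
#' @param sim output of [simulateCogsData()].
#' @param dir output directory (created if needed).
#' @param gzip gzip the larger TSVs.
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulation <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  z <- if (gzip) ".gz" else ""
  paths <- c(gwas = file.path(dir, paste0("gwas.tsv", z)),
             rmap = file.path(dir, "fragments.rmap"),
             baitmap = file.path(dir, "fragments.baitmap"),
             interactions = file.path(dir, paste0("interactions.tsv", z)),
             interactions_binned = file.path(dir, paste0("interactions_binned.tsv", z)),
             ld_blocks = file.path(dir, "ld_blocks.bed"),
             genes = file.path(dir, "genes.bed12"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.json"))
  writeGwas(sim$gwas, paths["gwas"], dialect = "hgi_r5")
  writeRmapBaitmap(sim$fmap, paths["rmap"], paths["baitmap"])
  writeInteractions(sim$interactions, paths["interactions"])
  writeInteractions(binOtherEnds(sim$interactions, sim$config@binBp),
                    paths["interactions_binned"])
  writeBed(sim$blocks, paths["ld_blocks"])
  writeGeneModelsBed12(sim$genes, paths["genes"])
  writeExpression(sim$expression, paths["expression"])
  writeTsv(as.data.frame(truthEntries(sim$truth)), paths["truth"])
  cfg <- sim$config
  manifest <- sprintf(paste0(
    '{\n  "generator": "cogsr",\n  "seed": %d,\n  "n_chromosomes": %d,\n',
    '  "chrom_length_bp": %d,\n  "n_genes": %d,\n  "n_blocks_per_chrom": %d,\n',
    '  "n_variants_per_block": %d,\n  "n_cell_types": %d,\n',
    '  "n_cases": %d,\n  "n_controls": %d,\n  "planted_effects": %d\n}'),
    cfg@seed, cfg@nChromosomes, cfg@chromLengthBp, cfg@nGenes, cfg@nBlocks,
    cfg@nVariantsPerBlock, cfg@nCellTypes, cfg@nCases, cfg@nControls,
    length(cfg@plantedEffects))
  writeLines(manifest, paths["manifest"])
  invisible(paths)
}
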
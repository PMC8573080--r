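---
title: "Gene prioritisation from GWAS summary statistics and Promoter Capture Hi-C: model and methods"
author: "cogsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene prioritisation from GWAS and PCHi-C: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogsr)
```

## The problem

Most GWAS variants fall in non-coding regulatory DNA, often hundreds of
kilobases from the genes they control, reaching their target promoters
through 3D chromosomal contacts. Promoter Capture Hi-C (PCHi-C) measures
those contacts at restriction-fragment resolution: each *bait* (a captured,
promoter-containing fragment) is paired with *other-end* fragments it
touches, with a CHiCAGO confidence score per cell type. The COGS (Capture
Hi-C Omnibus Gene Score) approach turns a GWAS plus a PCHi-C interaction
pool into a per-gene probability of harbouring a causal variant, giving a
principled variant-to-gene assignment that a nearest-gene heuristic cannot.

## The model

**Fine-mapping.** For a case-control GWAS with $N$ samples, case fraction
$s$, and a variant of minor allele frequency $f$, the sampling variance of
the log odds ratio is approximately

$$V = \frac{1}{2\,N\,f(1-f)\,s(1-s)}.$$

With a $\mathrm{Normal}(0, W)$ prior on the true log OR (default
$W = 0.2^2 = 0.04$, the conventional prior sd for complex-trait log odds
ratios), the log approximate Bayes factor for association at a variant with
z-score $z$ is

$$\log \mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right],
\qquad r = \frac{W}{V+W}.$$

Under the assumption of at most one causal variant per LD block (blocks from
an ldetect-style partition; the partitions exclude sex chromosomes, so
sex-chromosome variants are dropped at block assignment), the posterior
probability that variant $i$ is the causal one in its block is the softmax
of the log ABFs. Two normalisations are provided because "at most one" is
compatible with either reading: `exactly_one_causal` (default; posteriors
sum to 1 in every block) and `null_model` (an explicit no-causal term with
per-variant prior `pi0Prior` joins the denominator, so posteriors sum to at
most 1). The default is a documented package choice, not a claim about any
particular published run.

**Gene-associated regions.** Every gene collects three region categories:

* *coding* — the union of its annotated exons (all transcripts; the source
  annotation rarely distinguishes CDS reliably across biotypes, so exon
  union is the default);
* *promoter* — each baited promoter fragment plus `flankCount` flanking
  fragments per side (default 1: the immediate flanks). Promoters absent
  from the capture design receive *virtual baits* so their proximal variants
  can still be scored; virtual baits carry no interactions. A promoter whose
  TSS lands on an already-captured fragment shares that fragment's bait —
  and hence its interactions — exactly as co-baited promoters do in real
  designs;
* *interacting* — every other end whose CHiCAGO score exceeds 5 (strictly)
  in at least one cell type of the dataset, pooled across cell types.
  DpnII-style designs are handled by snapping other ends to 5-kb bins
  (baits stay unbinned), max-pooling scores within a bin.

All interval arithmetic is half-open with respect to the source files'
0-based coordinates: a position sitting exactly on a fragment's end
boundary belongs to the next fragment. Internally this is realised with
1-based closed `GRanges`, converting once at load time. Virtual baits are
flanked identically to real baits, including in the binned design (the
neighbouring bins), a choice made once and applied uniformly.

**Score aggregation.** Within block $b$, the events "variant $i$ is causal"
are mutually exclusive, so the probability that the block's causal variant
falls inside the gene's regions is the plain sum $s_b = \sum_i \pi_i$ over
the gene's variants there (clamped at 1 against floating-point overshoot).
A variant falling in several categories or regions of one gene counts once
(these are probabilities, not evidence weights); for the per-category
decomposition its mass is attributed by the precedence coding > promoter >
interacting. Blocks are treated as independent, so

$$G = 1 - \prod_b (1 - s_b)$$

is the probability of at least one causal variant in at least one
gene-associated region — the COGS score. Genes may legitimately share
regions (shared baits, shared enhancers) and then share posterior mass; no
attempt is made to fine-map a peak to a single top gene. Prioritisation
uses the conventional strict threshold $G > 0.3$; scores are reported at 6
decimals and compared at 1e-9 in tests.

## The synthetic world

The generator exists so every stage is testable offline with planted ground
truth. Its defaults state a world chosen once, on realism grounds:

* HindIII-like fragments, exponential lengths with mean 4,000 bp, tiling
  each chromosome exactly; 5-kb bins for the DpnII-style dialect.
* LD blocks of ~2 Mb (two per 4-Mb chromosome), the ldetect scale; 20
  variants per block; MAF ~ Uniform(0.05, 0.5).
* HGI-scale sample sizes (49,000 cases / 2,000,000 controls).
* CHiCAGO scores exponentially distributed with a mean decaying over
  ~0.5 Mb of bait distance, so proximal contacts score systematically
  higher; ~5 other ends per bait at exponentially distributed distances
  (mean 300 kb).
* 20% of promoters left unbaited, to exercise virtual-bait logic.
* LD is modelled at the z-score level: the causal variant draws
  $z \sim \mathrm{Normal}(\beta/\sqrt{V}, 1)$ and a variant at rank
  distance $k$ draws $z \sim \mathrm{Normal}(\lambda^k \beta/\sqrt{V_c},
  1)$ with decay $\lambda = 0.5$ — the realistic correlation between
  variants sampled ~100 kb apart, and the regime in which a planted causal
  is recoverable at all (at $\lambda$ near 1 the causal and its neighbour
  are statistically exchangeable by construction, and no method could
  separate them). COGS consumes only summary statistics, so no haplotypes
  are simulated.
* A planted effect can be stated as `beta` or as `zMean`; the latter is
  converted through the planted variant's own sampling variance
  ($\beta = z_\mathrm{mean}\sqrt{V}$), pinning the causal z-score mean
  where a test states it.
* All randomness flows from one seed through per-table sub-streams; the
  same config is byte-identical on disk across runs.
* One causal per block, mirroring the model's own assumption; a
  `maxCausalPerBlock = 2` switch exists to probe misspecification.

What the generator does **not** emulate: realistic allele-frequency spectra,
haplotype structure and imputation artefacts, coverage-driven CHiCAGO score
calibration, trans-chromosomal contacts, or gene-density and TAD structure.
A green recovery test therefore establishes that the pipeline's arithmetic
and plumbing recover planted signal under its own model assumptions — not
that those assumptions hold in any real dataset.

## Downstream analyses

* **Nearest-exon baseline** — variants with $p < 10^{-8}$ assigned to the
  gene of the closest exon (distance to the exon boundary, not the TSS);
  equidistant ties report all tied genes with a flag, since no standard tie
  rule exists.
* **Precision-recall calibration** — against a reference set (e.g.
  differentially expressed genes), sweeping the score threshold over
  $[0, 1]$: precision $|P \cap R|/|P|$, recall $|P \cap R|/|R|$, and
  fold-enrichment over the background rate. The reference is restricted by
  default to genes with a non-zero score (configurable), so the comparison
  is among genes the method could in principle return.
* **Preranked GSEA** — the weighted Kolmogorov–Smirnov running-sum
  statistic (weight exponent 1 by default, the standard choice; 0 gives
  the classic KS), gene-label permutations (the only scheme defined for a
  preranked list), NES normalised by the mean same-sign permuted ES, and
  FDR by the pooled positive/negative-tail convention. The seed is a
  mandatory argument.
* **Hypergeometric ORA** — upper-tail test per annotation set with
  Benjamini–Hochberg adjustment, significant at adjusted $p < 0.05$.
* **Expression clustering** — per-gene z-scaling, k-means with 25 restarts
  at a fixed seed over a k grid; k is selected by maximal mean silhouette
  width, with the elbow (within-cluster SS) curve emitted for inspection
  only — the two criteria are named jointly in common practice without an
  arbitration rule, so one had to be primary. A top-quantile expression
  filter (per-gene max by default; mean available, as sources differ on
  this) mirrors restricting such analyses to well-expressed genes; boundary
  ties are kept.

## Numerical choices and degenerate inputs

* Log-sum-exp stabilisation everywhere Bayes factors are normalised; ties
  in log ABF give exactly equal posteriors.
* `W = 0` gives $\log\mathrm{ABF} = 0$ for every variant (degenerate
  point-null prior); boundary MAF or case fractions are domain errors.
* $p = 0$ (underflow in source files) caps $|z|$ at `zMax` (default 40)
  with a warning when converted, but a literal $p = 0$ row in a GWAS file
  is dropped at load as invariant-violating.
* When both $p$ and $\beta/\mathrm{se}$ are present, $\beta/\mathrm{se}$
  wins (direction is irrelevant; only $|z|$ enters the ABF).
* Variants below `mafMin` (default 0.01) are excluded before fine-mapping:
  the variance approximation degenerates at rare alleles.
* Duplicate variant positions keep the row with the smallest p
  (deterministic and conservative); malformed input lines raise typed
  errors naming the line, never a silent partial load.
* Constant-expression genes are dropped before z-scaling; empty LD blocks
  and empty ranked lists are errors, not zeros.

## A worked example

```{r example, eval = FALSE}
cfg <- SyntheticConfig(seed = 7, plantedEffects = list(
  plantedEffect(3, "interacting", zMean = 8)))
sim <- simulateCogsData(cfg)
res <- runCogs(sim$gwas, sim$fmap, sim$interactions, sim$blocks, sim$genes,
               trait = "synthetic", dataset = "fragment")
head(as.data.frame(geneScores(res))[order(-geneScores(res)$score), ])
```

The planted target attains the top genome-wide score with its mass in the
interacting category; see the README for printed output, and
`scripts/acceptance.R` for the full seeded end-to-end run (both PCHi-C
dialects, run combination and precision-recall calibration).

## Known limitations

* Single-causal fine-mapping only; no LD-matrix-based multi-causal
  modelling. Strong violations (two causals per block) dilute, and can
  split, posterior mass — the generator's misspecification switch lets you
  observe this.
* Block independence is assumed exactly; real adjacent blocks retain
  residual LD.
* The case-control variance approximation degrades for rare variants and
  extreme case fractions.
* Scores are pooled across cell types within a dataset; no cell-type
  specificity is claimed for any single gene.
* GTF parsing requires `gene_id` attributes; transcript-level TSSs are
  used when transcript features are present, else gene starts.
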
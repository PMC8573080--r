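test_that("prioritisation uses a strict threshold", {
  df <- data.frame(gene_id = c("A", "B", "C"), score = c(0.31, 0.30, 0.29))
  expect_equal(prioritise(df, 0.3), "A")
  expect_setequal(prioritise(df, 0), c("A", "B", "C"))
  expect_equal(prioritise(df, 1), character(0))
})

test_that("nearest-exon assignment handles containment, distance and ties", {
  genes <- toyGenes(list(
    GA = list(exons = list(c(1000, 2000))),
    GB = list(exons = list(c(2400, 3000)))))
  gwas <- data.frame(
    variant_id = c("in_exon", "nearer_a", "tie", "weak"),
    chrom = "chr1", pos = c(1500, 2100, 2200, 1200),
    p = c(1e-10, 1e-9, 1e-12, 0.5))
  out <- nearestExonAssign(gwas, genes, pThreshold = 1e-8)
  asg <- out$assignments
  expect_equal(asg$gene_id[asg$variant_id == "in_exon"], "GA")
  expect_equal(asg$distance[asg$variant_id == "in_exon"], 0)
  expect_equal(asg$gene_id[asg$variant_id == "nearer_a"], "GA")  # 100 vs 300 bp
  # pos 2200: 200 bp from GA's exon end, 200 bp from GB's start -> both, flagged
  tie <- asg[asg$variant_id == "tie", ]
  expect_setequal(tie$gene_id, c("GA", "GB"))
  expect_true(all(tie$tie))
  expect_false("weak" %in% asg$variant_id)  # p above threshold
  expect_setequal(out$genes, c("GA", "GB"))
})

test_that("set comparison reports exact overlap counts", {
  cmp <- compareSets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(cmp$n_intersect, 2)
  expect_equal(cmp$jaccard, 0.5)
  expect_equal(compareSets(c("a", "b"), c("a", "b"))$jaccard, 1)
  expect_equal(compareSets("a", "b")$n_intersect, 0)
})

test_that("precision-recall matches enumeration and is monotone in threshold", {
  df <- data.frame(gene_id = c("A", "B", "C", "D"), score = c(0.9, 0.5, 0.4, 0.1))
  pr <- precisionRecall(df, reference = c("A", "C"), thresholds = c(0, 0.3, 0.45, 0.95))
  expect_equal(pr$precision[pr$threshold == 0.3], 2 / 3)
  expect_equal(pr$recall[pr$threshold == 0.3], 1)
  expect_equal(pr$recall[pr$threshold == 0], 1)
  # reference = universe: precision 1 wherever any gene is prioritised
  prU <- precisionRecall(df, reference = df$gene_id, thresholds = c(0, 0.5))
  expect_true(all(prU$precision == 1))
  # fold-enrichment at threshold 0 is the background rate ratio, i.e. 1
  expect_equal(pr$fold_enrichment[pr$threshold == 0], 1)
  # property: recall and n_prioritised non-increasing over random instances
  set.seed(7)
  for (i in 1:20) {
    d <- data.frame(gene_id = paste0("g", 1:50), score = runif(50))
    p <- precisionRecall(d, sample(d$gene_id, 12), thresholds = seq(0, 1, 0.1))
    expect_true(all(diff(p$recall) <= 1e-12))
    expect_true(all(diff(p$n_prioritised) <= 0))
  }
})

test_that("GSEA enrichment scores match a brute-force running sum", {
  # independent O(N) oracle, recomputed per position
  bruteEs <- function(scores, hits, w) {
    n <- length(scores)
    nr <- sum(abs(scores[hits])^w)
    best <- 0
    run <- 0
    for (i in seq_len(n)) {
      run <- run + if (i %in% hits) abs(scores[i])^w / nr else -1 / (n - length(hits))
      if (abs(run) > abs(best)) best <- run
    }
    best
  }
  scores <- c(5, 4, 3.5, 2, 1.5, 1, 0.5, 0.2)
  ranked <- data.frame(gene_id = paste0("g", 1:8), score = scores)
  for (hits in list(c(1, 2, 3), c(6, 7, 8), c(1, 5, 8))) {
    sets <- list(S = paste0("g", hits))
    for (w in c(0, 1)) {
      got <- gseaPreranked(ranked, sets, nPerm = 10, exponent = w, seed = 1)
      expect_equal(got$es, bruteEs(scores, hits, w), tolerance = 1e-12)
    }
  }
  # extreme case: the set containing only the top gene, exponent 0 -> ES = 1
  top <- gseaPreranked(ranked, list(S = "g1"), nPerm = 10, exponent = 0, seed = 1)
  expect_equal(top$es, 1)
  # reversing the ranking flips the sign of ES
  fwd <- gseaPreranked(ranked, list(S = paste0("g", c(1, 2, 3))),
                       nPerm = 10, exponent = 1, seed = 1)
  rev <- gseaPreranked(transform(ranked, score = -score),
                       list(S = paste0("g", c(1, 2, 3))),
                       nPerm = 10, exponent = 1, seed = 1)
  expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
  expect_true(abs(fwd$es) <= 1)
  expect_error(gseaPreranked(ranked, list(S = ranked$gene_id), nPerm = 5),
               "whole ranked list", class = "cogsr_data_error")
})

test_that("GSEA nominal p-values are uniform for random gene sets", {
  set.seed(21)
  scores <- sort(rexp(60), decreasing = TRUE)
  ranked <- data.frame(gene_id = paste0("g", 1:60), score = scores)
  ps <- vapply(1:300, function(i) {
    s <- list(S = sample(ranked$gene_id, 8))
    gseaPreranked(ranked, s, nPerm = 199, seed = 1e6 + i)$p
  }, 0)
  # permutation p-values are discrete: tie warning from ks.test is expected
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("hypergeometric ORA matches combinatorics and BH adjustment", {
  universe <- paste0("g", 1:20)
  res <- oraHypergeometric(paste0("g", 1:5), list(S = paste0("g", 1:5)), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 6.449e-5, tolerance = 1e-3)
  # exhaustive-enumeration oracle on a small universe
  enumP <- function(nSet, nPick, minOv, N) {
    sum(vapply(minOv:min(nSet, nPick), function(k)
      choose(nSet, k) * choose(N - nSet, nPick - k), 0)) / choose(N, nPick)
  }
  set.seed(5)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- paste0("u", seq_len(N))
    s <- sample(uni, sample(2:(N - 2), 1))
    p <- sample(uni, sample(2:(N - 2), 1))
    got <- oraHypergeometric(p, list(S = s), uni)
    expect_equal(got$p, enumP(length(s), length(p), got$n_overlap, N),
                 tolerance = 1e-12)
  }
  # BH on three sets with p = .01/.02/.03 adjusts all to .03
  ps <- c(0.01, 0.02, 0.03)
  sets <- list(A = paste0("g", 1:3), B = paste0("g", 1:9), C = paste0("g", 1:2))
  expect_equal(p.adjust(ps, "BH"), rep(0.03, 3))
  mid <- oraHypergeometric(paste0("g", 1:5), list(S = paste0("g", 4:12)), universe)
  expect_gt(mid$p, 0.05)  # overlap near expectation: not significant
})

test_that("k-means with silhouette selection recovers planted expression blocks", {
  set.seed(3)
  m <- rbind(
    matrix(rnorm(20 * 6, mean = rep(c(10, 0), each = 3 * 20)), 20, 6),
    matrix(rnorm(20 * 6, mean = rep(c(0, 10), each = 3 * 20)), 20, 6))
  rownames(m) <- paste0("g", 1:40)
  colnames(m) <- paste0("s", 1:6)
  m <- abs(m)
  cl <- clusterExpression(m, kRange = 2:6, seed = 9)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$cluster[1:20])), 1)
  expect_equal(length(unique(cl$cluster[21:40])), 1)
  expect_false(cl$cluster[1] == cl$cluster[21])
  # permuting sample order leaves the clustering untouched
  cl2 <- clusterExpression(m[, c(4, 1, 6, 2, 3, 5)], kRange = 2:6, seed = 9)
  expect_equal(cl2$cluster, cl$cluster)
  # constant gene dropped with a message; k-range guard rejects k >= n
  m2 <- rbind(m, gconst = rep(5, 6))
  expect_message(clusterExpression(m2, kRange = 2:3, seed = 1), "constant")
  expect_error(clusterExpression(m[1:3, ], kRange = 5), class = "cogsr_data_error")
})

test_that("top-expression filter keeps the stated quantile with ties", {
  m <- matrix(seq_len(300), nrow = 100)   # distinct per-gene maxima
  rownames(m) <- paste0("g", 1:100)
  expect_equal(length(topExpressionFilter(m, 0.75)), 25)
  flat <- matrix(1, nrow = 10, ncol = 3, dimnames = list(paste0("g", 1:10), NULL))
  expect_equal(length(topExpressionFilter(flat, 0.75)), 10)  # ties kept
  expect_error(topExpressionFilter(matrix(numeric(0), 0, 0)),
               class = "cogsr_data_error")
})
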
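test_that("target sets indistinguishable from background are not called shifted", {
  set.seed(21)
  vals <- rnorm(50, 0, 0.1)
  tbl <- toy_diff_table(paste0("g", 1:50), vals)
  targets <- paste0("g", 1:10)
  tbl$log2_ratio[1:10] <- sample(vals[11:50], 10)  # same distribution
  res <- target_set_shift(tbl, targets, abundance_floor = 0)
  expect_gt(res$p, 0.05)
  # exactly equal values: mean difference 0, p = 1 by the degenerate branch
  tbl2 <- toy_diff_table(paste0("g", 1:6), rep(0.4, 6))
  res2 <- target_set_shift(tbl2, paste0("g", 1:3), abundance_floor = 0)
  expect_equal(res2$mean_log2 - mean(tbl2$log2_ratio[4:6]), 0)
  expect_gte(res2$p, 0.99)
})

test_that("the confidence band is mean +/- 1.96 x SD, degenerate when SD = 0", {
  tbl <- toy_diff_table(paste0("g", 1:6), c(1, 1, 1, 0, 0.2, -0.2))
  res <- target_set_shift(tbl, paste0("g", 1:3), abundance_floor = 0)
  expect_equal(res$mean_log2, 1)
  expect_equal(res$sd_log2, 0)
  expect_equal(c(res$ci_lo, res$ci_hi), c(1, 1))
})

test_that("the pooled Student t matches the textbook formula to 1e-10", {
  targets_lr <- c(0.8, 1.0, 1.2)
  bg_lr <- c(-0.1, 0.0, 0.1, 0.0)
  tbl <- toy_diff_table(paste0("g", 1:7), c(targets_lr, bg_lr))
  res <- target_set_shift(tbl, paste0("g", 1:3), abundance_floor = 0)
  n1 <- 3; n2 <- 4
  sp2 <- ((n1 - 1) * var(targets_lr) + (n2 - 1) * var(bg_lr)) / (n1 + n2 - 2)
  t_or <- (mean(targets_lr) - mean(bg_lr)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_or <- 2 * pt(-abs(t_or), n1 + n2 - 2)
  expect_equal(res$t, t_or, tolerance = 1e-10)
  expect_equal(res$p, p_or, tolerance = 1e-10)
})

test_that("the abundance floor removes low-TPM genes before the activity test", {
  tbl <- toy_diff_table(paste0("g", 1:8), c(2, 2, 2, 0, 0, 0, 0, 0),
                        mean_abundance = c(0.5, 10, 10, 10, 10, 10, 10, 0.2))
  res <- target_set_shift(tbl, paste0("g", 1:3))  # default floor 1 (TPM)
  expect_equal(res$n_targets_used, 2)
  res0 <- target_set_shift(tbl, paste0("g", 1:3), abundance_floor = 0)
  expect_equal(res0$n_targets_used, 3)
})

test_that("fewer than two usable targets yields a flagged result, not an error", {
  tbl <- toy_diff_table(paste0("g", 1:5), c(1, 0, 0, 0, 0),
                        mean_abundance = c(10, 0.1, 10, 10, 10))
  expect_warning(res <- target_set_shift(tbl, c("g1", "g2")), "fewer than 2")
  expect_true(res$low_targets)
  expect_true(is.na(res$p))
  expect_equal(res$mean_log2, 1)
})

test_that("ranking metric combines FDR and direction as signed -log10", {
  tbl <- toy_diff_table(c("dn", "up"), c(-0.8, 1.2), p_adj = c(0.01, 0.001))
  rl <- make_ranked_list(tbl)
  expect_equal(rl$score[rl$gene == "dn"], -2)
  expect_equal(rl$score[rl$gene == "up"], 3)
  expect_equal(rl$gene, c("up", "dn"))  # descending
})

test_that("rank order matches an independent sort oracle and breaks ties stably", {
  set.seed(22)
  n <- 20
  tbl <- toy_diff_table(sprintf("g%02d", sample(n)), round(rnorm(n), 1),
                        p_adj = round(runif(n), 2))
  rl <- make_ranked_list(tbl)
  score <- sign(tbl$log2_ratio) * -log10(pmax(tbl$p_adj, 1e-300))
  oracle <- tbl$feature[order(-score, -abs(tbl$log2_ratio), tbl$feature)]
  expect_equal(rl$gene, oracle)
  # identical scores resolve deterministically across runs
  tbl2 <- toy_diff_table(c("b", "a"), c(0.5, 0.5), p_adj = c(0.1, 0.1))
  expect_equal(make_ranked_list(tbl2)$gene, c("a", "b"))
})

test_that("single-member set at rank 1 attains ES = 1", {
  rl <- data.frame(gene = paste0("g", 1:10), score = seq(5, 0.5, by = -0.5))
  res <- preranked_enrichment(rl, "g1", n_permutations = 50, seed = 1)
  expect_equal(res$es, 1)
})

test_that("single-member set at the bottom gives the closed-form walk minimum", {
  # N - 1 misses each subtract 1/(N - 1), so the walk bottoms out at exactly
  # -1 just before the final hit returns it to 0
  n <- 10
  rl <- data.frame(gene = paste0("g", 1:n), score = seq(5, 0.5, by = -0.5))
  res <- preranked_enrichment(rl, paste0("g", n), weight_p = 0,
                              n_permutations = 50, seed = 1)
  expect_equal(res$es, -1)
  # with the member at rank 5 the walk dips to -4/9 then peaks at
  # -4/9 + 1 = 5/9 right after the hit, which is the larger deviation
  res2 <- preranked_enrichment(rl, "g5", weight_p = 0,
                               n_permutations = 50, seed = 1)
  expect_equal(res2$es, 5 / 9)
})

test_that("weighted ES equals the brute-force cumulative-walk oracle", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    scores <- sort(round(rnorm(n, 0, 2), 2), decreasing = TRUE)
    rl <- data.frame(gene = paste0("g", 1:n), score = scores)
    set_size <- sample(1:(n - 1), 1)
    members <- sample(rl$gene, set_size)
    for (wp in c(0, 1)) {
      res <- preranked_enrichment(rl, members, weight_p = wp,
                                  n_permutations = 10, seed = i)
      expect_equal(res$es, es_oracle(scores, rl$gene %in% members, wp),
                   info = sprintf("i=%d wp=%g", i, wp))
    }
  }
})

test_that("ES with weight 0 equals the classic KS walk statistic", {
  set.seed(24)
  n <- 15
  scores <- sort(rnorm(n), decreasing = TRUE)
  rl <- data.frame(gene = paste0("g", 1:n), score = scores)
  members <- paste0("g", c(2, 5, 6, 11))
  res <- preranked_enrichment(rl, members, weight_p = 0, n_permutations = 10,
                              seed = 1)
  hit <- rl$gene %in% members
  nh <- sum(hit)
  walk <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  expect_equal(res$es, walk[which.max(abs(walk))])
})

test_that("negating all scores negates the enrichment score", {
  set.seed(25)
  n <- 18
  scores <- sort(rnorm(n, 1), decreasing = TRUE)
  rl <- data.frame(gene = paste0("g", 1:n), score = scores)
  members <- paste0("g", c(1, 2, 4))
  es_pos <- preranked_enrichment(rl, members, n_permutations = 10, seed = 1)$es
  rl_neg <- data.frame(gene = rev(rl$gene), score = rev(-scores))
  es_neg <- preranked_enrichment(rl_neg, members, n_permutations = 10, seed = 1)$es
  expect_equal(es_neg, -es_pos)
})

test_that("ES agrees with the fgsea reference implementation on a tie-free list", {
  skip_if_not_installed("fgsea")
  set.seed(26)
  n <- 40
  scores <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  rl <- data.frame(gene = paste0("g", 1:n), score = scores)
  members <- sample(rl$gene, 8)
  res <- preranked_enrichment(rl, members, n_permutations = 10, seed = 1)
  stats <- setNames(rl$score, rl$gene)
  fg <- suppressWarnings(
    fgsea::fgsea(list(set = members), stats, nperm = 100, gseaParam = 1)
  )
  expect_equal(res$es, fg$ES[1], tolerance = 1e-12)
})

test_that("degenerate gene sets are rejected", {
  rl <- data.frame(gene = paste0("g", 1:5), score = 5:1)
  expect_error(preranked_enrichment(rl, "absent"), "does not intersect")
  expect_error(preranked_enrichment(rl, rl$gene), "whole ranked list")
})

test_that("target correlation recovers perfect and formula correlations", {
  atac <- toy_diff_table(paste0("g", 1:5), c(0.1, 0.4, -0.2, 0.9, 0.3))
  rna_same <- atac
  expect_equal(target_correlation(atac, rna_same, atac$feature)$r, 1)
  rna_neg <- toy_diff_table(atac$feature, -atac$log2_ratio)
  expect_equal(target_correlation(atac, rna_neg, atac$feature)$r, -1)
  # 5-pair toy data against the covariance formula
  y <- c(0.2, 0.1, -0.4, 1.1, 0.0)
  rna <- toy_diff_table(atac$feature, y)
  x <- atac$log2_ratio
  r_or <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- target_correlation(atac, rna, atac$feature)
  expect_equal(res$r, r_or, tolerance = 1e-12)
  expect_equal(res$n, 5)
  flat <- toy_diff_table(atac$feature, rep(0.3, 5))
  expect_error(target_correlation(flat, rna, atac$feature), "zero variance")
  expect_error(target_correlation(atac, rna, c("g1", "g2")), ">= 3 genes")
})

test_that("driver ranking orders by p, then |shift|, then TF id", {
  acts <- rbind(
    target_set_shift(toy_diff_table(paste0("g", 1:10),
                                    c(rep(1, 3), rnorm(7, 0, 0.01))),
                     paste0("g", 1:3), abundance_floor = 0, tf = "TFX"),
    target_set_shift(toy_diff_table(paste0("g", 1:10), rnorm(10, 0, 0.01)),
                     paste0("g", 4:6), abundance_floor = 0, tf = "TFY")
  )
  rk <- rank_drivers(acts)
  expect_equal(rk$tf[1], "TFX")
  expect_equal(rk$rank, 1:2)
  # singleton
  expect_equal(rank_drivers(acts[1, , drop = FALSE])$rank, 1)
  # identical stats resolve lexicographically
  ties <- acts[c(1, 1), ]
  ties$tf <- c("TFB", "TFA")
  expect_equal(rank_drivers(ties)$tf, c("TFA", "TFB"))
})
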
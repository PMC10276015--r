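# TF activity inference from differential tables: target-set shift tests
# against the transcriptome/peak background, preranked weighted
# Kolmogorov-Smirnov enrichment with a gene-set permutation null, cross-layer
# target correlation, and driver ranking.

#' Score TF activity as a shift of its target set's log2 ratios
#'
#' Compares the distribution of log2 ratios of a regulon's target genes
#' either against all non-target genes in the table (`comparator =
#' "background"`, two-sample test) or against zero (`comparator = "zero"`,
#' one-sample test). The test is Student's pooled-variance t by default
#' (`var_equal = TRUE`), two-sided. The confidence interval is reported as
#' mean +/- 1.96 x SD of the target log2 ratios (the convention of the
#' target-set analyses this reproduces; note it is an SD band, not an SEM
#' band -- pass `ci = "sem"` for a standard-error interval).
#'
#' Features with mean abundance below `abundance_floor` are removed before
#' the analysis (default 1, the TPM < 1 filter for expression layers; use 0
#' for peak layers, which are analyzed unfiltered).
#'
#' @param table Differential table (schema of [differential_summary()]).
#' @param targets Character vector of target gene ids (one regulon).
#' @param comparator `"background"` (default) or `"zero"`.
#' @param abundance_floor Minimum `mean_abundance` to use a feature.
#' @param var_equal Use the pooled-variance Student t (default); `FALSE`
#'   gives Welch.
#' @param ci `"sd"` (default, mean +/- 1.96 SD) or `"sem"`.
#' @param tf Optional TF id recorded in the result.
#' @return A one-row data frame: `tf`, `n_targets_used`, `mean_log2`,
#'   `sd_log2`, `ci_lo`, `ci_hi`, `t`, `p`, `comparator`, `low_targets`
#'   (TRUE when fewer than 2 usable targets remained, in which case `t` and
#'   `p` are `NA`).
#' @export
target_set_shift <- function(table, targets, comparator = c("background", "zero"),
                             abundance_floor = 1, var_equal = TRUE,
                             ci = c("sd", "sem"), tf = NA_character_) {
  comparator <- match.arg(comparator)
  ci <- match.arg(ci)
  tbl <- table[table$mean_abundance >= abundance_floor, , drop = FALSE]
  in_set <- tbl$feature %in% targets
  x <- tbl$log2_ratio[in_set]
  res <- data.frame(tf = tf, n_targets_used = length(x),
                    mean_log2 = NA_real_, sd_log2 = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    t = NA_real_, p = NA_real_,
                    comparator = comparator, low_targets = FALSE)
  if (length(x) < 2L) {
    warning("fewer than 2 usable targets after filtering", call. = FALSE)
    res$low_targets <- TRUE
    if (length(x) == 1L) res$mean_log2 <- x
    return(res)
  }
  res$mean_log2 <- mean(x)
  res$sd_log2 <- stats::sd(x)
  half <- if (ci == "sd") 1.96 * res$sd_log2 else 1.96 * res$sd_log2 / sqrt(length(x))
  res$ci_lo <- res$mean_log2 - half
  res$ci_hi <- res$mean_log2 + half

  ht <- tryCatch({
    if (comparator == "background") {
      bg <- tbl$log2_ratio[!in_set]
      if (length(bg) < 2L) stop("background needs >= 2 non-target genes")
      stats::t.test(x, bg, var.equal = var_equal)
    } else {
      stats::t.test(x, mu = 0)
    }
  }, error = function(e) {
    if (grepl("essentially constant", conditionMessage(e))) {
      # zero variance everywhere: p defined by whether the means differ
      delta <- if (comparator == "background") mean(x) - mean(tbl$log2_ratio[!in_set]) else mean(x)
      list(statistic = if (delta == 0) 0 else Inf * sign(delta),
           p.value = if (delta == 0) 1 else 0)
    } else {
      stop(e)
    }
  })
  res$t <- unname(ht$statistic)
  res$p <- ht$p.value
  res
}

#' Build a ranked gene list from a differential table
#'
#' The default `signed_logfdr` metric scores each gene as
#' `sign(log2_ratio) * -log10(max(p_adj, 1e-300))`, combining effect
#' direction with FDR strength; `lfc` ranks by the log2 ratio itself. The
#' list is sorted in descending score order with deterministic tie-breaking
#' (larger |log2 ratio| first, then lexicographic gene id).
#'
#' @param table Differential table with `p_adj` present.
#' @param metric `"signed_logfdr"` (default) or `"lfc"`.
#' @return A data frame with columns `gene`, `score`, sorted descending;
#'   the metric name is attached as attribute `"metric"`.
#' @export
make_ranked_list <- function(table, metric = c("signed_logfdr", "lfc")) {
  metric <- match.arg(metric)
  if (metric == "signed_logfdr") {
    stopifnot("p_adj" %in% names(table))
    score <- sign(table$log2_ratio) * -log10(pmax(table$p_adj, 1e-300))
  } else {
    score <- table$log2_ratio
  }
  ord <- order(-score, -abs(table$log2_ratio), table$feature)
  out <- data.frame(gene = table$feature[ord], score = score[ord])
  if (anyDuplicated(out$gene)) stop("duplicate gene in ranked list", call. = FALSE)
  attr(out, "metric") <- metric
  out
}

# Weighted KS running-sum enrichment score for hit positions in a ranked
# score vector. Hits add |score|^p normalized by the sum over hits; misses
# subtract 1/(N - Nh). ES is the signed maximum deviation from zero.
es_walk <- function(scores, hit, weight_p) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores[hit])^weight_p
  nr <- sum(w)
  step <- numeric(n)
  step[hit] <- if (nr > 0) w / nr else 1 / nh
  step[!hit] <- -1 / (n - nh)
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Preranked weighted Kolmogorov-Smirnov enrichment
#'
#' Computes the classic weighted running-sum enrichment score of a gene set
#' on a ranked list: walking down the list, set members increment the sum by
#' their |score|^`weight_p` (normalized over members) and non-members
#' decrement it by 1/(N - Nh); the enrichment score ES is the signed maximum
#' deviation. The null is built from size-matched random gene sets
#' (`n_permutations` draws); NES = ES / mean(|permuted ES| of the same
#' sign), and the permutation p-value uses the add-one correction
#' `p = (1 + #{same-sign |ES_perm| >= |ES|}) / (1 + #same-sign)`.
#'
#' @param ranked Ranked list from [make_ranked_list()] (columns `gene`,
#'   `score`, descending).
#' @param gene_set Character vector of member gene ids; must intersect the
#'   ranked list and must not contain it entirely.
#' @param weight_p Weighting exponent; 1 (default) is the standard weighted
#'   statistic, 0 recovers the unweighted Kolmogorov-Smirnov walk.
#' @param n_permutations Number of random-set permutations. Default 1000.
#' @param seed Seed for the permutation draws.
#' @param set_name Optional label carried into the result.
#' @return A one-row data frame: `set_name`, `n_hits`, `es`, `nes`, `p`,
#'   `n_permutations`, `seed`.
#' @export
preranked_enrichment <- function(ranked, gene_set, weight_p = 1,
                                 n_permutations = 1000, seed = 1,
                                 set_name = NA_character_) {
  genes <- ranked$gene
  scores <- ranked$score
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (nh == n) stop("gene set contains the whole ranked list; miss decrement undefined",
                    call. = FALSE)
  es <- es_walk(scores, hit, weight_p)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      es_walk(scores, h, weight_p)
    }, 0)
  })
  if (es == 0) {
    nes <- 0
    p <- 1
  } else {
    same <- sign(perm) == sign(es)
    denom <- mean(abs(perm[same]))
    nes <- if (sum(same) > 0 && denom > 0) es / denom else NA_real_
    p <- (1 + sum(same & abs(perm) >= abs(es))) / (1 + sum(same))
  }
  data.frame(set_name = set_name, n_hits = nh, es = es, nes = nes, p = p,
             n_permutations = n_permutations, seed = seed)
}

#' Correlate chromatin accessibility with expression over a target set
#'
#' Pearson correlation between promoter-accessibility log2 ratios and
#' expression log2 ratios across the genes of one regulon, with the
#' two-sided p-value from the t transform of r.
#'
#' @param atac_table Gene-level differential table for the promoter ATAC
#'   layer (post [collapse_features_to_gene()]).
#' @param rna_table Differential table for the expression layer.
#' @param targets Character vector of regulon target gene ids.
#' @return A list with `r`, `p`, `n` (genes used).
#' @export
target_correlation <- function(atac_table, rna_table, targets) {
  genes <- Reduce(intersect, list(atac_table$feature, rna_table$feature, targets))
  if (length(genes) < 3L) stop("need >= 3 genes shared by both tables and the regulon",
                               call. = FALSE)
  x <- atac_table$log2_ratio[match(genes, atac_table$feature)]
  y <- rna_table$log2_ratio[match(genes, rna_table$feature)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one coordinate; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' Rank candidate driver TFs by target-set activity
#'
#' Orders a table of [target_set_shift()] results by ascending p-value, ties
#' by descending |mean log2 shift|, then lexicographic TF id; `NA` p-values
#' sort last. All rows must come from the same layer and comparator.
#'
#' @param activities Data frame of stacked [target_set_shift()] rows.
#' @return The table sorted with a `rank` column prepended.
#' @export
rank_drivers <- function(activities) {
  stopifnot(nrow(activities) >= 1L)
  if (length(unique(activities$comparator)) != 1L) {
    stop("activities mix comparators; rank within one comparator", call. = FALSE)
  }
  p <- activities$p
  p[is.na(p)] <- Inf
  ord <- order(p, -abs(activities$mean_log2), activities$tf)
  out <- activities[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
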
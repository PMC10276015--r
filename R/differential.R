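# Generic differential summarization of a two-group replicate matrix.
# The engine is a per-feature Welch unequal-variance t-test on
# log2(abundance + pseudocount) with Benjamini-Hochberg correction -- a
# deliberately simple stand-in for count-model engines (DESeq2/edgeR/
# DiffBind); tables from those engines can be imported through the
# differential-table TSV schema and flow through the rest of the pipeline
# unchanged.

#' Differential summary of a two-group replicate matrix
#'
#' For every feature computes the log2 ratio of group mean abundances
#' (treatment over control, with a pseudocount), a two-sided Welch t-test
#' p-value on the log2-transformed replicate values, and the BH-adjusted
#' p-value over all retained features. Features whose mean abundance across
#' all samples falls below `abundance_floor` are removed before testing, so
#' the multiplicity correction only spans features that were actually tested.
#'
#' A feature with zero variance in both groups and identical group means gets
#' p = 1 (no evidence against the null); zero variance with different means
#' gets p = 0.
#'
#' @param x A `replicate_matrix` (see [replicate_matrix()]), or a numeric
#'   matrix if `groups` is supplied.
#' @param groups Named character vector mapping samples to two group labels
#'   (ignored when `x` is a `replicate_matrix`).
#' @param treatment Group label of the treatment (numerator) condition. When
#'   `NULL`, a label among `"treatment"`, `"trt"`, `"unx"`, `"case"` is used
#'   if present, otherwise an error asks for an explicit choice.
#' @param pseudocount Abundance added before the log2 transform; stabilizes
#'   ratios of near-zero abundances. Default 0.5.
#' @param abundance_floor Minimum mean abundance (over all samples) for a
#'   feature to be tested. Default 0 (keep everything).
#' @return A data frame with columns `feature`, `log2_ratio`, `p`, `p_adj`,
#'   `mean_abundance`, ordered as the retained input rows.
#' @examples
#' m <- matrix(c(8, 8, 8, 2, 2, 2), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' g <- setNames(rep(c("treatment", "control"), each = 3), colnames(m))
#' differential_summary(replicate_matrix(m, g), pseudocount = 1e-9)
#' @export
differential_summary <- function(x, groups = NULL, treatment = NULL,
                                 pseudocount = 0.5, abundance_floor = 0) {
  if (inherits(x, "replicate_matrix")) {
    groups <- x$groups
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(groups), pseudocount > 0)
  groups <- groups[colnames(x)]
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(treatment)) {
    hit <- intersect(c("treatment", "trt", "unx", "case"), lev)
    if (length(hit) != 1L) {
      stop("cannot infer treatment group from labels {",
           paste(lev, collapse = ", "), "}; pass `treatment=`", call. = FALSE)
    }
    treatment <- hit
  }
  if (!treatment %in% lev) stop("treatment label not found in groups", call. = FALSE)
  trt <- x[, groups == treatment, drop = FALSE]
  ctl <- x[, groups != treatment, drop = FALSE]
  if (ncol(trt) < 2L || ncol(ctl) < 2L) {
    stop("both groups need >= 2 samples for testing", call. = FALSE)
  }

  mean_abundance <- rowMeans(x)
  keep <- mean_abundance >= abundance_floor
  if (!any(keep)) stop("all features removed by abundance_floor", call. = FALSE)
  trt <- trt[keep, , drop = FALSE]
  ctl <- ctl[keep, , drop = FALSE]

  log2_ratio <- log2((rowMeans(trt) + pseudocount) / (rowMeans(ctl) + pseudocount))
  wt <- row_welch(log2(trt + pseudocount), log2(ctl + pseudocount))

  data.frame(feature = rownames(trt),
             log2_ratio = unname(log2_ratio),
             p = wt$p,
             p_adj = bh_adjust(wt$p),
             mean_abundance = unname(mean_abundance[keep]),
             row.names = NULL)
}

# Vectorized two-sided Welch t-test across matrix rows (a: treatment,
# b: control). Equivalent to stats::t.test(a_i, b_i) row by row; vectorized
# because studies can carry 1e5+ features per layer.
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- ifelse(ma[degen] == mb[degen], 0, Inf * sign(ma[degen] - mb[degen]))
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
    df[degen] <- NA_real_
  }
  list(t = unname(t), df = unname(df), p = unname(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and the
#' result is capped at 1. A thin validating wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Define a threshold policy for calling features up or down
#'
#' A feature is flagged `up` iff its p-value (raw or adjusted, per `p_field`)
#' is strictly below `p_cut` and its log2 ratio strictly above `lfc_cut`;
#' `down` symmetrically below `-lfc_cut`; otherwise `ns`. All inequalities
#' are strict, so a feature sitting exactly on a cutoff is not flagged.
#'
#' @param lfc_cut Minimum |log2 ratio| (exclusive), >= 0.
#' @param p_cut p-value cutoff (exclusive), in (0, 1).
#' @param p_field `"p_adj"` (default) or `"p"`: which p-value the cutoff
#'   applies to.
#' @param abundance_floor Minimum mean abundance a feature must have had to
#'   be tested; recorded on the policy for provenance (the filter itself is
#'   applied in [differential_summary()]).
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(lfc_cut, p_cut, p_field = c("p_adj", "p"),
                             abundance_floor = 0) {
  p_field <- match.arg(p_field)
  stopifnot(is_scalar_num(lfc_cut), lfc_cut >= 0,
            is_scalar_num(p_cut), p_cut > 0, p_cut < 1)
  structure(list(lfc_cut = lfc_cut, p_cut = p_cut, p_field = p_field,
                 abundance_floor = abundance_floor),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("threshold_policy: %s < %g and |log2_ratio| > %g (abundance floor %g)\n",
              x$p_field, x$p_cut, x$lfc_cut, x$abundance_floor))
  invisible(x)
}

#' Shipped layer-specific threshold presets
#'
#' `policy_rna()`: adjusted p < 0.05 and |log2 ratio| > 0.5, the transcript
#' cutoff. `policy_proteome()`: raw p < 0.1 and |log2 ratio| > 0.2, the
#' reporter-intensity cutoff (the 0.2 band corresponds to a >99% confidence
#' interval of null protein ratios). `policy_atac_dar()`: FDR-only cutoff for
#' differentially accessible regions, no fold-change requirement; both the
#' 0.05 and the stricter 0.01 FDR variants are shipped because both appear as
#' DAR definitions in practice -- pass `fdr = 0.01` for the strict one.
#'
#' @param fdr FDR cutoff for the DAR preset (0.05 default, 0.01 available).
#' @return A [threshold_policy()].
#' @export
policy_rna <- function() threshold_policy(lfc_cut = 0.5, p_cut = 0.05, p_field = "p_adj")

#' @rdname policy_rna
#' @export
policy_proteome <- function() threshold_policy(lfc_cut = 0.2, p_cut = 0.1, p_field = "p")

#' @rdname policy_rna
#' @export
policy_atac_dar <- function(fdr = 0.05) {
  threshold_policy(lfc_cut = 0, p_cut = fdr, p_field = "p_adj")
}

#' Flag a differential table under a threshold policy
#'
#' @param table Differential table (schema of [differential_summary()]).
#' @param policy A [threshold_policy()].
#' @return The table with a `flag` column (`"up"`, `"down"`, `"ns"`); the
#'   applied policy is attached as attribute `"policy"`. Use [flag_counts()]
#'   for the summary counts.
#' @export
apply_thresholds <- function(table, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  pv <- table[[policy$p_field]]
  lfc <- table$log2_ratio
  flag <- rep("ns", nrow(table))
  flag[pv < policy$p_cut & lfc > policy$lfc_cut] <- "up"
  flag[pv < policy$p_cut & lfc < -policy$lfc_cut] <- "down"
  table$flag <- flag
  attr(table, "policy") <- policy
  table
}

#' Summary counts of a flagged differential table
#'
#' @param table A differential table with a `flag` column (from
#'   [apply_thresholds()]).
#' @return A list with `n_up`, `n_down`, `n_total` and `flagged_fraction_pct`
#'   (percent of features flagged either way, rounded to one decimal, the
#'   convention used when such fractions are reported).
#' @examples
#' tbl <- data.frame(feature = c("a", "b", "c"),
#'                   flag = c("up", "ns", "down"))
#' flag_counts(tbl)  # 66.7% flagged
#' @export
flag_counts <- function(table) {
  stopifnot("flag" %in% names(table))
  n_up <- sum(table$flag == "up")
  n_down <- sum(table$flag == "down")
  n_total <- nrow(table)
  frac <- if (n_total == 0L) 0 else round(100 * (n_up + n_down) / n_total, 1)
  list(n_up = n_up, n_down = n_down, n_total = n_total,
       flagged_fraction_pct = frac)
}
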
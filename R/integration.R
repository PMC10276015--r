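# Cross-layer concordance integration: gene x layer log2-ratio matrix,
# per-layer z-score binarization, logical-score summation and selection of
# genes that respond in more layers than a score threshold, followed by
# over-representation analysis of the selected genes.

#' Assemble gene-level differential tables into a gene x layer matrix
#'
#' Takes the union of gene ids across layers; a gene absent from a layer is
#' missing (`NA`) there, which is distinct from a zero log2 ratio and
#' contributes nothing to the concordance score. Tables must already be
#' gene-level (one row per gene; see [collapse_features_to_gene()]).
#'
#' @param tables Named list of gene-level differential tables; names are the
#'   layer ids.
#' @return A numeric matrix of log2 ratios, genes x layers, with `NA` for
#'   missing gene/layer pairs.
#' @export
build_layer_matrix <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)),
            all(nzchar(names(tables))))
  for (layer in names(tables)) {
    tbl <- tables[[layer]]
    if (anyDuplicated(tbl$feature)) {
      stop("duplicate gene in layer '", layer,
           "'; collapse features to gene level first", call. = FALSE)
    }
    if (any(!is.finite(tbl$log2_ratio))) {
      stop("non-finite log2 ratio in layer '", layer, "'", call. = FALSE)
    }
  }
  genes <- sort(unique(unlist(lapply(tables, `[[`, "feature"))))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(tables),
                dimnames = list(genes, names(tables)))
  for (layer in names(tables)) {
    tbl <- tables[[layer]]
    mat[tbl$feature, layer] <- tbl$log2_ratio
  }
  mat
}

#' Z-score each layer and binarize into differential flags
#'
#' Within each layer (column), log2 ratios are standardized over the
#' non-missing genes using the layer mean and sample SD (n - 1 denominator),
#' and a gene is flagged differential in that layer iff |z| strictly exceeds
#' `z_threshold`. Missing entries stay missing and never contribute a flag.
#' In the default `"abs"` mode flags are 0/1 regardless of direction (as the
#' concordance scheme defines them); `mode = "signed"` is an extension that
#' flags +1/-1 by direction so that sign-concordant responses can be scored
#' via `|sum|` downstream.
#'
#' @param mat Gene x layer matrix from [build_layer_matrix()].
#' @param z_threshold Flag cutoff on |z| (strict). Default 1.96.
#' @param mode `"abs"` (default) or `"signed"`.
#' @return A list with matrices `z` and `flags` (same shape as `mat`, `NA`
#'   where missing).
#' @export
zscore_binarize <- function(mat, z_threshold = 1.96, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat))
  z <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    obs <- !is.na(x)
    if (sum(obs) < 3L) {
      stop("layer '", colnames(mat)[j], "' has fewer than 3 observed genes",
           call. = FALSE)
    }
    s <- stats::sd(x[obs])
    if (s == 0) stop("layer '", colnames(mat)[j], "' has zero spread", call. = FALSE)
    z[, j] <- (x - mean(x[obs])) / s
  }
  flags <- ifelse(abs(z) > z_threshold, 1, 0)
  if (mode == "signed") flags <- flags * sign(z)
  list(z = z, flags = flags)
}

#' Sum layer flags into concordance scores and select genes
#'
#' Each gene's score is the sum of its per-layer logical flags (missing
#' layers contribute 0); a gene is selected iff its score strictly exceeds
#' `score_threshold` -- with the defaults, differential in more than 3 of
#' the layers. For signed flags the score is the absolute value of the
#' flag sum, so only direction-concordant responses accumulate.
#'
#' @param flags Flag matrix from [zscore_binarize()].
#' @param score_threshold Strict lower cutoff on the score. Default 3.
#' @return A data frame with columns `gene`, `score`, `n_layers_present`,
#'   `selected`, sorted by descending score then gene id.
#' @export
concordance_select <- function(flags, score_threshold = 3) {
  stopifnot(is.matrix(flags))
  score <- abs(rowSums(flags, na.rm = TRUE))
  out <- data.frame(gene = rownames(flags),
                    score = unname(score),
                    n_layers_present = unname(rowSums(!is.na(flags))),
                    selected = unname(score > score_threshold))
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a full concordance table for a study
#'
#' Convenience wrapper chaining [build_layer_matrix()],
#' [zscore_binarize()] and [concordance_select()].
#'
#' @inheritParams build_layer_matrix
#' @inheritParams zscore_binarize
#' @inheritParams concordance_select
#' @return A list with `z`, `flags` (gene x layer matrices) and `table`
#'   (the scored, sorted selection table).
#' @export
concordance_table <- function(tables, z_threshold = 1.96, score_threshold = 3,
                              mode = c("abs", "signed")) {
  mat <- build_layer_matrix(tables)
  zb <- zscore_binarize(mat, z_threshold = z_threshold, mode = mode)
  list(z = zb$z, flags = zb$flags,
       table = concordance_select(zb$flags, score_threshold = score_threshold))
}

#' Over-representation analysis of a gene selection against term sets
#'
#' One-sided hypergeometric (Fisher) enrichment of the selected genes in
#' each annotation term, BH-adjusted across terms. Terms are intersected
#' with the universe first; terms that become empty are skipped with a
#' warning. An optional chi-squared variant tests the same 2x2 table with
#' `stats::chisq.test` (without continuity correction).
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param term_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all eligible gene ids; defaults to
#'   genes present in at least one layer when called from a concordance
#'   workflow -- here it must be given explicitly.
#' @param method `"hypergeometric"` (default) or `"chisq"`.
#' @return A data frame with one row per tested term: `term`, `k` (overlap),
#'   `K` (term size in universe), `n` (selection size), `N` (universe
#'   size), `p`, `p_adj`, sorted by p.
#' @export
ora_enrich <- function(selected, term_sets, universe,
                       method = c("hypergeometric", "chisq")) {
  method <- match.arg(method)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(selected) == 0L) stop("empty selection", call. = FALSE)
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    stop("selected genes must be contained in the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(term_sets), function(term) {
    members <- intersect(term_sets[[term]], universe)
    if (length(members) == 0L) {
      warning("term '", term, "' disjoint from universe; skipped", call. = FALSE)
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (method == "hypergeometric") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
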
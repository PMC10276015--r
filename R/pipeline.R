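# End-to-end convenience wrappers: from a synthetic (or imported) study to
# gene-level differential tables per layer and the concordance selection.

#' Differential tables for every layer of a study, on a gene key
#'
#' Runs [differential_summary()] on each layer's replicate matrix and
#' collapses peak-keyed ATAC layers to gene level using the study's
#' peak-to-gene mapping ([collapse_features_to_gene()], max-abs policy).
#' Peaks without an assigned gene (intergenic) drop out at the collapse.
#'
#' @param study A [simulate_study()] result.
#' @param treatment Treatment group label. Default `"unx"`.
#' @param pseudocount Passed to [differential_summary()].
#' @return Named list of gene-level differential tables, one per layer.
#' @export
study_differential <- function(study, treatment = "unx", pseudocount = 0.5) {
  stopifnot(inherits(study, "synthetic_study"))
  peak_map <- data.frame(feature = study$peaks$name, gene = study$peaks$gene)
  out <- lapply(names(study$layers), function(layer) {
    tbl <- differential_summary(study$layers[[layer]], treatment = treatment,
                                pseudocount = pseudocount)
    if (startsWith(layer, "atac_")) {
      tbl <- collapse_features_to_gene(tbl, peak_map, policy = "max_abs")
    }
    tbl
  })
  setNames(out, names(study$layers))
}

#' Run the concordance integration on a study
#'
#' Chains [study_differential()] and [concordance_table()]: per-layer
#' differential summaries, gene x layer log2-ratio matrix, per-layer
#' z-score binarization at `z_threshold` and selection of genes whose flag
#' sum strictly exceeds `score_threshold`.
#'
#' @inheritParams study_differential
#' @inheritParams concordance_table
#' @return A list with `diff_tables`, `z`, `flags` and `table` (the scored
#'   selection table of [concordance_select()]).
#' @export
run_concordance <- function(study, treatment = "unx", z_threshold = 1.96,
                            score_threshold = 3) {
  tables <- study_differential(study, treatment = treatment)
  ct <- concordance_table(tables, z_threshold = z_threshold,
                          score_threshold = score_threshold)
  c(list(diff_tables = tables), ct)
}

#' Score and rank all regulons of a study on one layer
#'
#' Applies [target_set_shift()] with every regulon against the given
#' gene-level differential table and ranks the TFs with [rank_drivers()].
#'
#' @param table Gene-level differential table for one layer.
#' @param regulons Named list of target-gene sets (e.g. `study$regulons`).
#' @param ... Passed to [target_set_shift()].
#' @return The ranked TF table of [rank_drivers()].
#' @export
score_regulons <- function(table, regulons, ...) {
  rows <- lapply(names(regulons), function(tf) {
    target_set_shift(table, regulons[[tf]], tf = tf, ...)
  })
  rank_drivers(do.call(rbind, rows))
}
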
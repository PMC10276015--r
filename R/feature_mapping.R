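# Maps layer-specific features onto genes so every omics layer shares one
# gene-level key space: strand-aware promoter-TSS windows for ATAC peaks,
# a promoter > intronic > intergenic region classification, and a collapse
# of multi-feature layers (peaks, phosphosites) to one record per gene.

#' Define a promoter window around the TSS
#'
#' The window spans `upstream` bp upstream to `downstream` bp downstream of
#' the transcription start site, measured in the gene's orientation. The
#' default (-1000, +100) is the promoter-TSS definition used throughout the
#' pipeline.
#'
#' @param upstream Non-negative bp upstream of the TSS. Default 1000.
#' @param downstream Non-negative bp downstream of the TSS. Default 100.
#' @return A `promoter_window` object.
#' @export
promoter_window <- function(upstream = 1000, downstream = 100) {
  stopifnot(is_scalar_num(upstream), upstream >= 0,
            is_scalar_num(downstream), downstream >= 0,
            upstream + downstream > 0)
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_window")
}

# Genomic half-open window [start, end) covering the promoter positions
# tss - upstream .. tss + downstream in gene orientation.
promoter_span <- function(genes, window) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - window$upstream, genes$tss - window$downstream)
  end <- ifelse(plus, genes$tss + window$downstream + 1L, genes$tss + window$upstream + 1L)
  data.frame(start = pmax(start, 0L), end = end)
}

# Signed distance from peak midpoint to TSS in gene orientation; fractional
# midpoints are rounded toward the TSS.
tss_distance <- function(peak_start, peak_end, tss, strand) {
  mid <- (peak_start + peak_end - 1) / 2
  frac <- mid != floor(mid)
  toward_up <- tss > mid
  mid[frac] <- ifelse(toward_up[frac], ceiling(mid[frac]), floor(mid[frac]))
  ifelse(strand == "+", mid - tss, tss - mid)
}

#' Assign peaks to promoter-TSS regions
#'
#' A peak is promoter-assigned iff it shares at least one base with a gene's
#' promoter window (see [promoter_window()]); for minus-strand genes the
#' window is mirrored in genomic coordinates. When a peak overlaps several
#' promoter windows the gene with the smallest |distance to TSS| wins, ties
#' broken by lexicographic gene id, so one peak annotates at most one gene.
#'
#' @param peaks Data frame of 0-based half-open intervals with columns
#'   `chrom`, `start`, `end`, `name` (see [read_bed()]).
#' @param genes Gene-model data frame (see [read_gene_models()]); strands
#'   must be `+` or `-` (orientation is required for the window).
#' @param window A [promoter_window()].
#' @return A data frame, one row per peak, with columns `peak`,
#'   `region_class` (`"promoter-TSS"` or `NA`), `gene` and
#'   `distance_to_tss` (signed bp in gene orientation, negative = upstream;
#'   `NA` for unassigned peaks).
#' @export
assign_to_promoter <- function(peaks, genes, window = promoter_window()) {
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' for promoter assignment", call. = FALSE)
  }
  validate_gene_models(genes)
  ann <- data.frame(peak = peaks$name,
                    region_class = NA_character_,
                    gene = NA_character_,
                    distance_to_tss = NA_real_)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(ann)
  prom <- promoter_span(genes, window)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  pr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(prom$start + 1L, prom$end))
  hits <- GenomicRanges::findOverlaps(pk, pr, minoverlap = 1L)
  if (length(hits) == 0L) return(ann)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- tss_distance(peaks$start[qi], peaks$end[qi], genes$tss[si], genes$strand[si])
  ord <- order(qi, abs(d), genes$gene_id[si])
  first <- !duplicated(qi[ord])
  pick <- ord[first]
  ann$region_class[qi[pick]] <- "promoter-TSS"
  ann$gene[qi[pick]] <- genes$gene_id[si[pick]]
  ann$distance_to_tss[qi[pick]] <- d[pick]
  ann
}

parse_coord_list <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), as.integer)
}

#' Classify peaks as promoter-TSS, intronic or intergenic
#'
#' Precedence is promoter-TSS > intronic > intergenic. A peak is intronic
#' for a gene when it overlaps the gene span but none of its exons and no
#' promoter window; peaks matching no gene (or only exonic, non-promoter
#' overlap) are intergenic with no assigned gene. Ties across genes are
#' broken by smallest |distance to TSS|, then lexicographic gene id.
#'
#' @inheritParams assign_to_promoter
#' @return A data frame, one row per peak, with columns `peak`,
#'   `region_class` (`"promoter-TSS"`, `"intronic"`, `"intergenic"`),
#'   `gene` (`NA` for intergenic) and `distance_to_tss`.
#' @export
classify_region <- function(peaks, genes, window = promoter_window()) {
  ann <- assign_to_promoter(peaks, genes, window)
  ann$region_class[is.na(ann$region_class)] <- "intergenic"
  todo <- which(ann$region_class == "intergenic")
  if (length(todo) == 0L || nrow(genes) == 0L) return(ann)

  gr_pk <- GenomicRanges::GRanges(peaks$chrom[todo],
                                  IRanges::IRanges(peaks$start[todo] + 1L, peaks$end[todo]))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_pk, gr_gene, minoverlap = 1L)
  if (length(hits) == 0L) return(ann)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  exon_starts <- parse_coord_list(genes$exon_starts)
  exon_ends <- parse_coord_list(genes$exon_ends)
  # keep only (peak, gene) pairs with no exon overlap
  keep <- vapply(seq_along(qi), function(k) {
    i <- todo[qi[k]]; g <- si[k]
    !any(peaks$start[i] < exon_ends[[g]] & peaks$end[i] > exon_starts[[g]])
  }, TRUE)
  if (!any(keep)) return(ann)
  qi <- qi[keep]; si <- si[keep]
  d <- tss_distance(peaks$start[todo[qi]], peaks$end[todo[qi]],
                    genes$tss[si], genes$strand[si])
  ord <- order(qi, abs(d), genes$gene_id[si])
  first <- !duplicated(qi[ord])
  pick <- ord[first]
  rows <- todo[qi[pick]]
  ann$region_class[rows] <- "intronic"
  ann$gene[rows] <- genes$gene_id[si[pick]]
  ann$distance_to_tss[rows] <- d[pick]
  ann
}

#' Collapse a feature-level differential table to gene level
#'
#' Multi-feature layers (ATAC peaks, phosphosites) are reduced to one record
#' per gene so layers can be integrated on a shared gene key. Under the
#' default `max_abs` policy the feature with the largest |log2 ratio| speaks
#' for the gene (ties broken by smaller p, then feature id); under `mean`
#' the log2 ratios and mean abundances are averaged and the p-values are
#' taken from the feature with the smallest p. The chosen feature id is kept
#' in `source_feature` for provenance. Genes with no mapped feature are
#' absent from the output (missing, not zero). Features mapping to more
#' than one gene are dropped with a warning.
#'
#' @param table Feature-level differential table.
#' @param mapping Data frame with columns `feature` and `gene` (e.g. built
#'   from [classify_region()] output or a phosphosite-to-gene table);
#'   features with `NA` gene are ignored.
#' @param policy `"max_abs"` (default) or `"mean"`.
#' @return A gene-level differential table with `feature` = gene id and a
#'   `source_feature` provenance column.
#' @export
collapse_features_to_gene <- function(table, mapping, policy = c("max_abs", "mean")) {
  policy <- match.arg(policy)
  stopifnot(all(c("feature", "gene") %in% names(mapping)))
  mapping <- mapping[!is.na(mapping$gene), c("feature", "gene")]
  mapping <- unique(mapping)
  multi <- unique(mapping$feature[duplicated(mapping$feature)])
  if (length(multi)) {
    warning(length(multi), " feature(s) mapping to multiple genes dropped",
            call. = FALSE)
    mapping <- mapping[!mapping$feature %in% multi, ]
  }
  df <- merge(table, mapping, by = "feature")
  if (nrow(df) == 0L) {
    out <- table[0, , drop = FALSE]
    out$source_feature <- character()
    return(out)
  }
  split_rows <- split(seq_len(nrow(df)), df$gene)
  rows <- lapply(split_rows, function(idx) {
    sub <- df[idx, , drop = FALSE]
    if (policy == "max_abs") {
      o <- order(-abs(sub$log2_ratio), sub$p, sub$feature)
      best <- sub[o[1L], ]
      data.frame(feature = best$gene, log2_ratio = best$log2_ratio,
                 p = best$p, p_adj = best$p_adj,
                 mean_abundance = best$mean_abundance,
                 source_feature = best$feature)
    } else {
      o <- order(sub$p, sub$feature)
      best <- sub[o[1L], ]
      data.frame(feature = best$gene, log2_ratio = mean(sub$log2_ratio),
                 p = best$p, p_adj = best$p_adj,
                 mean_abundance = mean(sub$mean_abundance),
                 source_feature = best$feature)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$feature)) {
    stop("internal error: duplicate gene rows after collapse", call. = FALSE)
  }
  out
}
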
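# Readers and writers for the plain-text formats the pipeline exchanges:
# BED intervals, GMT gene sets, TSV replicate matrices with a group sidecar,
# TSV gene-model tables and TSV differential tables. All genomic coordinates
# are 0-based half-open on disk and in memory; `to_display_coords()` converts
# to the 1-based inclusive convention used by genome browsers.

DIFF_COLUMNS <- c("feature", "log2_ratio", "p", "p_adj", "mean_abundance")

#' Read a BED file of genomic intervals
#'
#' Parses BED3-BED6 records into a data frame of 0-based half-open intervals.
#' Malformed records (non-integer coordinates, `start >= end`, too few
#' columns) raise an error naming the offending line rather than being
#' silently coerced.
#'
#' @param path Path to a BED file (plain text, tab-separated, no header).
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`. `name` defaults to `"."` and `strand` to `"."` when the
#'   corresponding columns are absent.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tpkA\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stop_parse(path, i, "BED record has fewer than 3 columns")
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end)) {
      stop_parse(path, i, "non-integer BED coordinates")
    }
    if (start < 0) stop_parse(path, i, "negative BED start coordinate")
    if (start >= end) stop_parse(path, i, "empty or inverted BED interval (start >= end)")
    strand <- if (length(f) >= 6L) f[6L] else "."
    if (!strand %in% c("+", "-", ".")) stop_parse(path, i, "invalid strand field")
    out[[i]] <- list(chrom = f[1L], start = as.integer(start), end = as.integer(end),
                     name = if (length(f) >= 4L) f[4L] else ".", strand = strand)
  }
  data.frame(chrom = vapply(out, `[[`, "", "chrom"),
             start = vapply(out, `[[`, 0L, "start"),
             end = vapply(out, `[[`, 0L, "end"),
             name = vapply(out, `[[`, "", "name"),
             strand = vapply(out, `[[`, "", "strand"))
}

#' Write intervals to a BED file
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `strand` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", nrow(intervals))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), name, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a line are removed with a warning; a line with
#' fewer than three fields is a parse error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (set name -> members), with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) stop_parse(path, i, "GMT line has fewer than 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': %d duplicate member(s) removed",
                      f[1L], sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    desc[[f[1L]]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of set descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(description)) description <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate abundance matrix with its group sidecar
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and feature identifiers in the first column; the sidecar maps every sample
#' to one of exactly two groups (two tab-separated columns `sample`, `group`,
#' with header).
#'
#' @param path Path to the feature x sample TSV.
#' @param groups_path Path to the sample-to-group sidecar TSV.
#' @return A `replicate_matrix`: list with `values` (numeric matrix, features
#'   x samples) and `groups` (named character vector, sample -> group).
#' @export
read_matrix <- function(path, groups_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs a feature column plus >=1 sample column", call. = FALSE)
  features <- as.character(raw[[1L]])
  if (anyDuplicated(features)) {
    stop("duplicate feature id(s) in matrix: ",
         paste(unique(features[duplicated(features)]), collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- features
  if (any(!is.finite(values))) stop("non-finite value in matrix", call. = FALSE)
  if (any(values < 0)) stop("negative value in matrix", call. = FALSE)
  g <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(g) < 2L) stop("groups sidecar needs columns sample, group", call. = FALSE)
  groups <- setNames(as.character(g[[2L]]), as.character(g[[1L]]))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("sample(s) in matrix header missing from groups file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- groups[colnames(values)]
  if (length(unique(groups)) != 2L) {
    stop("groups sidecar must define exactly two groups, got: ",
         paste(unique(groups), collapse = ", "), call. = FALSE)
  }
  replicate_matrix(values, groups)
}

#' Construct a replicate matrix
#'
#' @param values Non-negative numeric matrix, features x samples, with row
#'   and column names.
#' @param groups Named character vector mapping every sample (column) to one
#'   of two group labels.
#' @return A `replicate_matrix` object.
#' @export
replicate_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("replicate matrix values must be finite and >= 0", call. = FALSE)
  }
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample must have a group label", call. = FALSE)
  }
  groups <- groups[colnames(values)]
  structure(list(values = values, groups = groups), class = "replicate_matrix")
}

#' @export
print.replicate_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("replicate_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a replicate matrix and its group sidecar
#'
#' @param x A `replicate_matrix`.
#' @param path Output path for the feature x sample TSV.
#' @param groups_path Output path for the sample-to-group sidecar.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, groups_path) {
  stopifnot(inherits(x, "replicate_matrix"))
  df <- data.frame(feature = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(sample = names(x$groups), group = unname(x$groups))
  utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential table
#'
#' @param path TSV with at least the columns `feature`, `log2_ratio`, `p`,
#'   `p_adj`, `mean_abundance` (the schema produced by
#'   [differential_summary()]; external engines such as DESeq2 output can be
#'   imported by renaming columns to this schema).
#' @return A data frame with the mandatory columns (plus any extras present).
#' @export
read_diff_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(DIFF_COLUMNS, names(df))
  if (length(missing)) {
    stop("differential table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$feature <- as.character(df$feature)
  if (anyDuplicated(df$feature)) stop("duplicate feature id in differential table", call. = FALSE)
  bad <- !is.na(df$p) & (df$p < 0 | df$p > 1)
  if (any(bad)) stop("p outside [0, 1] in differential table", call. = FALSE)
  df
}

#' Write a differential table
#'
#' @param table Data frame with the differential-table schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(table, path) {
  missing <- setdiff(DIFF_COLUMNS, names(table))
  if (length(missing)) {
    stop("differential table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header and columns `gene_id`, `chrom`, `strand`, `tss`,
#' `start`, `end`, `exon_starts`, `exon_ends` (exon coordinates as
#' comma-separated lists; all coordinates 0-based half-open).
#'
#' @param path Path to the gene-model TSV.
#' @return A data frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end",
            "exon_starts", "exon_ends")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gene-model table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_gene_models(df)
  df
}

#' Write a gene-model table
#'
#' @param genes Gene-model data frame (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_gene_models <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene model strand must be '+' or '-'", call. = FALSE)
  }
  plus <- genes$strand == "+"
  ok <- ifelse(plus, genes$tss == genes$start, genes$tss == genes$end - 1L)
  if (!all(ok)) stop("TSS inconsistent with span and strand", call. = FALSE)
  invisible(genes)
}

#' Convert between internal and display genomic coordinates
#'
#' Internal coordinates are 0-based half-open `[start, end)`; display
#' coordinates are the 1-based fully-inclusive `[first, last]` convention of
#' genome browsers. The two functions are exact inverses.
#'
#' @param start,end Internal 0-based half-open coordinates.
#' @return For `to_display_coords()`, a list with 1-based inclusive `first`
#'   and `last`; `from_display_coords()` inverts it.
#' @examples
#' to_display_coords(0, 100)    # first = 1, last = 100
#' from_display_coords(1, 100)  # start = 0, end = 100
#' @export
to_display_coords <- function(start, end) {
  stopifnot(all(start < end))
  list(first = start + 1L, last = end)
}

#' @rdname to_display_coords
#' @param first,last Display 1-based inclusive coordinates.
#' @export
from_display_coords <- function(first, last) {
  stopifnot(all(first <= last))
  list(start = first - 1L, end = last)
}
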
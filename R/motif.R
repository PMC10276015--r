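# Consensus (IUPAC) motif scanning, motif-proportion enrichment in
# differentially accessible regions, and aggregate Tn5 footprint profiles.
# Consensus matching -- not PWM log-odds scoring -- is the scanning model
# here: a motif is a degenerate-base pattern and a hit is an exact class
# match at every position.

IUPAC_CLASS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  # N in a motif matches any sequence base, including an unknown N;
  # every other symbol never matches a sequence N.
  N = c("A", "C", "G", "T", "N")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D")

#' Reverse complement of a DNA or IUPAC string
#'
#' @param x Character string over the IUPAC alphabet.
#' @return The reverse complement.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(COMPLEMENT))
  if (length(bad)) stop("invalid base(s): ", paste(bad, collapse = ", "), call. = FALSE)
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad)) {
    stop("invalid IUPAC symbol(s) in motif: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASS[[ch]]
    if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, ""), collapse = "")
}

scan_one_strand <- function(sequence, motif) {
  rx <- sprintf("(?=%s)", iupac_regex(motif))
  m <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every 0-based start position where each motif symbol's IUPAC
#' class contains the sequence base, including overlapping occurrences. An
#' `N` in the sequence matches only the motif symbol `N`. With
#' `both_strands`, the reverse complement is scanned too and minus-strand
#' hits are reported at their plus-strand start coordinates.
#'
#' @param sequence DNA string over `{A, C, G, T, N}` (case-insensitive).
#' @param motif IUPAC consensus string (e.g. `"RGGTCA"`).
#' @param both_strands Also scan the reverse complement. Default TRUE.
#' @return A data frame with columns `position` (0-based start on the plus
#'   strand) and `strand`, sorted by position then strand.
#' @examples
#' scan_consensus("ACGTACGT", "ACGT", both_strands = FALSE)
#' @export
scan_consensus <- function(sequence, motif, both_strands = TRUE) {
  sequence <- toupper(sequence)
  seq_chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1L]])
  bad <- setdiff(seq_chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("sequence must be over {A,C,G,T,N}; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fwd <- scan_one_strand(sequence, motif)
  hits <- data.frame(position = fwd,
                     strand = rep("+", length(fwd)))
  if (both_strands) {
    m <- nchar(motif)
    L <- nchar(sequence)
    rev_hits <- scan_one_strand(reverse_complement(sequence), motif)
    minus <- L - rev_hits - m
    hits <- rbind(hits, data.frame(position = minus,
                                   strand = rep("-", length(minus))))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Motif-proportion enrichment in differentially accessible regions
#'
#' Compares the fraction of peaks carrying a motif between the full peak
#' set and its differentially accessible subset. The one-sided p-value is
#' the hypergeometric upper tail (DAR peaks drawn from all peaks); the odds
#' ratio comes from the 2x2 table with a Haldane 0.5 correction applied
#' only when some cell is zero.
#'
#' @param motif_flag Logical vector, one per peak: does the peak carry the
#'   motif?
#' @param is_dar Logical vector, same length: is the peak differentially
#'   accessible?
#' @param motif_name Optional label.
#' @return A one-row data frame: `motif`, `prop_all`, `prop_dar`,
#'   `odds_ratio`, `p`.
#' @export
motif_proportion_enrichment <- function(motif_flag, is_dar, motif_name = NA_character_) {
  stopifnot(is.logical(motif_flag), is.logical(is_dar),
            length(motif_flag) == length(is_dar))
  n_all <- length(motif_flag)
  n_dar <- sum(is_dar)
  if (n_dar == 0L) stop("empty DAR set", call. = FALSE)
  K <- sum(motif_flag)
  k <- sum(motif_flag & is_dar)
  p <- stats::phyper(k - 1, K, n_all - K, n_dar, lower.tail = FALSE)
  a <- k; b <- n_dar - k; c <- K - k; d <- n_all - K - b
  if (min(a, b, c, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  data.frame(motif = motif_name,
             prop_all = K / n_all,
             prop_dar = k / n_dar,
             odds_ratio = (a * d) / (b * c),
             p = p)
}

#' Aggregate Tn5 insertion counts into a footprint profile
#'
#' Averages per-base insertion counts across motif sites, reversing
#' minus-strand site rows first so all sites share the motif's orientation.
#' An optional multiplicative `scale_factor` allows library-size scaling
#' when comparing conditions (both the raw and scaled profiles are
#' meaningful; the factor applied is recorded in the result).
#'
#' @param cuts Integer matrix of insertion counts, rows = motif sites,
#'   columns = offsets (symmetric around the motif center); column names,
#'   when parseable as integers, are used as offsets.
#' @param site_strands Character vector (`"+"`/`"-"`), one per site.
#' @param condition Optional condition label.
#' @param scale_factor Multiplier applied to the mean profile. Default 1.
#' @return A list with `condition`, `offsets`, `mean_count`, `n_sites`,
#'   `scale_factor`.
#' @export
footprint_profile <- function(cuts, site_strands, condition = NA_character_,
                              scale_factor = 1) {
  stopifnot(is.matrix(cuts), length(site_strands) == nrow(cuts))
  if (any(cuts < 0)) stop("insertion counts must be >= 0", call. = FALSE)
  if (!all(site_strands %in% c("+", "-"))) {
    stop("site strands must be '+' or '-'", call. = FALSE)
  }
  minus <- site_strands == "-"
  if (any(minus)) {
    cuts[minus, ] <- cuts[minus, rev(seq_len(ncol(cuts))), drop = FALSE]
  }
  offsets <- suppressWarnings(as.integer(colnames(cuts)))
  if (length(offsets) == 0L || any(is.na(offsets))) {
    half <- (ncol(cuts) - 1) / 2
    offsets <- seq_len(ncol(cuts)) - 1 - floor(half)
  }
  list(condition = condition,
       offsets = offsets,
       mean_count = unname(colMeans(cuts)) * scale_factor,
       n_sites = nrow(cuts),
       scale_factor = scale_factor)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
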
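# Shared fixtures and independent oracles used across test files.

# Minimal differential table with sensible defaults.
toy_diff_table <- function(feature, log2_ratio, p = NULL, p_adj = NULL,
                           mean_abundance = 10) {
  n <- length(feature)
  if (is.null(p)) p <- rep(0.5, n)
  if (is.null(p_adj)) p_adj <- p
  data.frame(feature = feature, log2_ratio = log2_ratio, p = p, p_adj = p_adj,
             mean_abundance = rep_len(mean_abundance, n))
}

# A small config that keeps simulation cheap in unit tests.
tiny_config <- function(...) {
  args <- list(n_genes = 200, n_tfs = 4, targets_per_tf = 20,
               n_cut_sites = 50, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Independent step-up BH oracle: literal cummin-over-sorted definition,
# written directly from the procedure, no shared code with bh_adjust().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Brute-force weighted running-sum ES oracle: explicit loop over the list.
es_oracle <- function(scores, is_hit, weight_p) {
  n <- length(scores)
  nh <- sum(is_hit)
  nr <- sum(abs(scores[is_hit])^weight_p)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      running <- running + if (nr > 0) abs(scores[i])^weight_p / nr else 1 / nh
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Per-base promoter-overlap oracle: enumerate every base of the peak and ask
# whether it falls in the gene's oriented promoter window.
promoter_overlap_oracle <- function(peak_start, peak_end, tss, strand,
                                    upstream = 1000, downstream = 100) {
  bases <- seq(peak_start, peak_end - 1)
  if (strand == "+") {
    any(bases >= tss - upstream & bases <= tss + downstream)
  } else {
    any(bases >= tss - downstream & bases <= tss + upstream)
  }
}

# Hypergeometric upper-tail oracle by direct enumeration of choose() terms:
# P(X >= k) drawing n from N with K successes.
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Exhaustive IUPAC expansion oracle for consensus scanning (plus strand):
# expand the motif into all literal words and string-match each.
iupac_expand_oracle <- function(sequence, motif) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T", "N"))
  chars <- strsplit(motif, "")[[1]]
  words <- Reduce(function(acc, ch) {
    unlist(lapply(acc, function(w) paste0(w, classes[[ch]])))
  }, chars, accumulate = FALSE, init = "")
  m <- nchar(motif)
  L <- nchar(sequence)
  hits <- integer()
  if (L >= m) {
    for (pos in 0:(L - m)) {
      if (substr(sequence, pos + 1, pos + m) %in% words) hits <- c(hits, pos)
    }
  }
  hits
}

# All permutations of 1..n as a list of index vectors.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
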
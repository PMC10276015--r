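# Synthetic multi-omics study generator with planted driver TFs.
#
# A study emulates a two-condition (sham vs treatment) design measured on
# nine omics layers -- promoter and distal chromatin accessibility, two
# expression timepoints, three proteome tables and two phosphoproteome
# tables -- all reduced downstream to per-gene log2(treatment/sham)
# summaries. A configured driver TF shifts its regulon targets by +delta in
# the layers it affects; a background fraction of non-target genes receives
# random +/-delta shifts independently per layer, so layer-concordant
# response (not mere per-layer differential count) is what distinguishes
# driver targets. Ground truth is recorded exactly for recovery benchmarks.

DEFAULT_LAYERS <- c("atac_promoter", "atac_distal",
                    "rna_s1_24h", "rna_s1_72h",
                    "prot_whole_24h", "prot_cortex_24h", "prot_whole_72h",
                    "phos_whole_24h", "phos_whole_72h")

#' Configure a synthetic multi-omics study
#'
#' All stochastic components of the generator are controlled by `seed`;
#' identical configurations produce bit-identical studies.
#'
#' @param n_genes Number of genes. Default 2000.
#' @param n_tfs Number of TF regulons. Default 10.
#' @param targets_per_tf Targets per regulon. Default 50.
#' @param regulons_disjoint Should regulons partition distinct genes?
#'   Default TRUE (requires `n_tfs * targets_per_tf <= n_genes`).
#' @param layers Character vector of layer ids. Default: the nine-layer
#'   design (promoter/distal ATAC, 24 h/72 h RNA, three proteomes, two
#'   phosphoproteomes).
#' @param replicates_per_group Replicates in each condition per layer.
#'   Default 4.
#' @param driver_tfs List of drivers, each `list(tf =, delta =, layers =)`:
#'   the TF id, its activation effect in log2 units, and the layer ids it
#'   affects. Default: one driver (`TF01`, delta = 1) affecting the two RNA
#'   layers, the 24 h whole-kidney proteome and the 24 h phosphoproteome.
#' @param background_de_fraction Fraction of non-target genes receiving a
#'   random +/-`background_delta` shift, drawn independently per layer.
#'   Default 0.05.
#' @param background_delta Magnitude of background shifts (log2). Default 1.
#' @param noise_sd Replicate noise SD on the log2 scale. Default 0.25.
#' @param baseline_log_mean,baseline_log_sd Per-gene-per-layer baseline
#'   log2 abundance distribution. Defaults 6 and 1.5 (TPM-like abundances
#'   centred near 64 with most mass well above the TPM = 1 floor).
#' @param promoter_peak_fraction Fraction of peaks placed inside their
#'   gene's promoter-TSS window. Default 0.5; the rest split between
#'   intronic and intergenic placement.
#' @param motif_planting_rate_target,motif_planting_rate_background
#'   Probability that a peak of a driver-target (resp. other) gene carries
#'   the driver motif. Defaults 0.6 and 0.28.
#' @param footprint_depth Relative Tn5 insertion dip over the motif span,
#'   in \[0, 1\]. Default 0.5.
#' @param flank_halfwidth Half-width of the footprint window in bp.
#'   Default 100.
#' @param cut_lambda Mean insertion count per base in open flanks.
#'   Default 20.
#' @param n_cut_sites Motif sites in the cut-count matrices. Default 200.
#' @param treatment_flank_gain Multiplicative accessibility gain of the
#'   treatment condition around bound motifs. Default 1.5.
#' @param motif_length Motif span in bp for the footprint dip. Default 10.
#' @param gene_length,intergenic_gap,peak_width Genome geometry in bp.
#' @param chrom_length Chromosome length; `NULL` (default) sizes it to fit
#'   the gene bodies exactly. A length too small to pack the genes is an
#'   error.
#' @param seed Integer seed controlling every random draw.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 2000,
                       n_tfs = 10,
                       targets_per_tf = 50,
                       regulons_disjoint = TRUE,
                       layers = DEFAULT_LAYERS,
                       replicates_per_group = 4,
                       driver_tfs = list(list(tf = "TF01", delta = 1,
                                              layers = c("rna_s1_24h", "rna_s1_72h",
                                                         "prot_whole_24h",
                                                         "phos_whole_24h"))),
                       background_de_fraction = 0.05,
                       background_delta = 1,
                       noise_sd = 0.25,
                       baseline_log_mean = 6,
                       baseline_log_sd = 1.5,
                       promoter_peak_fraction = 0.5,
                       motif_planting_rate_target = 0.6,
                       motif_planting_rate_background = 0.28,
                       footprint_depth = 0.5,
                       flank_halfwidth = 100,
                       cut_lambda = 20,
                       n_cut_sites = 200,
                       treatment_flank_gain = 1.5,
                       motif_length = 10,
                       gene_length = 4000,
                       intergenic_gap = 3000,
                       peak_width = 200,
                       chrom_length = NULL,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_tfs = n_tfs, targets_per_tf = targets_per_tf,
              regulons_disjoint = isTRUE(regulons_disjoint), layers = layers,
              replicates_per_group = replicates_per_group,
              driver_tfs = driver_tfs,
              background_de_fraction = background_de_fraction,
              background_delta = background_delta, noise_sd = noise_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              promoter_peak_fraction = promoter_peak_fraction,
              motif_planting_rate_target = motif_planting_rate_target,
              motif_planting_rate_background = motif_planting_rate_background,
              footprint_depth = footprint_depth,
              flank_halfwidth = flank_halfwidth, cut_lambda = cut_lambda,
              n_cut_sites = n_cut_sites,
              treatment_flank_gain = treatment_flank_gain,
              motif_length = motif_length, gene_length = gene_length,
              intergenic_gap = intergenic_gap, peak_width = peak_width,
              chrom_length = chrom_length, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is_count(cfg$n_genes), is_count(cfg$n_tfs), is_count(cfg$targets_per_tf),
            is_count(cfg$replicates_per_group, min = 2L),
            is_count(cfg$n_cut_sites), is_count(cfg$motif_length),
            is_count(cfg$gene_length), is_count(cfg$intergenic_gap),
            is_count(cfg$peak_width))
  stopifnot(is.character(cfg$layers), length(cfg$layers) >= 1L,
            !anyDuplicated(cfg$layers))
  props <- c(cfg$background_de_fraction, cfg$promoter_peak_fraction,
             cfg$motif_planting_rate_target, cfg$motif_planting_rate_background,
             cfg$footprint_depth)
  if (!all(vapply(props, is_proportion, TRUE))) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is_scalar_num(cfg$noise_sd), cfg$noise_sd > 0,
            is_scalar_num(cfg$baseline_log_sd), cfg$baseline_log_sd > 0,
            is_scalar_num(cfg$background_delta),
            is_scalar_num(cfg$treatment_flank_gain), cfg$treatment_flank_gain > 0,
            is_scalar_num(cfg$cut_lambda), cfg$cut_lambda > 0,
            is_count(cfg$flank_halfwidth))
  if (cfg$flank_halfwidth < ceiling(cfg$motif_length / 2)) {
    stop("flank_halfwidth must be at least the motif half-length", call. = FALSE)
  }
  if (cfg$regulons_disjoint && cfg$n_tfs * cfg$targets_per_tf > cfg$n_genes) {
    stop("disjoint regulons infeasible: n_tfs * targets_per_tf > n_genes",
         call. = FALSE)
  }
  for (d in cfg$driver_tfs) {
    stopifnot(is.list(d), !is.null(d$tf), is_scalar_num(d$delta))
    if (!all(d$layers %in% cfg$layers)) {
      stop("driver '", d$tf, "' affects unknown layer(s)", call. = FALSE)
    }
  }
  stopifnot(is_count(cfg$seed, min = 0L))
  invisible(cfg)
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
tf_ids <- function(n) sprintf("TF%02d", seq_len(n))

#' Simulate TF regulons
#'
#' Draws `n_tfs` regulons of exactly `targets_per_tf` target genes each.
#' When `regulons_disjoint`, targets are sampled without replacement across
#' regulons so the regulons partition a subset of the gene space; otherwise
#' each regulon samples independently (expected pairwise overlap of two
#' size-k regulons is then k^2 / n_genes). Deterministic under the config
#' seed. Drivers listed in `driver_tfs` must name one of the generated TFs.
#'
#' @param config A [sim_config()].
#' @return Named list of character vectors (TF id -> target gene ids).
#' @export
simulate_regulons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids(config$n_genes)
  tfs <- tf_ids(config$n_tfs)
  with_seed(config$seed + 1L, {
    if (config$regulons_disjoint) {
      picked <- sample(genes, config$n_tfs * config$targets_per_tf)
      sets <- split(picked, rep(seq_len(config$n_tfs), each = config$targets_per_tf))
    } else {
      sets <- lapply(seq_len(config$n_tfs), function(i) {
        sample(genes, config$targets_per_tf)
      })
    }
    setNames(lapply(sets, sort), tfs)
  })
}

#' Generate the genomic fixture of a synthetic study
#'
#' Lays out `n_genes` non-overlapping gene bodies on one linear chromosome
#' with alternating strands, three exons each, and one ATAC peak per gene:
#' a `promoter_peak_fraction` share of peaks is placed inside the gene's
#' promoter-TSS window (orientation-aware), the remainder split between a
#' first-intron and an intergenic placement. Each peak carries a motif flag
#' planted at `motif_planting_rate_target` when its gene is a driver-TF
#' target (per [simulate_regulons()]) and at
#' `motif_planting_rate_background` otherwise.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (gene-model data frame, see
#'   [read_gene_models()]) and `peaks` (interval data frame with extra
#'   columns `gene`, `region`, `motif_flag`).
#' @export
make_genome_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  glen <- config$gene_length
  gap <- config$intergenic_gap
  pitch <- glen + gap
  needed <- n * pitch + gap
  if (!is.null(config$chrom_length) && config$chrom_length < needed) {
    stop("gene bodies cannot be packed into chromosome length ",
         config$chrom_length, " (need ", needed, ")", call. = FALSE)
  }
  ids <- gene_ids(n)
  start <- gap + (seq_len(n) - 1L) * pitch
  end <- start + glen
  strand <- rep(c("+", "-"), length.out = n)
  tss <- ifelse(strand == "+", start, end - 1L)
  # three exons at fixed offsets within the body; introns in between
  e1 <- round(glen * 0.1); e2a <- round(glen * 0.45); e2b <- round(glen * 0.55)
  e3 <- round(glen * 0.9)
  genes <- data.frame(gene_id = ids, chrom = "chr1", strand = strand,
                      tss = tss, start = start, end = end,
                      exon_starts = paste(start, start + e2a, start + e3, sep = ","),
                      exon_ends = paste(start + e1, start + e2b, end, sep = ","))
  validate_gene_models(genes)

  regulons <- simulate_regulons(config)
  drivers <- vapply(config$driver_tfs, `[[`, "", "tf")
  target_genes <- unique(unlist(regulons[intersect(drivers, names(regulons))]))

  pk <- with_seed(config$seed + 2L, {
    w <- config$peak_width
    region <- ifelse(stats::runif(n) < config$promoter_peak_fraction, "promoter-TSS",
                     ifelse(stats::runif(n) < 0.5, "intronic", "intergenic"))
    pstart <- integer(n)
    # promoter: centred on the TSS (always overlaps the window on either strand)
    pstart[region == "promoter-TSS"] <- tss[region == "promoter-TSS"] - w %/% 2L
    # intronic: inside the first intron, clear of any promoter window
    pstart[region == "intronic"] <- start[region == "intronic"] + e1 + 100L
    # intergenic: in the upstream gap, clear of this and the previous
    # gene's promoter windows
    pstart[region == "intergenic"] <- start[region == "intergenic"] - 1800L
    rate <- ifelse(ids %in% target_genes,
                   config$motif_planting_rate_target,
                   config$motif_planting_rate_background)
    motif <- stats::runif(n) < rate
    data.frame(chrom = "chr1", start = pstart, end = pstart + w,
               name = sprintf("peak%05d", seq_len(n)), strand = ".",
               gene = ids, region = region, motif_flag = motif)
  })
  pk$gene[pk$region == "intergenic"] <- NA_character_
  list(genes = genes, peaks = pk)
}

#' Simulate a complete synthetic multi-omics study
#'
#' Generates regulons, the genomic fixture, replicate abundance matrices
#' for every layer and footprint cut-count matrices, recording the planted
#' truth. Replicate abundances are `2^(baseline + effect * treated +
#' Gaussian noise)`; driver targets receive `+delta` in the driver's
#' affected layers (treatment group only), and per layer an independent
#' `background_de_fraction` of the remaining genes receives a random
#' `+/-background_delta` shift. The two ATAC layers are keyed by peak id
#' (promoter peaks in `atac_promoter`, intronic/intergenic peaks in
#' `atac_distal`) with each peak inheriting its gene's effect; the other
#' layers are keyed by gene id.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_study`: list with `config`, `layers` (named list of
#'   [replicate_matrix()]), `regulons`, `genes`, `peaks`, `cut_counts`
#'   (see [simulate_cut_counts()]) and `truth` (list with `driver_tfs`,
#'   `effect` -- data frame `gene`, `layer`, `delta`, `source` -- and
#'   `is_true_target`, a named logical over genes).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  regulons <- simulate_regulons(config)
  genome <- make_genome_fixture(config)
  genes <- gene_ids(config$n_genes)
  drivers <- vapply(config$driver_tfs, `[[`, "", "tf")
  unknown <- setdiff(drivers, names(regulons))
  if (length(unknown)) {
    stop("driver TF(s) not among simulated regulons: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  target_genes <- unique(unlist(regulons[drivers]))
  is_true_target <- setNames(genes %in% target_genes, genes)

  R <- config$replicates_per_group
  samples <- c(sprintf("sham_%d", seq_len(R)), sprintf("unx_%d", seq_len(R)))
  groups <- setNames(rep(c("sham", "unx"), each = R), samples)
  treated <- groups == "unx"

  out <- with_seed(config$seed + 3L, {
    effect_rows <- list()
    layer_mats <- list()
    for (layer in config$layers) {
      eff <- setNames(numeric(length(genes)), genes)
      src <- setNames(character(length(genes)), genes)
      for (d in config$driver_tfs) {
        if (layer %in% d$layers) {
          tg <- regulons[[d$tf]]
          eff[tg] <- eff[tg] + d$delta
          src[tg] <- d$tf
        }
      }
      bg_pool <- genes[eff == 0 & !is_true_target]
      n_bg <- round(config$background_de_fraction * length(bg_pool))
      if (n_bg > 0) {
        bg <- sample(bg_pool, n_bg)
        eff[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) * config$background_delta
        src[bg] <- "background"
      }
      nz <- eff != 0
      if (any(nz)) {
        effect_rows[[layer]] <- data.frame(gene = genes[nz], layer = layer,
                                           delta = unname(eff[nz]),
                                           source = unname(src[nz]))
      }
      if (layer %in% c("atac_promoter", "atac_distal")) {
        sel <- if (layer == "atac_promoter") genome$peaks$region == "promoter-TSS"
               else genome$peaks$region != "promoter-TSS"
        feat <- genome$peaks$name[sel]
        feat_gene <- genome$peaks$gene[sel]
        feat_eff <- ifelse(is.na(feat_gene), 0, eff[feat_gene])
      } else {
        feat <- genes
        feat_eff <- unname(eff)
      }
      nf <- length(feat)
      if (nf == 0L) {
        stop("layer '", layer, "' has no features under this configuration ",
             "(e.g. promoter_peak_fraction leaves a peak class empty)",
             call. = FALSE)
      }
      base <- stats::rnorm(nf, config$baseline_log_mean, config$baseline_log_sd)
      log2_ab <- outer(base, rep(1, 2 * R)) +
        outer(feat_eff, as.numeric(treated)) +
        matrix(stats::rnorm(nf * 2 * R, 0, config$noise_sd), nrow = nf)
      values <- 2^log2_ab
      dimnames(values) <- list(feat, samples)
      layer_mats[[layer]] <- replicate_matrix(values, groups)
    }
    list(effect = if (length(effect_rows)) do.call(rbind, c(effect_rows, make.row.names = FALSE))
         else data.frame(gene = character(), layer = character(),
                         delta = numeric(), source = character()),
         layers = layer_mats)
  })

  cuts <- simulate_cut_counts(config)

  structure(list(config = config,
                 layers = out$layers,
                 regulons = regulons,
                 genes = genome$genes,
                 peaks = genome$peaks,
                 cut_counts = cuts,
                 truth = list(driver_tfs = drivers,
                              effect = out$effect,
                              is_true_target = is_true_target)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d genes, %d layers, %d regulons, ",
                     "%d driver(s) [%s]\n"),
              x$config$n_genes, length(x$layers), length(x$regulons),
              length(x$truth$driver_tfs),
              paste(x$truth$driver_tfs, collapse = ", ")))
  invisible(x)
}

#' Simulate Tn5 cut-count matrices around motif sites
#'
#' Draws Poisson insertion counts per base in a window of
#' `+/-flank_halfwidth` bp around `n_cut_sites` motif sites for the two
#' conditions. Both conditions carry a multiplicative dip of
#' `(1 - footprint_depth)` over the central motif span; the treatment
#' condition's profile is additionally scaled by `treatment_flank_gain`,
#' emulating increased accessibility around bound motifs. Site strands
#' alternate so strand-aware aggregation is exercised downstream.
#'
#' @param config A [sim_config()].
#' @return A list with integer matrices `sham` and `unx` (rows = sites,
#'   columns = offsets, column names are the signed offsets), `strands`,
#'   and `offsets`.
#' @export
simulate_cut_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  F <- config$flank_halfwidth
  offsets <- seq(-F, F)
  half_motif <- config$motif_length / 2
  dip <- ifelse(abs(offsets) <= half_motif, 1 - config$footprint_depth, 1)
  n <- config$n_cut_sites
  strands <- rep(c("+", "-"), length.out = n)
  with_seed(config$seed + 4L, {
    lam_sham <- config$cut_lambda * dip
    lam_unx <- config$cut_lambda * config$treatment_flank_gain * dip
    draw <- function(lam) {
      m <- matrix(stats::rpois(n * length(offsets), rep(lam, each = n)), nrow = n)
      dimnames(m) <- list(sprintf("site%04d", seq_len(n)), offsets)
      m
    }
    list(sham = draw(lam_sham), unx = draw(lam_unx),
         strands = strands, offsets = offsets)
  })
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the community-standard interchange files: peaks as BED, regulons
#' as GMT, per-layer replicate matrices with group sidecars as TSV, the
#' gene-model table as TSV and the cut-count matrices as TSV.
#'
#' @param study A [simulate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bed(study$peaks, file.path(outdir, "peaks.bed"))
  write_gmt(study$regulons, file.path(outdir, "regulons.gmt"))
  write_gene_models(study$genes, file.path(outdir, "gene_models.tsv"))
  for (layer in names(study$layers)) {
    write_matrix(study$layers[[layer]],
                 file.path(outdir, paste0(layer, ".tsv")),
                 file.path(outdir, paste0(layer, ".groups.tsv")))
  }
  for (cond in c("sham", "unx")) {
    m <- study$cut_counts[[cond]]
    df <- data.frame(site = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(outdir, paste0("cut_counts_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
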
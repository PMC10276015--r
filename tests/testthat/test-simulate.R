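test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 10, n_tfs = 3, targets_per_tf = 5),
               "disjoint regulons infeasible")
  expect_error(sim_config(background_de_fraction = 1.5), "proportions")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(flank_halfwidth = 3, motif_length = 10),
               "flank_halfwidth")
  expect_error(sim_config(driver_tfs = list(list(tf = "TF01", delta = 1,
                                                 layers = "nolayer"))),
               "unknown layer")
  expect_error(simulate_study(sim_config(
    n_tfs = 2, driver_tfs = list(list(tf = "TF99", delta = 1,
                                      layers = "rna_s1_24h")))),
    "not among simulated regulons")
})

test_that("regulons have the configured size and partition when disjoint", {
  cfg <- tiny_config(n_genes = 10 * 20, n_tfs = 10, targets_per_tf = 20)
  regs <- simulate_regulons(cfg)
  expect_length(regs, 10)
  expect_true(all(lengths(regs) == 20))
  all_targets <- unlist(regs)
  expect_false(anyDuplicated(all_targets) > 0)
  expect_setequal(all_targets, sprintf("gene%05d", 1:200))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config()
  expect_identical(simulate_regulons(cfg), simulate_regulons(cfg))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$layers, s2$layers)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$cut_counts, s2$cut_counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(tiny_config(seed = 43))
  expect_false(identical(s1$layers, s3$layers))
})

test_that("non-disjoint regulon overlap matches the hypergeometric expectation", {
  # two size-k sets drawn independently from n genes overlap k^2/n on average
  n <- 200; k <- 20
  overlaps <- vapply(1:1000, function(i) {
    cfg <- sim_config(n_genes = n, n_tfs = 2, targets_per_tf = k,
                      regulons_disjoint = FALSE, seed = i)
    regs <- simulate_regulons(cfg)
    length(intersect(regs[[1]], regs[[2]]))
  }, 0)
  expected <- k^2 / n
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 4 * se + 1e-9)
})

test_that("promoter_peak_fraction = 1 makes every peak promoter-assignable", {
  cfg <- tiny_config(promoter_peak_fraction = 1)
  fx <- make_genome_fixture(cfg)
  ann <- assign_to_promoter(fx$peaks, fx$genes)
  expect_true(all(ann$region_class == "promoter-TSS"))
  # and the planted region labels are recovered by classification
  cls <- classify_region(fx$peaks, fx$genes)
  expect_true(all(cls$region_class == "promoter-TSS"))
})

test_that("planted region labels are recovered by independent classification", {
  cfg <- tiny_config(promoter_peak_fraction = 0.5)
  fx <- make_genome_fixture(cfg)
  cls <- classify_region(fx$peaks, fx$genes)
  expect_equal(cls$region_class, fx$peaks$region)
  # peaks assigned to the generating gene wherever a gene is defined
  has_gene <- !is.na(fx$peaks$gene)
  expect_equal(cls$gene[has_gene], fx$peaks$gene[has_gene])
})

test_that("generated peaks survive a BED round trip", {
  cfg <- tiny_config()
  fx <- make_genome_fixture(cfg)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(fx$peaks, f)
  back <- read_bed(f)
  expect_equal(back$start, fx$peaks$start)
  expect_equal(back$end, fx$peaks$end)
  expect_equal(back$name, fx$peaks$name)
})

test_that("an explicit chromosome too short for the genes is an error", {
  expect_error(make_genome_fixture(tiny_config(chrom_length = 1000)),
               "cannot be packed")
})

test_that("truth records exactly the genes with planted effects", {
  cfg <- tiny_config(background_de_fraction = 0.1)
  st <- simulate_study(cfg)
  eff <- st$truth$effect
  expect_true(all(eff$delta != 0))
  # driver rows cover exactly regulon targets in affected layers
  driver <- cfg$driver_tfs[[1]]
  for (layer in driver$layers) {
    drv_rows <- eff[eff$layer == layer & eff$source == driver$tf, ]
    expect_setequal(drv_rows$gene, st$regulons[[driver$tf]])
    expect_true(all(drv_rows$delta == driver$delta))
  }
  # no effects in unaffected layers beyond background
  for (layer in setdiff(names(st$layers), driver$layers)) {
    expect_true(all(eff$source[eff$layer == layer] == "background"))
  }
  # background shifts only hit non-target genes
  bg <- eff[eff$source == "background", ]
  expect_true(all(!st$truth$is_true_target[bg$gene]))
  expect_true(all(abs(bg$delta) == cfg$background_delta))
})

test_that("planted log2 shifts are recovered without bias", {
  cfg <- sim_config(n_genes = 1000, seed = 5)
  st <- simulate_study(cfg)
  tbl <- differential_summary(st$layers[["rna_s1_24h"]], treatment = "unx")
  targets <- st$regulons[["TF01"]]
  obs <- tbl$log2_ratio[tbl$feature %in% targets]
  # closed-form sampling error of the mean over n targets:
  # each observed ratio has SD noise_sd * sqrt(2 / R)
  tol <- 3 * cfg$noise_sd * sqrt(2 / cfg$replicates_per_group) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 1.0), tol + 0.02)  # small pseudocount shrinkage
})

test_that("a null study carries no truth rows and calibrated raw p-values", {
  cfg <- sim_config(n_genes = 6000, n_tfs = 2, targets_per_tf = 10,
                    layers = "rna_s1_24h", driver_tfs = list(),
                    background_de_fraction = 0, seed = 9)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$truth$effect), 0)
  expect_false(any(st$truth$is_true_target))
  tbl <- differential_summary(st$layers[["rna_s1_24h"]], treatment = "unx")
  # raw Welch p-values should be Uniform(0,1) under the null
  ks <- suppressWarnings(ks.test(tbl$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # per-layer |z| > 1.96 flag rate ~ 5%
  zb <- zscore_binarize(build_layer_matrix(list(l = tbl)))
  rate <- mean(zb$flags)
  se <- sqrt(0.05 * 0.95 / nrow(tbl))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("cut-count matrices have the configured geometry and null behavior", {
  cfg <- tiny_config(n_cut_sites = 400, footprint_depth = 0, cut_lambda = 15)
  cuts <- simulate_cut_counts(cfg)
  expect_equal(dim(cuts$sham), c(400, 2 * cfg$flank_halfwidth + 1))
  expect_equal(cuts$offsets, -cfg$flank_halfwidth:cfg$flank_halfwidth)
  # depth 0: flat profile, per-offset means within Poisson error of lambda
  mean_per_offset <- colMeans(cuts$sham)
  expect_true(all(abs(mean_per_offset - 15) < 4 * sqrt(15 / 400)))
  expect_identical(simulate_cut_counts(cfg)$sham, cuts$sham)
})

test_that("a study writes to plain-text files that read back consistently", {
  cfg <- tiny_config()
  st <- simulate_study(cfg)
  outdir <- withr::local_tempdir()
  write_study(st, outdir)
  regs <- read_gmt(file.path(outdir, "regulons.gmt"))
  expect_equal(regs$TF01, st$regulons$TF01)
  rm <- read_matrix(file.path(outdir, "rna_s1_24h.tsv"),
                    file.path(outdir, "rna_s1_24h.groups.tsv"))
  expect_equal(dim(rm$values), dim(st$layers[["rna_s1_24h"]]$values))
  expect_equal(rm$values[1, 1], st$layers[["rna_s1_24h"]]$values[1, 1],
               tolerance = 1e-6)
  genes <- read_gene_models(file.path(outdir, "gene_models.tsv"))
  expect_equal(genes$tss, st$genes$tss)
})
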
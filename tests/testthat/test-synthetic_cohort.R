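test_that("an empty configuration yields an empty bundle and truth table", {
  b <- generate_cohort(sim_config(n_cases = 0, n_controls = 0, seed = 1))
  expect_equal(nrow(b$samples), 0)
  expect_equal(nrow(b$variants), 0)
  expect_equal(nrow(b$truth), 0)
})

test_that("spiked events are book-kept in the truth table", {
  cfg <- sim_config(n_cases = 2, n_controls = 0, seed = 3,
                    slofv_case_excess = 0, make_depth = FALSE,
                    spike_specs = list(spike_spec("aneuploidy", 1,
                                                  chrom = "21")))
  b <- generate_cohort(cfg)
  tr <- b$truth[b$truth$sample == "CASE001", ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$kind, "aneuploidy")
  expect_equal(tr$chrom, "21")

  bad <- sim_config(n_cases = 1, n_controls = 0, seed = 3,
                    spike_specs = list(spike_spec("aneuploidy", 5,
                                                  chrom = "21")))
  expect_error(generate_cohort(bad), "out of range")
})

test_that("a fixed seed reproduces the bundle exactly", {
  cfg <- sim_config(n_cases = 3, n_controls = 2, seed = 17,
                    spike_specs = list(spike_spec("snv", 2)))
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$cnvs, b2$cnvs)
  expect_identical(b1$samples, b2$samples)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$depth_profiles, b2$depth_profiles)
})

test_that("per-sample draws are stable when the cohort grows", {
  cfg_small <- sim_config(n_cases = 2, n_controls = 0, seed = 23,
                          slofv_case_excess = 0, make_depth = FALSE)
  cfg_big <- sim_config(n_cases = 6, n_controls = 3, seed = 23,
                        slofv_case_excess = 0, make_depth = FALSE)
  v_small <- generate_cohort(cfg_small)$variants
  v_big <- generate_cohort(cfg_big)$variants
  expect_identical(v_small[v_small$sample == "CASE002", ],
                   v_big[v_big$sample == "CASE002", ])
})

test_that("depth-profile means scale with copy number", {
  cfg <- sim_config(seed = 5, dispersion = 0, gc_bias_strength = 0,
                    genome_scale = 1 / 4, bin_width = 50e3)
  g <- synthetic_genome(cfg)
  expect_gt(nrow(g$bins), 1e4)
  p <- generate_depth_profile(c(X = 2, Y = 0, "18" = 3), cfg, g,
                              sample_id = "T", seed = 7)
  auto_dis <- p$count[p$chrom %in% as.character(c(1:17, 19:22))]
  m18 <- mean(p$count[p$chrom == "18"])
  expect_equal(m18 / mean(auto_dis), 1.5, tolerance = 0.01)
  # X monosomy halves the X mean relative to a disomic X
  p45x <- generate_depth_profile(c(X = 1, Y = 0), cfg, g, sample_id = "X",
                                 seed = 8)
  pxx <- generate_depth_profile(c(X = 2, Y = 0), cfg, g, sample_id = "XX",
                                seed = 9)
  expect_equal(mean(p45x$count[p45x$chrom == "X"]) /
                 mean(pxx$count[pxx$chrom == "X"]), 0.5, tolerance = 0.02)
  # Poisson limit: per-chromosome means within 1% of the analytic value
  for (ch in c("1", "7", "16")) {
    expect_equal(mean(p$count[p$chrom == ch]), cfg$mean_reads_per_bin,
                 tolerance = 0.01)
  }
  expect_error(
    generate_depth_profile(c(X = 5, Y = 0), cfg, g),
    "0..4")
  bad <- cfg
  bad$mean_reads_per_bin <- 0
  expect_error(generate_depth_profile(c(X = 1, Y = 1), bad, g), "positive")
  expect_error(sim_config(mean_reads_per_bin = -3), "positive")
})

test_that("the SLoFV spike adds Poisson-many cohort-unique LoF variants", {
  cfg <- sim_config(n_cases = 100, n_controls = 0, seed = 31,
                    slofv_case_excess = 0, make_depth = FALSE,
                    background_snv_rate = 20)
  b <- generate_cohort(cfg)
  expect_identical(spike_slofv_excess(b, 0), b)
  b5 <- spike_slofv_excess(b, 5, seed = 99)
  added <- attr(b5, "slofv_spiked")
  expect_lt(abs(added - 500), 3 * sqrt(500))
  extra <- b5$variants[seq(nrow(b$variants) + 1, nrow(b5$variants)), ]
  expect_true(all(extra$consequence %in% lof_consequences()))
  expect_true(all(extra$af_public == 0))
  # each added variant passes burden QC and is seen in exactly one sample
  expect_equal(nrow(qc_filter(extra)), nrow(extra))
  flags <- find_singletons(b5$variants)
  extra_keys <- paste(extra$chrom, extra$pos, extra$ref, extra$alt)
  all_keys <- paste(b5$variants$chrom, b5$variants$pos, b5$variants$ref,
                    b5$variants$alt)
  expect_true(all(flags[all_keys %in% extra_keys]))
})

test_that("with zero excess, case and control burdens are exchangeable", {
  rejections <- 0
  for (s in 1:30) {
    cfg <- sim_config(n_cases = 40, n_controls = 40, seed = 1000 + s,
                      slofv_case_excess = 0, make_depth = FALSE,
                      background_snv_rate = 40)
    bt <- burden_test(count_burden(generate_cohort(cfg)), "lof", 0.001)
    if (bt$p.value < 0.001) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("spiked events are recoverable from the emitted data", {
  cfg <- sim_config(
    n_cases = 3, n_controls = 0, seed = 41, slofv_case_excess = 0,
    spike_specs = list(
      spike_spec("snv", 1, consequence = "missense", class = "LP"),
      spike_spec("intragenic_cnv", 2, gene = "G005"),
      spike_spec("cnv", 3, chrom = "4", start = 1000001, end = 2200000,
                 copy_number = 3)))
  b <- generate_cohort(cfg)
  tr_snv <- b$truth[b$truth$kind == "snv", ]
  v <- b$variants
  expect_true(any(v$sample == tr_snv$sample & v$chrom == tr_snv$chrom &
                    v$pos == tr_snv$start))
  tr_ig <- b$truth[b$truth$kind == "intragenic_cnv", ]
  expect_true(any(b$cnvs$sample == tr_ig$sample &
                    b$cnvs$start == tr_ig$start &
                    b$cnvs$end == tr_ig$end))
  p <- b$depth_profiles[["CASE003"]]
  spiked_bins <- p$chrom == "4" & p$start >= 1000001 & p$end <= 2200000
  other <- p$chrom == "4" & !spiked_bins
  expect_gt(mean(p$count[spiked_bins]) / mean(p$count[other]), 1.3)
})
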
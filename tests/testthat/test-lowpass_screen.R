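# Shared scaffolding for the low-pass tests: one reduced genome, profiles
# drawn at the default noise model.
lp_cfg <- sim_config(seed = 101)
lp_genome <- synthetic_genome(lp_cfg)

test_that("GC correction is exact on flat profiles and removes a known
           GC curve", {
  bins <- lp_genome$bins
  flat <- data.frame(sample = "F", bins[, c("chrom", "start", "end")],
                     count = 500, gc = 0.5)
  cf <- gc_correct(flat)
  expect_true(all(cf$ratio == 1))

  curve <- bins
  curve$sample <- "Q"
  curve$count <- 500 * (1 - 3 * (curve$gc - 0.45)^2)
  pre_spread <- stats::sd(curve$count / stats::median(curve$count))
  post <- gc_correct(curve)
  expect_lt(stats::sd(post$ratio), 0.01 * pre_spread)
})

test_that("GC correction normalises the autosomal median to 1 and is
           idempotent on its own output", {
  p <- generate_depth_profile(c(X = 1, Y = 1), lp_cfg, lp_genome,
                              sample_id = "A", seed = 11)
  pc <- gc_correct(p)
  auto <- pc$chrom %in% as.character(1:22)
  expect_lt(abs(stats::median(pc$ratio[auto]) - 1), 1e-6)
  pc2 <- gc_correct(pc)
  expect_lt(max(abs(pc2$ratio - pc$ratio)), 1e-9)
})

test_that("a trisomic chromosome keeps its 1.5 ratio through correction", {
  p <- generate_depth_profile(c(X = 2, Y = 0, "13" = 3), lp_cfg, lp_genome,
                              sample_id = "T", seed = 13)
  pc <- gc_correct(p)
  expect_equal(stats::median(pc$ratio[pc$chrom == "13"]), 1.5,
               tolerance = 0.03)
})

test_that("too few autosomal bins is an error", {
  small <- lp_genome$bins[1:30, ]
  small$count <- 500
  expect_error(gc_correct(cbind(sample = "S", small)), "insufficient bins")
})

test_that("aneuploidy calls are complete and specific across seeds", {
  for (s in 1:10) {
    pe <- gc_correct(generate_depth_profile(c(X = 1, Y = 1), lp_cfg,
                                            lp_genome, sample_id = "E",
                                            seed = 400 + s))
    expect_equal(nrow(call_aneuploidy(pe)), 0)
    chrom <- as.character(sample(1:22, 1))
    pt <- gc_correct(generate_depth_profile(
      stats::setNames(c(1, 1, 3), c("X", "Y", chrom)), lp_cfg, lp_genome,
      sample_id = "T", seed = 500 + s))
    ca <- call_aneuploidy(pt)
    expect_true(any(ca$chrom == chrom & ca$direction == "gain" &
                      ca$copy_number == 3))
  }
})

test_that("45,X is called as an X loss with quiet autosomes", {
  px <- gc_correct(generate_depth_profile(c(X = 1, Y = 0), lp_cfg,
                                          lp_genome, sample_id = "X",
                                          seed = 77))
  ca <- call_aneuploidy(px)
  expect_true(any(ca$chrom == "X" & ca$direction == "loss"))
  expect_false(any(ca$chrom %in% as.character(1:22)))
})

test_that("an intermediate sex-chromosome state is flagged possible
           mosaic", {
  # X at ~1.5 copies in a male background emulates a mosaic XXY signal
  p <- generate_depth_profile(c(X = 1, Y = 1), lp_cfg, lp_genome,
                              sample_id = "M", seed = 79)
  p$count[p$chrom == "X"] <- round(p$count[p$chrom == "X"] * 1.5)
  ca <- call_aneuploidy(gc_correct(p))
  x <- ca[ca$chrom == "X", ]
  expect_equal(nrow(x), 1)
  expect_true(x$mosaic)
})

test_that("segmentation recovers spiked CNVs and stays quiet on flat
           profiles", {
  # 5-Mb deletion on the largest chromosome
  p <- generate_depth_profile(
    c(X = 1, Y = 1), lp_cfg, lp_genome,
    cnv_regions = data.frame(chrom = "1", start = 3000001, end = 8000000,
                             copy_number = 1),
    sample_id = "D", seed = 21)
  segs <- segment_cnvs(gc_correct(p))
  hit <- segs[segs$chrom == "1" & segs$copy_number == 1, ]
  expect_gte(nrow(hit), 1)
  ov <- sum(pmin(hit$end, 8000000) - pmax(hit$start, 3000001) + 1)
  expect_gte(ov, 0.9 * 5e6)

  flat <- gc_correct(generate_depth_profile(c(X = 1, Y = 1), lp_cfg,
                                            lp_genome, sample_id = "F",
                                            seed = 22))
  expect_equal(nrow(segment_cnvs(flat)), 0)
})

test_that("a 16.5-Mb duplication is called at copy number 3 in the
           chromosomal tier", {
  cfg <- sim_config(seed = 5, genome_scale = 1, bin_width = 500e3)
  g <- synthetic_genome(cfg)
  p <- generate_depth_profile(
    c(X = 1, Y = 1), cfg, g,
    cnv_regions = data.frame(chrom = "2", start = 30000001, end = 46500000,
                             copy_number = 3),
    sample_id = "G", seed = 23)
  segs <- segment_cnvs(gc_correct(p), min_size = 1e6)
  hit <- segs[segs$chrom == "2" & segs$copy_number == 3, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$size_tier, "chromosomal")
  expect_gte(hit$size_bp, 16e6)
})

test_that("size tiers partition sizes with exact boundaries", {
  expect_equal(assign_size_tier(14.8e6), "chromosomal")
  expect_equal(assign_size_tier(442e3), "submicroscopic")
  expect_equal(assign_size_tier(1300), "intragenic")
  # boundary regression: 100 kb and 5 Mb belong to the middle tier
  expect_equal(assign_size_tier(c(50, 100e3 - 1, 100e3, 5e6, 5e6 + 1)),
               c("intragenic", "intragenic", "submicroscopic",
                 "submicroscopic", "chromosomal"))
  expect_error(assign_size_tier(49), "50 bp")
  sizes <- c(50, 99, 5000, 99999, 100000, 123456, 4999999, 5e6, 5000001,
             2.5e7)
  tiers <- assign_size_tier(sizes)
  expect_true(all(tiers %in% c("intragenic", "submicroscopic",
                               "chromosomal")))
})

test_that("segmentation validates min_size and turbulent profiles fail
           the dispersion gate", {
  p <- gc_correct(generate_depth_profile(c(X = 1, Y = 1), lp_cfg,
                                         lp_genome, sample_id = "Q",
                                         seed = 31))
  expect_error(segment_cnvs(p, min_size = 10e3), "bin width")
  expect_true(depth_profile_qc(p))
  turb <- sim_config(seed = 6, dispersion = 0.5)
  pt <- gc_correct(generate_depth_profile(c(X = 1, Y = 1), turb, lp_genome,
                                          sample_id = "W", seed = 32))
  expect_false(depth_profile_qc(pt))
})
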
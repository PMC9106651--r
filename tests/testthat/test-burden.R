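test_that("burden QC bounds are inclusive and match a literal predicate", {
  th <- default_thresholds()
  base <- random_variant_table(1, 1)
  probe <- function(depth, alt, ref, alt_allele) {
    v <- base
    v$depth <- depth; v$alt_depth <- alt; v$ref <- ref; v$alt <- alt_allele
    nrow(qc_filter(v, th))
  }
  expect_equal(probe(19, 10, "A", "G"), 0)   # depth below 20
  expect_equal(probe(20, 3, "A", "G"), 1)    # inclusive boundaries
  expect_equal(probe(20, 2, "A", "G"), 0)    # alt depth below 3
  expect_equal(probe(60, 30, "ATTTTTT", "A"), 0)  # 6-bp deletion
  expect_equal(probe(60, 30, "ATTTTT", "A"), 0)   # ref spans 6 bases
  expect_equal(probe(60, 30, "ATTTT", "A"), 1)    # 5 bp passes

  df <- random_variant_table(3000, 7)
  expect_equal(qc_filter(df, th), df[oracle_qc(df, th), ],
               ignore_attr = TRUE)
})

test_that("deleteriousness uses strict score bounds and LoF classes", {
  th <- default_thresholds()
  v <- random_variant_table(1, 2)
  shape <- function(csq, sift = "damaging", cadd = 25, mcap = 0.03,
                    revel = 0.6) {
    v$consequence <- csq; v$sift_class <- sift
    v$cadd <- cadd; v$mcap <- mcap; v$revel <- revel
    is_deleterious(v, th)
  }
  expect_equal(shape("frameshift"), "lof")
  expect_equal(shape("canonical_splice"), "lof")
  expect_equal(shape("missense"), "damaging_missense")
  expect_equal(shape("missense", revel = 0.5), "none")   # strict ">"
  expect_equal(shape("missense", cadd = 20), "none")
  expect_equal(shape("missense", mcap = 0.025), "none")
  expect_equal(shape("missense", sift = "missing"), "none")
  expect_equal(shape("missense", cadd = NA), "none")
  expect_equal(shape("synonymous"), "none")

  df <- random_variant_table(3000, 8)
  expect_equal(is_deleterious(df, th), oracle_deleterious(df, th))
})

test_that("singleton flags equal brute-force occurrence counting", {
  df <- data.frame(
    sample = c("A", "B", "B", "C"),
    chrom = "1", pos = c(100, 100, 200, 300), ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  expect_equal(find_singletons(df), c(FALSE, FALSE, TRUE, TRUE))
  # the same allele twice in one sample is still a singleton (one carrier)
  dup <- data.frame(sample = c("A", "A"), chrom = "1", pos = 5,
                    ref = "A", alt = "T")
  expect_equal(find_singletons(dup), c(TRUE, TRUE))
  for (seed in c(3, 13)) {
    rnd <- random_variant_table(800, seed, n_samples = 12)
    rnd$pos <- sample(1:300, nrow(rnd), replace = TRUE)  # force sharing
    rnd <- rnd[!duplicated(rnd[, c("sample", "chrom", "pos", "ref",
                                   "alt")]), ]
    expect_equal(find_singletons(rnd), oracle_singletons(rnd))
  }
  # the flag is an allele-level property of the counting population: the
  # pos-100 allele is carried by exactly one sample of {B, C}, so both of
  # its rows are flagged
  expect_equal(find_singletons(df, within = c("B", "C")),
               c(TRUE, TRUE, TRUE, TRUE))
})

test_that("burden counts nest across MAF strata and match brute force", {
  cfg <- sim_config(n_cases = 15, n_controls = 15, seed = 91,
                    slofv_case_excess = 2, make_depth = FALSE,
                    background_snv_rate = 40)
  b <- generate_cohort(cfg)
  th <- default_thresholds()
  res <- count_burden(b, th)
  # nesting per sample and kind
  for (k in c("lof", "damaging_missense")) {
    cc <- res$counts[res$counts$kind == k, ]
    w <- reshape(cc[, c("sample", "stratum", "count")],
                 idvar = "sample", timevar = "stratum", direction = "wide")
    expect_true(all(w[[2]] <= w[[3]] & w[[3]] <= w[[4]]))
  }
  # brute-force triple predicate on the QC-passed table
  hq <- qc_filter(b$variants, th)
  sing <- oracle_singletons(hq)
  kind <- oracle_deleterious(hq, th)
  for (k in c("lof", "damaging_missense")) {
    for (s in th$maf_strata) {
      want <- table(factor(hq$sample[sing & kind == k & hq$af_public <= s],
                           levels = b$samples$sample))
      got <- res$counts[res$counts$kind == k & res$counts$stratum == s, ]
      expect_equal(got$count, as.integer(want))
    }
  }
  # a sample with no variants has an all-zero row
  b2 <- b
  b2$samples <- rbind(b2$samples,
                      data.frame(sample = "EMPTY", arm = "control",
                                 sex = "female", phenotypes = ""))
  res2 <- count_burden(b2, th)
  expect_true(all(res2$counts$count[res2$counts$sample == "EMPTY"] == 0))
})

test_that("the rank-sum test matches its exact and approximate oracles", {
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(wilcoxon_two_sided(c(5, 1, 9, 4), c(5, 1, 9, 4))$p.value, 1)
  expect_error(wilcoxon_two_sided(numeric(), 1:3), "nonempty")

  set.seed(55)
  for (k in 1:40) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    v <- sample.int(1000, n + m)  # tie-free
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(wilcoxon_two_sided(x, y)$p.value,
                 oracle_perm_wilcoxon(x, y), tolerance = 1e-12)
  }
  # tied, larger samples: agree with the standard implementation
  set.seed(56)
  for (k in 1:10) {
    x <- rpois(40, 8); y <- rpois(55, 9)
    ours <- wilcoxon_two_sided(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the panel screen restricts the singleton deleterious set", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, seed = 95,
                    slofv_case_excess = 0, make_depth = FALSE,
                    background_snv_rate = 30,
                    spike_specs = list(spike_spec("snv", 4)))
  b <- generate_cohort(cfg)
  spiked_gene <- b$truth$gene[b$truth$kind == "snv"]
  sub <- c("CASE004", "CASE005")
  out <- pcp_panel_screen(b, panel = spiked_gene, subgroup = sub)
  expect_true(all(out$subgroup_hits$gene %in% spiked_gene))
  expect_true(any(out$subgroup_hits$sample == "CASE004"))
  expect_equal(nrow(out$control_hits[out$control_hits$gene ==
                                       spiked_gene, ]), 0)
  # subset property: hits are within the full singleton-deleterious set
  hq <- qc_filter(b$variants)
  full <- hq[find_singletons(hq) & is_deleterious(hq) != "none", ]
  keys <- paste(full$sample, full$chrom, full$pos)
  expect_true(all(paste(out$subgroup_hits$sample, out$subgroup_hits$chrom,
                        out$subgroup_hits$pos) %in% keys))
  expect_error(pcp_panel_screen(b, character(), sub), "nonempty")
  expect_warning(pcp_panel_screen(b, c(spiked_gene, "NOSUCH"), sub),
                 "NOSUCH")
})
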
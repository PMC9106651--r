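test_that("candidate gene lists follow descendant-closure semantics", {
  expect_equal(build_candidate_genes(character(),
                                     data.frame(term = "T001",
                                                gene = "TUBA1A"),
                                     data.frame(term = "T001",
                                                parent = "R")),
               character())
  hpo <- data.frame(term = c("leaf", "leaf"), gene = c("TUBA1A", "ARX"))
  ont <- data.frame(term = "leaf", parent = "root")
  expect_equal(build_candidate_genes("leaf", hpo, ont),
               c("ARX", "TUBA1A"))
  expect_error(build_candidate_genes("nope", hpo, ont), "nope")

  # brute-force union over the term closure on random toy ontologies
  for (seed in c(2, 9)) {
    toy <- random_ontology(100, 60, seed)
    set.seed(seed + 1)
    for (k in 1:10) {
      q <- sample(toy$terms, sample(1:4, 1))
      expect_equal(build_candidate_genes(q, toy$hpo_map, toy$ontology),
                   oracle_candidate_genes(q, toy$hpo_map, toy$ontology))
    }
  }
})

test_that("adding phenotype terms never shrinks the candidate set", {
  toy <- random_ontology(80, 40, 5)
  set.seed(6)
  for (k in 1:20) {
    q <- sample(toy$terms, 2)
    small <- build_candidate_genes(q[1], toy$hpo_map, toy$ontology)
    big <- build_candidate_genes(q, toy$hpo_map, toy$ontology)
    expect_true(all(small %in% big))
  }
})

test_that("the diagnostic SNV filter matches a literal predicate", {
  th <- default_thresholds()
  cand <- sprintf("G%03d", 1:20)
  df <- random_variant_table(2000, 33)
  kept <- filter_snvs_for_diagnosis(df, cand, th)
  expect_equal(kept, df[oracle_snv_filter(df, cand, th), ],
               ignore_attr = TRUE)
  # quoted behaviours: common variants out, canonical splice in
  row <- df[1, ]
  row$af_public <- 0.02; row$af_inhouse <- 0
  row$consequence <- "missense"; row$gene <- "G001"
  expect_equal(nrow(filter_snvs_for_diagnosis(row, cand, th)), 0)
  row$af_public <- 0
  row$consequence <- "canonical_splice"
  expect_equal(nrow(filter_snvs_for_diagnosis(row, cand, th)), 1)
  row$consequence <- "intronic"
  expect_equal(nrow(filter_snvs_for_diagnosis(row, cand, th)), 0)
  # boundary: MAF exactly 0.01 is retained ("> 0.01" is filtered out)
  row$consequence <- "missense"; row$af_public <- 0.01
  expect_equal(nrow(filter_snvs_for_diagnosis(row, cand, th)), 1)
})

test_that("the evidence-combining engine reproduces the published table", {
  expect_equal(classify_variant(c("PVS1", "PM2", "PP4")), "P")
  expect_equal(classify_variant("PVS1,PM2"), "LP")
  expect_equal(classify_variant(character()), "VUS")
  expect_equal(classify_variant("BA1"), "B")
  expect_equal(classify_variant(c("BS1", "BS2")), "B")
  expect_equal(classify_variant(c("BS1", "BP1")), "LB")
  expect_equal(classify_variant(c("BP1", "BP2")), "LB")
  expect_equal(classify_variant(c("PVS1", "PS1", "BA1")), "VUS")
  expect_equal(classify_variant(c("PM1", "PM2", "PM3")), "LP")
  expect_equal(classify_variant(c("PS1", "PS2")), "P")
  expect_error(classify_variant("PX9"), "unknown evidence tag")

  # random tag sets against the literal rule-list oracle
  for (seed in 1:200) {
    tags <- random_acmg_tags(seed)
    cnt <- function(p) sum(startsWith(tags, p) &
                             !startsWith(tags, paste0(p, "S")))
    got <- classify_variant(tags)
    want <- oracle_acmg(sum(startsWith(tags, "PVS")),
                        sum(startsWith(tags, "PS")),
                        sum(startsWith(tags, "PM")),
                        sum(startsWith(tags, "PP")),
                        sum(startsWith(tags, "BA")),
                        sum(startsWith(tags, "BS")),
                        sum(startsWith(tags, "BP")))
    expect_equal(got, want, info = paste(tags, collapse = ","))
  }
})

test_that("fixture evidence tags reproduce every printed SNV class", {
  fx <- load_paper_fixture()
  snv <- fx$snv_table
  got <- vapply(snv$evidence_tags, classify_variant, character(1),
                USE.NAMES = FALSE)
  expect_equal(got, snv$class)
  stil_fs <- snv[snv$gene == "STIL" & grepl("2344", snv$hgvs_c), ]
  expect_equal(classify_variant(stil_fs$evidence_tags), "P")
})

test_that("CNV scores map onto the five-tier scale", {
  expect_equal(score_cnv(0.99), "P")
  expect_equal(score_cnv(0.95), "LP")
  expect_equal(score_cnv(0.90), "LP")
  expect_equal(score_cnv(0.89), "VUS")
  expect_equal(score_cnv(0.3), "LB")
  expect_equal(score_cnv(0), "B")
})

test_that("small-CNV assessment keeps rare exon-overlapping events", {
  set.seed(44)
  exon_bed <- withr::local_tempfile(fileext = ".bed")
  starts <- sort(sample.int(5e6, 50))
  writeLines(paste("7", starts, starts + 200,
                   sprintf("EX%02d", 1:50), sep = "\t"), exon_bed)
  exon_map <- read_intervals(exon_bed)

  n <- 500
  st <- sample.int(5e6, n)
  cnvs <- data.frame(
    sample = "S1", chrom = sample(c("7", "8"), n, replace = TRUE),
    start = st, end = st + sample(c(59, 999, 4159, 80000), n,
                                  replace = TRUE),
    copy_number = 1L,
    freq_inhouse = sample(c(0, 0.005, 0.01, 0.2), n, replace = TRUE))
  cnvs$size_bp <- cnvs$end - cnvs$start + 1
  kept <- triage_small_cnvs(cnvs, exon_map)
  # literal oracle: exon overlap and frequency strictly below 0.01
  want <- logical(n)
  for (i in seq_len(n)) {
    ov <- any(cnvs$chrom[i] == "7" & cnvs$start[i] <= starts + 200 &
                cnvs$end[i] >= starts + 1)
    want[i] <- ov && cnvs$freq_inhouse[i] < 0.01
  }
  expect_setequal(paste(kept$start, kept$end),
                  paste(cnvs$start[want], cnvs$end[want]))
  expect_true(!is.unsorted(rev(kept$size_bp)))
  # frequency at exactly 0.01 is excluded (strictly below)
  at <- cnvs[1, ]; at$chrom <- "7"; at$start <- starts[1]
  at$end <- starts[1] + 4159; at$size_bp <- 4160; at$freq_inhouse <- 0.01
  expect_equal(nrow(triage_small_cnvs(at, exon_map)), 0)
  at$freq_inhouse <- 0
  expect_equal(nrow(triage_small_cnvs(at, exon_map)), 1)
})

test_that("finding categories follow the primary/secondary/carrier rules", {
  expect_equal(assign_finding_category("P", TRUE), "primary")
  expect_equal(assign_finding_category("LP", FALSE, "BRCA2",
                                       sf_gene_list = "BRCA2"), "secondary")
  expect_equal(assign_finding_category("P", FALSE, "CC2D2A",
                                       inheritance = "AR",
                                       zygosity = "het"), "carrier")
  expect_equal(assign_finding_category("LP", FALSE, "SHH",
                                       inheritance = "AD"), "incidental")
  expect_equal(assign_finding_category("VUS", TRUE), "none")
})

test_that("the cascade assigns one stage per sample and respects stage
           precedence", {
  cfg <- sim_config(
    n_cases = 5, n_controls = 0, seed = 61, slofv_case_excess = 0,
    spike_specs = list(
      spike_spec("aneuploidy", 1, chrom = "18"),
      spike_spec("snv", 2),
      spike_spec("intragenic_cnv", 2, gene = "G020"),
      spike_spec("snv", 3, consequence = "missense", class = "LP"),
      spike_spec("intragenic_cnv", 4, gene = "G030")))
  b <- generate_cohort(cfg)
  tc <- triage_cohort(b)
  dx <- tc$diagnoses

  expect_equal(dx$stage[dx$sample == "CASE001"], 1L)
  # a stage-1 diagnosis leaves SNVs uninterpreted
  f1 <- tc$findings[tc$findings$sample == "CASE001", ]
  expect_false(any(f1$kind == "snv"))
  # SNV diagnosis pre-empts the small-CNV stage
  expect_equal(dx$stage[dx$sample == "CASE002"], 2L)
  f2 <- tc$findings[tc$findings$sample == "CASE002", ]
  expect_false(any(f2$kind == "small_cnv"))
  expect_equal(dx$stage[dx$sample == "CASE003"], 2L)
  expect_equal(dx$stage[dx$sample == "CASE004"], 3L)
  expect_equal(dx$tier[dx$sample == "CASE004"], "intragenic")
  # nothing spiked: undiagnosed
  expect_false(dx$diagnosed[dx$sample == "CASE005"])
  # exclusivity: every diagnosed sample has exactly one stage
  expect_true(all(!dx$diagnosed | dx$stage %in% 1:3))
  expect_equal(sum(dx$diagnosed),
               sum(table(dx$stage[dx$diagnosed])))
})

test_that("a missing depth profile skips stage 1 with a warning but SNV
           triage still runs", {
  cfg <- sim_config(n_cases = 1, n_controls = 0, seed = 71,
                    slofv_case_excess = 0, make_depth = FALSE,
                    spike_specs = list(spike_spec("snv", 1)))
  b <- generate_cohort(cfg)
  expect_warning(d <- triage_sample("CASE001", b), "depth profile")
  expect_true(d$diagnosed)
  expect_equal(d$stage, 2L)
  expect_match(d$qc, "low-pass stage skipped")
})

test_that("enlarging the candidate gene set never undiagnoses a sample", {
  cfg <- sim_config(n_cases = 3, n_controls = 0, seed = 81,
                    slofv_case_excess = 0, make_depth = FALSE,
                    spike_specs = list(spike_spec("snv", 1),
                                       spike_spec("snv", 2)))
  b <- generate_cohort(cfg)
  before <- triage_cohort(b)$diagnoses
  # give every case every leaf phenotype: candidate sets only grow
  b$samples$phenotypes <- paste(b$resources$leaves, collapse = ";")
  after <- triage_cohort(b)$diagnoses
  expect_true(all(!before$diagnosed | after$diagnosed))
})
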
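# Shared fixtures and independent brute-force oracles. Oracles are written
# as literal row-by-row evaluations so they stay independent of the
# vectorised implementation paths they check.

random_variant_table <- function(n, seed, n_samples = 5) {
  set.seed(seed)
  csq <- sample(consequence_vocabulary(), n, replace = TRUE)
  ref <- ifelse(stats::runif(n) < 0.8, "A",
                vapply(sample(2:8, n, replace = TRUE), function(L) {
                  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = "")
                }, character(1)))
  df <- data.frame(
    sample = sample(sprintf("S%02d", 1:n_samples), n, replace = TRUE),
    chrom = sample(c(1:22, "X"), n, replace = TRUE),
    pos = sample.int(5e6, n, replace = TRUE),
    ref = ref,
    alt = ifelse(nchar(ref) > 1, substr(ref, 1, 1), "G"),
    zygosity = sample(c("het", "hom", "hemi"), n, replace = TRUE),
    depth = sample(10:60, n, replace = TRUE),
    gene = sample(c(sprintf("G%03d", 1:40), NA), n, replace = TRUE),
    consequence = csq,
    sift_class = sample(c("damaging", "tolerated", "missing"), n,
                        replace = TRUE),
    cadd = round(stats::runif(n, 0, 40), 3),
    mcap = round(stats::runif(n, 0, 0.1), 4),
    revel = round(stats::runif(n, 0, 1), 4),
    af_public = round(sample(c(0, 0, 0.0005, 0.005, 0.02, 0.2),
                             n, replace = TRUE) *
                        stats::runif(n, 0.5, 1.5), 6),
    af_inhouse = round(sample(c(0, 0, 0.0008, 0.008, 0.05), n,
                              replace = TRUE) * stats::runif(n, 0.5, 1.5), 6),
    stringsAsFactors = FALSE
  )
  df$af_public <- pmin(df$af_public, 1)
  df$af_inhouse <- pmin(df$af_inhouse, 1)
  df$alt_depth <- pmin(df$depth, sample(0:40, n, replace = TRUE))
  # occasionally missing scores
  df$cadd[stats::runif(n) < 0.1] <- NA
  df$mcap[stats::runif(n) < 0.1] <- NA
  df$revel[stats::runif(n) < 0.1] <- NA
  df[!duplicated(df[, c("sample", "chrom", "pos", "ref", "alt")]), ]
}

# random ontology: a tree over n_terms with random annotations
random_ontology <- function(n_terms, n_genes, seed) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  parent <- c(NA, terms[vapply(2:n_terms, function(i) {
    sample.int(i - 1, 1)
  }, integer(1))])
  ontology <- data.frame(term = terms[-1], parent = parent[-1],
                         stringsAsFactors = FALSE)
  genes <- sprintf("GEN%03d", seq_len(n_genes))
  hpo_map <- data.frame(
    term = sample(terms, n_terms * 3, replace = TRUE),
    gene = sample(genes, n_terms * 3, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(terms = terms, ontology = ontology, hpo_map = hpo_map)
}

# oracle: transitive descendant closure by fixpoint iteration
oracle_candidate_genes <- function(query, hpo_map, ontology) {
  closure <- unique(query)
  repeat {
    more <- ontology$term[ontology$parent %in% closure]
    new <- union(closure, more)
    if (length(new) == length(closure)) break
    closure <- new
  }
  sort(unique(hpo_map$gene[hpo_map$term %in% closure]))
}

# oracle: literal per-row re-statement of the diagnostic SNV filter
oracle_snv_filter <- function(df, cand, th) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    worst <- max(df$af_public[i], df$af_inhouse[i])
    keep[i] <- worst <= th$maf_diagnostic &&
      !(df$consequence[i] %in% c("intronic", "noncoding")) &&
      !is.na(df$gene[i]) && df$gene[i] %in% cand
  }
  keep
}

# oracle: literal per-row burden QC
oracle_qc <- function(df, th) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- df$depth[i] >= th$qc_depth &&
      df$alt_depth[i] >= th$qc_alt_depth &&
      max(nchar(df$ref[i]), nchar(df$alt[i])) <= th$qc_max_len_bp
  }
  keep
}

# oracle: literal per-row deleteriousness kind
oracle_deleterious <- function(df, th) {
  out <- character(nrow(df))
  lof <- c("nonsense", "frameshift", "canonical_splice", "stop_loss")
  for (i in seq_len(nrow(df))) {
    if (df$consequence[i] %in% lof) {
      out[i] <- "lof"
    } else if (df$consequence[i] == "missense" &&
                 !is.na(df$sift_class[i]) && df$sift_class[i] == "damaging" &&
                 !is.na(df$cadd[i]) && df$cadd[i] > th$cadd &&
                 !is.na(df$mcap[i]) && df$mcap[i] > th$mcap &&
                 !is.na(df$revel[i]) && df$revel[i] > th$revel) {
      out[i] <- "damaging_missense"
    } else {
      out[i] <- "none"
    }
  }
  out
}

# oracle: count allele occurrences sample-by-sample
oracle_singletons <- function(df) {
  key <- paste(df$chrom, df$pos, df$ref, df$alt)
  out <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    carriers <- unique(df$sample[key == key[i]])
    out[i] <- length(carriers) == 1
  }
  out
}

# oracle: exhaustive two-sided permutation p for the rank-sum statistic
oracle_perm_wilcoxon <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  v <- c(x, y)
  mu <- n * m / 2
  obs <- sum(rank(v)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(N, n)
  stats_all <- apply(combs, 2, function(idx) {
    sum(rank(v)[idx]) - n * (n + 1) / 2
  })
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# oracle: literal restatement of the published ACMG combining table as an
# explicit rule list over category counts
oracle_acmg <- function(pvs, ps, pm, pp, ba, bs, bp) {
  path_rules <- list(
    function() pvs >= 1 && ps >= 1,
    function() pvs >= 1 && pm >= 2,
    function() pvs >= 1 && pm == 1 && pp >= 1,
    function() pvs >= 1 && pp >= 2,
    function() pvs >= 2,
    function() ps >= 2,
    function() ps == 1 && pm >= 3,
    function() ps == 1 && pm == 2 && pp >= 2,
    function() ps == 1 && pm == 1 && pp >= 4
  )
  lp_rules <- list(
    function() pvs == 1 && pm == 1,
    function() ps == 1 && pm %in% 1:2,
    function() ps == 1 && pp >= 2,
    function() pm >= 3,
    function() pm == 2 && pp >= 2,
    function() pm == 1 && pp >= 4
  )
  is_p <- any(vapply(path_rules, function(f) f(), logical(1)))
  is_lp <- any(vapply(lp_rules, function(f) f(), logical(1)))
  is_b <- ba >= 1 || bs >= 2
  is_lb <- (bs == 1 && bp >= 1) || bp >= 2
  path <- if (is_p) "P" else if (is_lp) "LP" else NA
  ben <- if (is_b) "B" else if (is_lb) "LB" else NA
  if (!is.na(path) && !is.na(ben)) return("VUS")
  if (!is.na(path)) return(path)
  if (!is.na(ben)) return(ben)
  "VUS"
}

random_acmg_tags <- function(seed) {
  set.seed(seed)
  pool <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
            "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  sample(pool, sample(0:6, 1), replace = FALSE)
}
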
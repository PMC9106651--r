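# Synthetic cohort generator. Emulates the statistical structure the
# downstream stages assume: binned low-pass read-depth profiles with GC bias
# and overdispersed counts, a background of annotated small variants with a
# frequency spectrum concentrated near zero, spiked pathogenic events
# (aneuploidies, CNVs > 100 kb, diagnostic SNVs, intragenic CNVs) with a
# truth table, phenotype-term assignments wired to a toy ontology, and a
# tunable case-only excess of cohort-unique loss-of-function variants.
#
# The genome is a reduced 24-chromosome model (default 1/20 of human scale)
# so a full cohort simulates in seconds; every stochastic draw flows from a
# per-sample stream derived from one global seed, so a sample's data do not
# change when the cohort grows. Internally samples produce plain column
# lists that are assembled into one table per cohort (a cohort of hundreds
# of samples must simulate in about a second for replicated calibration
# studies to be practical).

# hg19 chromosome lengths (bp), scaled down by `genome_scale`.
.HG19_LEN <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
)

.sample_seed <- function(seed, i, salt = 0L) {
  ((seed %% 100003) * 20011 + i * 7919 + salt * 104729) %% 2147483647 + 1
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the cohort emulates: case and
#' control arms at the scale of the deep-sequenced comparison (136 vs 200),
#' ~0.5x low-pass coverage (100-bp reads in 100-kb bins give a mean of 500
#' reads per bin), negative-binomial count noise, a quadratic GC bias bump,
#' a background small-variant rate whose loss-of-function fraction yields a
#' control median of about 9 singleton LoF variants per sample at
#' MAF <= 0.001, and a case excess calibrated so case medians sit near 13.5.
#'
#' @param n_cases,n_controls Arm sizes.
#' @param seed Global integer seed; all draws derive from it.
#' @param bin_width Depth-profile bin width (bp).
#' @param mean_reads_per_bin Expected reads per disomic bin.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param gc_bias_strength Amplitude of the quadratic GC bias (0 disables).
#' @param genome_scale Fraction of human chromosome lengths to simulate.
#' @param background_snv_rate Expected background small variants per sample.
#' @param slofv_case_excess Expected extra cohort-unique LoF variants per
#'   case (Poisson mean; 0 makes arms exchangeable).
#' @param spike_specs List of [spike_spec()] objects.
#' @param maf_spectrum List: `p_zero` (mass at frequency 0) and Beta shape
#'   parameters `shape1`, `shape2` for nonzero background frequencies.
#' @param pool_size Number of shared polymorphic sites (non-singletons).
#' @param p_shared Probability a background variant is drawn from the pool.
#' @param small_cnv_rate Expected background small CNVs per sample.
#' @param make_depth Emit low-pass depth profiles (disable for burden-only
#'   simulations, where they are never read).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 136, n_controls = 200, seed = 1,
                       bin_width = 100e3, mean_reads_per_bin = 500,
                       dispersion = 0.01, gc_bias_strength = 4,
                       genome_scale = 1 / 20,
                       background_snv_rate = 88,
                       slofv_case_excess = 4.5,
                       spike_specs = list(),
                       maf_spectrum = list(p_zero = 0.6, shape1 = 0.3,
                                           shape2 = 60),
                       pool_size = 3000, p_shared = 0.3,
                       small_cnv_rate = 10,
                       make_depth = TRUE) {
  stopifnot(n_cases >= 0, n_controls >= 0, slofv_case_excess >= 0,
            bin_width > 0, background_snv_rate >= 0)
  if (mean_reads_per_bin <= 0) stop("mean_reads_per_bin must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Describe one spiked pathogenic event
#'
#' @param kind One of `"aneuploidy"`, `"cnv"`, `"snv"`, `"intragenic_cnv"`.
#' @param sample Index (1-based, into the case arm) of the target sample.
#' @param chrom Chromosome (aneuploidy/CNV kinds).
#' @param start,end Coordinates (CNV kinds; sizes are validated against the
#'   tier the kind implies).
#' @param copy_number Intended copy number (CNV/aneuploidy kinds).
#' @param gene Target gene (snv / intragenic_cnv kinds; resolved against the
#'   synthetic gene table at generation time).
#' @param consequence Consequence label for snv spikes.
#' @param class Intended truth class, `"P"` or `"LP"`.
#' @param syndrome Free-text truth label.
#' @return List of class `"spike_spec"`.
#' @export
spike_spec <- function(kind, sample, chrom = NULL, start = NULL, end = NULL,
                       copy_number = NULL, gene = NULL, consequence = NULL,
                       class = "P", syndrome = "synthetic syndrome") {
  kind <- match.arg(kind, c("aneuploidy", "cnv", "snv", "intragenic_cnv"))
  stopifnot(class %in% c("P", "LP"))
  if (kind == "cnv") {
    stopifnot(!is.null(start), !is.null(end), (end - start + 1) >= 100e3)
  }
  if (kind == "intragenic_cnv" && !is.null(start)) {
    sz <- end - start + 1
    stopifnot(sz >= 50, sz < 100e3)
  }
  structure(list(kind = kind, sample = sample, chrom = chrom, start = start,
                 end = end, copy_number = copy_number, gene = gene,
                 consequence = consequence, class = class,
                 syndrome = syndrome), class = "spike_spec")
}

#' Build the reduced synthetic genome
#'
#' @param config A [sim_config()].
#' @return List with `chroms` (lengths) and `bins` (chrom, start, end, gc):
#'   the binned scaffold every depth profile shares. GC per bin is a smooth
#'   deterministic wave plus seed-derived jitter, identical across samples.
#' @export
synthetic_genome <- function(config) {
  len <- pmax(round(.HG19_LEN * config$genome_scale / config$bin_width), 3) *
    config$bin_width
  nb <- len / config$bin_width
  bins <- data.frame(
    chrom = rep(names(len), nb),
    start = unlist(lapply(nb, function(n) {
      seq(0, by = config$bin_width, length.out = n) + 1
    }), use.names = FALSE),
    end = unlist(lapply(nb, function(n) seq_len(n) * config$bin_width),
                 use.names = FALSE),
    stringsAsFactors = FALSE
  )
  set.seed(.sample_seed(config$seed, 0L, salt = 1L))
  i <- seq_len(nrow(bins))
  bins$gc <- pmin(0.75, pmax(0.25,
    0.45 + 0.10 * sin(i / 37) + 0.05 * sin(i / 11) +
      stats::rnorm(nrow(bins), 0, 0.01)))
  list(chroms = len, bins = bins)
}

.gc_bias_factor <- function(gc, strength) {
  pmax(0.05, 1 - strength * (gc - 0.45)^2)
}

#' Simulate one binned low-pass depth profile
#'
#' Per-bin counts are drawn from a negative-binomial whose mean scales
#' linearly with the local copy number and with the smooth GC-bias curve.
#'
#' @param karyotype Named integer vector of per-chromosome copy counts
#'   (values 0-4); chromosomes omitted default to 2 (autosomes) while X/Y
#'   must be given explicitly for non-default sexes.
#' @param config A [sim_config()].
#' @param genome Output of [synthetic_genome()] (built from `config` when
#'   missing).
#' @param cnv_regions Optional data frame (chrom, start, end, copy_number)
#'   of focal copy-number overrides.
#' @param sample_id Sample label stored in the profile.
#' @param seed Stream seed (defaults to the config seed).
#' @return Data frame (sample, chrom, start, end, count, gc) of class
#'   `"depth_profile"`.
#' @export
generate_depth_profile <- function(karyotype = c(X = 1, Y = 1), config,
                                   genome = NULL, cnv_regions = NULL,
                                   sample_id = "S1", seed = config$seed) {
  if (config$mean_reads_per_bin <= 0) {
    stop("mean_reads_per_bin must be positive")
  }
  if (length(karyotype) &&
      (any(karyotype < 0) || any(karyotype > 4))) {
    stop("copy counts must lie in 0..4")
  }
  if (is.null(genome)) genome <- synthetic_genome(config)
  bins <- genome$bins
  cn <- rep(2, nrow(bins))
  for (ch in names(karyotype)) cn[bins$chrom == ch] <- karyotype[[ch]]
  if (!is.null(cnv_regions) && nrow(cnv_regions)) {
    for (k in seq_len(nrow(cnv_regions))) {
      hit <- bins$chrom == cnv_regions$chrom[k] &
        bins$start <= cnv_regions$end[k] & bins$end >= cnv_regions$start[k]
      cn[hit] <- cnv_regions$copy_number[k]
    }
  }
  mu <- config$mean_reads_per_bin * (cn / 2) *
    .gc_bias_factor(bins$gc, config$gc_bias_strength)
  set.seed(seed)
  counts <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  out <- data.frame(sample = sample_id, bins[, c("chrom", "start", "end")],
                    count = counts, gc = bins$gc, stringsAsFactors = FALSE)
  class(out) <- c("depth_profile", "data.frame")
  out
}

# Synthetic annotation resources shared by a cohort: a gene table with exon
# intervals, a toy phenotype ontology with term->gene annotations, and the
# dosage-region table spiked events register themselves in.
.build_resources <- function(config, genome) {
  set.seed(.sample_seed(config$seed, 0L, salt = 2L))
  n_genes <- 200
  auto <- names(genome$chroms)[1:22]
  gchrom <- sample(auto, n_genes, replace = TRUE)
  gstart <- floor(stats::runif(n_genes) *
                    (unname(genome$chroms[gchrom]) - 20000)) + 1
  genes <- data.frame(
    gene = sprintf("G%03d", seq_len(n_genes)), chrom = gchrom,
    start = gstart, end = gstart + 12000, stringsAsFactors = FALSE
  )
  estart <- rep(genes$start, each = 5) + rep((0:4) * 2500, times = n_genes)
  exon_map <- GenomicRanges::GRanges(
    rep(genes$chrom, each = 5),
    IRanges::IRanges(estart, estart + 149),
    label = paste0(rep(genes$gene, each = 5), "_exon", rep(1:5, n_genes)))

  # toy ontology: root -> 5 branch terms -> 5 leaves each
  terms <- sprintf("HP:%07d", 1:31)
  root <- terms[1]; branches <- terms[2:6]; leaves <- terms[7:31]
  ontology <- rbind(
    data.frame(term = branches, parent = root, stringsAsFactors = FALSE),
    data.frame(term = leaves, parent = rep(branches, each = 5),
               stringsAsFactors = FALSE)
  )
  hpo_map <- data.frame(
    term = rep(leaves, each = 8),
    gene = unlist(lapply(leaves, function(t) sample(genes$gene, 8)),
                  use.names = FALSE),
    stringsAsFactors = FALSE
  )
  # a few direct annotations on branch terms, so closure matters
  hpo_map <- rbind(hpo_map, data.frame(
    term = branches, gene = sample(genes$gene, length(branches)),
    stringsAsFactors = FALSE))
  list(genes = genes, exon_map = exon_map, ontology = ontology,
       hpo_map = hpo_map, sf_genes = sort(sample(genes$gene, 10)),
       branches = branches, leaves = leaves)
}

# vectorised position draw: positions in residue classes 0..8 (mod 10);
# the 9 (mod 10) class is reserved for spiked cohort-unique variants
.draw_positions <- function(chrom, chrom_len) {
  len <- unname(chrom_len[chrom])
  (floor(stats::runif(length(chrom)) * (len %/% 10 - 2)) + 1) * 10 +
    sample(0:8, length(chrom), replace = TRUE)
}

.draw_maf <- function(n, spec) {
  af <- numeric(n)
  nz <- stats::runif(n) >= spec$p_zero
  af[nz] <- stats::rbeta(sum(nz), spec$shape1, spec$shape2)
  pmin(af, 1)
}

# Shared polymorphic sites: alleles that recur across samples, so the
# singleton detector has genuine non-singletons to reject.
.build_pool <- function(config, genome, resources) {
  set.seed(.sample_seed(config$seed, 0L, salt = 3L))
  n <- config$pool_size
  auto <- names(genome$chroms)[1:22]
  chrom <- sample(auto, n, replace = TRUE)
  pos <- .draw_positions(chrom, genome$chroms)
  csq <- sample(consequence_vocabulary(), n, replace = TRUE,
                prob = c(.42, .05, .08, .04, .03, .15, .05, .13, .05))
  af <- .draw_maf(n, config$maf_spectrum)
  # pool sites are, by design, mostly seen more than once; give them a
  # frequency floor so the MAF strata above zero are populated
  af <- pmax(af, 1 / (2 * 790))
  list(
    chrom = chrom, pos = pos, ref = rep("A", n), alt = rep("G", n),
    consequence = csq,
    gene = sample(c(resources$genes$gene, rep(NA, 60)), n, replace = TRUE),
    af_public = af,
    af_inhouse = pmin(1, af * stats::runif(n, 0.5, 1.5)),
    n = n
  )
}

# consequence composition of background variants (LoF mass 0.20)
.CSQ_PROBS <- c(missense = 0.42, nonsense = 0.05, frameshift = 0.08,
                canonical_splice = 0.04, stop_loss = 0.03,
                synonymous = 0.15, inframe_indel = 0.05, intronic = 0.13,
                noncoding = 0.05)

.VAR_FIELDS <- c("sample", "chrom", "pos", "ref", "alt", "zygosity",
                 "depth", "alt_depth", "gene", "consequence", "sift_class",
                 "cadd", "mcap", "revel", "af_public", "af_inhouse")

.cols_to_df <- function(cols_list, fields, empty) {
  keep <- Filter(function(x) length(x[[1]]) > 0, cols_list)
  if (!length(keep)) return(empty)
  out <- lapply(fields, function(f) {
    unlist(lapply(keep, `[[`, f), use.names = FALSE)
  })
  names(out) <- fields
  as.data.frame(out, stringsAsFactors = FALSE)
}

.random_indel <- function(n, max_keep = 4) {
  # deletion alleles; ~15% exceed the 5-bp QC bound on purpose
  len <- ifelse(stats::runif(n) < 0.85,
                sample(1:max_keep, n, replace = TRUE),
                sample(6:9, n, replace = TRUE))
  base <- c("A", "C", "G", "T")
  ref <- vapply(len + 1, function(L) {
    paste(base[sample.int(4, L, replace = TRUE)], collapse = "")
  }, character(1))
  list(ref = ref, alt = substr(ref, 1, 1))
}

# One sample's background variants, as a list of column vectors.
.gen_sample_variants <- function(sample_id, config, genome, resources, pool,
                                 stream_seed) {
  set.seed(stream_seed)
  n <- stats::rpois(1, config$background_snv_rate)
  empty <- list(sample = character(), chrom = character(), pos = integer(),
                ref = character(), alt = character(), zygosity = character(),
                depth = integer(), alt_depth = integer(), gene = character(),
                consequence = character(), sift_class = character(),
                cadd = numeric(), mcap = numeric(), revel = numeric(),
                af_public = numeric(), af_inhouse = numeric())
  if (n == 0) return(empty)
  shared <- stats::runif(n) < config$p_shared
  csq <- character(n)
  chrom <- character(n); pos <- numeric(n)
  ref <- rep("A", n); alt <- rep("G", n)
  gene <- rep(NA_character_, n)
  afp <- numeric(n); afi <- numeric(n)

  if (any(shared)) {
    idx <- sample.int(pool$n, sum(shared), replace = TRUE)
    chrom[shared] <- pool$chrom[idx]; pos[shared] <- pool$pos[idx]
    ref[shared] <- pool$ref[idx]; alt[shared] <- pool$alt[idx]
    csq[shared] <- pool$consequence[idx]; gene[shared] <- pool$gene[idx]
    afp[shared] <- pool$af_public[idx]; afi[shared] <- pool$af_inhouse[idx]
  }
  npriv <- sum(!shared)
  if (npriv) {
    auto <- names(genome$chroms)[1:22]
    pchrom <- sample(auto, npriv, replace = TRUE)
    chrom[!shared] <- pchrom
    pos[!shared] <- .draw_positions(pchrom, genome$chroms)
    pcsq <- sample(names(.CSQ_PROBS), npriv, replace = TRUE,
                   prob = unname(.CSQ_PROBS))
    csq[!shared] <- pcsq
    gene[!shared] <- sample(c(resources$genes$gene, rep(NA, 60)), npriv,
                            replace = TRUE)
    pafp <- .draw_maf(npriv, config$maf_spectrum)
    afp[!shared] <- pafp
    afi[!shared] <- ifelse(pafp == 0,
                           ifelse(stats::runif(npriv) < 0.9, 0,
                                  stats::rbeta(npriv, 0.3, 200)),
                           pmin(1, pafp * stats::runif(npriv, 0.5, 1.5)))
    indel <- csq %in% c("frameshift", "inframe_indel") & !shared
    if (any(indel)) {
      ri <- .random_indel(sum(indel))
      ref[indel] <- ri$ref; alt[indel] <- ri$alt
    }
  }
  depth <- stats::rnbinom(n, mu = 40, size = 20) + 1L
  alt_depth <- stats::rbinom(n, depth, 0.5)
  damaging <- csq == "missense" & stats::runif(n) < 0.25
  sift <- rep("missing", n)
  mis <- csq == "missense"
  sift[mis & damaging] <- "damaging"
  sift[mis & !damaging] <- sample(c("tolerated", "missing"),
                                  sum(mis & !damaging), replace = TRUE,
                                  prob = c(.8, .2))
  cadd <- ifelse(damaging, stats::runif(n, 21, 35), stats::runif(n, 0, 24))
  mcap <- ifelse(damaging, stats::runif(n, 0.026, 0.4),
                 stats::runif(n, 0, 0.05))
  revel <- ifelse(damaging, stats::runif(n, 0.51, 0.95),
                  stats::runif(n, 0, 0.6))
  keep <- !duplicated(paste(chrom, pos, ref, alt))
  list(sample = rep(sample_id, sum(keep)), chrom = chrom[keep],
       pos = as.integer(pos[keep]), ref = ref[keep], alt = alt[keep],
       zygosity = sample(c("het", "hom"), n, replace = TRUE,
                         prob = c(.9, .1))[keep],
       depth = as.integer(depth[keep]),
       alt_depth = as.integer(alt_depth[keep]), gene = gene[keep],
       consequence = csq[keep], sift_class = sift[keep], cadd = cadd[keep],
       mcap = mcap[keep], revel = revel[keep], af_public = afp[keep],
       af_inhouse = afi[keep])
}

.CNV_FIELDS <- c("sample", "chrom", "start", "end", "copy_number",
                 "size_bp", "freq_inhouse")

.empty_cnv_cols <- function() {
  list(sample = character(), chrom = character(), start = numeric(),
       end = numeric(), copy_number = integer(), size_bp = numeric(),
       freq_inhouse = numeric())
}

.gen_sample_small_cnvs <- function(sample_id, config, genome, stream_seed) {
  set.seed(stream_seed)
  n <- stats::rpois(1, config$small_cnv_rate)
  if (n == 0) return(.empty_cnv_cols())
  auto <- names(genome$chroms)[1:22]
  chrom <- sample(auto, n, replace = TRUE)
  size <- pmin(round(exp(stats::runif(n, log(60), log(9e4)))), 99999)
  start <- floor(stats::runif(n) *
                   (unname(genome$chroms[chrom]) - size - 1)) + 1
  list(sample = rep(sample_id, n), chrom = chrom, start = start,
       end = start + size - 1,
       copy_number = sample(c(1L, 3L), n, replace = TRUE),
       size_bp = size,
       freq_inhouse = ifelse(stats::runif(n) < 0.6,
                             stats::runif(n, 0.01, 0.4),
                             ifelse(stats::runif(n) < 0.5, 0,
                                    stats::runif(n, 0, 0.009))))
}

#' Generate a synthetic case-control cohort
#'
#' Cases and controls are drawn from an identical background model except
#' for `slofv_case_excess`; every spiked event is recorded in the truth
#' table and materialised in the emitted variant / CNV / depth data.
#'
#' @param config A [sim_config()].
#' @return List of class `"cohort_bundle"`: `samples`, `variants`, `cnvs`,
#'   `depth_profiles` (named list, empty when disabled), `truth`, and
#'   `resources` (genome, gene/exon maps, toy ontology, dosage regions,
#'   curated evidence table, secondary-findings gene list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_all <- config$n_cases + config$n_controls
  genome <- synthetic_genome(config)
  resources <- .build_resources(config, genome)
  pool <- .build_pool(config, genome, resources)

  samples <- data.frame(
    sample = c(sprintf("CASE%03d", seq_len(config$n_cases)),
               sprintf("CTRL%03d", seq_len(config$n_controls))),
    arm = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    stringsAsFactors = FALSE
  )
  if (n_all > 0) {
    set.seed(.sample_seed(config$seed, 0L, salt = 4L))
    samples$sex <- sample(c("male", "female"), n_all, replace = TRUE)
    samples$phenotypes <- vapply(seq_len(n_all), function(i) {
      paste(sample(resources$leaves, sample(1:2, 1)), collapse = ";")
    }, character(1))
  } else {
    samples$sex <- character(0)
    samples$phenotypes <- character(0)
  }

  spikes <- config$spike_specs
  for (sp in spikes) {
    if (sp$sample < 1 || sp$sample > config$n_cases) {
      stop("spike target sample out of range: ", sp$sample)
    }
  }

  truth <- list(); dosage <- list(); evidence <- list()
  variants <- vector("list", n_all); cnvs <- vector("list", n_all)
  profiles <- list()

  for (i in seq_len(n_all)) {
    sid <- samples$sample[i]
    variants[[i]] <- .gen_sample_variants(
      sid, config, genome, resources, pool,
      .sample_seed(config$seed, i, salt = 5L))
    cnvs[[i]] <- .gen_sample_small_cnvs(
      sid, config, genome, .sample_seed(config$seed, i, salt = 6L))

    my_spikes <- if (i <= config$n_cases) {
      Filter(function(sp) sp$sample == i, spikes)
    } else list()

    karyotype <- c(X = if (samples$sex[i] == "male") 1 else 2,
                   Y = if (samples$sex[i] == "male") 1 else 0)
    cnv_regions <- NULL
    for (sp in my_spikes) {
      if (sp$kind == "aneuploidy") {
        cnv <- if (is.null(sp$copy_number)) 3L else sp$copy_number
        karyotype[sp$chrom] <- cnv
        truth[[length(truth) + 1]] <- data.frame(
          sample = sid, kind = "aneuploidy", chrom = sp$chrom,
          start = NA, end = NA, copy_number = cnv, gene = NA,
          class = sp$class, syndrome = sp$syndrome, stringsAsFactors = FALSE)
      } else if (sp$kind == "cnv") {
        cnv_regions <- rbind(cnv_regions, data.frame(
          chrom = sp$chrom, start = sp$start, end = sp$end,
          copy_number = sp$copy_number))
        dosage[[length(dosage) + 1]] <- data.frame(
          chrom = sp$chrom, start = sp$start, end = sp$end,
          score = if (sp$class == "P") 0.99 else 0.95, relevant = TRUE,
          syndrome = sp$syndrome, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          sample = sid, kind = "cnv", chrom = sp$chrom, start = sp$start,
          end = sp$end, copy_number = sp$copy_number, gene = NA,
          class = sp$class, syndrome = sp$syndrome, stringsAsFactors = FALSE)
      } else if (sp$kind == "snv") {
        sv <- .spike_snv(sid, sp, samples$phenotypes[i], resources, config, i)
        variants[[i]] <- Map(c, variants[[i]], sv$variant)
        evidence[[length(evidence) + 1]] <- sv$evidence
        truth[[length(truth) + 1]] <- data.frame(
          sample = sid, kind = "snv", chrom = sv$variant$chrom,
          start = sv$variant$pos, end = sv$variant$pos,
          copy_number = NA, gene = sv$variant$gene, class = sp$class,
          syndrome = sp$syndrome, stringsAsFactors = FALSE)
        samples$phenotypes[i] <- sv$phenotypes
      } else { # intragenic_cnv
        g <- resources$genes[resources$genes$gene == sp$gene, ]
        if (nrow(g) == 0) stop("unknown spike gene: ", sp$gene)
        st <- if (is.null(sp$start)) g$start else sp$start
        en <- if (is.null(sp$end)) g$start + 2999 else sp$end
        cn_ <- if (is.null(sp$copy_number)) 1L else sp$copy_number
        cnvs[[i]] <- Map(c, cnvs[[i]], list(
          sample = sid, chrom = g$chrom, start = st, end = en,
          copy_number = cn_, size_bp = en - st + 1, freq_inhouse = 0))
        dosage[[length(dosage) + 1]] <- data.frame(
          chrom = g$chrom, start = st, end = en,
          score = if (sp$class == "P") 0.99 else 0.95, relevant = TRUE,
          syndrome = sp$syndrome, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          sample = sid, kind = "intragenic_cnv", chrom = g$chrom,
          start = st, end = en, copy_number = cn_, gene = sp$gene,
          class = sp$class, syndrome = sp$syndrome, stringsAsFactors = FALSE)
      }
    }
    if (config$make_depth) {
      profiles[[sid]] <- generate_depth_profile(
        karyotype, config, genome, cnv_regions, sample_id = sid,
        seed = .sample_seed(config$seed, i, salt = 7L))
    }
  }

  bundle <- structure(list(
    samples = samples,
    variants = .cols_to_df(variants, .VAR_FIELDS, empty_variant_table()),
    cnvs = .cols_to_df(cnvs, .CNV_FIELDS,
                       as.data.frame(.empty_cnv_cols(),
                                     stringsAsFactors = FALSE)),
    depth_profiles = profiles,
    truth = if (length(truth)) {
      do.call(rbind, c(truth, list(make.row.names = FALSE)))
    } else data.frame(sample = character(), kind = character()),
    resources = c(resources, list(
      genome = genome,
      dosage_db = if (length(dosage)) {
        do.call(rbind, c(dosage, list(make.row.names = FALSE)))
      } else data.frame(chrom = character(), start = numeric(),
                        end = numeric(), score = numeric(),
                        relevant = logical(), syndrome = character()),
      evidence = if (length(evidence)) {
        do.call(rbind, c(evidence, list(make.row.names = FALSE)))
      } else data.frame(sample = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), tags = character(),
                        phenotype_relevant = logical())))
  ), class = "cohort_bundle")

  if (config$slofv_case_excess > 0 && config$n_cases > 0) {
    bundle <- spike_slofv_excess(bundle, config$slofv_case_excess,
                                 seed = .sample_seed(config$seed, 0L,
                                                     salt = 8L))
  }
  bundle
}

# Spiked diagnostic SNV: lands in a gene annotated to one of the sample's
# phenotype terms (adding a term when needed) with curated evidence tags
# strong enough for the intended class.
.spike_snv <- function(sid, sp, phenotypes, resources, config, i) {
  set.seed(.sample_seed(config$seed, i, salt = 9L))
  gene <- sp$gene
  if (is.null(gene)) {
    terms <- strsplit(phenotypes, ";")[[1]]
    cand <- resources$hpo_map$gene[resources$hpo_map$term %in% terms]
    gene <- if (length(cand)) cand[1] else resources$hpo_map$gene[1]
  }
  if (!gene %in% resources$hpo_map$gene[resources$hpo_map$term %in%
                                          strsplit(phenotypes, ";")[[1]]]) {
    extra <- resources$hpo_map$term[resources$hpo_map$gene == gene][1]
    if (is.na(extra)) stop("spike gene has no phenotype annotation: ", gene)
    phenotypes <- paste(unique(c(strsplit(phenotypes, ";")[[1]], extra)),
                        collapse = ";")
  }
  g <- resources$genes[resources$genes$gene == gene, ]
  csq <- if (is.null(sp$consequence)) "frameshift" else sp$consequence
  pos <- as.integer(g$start + 75)
  variant <- list(
    sample = sid, chrom = g$chrom, pos = pos, ref = "CA", alt = "C",
    zygosity = "het", depth = 45L, alt_depth = 21L, gene = gene,
    consequence = csq, sift_class = "missing", cadd = 32, mcap = NA_real_,
    revel = NA_real_, af_public = 0, af_inhouse = 0)
  if (csq == "missense") {
    variant$sift_class <- "damaging"; variant$mcap <- 0.3; variant$revel <- 0.8
  }
  tags <- if (sp$class == "P") "PVS1,PM2,PP4" else "PVS1,PM2"
  if (csq == "missense") {
    tags <- if (sp$class == "P") "PS1,PM1,PM2,PM5" else "PM1,PM2,PP3,PP4"
  }
  list(variant = variant,
       evidence = data.frame(sample = sid, chrom = g$chrom, pos = pos,
                             ref = "CA", alt = "C", tags = tags,
                             phenotype_relevant = TRUE,
                             stringsAsFactors = FALSE),
       phenotypes = phenotypes)
}

#' Add a case-only excess of cohort-unique loss-of-function variants
#'
#' Each case receives a Poisson(`rate`) number of extra loss-of-function
#' variants. Added variants are absent from every population database
#' (frequency 0), pass the burden QC filters by construction (depth 40,
#' alternate depth 20, allele length <= 5 bp) and occupy positions the
#' background never uses (a reserved residue class, drawn without
#' replacement per chromosome), so each is observed in exactly one sample.
#'
#' @param bundle A `cohort_bundle`.
#' @param rate Expected extra variants per case (>= 0).
#' @param seed Stream seed.
#' @return The bundle with extra case variants appended.
#' @export
spike_slofv_excess <- function(bundle, rate, seed = 1) {
  stopifnot(rate >= 0)
  if (rate == 0) return(bundle)
  cases <- bundle$samples$sample[bundle$samples$arm == "case"]
  if (!length(cases)) return(bundle)
  set.seed(seed)
  counts <- stats::rpois(length(cases), rate)
  total <- sum(counts)
  if (total == 0) return(bundle)
  genome <- bundle$resources$genome
  auto <- names(genome$chroms)[1:22]
  chrom <- sample(auto, total, replace = TRUE)
  # positions = 9 (mod 10), unique within each chromosome by construction
  pos <- numeric(total)
  for (ch in unique(chrom)) {
    k <- chrom == ch
    pos[k] <- sample.int(genome$chroms[[ch]] %/% 10L, sum(k)) * 10 - 1
  }
  lof <- lof_consequences()
  add <- data.frame(
    sample = rep(cases, counts), chrom = chrom, pos = as.integer(pos),
    ref = "T", alt = "TA", zygosity = "het", depth = 40L, alt_depth = 20L,
    gene = sample(bundle$resources$genes$gene, total, replace = TRUE),
    consequence = sample(lof, total, replace = TRUE),
    sift_class = "missing", cadd = NA_real_, mcap = NA_real_,
    revel = NA_real_, af_public = 0, af_inhouse = 0, stringsAsFactors = FALSE)
  bundle$variants <- rbind(bundle$variants, add)
  attr(bundle, "slofv_spiked") <- total
  bundle
}
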
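# Case-control rare singleton deleterious-variant burden analysis: QC
# filtering, the deleteriousness predicate (loss-of-function classes, or
# missense damaging under all four in-silico algorithms), singleton
# detection over the analysis cohort, per-sample counts in nested public-MAF
# strata, and a two-sided Wilcoxon rank-sum comparison of arms.

#' QC-filter variants for the burden analysis
#'
#' Retains calls with total depth >= `th$qc_depth`, alternate-allele depth
#' >= `th$qc_alt_depth` and allele length (`max(nchar(ref), nchar(alt))`)
#' at most `th$qc_max_len_bp`. All bounds are inclusive.
#'
#' @param variants Variant table.
#' @param th Thresholds.
#' @return The retained subset.
#' @export
qc_filter <- function(variants, th = default_thresholds()) {
  if (!nrow(variants)) return(variants)
  keep <- variants$depth >= th$qc_depth &
    variants$alt_depth >= th$qc_alt_depth &
    pmax(nchar(variants$ref), nchar(variants$alt)) <= th$qc_max_len_bp
  variants[keep & !is.na(keep), , drop = FALSE]
}

#' Deleteriousness kind of each variant
#'
#' `"lof"` for nonsense, frameshift, canonical splice-site and stop-loss
#' consequences; `"damaging_missense"` for missense variants called
#' damaging by SIFT with CADD > 20, M-CAP > 0.025 and REVEL > 0.5 (strict
#' inequalities; a missing score never counts as damaging); `"none"`
#' otherwise.
#'
#' @param variants Variant table.
#' @param th Thresholds.
#' @return Character vector, one of `"lof"`, `"damaging_missense"`,
#'   `"none"` per row.
#' @export
is_deleterious <- function(variants, th = default_thresholds()) {
  if (!nrow(variants)) return(character())
  lof <- variants$consequence %in% lof_consequences()
  dm <- variants$consequence == "missense" &
    !is.na(variants$sift_class) & variants$sift_class == "damaging" &
    !is.na(variants$cadd) & variants$cadd > th$cadd &
    !is.na(variants$mcap) & variants$mcap > th$mcap &
    !is.na(variants$revel) & variants$revel > th$revel
  ifelse(lof, "lof", ifelse(dm, "damaging_missense", "none"))
}

#' Flag singleton alleles
#'
#' An allele (chrom, pos, ref, alt) is a singleton when it is observed in
#' exactly one sample of the counting population. By default occurrences
#' are counted over the combined case + control table, which keeps the two
#' arms' counts comparable; restrict `within` to count within one arm.
#'
#' @param variants Cohort variant table.
#' @param within Optional character vector of samples defining the counting
#'   population (default: all samples present).
#' @return Logical vector per row of `variants`: `TRUE` when the row's
#'   allele is observed in exactly one sample of the counting population.
#' @export
find_singletons <- function(variants, within = NULL) {
  if (!nrow(variants)) return(logical())
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  in_pop <- if (is.null(within)) rep(TRUE, nrow(variants)) else
    variants$sample %in% within
  occ <- paste(variants$sample, key)[in_pop]
  n_samples <- table(key[in_pop][!duplicated(occ)])
  cnt <- as.vector(n_samples[key])
  cnt[is.na(cnt)] <- 0L
  cnt == 1L
}

#' Per-sample singleton deleterious-variant counts by MAF stratum
#'
#' Applies QC, flags singletons over the analysis population, and counts
#' per sample, deleteriousness kind and nested public-MAF stratum
#' (`MAF = 0` means absent from every public reference; the strata nest, so
#' counts are monotone nondecreasing across them).
#'
#' @param bundle A `cohort_bundle` (needs `samples` with `arm` and
#'   `variants`), or a list with those two elements.
#' @param th Thresholds.
#' @param singleton_within `"combined"` (default) to count allele
#'   occurrences across both arms, or `"cases"` to count within cases only.
#' @return List of class `"burden_result"`: `counts` (sample, arm, kind,
#'   stratum, count), `wide` (sample x stratum matrix per kind), and the
#'   strata used.
#' @export
count_burden <- function(bundle, th = default_thresholds(),
                         singleton_within = c("combined", "cases")) {
  singleton_within <- match.arg(singleton_within)
  samples <- bundle$samples
  hq <- qc_filter(bundle$variants, th)
  pop <- if (singleton_within == "cases") {
    samples$sample[samples$arm == "case"]
  } else samples$sample
  singleton <- find_singletons(hq, within = pop)
  kind <- is_deleterious(hq, th)
  strata <- th$maf_strata
  out <- list()
  for (k in c("lof", "damaging_missense")) {
    for (s in strata) {
      hit <- singleton & kind == k & hq$af_public <= s
      tab <- table(factor(hq$sample[hit], levels = samples$sample))
      out[[length(out) + 1]] <- data.frame(
        sample = samples$sample, arm = samples$arm, kind = k,
        stratum = s, count = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, out)
  structure(list(counts = counts, strata = strata,
                 n_cases = sum(samples$arm == "case"),
                 n_controls = sum(samples$arm == "control")),
            class = "burden_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. The p-value is exact (from
#' the tie-free rank-sum distribution) when `min(n, m)` is at most
#' `exact_cutoff` and the data are tie-free; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. The returned p is clamped to (0, 1].
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_cutoff Largest `min(n, m)` for the exact path (default 12).
#' @return List: `statistic` (Mann-Whitney U for `x`), `p.value`, `method`.
#' @export
#' @examples
#' wilcoxon_two_sided(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
wilcoxon_two_sided <- function(x, y, exact_cutoff = 12L) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n, m) <= exact_cutoff) {
    p <- if (W > n * m / 2) {
      stats::pwilcox(W - 1, n, m, lower.tail = FALSE) * 2
    } else {
      stats::pwilcox(W, n, m) * 2
    }
    p <- min(1, p)
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- (n * m / 12) *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p.value = 1,
                               method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin))
  list(statistic = W, p.value = p, method = "normal")
}

#' Compare case and control burden in one stratum
#'
#' @param result A `burden_result` from [count_burden()].
#' @param kind `"lof"` or `"damaging_missense"`.
#' @param stratum One of the strata in `result$strata`.
#' @return List: medians per arm, Wilcoxon statistic and two-sided p.
#' @export
burden_test <- function(result, kind = "lof", stratum = 0.001) {
  cc <- result$counts[result$counts$kind == kind &
                        result$counts$stratum == stratum, ]
  x <- cc$count[cc$arm == "case"]
  y <- cc$count[cc$arm == "control"]
  wt <- wilcoxon_two_sided(x, y)
  list(kind = kind, stratum = stratum,
       median_cases = stats::median(x), median_controls = stats::median(y),
       statistic = wt$statistic, p.value = wt$p.value, method = wt$method,
       n_cases = length(x), n_controls = length(y))
}

#' Screen a gene panel for singleton deleterious variants
#'
#' Restricts the QC-passed singleton deleterious set to a gene panel (e.g.
#' the planar-cell-polarity genes implicated in neural tube defects) and
#' reports hits separately for a sample subgroup and for the control arm.
#'
#' @param bundle A `cohort_bundle`.
#' @param panel Character vector of panel gene symbols (nonempty).
#' @param subgroup Character vector of case samples forming the subgroup.
#' @param th Thresholds.
#' @return List: `subgroup_hits` and `control_hits` (variant tables).
#' @export
pcp_panel_screen <- function(bundle, panel, subgroup,
                             th = default_thresholds()) {
  if (!length(panel)) stop("panel must be nonempty")
  known <- unique(bundle$variants$gene)
  missing <- setdiff(panel, known)
  if (length(missing)) {
    warning("panel gene(s) not observed in cohort: ",
            paste(missing, collapse = ", "))
  }
  hq <- qc_filter(bundle$variants, th)
  hit <- find_singletons(hq) & is_deleterious(hq, th) != "none" &
    !is.na(hq$gene) & hq$gene %in% panel
  controls <- bundle$samples$sample[bundle$samples$arm == "control"]
  list(subgroup_hits = hq[hit & hq$sample %in% subgroup, , drop = FALSE],
       control_hits = hq[hit & hq$sample %in% controls, , drop = FALSE])
}
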
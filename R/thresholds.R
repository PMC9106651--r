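#' Default interpretation and QC thresholds
#'
#' Bundles every cutoff the triage cascade and the burden analysis use, so a
#' single object can be passed through the pipeline and overridden in one
#' place. Defaults follow the clinical workflow the package implements:
#' variants with a minor allele frequency above 1% in either the public or
#' the in-house database are never considered diagnostic; burden QC keeps
#' calls with total depth >= 20, alternate-allele depth >= 3 and allele
#' length <= 5 bp; a missense variant counts as damaging only when SIFT calls
#' it damaging and CADD > 20, M-CAP > 0.025 and REVEL > 0.5 all hold; CNV
#' pathogenicity scores map to classes with pathogenic >= 0.99 and likely
#' pathogenic in [0.90, 0.99).
#'
#' @param maf_diagnostic Diagnostic MAF ceiling (variants above are dropped).
#' @param small_cnv_freq In-house frequency ceiling for assessable small CNVs
#'   (strictly below).
#' @param qc_depth Minimum total read depth for burden QC.
#' @param qc_alt_depth Minimum alternate-allele read depth for burden QC.
#' @param qc_max_len_bp Maximum allele length (bp) for burden QC,
#'   `max(nchar(ref), nchar(alt))`.
#' @param cadd,mcap,revel Strict lower bounds for the damaging-missense
#'   predicate.
#' @param cnv_score_pathogenic CNV score at or above which class is `"P"`.
#' @param cnv_score_lp_low,cnv_score_lp_high Closed likely-pathogenic band;
#'   scores in `[lp_low, pathogenic)` are `"LP"` (the printed band 0.90-0.98
#'   with the gap to 0.99 closed from the left).
#' @param maf_strata Nested public-MAF strata for burden counting.
#' @param z_gain,z_loss Aneuploidy z-score thresholds (gain / loss).
#' @param ratio_gain,ratio_loss Segmentation and aneuploidy effect-size
#'   thresholds on the GC-corrected copy ratio.
#' @param dispersion_cap QC gate: profiles whose autosomal ratio median
#'   absolute deviation exceeds this are flagged as failed CNV calling.
#' @param exact_cutoff Largest `min(n, m)` for which the Wilcoxon p-value is
#'   computed from the exact tie-free distribution.
#'
#' @return A list of class `"cns_thresholds"`.
#' @export
#' @examples
#' th <- default_thresholds()
#' th$maf_diagnostic
default_thresholds <- function(maf_diagnostic = 0.01,
                               small_cnv_freq = 0.01,
                               qc_depth = 20L,
                               qc_alt_depth = 3L,
                               qc_max_len_bp = 5L,
                               cadd = 20,
                               mcap = 0.025,
                               revel = 0.5,
                               cnv_score_pathogenic = 0.99,
                               cnv_score_lp_low = 0.90,
                               cnv_score_lp_high = 0.98,
                               maf_strata = c(0, 0.001, 0.01),
                               z_gain = 3.5,
                               z_loss = 3.5,
                               ratio_gain = 1.25,
                               ratio_loss = 0.75,
                               dispersion_cap = 0.25,
                               exact_cutoff = 12L) {
  stopifnot(maf_diagnostic >= 0, small_cnv_freq >= 0,
            qc_depth >= 0, qc_alt_depth >= 0, qc_max_len_bp >= 0,
            cnv_score_lp_low <= cnv_score_lp_high,
            cnv_score_lp_high < cnv_score_pathogenic)
  structure(list(
    maf_diagnostic = maf_diagnostic,
    small_cnv_freq = small_cnv_freq,
    qc_depth = qc_depth,
    qc_alt_depth = qc_alt_depth,
    qc_max_len_bp = qc_max_len_bp,
    cadd = cadd, mcap = mcap, revel = revel,
    cnv_score_pathogenic = cnv_score_pathogenic,
    cnv_score_lp_low = cnv_score_lp_low,
    cnv_score_lp_high = cnv_score_lp_high,
    maf_strata = sort(maf_strata),
    z_gain = z_gain, z_loss = z_loss,
    ratio_gain = ratio_gain, ratio_loss = ratio_loss,
    dispersion_cap = dispersion_cap,
    exact_cutoff = exact_cutoff
  ), class = "cns_thresholds")
}

#' Consequence vocabulary accepted throughout the pipeline
#'
#' @return Character vector of the accepted consequence labels.
#' @export
consequence_vocabulary <- function() {
  c("missense", "nonsense", "frameshift", "canonical_splice", "stop_loss",
    "synonymous", "inframe_indel", "intronic", "noncoding")
}

#' Loss-of-function consequence classes
#' @return Character vector: the consequence labels treated as LoF.
#' @export
lof_consequences <- function() {
  c("nonsense", "frameshift", "canonical_splice", "stop_loss")
}

# Size-tier boundaries (bp). The 100 kb - 5 Mb band is closed at both ends;
# > 5 Mb is strictly above; the intragenic band is [50 bp, 100 kb).
.TIER_SMALL_MIN <- 50
.TIER_SUBMICRO_MIN <- 100e3
.TIER_CHROMOSOMAL_MIN <- 5e6

#' Assign a copy-number event to a resolution tier
#'
#' Events are tiered by size the way clinical testing modalities resolve
#' them: `"chromosomal"` (> 5 Mb, karyotype scale), `"submicroscopic"`
#' (100 kb - 5 Mb inclusive at both ends, microarray scale) and
#' `"intragenic"` (50 bp up to but excluding 100 kb, only visible to
#' sequencing). Every valid size maps to exactly one tier.
#'
#' @param size_bp Event size(s) in bp (numeric, vectorised).
#' @return Character vector of tiers.
#' @export
#' @examples
#' assign_size_tier(c(14.8e6, 442e3, 1300))
assign_size_tier <- function(size_bp) {
  if (!is.numeric(size_bp) || any(!is.finite(size_bp))) {
    stop("size_bp must be finite numeric")
  }
  if (any(size_bp < .TIER_SMALL_MIN)) {
    stop("size below 50 bp is not a reportable copy-number event")
  }
  ifelse(size_bp > .TIER_CHROMOSOMAL_MIN, "chromosomal",
         ifelse(size_bp >= .TIER_SUBMICRO_MIN, "submicroscopic", "intragenic"))
}

#' Map a CNV pathogenicity score to a five-tier class
#'
#' The score is the curated (or heuristic) evidence-point total for the
#' event, on a nonnegative scale where >= 0.99 is pathogenic and
#' [0.90, 0.99) likely pathogenic. Lower scores fall through documented
#' sub-bounds: [0.50, 0.90) VUS, [0.10, 0.50) likely benign, below 0.10
#' benign.
#'
#' @param score Numeric vector of evidence points.
#' @return Character vector of classes in `{"P","LP","VUS","LB","B"}`.
#' @export
#' @examples
#' score_cnv(c(0.99, 0.95, 0))
score_cnv <- function(score) {
  stopifnot(is.numeric(score), all(is.finite(score)))
  ifelse(score >= 0.99, "P",
         ifelse(score >= 0.90, "LP",
                ifelse(score >= 0.50, "VUS",
                       ifelse(score >= 0.10, "LB", "B"))))
}
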
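# Low-pass read-depth screen: GC-bias correction of binned counts, a
# z-score whole-chromosome aneuploidy caller with inferred sex baselines,
# and run-merging segmentation of copy-ratio deviations into CNV calls of
# 100 kb and above. Replaces the external caller the workflow it models
# relied on with a defined, testable detector.

.AUTOSOMES <- as.character(1:22)

.is_autosome <- function(chrom) sub("^chr", "", chrom) %in% .AUTOSOMES

#' GC-correct a binned depth profile
#'
#' Expected count as a function of GC is estimated by a rolling-median
#' regression over GC deciles of the autosomal bins (decile medians
#' interpolated smoothly at each bin's GC), each bin's ratio is its count
#' over that expectation, and ratios are rescaled so the genome-wide
#' autosomal median ratio is exactly 1. Sex-chromosome bins are corrected
#' against the autosomal curve, so a disomic X sits near ratio 1 and a
#' single-copy X near 0.5.
#'
#' @param profile Depth profile (columns chrom, start, end, count, gc).
#' @param n_bands Number of GC quantile bands (default 10).
#' @return The profile with `expected` and `ratio` columns appended.
#' @export
gc_correct <- function(profile, n_bands = 10) {
  stopifnot(all(c("chrom", "count", "gc") %in% names(profile)))
  auto <- .is_autosome(profile$chrom)
  if (sum(auto) < 50) stop("insufficient bins: need >= 50 autosomal bins")
  gc_a <- profile$gc[auto]
  cnt_a <- profile$count[auto]
  brks <- unique(stats::quantile(gc_a, probs = seq(0, 1, length.out =
                                                     n_bands + 1)))
  if (length(brks) < 3) {
    # (near-)constant GC: a single global expectation
    expected <- rep(stats::median(cnt_a), nrow(profile))
  } else {
    band <- cut(gc_a, brks, include.lowest = TRUE)
    med <- tapply(cnt_a, band, stats::median)
    mid <- tapply(gc_a, band, stats::median)
    ok <- !is.na(med) & med > 0
    if (sum(ok) < 2) {
      expected <- rep(stats::median(cnt_a), nrow(profile))
    } else {
      # fmm end conditions extrapolate smoothly into the short GC tails
      # beyond the outermost band medians
      fit <- stats::spline(mid[ok], med[ok], xout = profile$gc,
                           method = "fmm")
      expected <- pmax(fit$y, 1e-8)
    }
  }
  ratio <- profile$count / expected
  g <- stats::median(ratio[auto])
  if (g <= 0) stop("degenerate profile: autosomal median ratio is 0")
  profile$expected <- expected * g
  profile$ratio <- ratio / g
  profile
}

#' Dispersion QC gate for a corrected profile
#'
#' Profiles whose autosomal copy-ratio median absolute deviation exceeds
#' `th$dispersion_cap` are flagged as failed CNV calling (read-depth
#' turbulence); their depth stage is skipped and the failure recorded.
#'
#' @param profile GC-corrected profile.
#' @param th Thresholds ([default_thresholds()]).
#' @return `TRUE` if the profile passes.
#' @export
depth_profile_qc <- function(profile, th = default_thresholds()) {
  stats::mad(profile$ratio[.is_autosome(profile$chrom)]) <= th$dispersion_cap
}

.chrom_stats <- function(profile) {
  sp <- split(profile$ratio, profile$chrom)
  data.frame(
    chrom = names(sp),
    median_ratio = vapply(sp, stats::median, numeric(1)),
    n_bins = lengths(sp),
    se = vapply(sp, function(r) {
      s <- stats::mad(r)
      if (s == 0) s <- stats::sd(r)
      if (is.na(s) || s == 0) s <- 1e-6
      1.2533 * s / sqrt(length(r))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Infer chromosomal sex from corrected X/Y ratios
#'
#' @param profile GC-corrected profile.
#' @return `"male"` if Y material is present (median Y ratio >= 0.25),
#'   else `"female"`.
#' @export
infer_sex <- function(profile) {
  y <- profile$ratio[sub("^chr", "", profile$chrom) == "Y"]
  if (length(y) && stats::median(y) >= 0.25) "male" else "female"
}

#' Call whole-chromosome aneuploidies
#'
#' Each chromosome's median corrected ratio is compared with its baseline
#' (1 for autosomes; X/Y baselines follow the inferred sex) through a
#' z-score using the within-chromosome robust standard error. A call
#' requires both statistical evidence (|z| beyond `th$z_gain` / `th$z_loss`)
#' and a copy-ratio effect beyond the segmentation thresholds, which keeps
#' euploid profiles quiet. Implied copy numbers far from an integer are
#' flagged `"possible_mosaic"` rather than called as full events.
#'
#' @param profile GC-corrected profile.
#' @param th Thresholds.
#' @return Data frame: chrom, direction (gain/loss), z, median_ratio,
#'   copy_number, mosaic. Zero rows on a quiet profile.
#' @export
call_aneuploidy <- function(profile, th = default_thresholds()) {
  if (is.null(profile$ratio)) stop("profile is not GC-corrected")
  st <- .chrom_stats(profile)
  st$chrom_plain <- sub("^chr", "", st$chrom)
  sex <- infer_sex(profile)
  st$baseline <- ifelse(st$chrom_plain %in% .AUTOSOMES, 1,
                        ifelse(st$chrom_plain == "X",
                               if (sex == "male") 0.5 else 1,
                               if (sex == "male") 0.5 else 0))
  calls <- list()
  for (k in seq_len(nrow(st))) {
    base <- st$baseline[k]
    m <- st$median_ratio[k]
    z <- (m - base) / st$se[k]
    if (base == 0) {
      # Y in an inferred female: material present at all is a gain
      if (m >= 0.25) {
        calls[[length(calls) + 1]] <- data.frame(
          chrom = st$chrom[k], direction = "gain", z = z, median_ratio = m,
          copy_number = round(2 * m), mosaic = abs(2 * m - round(2 * m)) > 0.3,
          stringsAsFactors = FALSE)
      }
      next
    }
    gain <- z >= th$z_gain && m >= base * th$ratio_gain
    loss <- z <= -th$z_loss && m <= base * th$ratio_loss
    if (!gain && !loss) next
    copies <- 2 * m  # corrected ratio is per-disomic-copy on every chromosome
    calls[[length(calls) + 1]] <- data.frame(
      chrom = st$chrom[k], direction = if (gain) "gain" else "loss", z = z,
      median_ratio = m, copy_number = round(copies),
      mosaic = abs(copies - round(copies)) > 0.3, stringsAsFactors = FALSE)
  }
  if (!length(calls)) {
    return(data.frame(chrom = character(), direction = character(),
                      z = numeric(), median_ratio = numeric(),
                      copy_number = numeric(), mosaic = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Segment copy-number variants from a corrected profile
#'
#' Contiguous runs of bins whose ratio deviates beyond the segmentation
#' thresholds (gaps of up to `merge_gap` quiet bins are bridged) are merged
#' into segments; segments shorter than `min_size` or without strong
#' aggregate evidence (|segment z| below `seg_z`) are discarded. The copy
#' number estimate is `round(2 * mean ratio)` for autosomes.
#'
#' @param profile GC-corrected profile.
#' @param min_size Minimum segment size in bp (default 100 kb).
#' @param th Thresholds.
#' @param exclude_chroms Chromosomes to skip (e.g. called aneuploid).
#' @param merge_gap Number of non-deviating bins a run may bridge.
#' @param seg_z Minimum aggregate segment z-score.
#' @return Data frame of calls: chrom, start, end, size_bp, size_tier,
#'   copy_number, mean_ratio, z, event.
#' @export
segment_cnvs <- function(profile, min_size = 100e3,
                         th = default_thresholds(),
                         exclude_chroms = character(), merge_gap = 1,
                         seg_z = 4) {
  if (is.null(profile$ratio)) stop("profile is not GC-corrected")
  bin_width <- stats::median(profile$end - profile$start + 1)
  if (min_size < bin_width) {
    stop("min_size must be at least the bin width (", bin_width, " bp)")
  }
  auto_r <- profile$ratio[.is_autosome(profile$chrom)]
  noise <- stats::mad(auto_r)
  if (noise == 0) noise <- max(stats::sd(auto_r), 1e-6)
  sex <- infer_sex(profile)
  out <- list()
  for (ch in setdiff(unique(profile$chrom), exclude_chroms)) {
    plain <- sub("^chr", "", ch)
    base <- if (plain %in% .AUTOSOMES) 1 else
      if (plain == "X") (if (sex == "male") 0.5 else 1) else
        (if (sex == "male") 0.5 else 0)
    if (base == 0) next  # no baseline copy to segment against
    p <- profile[profile$chrom == ch, ]
    p <- p[order(p$start), ]
    rel <- p$ratio / base
    state <- ifelse(rel >= th$ratio_gain, 1L,
                    ifelse(rel <= th$ratio_loss, -1L, 0L))
    runs <- .merge_runs(state, merge_gap)
    for (r in runs) {
      i <- r$from:r$to
      start <- p$start[r$from]; end <- p$end[r$to]
      size <- end - start + 1
      if (size < min_size) next
      mr <- mean(p$ratio[i])
      z <- (mr / base - 1) / (noise / sqrt(length(i)))
      if (abs(z) < seg_z) next
      cn <- round(2 * mr)
      if (cn == round(2 * base)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start, end = end, size_bp = size,
        size_tier = assign_size_tier(size), copy_number = cn,
        mean_ratio = mr, z = z,
        event = sprintf("%s(%s:%d-%d)x%d",
                        if (cn < 2) "del" else "dup", ch, start, end, cn),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size_bp = numeric(),
                      size_tier = character(), copy_number = numeric(),
                      mean_ratio = numeric(), z = numeric(),
                      event = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Runs of identical nonzero state, bridging up to `gap` zero bins between
# runs of the same sign.
.merge_runs <- function(state, gap) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- which(r$values != 0)
  if (!length(segs)) return(list())
  merged <- list()
  cur <- list(from = starts[segs[1]], to = ends[segs[1]],
              sign = r$values[segs[1]])
  if (length(segs) > 1) {
    for (s in segs[-1]) {
      gap_len <- starts[s] - cur$to - 1
      if (r$values[s] == cur$sign && gap_len <= gap) {
        cur$to <- ends[s]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- list(from = starts[s], to = ends[s], sign = r$values[s])
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  merged
}
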
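# External representations: the tab-delimited variant dialect (read/write),
# VCF (read, via vcfR), BED intervals (read/write, held as GRanges), simple
# frequency databases, and the packaged fixture re-encoding the published
# cohort tables. All coordinate conversions live here: small variants are
# 1-based (VCF convention), BED input is 0-based half-open and converted to
# 1-based closed GRanges on the way in.

# Internal <-> external column names of the TSV variant dialect.
.VAR_COLS <- c(
  sample = "SAMPLE", chrom = "CHROM", pos = "POS", ref = "REF", alt = "ALT",
  zygosity = "ZYGOSITY", depth = "DP", alt_depth = "AD_ALT", gene = "GENE",
  consequence = "CSQ", sift_class = "SIFT_CLASS", cadd = "CADD",
  mcap = "MCAP", revel = "REVEL", af_public = "AF_PUBLIC",
  af_inhouse = "AF_INHOUSE"
)

#' Construct an empty variant table
#'
#' @return Zero-row data frame with the canonical variant columns.
#' @export
empty_variant_table <- function() {
  data.frame(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), zygosity = character(),
    depth = integer(), alt_depth = integer(), gene = character(),
    consequence = character(), sift_class = character(), cadd = numeric(),
    mcap = numeric(), revel = numeric(), af_public = numeric(),
    af_inhouse = numeric(), stringsAsFactors = FALSE
  )
}

.validate_variant_table <- function(df, file = "<table>") {
  df$pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(df$pos) | df$pos < 1 | is.na(df$ref) | df$ref == "" |
                 is.na(df$alt) | df$alt == "")
  if (length(bad)) {
    stop(sprintf("malformed variant row at line %d of %s", bad[1] + 1L, file))
  }
  vocab <- consequence_vocabulary()
  unknown <- setdiff(unique(df$consequence[!is.na(df$consequence)]), vocab)
  if (length(unknown)) {
    stop(sprintf(
      "unknown consequence label(s) %s; accepted vocabulary: %s",
      paste(unknown, collapse = ", "), paste(vocab, collapse = ", ")
    ))
  }
  for (col in c("depth", "alt_depth")) df[[col]] <- as.integer(df[[col]])
  for (col in c("cadd", "mcap", "revel")) df[[col]] <- as.numeric(df[[col]])
  # missing population frequency means "not observed" and is read as 0
  for (col in c("af_public", "af_inhouse")) {
    x <- as.numeric(df[[col]])
    x[is.na(x)] <- 0
    if (any(x < 0 | x > 1)) stop("allele frequencies must lie in [0, 1]")
    df[[col]] <- x
  }
  df$sift_class[is.na(df$sift_class) | df$sift_class == ""] <- "missing"
  bad_ad <- which(!is.na(df$alt_depth) & !is.na(df$depth) &
                    df$alt_depth > df$depth)
  if (length(bad_ad)) {
    stop(sprintf("alt depth exceeds total depth at line %d of %s",
                 bad_ad[1] + 1L, file))
  }
  dup <- duplicated(df[, c("sample", "chrom", "pos", "ref", "alt")])
  if (any(dup)) {
    stop(sprintf("duplicate (sample, chrom, pos, ref, alt) key at line %d",
                 which(dup)[1] + 1L))
  }
  rownames(df) <- NULL
  df
}

#' Read a per-sample annotated variant table
#'
#' Supports two dialects: `"tsv"`, the package's flat tab-delimited mirror of
#' VCF columns plus annotation columns (GENE, CSQ, SIFT_CLASS, CADD, MCAP,
#' REVEL, AF_PUBLIC, AF_INHOUSE), and `"vcf"`, a VCF 4.x file whose INFO
#' field carries the same annotations (keys GENE, CSQ, SIFT, CADD, MCAP,
#' REVEL, AF_PUB, AF_IH) and whose per-sample FORMAT fields provide GT, DP
#' and AD. Coordinates are 1-based in both dialects and preserved as such.
#' Missing population frequencies are interpreted as 0 (allele absent from
#' the database); missing SIFT calls become `"missing"`.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Data frame of variant records (one row per sample-allele).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            na.strings = c("NA", "."), check.names = FALSE)
    missing_cols <- setdiff(unname(.VAR_COLS), names(df))
    if (length(missing_cols)) {
      stop("variant table is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    df <- df[, unname(.VAR_COLS)]
    names(df) <- names(.VAR_COLS)
    return(.validate_variant_table(df, basename(path)))
  }
  .read_variant_vcf(path)
}

.info_field <- function(info, key) {
  hit <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
  out <- rep(NA_character_, length(info))
  out[hit > 0] <- sub(paste0("^;?", key, "="), "", regmatches(info, hit))
  out
}

.read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variant_table())
  info <- vcfR::getINFO(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  recs <- list()
  for (s in samples) {
    g <- gt[, s]
    keep <- which(!is.na(g) & grepl("1", g))
    if (!length(keep)) next
    zyg <- vapply(g[keep], function(x) {
      al <- strsplit(x, "[/|]")[[1]]
      if (length(al) == 1) "hemi" else if (all(al == "1")) "hom" else "het"
    }, character(1))
    altd <- vapply(ad[keep, s], function(x) {
      if (is.na(x)) return(NA_integer_)
      as.integer(strsplit(x, ",")[[1]][2])
    }, integer(1))
    recs[[s]] <- data.frame(
      sample = s, chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep], alt = fix$ALT[keep], zygosity = unname(zyg),
      depth = as.integer(dp[keep, s]), alt_depth = altd,
      gene = .info_field(info[keep], "GENE"),
      consequence = .info_field(info[keep], "CSQ"),
      sift_class = .info_field(info[keep], "SIFT"),
      cadd = as.numeric(.info_field(info[keep], "CADD")),
      mcap = as.numeric(.info_field(info[keep], "MCAP")),
      revel = as.numeric(.info_field(info[keep], "REVEL")),
      af_public = as.numeric(.info_field(info[keep], "AF_PUB")),
      af_inhouse = as.numeric(.info_field(info[keep], "AF_IH")),
      stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) return(empty_variant_table())
  out <- do.call(rbind, recs)
  .validate_variant_table(out, basename(path))
}

#' Write a variant table in the TSV dialect
#'
#' @param variants Variant data frame (canonical columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  stopifnot(all(names(.VAR_COLS) %in% names(variants)))
  out <- variants[, names(.VAR_COLS)]
  names(out) <- unname(.VAR_COLS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a BED interval file
#'
#' BED input is 0-based half-open; intervals are converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] on the way in and sorted per
#' chromosome, so downstream overlap queries use the standard machinery.
#'
#' @param path BED file (3 or 4 columns; the 4th becomes the `label` column).
#' @return A `GRanges` with an mcols column `label`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", colClasses = "character",
                      comment.char = "#"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(GenomicRanges::GRanges(label = character()))
  }
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns")
  start0 <- suppressWarnings(as.numeric(raw[[2]]))
  end0 <- suppressWarnings(as.numeric(raw[[3]]))
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("non-numeric coordinate in BED file ", basename(path))
  }
  if (any(start0 >= end0)) {
    stop(sprintf("BED interval with start >= end at line %d",
                 which(start0 >= end0)[1]))
  }
  label <- if (ncol(raw) >= 4) raw[[4]] else rep(NA_character_, nrow(raw))
  gr <- GenomicRanges::GRanges(
    seqnames = raw[[1]],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    label = label
  )
  GenomicRanges::sort(gr)
}

#' Write intervals back to BED
#'
#' @param gr `GRanges` with optional `label` mcols column.
#' @param path Output BED path (written 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    label = if ("label" %in% names(S4Vectors::mcols(gr))) {
      S4Vectors::mcols(gr)$label
    } else NA_character_
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = ".")
  invisible(path)
}

#' Build a frequency database lookup
#'
#' A frequency database maps small-variant alleles (chrom, pos, ref, alt) and
#' CNV event keys to allele frequencies in `[0, 1]`; an absent key is
#' interpreted as frequency 0.
#'
#' @param snv Data frame with columns chrom, pos, ref, alt, af (optional).
#' @param cnv Data frame with columns key, af (optional).
#' @param source Name of the database.
#' @return List of class `"frequency_db"`.
#' @export
frequency_db <- function(snv = NULL, cnv = NULL, source = "inhouse") {
  snv_map <- numeric()
  if (!is.null(snv) && nrow(snv)) {
    stopifnot(all(snv$af >= 0 & snv$af <= 1))
    snv_map <- stats::setNames(
      snv$af, paste(snv$chrom, snv$pos, snv$ref, snv$alt, sep = ":"))
  }
  cnv_map <- numeric()
  if (!is.null(cnv) && nrow(cnv)) {
    stopifnot(all(cnv$af >= 0 & cnv$af <= 1))
    cnv_map <- stats::setNames(cnv$af, cnv$key)
  }
  structure(list(source = source, snv = snv_map, cnv = cnv_map),
            class = "frequency_db")
}

#' Look up small-variant frequencies (vectorised; missing key is 0)
#'
#' @param db A `frequency_db`.
#' @param chrom,pos,ref,alt Allele key vectors.
#' @return Numeric vector of frequencies.
#' @export
lookup_frequency <- function(db, chrom, pos, ref, alt) {
  key <- paste(chrom, pos, ref, alt, sep = ":")
  out <- unname(db$snv[key])
  out[is.na(out)] <- 0
  out
}

#' Look up CNV event frequencies (vectorised; missing key is 0)
#'
#' @param db A `frequency_db`.
#' @param key Character vector of event keys.
#' @return Numeric vector of frequencies.
#' @export
lookup_cnv_frequency <- function(db, key) {
  out <- unname(db$cnv[key])
  out[is.na(out)] <- 0
  out
}
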
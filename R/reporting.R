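# Reporting layer: diagnostic-yield tables by group, the resolution-tier
# breakdown with cascade (shrinking) denominators, the recurrent-gene tally
# over primary findings, and inheritance-mode percentages over the curated
# gene-mode table.

# round half away from zero; reproduces every printed percentage from its
# printed fraction
.round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic yield by group
#'
#' One row per group label plus an overall row. A sample carrying several
#' labels is counted in each of its groups (repeated counting, so
#' per-group numerators may sum above the overall diagnosed count); the
#' overall row counts each sample once. Percentages are rounded to one
#' decimal, half away from zero; an empty group gets `NA` percent.
#'
#' @param diagnoses Data frame with columns `sample` and `diagnosed`
#'   (logical).
#' @param groups Data frame (sample, label), possibly several rows per
#'   sample; defaults to a single overall group.
#' @return Data frame: label, diagnosed, total, percent.
#' @export
diagnostic_yield <- function(diagnoses, groups = NULL) {
  stopifnot(all(c("sample", "diagnosed") %in% names(diagnoses)))
  rows <- list()
  if (!is.null(groups)) {
    stopifnot(all(groups$sample %in% diagnoses$sample))
    dx <- stats::setNames(diagnoses$diagnosed, diagnoses$sample)
    for (lab in unique(groups$label)) {
      s <- unique(groups$sample[groups$label == lab])
      rows[[lab]] <- data.frame(
        label = lab, diagnosed = sum(dx[s]), total = length(s),
        stringsAsFactors = FALSE)
    }
  }
  rows[["overall"]] <- data.frame(
    label = "overall", diagnosed = sum(diagnoses$diagnosed),
    total = nrow(diagnoses), stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$percent <- ifelse(out$total == 0, NA_real_,
                        .round_half_away(100 * out$diagnosed / out$total, 1))
  out
}

.TIER_ORDER <- c("chromosomal", "submicroscopic", "snv", "intragenic")

#' Resolution-tier breakdown with cascade denominators
#'
#' Counts primary diagnoses per resolution tier in cascade order
#' (chromosomal including aneuploidy, then submicroscopic, then SNV, then
#' intragenic CNV). Each tier's denominator is the number of samples still
#' undiagnosed when that tier is reached, so denominators shrink along the
#' cascade.
#'
#' @param diagnoses Data frame with columns `sample`, `diagnosed`, `tier`
#'   (`NA` tier for undiagnosed samples).
#' @return Data frame: tier, diagnosed, denominator, percent.
#' @export
tier_breakdown <- function(diagnoses) {
  if (any(diagnoses$diagnosed & is.na(diagnoses$tier))) {
    stop("diagnosed sample without a resolution tier")
  }
  bad <- setdiff(stats::na.omit(unique(diagnoses$tier)), .TIER_ORDER)
  if (length(bad)) stop("unknown tier(s): ", paste(bad, collapse = ", "))
  denom <- nrow(diagnoses)
  out <- list()
  for (tier in .TIER_ORDER) {
    d <- sum(diagnoses$diagnosed & diagnoses$tier == tier, na.rm = TRUE)
    out[[tier]] <- data.frame(
      tier = tier, diagnosed = d, denominator = denom,
      percent = ifelse(denom == 0, NA_real_,
                       .round_half_away(100 * d / denom, 1)),
      stringsAsFactors = FALSE)
    denom <- denom - d
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tally key genes across primary findings
#'
#' Collects the gene of every primary finding (for CNV findings, the
#' curated critical genes; several per event allowed, comma-separated) and
#' counts the number of distinct diagnosed fetuses per gene. A gene seen in
#' two or more fetuses is recurrent; two findings in the same fetus and
#' gene count once.
#'
#' @param findings Data frame with columns `sample`, `category`, `gene`
#'   and optionally `critical_genes`.
#' @return Data frame: gene, n_samples, recurrent — sorted by n_samples
#'   then gene.
#' @export
recurrent_genes <- function(findings) {
  prim <- findings[findings$category == "primary", , drop = FALSE]
  empty <- data.frame(gene = character(), n_samples = integer(),
                      recurrent = logical(), stringsAsFactors = FALSE)
  if (!nrow(prim)) return(empty)
  pairs <- list()
  if (nrow(prim)) {
    g1 <- data.frame(sample = prim$sample, gene = prim$gene,
                     stringsAsFactors = FALSE)
    pairs[[1]] <- g1[!is.na(g1$gene) & g1$gene != "", ]
    if ("critical_genes" %in% names(prim)) {
      cg <- prim$critical_genes
      cg[is.na(cg)] <- ""
      expand <- strsplit(cg, ",")
      pairs[[2]] <- data.frame(
        sample = rep(prim$sample, lengths(expand)),
        gene = trimws(unlist(expand)), stringsAsFactors = FALSE)
      pairs[[2]] <- pairs[[2]][pairs[[2]]$gene != "", ]
    }
  }
  pg <- unique(do.call(rbind, c(pairs, list(make.row.names = FALSE))))
  if (!nrow(pg)) return(empty)
  tab <- table(pg$gene)
  out <- data.frame(gene = names(tab), n_samples = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$recurrent <- out$n_samples >= 2
  out[order(-out$n_samples, out$gene), , drop = FALSE]
}

#' Inheritance-mode percentages over a key-gene set
#'
#' @param genes Character vector of key genes (each must be annotated).
#' @param gene_modes Data frame (gene, mode) with modes in
#'   `{"AD","AR","XL","XLD"}`.
#' @param collapse_x Report XL and XLD together as `"XL"` (default), the
#'   way inheritance splits are usually summarised.
#' @return Data frame: mode, n, percent (percent rounded to nearest
#'   integer, half away from zero).
#' @export
inheritance_breakdown <- function(genes, gene_modes, collapse_x = TRUE) {
  idx <- match(genes, gene_modes$gene)
  if (anyNA(idx)) {
    stop("no inheritance mode annotated for gene(s): ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  mode <- gene_modes$mode[idx]
  if (collapse_x) mode[mode %in% c("XL", "XLD")] <- "XL"
  tab <- table(mode)
  data.frame(mode = names(tab), n = as.integer(tab),
             percent = .round_half_away(100 * as.integer(tab) /
                                          length(genes), 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full fixture report
#'
#' Runs the reporting layer over the packaged fixture: overall and subgroup
#' yields, the resolution-tier breakdown, the key-gene tally and the
#' inheritance split over the mode-annotated diagnostic-SNV genes.
#'
#' @param fx A `cns_fixture` ([load_paper_fixture()]).
#' @return List: `yield`, `tiers`, `genes`, `inheritance`.
#' @export
fixture_report <- function(fx = load_paper_fixture()) {
  dx <- fixture_diagnoses(fx)
  groups <- data.frame(sample = dx$sample, label = dx$subgroup,
                       stringsAsFactors = FALSE)
  genes <- recurrent_genes(fx$findings)
  list(
    yield = diagnostic_yield(dx, groups),
    tiers = tier_breakdown(dx),
    genes = genes,
    inheritance = inheritance_breakdown(
      intersect(genes$gene, fx$gene_modes$gene), fx$gene_modes)
  )
}

#' Bar-and-line yield plot
#'
#' Bars show diagnosed and total counts per group; the line shows the
#' diagnostic rate.
#'
#' @param yield Output of [diagnostic_yield()].
#' @param main Plot title.
#' @return Invisibly, the yield table.
#' @export
plot_yield <- function(yield, main = "Diagnostic yield") {
  y <- yield[yield$label != "overall", , drop = FALSE]
  if (!nrow(y)) y <- yield
  bp <- graphics::barplot(rbind(y$diagnosed, y$total - y$diagnosed),
                          names.arg = y$label, las = 2,
                          col = c("steelblue", "grey85"),
                          ylab = "cases", main = main)
  graphics::par(new = TRUE)
  graphics::plot(bp, y$percent, type = "b", axes = FALSE, xlab = "",
                 ylab = "", lty = 2, pch = 19,
                 ylim = c(0, 100), xlim = range(bp) + c(-0.5, 0.5))
  graphics::axis(4)
  graphics::mtext("diagnostic rate (%)", side = 4, line = 2)
  invisible(yield)
}

#' Case vs control burden histograms
#'
#' @param result A `burden_result`.
#' @param kind,stratum Which count distribution to draw.
#' @return Invisibly, the test summary from [burden_test()].
#' @export
plot_burden <- function(result, kind = "lof", stratum = 0.001) {
  cc <- result$counts[result$counts$kind == kind &
                        result$counts$stratum == stratum, ]
  x <- cc$count[cc$arm == "case"]; y <- cc$count[cc$arm == "control"]
  brk <- seq(-0.5, max(c(x, y)) + 0.5, by = 1)
  hx <- graphics::hist(x, breaks = brk, plot = FALSE)
  hy <- graphics::hist(y, breaks = brk, plot = FALSE)
  graphics::plot(hx$mids, hx$density, type = "h", lwd = 6, col = "tomato3",
                 xlab = "singleton deleterious variants per sample",
                 ylab = "density",
                 main = sprintf("%s, MAF <= %g", kind, stratum))
  graphics::points(hy$mids + 0.25, hy$density, type = "h", lwd = 6,
                   col = "grey50")
  graphics::abline(v = stats::median(x), col = "tomato3", lty = 1)
  graphics::abline(v = stats::median(y), col = "grey50", lty = 2)
  invisible(burden_test(result, kind, stratum))
}
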
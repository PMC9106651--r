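# Primary-diagnosis cascade: low-pass findings first; if uninformative,
# phenotype-driven SNV interpretation against an HPO-derived candidate gene
# list with a deterministic ACMG combining-rule engine; if still
# uninformative, assessment of exon-containing small CNVs (50 bp - 100 kb).
# Every reportable variant gets a five-tier class and a finding category
# (primary / incidental / secondary / carrier).

#' Build a phenotype-driven candidate gene list
#'
#' Genes annotated to each query term or to any of its descendant terms
#' (standard annotation-propagation semantics: an annotation to a specific
#' term implies the more general ancestors), unioned over the query set.
#' Adding a term can therefore never shrink the result.
#'
#' @param terms Character vector of phenotype term ids.
#' @param hpo_map Data frame (term, gene): term-to-gene annotations.
#' @param ontology Data frame (term, parent): is-a edges.
#' @return Sorted character vector of candidate genes.
#' @export
build_candidate_genes <- function(terms, hpo_map, ontology) {
  if (!length(terms)) return(character())
  universe <- unique(c(ontology$term, ontology$parent))
  unknown <- setdiff(terms, universe)
  if (length(unknown)) {
    stop("unknown phenotype term(s): ", paste(unknown, collapse = ", "))
  }
  children <- split(ontology$term, ontology$parent)
  closure <- character()
  queue <- unique(terms)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (t %in% closure) next
    closure <- c(closure, t)
    queue <- c(queue, children[[t]])
  }
  sort(unique(hpo_map$gene[hpo_map$term %in% closure]))
}

#' Frequency/consequence/candidate-gene filter for diagnostic SNVs
#'
#' A variant survives iff its worst population frequency
#' (`max(af_public, af_inhouse)`, optionally supplemented from `freq_db`)
#' does not exceed `th$maf_diagnostic`, its consequence is neither intronic
#' nor noncoding (canonical splice-site changes carry their own consequence
#' label and survive), and it lies on a candidate gene.
#'
#' @param variants Variant table (canonical columns).
#' @param candidate_genes Character vector from [build_candidate_genes()].
#' @param th Thresholds.
#' @param freq_db Optional [frequency_db()] supplying additional in-house
#'   frequencies.
#' @return The retained subset of `variants`.
#' @export
filter_snvs_for_diagnosis <- function(variants, candidate_genes,
                                      th = default_thresholds(),
                                      freq_db = NULL) {
  if (!nrow(variants)) return(variants)
  af_ih <- variants$af_inhouse
  if (!is.null(freq_db)) {
    af_ih <- pmax(af_ih, lookup_frequency(freq_db, variants$chrom,
                                          variants$pos, variants$ref,
                                          variants$alt))
  }
  keep <- pmax(variants$af_public, af_ih) <= th$maf_diagnostic &
    !(variants$consequence %in% c("intronic", "noncoding")) &
    !is.na(variants$gene) & variants$gene %in% candidate_genes
  variants[keep, , drop = FALSE]
}

.ACMG_TAGS <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

#' Classify a variant from ACMG-style evidence tags
#'
#' A reduced, fully deterministic implementation of the published
#' evidence-combining rules over curated tags. Tags are the standard codes
#' (PVS1; PS1-PS4; PM1-PM6; PP1-PP5; BA1; BS1-BS4; BP1-BP7). Pathogenic and
#' likely-pathogenic combinations follow the published combining table;
#' benign-side rules are BA1 alone or two strong benign for benign, one
#' strong plus one supporting or two supporting for likely benign. When
#' both pathogenic- and benign-side criteria fire, or neither does, the
#' class is VUS.
#'
#' @param tags Character vector of tags, or a single comma-separated string.
#' @return One of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @export
#' @examples
#' classify_variant(c("PVS1", "PM2", "PP4"))  # "P"
#' classify_variant("PVS1,PM2")               # "LP"
#' classify_variant(character())              # "VUS"
classify_variant <- function(tags) {
  if (length(tags) == 1 && grepl(",", tags)) {
    tags <- strsplit(tags, ",")[[1]]
  }
  tags <- trimws(tags[nzchar(trimws(tags))])
  unknown <- setdiff(tags, .ACMG_TAGS)
  if (length(unknown)) {
    stop("unknown evidence tag(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(.ACMG_TAGS, collapse = ", "))
  }
  pvs <- sum(grepl("^PVS", tags)); ps <- sum(grepl("^PS", tags))
  pm <- sum(grepl("^PM", tags)); pp <- sum(grepl("^PP", tags))
  ba <- sum(grepl("^BA", tags)); bs <- sum(grepl("^BS", tags))
  bp <- sum(grepl("^BP", tags))

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    pvs >= 2 ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs == 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- if (pathogenic) "P" else if (likely_pathogenic) "LP" else NA
  ben_side <- if (benign) "B" else if (likely_benign) "LB" else NA
  if (!is.na(path_side) && !is.na(ben_side)) return("VUS")
  if (!is.na(path_side)) return(path_side)
  if (!is.na(ben_side)) return(ben_side)
  "VUS"
}

#' Assess small CNVs for diagnostic review
#'
#' Only exon-containing events with an in-house frequency strictly below
#' `th$small_cnv_freq` are retained, ordered by size descending — the
#' shortlist a clinical review panel would assess.
#'
#' @param cnvs Data frame of small CNV calls (chrom, start, end, size_bp,
#'   freq_inhouse, ...); all events must be in [50 bp, 100 kb).
#' @param exon_map `GRanges` of exon intervals ([read_intervals()]).
#' @param th Thresholds.
#' @param freq_db Optional [frequency_db()] supplying event frequencies by
#'   `key` column when `freq_inhouse` is absent.
#' @return The retained, size-ordered subset.
#' @export
triage_small_cnvs <- function(cnvs, exon_map, th = default_thresholds(),
                              freq_db = NULL) {
  if (!nrow(cnvs)) return(cnvs)
  stopifnot(all(cnvs$size_bp >= 50 & cnvs$size_bp < 100e3))
  freq <- cnvs$freq_inhouse
  if (is.null(freq)) freq <- lookup_cnv_frequency(freq_db, cnvs$key)
  gr <- GenomicRanges::GRanges(cnvs$chrom,
                               IRanges::IRanges(cnvs$start, cnvs$end))
  n_exons <- GenomicRanges::countOverlaps(gr, exon_map)
  keep <- n_exons >= 1 & freq < th$small_cnv_freq
  out <- cnvs[keep, , drop = FALSE]
  out[order(-out$size_bp), , drop = FALSE]
}

#' Assign a finding category to a classified variant
#'
#' Pathogenic / likely pathogenic findings relevant to the prenatal
#' phenotype are primary; otherwise membership of the secondary-findings
#' gene list makes them secondary, heterozygosity in a recessive-disease
#' gene makes them carrier findings, and anything else is incidental.
#' Findings below LP get category `"none"`.
#'
#' @param class Five-tier class.
#' @param phenotype_relevant Logical: linked to the imaging phenotype.
#' @param gene Gene symbol (may be `NA`).
#' @param sf_gene_list Character vector: recommended secondary-findings
#'   genes.
#' @param inheritance Disease inheritance mode (`"AD"`, `"AR"`, `"XL"`,
#'   `"XLD"`, or `NA`).
#' @param zygosity `"het"`, `"hom"` or `"hemi"`.
#' @return One of `"primary"`, `"secondary"`, `"carrier"`, `"incidental"`,
#'   `"none"`.
#' @export
assign_finding_category <- function(class, phenotype_relevant, gene = NA,
                                    sf_gene_list = character(),
                                    inheritance = NA, zygosity = "het") {
  if (!class %in% c("P", "LP")) return("none")
  if (isTRUE(phenotype_relevant)) return("primary")
  if (!is.na(gene) && gene %in% sf_gene_list) return("secondary")
  if (!is.na(inheritance) && inheritance == "AR" && zygosity == "het") {
    return("carrier")
  }
  "incidental"
}

# Score CNV calls against a dosage-region table: the evidence points of the
# best-matching region (>= `min_cover` of the region covered by the call);
# calls hitting no curated region get a low default score.
.score_calls_against_db <- function(calls, dosage_db, min_cover = 0.5,
                                    default_score = 0.3) {
  if (!nrow(calls)) return(numeric())
  if (is.null(dosage_db) || !nrow(dosage_db)) {
    return(rep(default_score, nrow(calls)))
  }
  score <- rep(default_score, nrow(calls))
  relevant <- rep(FALSE, nrow(calls))
  for (k in seq_len(nrow(calls))) {
    same <- dosage_db$chrom == calls$chrom[k]
    if (!any(same)) next
    db <- dosage_db[same, , drop = FALSE]
    ov <- pmax(0, pmin(db$end, calls$end[k]) - pmax(db$start, calls$start[k])
               + 1)
    cover <- ov / (db$end - db$start + 1)
    hit <- which(cover >= min_cover)
    if (length(hit)) {
      best <- hit[which.max(db$score[hit])]
      score[k] <- db$score[best]
      relevant[k] <- isTRUE(db$relevant[best])
    }
  }
  attr(score, "relevant") <- relevant
  score
}

#' Run the primary-diagnosis cascade for one sample
#'
#' Stage 1 interprets the low-pass depth profile (aneuploidies, then CNVs
#' >= 100 kb scored against the dosage-region table); any primary finding
#' stops the cascade, mirroring the two-stage sequencing design. Stage 2
#' triages SNVs against the phenotype-driven candidate gene list, with
#' classes from curated evidence tags. Stage 3 assesses exon-containing
#' rare small CNVs only when stage 2 was uninformative.
#'
#' @param sample_id Sample to triage.
#' @param bundle A `cohort_bundle` (from [generate_cohort()] or assembled
#'   from files).
#' @param th Thresholds.
#' @return List of class `"cns_diagnosis"`: `sample`, `diagnosed`, `stage`
#'   (1, 2, 3 or `NA`), `tier`, `findings` (data frame), `qc` (character
#'   vector of QC notes).
#' @export
triage_sample <- function(sample_id, bundle, th = default_thresholds()) {
  if (!sample_id %in% bundle$samples$sample) {
    stop("sample not in bundle: ", sample_id)
  }
  res <- bundle$resources
  qc <- character()
  findings <- list()
  diagnosed_tier <- NA_character_
  stage <- NA_integer_

  ## stage 1: low-pass aneuploidy + large CNV screen
  prof <- bundle$depth_profiles[[sample_id]]
  if (is.null(prof)) {
    qc <- c(qc, "no depth profile; low-pass stage skipped")
    warning("sample ", sample_id,
            ": missing depth profile, low-pass stage skipped")
  } else {
    prof <- gc_correct(prof)
    if (!depth_profile_qc(prof, th)) {
      qc <- c(qc, "CNV calling failed (read-depth turbulence)")
    } else {
      aneu <- call_aneuploidy(prof, th)
      full <- aneu[!aneu$mosaic, , drop = FALSE]
      if (nrow(full)) {
        findings[[length(findings) + 1]] <- data.frame(
          sample = sample_id, kind = "aneuploidy",
          event = paste0(ifelse(full$direction == "gain", "+", "-"),
                         full$chrom),
          gene = NA_character_, class = "P", category = "primary",
          tier = "chromosomal", size_bp = NA_real_,
          detail = sprintf("z=%.1f", full$z), stringsAsFactors = FALSE)
        diagnosed_tier <- "chromosomal"; stage <- 1L
      }
      if (nrow(aneu[aneu$mosaic, , drop = FALSE])) {
        m <- aneu[aneu$mosaic, , drop = FALSE]
        findings[[length(findings) + 1]] <- data.frame(
          sample = sample_id, kind = "aneuploidy_mosaic",
          event = paste0("possible mosaic ", m$chrom), gene = NA_character_,
          class = "VUS", category = "none", tier = "chromosomal",
          size_bp = NA_real_, detail = sprintf("z=%.1f", m$z),
          stringsAsFactors = FALSE)
      }
      if (is.na(diagnosed_tier)) {
        segs <- segment_cnvs(prof, min_size = 100e3, th = th,
                             exclude_chroms = unique(aneu$chrom))
        if (nrow(segs)) {
          score <- .score_calls_against_db(segs, res$dosage_db)
          cls <- score_cnv(score)
          relevant <- attr(score, "relevant")
          cat_ <- vapply(seq_along(cls), function(j) {
            assign_finding_category(cls[j], relevant[j],
                                    sf_gene_list = res$sf_genes)
          }, character(1))
          rep_ <- cls %in% c("P", "LP")
          if (any(rep_)) {
            findings[[length(findings) + 1]] <- data.frame(
              sample = sample_id, kind = "cnv", event = segs$event[rep_],
              gene = NA_character_, class = cls[rep_],
              category = cat_[rep_], tier = segs$size_tier[rep_],
              size_bp = segs$size_bp[rep_],
              detail = sprintf("score=%.2f", score[rep_]),
              stringsAsFactors = FALSE)
            if (any(cat_[rep_] == "primary")) {
              prim_tiers <- segs$size_tier[rep_][cat_[rep_] == "primary"]
              diagnosed_tier <- if ("chromosomal" %in% prim_tiers) {
                "chromosomal"
              } else "submicroscopic"
              stage <- 1L
            }
          }
        }
      }
    }
  }

  ## stage 2: SNV triage (skipped when stage 1 diagnosed the sample)
  if (is.na(diagnosed_tier)) {
    terms <- strsplit(
      bundle$samples$phenotypes[bundle$samples$sample == sample_id],
      ";")[[1]]
    cand <- build_candidate_genes(terms, res$hpo_map, res$ontology)
    vars <- bundle$variants[bundle$variants$sample == sample_id, ,
                            drop = FALSE]
    shortlist <- filter_snvs_for_diagnosis(vars, cand, th)
    if (nrow(shortlist)) {
      ev <- res$evidence
      key <- paste(shortlist$sample, shortlist$chrom, shortlist$pos,
                   shortlist$ref, shortlist$alt)
      ekey <- paste(ev$sample, ev$chrom, ev$pos, ev$ref, ev$alt)
      idx <- match(key, ekey)
      cls <- vapply(seq_len(nrow(shortlist)), function(j) {
        if (is.na(idx[j])) return("VUS")
        classify_variant(ev$tags[idx[j]])
      }, character(1))
      relevant <- ifelse(is.na(idx), FALSE, ev$phenotype_relevant[idx])
      cat_ <- vapply(seq_len(nrow(shortlist)), function(j) {
        assign_finding_category(cls[j], relevant[j], shortlist$gene[j],
                                res$sf_genes, NA, shortlist$zygosity[j])
      }, character(1))
      rep_ <- cls %in% c("P", "LP")
      if (any(rep_)) {
        findings[[length(findings) + 1]] <- data.frame(
          sample = sample_id, kind = "snv",
          event = paste0(shortlist$gene[rep_], ":", shortlist$chrom[rep_],
                         ":", shortlist$pos[rep_]),
          gene = shortlist$gene[rep_], class = cls[rep_],
          category = cat_[rep_], tier = "snv", size_bp = NA_real_,
          detail = "", stringsAsFactors = FALSE)
        if (any(cat_[rep_] == "primary")) {
          diagnosed_tier <- "snv"; stage <- 2L
        }
      }
    }
  }

  ## stage 3: small-CNV assessment, only after uninformative SNV triage
  if (is.na(diagnosed_tier) && !is.null(bundle$cnvs)) {
    sc <- bundle$cnvs[bundle$cnvs$sample == sample_id, , drop = FALSE]
    if (nrow(sc)) {
      assessed <- triage_small_cnvs(sc, res$exon_map, th)
      if (nrow(assessed)) {
        score <- .score_calls_against_db(assessed, res$dosage_db)
        cls <- score_cnv(score)
        relevant <- attr(score, "relevant")
        rep_ <- cls %in% c("P", "LP")
        if (any(rep_)) {
          cat_ <- ifelse(relevant[rep_], "primary", "incidental")
          findings[[length(findings) + 1]] <- data.frame(
            sample = sample_id, kind = "small_cnv",
            event = sprintf("%s(%s:%d-%d)x%d",
                            ifelse(assessed$copy_number[rep_] < 2, "del",
                                   "dup"),
                            assessed$chrom[rep_],
                            as.integer(assessed$start[rep_]),
                            as.integer(assessed$end[rep_]),
                            assessed$copy_number[rep_]),
            gene = NA_character_, class = cls[rep_], category = cat_,
            tier = "intragenic", size_bp = assessed$size_bp[rep_],
            detail = sprintf("score=%.2f", score[rep_]),
            stringsAsFactors = FALSE)
          if (any(cat_ == "primary")) {
            diagnosed_tier <- "intragenic"; stage <- 3L
          }
        }
      }
    }
  }

  structure(list(
    sample = sample_id,
    diagnosed = !is.na(diagnosed_tier),
    stage = stage,
    tier = diagnosed_tier,
    findings = if (length(findings)) {
      do.call(rbind, c(findings, list(make.row.names = FALSE)))
    } else data.frame(sample = character(), kind = character(),
                      event = character(), gene = character(),
                      class = character(), category = character(),
                      tier = character(), size_bp = numeric(),
                      detail = character(), stringsAsFactors = FALSE),
    qc = qc
  ), class = "cns_diagnosis")
}

#' Run the cascade over every sample of a bundle
#'
#' @param bundle A `cohort_bundle`.
#' @param th Thresholds.
#' @param samples Samples to triage (default: all case-arm samples, or all
#'   samples when the bundle has no arm column).
#' @return List: `diagnoses` (one row per sample: sample, diagnosed, stage,
#'   tier), `findings` (all reportable findings), `qc` (named list).
#' @export
triage_cohort <- function(bundle, th = default_thresholds(),
                          samples = NULL) {
  if (is.null(samples)) {
    samples <- if ("arm" %in% names(bundle$samples)) {
      bundle$samples$sample[bundle$samples$arm == "case"]
    } else bundle$samples$sample
  }
  out <- lapply(samples, function(s) {
    suppressWarnings(triage_sample(s, bundle, th))
  })
  diagnoses <- data.frame(
    sample = samples,
    diagnosed = vapply(out, `[[`, logical(1), "diagnosed"),
    stage = vapply(out, `[[`, integer(1), "stage"),
    tier = vapply(out, `[[`, character(1), "tier"),
    stringsAsFactors = FALSE
  )
  findings <- do.call(rbind, c(lapply(out, `[[`, "findings"),
                               list(make.row.names = FALSE)))
  qc <- stats::setNames(lapply(out, `[[`, "qc"), samples)
  list(diagnoses = diagnoses, findings = findings,
       qc = qc[vapply(qc, length, integer(1)) > 0])
}
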
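---
title: "Methods: two-stage WGS triage and singleton-LoF burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage WGS triage and singleton-LoF burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnstriage)
```

## The problem

Structural anomalies of the fetal central nervous system (CNS) are among the
most common findings in prenatal imaging, and their genetic causes span every
variant resolution: whole-chromosome aneuploidies, large copy-number variants
(CNVs), single-nucleotide variants and small indels (SNVs), and intragenic
CNVs of 50 bp to 100 kb that sit below the resolution of chromosomal
microarrays. `cnstriage` implements, as reusable and tested code, a
diagnostic workflow built around two-stage whole-genome sequencing (WGS):

1. **Low-pass screen (~0.5x).** Binned read depth is GC-corrected and
   screened for aneuploidies and CNVs above 100 kb. A sample diagnosed here
   never proceeds further.
2. **Deep-WGS SNV triage (~40x).** Remaining samples have their small
   variants filtered by population frequency and consequence, restricted to
   a phenotype-driven candidate gene list built from HPO-style terms, and
   classified through a deterministic ACMG-style evidence-combining engine.
3. **Small-CNV assessment.** Only when SNV triage is uninformative are
   exon-containing, rare (in-house frequency < 0.01) CNVs of 50 bp - 100 kb
   assessed.

Each reportable variant receives a five-tier class (P / LP / VUS / LB / B)
and a finding category (primary when phenotype-relevant; otherwise
secondary, carrier, or incidental). The reporting layer aggregates primary
findings into diagnostic yields by subgroup and by resolution tier with
cascade (shrinking) denominators, tallies recurrent genes, and summarises
inheritance modes. A companion case-control module tests whether rare
singleton loss-of-function variants (SLoFVs) are enriched in affected
fetuses, using a two-sided Wilcoxon rank-sum comparison of per-sample
counts.

## Coordinate and format conventions

Small variants are 1-based (VCF convention); interval files are read as
0-based half-open BED and converted on input to 1-based closed
`GRanges`. All conversions happen in the I/O layer only. The tab-delimited
variant dialect mirrors VCF columns plus flat annotation columns (GENE,
CSQ, SIFT_CLASS, CADD, MCAP, REVEL, AF_PUBLIC, AF_INHOUSE) so the pipeline
is fully testable with plain-text inputs; VCF 4.x is read through `vcfR`.
A missing population frequency is read as 0 ("absent from the database"),
while missing in-silico scores stay missing and never count as damaging —
the conservative choice, since fabricated support would inflate
classifications.

## Thresholds

All cutoffs live in one object, `default_thresholds()`:

| parameter | default | role |
|---|---|---|
| `maf_diagnostic` | 0.01 | worst-of-databases MAF ceiling for diagnostic SNVs |
| `small_cnv_freq` | 0.01 | in-house frequency bound (strict) for assessable small CNVs |
| `qc_depth`, `qc_alt_depth`, `qc_max_len_bp` | 20, 3, 5 | burden QC (inclusive bounds) |
| `cadd`, `mcap`, `revel` | 20, 0.025, 0.5 | strict lower bounds for damaging missense |
| `cnv_score_pathogenic`, LP band | 0.99, [0.90, 0.99) | CNV score-to-class mapping |
| `z_gain` / `z_loss` | 3.5 | aneuploidy z thresholds |
| `ratio_gain` / `ratio_loss` | 1.25 / 0.75 | copy-ratio effect-size thresholds |
| `dispersion_cap` | 0.25 | MAD gate flagging failed CNV calling |

The MAF filter uses the *maximum* of the public and in-house frequencies:
"common in either database" excludes a variant, the stricter of the two
readings of an "and"-worded filter and the one consistent with clinical
practice. MAF exactly 0.01 is retained (only "> 0.01" is filtered).
Canonical splice-site changes carry their own consequence label and
survive the intron filter; deeper intronic positions do not.

## Low-pass screen

**GC correction.** Expected depth as a function of GC is a rolling-median
regression over GC deciles of the autosomal bins: per-decile medians at the
decile GC medians, interpolated smoothly (an `fmm` cubic spline, which
extrapolates into the short GC tails rather than clamping them flat).
Ratios are rescaled so the autosomal median is exactly 1 (to 1e-6). Because
band medians are used, the correction is robust to a trisomic chromosome in
the fit set, and on a noiseless profile whose counts follow a smooth GC
curve it removes more than 99% of the induced spread. Profiles need at
least 50 autosomal bins.

**Aneuploidy calling.** Per chromosome, the median corrected ratio is
compared to its baseline (1 for autosomes; X/Y baselines from the inferred
sex, with sex inferred from the Y signal) via a z-score using the
within-chromosome robust standard error. A call requires *both* `|z|`
beyond 3.5 *and* a copy-ratio effect beyond 1.25/0.75. The effect-size
guard is deliberate: with ~24-125 bins per chromosome, a pure z rule at
3.5 would admit rare euploid false calls across many simulated samples,
while a euploid chromosome essentially never reaches a median ratio of
1.25. Implied copy numbers more than 0.3 away from an integer are flagged
`possible_mosaic` and excluded from full-event calls, which is how an
intermediate sex-chromosome state (e.g. a mosaic XXY signal) is reported.

**Segmentation.** Bins whose ratio (relative to the chromosome baseline)
deviates beyond 1.25/0.75 are merged into runs, bridging up to one quiet
bin; segments shorter than `min_size` (default 100 kb) or with aggregate
`|z| < 4` are discarded, and copy number is `round(2 * mean ratio)`. The
size-tier rule is a partition: > 5 Mb chromosomal; 100 kb - 5 Mb inclusive
submicroscopic; 50 bp up to (excluding) 100 kb intragenic. The boundary
convention (closed middle band) is a package decision; both boundaries are
regression-tested exactly.

**QC gate.** Profiles whose autosomal ratio MAD exceeds `dispersion_cap`
are flagged "CNV calling failed" and skip the depth stage — a defined
stand-in for the read-depth-turbulence failures the workflow must tolerate;
SNV triage still runs for such samples.

## ACMG-style classification

`classify_variant()` is a reduced, fully deterministic implementation of
the published evidence-combining rules over curated tags (PVS1, PS1-4,
PM1-6, PP1-5, BA1, BS1-4, BP1-7). Pathogenic requires e.g. PVS1 plus one
moderate and one supporting, or two strong; likely pathogenic e.g. PVS1
plus one moderate; benign-side rules mirror the published table; a conflict
between fired pathogenic- and benign-side rules yields VUS, as does an
empty tag set. Tags are curated inputs — automated evidence generation
(literature, segregation) is out of scope because that judgment was made by
a clinical review panel in the workflow this package models. CNV
classification consumes a nonnegative evidence-point score: >= 0.99 P,
[0.90, 0.99) LP, then VUS / LB / B at 0.50 / 0.10. (This package keeps the
score nonnegative with benign classes at the low end, rather than the
signed ClinGen scale; a score of 0 means "no pathogenic evidence at all"
and maps to the benign side.)

The candidate gene list is the union of genes annotated to each phenotype
term *or to any descendant term* — standard annotation-propagation
semantics, so adding a term can never shrink the list, and a diagnosed
sample can never become undiagnosed when the phenotype description is
enriched.

## Burden analysis

High-quality variants (depth >= 20, alt depth >= 3, allele length <= 5 bp,
with length = `max(nchar(ref), nchar(alt))` — the package's definition of
"variant <= 5 bp") are flagged as singletons when their allele is carried
by exactly one sample of the counting population. By default occurrences
are counted over the combined case + control table, which keeps the two
arms' counts comparable; counting within cases only is available as a
switch. Deleterious kinds: loss-of-function (nonsense, frameshift,
canonical splice, stop-loss) and damaging missense (SIFT damaging *and*
CADD > 20 *and* M-CAP > 0.025 *and* REVEL > 0.5, all strict). Counts are
accumulated per sample in nested public-MAF strata {0, <= 0.001, <= 0.01}
(the in-house database is excluded from stratification because it defines
the control arm and would be circular); nesting makes per-sample counts
monotone across strata by construction, and this is property-tested.

`wilcoxon_two_sided()` uses midranks; the p-value is exact (tie-free
rank-sum distribution) when `min(n, m) <= 12` without ties, otherwise a
normal approximation with tie-corrected variance and continuity
correction, clamped to (0, 1]. The exact path is verified against
exhaustive enumeration of all rank allocations for `min(n, m) <= 7`, and
the approximate path against the standard implementation on tied data.

## The synthetic cohort generator

The generator defines the conditions under which every stochastic claim is
tested. It emulates:

* a reduced 24-chromosome genome (default 1/20 of human lengths) with a
  smooth per-bin GC track, so full cohorts simulate in about a second;
* low-pass depth: negative-binomial counts (variance mu + 0.01 mu^2, i.e.
  ~11% CV at the default 500 reads per 100-kb bin, matching ~0.5x coverage
  with 100-bp reads) whose mean scales linearly with local copy number and
  with a quadratic GC-bias bump — the simplest model exhibiting the
  artifact GC correction must remove;
* background small variants at 88 per sample: 30% drawn from a pool of
  3000 shared polymorphic sites (the non-singletons), the rest private,
  with a frequency spectrum concentrated near zero (60% exactly 0, the
  remainder Beta(0.3, 60)) so all three MAF strata are populated, and a
  consequence mix with 20% loss-of-function mass;
* spiked pathogenic events (aneuploidies, CNVs >= 100 kb, diagnostic SNVs
  with curated evidence tags, exon-overlapping intragenic CNVs), each
  recorded in a truth table and materialised in the emitted data;
* a case-only excess of cohort-unique LoF variants, Poisson with mean
  `slofv_case_excess` (default 4.5), placed in a reserved coordinate
  residue class so each is a singleton by construction and passes QC.

The background rate and excess were calibrated once so that simulated
control and case medians of singleton LoF variants at MAF <= 0.001 sit at
approximately 9 and 13.5 — the medians the analysis is meant to
discriminate — and are not revisited. With the excess at 0, cases and
controls are exchangeable by construction, which grounds the null
calibration study.

Reproducibility: one global seed; every sample draws from its own derived
stream, so a sample's data are identical whether it is simulated in a
cohort of 2 or 200 (tested).

What the generator does *not* emulate: read-level data, linkage and allele
correlation structure, trio inheritance, mosaicism fractions, segmental
duplication artifacts, or a realistic site-frequency spectrum. Passing
tests therefore demonstrate the correctness and calibration of the
*methods* under a controlled model, not the diagnostic yield to be expected
on real cohorts.

## Replication study sizes

The replicated studies in the test-suite and acceptance script use: 50
simulation seeds for detector power/specificity (one trisomy + one
monosomy + one euploid profile and two CNVs >= 1 Mb per seed); 500
exchangeable cohorts of 60 cases / 80 controls for the null calibration of
the burden test (the test's level does not depend on the study's exact arm
sizes, so a smaller cohort is used for the replicated level study); and 100
cohorts at the full 136 / 200 scale for power, where the test is expected
to reach p < 1e-6 in at least 95% of runs. A CNV counts as detected when
called segments of the right direction cover at least half of the spiked
interval.

## The packaged fixture

`load_paper_fixture()` ships a plain-text re-encoding of a published
cohort's summary tables: 162 case samples (114 CNS-only, 48 CNS+other,
81:81 chromosomal sex, 136 deep-sequenced), the per-event table of 18
aneuploid patients, 21 diagnostic CNVs and 3 intragenic CNVs, the 26
diagnostic SNVs with curated ACMG evidence tags that reproduce each printed
class through `classify_variant()`, and a gene-to-inheritance-mode table.
Two accountings coexist in the source and are both stored: patient-level
(18 + 17 + 3 + 24 = 62 diagnosed) and event-level (21 CNVs, 26 SNVs, since
four patients carry two CNVs and two patients carry two SNVs). The key-gene
tally (29 distinct genes, 5 recurrent) requires critical genes for the
syndromic CNV regions; three are established in the source tables (KAT6A,
NF1, TM4SF20) and seven more are curated from the clinical literature of
the named syndromes (PAFAH1B1, YWHAE, MNX1, ZIC2, HDAC4, DLL1, ACTB) — the
fixture metadata flags this curation as synthetic. The inheritance split
(70% AD / 15% AR / 15% X-linked) is computed over the 20 mode-annotated
diagnostic-SNV genes, the only set for which the source prints disease and
inheritance annotations (and the only set from which those integer
percentages can arise). Individual-level subgroup/sex/phenotype assignments
beyond named patients are synthetic curation satisfying every published
marginal total. A checksum manifest guards the fixture against silent
edits.

## Worked example

```{r example}
rep <- fixture_report()
rep$yield
rep$tiers
rep$inheritance

cfg <- sim_config(n_cases = 20, n_controls = 20, seed = 1,
                  make_depth = FALSE)
res <- count_burden(generate_cohort(cfg))
burden_test(res, kind = "lof", stratum = 0.001)
```

## Known limitations

* Balanced rearrangements, triploidy, and mosaic-fraction estimation are
  out of scope (the screen only flags non-integer sex-chromosome states).
* Evidence tags and CNV evidence points are curated inputs; the engine
  combines but does not generate evidence.
* The dispersion QC gate is a defined stand-in for an unspecified
  real-world failure mode; its cap is configurable.
* The Beta-like background frequency spectrum is a modelling convenience,
  not an inference about any real population database.
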
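# Generates the plain-text fixture under inst/extdata/fixture/.
# Run from the repository root: Rscript tools/make_fixture.R
# The fixture re-encodes the published cohort tables; individual-level
# subgroup/sex/phenotype assignment beyond named patients is synthetic.

dir.create("inst/extdata/fixture", recursive = TRUE, showWarnings = FALSE)
out <- function(x) file.path("inst/extdata/fixture", x)

## ---- Table 1: aneuploidies, CNVs, intragenic CNVs ------------------------

aneu <- function(ids, chrom, cn, event, syndrome) {
  data.frame(sample = paste0("P", ids), kind = "aneuploidy", event = event,
             chrom = chrom, start = NA, end = NA, copy_number = cn,
             size_bp = NA, syndrome = syndrome, class = "P",
             critical_genes = "", stringsAsFactors = FALSE)
}
cnv <- function(id, event, chrom, start, end, cn, syndrome, class = "P",
                crit = "") {
  data.frame(sample = paste0("P", id), kind = NA, event = event,
             chrom = as.character(chrom), start = start, end = end,
             copy_number = cn, size_bp = end - start + 1,
             syndrome = syndrome, class = class, critical_genes = crit,
             stringsAsFactors = FALSE)
}

cnv_events <- rbind(
  aneu(c(79, 102, 240, 103, 350, 482), "18", 3, "+18", "Trisomy 18"),
  aneu(c(155, 351, 438, 871, 747, 901), "13", 3, "+13", "Trisomy 13"),
  aneu(c(827, 1008, 1142, 1506), "21", 3, "+21", "Trisomy 21"),
  aneu(c(112, 772), "X", 1, "45,X", "Turner syndrome"),
  cnv(938, "del(1p36.2p36.3).seq(823534-15632453)x1", 1, 823534, 15632453, 1,
      "1p36 deletion syndrome"),
  cnv(864, "dup(2q36.3q37.3).seq(226537458-242997727)x3", 2, 226537458,
      242997727, 3, "2q36.3q37.3 duplication", crit = "HDAC4"),
  cnv(864, "del(6q26q27).seq(161507517-170879606)x1", 6, 161507517,
      170879606, 1, "Terminal 6q deletions"),
  cnv(470, "del(3q12.1q21.2).seq(99540858-125130561)x1", 3, 99540858,
      125130561, 1, "3q13.31 deletion syndrome region"),
  cnv(244, "del(4q31.3q32.1).seq(153436540-160087839)x1", 4, 153436540,
      160087839, 1, ""),
  cnv(186, "dup(5p14.3p15.3).seq(10429-23273021)x3", 5, 10429, 23273021, 3,
      ""),
  cnv(186, "del(18p11.3p11.3).seq(111935-4272634)x1", 18, 111935, 4272634, 1,
      ""),
  cnv(116, "del(6q25.3q27).seq(160630268-170879606)x1", 6, 160630268,
      170879606, 1, "Terminal 6q deletions", crit = "DLL1"),
  cnv(456, "dup(7p22.1).seq(5029498-6809995)x3", 7, 5029498, 6809995, 3,
      "7p22.1 microduplication syndrome", crit = "ACTB"),
  cnv(190, "del(7q35q36.3).seq(149299056-159068966)x1", 7, 149299056,
      159068966, 1, "Currarino syndrome", crit = "MNX1"),
  cnv(238, "del(7q33q36.3).seq(137529688-159068966)x1", 7, 137529688,
      159068966, 1, ""),
  cnv(422, "del(7q35q36.1).seq(145049787-159068966)x1", 7, 145049787,
      159068966, 1, ""),
  cnv(422, "dup(19q13.42q13.43).seq(55330867-59044235)x3", 19, 55330867,
      59044235, 3, ""),
  cnv(653, "del(8p11.21).seq(41835654-41836946)x1", 8, 41835654, 41836946, 1,
      "KAT6A exon 6", crit = "KAT6A"),
  cnv(532, "dup(9p24.1p24.3).seq(10001-6476812)x3", 9, 10001, 6476812, 3, ""),
  cnv(664, "del(13q22.1q34).seq(74369596-115054392)x1", 13, 74369596,
      115054392, 1, "13q deletion syndrome", crit = "ZIC2"),
  cnv(931, "dup(13q31.2q34).seq(89863557-115054392)x3", 13, 89863557,
      115054392, 3, "Partial 13q trisomy"),
  cnv(931, "del(20p13).seq(60001-2226344)x1", 20, 60001, 2226344, 1,
      "20p13 microdeletion syndrome"),
  cnv(796, "del(17p13.2p13.3).seq(1081133-4774754)x1", 17, 1081133, 4774754,
      1, "17p13.3 deletion syndrome", crit = "PAFAH1B1"),
  cnv(882, "dup(17p13.3).seq(1150479-1592862)x3", 17, 1150479, 1592862, 3,
      "17p13.3 microduplication syndrome", crit = "YWHAE"),
  cnv(884, "del(17q11.2).seq(29447084-29503935)x1", 17, 29447084, 29503935,
      1, "NF1 microdeletion syndrome, NF1 exon 2-5", crit = "NF1"),
  # cytoband printed as 17q11.2 in the source table; coordinates (and
  # TM4SF20) are on chromosome 2
  cnv(954, "del(17q11.2).seq(228230706-228234866)x1", 2, 228230706,
      228234866, 1, "TM4SF20 exon 3", class = "LP", crit = "TM4SF20"),
  cnv(810, "del(18p11.2p11.3).seq(111935-15323954)x1", 18, 111935, 15323954,
      1, ""),
  cnv(1004, "del(18p11.2p11.3).seq(111935-15334797)x1", 18, 111935, 15334797,
      1, "")
)
is_cnv <- is.na(cnv_events$kind)
cnv_events$kind[is_cnv] <-
  ifelse(cnv_events$size_bp[is_cnv] < 100e3, "small_cnv", "cnv")
stopifnot(sum(cnv_events$kind == "aneuploidy") == 18,
          sum(cnv_events$kind == "cnv") == 21,
          sum(cnv_events$kind == "small_cnv") == 3)
write.table(cnv_events, out("cnv_events.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## ---- Table 2: diagnostic SNVs --------------------------------------------

snv <- function(id, gene, hgvs_c, hgvs_p, zyg, class, disease, mode, csq,
                tags) {
  data.frame(sample = paste0("P", id), gene = gene, hgvs_c = hgvs_c,
             hgvs_p = hgvs_p, zygosity = zyg, class = class,
             disease = disease, inheritance = mode, consequence = csq,
             evidence_tags = tags, stringsAsFactors = FALSE)
}
fsP <- "PVS1,PM2,PP4"; fsLP <- "PVS1,PM2"
msLP1 <- "PM1,PM2,PP3,PP4"; msLP2 <- "PM2,PM3,PP3,PP4"
msLP3 <- "PM1,PM2,PP2,PP3"; msP <- "PS1,PM1,PM2,PM5"

snv_events <- rbind(
  snv(49, "KAT6B", "c.3747delA", "p.Gly1251Glufs*21", "het", "P",
      "Genitopatellar syndrome", "AD", "frameshift", fsP),
  snv(432, "STIL", "c.3835C>T", "p.Arg1279Cys", "het", "LP",
      "Microcephaly 7, primary", "AR", "missense", msLP1),
  snv(432, "STIL", "c.2344_2347delTTGC", "p.Leu782Thrfs*2", "het", "P",
      "Microcephaly 7, primary", "AR", "frameshift", fsP),
  snv(211, "CC2D2A", "c.3829T>C", "p.Cys1277Arg", "het", "LP",
      "Joubert syndrome 9", "AR", "missense", msLP2),
  snv(211, "CC2D2A", "c.3874G>T", "p.Asp1292Tyr", "het", "LP",
      "Joubert syndrome 9", "AR", "missense", msLP2),
  snv(234, "KAT6B", "c.3660dup", "p.Arg1221*fs*1", "het", "P",
      "Genitopatellar syndrome", "AD", "frameshift", fsP),
  snv(246, "TUBA1A", "c.748G>T", "p.Val250Phe", "het", "LP",
      "Lissencephaly 3", "AD", "missense", msLP3),
  snv(273, "GJC2", "c.1125_1135delCGGCCTCCCTG", "p.Ala379Glyfs*109", "het",
      "LP", "Lymphatic malformation 3", "AD", "frameshift", fsLP),
  snv(348, "DNM1L", "c.345_346delAG", "p.Glu116Lysfs*6", "het", "LP",
      "Encephalopathy", "AD", "frameshift", fsLP),
  snv(357, "FGFR3", "c.1948A>G", "p.Lys650Glu", "het", "P",
      "Thanatophoric dysplasia", "AD", "missense", msP),
  snv(431, "TUBA1A", "c.614A>T", "p.Asp205Val", "het", "LP",
      "Lissencephaly 3", "AD", "missense", msLP3),
  snv(464, "PDHA1", "c.923_929delAGGAAGT", "p.Ser312Valfs*1", "het", "LP",
      "Pyruvate dehydrogenase E1-alpha deficiency", "XLD", "frameshift",
      fsLP),
  snv(479, "GLI2", "c.94dup", "p.Ala32Glyfs*34", "het", "LP",
      "Culler-Jones syndrome; Holoprosencephaly 9", "AD", "frameshift",
      fsLP),
  snv(558, "PTPN11", "c.1403C>T", "p.Thr468Met", "het", "P",
      "Noonan syndrome 1", "AD", "missense", msP),
  snv(627, "NSD1", "c.5177C>T", "p.Pro1726Leu", "het", "LP",
      "Sotos syndrome", "AD", "missense", msLP3),
  snv(648, "FOXG1", "c.171_180delCCCGCCGCCG", "p.Pro60Argfs*129", "het",
      "LP", "Rett syndrome, congenital variant", "AD", "frameshift", fsLP),
  snv(730, "FANCC", "c.1330-1G>A", "", "hom", "LP",
      "Fanconi anemia, complementation group C", "AR", "canonical_splice",
      fsLP),
  snv(733, "SIX3", "c.339G>A", "p.Trp113Stop", "het", "P",
      "Holoprosencephaly 2", "AD", "nonsense", fsP),
  snv(836, "SOX2", "c.480C>G", "p.Tyr160Stop", "het", "P",
      "Optic nerve hypoplasia and abnormalities of CNS", "AD", "nonsense",
      fsP),
  snv(903, "OFD1", "c.1103_1106delTGAT", "p.Ile369Lysfs*18", "het", "LP",
      "Orofaciodigital syndrome I", "XLD", "frameshift", fsLP),
  snv(924, "ARX", "c.1074-1G>A", "", "het", "LP", "Lissencephaly", "XL",
      "canonical_splice", fsLP),
  snv(2942, "NID1", "c.1786C>T", "p.Arg596*", "het", "LP",
      "Dandy-Walker malformation", "AD", "nonsense", fsLP),
  snv(993, "PDHA1", "c.933_936delAAGT", "p.Ser312Argfs*13", "het", "P",
      "Pyruvate dehydrogenase E1-alpha deficiency", "XLD", "frameshift",
      fsP),
  snv(1278, "CC2D2A", "c.4333C>T", "p.Arg1445*", "hom", "P",
      "Meckel syndrome 6", "AR", "nonsense", fsP),
  snv(222, "PTCH1", "c.2757_2758delCT", "p.Phe919Leufs*39", "het", "LP",
      "Basal cell nevus syndrome", "AD", "frameshift", fsLP),
  snv(114, "NF1", "c.1742dup", "p.Leu581Phefs*6", "het", "P",
      "Neurofibromatosis, type I", "AD", "frameshift", fsP)
)
stopifnot(nrow(snv_events) == 26,
          length(unique(snv_events$sample)) == 24,
          length(unique(snv_events$gene)) == 20)
write.table(snv_events, out("snv_events.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## ---- gene -> inheritance mode table (Fig. 2b-style, 20 annotated genes) --

gm <- unique(snv_events[, c("gene", "inheritance")])
stopifnot(nrow(gm) == 20)
names(gm) <- c("gene", "mode")
stopifnot(sum(gm$mode == "AD") == 14, sum(gm$mode == "AR") == 3,
          sum(gm$mode %in% c("XL", "XLD")) == 3)
write.table(gm[order(gm$gene), ], out("gene_modes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- sample table ---------------------------------------------------------

tier_of <- function(s) {
  ev <- cnv_events[cnv_events$sample == s, ]
  sv <- snv_events[snv_events$sample == s, ]
  if (nrow(ev) && any(ev$kind == "aneuploidy")) return("chromosomal")
  if (nrow(ev) && any(ev$kind == "cnv")) {
    big <- max(ev$size_bp[ev$kind == "cnv"])
    return(if (big > 5e6) "chromosomal" else "submicroscopic")
  }
  if (nrow(sv)) return("snv")
  if (nrow(ev)) return("intragenic")
  NA_character_
}
diagnosed <- unique(c(cnv_events$sample, snv_events$sample))
stopifnot(length(diagnosed) == 62)
tiers <- vapply(diagnosed, tier_of, character(1))
stopifnot(sum(tiers == "chromosomal") == 32,
          sum(tiers == "submicroscopic") == 3,
          sum(tiers == "snv") == 24, sum(tiers == "intragenic") == 3)

named_undx <- paste0("P", c(1133, 135, 382, 175, 866, 37, 221))
synth <- sprintf("S%03d", 1:93)
all_ids <- c(diagnosed, named_undx, synth)
stopifnot(length(all_ids) == 162)

# subgroup: CNS+other = 21 chromosomal + 1 submicroscopic + 12 SNV +
# 14 undiagnosed = 48; everyone else CNS-only (114)
cns_other <- c(
  paste0("P", c(79, 102, 240, 103, 350, 482,          # T18
                155, 351, 438, 871, 747, 901,         # T13
                827, 1008, 1142, 1506,                # T21
                112,                                  # 45,X
                938, 864, 186, 244,                   # large CNVs (21 total)
                882,                                  # submicroscopic (1)
                49, 234, 357, 558, 627, 273, 348, 464, 903, 730, 1278,
                222,                                  # SNV (12)
                1133, 37)),                           # undiagnosed named
  sprintf("S%03d", 1:12)                              # undiagnosed synthetic
)
stopifnot(length(cns_other) == 48, all(cns_other %in% all_ids))
subgroup <- ifelse(all_ids %in% cns_other, "cns_plus_other", "cns_only")

# chromosomal sex: constrained patients first, then alternate to 81/81
sex <- setNames(rep(NA_character_, length(all_ids)), all_ids)
sex[c("P112", "P772", "P464", "P993", "P903", "P924")] <- "female"
sex["P1133"] <- "male"  # mosaic 47,XXY
free <- names(sex)[is.na(sex)]
n_f_needed <- 81 - sum(sex == "female", na.rm = TRUE)
sex[free[seq_len(n_f_needed)]] <- "female"
sex[is.na(sex)] <- "male"
stopifnot(sum(sex == "female") == 81, sum(sex == "male") == 81)

# two-stage sequencing: 26 cases were low-pass only (a subset of the
# stage-1-diagnosed); the remaining 136 carry deep WGS data
lowpass_only <- paste0("P", c(79, 102, 240, 103, 350, 482, 155, 351, 438,
                              871, 747, 901, 827, 1008, 1142, 1506, 112, 772,
                              938, 864, 186, 244, 470, 116, 190, 238))
stopifnot(length(lowpass_only) == 26,
          all(tiers[lowpass_only] == "chromosomal"))
deep <- !(all_ids %in% lowpass_only)
stopifnot(sum(deep) == 136)

cnv_fail <- sprintf("S%03d", 90:92)          # read-depth turbulence QC gate
small_cnv_fail <- sprintf("S%03d", 86:89)    # small-CNV QC failures

# phenotype labels (11 anomaly classes); NTD and hydrocephalus are the
# largest groups (34 each); assignment beyond named patients is synthetic
pheno <- setNames(rep(NA_character_, length(all_ids)), all_ids)
ntd_dx <- c("P79", "P422", "P244", "P1278")
pheno[ntd_dx] <- "ntd"
pheno[c("P135", "P382", "P175", "P866")] <- "ntd"
pheno["P37"] <- "ntd;microcephaly"
pheno["P1133"] <- "chiari_ii"
pheno[c("P114")] <- "hydrocephalus"
pheno[c("P954", "P884")] <- "ventriculomegaly"
pheno[c("P733", "P836", "P479")] <- "holoprosencephaly"
pheno[c("P246", "P431", "P796", "P924")] <- "cerebellar_hypoplasia"
pheno["P2942"] <- "dandy_walker"
pheno[c("P432", "P211")] <- "microcephaly"
labels <- c("ntd", "hydrocephalus", "ventriculomegaly", "acc",
            "holoprosencephaly", "cerebellar_hypoplasia", "dandy_walker",
            "microcephaly", "arachnoid_cyst", "destructive_lesion",
            "abnormal_echo")
# fill NTDs to 34 from synthetic undiagnosed, then cycle the rest
need_ntd <- 34 - sum(grepl("ntd", pheno), na.rm = TRUE)
fill <- names(pheno)[is.na(pheno)]
pheno[fill[seq_len(need_ntd)]] <- "ntd"
fill <- names(pheno)[is.na(pheno)]
pheno[fill] <- rep(setdiff(labels, "ntd"), length.out = length(fill))

samples <- data.frame(
  sample = all_ids,
  arm = "case",
  sex = unname(sex[all_ids]),
  subgroup = subgroup,
  deep_wgs = as.integer(deep),
  cnv_call_failed = as.integer(all_ids %in% cnv_fail),
  small_cnv_qc_failed = as.integer(all_ids %in% small_cnv_fail),
  phenotypes = unname(pheno[all_ids]),
  stringsAsFactors = FALSE
)
write.table(samples, out("samples.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## ---- low-pass extras (non-diagnostic call) -------------------------------

extras <- data.frame(
  sample = "P1133", kind = "aneuploidy_mosaic", event = "possible mosaic 47,XXY",
  chrom = "X", class = "VUS", category = "none",
  note = "no established link to the imaging phenotype",
  stringsAsFactors = FALSE
)
write.table(extras, out("lowpass_extras.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## ---- metadata -------------------------------------------------------------

meta <- c(
  n_samples = 162, n_cns_only = 114, n_cns_plus_other = 48,
  n_male = 81, n_female = 81,
  n_deep_wgs = 136, n_lowpass_only = 26,
  n_diagnosed = 62,
  n_aneuploid_patients = 18, n_cnv_patients = 17,
  n_small_cnv_patients = 3, n_snv_patients = 24,
  n_cnv_events_gt100kb = 21, n_snv_variants = 26,
  n_aneuploids_called_lowpass = 19, n_cnvs_called_lowpass = 342,
  n_cnv_call_failed = 3, n_small_cnv_qc_failed = 4,
  n_carrier_incidental_secondary = 8,
  note_accounting = paste(
    "patient-level accounting: 18 aneuploid + 17 CNV + 3 small-CNV + 24 SNV",
    "patients = 62 diagnosed; event-level accounting: 21 CNVs > 100 kb and",
    "26 diagnostic SNVs (four patients carry two CNVs; two patients carry",
    "two SNVs; both accountings stored, neither resolved away)"),
  note_curation = paste(
    "synthetic curation: subgroup/sex/phenotype assignment beyond named",
    "patients, and critical genes for seven syndromic CNV regions",
    "(PAFAH1B1, YWHAE, MNX1, ZIC2, HDAC4, DLL1, ACTB)")
)
write.table(data.frame(key = names(meta), value = unname(meta)),
            out("meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

## ---- manifest -------------------------------------------------------------

files <- c("cnv_events.tsv", "snv_events.tsv", "gene_modes.tsv",
           "samples.tsv", "lowpass_extras.tsv", "meta.tsv")
md5 <- tools::md5sum(file.path("inst/extdata/fixture", files))
writeLines(paste(unname(md5), files), out("MANIFEST"))
cat("fixture written:", sum(file.size(out(c(files, "MANIFEST")))), "bytes\n")
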
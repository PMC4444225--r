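#' Packaged worked-example fixtures
#'
#' [build_fixtures()] writes a self-contained set of small plain-text
#' fixtures that exercise the whole pipeline: the 163-gene clinical panel
#' (135 dominant, 24 recessive, 4 X-linked genes; cancer-associated genes
#' flagged; the recurrent *GEN1* frameshift artifact pre-excluded), variant
#' tables encoding the published per-patient LoF findings in the
#' carrier and non-carrier cohorts, cohort manifests for the 88 + 88
#' *BRCA1*/*BRCA2*-carrier samples and the 82 non-carrier samples, and the
#' clinical-mutation call set reproducing the detection accounting (75 of 88
#' *BRCA1* diagnoses expected detectable, 8 of them recovered only at low
#' quality; all 88 *BRCA2* diagnoses expected, 10 at low quality; 16 of the
#' 18 low-quality recoveries are indels).
#'
#' Gene symbols, inheritance modes, cancer flags, patient/gene/consequence
#' assignments and the detection accounting follow the published tables;
#' coding lengths, genomic coordinates, alleles and quality values are
#' deterministic synthetic placeholders (the underlying genomes are
#' access-controlled), which is sufficient for every statistic the package
#' computes from these fixtures.
#'
#' @name fixtures
NULL

panel_163_genes <- function() {
  dominant <- c(
    "ACTA2", "ACTC1", "ACVRL1", "APC", "APOB", "ATM", "ATR", "BAP1",
    "BARD1", "BMPR1A", "BRCA1", "BRCA2", "BRIP1", "CACNA1C", "CACNA1S",
    "CACNB2", "CDC73", "CDH1", "CDK4", "CDKN1A", "CDKN2A", "CDKN2B",
    "CHEK1", "CHEK2", "CNBP", "COL3A1", "CREBBP", "DMPK", "DSC2", "DSG2",
    "DSP", "EGFR", "ELAC2", "ENG", "EPCAM", "FAM175A", "FBN1", "FH",
    "FLCN", "GALNT12", "GCH1", "GEN1", "GPD1L", "GREM1", "HCN4",
    "HIP1", "HIP1R", "HMBS", "HOXB1", "HOXB13", "HTT", "JAK2", "KCNE1",
    "KCNE2", "KCNE3", "KCNH1", "KCNH2", "KCNJ2", "KCNQ1", "KDR", "KIT",
    "LDLR", "LMNA", "MEN1", "MET", "MITF", "MLH1", "MLH3", "MRE11A",
    "MSH2", "MSH6", "MUTYH", "MYBPC3", "MYH11", "MYH7", "MYL2", "MYL3",
    "MYLK", "NBN", "NF1", "NF2", "NTRK1", "PALB2", "PCSK9", "PDGFRA",
    "PKP2", "PLN", "PMS2", "PRKAG2", "PRKAR1A",
    "PROC", "PROS1", "PRSS1", "PTCH1", "PTEN", "RAD50", "RAD51",
    "RAD51C", "RAD51D", "RAS", "RB1", "RBBP8", "RBM20", "RET", "RYR1",
    "RYR2", "SCN1B", "SCN3B", "SCN5A", "SDHAF2", "SDHB", "SDHC", "SDHD",
    "SERPINC1", "SGCD", "SMAD3", "SMAD4", "SMARCB1", "SMO", "STK11",
    "TGFB3", "TGFBR1", "TGFBR2", "TMEM43", "TNNI3", "TNNT2", "TP53",
    "TP53BP1", "TPM1", "TSC1", "TSC2", "VHL", "WT1", "XRCC2", "XRCC3"
  )
  recessive <- c(
    "ATP7B", "BCHE", "BLM", "CASQ2", "CFTR", "COQ2", "COQ9", "CPT2",
    "F5", "GAA", "HAMP", "HFE", "HFE2", "IDUA", "INPP5B", "LDLRAP1",
    "PAH", "PCBD1", "PTS", "QDPR", "SERPINA1", "SLC25A13", "SLC37A4",
    "SLC7A9"
  )
  x_linked <- c("DMD", "EMD", "GLA", "OTC")
  cancer <- c(
    "APC", "ATM", "ATR", "BAP1", "BARD1", "BMPR1A", "BRCA1", "BRCA2",
    "BRIP1", "CDC73", "CDH1", "CDK4", "CDKN1A", "CDKN2A", "CDKN2B",
    "CHEK1", "CHEK2", "CREBBP", "EGFR", "ELAC2", "EPCAM", "FAM175A",
    "FH", "FLCN", "GALNT12", "GEN1", "GREM1", "HOXB13", "JAK2", "KDR",
    "KIT", "MEN1", "MET", "MITF", "MLH1", "MLH3", "MRE11A", "MSH2",
    "MSH6", "MUTYH", "NBN", "NF1", "NF2", "NTRK1", "PALB2", "PDGFRA",
    "PMS2", "PTCH1", "PTEN", "RAD50", "RAD51", "RAD51C", "RAD51D",
    "RAS", "RB1", "RET", "SDHAF2", "SDHB", "SDHC", "SDHD", "SMAD4",
    "SMARCB1", "SMO", "STK11", "TP53", "TP53BP1", "TSC1", "TSC2", "VHL",
    "WT1", "XRCC2", "XRCC3", "BLM"
  )
  genes <- c(dominant, recessive, x_linked)
  tibble(
    gene = genes,
    inheritance = rep(c("dominant", "recessive", "x_linked"),
                      c(length(dominant), length(recessive), length(x_linked))),
    cancer_associated = genes %in% cancer,
    # synthetic coding lengths (bp): deterministic log-normal placeholders
    coding_length = with_seed(163L, pmax(
      300L, as.integer(round(rlnorm(length(genes), log(2000), 0.7)))
    ))
  )
}

#' @rdname fixtures
#' @return [clinical_gene_panel()] returns the 163-gene panel as a
#'   `gene_panel` with *GEN1* on its exclusion list.
#' @export
clinical_gene_panel <- function() {
  gene_panel(panel_163_genes(), name = "clinical-163",
             excluded_genes = "GEN1")
}

# Synthetic genomic anchor for a gene: deterministic chrom/pos so a variant
# identity is stable across fixture tables.
gene_anchor <- function(gene) {
  h <- vapply(gene, function(g) {
    sum(utf8ToInt(g) * seq_along(utf8ToInt(g))) }, double(1))
  list(chrom = as.character((h %% 22) + 1), pos = as.integer(1e6 + h * 131))
}

lof_fixture_calls <- function(sample_id, gene, consequence, offset = 0L) {
  anchor <- gene_anchor(gene)
  is_fs <- consequence == "frameshift"
  variant_tbl(
    sample_id = sample_id, chrom = anchor$chrom,
    pos = anchor$pos + offset,
    ref = ifelse(is_fs, "CA", "C"), alt = ifelse(is_fs, "C", "T"),
    var_type = ifelse(is_fs, "del", "snv"), genotype = "het",
    qual_a = ifelse(is_fs, 250L, 200L), qual_b = ifelse(is_fs, 250L, 200L),
    consequence = consequence, gene = gene
  )
}

#' @rdname fixtures
#' @return [carrier_lof_findings()] returns the nine published LoF PPVs
#'   found in the carrier cohort as a variant tibble: six patients with
#'   variants in four genes of the 163-gene panel (CHEK2, ATM, RAD50,
#'   CDKN2B) and three further patients with variants in ClinVar genes
#'   outside the panel (ERCC3, DLEC1, FANCC).
#' @export
carrier_lof_findings <- function() {
  lof_fixture_calls(
    sample_id = c("BRCA1.60", "BRCA1.61", "BRCA2.7", "BRCA2.13",
                  "BRCA2.65", "BRCA2.93",
                  "BRCA1.48", "BRCA1.73", "BRCA1.74"),
    gene = c("CHEK2", "ATM", "RAD50", "ATM", "CDKN2B", "CHEK2",
             "ERCC3", "DLEC1", "FANCC"),
    consequence = c("splice_disrupt", "frameshift", "misstart", "nonsense",
                    "nonsense", "nonsense",
                    "nonsense", "splice_disrupt", "nonsense"),
    offset = c(0L, 0L, 0L, 10L, 0L, 10L, 0L, 0L, 0L)
  )
}

#' @rdname fixtures
#' @return [noncarrier_lof_findings()] returns the 19 published LoF PPVs in
#'   cancer-associated genes across 17 distinct non-carrier patients:
#'   12 confirming clinically diagnosed mutations, 3 discovered in the
#'   163-gene panel (PALB2, RAD51C) and 4 discovered in ClinVar genes
#'   (FANCM, ERCC3, FANCA).
#' @export
noncarrier_lof_findings <- function() {
  sample_id <- c(
    "UTSW3", "UTSW12", "UTSW13", "UTSW16", "UTSW31", "UTSW32", "UTSW38",
    "UTSW44", "UTSW53", "UTSW55", "UTSW78", "UTSW78",
    "UTSW9", "UTSW13", "UTSW36",
    "UTSW22", "UTSW51", "UTSW76", "UTSW82"
  )
  gene <- c(
    "TP53", "APC", "FH", "APC", "MSH6", "MSH6", "FH",
    "MSH2", "MSH6", "APC", "ATM", "RAD50",
    "PALB2", "RAD51C", "PALB2",
    "FANCM", "FANCM", "ERCC3", "FANCA"
  )
  consequence <- c(
    "nonsense", "frameshift", "frameshift", "frameshift", "frameshift",
    "nonsense", "frameshift", "nonsense", "frameshift", "frameshift",
    "frameshift", "frameshift",
    "nonsense", "nonsense", "nonsense",
    "nonsense", "nonsense", "nonsense", "nonsense"
  )
  # distinct variants within a gene get distinct offsets; recurrent ones
  # (the FH and FANCM variants) share theirs
  offset <- c(
    0L, 0L, 0L, 10L, 0L, 20L, 0L,
    0L, 30L, 20L, 20L, 10L,
    0L, 0L, 10L,
    0L, 0L, 0L, 0L
  )
  lof_fixture_calls(sample_id, gene, consequence, offset)
}

#' @rdname fixtures
#' @return [carrier_cohort_manifest()] returns the manifest of the 176
#'   carrier samples (cohorts `BRCA1`, `BRCA2`) with each sample's
#'   clinically diagnosed mutation and its detectability category;
#'   [noncarrier_cohort_manifest()] the 82-sample `nonBRCA` manifest.
#' @export
carrier_cohort_manifest <- function() {
  anchor1 <- gene_anchor("BRCA1")
  anchor2 <- gene_anchor("BRCA2")
  mk <- function(cohort, anchor, n, n_not_expected, n_low, n_low_indel,
                 n_high_indel) {
    # sample i's diagnosed mutation gets its own synthetic position
    i <- seq_len(n)
    category <- rep("snv", n)
    detect <- rep("high", n)
    if (n_not_expected > 0) {
      ne <- seq_len(n_not_expected)
      category[ne] <- rep(c("cnv", "ivs"), length.out = n_not_expected)
      detect[ne] <- "not_expected"
    }
    low <- seq(n_not_expected + 1, n_not_expected + n_low)
    detect[low] <- "low"
    category[low] <- c(rep("indel", n_low_indel),
                       rep("snv", n_low - n_low_indel))
    high_indel <- seq(n_not_expected + n_low + 1,
                      n_not_expected + n_low + n_high_indel)
    category[high_indel] <- "indel"
    tibble(
      sample_id = paste0(cohort, ".", i),
      cohort = cohort,
      clin_gene = cohort,
      clin_chrom = anchor$chrom,
      clin_pos = anchor$pos + i * 3L,
      clin_ref = ifelse(category == "indel", "TG", "T"),
      clin_alt = ifelse(category == "indel", "T", "A"),
      clin_category = category,
      detect = detect
    )
  }
  # BRCA1: 88 diagnoses, 13 CNV/IVS (not detectable by short-variant WGS),
  # 8 of the remaining 75 recovered only at low quality (7 indels);
  # BRCA2: 88 diagnoses all expected, 10 low quality (9 indels).
  m <- bind_rows(
    mk("BRCA1", anchor1, 88L, 13L, 8L, 7L, 20L),
    mk("BRCA2", anchor2, 88L, 0L, 10L, 9L, 25L)
  )
  cohort_manifest(m)
}

#' @rdname fixtures
#' @export
noncarrier_cohort_manifest <- function() {
  cohort_manifest(tibble(
    sample_id = paste0("UTSW", 1:82), cohort = "nonBRCA"
  ))
}

#' @rdname fixtures
#' @return [carrier_clinical_calls()] returns the WGS calls at the carrier
#'   samples' diagnosed mutation sites, with quality values encoding the
#'   published accounting: expected-detectable mutations are present, at
#'   high quality except for the low-quality recoveries; CNV/IVS diagnoses
#'   have no corresponding short-variant call.
#' @export
carrier_clinical_calls <- function() {
  m <- carrier_cohort_manifest()
  m <- m[m$expected_detectable %in% TRUE, ]
  is_indel <- m$clin_category == "indel"
  low <- m$detect == "low"
  q <- ifelse(low, ifelse(is_indel, 140L, 80L), ifelse(is_indel, 250L, 200L))
  variant_tbl(
    sample_id = m$sample_id, chrom = m$clin_chrom, pos = m$clin_pos,
    ref = m$clin_ref, alt = m$clin_alt,
    var_type = ifelse(is_indel, "del", "snv"), genotype = "het",
    qual_a = q, qual_b = q,
    consequence = ifelse(is_indel, "frameshift", "nonsense"),
    gene = m$clin_gene
  )
}

#' @rdname fixtures
#' @param dir output directory (created if needed).
#' @return [build_fixtures()] writes the fixture files and returns their
#'   paths invisibly (named list: `panel`, `clinvar_panel`,
#'   `carrier_variants`, `noncarrier_variants`, `manifest_carrier`,
#'   `manifest_noncarrier`, `clinical_calls`).
#' @export
build_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  panel <- panel_163_genes()
  panel$excluded <- panel$gene == "GEN1"
  readr::write_tsv(panel, p("gene_panel_163.tsv"), progress = FALSE)
  # reduced synthetic stand-in for a ClinVar-style gene list: the clinical
  # panel plus the out-of-panel genes of the published findings
  extra <- c("ERCC3", "DLEC1", "FANCC", "FANCM", "FANCA")
  clinvar <- bind_rows(
    panel,
    tibble(gene = extra, inheritance = "dominant", cancer_associated = TRUE,
           coding_length = with_seed(3209L, as.integer(
             round(rlnorm(length(extra), log(2000), 0.7)))),
           excluded = FALSE)
  )
  readr::write_tsv(clinvar, p("gene_panel_clinvar_synthetic.tsv"),
                   progress = FALSE)
  write_variant_table(carrier_lof_findings(), p("carrier_lof_findings.tsv"))
  write_variant_table(noncarrier_lof_findings(),
                      p("noncarrier_lof_findings.tsv"))
  mc <- carrier_cohort_manifest()
  readr::write_tsv(mc[setdiff(names(mc), c("detect", "expected_detectable"))],
                   p("manifest_carrier.tsv"), na = "", progress = FALSE)
  readr::write_tsv(noncarrier_cohort_manifest()[c("sample_id", "cohort")],
                   p("manifest_noncarrier.tsv"), na = "", progress = FALSE)
  write_variant_table(carrier_clinical_calls(), p("clinical_calls_carrier.tsv"))
  invisible(list(
    panel = p("gene_panel_163.tsv"),
    clinvar_panel = p("gene_panel_clinvar_synthetic.tsv"),
    carrier_variants = p("carrier_lof_findings.tsv"),
    noncarrier_variants = p("noncarrier_lof_findings.tsv"),
    manifest_carrier = p("manifest_carrier.tsv"),
    manifest_noncarrier = p("manifest_noncarrier.tsv"),
    clinical_calls = p("clinical_calls_carrier.tsv")
  ))
}
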
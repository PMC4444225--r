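test_that("nonsynonymous and LoF classification follow the class definitions", {
  x <- variant_tbl(
    pos = 1:9 * 10L,
    ref = c(rep("A", 7), "AC", "A"),
    alt = c(rep("T", 7), "A", "ACT"),
    var_type = c(rep("snv", 7), "del", "ins"),
    consequence = c("synonymous", "missense", "nonsense", "splice_disrupt",
                    "misstart", "nonstop", "other", "frameshift",
                    "inframe_indel")
  )
  expect_equal(is_nonsynonymous(x),
               c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(classify_lof(x),
               c("not_lof", "not_lof", "lof_snv", "lof_snv", "lof_snv",
                 "lof_snv", "not_lof", "lof_indel", "not_lof"))
})

test_that("rarity requires every present panel frequency below threshold", {
  x <- variant_tbl(
    pos = 1:4 * 10L,
    freq_esp = c(0.005, 0.005, NA, NA),
    freq_hapmap = c(0.003, 0.02, 0.02, NA)
  )
  expect_equal(is_rare(x), c(TRUE, FALSE, FALSE, TRUE))
  # novel in both panels passes: that is what makes novelty measurable
  expect_true(is_rare(x)[4])
})

test_that("PPV selection nests across modes and matches a brute-force filter", {
  cfg <- sim_config(
    n_genes = 60, n_samples = c(ctrl = 30, case = 30),
    planted_lof = tibble::tibble(
      gene = c("G0004", "G0010"), carrier_fraction = c(0.4, 0.3),
      cohort = "case", var_type = c("snv", "del")
    ),
    seed = 17
  )
  sim <- generate_cohort(cfg)
  panel <- sim_gene_panel(sim$genes)
  qc <- qc_config()

  sets <- lapply(c("all", "lof", "lof_snv"), function(m) {
    select_ppvs(sim$variants, panel, ppv_config(mode = m), qc)
  })
  key <- function(s) paste(s$sample_id, s$chrom, s$pos, s$alt)
  expect_true(all(key(sets[[3]]) %in% key(sets[[2]])))
  expect_true(all(key(sets[[2]]) %in% key(sets[[1]])))

  # independent oracle: plain base-R re-statement of the definition
  v <- sim$variants
  q <- ifelse(v$genotype == "hemi", v$qual_a, pmin(v$qual_a, v$qual_b))
  qpass <- ifelse(v$var_type == "snv", q >= 100, q > 150)
  nonsyn <- v$consequence %in% c("missense", "nonsense", "splice_disrupt",
                                 "misstart", "nonstop", "frameshift",
                                 "inframe_indel")
  rare <- (is.na(v$freq_esp) | v$freq_esp < 0.01) &
    (is.na(v$freq_hapmap) | v$freq_hapmap < 0.01)
  oracle <- v[qpass & nonsyn & rare & v$gene %in% sim$genes$gene, ]
  expect_setequal(key(sets[[1]]), key(oracle))
  lof_oracle <- oracle[
    (oracle$var_type == "snv" &
       oracle$consequence %in% c("nonsense", "splice_disrupt", "misstart",
                                 "nonstop")) |
      oracle$consequence == "frameshift", ]
  expect_setequal(key(sets[[2]]), key(lof_oracle))
})

test_that("PPV selection is idempotent and order-independent", {
  sim <- generate_cohort(sim_config(n_genes = 30,
                                    n_samples = c(ctrl = 15), seed = 23))
  panel <- sim_gene_panel(sim$genes)
  p1 <- select_ppvs(sim$variants, panel, ppv_config(), qc_config())
  p2 <- select_ppvs(p1, panel, ppv_config(), qc_config())
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  shuffled <- sim$variants[withr::with_seed(1, sample(nrow(sim$variants))), ]
  p3 <- select_ppvs(shuffled, panel, ppv_config(), qc_config())
  expect_equal(as.data.frame(p1), as.data.frame(p3))
})

test_that("lowering the frequency threshold never adds PPVs", {
  sim <- generate_cohort(sim_config(n_genes = 40,
                                    n_samples = c(ctrl = 25), seed = 29))
  panel <- sim_gene_panel(sim$genes)
  key <- function(s) paste(s$sample_id, s$chrom, s$pos, s$alt)
  prev <- NULL
  for (t in c(0.05, 0.01, 0.005, 0.001)) {
    s <- select_ppvs(sim$variants, panel, ppv_config(t), qc_config())
    if (!is.null(prev)) expect_true(all(key(s) %in% prev))
    prev <- key(s)
  }
})

test_that("panel exclusion removes genes from PPV selection and empty panels error", {
  x <- variant_tbl(sample_id = c("S1", "S1"), pos = c(10L, 20L),
                   gene = c("GENEA", "GENEB"))
  p <- tiny_panel(excluded = "GENEB")
  got <- select_ppvs(x, p, ppv_config(), qc_config())
  expect_equal(got$gene, "GENEA")
  all_excluded <- tiny_panel(genes = "GENEA", lengths = 100L,
                             excluded = "GENEA")
  expect_error(select_ppvs(x, all_excluded, ppv_config(), qc_config()),
               "empty")
})

test_that("clinical-mutation confirmation distinguishes quality and detectability", {
  manifest <- cohort_manifest(tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"), cohort = "ctrl",
    clin_gene = "BRCA1", clin_chrom = "17", clin_pos = 100L,
    clin_ref = c("T", "TG", "T", "T"), clin_alt = c("A", "T", "A", "A"),
    clin_category = c("snv", "indel", "cnv", "snv")
  ))
  calls <- variant_tbl(
    sample_id = c("S1", "S2"), chrom = "17", pos = 100L,
    ref = c("T", "TG"), alt = c("A", "T"),
    var_type = c("snv", "del"), genotype = "het",
    qual_a = c(120L, 140L), qual_b = c(130L, 140L),
    consequence = c("nonsense", "frameshift"), gene = "BRCA1"
  )
  st <- confirm_clinical_mutation(calls, manifest, qc_config())
  expect_equal(st$status[st$sample_id == "S1"], "detected_high_quality")
  expect_equal(st$status[st$sample_id == "S2"], "detected_low_quality")
  expect_equal(st$status[st$sample_id == "S3"], "not_expected")
  expect_equal(st$status[st$sample_id == "S4"], "not_detected")
})
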
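make_gv <- function(carriers, n_ctrl = 176, gene = "GENEA",
                    threshold = 0.02) {
  manifest <- cohort_manifest(tibble::tibble(
    sample_id = paste0("C", seq_len(n_ctrl)), cohort = "ctrl"
  ))
  ppvs <- if (carriers > 0) {
    variant_tbl(sample_id = paste0("C", seq_len(carriers)), gene = gene)
  } else {
    variant_tbl()[0, ]
  }
  gene_variance(ppvs, manifest, tiny_panel(), ctrl_cfg(threshold))
}

test_that("carrier fractions and the 2% rule follow the arithmetic", {
  gv3 <- make_gv(3)   # 3 of 176 carriers: 1.7%, interpretable
  row <- tidy(gv3)[tidy(gv3)$gene == "GENEA", ]
  expect_equal(row$carrier_fraction, 3 / 176)
  expect_equal(row$carrier_burden, 3 / 176)
  expect_true(row$interpretable)

  gv4 <- make_gv(4)   # 4 of 176: 2.27%, not interpretable
  row4 <- tidy(gv4)[tidy(gv4)$gene == "GENEA", ]
  expect_equal(row4$carrier_fraction, 4 / 176)
  expect_false(row4$interpretable)

  # strictness at the boundary: exactly 2% is not interpretable
  gv_edge <- make_gv(2, n_ctrl = 100)
  expect_false(tidy(gv_edge)$interpretable[tidy(gv_edge)$gene == "GENEA"][1])
})

test_that("genes without PPVs are reported and interpretable", {
  gv <- make_gv(0)
  t <- tidy(gv)
  expect_setequal(t$gene, c("GENEA", "GENEB", "GENEC"))
  expect_true(all(t$carrier_fraction == 0))
  expect_true(all(t$interpretable))
  expect_equal(percent_interpretable(gv), 100)
})

test_that("carriers are counted once however many PPVs they carry", {
  manifest <- two_cohort_manifest(10, 10)
  ppvs <- variant_tbl(sample_id = c("C1", "C1", "C2"),
                      pos = c(10L, 20L, 10L), gene = "GENEA")
  gv <- tidy(gene_variance(ppvs, manifest, tiny_panel(), ctrl_cfg()))
  row <- gv[gv$gene == "GENEA" & gv$cohort == "ctrl", ]
  expect_equal(row$n_carriers, 2L)      # C1 counted once
  expect_equal(row$n_ppvs, 3L)          # but both its PPVs kept in burden
  expect_equal(row$carrier_burden, 0.3)
  expect_true(row$carrier_fraction <= row$carrier_burden)
})

test_that("percent interpretable matches the generator truth with planted artifacts", {
  k <- 3; g <- 40
  planted <- tibble::tibble(
    gene = sprintf("G%04d", 1:k), carrier_fraction = 0.5,
    cohort = "ctrl", var_type = "snv"
  )
  cfg <- sim_config(n_genes = g, missense_rate = 0, planted_lof = planted,
                    n_samples = c(ctrl = 40, case = 20), seed = 37)
  sim <- generate_cohort(cfg)
  panel <- sim_gene_panel(sim$genes)
  ppvs <- select_ppvs(sim$variants, panel, ppv_config(mode = "lof"), qc = NULL)
  gv <- gene_variance(ppvs, sim$manifest, panel, ctrl_cfg())
  expect_equal(percent_interpretable(gv), 100 * (g - k) / g)
})

test_that("interpretability percentage honours gene exclusions", {
  gv <- make_gv(4)   # GENEA not interpretable
  expect_equal(percent_interpretable(gv), 100 * 2 / 3)
  expect_equal(percent_interpretable(gv, exclude_genes = "GENEA"), 100)
})

test_that("coding-size correlation is 1 for proportional counts and ~0 when permuted", {
  lengths <- as.integer(seq(500, 5000, length.out = 10))
  panel <- tiny_panel(genes = paste0("L", 1:10), lengths = lengths)
  counts_exact <- rep(paste0("L", 1:10), times = lengths / 500)
  ppvs <- variant_tbl(sample_id = "S", pos = seq_along(counts_exact) * 10L,
                      gene = counts_exact)
  expect_equal(coding_size_correlation(ppvs, panel), 1.0)

  # permutation baseline: breaking the length link kills the correlation
  r2s <- withr::with_seed(101, vapply(1:100, function(i) {
    perm <- tiny_panel(genes = paste0("L", 1:10), lengths = sample(lengths))
    coding_size_correlation(ppvs, perm)
  }, double(1)))
  expect_lt(mean(r2s), 0.2)

  # degenerate inputs give NA, not zero
  flat <- tiny_panel(genes = paste0("L", 1:10), lengths = rep(1000L, 10))
  expect_true(is.na(coding_size_correlation(ppvs, flat)))
  expect_true(is.na(coding_size_correlation(ppvs[0, ], flat)))
})

test_that("Poisson background gives a strong size correlation", {
  cfg <- sim_config(n_genes = 200, missense_rate = 2.8e-5,
                    n_samples = c(ctrl = 60, case = 40), seed = 41)
  sim <- generate_cohort(cfg)
  panel <- sim_gene_panel(sim$genes)
  ppvs <- select_ppvs(sim$variants, panel, ppv_config(), qc = NULL)
  expect_gt(coding_size_correlation(ppvs, panel), 0.5)
})

test_that("frequency-threshold sweep matches direct computation and is monotone", {
  sim <- generate_cohort(sim_config(n_genes = 50,
                                    n_samples = c(ctrl = 30, case = 20),
                                    seed = 43))
  panel <- sim_gene_panel(sim$genes)
  thresholds <- c(0.001, 0.005, 0.01, 0.05)
  sw <- frequency_threshold_sweep(sim$variants, panel, sim$manifest,
                                  thresholds, cfg = ctrl_cfg())
  expect_equal(sw$frequency_threshold, thresholds)
  expect_true(all(diff(sw$n_ppvs) >= 0))
  direct <- select_ppvs(sim$variants, panel, ppv_config(0.005), qc_config())
  gv <- gene_variance(direct, sim$manifest, panel, ctrl_cfg())
  expect_equal(sw$n_ppvs[2], nrow(direct))
  expect_equal(sw$percent_interpretable[2], percent_interpretable(gv))
})

test_that("restricting the PPV mode never lowers percent interpretable", {
  cfg <- sim_config(
    n_genes = 80, missense_rate = 5e-5,
    planted_lof = tibble::tibble(
      gene = c("G0002", "G0007"), carrier_fraction = c(0.3, 0.1),
      cohort = "ctrl", var_type = c("snv", "del")
    ),
    n_samples = c(ctrl = 50, case = 30), seed = 47
  )
  sim <- generate_cohort(cfg)
  panel <- sim_gene_panel(sim$genes)
  pct <- vapply(c("all", "lof", "lof_snv"), function(m) {
    ppvs <- select_ppvs(sim$variants, panel, ppv_config(mode = m), qc_config())
    percent_interpretable(gene_variance(ppvs, sim$manifest, panel, ctrl_cfg()))
  }, double(1))
  expect_true(pct[["all"]] <= pct[["lof"]])
  expect_true(pct[["lof"]] <= pct[["lof_snv"]])
})
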
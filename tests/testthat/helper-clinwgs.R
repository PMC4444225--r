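# Small in-code fixtures shared across tests.

tiny_panel <- function(genes = c("GENEA", "GENEB", "GENEC"),
                       lengths = c(1000L, 2000L, 3000L),
                       excluded = character()) {
  gene_panel(
    tibble::tibble(
      gene = genes, inheritance = "dominant",
      cancer_associated = FALSE, coding_length = lengths
    ),
    name = "tiny", excluded_genes = excluded
  )
}

two_cohort_manifest <- function(n_ctrl = 10, n_case = 10) {
  cohort_manifest(tibble::tibble(
    sample_id = c(paste0("C", seq_len(n_ctrl)), paste0("T", seq_len(n_case))),
    cohort = rep(c("ctrl", "case"), c(n_ctrl, n_case))
  ))
}

# Variance settings for synthetic two-cohort tests.
ctrl_cfg <- function(threshold = 0.02) {
  variance_config(interpretability_threshold = threshold,
                  control_cohorts = "ctrl", exclude_genes = character())
}

# Constant-quality, constant-error simulation config for replicate tests.
rep_cfg <- function(eps, n_sites = 300, seed = 1, q = 200L) {
  sim_config(
    n_sites = n_sites, seed = seed,
    q_law = function(n) rep(q, n),
    error_rate = function(qq) rep(eps, length(qq))
  )
}
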
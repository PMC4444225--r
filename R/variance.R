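#' Gene-variance configuration
#'
#' Settings for the per-gene carrier analysis and the clinical
#' interpretability call. A gene is "clinically interpretable" when fewer
#' than `interpretability_threshold` (strictly less than 2% by default) of
#' the control cohort's individuals carry a PPV in it: since PPVs are
#' defined at < 1% allele frequency, heterozygous carriers of any single
#' true rare variant are expected in < 2% of individuals, so a gene
#' exceeding that in a control population is dominated by recurrent
#' background calls and would flood reports with false-positive findings.
#'
#' @param interpretability_threshold carrier-fraction cutoff (default 0.02;
#'   strict: a fraction exactly at the threshold is *not* interpretable).
#' @param control_cohorts cohort label(s) pooled as the control population.
#' @param exclude_genes genes dropped from panel-percentage summaries
#'   (default `BRCA1`/`BRCA2`, whose carrier fractions are driven by the
#'   control cohort's own diagnostic mutations, not by background).
#' @return a `variance_config` list.
#' @export
variance_config <- function(interpretability_threshold = 0.02,
                            control_cohorts = c("BRCA1", "BRCA2"),
                            exclude_genes = c("BRCA1", "BRCA2")) {
  if (interpretability_threshold <= 0 || interpretability_threshold >= 1) {
    abort("interpretability_threshold must be in (0, 1)")
  }
  structure(list(
    interpretability_threshold = interpretability_threshold,
    control_cohorts = control_cohorts,
    exclude_genes = exclude_genes
  ), class = "variance_config")
}

#' Per-gene carrier statistics and interpretability across cohorts
#'
#' For every panel gene and cohort, computes the carrier fraction (fraction
#' of the cohort's individuals with at least one PPV in the gene) and the
#' carrier burden (mean PPV count per individual), then calls the gene
#' clinically interpretable iff its carrier fraction in the pooled control
#' cohort(s) is strictly below the threshold. Genes with no PPVs anywhere
#' are included (fraction 0, burden 0, interpretable).
#'
#' @param ppvs a `ppv_tbl` from [select_ppvs()] (one mode).
#' @param manifest cohort manifest covering every sample.
#' @param panel a `gene_panel`; all its non-excluded genes are reported.
#' @param cfg a [variance_config()].
#' @return a `gene_variance` object: tibble with one row per gene x cohort
#'   (`gene`, `cohort`, `n`, `n_carriers`, `n_ppvs`, `carrier_fraction`,
#'   `carrier_burden`, `interpretable`, `mode`), with [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
gene_variance <- function(ppvs, manifest, panel, cfg = variance_config()) {
  stopifnot(inherits(panel, "gene_panel"))
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) abort("empty cohort manifest")
  cohort_sizes <- manifest |> count(.data$cohort, name = "n")
  genes <- panel_genes(panel, drop_excluded = TRUE)
  mode <- attr(ppvs, "mode") %||% "all"
  ppvs <- as_tibble(ppvs) |>
    filter(.data$gene %in% genes) |>
    left_join(manifest[c("sample_id", "cohort")], by = "sample_id")
  per <- ppvs |>
    group_by(.data$gene, .data$cohort) |>
    summarise(
      n_carriers = n_distinct(.data$sample_id),
      n_ppvs = dplyr::n(), .groups = "drop"
    )
  grid <- tidyr::expand_grid(gene = genes, cohort = cohort_sizes$cohort) |>
    left_join(cohort_sizes, by = "cohort") |>
    left_join(per, by = c("gene", "cohort")) |>
    mutate(
      n_carriers = tidyr::replace_na(.data$n_carriers, 0L),
      n_ppvs = tidyr::replace_na(.data$n_ppvs, 0L),
      carrier_fraction = .data$n_carriers / .data$n,
      carrier_burden = .data$n_ppvs / .data$n
    )
  ctrl <- manifest |> filter(.data$cohort %in% cfg$control_cohorts)
  if (nrow(ctrl) == 0) {
    abort(paste0("no samples in control cohort(s): ",
                 paste(cfg$control_cohorts, collapse = ", ")))
  }
  ctrl_stats <- ppvs |>
    semi_join(ctrl, by = "sample_id") |>
    group_by(.data$gene) |>
    summarise(ctrl_carriers = n_distinct(.data$sample_id), .groups = "drop")
  n_ctrl <- nrow(ctrl)
  interp <- tibble(gene = genes) |>
    left_join(ctrl_stats, by = "gene") |>
    mutate(
      ctrl_carriers = tidyr::replace_na(.data$ctrl_carriers, 0L),
      interpretable =
        .data$ctrl_carriers / n_ctrl < cfg$interpretability_threshold
    )
  out <- grid |>
    left_join(interp[c("gene", "interpretable")], by = "gene") |>
    mutate(mode = mode) |>
    arrange(.data$gene, .data$cohort)
  structure(out, class = c("gene_variance", class(out)),
            config = cfg, mode = mode, n_control = n_ctrl,
            panel_name = attr(panel, "name"))
}

#' @export
tidy.gene_variance <- function(x, ...) as_tibble(x)

#' @export
glance.gene_variance <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_genes = n_distinct(x$gene),
    n_cohorts = n_distinct(x$cohort),
    n_control = attr(x, "n_control"),
    percent_interpretable = percent_interpretable(x),
    mode = attr(x, "mode"),
    interpretability_threshold = cfg$interpretability_threshold
  )
}

#' Percentage of clinically interpretable genes
#'
#' Percentage (0-100) of panel genes called interpretable, computed over the
#' analysed genes minus `cfg$exclude_genes`.
#'
#' @param gv a `gene_variance` object.
#' @param exclude_genes genes excluded from the percentage; defaults to the
#'   configuration the object was built with.
#' @return a single percentage.
#' @export
percent_interpretable <- function(gv, exclude_genes = NULL) {
  cfg <- attr(gv, "config")
  exclude_genes <- exclude_genes %||% cfg$exclude_genes
  per_gene <- as_tibble(gv) |>
    distinct(.data$gene, .data$interpretable) |>
    filter(!.data$gene %in% exclude_genes)
  if (nrow(per_gene) == 0) return(NA_real_)
  100 * mean(per_gene$interpretable)
}

#' Correlation of per-gene PPV counts with coding length
#'
#' Squared Pearson correlation between each gene's total PPV count (across
#' all samples) and its coding length. A strong correlation indicates the
#' PPV load tracks the gene's mutational target size rather than any
#' disease signal. Genes with zero PPVs are included at count 0.
#'
#' @param ppvs a variant/PPV tibble with a `gene` column.
#' @param panel a `gene_panel` supplying `coding_length`.
#' @return r-squared, or `NA` when either vector has zero variance or fewer
#'   than three genes are available.
#' @export
coding_size_correlation <- function(ppvs, panel) {
  tab <- as_tibble(panel) |>
    filter(!.data$gene %in% panel_excluded(panel)) |>
    left_join(
      as_tibble(ppvs) |> count(.data$gene, name = "n_ppvs"),
      by = "gene"
    ) |>
    mutate(n_ppvs = tidyr::replace_na(.data$n_ppvs, 0L))
  if (nrow(tab) < 3) return(NA_real_)
  if (stats::sd(tab$n_ppvs) == 0 || stats::sd(tab$coding_length) == 0) {
    return(NA_real_)
  }
  cor(tab$n_ppvs, tab$coding_length)^2
}

#' Sweep alternative rare-variant frequency thresholds
#'
#' Re-runs PPV selection and the gene-variance analysis at each frequency
#' threshold and reports how the PPV load and the percentage of
#' interpretable genes respond. PPV counts are non-decreasing in the
#' threshold (a looser cutoff can only add variants).
#'
#' @param x variant tibble (pre-QC; `qc` is applied inside).
#' @param panel a `gene_panel`.
#' @param manifest cohort manifest.
#' @param thresholds increasing frequency thresholds.
#' @param mode PPV mode, as in [ppv_config()].
#' @param qc a [qc_config()] or `NULL`.
#' @param cfg a [variance_config()].
#' @return tibble: `frequency_threshold`, `n_ppvs`, `mean_ppvs_per_individual`,
#'   `percent_interpretable`.
#' @export
frequency_threshold_sweep <- function(x, panel, manifest, thresholds,
                                      mode = "all", qc = qc_config(),
                                      cfg = variance_config()) {
  thresholds <- sort(thresholds)
  purrr::map(thresholds, function(t) {
    ppvs <- select_ppvs(x, panel, ppv_config(t, mode), qc)
    gv <- gene_variance(ppvs, manifest, panel, cfg)
    tibble(
      frequency_threshold = t,
      n_ppvs = nrow(ppvs),
      mean_ppvs_per_individual = nrow(ppvs) / nrow(as_tibble(manifest)),
      percent_interpretable = percent_interpretable(gv)
    )
  }) |> bind_rows()
}
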
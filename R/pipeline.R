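#' Run the end-to-end interpretation pipeline
#'
#' Orchestrates a full analysis: read and validate inputs, apply the
#' calibrated quality filter, select PPVs under each requested mode, compute
#' per-gene carrier statistics and interpretability, per-individual burden,
#' clinical-mutation confirmation (when the manifest records diagnoses), and
#' write all report tables plus a JSON run summary. Reports are regenerated
#' wholesale on every run; given identical inputs the outputs are
#' byte-identical.
#'
#' @param variants variant tibble, or a path read via
#'   [read_variant_table()].
#' @param panel a `gene_panel` or a TSV path.
#' @param manifest manifest tibble or TSV path.
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @param qc a [qc_config()].
#' @param modes PPV modes to analyse.
#' @param frequency_threshold rare-variant cutoff passed to [ppv_config()].
#' @param var_cfg a [variance_config()].
#' @param dialect variant-table dialect when `variants` is a path.
#' @return (invisibly) a list with `summary` (headline statistics, the JSON
#'   content), `gene_variance` (named list of `gene_variance` objects per
#'   mode), `ppvs` (named list of `ppv_tbl`s), `burden`, `detection`,
#'   `qc_summary`.
#' @export
run_pipeline <- function(variants, panel, manifest, out_dir = NULL,
                         qc = qc_config(), modes = c("all", "lof", "lof_snv"),
                         frequency_threshold = 0.01,
                         var_cfg = variance_config(),
                         dialect = "tsv") {
  if (is.character(variants)) variants <- read_variant_table(variants, dialect)
  if (is.character(panel)) panel <- read_gene_panel(panel)
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  manifest <- cohort_manifest(manifest)
  if (nrow(manifest) == 0) abort("pipeline: empty cohort manifest")
  variants <- as_tibble(variants)

  filtered <- apply_quality_filter(variants, qc)
  ppvs <- purrr::map(setNames(modes, modes), function(m) {
    select_ppvs(filtered$retained, panel,
                ppv_config(frequency_threshold, m), qc = NULL)
  })
  gvs <- purrr::map(ppvs, gene_variance, manifest = manifest, panel = panel,
                    cfg = var_cfg)
  burden <- purrr::map(ppvs, ppv_burden, manifest = manifest)

  detection <- NULL
  if (any(!is.na(manifest$clin_gene))) {
    statuses <- confirm_clinical_mutation(variants, manifest, qc)
    detection <- statuses |>
      group_by(.data$cohort) |>
      dplyr::group_modify(~ detection_rate(.x)) |>
      ungroup()
  }

  summary <- list(
    n_samples = nrow(manifest),
    cohorts = as.list(table(manifest$cohort)),
    qc = list(
      snv_min_quality = qc$snv_min_quality,
      indel_min_quality = qc$indel_min_quality,
      snv_fraction_excluded =
        filtered$summary$fraction_excluded[filtered$summary$var_class == "snv"],
      indel_fraction_excluded =
        filtered$summary$fraction_excluded[filtered$summary$var_class == "indel"]
    ),
    modes = purrr::map(setNames(modes, modes), function(m) {
      g <- glance(ppvs[[m]])
      list(
        n_ppvs = g$n_ppvs,
        n_unique_variants = g$n_unique_variants,
        novel_fraction = g$novel_fraction,
        percent_interpretable = percent_interpretable(gvs[[m]]),
        mean_ppvs_per_individual = purrr::set_names(
          as.list(glance(burden[[m]])$mean_ppvs),
          glance(burden[[m]])$cohort
        )
      )
    }),
    coding_size_r2 = coding_size_correlation(ppvs[[modes[1]]], panel)
  )
  if (!is.null(detection)) {
    summary$detection <- purrr::set_names(
      purrr::map(seq_len(nrow(detection)), function(i) as.list(detection[i, -1])),
      detection$cohort
    )
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (m in modes) {
      readr::write_tsv(tidy(gvs[[m]]),
                       file.path(out_dir, paste0("gene_variance_", m, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(burden_histogram(burden[[m]]),
                       file.path(out_dir, paste0("burden_histogram_", m, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(as_tibble(ppvs[[m]]),
                       file.path(out_dir, paste0("ppvs_", m, ".tsv")),
                       na = "", progress = FALSE)
    }
    readr::write_tsv(filtered$summary, file.path(out_dir, "qc_summary.tsv"),
                     progress = FALSE)
    if (!is.null(detection)) {
      readr::write_tsv(detection, file.path(out_dir, "detection_rates.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(summary = summary, gene_variance = gvs, ppvs = ppvs,
                 burden = burden, detection = detection,
                 qc_summary = filtered$summary))
}
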
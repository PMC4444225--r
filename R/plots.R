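#' Plot a replicate-concordance threshold sweep
#'
#' Concordance and fraction of calls excluded as a function of the quality
#' threshold, the view used to pick the SNV and indel quality cutoffs.
#'
#' @param object a `concordance_sweep` from [sweep_thresholds()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.concordance_sweep <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("concordance", "fraction_excluded"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "quality threshold", y = NULL, colour = NULL,
      title = paste0("Replicate genotype concordance (",
                     object$var_class[1], ")")
    ) +
    ggplot2::theme_minimal()
}

#' Gene-variance plot
#'
#' Per-gene carrier burden (mean PPVs per individual) in the control
#' cohort(s) against the remaining cohort(s). Genes in the shaded band have
#' a control-cohort carrier fraction at or above the interpretability
#' threshold and are not clinically interpretable; one point may represent
#' several genes (in particular the origin collects all genes without PPVs).
#'
#' @param object a `gene_variance` object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.gene_variance <- function(object, ...) {
  cfg <- attr(object, "config")
  x <- as_tibble(object) |>
    mutate(group = if_else(.data$cohort %in% cfg$control_cohorts,
                           "control", "test")) |>
    group_by(.data$gene, .data$group, .data$interpretable) |>
    summarise(
      burden = sum(.data$n_ppvs) / sum(.data$n),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "group", values_from = "burden",
                       values_fill = 0)
  if (!"test" %in% names(x)) x$test <- 0
  ggplot2::ggplot(x, ggplot2::aes(x = .data$control, y = .data$test,
                                  colour = .data$interpretable)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "grey30", `FALSE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "carrier burden, control cohort (PPVs per individual)",
      y = "carrier burden, test cohort (PPVs per individual)",
      colour = "interpretable",
      title = paste0("Gene variance (mode: ", attr(object, "mode"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' PPV burden histogram
#'
#' Distribution of per-individual PPV counts by cohort.
#'
#' @param object a `ppv_burden` from [ppv_burden()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.ppv_burden <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_ppvs, fill = .data$cohort)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "PPVs per individual", y = "individuals",
                  fill = "cohort") +
    ggplot2::theme_minimal()
}
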
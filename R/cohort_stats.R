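#' Per-individual PPV burden
#'
#' Counts PPVs per sample (samples with zero PPVs included via the
#' manifest) for histogramming and per-cohort means.
#'
#' @param ppvs a `ppv_tbl` or variant tibble.
#' @param manifest cohort manifest covering every sample.
#' @return a `ppv_burden` tibble: `sample_id`, `cohort`, `n_ppvs`.
#'   [glance()] gives per-cohort `n`, `mean_ppvs`; [autoplot()] draws the
#'   burden histogram by cohort.
#' @export
ppv_burden <- function(ppvs, manifest) {
  manifest <- as_tibble(manifest)
  out <- manifest[c("sample_id", "cohort")] |>
    left_join(
      as_tibble(ppvs) |> count(.data$sample_id, name = "n_ppvs"),
      by = "sample_id"
    ) |>
    mutate(n_ppvs = tidyr::replace_na(.data$n_ppvs, 0L))
  structure(out, class = c("ppv_burden", class(out)))
}

#' @export
glance.ppv_burden <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$cohort) |>
    summarise(n = dplyr::n(), mean_ppvs = mean(.data$n_ppvs),
              median_ppvs = median(.data$n_ppvs), .groups = "drop")
}

#' Burden histogram table
#'
#' @param x a `ppv_burden`.
#' @return tibble: `cohort`, `n_ppvs`, `n_samples`.
#' @export
burden_histogram <- function(x) {
  as_tibble(x) |> count(.data$cohort, .data$n_ppvs, name = "n_samples")
}

#' Clinical-mutation detection rate
#'
#' Summarises [confirm_clinical_mutation()] statuses: the detection rate is
#' the fraction of *expected-detectable* mutations (everything except
#' `not_expected`, i.e. excluding CNV and intronic IVS diagnoses) confirmed
#' at high quality. Mutations recovered only at low quality are reported
#' separately.
#'
#' @param statuses tibble with a `status` column (and optionally `cohort`;
#'   filter or group upstream for per-cohort rates).
#' @return one-row tibble: `n_total`, `n_expected`, `n_high_quality`,
#'   `n_low_quality`, `n_not_detected`, `detection_rate_pct`.
#' @export
detection_rate <- function(statuses) {
  s <- as_tibble(statuses)$status
  n_expected <- sum(s != "not_expected")
  if (n_expected == 0) abort("no expected-detectable mutations")
  tibble(
    n_total = length(s),
    n_expected = n_expected,
    n_high_quality = sum(s == "detected_high_quality"),
    n_low_quality = sum(s == "detected_low_quality"),
    n_not_detected = sum(s == "not_detected"),
    detection_rate_pct = 100 * sum(s == "detected_high_quality") / n_expected
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by inverting
#' the binomial tail probabilities (beta-quantile form). The lower bound is
#' 0 when `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k number of successes (vectorised).
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return tibble: `k`, `n`, `estimate`, `lower`, `upper`, `level`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    abort("need 0 <= k <= n and n >= 1")
  }
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  alpha <- 1 - level
  k <- as.integer(k)
  n <- as.integer(rep_len(n, length(k)))
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(k = k, n = n, estimate = k / n, lower = lower, upper = upper,
         level = level)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (within a small
#' relative tolerance to absorb floating-point ties).
#'
#' @param a,b,c,d cell counts (`a b / c d`), vectorised.
#' @return tibble: `a`, `b`, `c`, `d`, `odds_ratio` (sample OR, `Inf`/`NaN`
#'   possible on zero cells), `p_value`.
#' @export
fisher_exact <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), len); b <- rep_len(as.integer(b), len)
  c <- rep_len(as.integer(c), len); d <- rep_len(as.integer(d), len)
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  p <- vapply(seq_len(len), function(i) {
    m <- a[i] + c[i]        # column-1 margin
    nn <- b[i] + d[i]       # column-2 margin
    r1 <- a[i] + b[i]       # row-1 margin
    if (m + nn == 0) abort("all cells are zero")
    support <- max(0L, r1 - nn):min(r1, m)
    probs <- dhyper(support, m, nn, r1)
    p_obs <- probs[match(a[i], support)]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }, double(1))
  tibble(a = a, b = b, c = c, d = d,
         odds_ratio = (a * d) / (b * c), p_value = pmin(1, p))
}

#' Deleteriousness-score distribution by consequence class
#'
#' Summarises an optional per-variant deleteriousness score (CADD-like)
#' within each consequence class: count, median and quartiles over scored
#' calls, with the number of unscored calls reported alongside.
#'
#' @param x variant tibble with `consequence` and `score` columns.
#' @return tibble: `consequence`, `n_scored`, `n_unscored`, `median`,
#'   `q25`, `q75`.
#' @export
summarize_scores_by_class <- function(x) {
  x <- as_tibble(x)
  x |>
    group_by(.data$consequence) |>
    summarise(
      n_scored = sum(!is.na(.data$score)),
      n_unscored = sum(is.na(.data$score)),
      median = if (any(!is.na(.data$score)))
        median(.data$score, na.rm = TRUE) else NA_real_,
      q25 = if (any(!is.na(.data$score)))
        quantile(.data$score, 0.25, na.rm = TRUE, names = FALSE) else NA_real_,
      q75 = if (any(!is.na(.data$score)))
        quantile(.data$score, 0.75, na.rm = TRUE, names = FALSE) else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$n_scored + .data$n_unscored > 0)
}
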
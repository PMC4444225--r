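#' Quality-filter configuration
#'
#' Thresholds for the per-allele variant quality filter, calibrated from
#' replicate genotype concordance. SNVs are retained only when the quality
#' condition holds for both alleles (strict reading; hemizygous calls compare
#' the single allele quality alone); indels (insertions, deletions and block
#' substitutions) are retained only when strictly above `indel_min_quality`
#' (exclusive bound).
#'
#' @param snv_min_quality SNV per-allele minimum quality (inclusive bound;
#'   default 100).
#' @param indel_min_quality indel minimum quality (exclusive bound; default
#'   150: a quality of exactly 150 is excluded).
#' @param snv_rule `"strict"` retains an SNV only if *both* allele qualities
#'   pass; `"lenient"` excludes it only if both fail.
#' @param sweep_grid integer thresholds for calibration sweeps.
#' @return a `qc_config` list.
#' @export
qc_config <- function(snv_min_quality = 100L, indel_min_quality = 150L,
                      snv_rule = c("strict", "lenient"),
                      sweep_grid = seq(50L, 100L, by = 5L)) {
  snv_rule <- match.arg(snv_rule)
  if (snv_min_quality < 0 || indel_min_quality < 0) {
    abort("quality thresholds must be non-negative")
  }
  structure(list(
    snv_min_quality = as.integer(snv_min_quality),
    indel_min_quality = as.integer(indel_min_quality),
    snv_rule = snv_rule,
    sweep_grid = as.integer(sweep_grid)
  ), class = "qc_config")
}

var_class_of <- function(var_type) {
  ifelse(var_type == "snv", "snv", "indel")
}

# Effective per-call quality used by sweeps and filters: the min of the two
# allele qualities for diploid calls (strict rule), qual_a alone for
# hemizygous, the max for the lenient SNV rule.
call_quality <- function(x, rule = "strict") {
  q2 <- ifelse(x$genotype == "hemi", x$qual_a, x$qual_b)
  if (rule == "strict") pmin(x$qual_a, q2) else pmax(x$qual_a, q2)
}

#' Genotype concordance between replicate genomes at a quality threshold
#'
#' Compares two call sets from the same individual. The comparison universe
#' is the set of sites (`chrom:pos:ref:alt`) of the requested class that are
#' called with quality at or above `threshold` in *both* replicates;
#' concordance is the fraction of that universe with identical genotype.
#' `fraction_excluded` is the fraction of all distinct sites of the class
#' (union of both replicates) that fail to make the universe.
#'
#' @param rep_a,rep_b variant tibbles from the same individual.
#' @param threshold integer quality threshold (inclusive).
#' @param var_class `"snv"` or `"indel"`.
#' @return one-row tibble: `threshold`, `var_class`, `n_sites`,
#'   `concordance` (`NA` if the universe is empty, never 0 by convention),
#'   `fraction_excluded`.
#' @export
genotype_concordance <- function(rep_a, rep_b, threshold,
                                 var_class = c("snv", "indel")) {
  var_class <- match.arg(var_class)
  pick <- function(x) {
    x <- as_tibble(x)
    x <- x[var_class_of(x$var_type) == var_class, ]
    tibble(
      key = paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"),
      genotype = x$genotype,
      q = call_quality(x)
    )
  }
  a <- pick(rep_a)
  b <- pick(rep_b)
  all_sites <- union(a$key, b$key)
  a_pass <- a[a$q >= threshold, ]
  b_pass <- b[b$q >= threshold, ]
  universe <- intersect(a_pass$key, b_pass$key)
  n <- length(universe)
  conc <- if (n == 0) NA_real_ else {
    ga <- a_pass$genotype[match(universe, a_pass$key)]
    gb <- b_pass$genotype[match(universe, b_pass$key)]
    mean(ga == gb)
  }
  tibble(
    threshold = as.integer(threshold), var_class = var_class,
    n_sites = n, concordance = conc,
    fraction_excluded = if (length(all_sites) == 0) NA_real_ else
      1 - n / length(all_sites)
  )
}

#' Sweep quality thresholds over replicate pairs
#'
#' Averages [genotype_concordance()] over one or more replicate pairs at each
#' threshold of the grid (mean over pairs, the convention used to summarise
#' multi-individual calibration panels). The result is plot-ready and has an
#' [autoplot()] method.
#'
#' @param rep_pairs list of `list(rep_a =, rep_b =)` pairs (the output of
#'   [generate_replicate_pair()] works directly).
#' @param grid integer thresholds, e.g. `50:100` for SNVs or
#'   `seq(0, 300, 25)` for indels.
#' @param var_class `"snv"` or `"indel"`.
#' @return a `concordance_sweep` tibble ordered by threshold: `threshold`,
#'   `var_class`, `concordance`, `fraction_excluded`, `n_pairs`.
#' @export
sweep_thresholds <- function(rep_pairs, grid, var_class = c("snv", "indel")) {
  var_class <- match.arg(var_class)
  if (length(grid) == 0) abort("threshold grid is empty")
  if (length(rep_pairs) == 0) abort("need at least one replicate pair")
  if (!is.null(rep_pairs$rep_a)) rep_pairs <- list(rep_pairs)
  pts <- purrr::map(sort(as.integer(grid)), function(t) {
    per_pair <- purrr::map(rep_pairs, function(p) {
      genotype_concordance(p$rep_a, p$rep_b, t, var_class)
    }) |> bind_rows()
    tibble(
      threshold = t, var_class = var_class,
      concordance = mean(per_pair$concordance, na.rm = TRUE),
      fraction_excluded = mean(per_pair$fraction_excluded, na.rm = TRUE),
      n_pairs = nrow(per_pair)
    )
  }) |> bind_rows()
  structure(pts, class = c("concordance_sweep", class(pts)))
}

#' Apply the calibrated quality filter
#'
#' SNVs are retained iff both allele qualities are at or above
#' `qc$snv_min_quality` (under the default strict rule); indels are retained
#' iff their quality is strictly greater than `qc$indel_min_quality`.
#' Hemizygous calls compare `qual_a` alone.
#'
#' @param x variant tibble.
#' @param qc a [qc_config()].
#' @return list with `retained` (variant tibble), `excluded` (variant
#'   tibble) and `summary` (per-class tibble: `var_class`, `n_input`,
#'   `n_retained`, `n_excluded`, `fraction_excluded`).
#' @export
apply_quality_filter <- function(x, qc = qc_config()) {
  x <- as_tibble(x)
  keep <- quality_pass(x, qc)
  cls <- var_class_of(x$var_type)
  summary <- tibble(var_class = c("snv", "indel")) |>
    mutate(
      n_input = vapply(.data$var_class, function(cl) sum(cls == cl),
                       integer(1), USE.NAMES = FALSE),
      n_retained = vapply(.data$var_class, function(cl) sum(keep & cls == cl),
                          integer(1), USE.NAMES = FALSE),
      n_excluded = .data$n_input - .data$n_retained,
      fraction_excluded = ifelse(.data$n_input == 0, NA_real_,
                                 .data$n_excluded / .data$n_input)
    )
  list(retained = x[keep, ], excluded = x[!keep, ], summary = summary)
}

# Vectorised pass/fail under a qc_config.
quality_pass <- function(x, qc) {
  is_snv <- x$var_type == "snv"
  q_strict <- call_quality(x, "strict")
  q_snv <- call_quality(x, qc$snv_rule)
  ifelse(is_snv, q_snv >= qc$snv_min_quality, q_strict > qc$indel_min_quality)
}
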
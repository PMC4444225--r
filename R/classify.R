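#' PPV classification configuration
#'
#' A potentially pathogenic variant (PPV) is a nonsynonymous variant with
#' allele frequency below `frequency_threshold` in both population reference
#' panels; a variant absent from a panel counts as passing that panel
#' (novel). `mode` optionally restricts PPVs to loss-of-function variants
#' (`"lof"`: nonsense/splice-disrupt/misstart/nonstop SNVs plus frameshift
#' indels) or to LoF SNVs only (`"lof_snv"`).
#'
#' @param frequency_threshold frequency cutoff, exclusive (default 0.01).
#' @param mode `"all"`, `"lof"` or `"lof_snv"`.
#' @return a `ppv_config` list.
#' @export
ppv_config <- function(frequency_threshold = 0.01,
                       mode = c("all", "lof", "lof_snv")) {
  mode <- match.arg(mode)
  if (frequency_threshold <= 0 || frequency_threshold > 1) {
    abort("frequency_threshold must be in (0, 1]")
  }
  structure(list(frequency_threshold = frequency_threshold, mode = mode),
            class = "ppv_config")
}

#' Is a call nonsynonymous?
#'
#' TRUE for missense, nonsense, splice-disrupting, misstart, nonstop,
#' frameshift and in-frame indel consequences; FALSE for synonymous and
#' `other` (unclassifiable consequences are never promoted to PPVs).
#'
#' @param x variant tibble (or its `consequence` column).
#' @return logical vector.
#' @export
is_nonsynonymous <- function(x) {
  cons <- if (is.data.frame(x)) x$consequence else x
  cons %in% NONSYNONYMOUS_CLASSES
}

#' Is a call rare in both reference panels?
#'
#' A call passes iff every *present* panel frequency is below the threshold;
#' an absent (`NA`) frequency passes, so novel variants are rare by
#' definition and remain distinguishable downstream.
#'
#' @param x variant tibble.
#' @param cfg a [ppv_config()].
#' @return logical vector.
#' @export
is_rare <- function(x, cfg = ppv_config()) {
  t <- cfg$frequency_threshold
  (is.na(x$freq_esp) | x$freq_esp < t) &
    (is.na(x$freq_hapmap) | x$freq_hapmap < t)
}

#' Loss-of-function classification
#'
#' `lof_snv`: SNVs predicted to truncate the protein (nonsense), disrupt
#' canonical splicing, alter the initiator methionine (misstart) or the stop
#' codon (nonstop). `lof_indel`: frameshift indels. In-frame insertions and
#' deletions are never LoF; everything else is `not_lof`.
#'
#' @param x variant tibble.
#' @return character vector over `lof_snv`, `lof_indel`, `not_lof`.
#' @export
classify_lof <- function(x) {
  dplyr::case_when(
    x$var_type == "snv" & x$consequence %in% LOF_SNV_CLASSES ~ "lof_snv",
    x$consequence == "frameshift" ~ "lof_indel",
    TRUE ~ "not_lof"
  )
}

#' Select potentially pathogenic variants
#'
#' Applies the full PPV definition to a variant table: quality pass (if a
#' [qc_config()] is supplied; pass `qc = NULL` for pre-filtered input),
#' nonsynonymous consequence, rare in both frequency panels, and gene in the
#' panel net of its excluded genes. `cfg$mode` then optionally restricts to
#' LoF or LoF-SNV variants.
#'
#' @param x variant tibble.
#' @param panel a `gene_panel`.
#' @param cfg a [ppv_config()].
#' @param qc a [qc_config()], or `NULL` if `x` is already quality-filtered.
#' @return a `ppv_tbl`: the PPV calls with an added `lof_class` column,
#'   ordered by sample, gene and position. [glance()] on it reports the PPV
#'   count, the distinct-variant count and the novel fraction.
#' @export
select_ppvs <- function(x, panel, cfg = ppv_config(), qc = qc_config()) {
  stopifnot(inherits(panel, "gene_panel"))
  genes <- panel_genes(panel, drop_excluded = TRUE)
  if (length(genes) == 0) abort("gene panel is empty after exclusions")
  x <- as_tibble(x)
  if (!is.null(qc)) x <- x[quality_pass(x, qc), ]
  keep <- is_nonsynonymous(x) & is_rare(x, cfg) &
    !is.na(x$gene) & x$gene %in% genes
  out <- x[keep, ]
  out$lof_class <- classify_lof(out)
  out <- switch(cfg$mode,
    all = out,
    lof = out[out$lof_class != "not_lof", ],
    lof_snv = out[out$lof_class == "lof_snv", ]
  )
  out <- arrange(out, .data$sample_id, .data$gene, .data$chrom, .data$pos, .data$alt)
  structure(out, class = c("ppv_tbl", class(out)), mode = cfg$mode)
}

#' @export
glance.ppv_tbl <- function(x, ...) {
  tibble(
    n_ppvs = nrow(x),
    n_unique_variants = n_unique_variants(x),
    n_samples = n_distinct(x$sample_id),
    novel_fraction = if (nrow(x) == 0) NA_real_ else
      mean(is.na(x$freq_esp) & is.na(x$freq_hapmap)),
    mode = attr(x, "mode") %||% NA_character_
  )
}

#' Count distinct variants in a PPV table
#'
#' Distinct `gene:chrom:pos:ref:alt` combinations across samples.
#'
#' @param x variant tibble.
#' @return integer count.
#' @export
n_unique_variants <- function(x) {
  if (nrow(x) == 0) return(0L)
  n_distinct(paste(x$gene, x$chrom, x$pos, x$ref, x$alt, sep = ":"))
}

#' Confirm clinically diagnosed mutations against WGS calls
#'
#' For each manifest sample with a recorded clinical mutation, looks for an
#' exact (gene, chrom, pos, ref, alt) match among that sample's calls.
#' Mutations of category `cnv` or `ivs` are outside what a short-variant
#' pipeline can detect and are flagged `not_expected`. Otherwise the status
#' is `detected_high_quality` when the matching call passes the quality
#' filter, `detected_low_quality` when it is present but fails it, and
#' `not_detected` when no matching call exists.
#'
#' @param x variant tibble (all samples' calls, unfiltered).
#' @param manifest cohort manifest (see [read_cohort_manifest()]).
#' @param qc a [qc_config()].
#' @return tibble: `sample_id`, `cohort`, `clin_gene`, `clin_category`,
#'   `status`.
#' @export
confirm_clinical_mutation <- function(x, manifest, qc = qc_config()) {
  manifest <- as_tibble(manifest)
  has_mut <- !is.na(manifest$clin_gene)
  m <- manifest[has_mut, ]
  x <- as_tibble(x)
  xkey <- paste(x$sample_id, x$gene, x$chrom, x$pos, x$ref, x$alt, sep = ":")
  mkey <- paste(m$sample_id, m$clin_gene, m$clin_chrom, m$clin_pos,
                m$clin_ref, m$clin_alt, sep = ":")
  pass <- quality_pass(x, qc)
  hit_pass <- match(mkey, xkey[pass])   # prefer a quality-passing match
  hit_any <- match(mkey, xkey)
  status <- dplyr::case_when(
    m$clin_category %in% c("cnv", "ivs") ~ "not_expected",
    !is.na(hit_pass) ~ "detected_high_quality",
    !is.na(hit_any) ~ "detected_low_quality",
    TRUE ~ "not_detected"
  )
  tibble(
    sample_id = m$sample_id, cohort = m$cohort,
    clin_gene = m$clin_gene, clin_category = m$clin_category,
    status = status
  )
}
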
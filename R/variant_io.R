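#' Variant call tables
#'
#' A variant call table is a tibble with one row per called (non-reference)
#' variant per sample. It is the common currency of the package: the reader
#' functions produce it, the synthetic-cohort generator emits it, and the QC,
#' classification and gene-variance stages consume it.
#'
#' Required columns:
#' \describe{
#'   \item{sample_id}{opaque sample identifier (character).}
#'   \item{chrom, pos}{1-based, VCF-style coordinates.}
#'   \item{ref, alt}{alleles over `A/C/G/T`; `"-"` denotes an absent allele
#'     and is permitted only in the TSV (masterVar-like) dialect.}
#'   \item{var_type}{one of `snv`, `ins`, `del`, `sub`.}
#'   \item{genotype}{`het`, `hom` or `hemi`.}
#'   \item{qual_a, qual_b}{per-allele variant quality scores (non-negative
#'     integers; `qual_b` is ignored for hemizygous calls).}
#'   \item{consequence}{coding consequence as annotated upstream: one of
#'     `missense`, `nonsense`, `splice_disrupt`, `misstart`, `nonstop`,
#'     `frameshift`, `inframe_indel`, `synonymous`, `other`. Consequences are
#'     taken from the input annotation, never recomputed.}
#'   \item{gene}{gene symbol, or `NA` for intergenic calls.}
#'   \item{freq_esp, freq_hapmap}{allele frequencies in the two population
#'     reference panels, in `[0, 1]`; `NA` means the variant is absent from
#'     the panel (novel), which is distinct from a frequency of zero.}
#'   \item{score}{optional deleteriousness score (e.g. CADD-like); `NA` if
#'     unscored.}
#' }
#'
#' @name variant_tbl
NULL

VARIANT_COLS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "var_type", "genotype",
  "qual_a", "qual_b", "consequence", "gene", "freq_esp", "freq_hapmap",
  "score"
)

#' Build a variant call table from vectors
#'
#' Convenience constructor used throughout the package (and its tests) to
#' assemble small variant tables in code. Columns not supplied get neutral
#' defaults; the result is validated.
#'
#' @param sample_id,chrom,pos,ref,alt,var_type,genotype,qual_a,qual_b,consequence,gene,freq_esp,freq_hapmap,score
#'   column vectors, recycled to a common length. See [variant_tbl].
#' @return a validated variant tibble.
#' @export
variant_tbl <- function(sample_id = "S1", chrom = "1", pos = 1L,
                        ref = "A", alt = "T", var_type = "snv",
                        genotype = "het", qual_a = 200L, qual_b = 200L,
                        consequence = "missense", gene = NA_character_,
                        freq_esp = NA_real_, freq_hapmap = NA_real_,
                        score = NA_real_) {
  x <- tibble(
    sample_id = as.character(sample_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    var_type = as.character(var_type), genotype = as.character(genotype),
    qual_a = as.integer(qual_a), qual_b = as.integer(qual_b),
    consequence = as.character(consequence), gene = as.character(gene),
    freq_esp = as.double(freq_esp), freq_hapmap = as.double(freq_hapmap),
    score = as.double(score)
  )
  chk <- validate_variants(x, allow_dash = TRUE)
  if (nrow(chk$rejected) > 0) {
    abort(paste0(
      "invalid variant rows: ",
      paste(unique(chk$rejected$reason), collapse = "; ")
    ))
  }
  chk$variants
}

# Row-wise invariant checks. Returns list(variants = valid rows,
# rejected = tibble(line, reason)). `line` is the 1-based data row number.
validate_variants <- function(x, allow_dash = FALSE) {
  x <- as_tibble(x)
  missing_cols <- setdiff(VARIANT_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "variant table is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- x[VARIANT_COLS]
  allele_ok <- function(a) {
    ok <- !is.na(a) & grepl("^[ACGT]+$", a)
    if (allow_dash) ok <- ok | (!is.na(a) & a == "-")
    ok
  }
  reasons <- rep(NA_character_, nrow(x))
  flag <- function(bad, msg) {
    ifelse(is.na(reasons) & bad, msg, reasons)
  }
  reasons <- flag(is.na(x$sample_id) | x$sample_id == "", "missing sample_id")
  reasons <- flag(is.na(x$pos) | x$pos < 1L, "pos must be a positive integer")
  reasons <- flag(!allele_ok(x$ref) | !allele_ok(x$alt), "malformed allele")
  reasons <- flag(!x$var_type %in% VAR_TYPES, "unknown var_type")
  reasons <- flag(!x$genotype %in% GENOTYPES, "unknown genotype")
  reasons <- flag(
    x$var_type == "snv" & !(nchar(x$ref) == 1L & nchar(x$alt) == 1L &
      x$ref != "-" & x$alt != "-"),
    "snv requires single-base ref and alt"
  )
  reasons <- flag(
    x$consequence %in% c("frameshift", "inframe_indel") &
      !x$var_type %in% c("ins", "del", "sub"),
    "frameshift/inframe_indel requires an indel var_type"
  )
  reasons <- flag(!x$consequence %in% CONSEQUENCE_LEVELS, "unknown consequence")
  reasons <- flag(
    is.na(x$qual_a) | x$qual_a < 0L |
      (x$genotype != "hemi" & (is.na(x$qual_b) | x$qual_b < 0L)),
    "allele qualities must be non-negative (both for diploid calls)"
  )
  bad_freq <- function(f) !is.na(f) & (f < 0 | f > 1)
  reasons <- flag(
    bad_freq(x$freq_esp) | bad_freq(x$freq_hapmap),
    "frequency outside [0, 1]"
  )
  bad <- !is.na(reasons)
  list(
    variants = x[!bad, , drop = FALSE],
    rejected = tibble(line = which(bad), reason = reasons[bad])
  )
}

#' Read a variant call table
#'
#' Reads per-sample variant calls from either the package's documented TSV
#' dialect (masterVar-like: one row per call, fixed column set, `"-"` alleles
#' permitted, empty/`.`/`NA` fields treated as absent) or from VCF 4.x. Rows
#' failing the type invariants are rejected, never silently dropped: the
#' returned tibble carries a `rejected` attribute with the 1-based data line
#' number and reason for every rejected row, retrievable with
#' [rejected_rows()].
#'
#' For the VCF dialect each sample genotype with at least one alternate
#' allele yields one call; `0/0` and `./.` genotypes contribute nothing. The
#' two per-allele qualities are read from a FORMAT field and the annotations
#' from INFO keys, with key names configurable via `vcf_keys` so that
#' differently annotated VCFs can be adapted without rewriting them.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param vcf_keys named list mapping the package's fields to VCF keys:
#'   `allele_quality` (FORMAT, two comma-separated integers), and INFO keys
#'   `gene`, `consequence`, `freq_esp`, `freq_hapmap`, `score`, `var_type`.
#' @return a variant tibble (see [variant_tbl]) with attribute `rejected`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               vcf_keys = default_vcf_keys()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path, vcf_keys)
}

#' @rdname read_variant_table
#' @param x a variant tibble returned by [read_variant_table()].
#' @export
rejected_rows <- function(x) {
  attr(x, "rejected") %||% tibble(line = integer(), reason = character())
}

read_variant_tsv <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), ref = readr::col_character(),
      alt = readr::col_character(), var_type = readr::col_character(),
      genotype = readr::col_character(), qual_a = readr::col_integer(),
      qual_b = readr::col_integer(), consequence = readr::col_character(),
      gene = readr::col_character(), freq_esp = readr::col_double(),
      freq_hapmap = readr::col_double(), score = readr::col_double()
    ),
    na = c("", "NA", "."), progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0(
      "malformed variant TSV ", path, " (line ", prob$row[1] + 1L, "): ",
      prob$expected[1], " expected, got ", prob$actual[1]
    ))
  }
  chk <- validate_variants(raw, allow_dash = TRUE)
  structure(chk$variants, rejected = chk$rejected)
}

default_vcf_keys <- function() {
  list(
    allele_quality = "AQ", gene = "GENE", consequence = "CSQCLASS",
    freq_esp = "AF_ESP", freq_hapmap = "AF_HAPMAP", score = "SCORE",
    var_type = "VT"
  )
}

read_variant_vcf <- function(path, vcf_keys) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading the vcf dialect requires the vcfR package")
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF header/body in ", path, ": ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(structure(variant_tbl()[0, ],
                     rejected = tibble(line = integer(), reason = character())))
  }
  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(?:^|;)", key, "=[^;]*"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(?:^|;)", key, "="), fix$INFO)
    out[hit] <- sub(paste0("^(?:;)?", key, "="), "",
                    regmatches(fix$INFO, regexpr(paste0("(?:^|;)", key, "=[^;]*"),
                                                 fix$INFO)))
    out
  }
  for (key in c("gene", "consequence", "var_type")) {
    if (!any(grepl(paste0(vcf_keys[[key]], "="), fix$INFO))) {
      abort(paste0("VCF is missing required INFO annotation '",
                   vcf_keys[[key]], "' (", key, ")"))
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT FORMAT field")
  aq <- vcfR::extract.gt(v, element = vcf_keys$allele_quality)
  if (is.null(aq)) {
    abort(paste0("VCF is missing required FORMAT field '",
                 vcf_keys$allele_quality, "' (allele_quality)"))
  }
  samples <- colnames(gt)
  site <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    var_type = info_get(vcf_keys$var_type),
    consequence = info_get(vcf_keys$consequence),
    gene = info_get(vcf_keys$gene),
    freq_esp = as.double(info_get(vcf_keys$freq_esp)),
    freq_hapmap = as.double(info_get(vcf_keys$freq_hapmap)),
    score = as.double(info_get(vcf_keys$score))
  )
  rows <- purrr::map(samples, function(s) {
    g <- gt[, s]
    q <- aq[, s]
    # non-reference, non-missing genotypes only
    alt_count <- ifelse(
      is.na(g) | grepl("\\.", g), 0L,
      stringr::str_count(g, "1")
    )
    ploidy <- ifelse(is.na(g), 2L, stringr::str_count(g, "[0-9.]"))
    keep <- alt_count > 0L
    if (!any(keep)) return(NULL)
    qs <- stringr::str_split_fixed(q[keep], ",", 2)
    geno <- dplyr::case_when(
      ploidy[keep] == 1L ~ "hemi",
      alt_count[keep] >= 2L ~ "hom",
      TRUE ~ "het"
    )
    dplyr::bind_cols(
      tibble(sample_id = s),
      site[keep, ],
      tibble(
        genotype = geno,
        qual_a = suppressWarnings(as.integer(qs[, 1])),
        qual_b = suppressWarnings(as.integer(qs[, 2]))
      )
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(structure(variant_tbl()[0, ],
                     rejected = tibble(line = integer(), reason = character())))
  }
  out$qual_b[out$genotype == "hemi" & is.na(out$qual_b)] <-
    out$qual_a[out$genotype == "hemi" & is.na(out$qual_b)]
  chk <- validate_variants(out[, VARIANT_COLS], allow_dash = FALSE)
  structure(chk$variants, rejected = chk$rejected)
}

#' Write a variant call table
#'
#' Writes the TSV dialect (default) or a minimal single/multi-sample VCF 4.2
#' carrying the package's annotations in INFO/FORMAT fields that
#' [read_variant_table()] can read back.
#'
#' @param x variant tibble.
#' @param path output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param vcf_keys key names, as in [read_variant_table()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, dialect = c("tsv", "vcf"),
                                vcf_keys = default_vcf_keys()) {
  dialect <- match.arg(dialect)
  x <- as_tibble(x)[VARIANT_COLS]
  if (dialect == "tsv") {
    readr::write_tsv(x, path, na = "", progress = FALSE)
    return(invisible(path))
  }
  if (any(x$ref == "-" | x$alt == "-", na.rm = TRUE)) {
    abort("'-' alleles cannot be written to the vcf dialect; left-normalize with an anchor base first")
  }
  samples <- sort(unique(x$sample_id))
  key <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  sites <- x[!duplicated(key), ]
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]
  fmt_num <- function(v) ifelse(is.na(v), NA_character_, format(v, scientific = FALSE, trim = TRUE))
  info <- function(s) {
    parts <- c(
      paste0(vcf_keys$var_type, "=", s$var_type),
      paste0(vcf_keys$consequence, "=", s$consequence),
      ifelse(is.na(s$gene), NA, paste0(vcf_keys$gene, "=", s$gene)),
      ifelse(is.na(s$freq_esp), NA, paste0(vcf_keys$freq_esp, "=", fmt_num(s$freq_esp))),
      ifelse(is.na(s$freq_hapmap), NA, paste0(vcf_keys$freq_hapmap, "=", fmt_num(s$freq_hapmap))),
      ifelse(is.na(s$score), NA, paste0(vcf_keys$score, "=", fmt_num(s$score)))
    )
    apply(matrix(parts, nrow = nrow(s)), 1, function(p) paste(p[!is.na(p)], collapse = ";"))
  }
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  lookup <- split(seq_len(nrow(x)), key)
  gt_cols <- vapply(seq_along(skey), function(i) {
    calls <- x[lookup[[skey[i]]], ]
    per_sample <- setNames(rep("0/0:.", length(samples)), samples)
    gts <- c(het = "0/1", hom = "1/1", hemi = "1")
    per_sample[calls$sample_id] <- paste0(
      gts[calls$genotype], ":", calls$qual_a, ",",
      ifelse(calls$genotype == "hemi", calls$qual_a, calls$qual_b)
    )
    paste(per_sample, collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", vcf_keys$var_type, ",Number=1,Type=String,Description=\"Variant type\">"),
    paste0("##INFO=<ID=", vcf_keys$consequence, ",Number=1,Type=String,Description=\"Coding consequence class\">"),
    paste0("##INFO=<ID=", vcf_keys$gene, ",Number=1,Type=String,Description=\"Gene symbol\">"),
    paste0("##INFO=<ID=", vcf_keys$freq_esp, ",Number=1,Type=Float,Description=\"Reference panel A allele frequency\">"),
    paste0("##INFO=<ID=", vcf_keys$freq_hapmap, ",Number=1,Type=Float,Description=\"Reference panel B allele frequency\">"),
    paste0("##INFO=<ID=", vcf_keys$score, ",Number=1,Type=Float,Description=\"Deleteriousness score\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=", vcf_keys$allele_quality, ",Number=2,Type=Integer,Description=\"Per-allele variant quality\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
    info(sites), paste0("GT:", vcf_keys$allele_quality), gt_cols,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene panel
#'
#' A gene panel is a named set of genes with inheritance mode, a
#' cancer-associated flag and a coding length, plus an optional exclusion
#' list (genes dropped from downstream analysis, e.g. recurrent sequencing
#' artifacts). Expected TSV columns: `gene`, `inheritance`
#' (`dominant`/`recessive`/`x_linked`), `cancer_associated` (logical),
#' `coding_length` (bp), optional logical `excluded`.
#'
#' @param path TSV file path.
#' @param name panel name; defaults to the file name.
#' @return a `gene_panel`: a tibble of entries with attributes `name` and
#'   `excluded_genes`.
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), inheritance = readr::col_character(),
    cancer_associated = readr::col_logical(),
    coding_length = readr::col_integer(),
    .default = readr::col_guess()
  ), progress = FALSE, show_col_types = FALSE)
  if (nrow(x) == 0) abort(paste0("empty gene panel: ", path))
  excluded <- if ("excluded" %in% names(x)) x$gene[isTRUE_v(x$excluded)] else character()
  gene_panel(
    x[setdiff(names(x), "excluded")],
    name = name %||% basename(path),
    excluded_genes = excluded
  )
}

isTRUE_v <- function(x) !is.na(x) & x

#' @rdname read_gene_panel
#' @param entries tibble/data frame with columns `gene`, `inheritance`,
#'   `cancer_associated`, `coding_length`.
#' @param excluded_genes character vector of genes to drop from analysis.
#' @export
gene_panel <- function(entries, name = "panel", excluded_genes = character()) {
  x <- as_tibble(entries)
  need <- c("gene", "inheritance", "cancer_associated", "coding_length")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene panel is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$gene)) {
    abort(paste0("duplicate gene symbols in panel: ",
                 paste(unique(x$gene[duplicated(x$gene)]), collapse = ", ")))
  }
  if (!all(x$inheritance %in% c("dominant", "recessive", "x_linked"))) {
    abort("inheritance must be dominant, recessive or x_linked")
  }
  if (any(is.na(x$coding_length) | x$coding_length <= 0)) {
    abort("coding_length must be a positive integer")
  }
  structure(x[need], class = c("gene_panel", class(x)),
            name = name, excluded_genes = as.character(excluded_genes))
}

#' @rdname read_gene_panel
#' @param panel a `gene_panel`.
#' @export
panel_genes <- function(panel, drop_excluded = TRUE) {
  g <- panel$gene
  if (drop_excluded) setdiff(g, attr(panel, "excluded_genes")) else g
}

#' @rdname read_gene_panel
#' @param drop_excluded drop the panel's excluded genes?
#' @export
panel_excluded <- function(panel) attr(panel, "excluded_genes")

#' Counts of panel genes by inheritance mode
#'
#' @param panel a `gene_panel`.
#' @return tibble with columns `inheritance`, `n`.
#' @export
panel_inheritance_counts <- function(panel) {
  as_tibble(panel) |> count(.data$inheritance, name = "n")
}

#' Read a cohort manifest
#'
#' The manifest assigns each sample to exactly one cohort and optionally
#' records its clinically diagnosed mutation. TSV columns: `sample_id`,
#' `cohort` (free label, e.g. `BRCA1`/`BRCA2`/`nonBRCA`), and optionally
#' `clin_gene`, `clin_chrom`, `clin_pos`, `clin_ref`, `clin_alt`,
#' `clin_category` (`snv`/`indel`/`cnv`/`ivs`). Mutations of category `cnv`
#' or `ivs` lie outside what the short-variant pipeline can detect; the
#' manifest flags those samples `expected_detectable = FALSE`.
#'
#' @param path TSV file path.
#' @return a tibble with one row per sample and an `expected_detectable`
#'   column (`NA` when no clinical mutation is recorded).
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), cohort = readr::col_character(),
    .default = readr::col_guess()
  ), na = c("", "NA", "."), progress = FALSE, show_col_types = FALSE)
  cohort_manifest(x)
}

#' @rdname read_cohort_manifest
#' @param x data frame with at least `sample_id` and `cohort`.
#' @export
cohort_manifest <- function(x) {
  x <- as_tibble(x)
  if (!all(c("sample_id", "cohort") %in% names(x))) {
    abort("manifest requires sample_id and cohort columns")
  }
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicated sample_id in manifest: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  for (col in c("clin_gene", "clin_chrom", "clin_ref", "clin_alt", "clin_category")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  if (!"clin_pos" %in% names(x)) x$clin_pos <- NA_integer_
  x$clin_pos <- as.integer(x$clin_pos)
  bad <- !is.na(x$clin_category) &
    !x$clin_category %in% c("snv", "indel", "cnv", "ivs")
  if (any(bad)) abort("clin_category must be snv, indel, cnv or ivs")
  x$expected_detectable <- ifelse(
    is.na(x$clin_category), NA, !x$clin_category %in% c("cnv", "ivs")
  )
  x
}
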
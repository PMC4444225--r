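#' Simulation configuration for synthetic clinical WGS cohorts
#'
#' Defines the statistical structure of a synthetic study: a gene set with
#' log-normal coding lengths, a Poisson background of rare missense calls
#' whose per-gene rate is proportional to coding length, planted
#' loss-of-function carriers at chosen carrier fractions, a novel fraction of
#' variants absent from the frequency panels, and a quality/error model for
#' replicate genome pairs in which the genotype-error probability is strictly
#' decreasing in the quality score.
#'
#' Defaults reproduce the study conditions the pipeline is designed around:
#' cohorts of 88 + 88 carrier samples and 82 non-carrier samples, a
#' background rate tuned so an individual carries roughly seven rare missense
#' calls across a 163-gene panel-sized gene set, and 46.33% of variants
#' novel.
#'
#' @param n_genes number of genes in the synthetic gene set.
#' @param coding_length_meanlog,coding_length_sdlog log-normal law of coding
#'   length in bp.
#' @param missense_rate expected rare missense calls per coding bp per
#'   individual (Poisson rate per gene = `missense_rate * coding_length`).
#' @param planted_lof tibble (or list coercible to one) with columns `gene`,
#'   `carrier_fraction`, `cohort`, `var_type` (`"snv"` plants a nonsense SNV,
#'   `"del"` a frameshift deletion). The planted variant is present in
#'   `floor(carrier_fraction * n)` distinct samples of the stated cohort.
#' @param novel_fraction fraction of background variants with no entry in
#'   either frequency panel.
#' @param n_samples named integer vector: samples per cohort label.
#' @param q_law function(n) returning n integer quality scores in 0..300.
#' @param error_rate function(q) returning the genotype-error probability,
#'   strictly decreasing in q (default: logistic).
#' @param n_sites number of true variant sites simulated for a replicate
#'   genome pair.
#' @param indel_fraction fraction of replicate-pair sites that are indels.
#' @param hom_fraction fraction of homozygous true genotypes.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       coding_length_meanlog = log(1500),
                       coding_length_sdlog = 0.8,
                       missense_rate = 2.8e-5,
                       planted_lof = NULL,
                       novel_fraction = 0.4633,
                       n_samples = c(BRCA1 = 88, BRCA2 = 88, nonBRCA = 82),
                       q_law = default_q_law,
                       error_rate = default_error_rate,
                       n_sites = 2000,
                       indel_fraction = 0.2,
                       hom_fraction = 0.3,
                       seed = 1L) {
  if (n_genes < 1) abort("n_genes must be positive")
  if (missense_rate < 0) abort("missense_rate must be non-negative")
  if (novel_fraction < 0 || novel_fraction > 1) {
    abort("novel_fraction must be in [0, 1]")
  }
  if (is.null(names(n_samples)) || any(n_samples < 1)) {
    abort("n_samples must be a named vector of positive cohort sizes")
  }
  if (!is.null(planted_lof)) {
    planted_lof <- as_tibble(planted_lof)
    if (!all(c("gene", "carrier_fraction", "cohort") %in% names(planted_lof))) {
      abort("planted_lof needs columns gene, carrier_fraction, cohort")
    }
    if (!"var_type" %in% names(planted_lof)) planted_lof$var_type <- "snv"
    if (any(planted_lof$carrier_fraction < 0 | planted_lof$carrier_fraction > 1)) {
      abort("carrier_fraction must be in [0, 1]")
    }
  }
  qs <- 0:300
  eps <- error_rate(qs)
  if (any(diff(eps) > 0) || any(eps < 0 | eps > 1)) {
    abort("error_rate must map quality to [0, 1] and be non-increasing in q")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    coding_length_meanlog = coding_length_meanlog,
    coding_length_sdlog = coding_length_sdlog,
    missense_rate = missense_rate,
    planted_lof = planted_lof,
    novel_fraction = novel_fraction,
    n_samples = n_samples,
    q_law = q_law,
    error_rate = error_rate,
    n_sites = as.integer(n_sites),
    indel_fraction = indel_fraction,
    hom_fraction = hom_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_q_law <- function(n) as.integer(round(300 * stats::rbeta(n, 5, 1.5)))

#' @rdname sim_config
#' @export
default_error_rate <- function(q) 0.3 / (1 + exp((q - 80) / 15))

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

sim_gene_table <- function(cfg) {
  lengths <- pmax(150L, as.integer(round(
    rlnorm(cfg$n_genes, cfg$coding_length_meanlog, cfg$coding_length_sdlog)
  )))
  tibble(
    gene = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = as.character(rep_len(1:22, cfg$n_genes)),
    start = cumsum(c(1L, head(lengths, -1) + 1000L)),
    coding_length = lengths
  )
}

draw_panel_freqs <- function(n, novel_fraction) {
  # Latent population frequency: 90% of mass below 1% so the rare-variant
  # filter passes most simulated variants by construction; the two panels see
  # correlated, jittered copies. Novel variants are absent from both.
  novel <- runif(n) < novel_fraction
  base <- ifelse(runif(n) < 0.9, runif(n, 0, 0.01), runif(n, 0.01, 0.2))
  jitter <- function(f) pmin(1, pmax(0, f * exp(rnorm(n, 0, 0.1))))
  tibble(
    freq_esp = ifelse(novel, NA_real_, jitter(base)),
    freq_hapmap = ifelse(novel, NA_real_, jitter(base))
  )
}

#' Generate a synthetic cohort of variant call sets
#'
#' Per gene g and individual, the number of background rare missense calls is
#' Poisson with mean `missense_rate * coding_length(g)`; planted LoF variants
#' (nonsense SNV or frameshift deletion) are inserted into
#' `floor(carrier_fraction * n)` randomly chosen samples of their cohort; a
#' `novel_fraction` of background variants carries no panel frequency and the
#' rest draw frequencies from a mixture with 90% of its mass below 1%.
#' Output is deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `manifest` (cohort manifest tibble) and
#'   `variants` (variant tibble, see [variant_tbl]), plus `genes` (the
#'   synthetic gene table, usable as a panel via [sim_gene_panel()]).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sim_gene_table(cfg)
    manifest <- cohort_manifest(tibble(
      sample_id = unlist(lapply(names(cfg$n_samples), function(co) {
        sprintf("%s.%03d", co, seq_len(cfg$n_samples[[co]]))
      })),
      cohort = rep(names(cfg$n_samples), cfg$n_samples)
    ))
    n_samp <- nrow(manifest)

    # Background missense calls: counts per sample x gene.
    lam <- cfg$missense_rate * genes$coding_length
    counts <- rpois(n_samp * cfg$n_genes, rep(lam, times = n_samp))
    idx <- which(counts > 0)
    reps <- counts[idx]
    gene_i <- rep(((idx - 1L) %% cfg$n_genes) + 1L, reps)
    samp_i <- rep(((idx - 1L) %/% cfg$n_genes) + 1L, reps)
    n_bg <- length(gene_i)
    bg <- if (n_bg > 0) {
      offset <- as.integer(floor(runif(n_bg) * genes$coding_length[gene_i]))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_bg, replace = TRUE)
      alt <- bases[(match(ref, bases) + sample(1:3, n_bg, replace = TRUE) - 1L) %% 4L + 1L]
      dplyr::bind_cols(
        tibble(
          sample_id = manifest$sample_id[samp_i],
          chrom = genes$chrom[gene_i],
          pos = genes$start[gene_i] + offset,
          ref = ref, alt = alt,
          var_type = "snv",
          genotype = ifelse(runif(n_bg) < 0.05, "hom", "het"),
          qual_a = cfg$q_law(n_bg), qual_b = cfg$q_law(n_bg),
          consequence = "missense",
          gene = genes$gene[gene_i]
        ),
        draw_panel_freqs(n_bg, cfg$novel_fraction),
        tibble(score = pmax(0, rnorm(n_bg, 15, 8)))
      )
    } else {
      NULL
    }

    planted <- NULL
    if (!is.null(cfg$planted_lof) && nrow(cfg$planted_lof) > 0) {
      planted <- purrr::pmap(cfg$planted_lof, function(gene, carrier_fraction,
                                                       cohort, var_type, ...) {
        gi <- match(gene, genes$gene)
        if (is.na(gi)) abort(paste0("planted gene not in synthetic gene set: ", gene))
        cohort_samples <- manifest$sample_id[manifest$cohort == cohort]
        if (length(cohort_samples) == 0) {
          abort(paste0("planted cohort has no samples: ", cohort))
        }
        k <- floor(carrier_fraction * length(cohort_samples))
        if (k < 1) {
          warn(paste0("carrier_fraction * n < 1 for gene ", gene,
                      "; planting zero carriers"))
          return(NULL)
        }
        carriers <- sample(cohort_samples, k)
        is_snv <- identical(var_type, "snv")
        tibble(
          sample_id = carriers,
          chrom = genes$chrom[gi],
          pos = genes$start[gi] + 7L,
          ref = if (is_snv) "C" else "CA",
          alt = if (is_snv) "T" else "C",
          var_type = if (is_snv) "snv" else "del",
          genotype = "het",
          qual_a = cfg$q_law(k), qual_b = cfg$q_law(k),
          consequence = if (is_snv) "nonsense" else "frameshift",
          gene = gene,
          freq_esp = NA_real_, freq_hapmap = NA_real_,
          score = pmax(0, rnorm(k, 35, 4))
        )
      })
      planted <- bind_rows(planted)
    }

    variants <- bind_rows(bg, planted)
    if (nrow(variants) == 0) {
      variants <- variant_tbl()[0, ]
    } else {
      variants <- variants[VARIANT_COLS] |>
        arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
    }
    list(manifest = manifest, variants = as_tibble(variants), genes = genes)
  })
}

#' Gene panel view of a synthetic gene table
#'
#' @param genes the `genes` element returned by [generate_cohort()].
#' @param name panel name.
#' @param excluded_genes genes to exclude downstream.
#' @export
sim_gene_panel <- function(genes, name = "synthetic", excluded_genes = character()) {
  gene_panel(
    tibble(
      gene = genes$gene, inheritance = "dominant",
      cancer_associated = FALSE, coding_length = genes$coding_length
    ),
    name = name, excluded_genes = excluded_genes
  )
}

#' Generate a replicate genome pair with quality-dependent genotype errors
#'
#' Simulates one individual's true non-reference genotypes at `cfg$n_sites`
#' sites and two independent replicate call sets of that individual. Each
#' replicate call draws a quality score from `cfg$q_law`; with probability
#' `cfg$error_rate(q)` the observed genotype is replaced by one of the two
#' other states (reference, het, hom) uniformly at random. Calls observed as
#' reference are absent from that replicate's table, which is how real
#' replicate discordance manifests as missing sites.
#'
#' @param cfg a [sim_config()].
#' @return list with `rep_a`, `rep_b` (variant tibbles) and `truth` (tibble
#'   of true genotypes per site).
#' @export
generate_replicate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_sites
    is_indel <- runif(m) < cfg$indel_fraction
    truth <- tibble(
      chrom = "1",
      pos = seq_len(m) * 10L,
      ref = ifelse(is_indel, "AC", "A"),
      alt = ifelse(is_indel, "A", "G"),
      var_type = ifelse(is_indel, "del", "snv"),
      consequence = ifelse(is_indel, "frameshift", "missense"),
      genotype = ifelse(runif(m) < cfg$hom_fraction, "hom", "het")
    )
    observe <- function(rep_id) {
      q <- cfg$q_law(m)
      err <- runif(m) < cfg$error_rate(q)
      states <- c("ref", "het", "hom")
      obs <- truth$genotype
      if (any(err)) {
        obs[err] <- vapply(which(err), function(i) {
          sample(setdiff(states, truth$genotype[i]), 1)
        }, character(1))
      }
      keep <- obs != "ref"
      tibble(
        sample_id = rep_id,
        chrom = truth$chrom[keep], pos = truth$pos[keep],
        ref = truth$ref[keep], alt = truth$alt[keep],
        var_type = truth$var_type[keep],
        genotype = obs[keep],
        qual_a = q[keep], qual_b = q[keep],
        consequence = truth$consequence[keep],
        gene = NA_character_,
        freq_esp = NA_real_, freq_hapmap = NA_real_, score = NA_real_
      )
    }
    list(rep_a = observe("repA"), rep_b = observe("repB"), truth = truth)
  })
}
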
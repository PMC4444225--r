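test_that("burden means and histograms follow the counts", {
  manifest <- two_cohort_manifest(2, 2)
  empty <- ppv_burden(variant_tbl()[0, ], manifest)
  expect_true(all(glance(empty)$mean_ppvs == 0))

  ppvs <- variant_tbl(sample_id = c("C1", "C1", "C2", "C2", "C2", "C2"),
                      pos = 1:6 * 10L, gene = "GENEA")
  b <- ppv_burden(ppvs, manifest)
  g <- glance(b)
  expect_equal(g$mean_ppvs[g$cohort == "ctrl"], 3.0)  # counts {2, 4}
  expect_equal(g$mean_ppvs[g$cohort == "case"], 0)
  h <- burden_histogram(b)
  expect_equal(h$n_samples[h$cohort == "ctrl" & h$n_ppvs == 2], 1)
})

test_that("synthetic cohort burden matches the generator expectation", {
  cfg <- sim_config(n_genes = 100, missense_rate = 3e-5, novel_fraction = 1,
                    n_samples = c(ctrl = 60), seed = 53)
  sim <- generate_cohort(cfg)
  panel <- sim_gene_panel(sim$genes)
  # all variants novel => all rare; no quality filter => pure Poisson count
  ppvs <- select_ppvs(sim$variants, panel, ppv_config(), qc = NULL)
  b <- glance(ppv_burden(ppvs, sim$manifest))
  lambda <- cfg$missense_rate * sum(sim$genes$coding_length)
  se <- sqrt(lambda / 60)
  expect_lt(abs(b$mean_ppvs - lambda), 4 * se)
})

test_that("detection rates reproduce the cohort accounting of the fixtures", {
  manifest <- carrier_cohort_manifest()
  calls <- carrier_clinical_calls()
  st <- confirm_clinical_mutation(calls, manifest, qc_config())
  r1 <- detection_rate(st[st$cohort == "BRCA1", ])
  expect_equal(r1$n_expected, 75)
  expect_equal(r1$n_high_quality, 67)
  expect_equal(round(r1$detection_rate_pct, 1), 89.3)
  r2 <- detection_rate(st[st$cohort == "BRCA2", ])
  expect_equal(r2$n_expected, 88)
  expect_equal(r2$n_low_quality, 10)
  expect_equal(round(r2$detection_rate_pct, 1), 88.6)
  # 16 of the 18 low-quality recoveries are indels
  low <- st[st$status == "detected_low_quality", ]
  expect_equal(nrow(low), 18)
  expect_equal(sum(low$clin_category == "indel"), 16)
  expect_error(
    detection_rate(tibble::tibble(status = "not_expected")),
    "expected-detectable"
  )
})

test_that("exact binomial CI matches tail-sum bisection and its bounds", {
  ci <- binomial_ci(17, 82)
  expect_equal(round(100 * ci$lower, 1), 12.6)
  expect_equal(round(100 * ci$upper, 1), 31.1)
  expect_equal(binomial_ci(0, 10)$lower, 0)
  expect_equal(binomial_ci(10, 10)$upper, 1)

  # oracle: invert the binomial tail sums by bisection, choose()-based
  tail_upper <- function(p, k, n) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  tail_lower <- function(p, k, n) sum(choose(n, 0:k) * p^(0:k) * (1 - p)^(n - (0:k)))
  bisect <- function(f, target, lo, hi) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid  # f increasing in p
    }
    (lo + hi) / 2
  }
  for (case in list(c(5, 10), c(17, 82), c(1, 30))) {
    k <- case[1]; n <- case[2]
    lower <- bisect(function(p) tail_upper(p, k, n), 0.025, 0, k / n)
    upper <- 1 - bisect(function(p) tail_lower(1 - p, k, n), 0.025, 0, 1 - k / n)
    got <- binomial_ci(k, n)
    expect_equal(got$lower, lower, tolerance = 1e-9)
    expect_equal(got$upper, upper, tolerance = 1e-9)
  }
  expect_error(binomial_ci(5, 4), "k <= n")
})

test_that("the 95% interval covers the truth at nominal rate", {
  draws <- withr::with_seed(59, stats::rbinom(1000, 82, 0.2))
  ci <- binomial_ci(draws, 82)
  coverage <- mean(ci$lower <= 0.2 & ci$upper >= 0.2)
  expect_gte(coverage, 0.93)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
  expect_equal(fisher_exact(1, 9, 1, 9)$p_value, 1.0)
  expect_equal(fisher_exact(5, 0, 0, 5)$p_value, 2 / choose(10, 5))

  # oracle: full hypergeometric enumeration with choose()
  enum_p <- function(a, b, c, d) {
    r1 <- a + b; m <- a + c; nn <- b + d; s <- a + c
    support <- max(0, r1 - nn):min(r1, m)
    probs <- choose(m, support) * choose(nn, r1 - support) / choose(m + nn, r1)
    sum(probs[probs <= probs[match(a, support)] * (1 + 1e-7)])
  }
  tabs <- withr::with_seed(61, matrix(stats::rpois(4 * 50, 4), ncol = 4))
  tabs <- tabs[rowSums(tabs) > 0, , drop = FALSE]
  ours <- fisher_exact(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])$p_value
  oracle <- apply(tabs, 1, function(r) enum_p(r[1], r[2], r[3], r[4]))
  expect_equal(ours, oracle, tolerance = 1e-12)
  # independent cross-check against the reference implementation
  ref <- apply(tabs, 1, function(r) {
    stats::fisher.test(matrix(r, 2, byrow = TRUE))$p.value
  })
  expect_equal(ours, ref, tolerance = 1e-7)
  # symmetry under row swap and column swap
  expect_equal(fisher_exact(3, 8, 5, 2)$p_value,
               fisher_exact(5, 2, 3, 8)$p_value)
  expect_equal(fisher_exact(3, 8, 5, 2)$p_value,
               fisher_exact(8, 3, 2, 5)$p_value)
  expect_error(fisher_exact(0, 0, 0, 0), "zero")
})

test_that("score summaries match a sort-based oracle and count unscored calls", {
  x <- variant_tbl(
    pos = 1:7 * 10L,
    consequence = c("missense", "missense", "missense", "nonsense",
                    "nonsense", "nonsense", "nonsense"),
    score = c(10, 20, 30, 5, NA, 15, 25)
  )
  s <- summarize_scores_by_class(x)
  mis <- s[s$consequence == "missense", ]
  expect_equal(mis$median, 20)
  expect_equal(mis$n_scored, 3)
  non <- s[s$consequence == "nonsense", ]
  expect_equal(non$n_unscored, 1)
  sorted <- sort(c(5, 15, 25))
  expect_equal(non$median, sorted[2])
  expect_equal(non$q25, unname(quantile(c(5, 15, 25), 0.25)))

  none <- summarize_scores_by_class(variant_tbl(score = NA_real_))
  expect_equal(none$n_scored, 0)
  expect_equal(none$n_unscored, 1)
  expect_true(is.na(none$median))
})
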
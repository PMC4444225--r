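---
title: "Methods: clinical interpretation of WGS variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical interpretation of WGS variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinwgs)
```

## The problem

Clinical genetics patients are usually tested with single-gene or gene-panel
assays. When whole-genome sequencing stands in for those assays, three
questions must be answered before any variant reaches a report: which calls
are technically reliable, which variants are plausibly pathogenic, and —
less obviously — which *genes* the assay can report on at all. This package
implements the full chain, from raw per-sample variant tables to per-gene
interpretability calls and exact cohort statistics, with a synthetic-data
generator standing in for protected patient genomes.

## Quality calibration from replicate concordance

Platform-provided variant quality scores are calibrated by sequencing two
tissues of the same individual and measuring genotype concordance as a
function of the quality threshold (`genotype_concordance()`,
`sweep_thresholds()`). At a threshold *t* the comparison universe is the set
of sites of the class (SNV or indel) called at quality ≥ *t* in both
replicates; concordance is the fraction of the universe with identical
genotypes, and the excluded fraction is reported alongside so the
sensitivity cost of a threshold is visible. An empty universe yields `NA`,
never 0. When several individuals contribute pairs, the sweep averages the
per-pair rates (averaging pooled sites instead would weight individuals by
their call counts; the per-pair average is reported because calibration
panels are deliberately balanced, and the alternative is a one-line change
on the sweep output).

The default filter (`qc_config()`) retains SNVs only when **both** allele
qualities are ≥ 100. The defining phrase for this filter — excluding SNVs
with quality below 100 "for both alleles" — admits a lenient reading
(exclude only when both fail); we default to the strict reading, which
matches the high-specificity intent of clinical reporting, and expose
`snv_rule = "lenient"` for the alternative. The indel bound is exclusive
(quality must be **> 150**; exactly 150 is excluded), following the verbatim
inclusion rule it implements. Hemizygous calls compare their single allele
quality alone. Two invariants hold by construction and are tested: raising
any threshold never grows the retained set, and retained + excluded = input
per class.

## PPV and LoF definitions

`select_ppvs()` composes four predicates: quality pass, nonsynonymous
consequence, rarity, and panel membership. Rarity (`is_rare()`) requires
every *present* reference-panel frequency to be below the threshold
(default 1%, exclusive); a variant absent from a panel passes that panel,
so novel variants are rare by definition and the novel fraction remains a
measurable output rather than an artifact of zero-filling. Consequences are
taken from the upstream annotation and never recomputed: this pipeline
interprets call sets, it does not annotate them, and the splice-disruption
window is therefore whatever the annotator used.

LoF classification (`classify_lof()`) is deliberately narrow: nonsense,
splice-disrupting, misstart and nonstop SNVs (`lof_snv`) and frameshift
indels (`lof_indel`); in-frame indels are never LoF. The three analysis
modes (`all` ⊇ `lof` ⊇ `lof_snv`) are nested by construction, which drives
the monotonicity properties tested throughout.

## The gene-variance analysis

For gene *g* and cohort *c*: carrier fraction `f_gc = k_gc / n_c` (distinct
individuals with ≥ 1 PPV) and carrier burden `b_gc = m_gc / n_c` (mean PPVs
per individual). Both are reported because they answer different questions:
the fraction drives interpretability, the burden drives the gene-variance
plots. A gene is *clinically interpretable* iff its carrier fraction in the
pooled control cohort(s) is **strictly below** the threshold (default 2%):
since PPVs are < 1% variants, heterozygous carriers of any single true rare
variant should occur in < 2% of individuals, so a control cohort exceeding
that reveals recurrent background (large mutational target, population
stratification, or platform artifacts) that would generate false-positive
reports. Exactly-2% is *not* interpretable, matching the strict reading of
"less than 2%". Genes with no PPVs in any cohort are included and count as
interpretable: an assay that never fires on a gene is trivially reportable
for it.

`percent_interpretable()` summarises a panel net of an exclusion set. Two
kinds of exclusion exist and are kept separate: the panel's own
`excluded_genes` (recurrent artifact genes — e.g. a frameshift deletion
called at high frequency in *every* cohort and unconfirmable by orthogonal
sequencing — configured on the panel so they never enter selection at all)
and `variance_config(exclude_genes=)` (default `BRCA1`/`BRCA2`), genes
whose control-cohort carrier fractions are inflated by the control cohort's
own diagnostic mutations and which would otherwise distort the percentage.
Both defaults are explicit configuration, not hard-coded behaviour.

`coding_size_correlation()` reports the squared Pearson correlation of
per-gene PPV counts with coding length. A high r² is the signature of
background load (bigger targets collect more rare missense variants); its
collapse under the LoF restriction is the main evidence that LoF PPVs carry
signal rather than target size. Zero variance in either vector yields `NA`,
not 0. A variant annotated to two overlapping genes counts once per gene,
so per-gene counts sum to at least the total PPV count.

## Exact statistics

Binomial confidence intervals are exact Clopper–Pearson, computed through
the beta-quantile form of the inverted tail sums. This construction was
validated, rather than assumed: the interval for 17 successes of 82 trials
reproduces 12.6–31.1% at one-decimal precision, the worked value the
analysis reports, and tests compare every interval with margins ≤ 30
against direct bisection of `choose()`-based tail sums. Fisher's exact test
uses the two-sided probability-mass rule (sum of hypergeometric
probabilities ≤ the observed table's, with a 1e-7 relative tolerance
absorbing floating-point ties — the dominant convention and the one
`stats::fisher.test` implements); tests verify exact agreement with full
enumeration over all tables with row margins ≤ 30. Reported percentages are
rounded half-up to one decimal.

Detection-rate accounting (`confirm_clinical_mutation()`,
`detection_rate()`) distinguishes four states. Mutations of category CNV or
IVS are `not_expected`: a short-variant pipeline cannot see them and they
are removed from the denominator rather than counted as misses. Matching is
exact on (gene, chrom, pos, ref, alt) after normalization — no fuzzy
windows — because confirmation must be deterministic and auditable.

## The synthetic-data generator

`generate_cohort()` emulates the structure the analysis assumes, under its
default *study conditions*: cohorts of 88 + 88 carrier and 82 non-carrier
samples; per-gene background missense counts Poisson with mean
`missense_rate × coding_length`, with coding lengths log-normal
(median 1.5 kb, sdlog 0.8) and the default rate 2.8 × 10⁻⁵ per bp per
individual chosen so an individual carries roughly seven rare missense
calls across a panel-scale gene set, the burden a clinical WGS analysis of
~160 genes reports; a novel fraction of 46.33%; and non-novel frequencies
drawn from a mixture with 90% of its mass below 1% (correlated between the
two panels through a shared latent frequency), so the rare-variant filter
passes most simulated variants by construction. Planted LoF variants are
placed in exactly `floor(π·n)` distinct samples of their cohort — planting
the count rather than Bernoulli carriers makes parameter-recovery tests
sharp — with qualities drawn from the same quality law as background calls,
so the quality filter can genuinely lose planted carriers.

`generate_replicate_pair()` shares one true genotype vector between two
replicates; each call draws a quality from `q_law` (default: a beta-shaped
law over 0–300 concentrated near 230) and is corrupted with probability
`error_rate(q)` into one of the two other states (reference, het, hom)
uniformly; corruption to reference removes the call, which is how real
replicate discordance includes missing sites. The error law defaults to a
logistic in q; only monotone non-increase is contractually required, since
concordance data constrain the shape only weakly. The uniform-corruption
model was chosen because its concordance has a closed form (under ε ≡ 0.5
the expected concordance over the both-called universe is 5/9), giving the
tests an independent oracle.

What the generator does **not** emulate — linkage disequilibrium, sequence
context, population stratification, platform-specific indel error profiles,
overlapping genes — bounds what passing tests show: they validate the
pipeline's logic and statistics, not the biology of any particular cohort.
Counts that depend on the real genomes (total PPV loads, observed percent
interpretable on the clinical panel, real concordance rates) are therefore
exercised as *properties* on synthetic cohorts, while everything derivable
from the published tables (panel composition, detection accounting, the
per-patient LoF findings, the 17/82 interval) is reproduced exactly from
packaged fixtures whose coordinates and qualities are synthetic
placeholders.

## Numerical and design choices

- Coordinates are 1-based VCF-style; `"-"` alleles are permitted only in
  the masterVar-like TSV dialect; the VCF dialect requires anchor-base
  indels. Key names for the VCF annotation fields are configurable.
- Parsers never drop rows silently: every input row is either a validated
  call or a line-numbered rejection (`rejected_rows()`).
- X-linked hemizygous calls count like heterozygous carriers for burden
  purposes; no compound-heterozygote logic is attempted (carrier status is
  what is reported).
- Ties at thresholds are resolved strictly and documented per filter
  (SNV ≥ 100 inclusive; indel > 150 exclusive; interpretability < 2%
  strict).
- Empty comparison universes, zero-variance correlations and empty score
  summaries return `NA`/empty results, never 0.
- `run_pipeline()` regenerates all reports wholesale; identical inputs give
  byte-identical outputs, and all simulation is seeded through
  `sim_config(seed=)`.

Test and simulation problem sizes (cohorts of tens of samples, 30–200
genes, 100–2000 replicate sites, 100-seed recovery loops, exhaustive oracle
enumeration up to margins of 30) were chosen so the full suite documents
each property with comfortable Monte-Carlo margins while remaining quick to
run on a laptop.

## Known limitations

The pipeline interprets annotated short variants only: no CNV or intronic
IVS detection, no transcript-model annotation, no liftover, no pedigree or
segregation analysis, and no in-silico pathogenicity prediction (the
optional score column is summarised per consequence class, nothing more).
The interpretability rule is a reporting-specificity device, not a
pathogenicity classifier: restricting to LoF modes raises specificity
mostly by emptying genes of PPVs, at a known cost in sensitivity that the
mode-nesting makes explicit.
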
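---
title: "Methods: paired crossover safety analysis of mucosal proteome and microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired crossover safety analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomics)
```

## The design and what the package computes

`crossomics` implements the statistical layer of a placebo-controlled,
two-formulation crossover safety study in which each of six subjects serves
as their own control. Two assays are analysed:

* a **label-free proteomics** table (382 proteins at the defaults) measured
  at four baseline time points plus pre-gel, 2 h and 24 h swabs for every
  arm x formulation cell, with technical replicates of a pooled reference;
* a **16S taxon count** table (~120 taxa, mean depth 58,671 reads) at two
  study baselines plus pre-gel, 24 h and 7 d swabs per cell, accompanied by
  14 positive-control replicates of one mixed specimen.

Every question is asked *within subject*: a post-gel sample against the
subject's baseline reference, or active arm against placebo at the matched
time point. A single comparison registry (`proteome_comparisons()`,
`microbiome_comparisons()`) encodes these pairings so the two assay
pipelines cannot drift apart. For the microbiome's "vs baseline"
comparisons the paired control is the subject's **pre-gel (t0) swab from
the same application**: it is paired within application, collected after
washout, and avoids an arbitrary choice among the study-baseline swabs.
The registries are plain tibbles, so other pairings are a `filter()` away.

## Proteome pipeline

The stages run in a fixed order: total-signal normalization, the
technical-replicate CV filter, median-profile normalization, the outlier
report, baseline averaging, then log2 paired testing with
Benjamini-Hochberg control.

**Normalization.** `normalize_total_signal()` rescales each sample so all
totals equal the cross-sample mean. `median_normalize()` then regresses
each sample's intensities on the across-sample median profile *without an
intercept on the raw intensity scale* and divides by the fitted slope. Two
choices deserve comment:

* The raw-scale fit was chosen over a log-scale fit because a no-intercept
  regression in log space is not invariant to the arbitrary overall
  intensity level (a common rescaling of the whole matrix changes all
  log-scale slopes), which makes the correction drift; the raw-scale fit
  is equally a pure per-sample rescaling, undoes a constant multiple of
  the profile exactly, and leaves the refit slope at exactly 1.
* Equal totals and unit median-profile slopes are *competing* constraints
  — two conditions per sample but only one scale factor — so no
  normalization can satisfy both at once. The pipeline applies the steps
  once, in the order above, and the later, finer correction (the median
  fit) is the one left exactly satisfied. Re-running the pipeline on
  identical input is bit-identical.

**CV filter.** Proteins whose coefficient of variation across the pooled
reference's technical replicates is 25% or more are removed
(`filter_by_replicate_cv()`, threshold configurable); the dropped set and
its CVs are attached to the result.

**Outliers.** `flag_outlier_samples()` reports samples whose total
normalized abundance falls outside `median ± 1.5 × IQR` (the literal
per-sample rule; Tukey's quartile fences are available via
`fence = "quartile"`). Outliers are *reported, never removed* — dropping a
sample would break the longitudinal pairing.

**Testing.** For each comparison, per-subject log2 ratios of treatment
over reference are formed (the reference is the arithmetic mean of the
subject's baseline samples, or the matched placebo sample for arm-vs-arm
contrasts), a two-tailed paired t test is applied per protein, and
q-values are computed by Benjamini-Hochberg within the comparison
(significant at q < 0.05). Protocols in this field sometimes describe
this step as a "local FDR" while naming Benjamini-Hochberg; the package
follows the named method, which controls the global false-discovery
rate. Proteins with a zero or missing intensity in a
needed ratio are excluded from that comparison with a warning rather than
imputed: in a six-subject design a fabricated value can dominate a test.
Proteins whose ratios are identically zero are reported with p = 1.

**Power.** `detectable_log2fc()` inverts the noncentral-t power function
for the paired design. At n = 6, alpha = 0.05 and power 0.8 the
standardized bound is 1.43; the generator's default within-pair sd of
1.603 log2 units was chosen so the design's detectable change is |2.3|
log2 — the package's reference operating point, exercised as a
Monte-Carlo property in the tests.

**Clustering.** `hierarchical_cluster()` uses 1 − Pearson correlation
with complete linkage. When baseline samples are clustered together with
post-gel samples the input should *not* be baseline-normalized (the
baseline columns would be artificially compressed); the function clusters
whatever matrix it is given, so this is the caller's contract, stated
here and in the help page. Trees export to Newick via `as_newick()`.

## Microbiome models

**Filtering.** `filter_taxa()` retains taxa with study-wide mean relative
abundance above 1e-5, detection in at least 25% of all samples, and — per
comparison — detection in at least 4 subjects. Relative abundances use
the recorded per-sample totals, which makes the filter idempotent.

**Diversity model.** Shannon diversity `H = -Σ p ln p` is bounded by
`ln(n_taxa)`, so `H / ln(n_taxa)` (Pielou-style evenness scaling — the
bound is the only natural scale available once the taxa set is fixed) is
mapped through a logit, clamped at 1e-6 from both ends. Paired transformed
values are modelled as

    yT_i ~ N(muT_i, sigmaT),  yC_i ~ N(muC_i, sigmaC),
    muT_i - muC_i = Delta.mu_i ~ Laplace(mu, sigma)

taken literally as displayed: each pair contributes one observation per
arm and its own free means, so the arm-level scales are weakly identified
and the heavy-tailed Laplace does the pooling across pairs. Priors are
weakly informative — N(0, 5) on locations, half-N(0, 2.5) on the three
scales (truncated below at 1e-3 for numerical stability). The posterior
of `mu` is the reported diversity effect.

**Measurement-error calibration.** The 14 positive-control replicates of
one fixed specimen estimate how technical noise grows as a taxon gets
rarer: per taxon detected in every replicate, the median `m` and variance
`v` of its log10 relative abundance are computed and `log10 v` is
regressed linearly on `m` (the simplest monotone form; a spline is not
justified by ~tens of calibration points). The returned
`sigma(m) = sqrt(10^(a + b m))` is floored at 1e-3 and a positive slope —
which would claim abundant taxa are noisier — is clamped to zero, so the
mapping is monotone non-increasing by construction.

**Abundance model.** For each taxon and comparison,

    yT_i ~ Bin(nReadsT_i, pT_i),    yC_i ~ Bin(nReadsC_i, pC_i)
    log10 pT_i ~ N(log10 tpT_i, sigmaT_i)
    log10 pC_i ~ N(log10 tpC_i, sigmaC_i)
    Delta_i = log10(tpT_i / tpC_i) ~ N(effect, sd_delta)

with `sigmaT_i`, `sigmaC_i` evaluated from the calibrated error model at
the taxon's median observed log10 abundance within the respective arm
(per-observation evaluation is available via `sigma_per`). The latent
log10 proportions are truncated just below 0 so `pT_i < 1`; all modelled
taxa are far below 10% relative abundance, so the truncation is inert.
Priors: N(0, 1) on `effect`, half-N(0, 1) on `sd_delta`, and a
logit-scale N(logit(pooled observed proportion), 2) prior on the true
control proportions. The posterior mean of `effect` — the mean of log10
ratios of true relative abundances — is the reported effect size; a
posterior mean of 0.301 corresponds to a 2-fold change.

**Posterior p-values and multiplicity.** The two-sided tail
`2 min(P(effect > 0), P(effect < 0))` is estimated from the draws when
the minority tail contains at least one draw. Below that resolution
(1,500 retained draws at the default settings, so 1/1500) a raw
empirical tail would cap p at 6.7e-4 — and after Benjamini-Hochberg over
~100 taxa no taxon could ever reach the study's q < 0.01 line, which
observed q-values many orders of magnitude smaller show is not how such
p-values are produced in practice. The tail is therefore refined by a
normal approximation to the effect's posterior, capped at the empirical
resolution and floored at 1e-16. q-values are Benjamini-Hochberg within
each comparison; significance is q < 0.01.

**MCMC.** Both models run 3 chains of 10,000 iterations with thinning 10
(`mcmc_settings()`). The first half of each chain is discarded as
warm-up — split between the engine's adaptive phase and a plain burn-in,
so sampling never starts mid-adaptation — and the remainder is thinned,
retaining 500 draws per chain. The test suite uses a fast profile
(3 × 2,000, thin 2) that retains the same number of draws from shorter
chains. Convergence is monitored by the potential scale reduction factor
`sqrt(((n-1)/n W + B/n)/W)`; fits above 1.1 on the headline parameter
carry a non-convergence flag and warning. With 500 retained draws per
chain the PSRF estimator's own Monte-Carlo noise is of order a few
percent, so occasional flags at the fast profile are expected and are
surfaced rather than hidden. `sample_posterior()` also accepts any
log-density function, sampled with an adaptive componentwise random-walk
Metropolis kernel (proposal scales tuned toward 44% acceptance during
warm-up, then frozen); the suite uses it as an independent engine to
cross-check the JAGS fits of both models on the same posteriors.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
external data; its defaults *are* the study conditions above. What it
emulates, and what it does not:

* **Proteome** (`gen_proteome_study()`): protein-level log2 means spread
  over ~4 orders of magnitude; subject offsets (sd 0.25 log2); i.i.d.
  Gaussian sample noise whose within-pair difference sd is 1.603 log2
  (the power operating point); planted log2 fold changes applied only at
  the configured arm/formulation/time point; 9 technical replicates of
  the pooled reference with 10% CV plus optional high-CV decoys. It does
  not emulate correlated protein modules, missingness structure, or
  intensity-dependent variance.
* **Microbiome** (`gen_microbiome_study()`): long-tailed mean
  rank-abundance profile (log10 sd 1.0); per-subject baseline
  compositions (log10 sd 0.3); diagonal logistic-normal per-sample noise
  (log10 sd 0.15 — a realistic day-scale within-subject fluctuation for
  rectal taxa); planted effects multiply proportions by `10^ratio` before
  renormalization, with a guard rejecting configurations whose perturbed
  mass exceeds 1; depths are log-normal around the mean depth (dispersion
  0.3; 0 gives exact depths) and counts are multinomial, so every column
  sums to its recorded depth. Crossover carryover is deliberately absent:
  observed effects resolved within the washout period, so truth carries
  no carryover term. Zeros occur naturally; the truth object records true
  proportions so recovery checks never divide by zero.
* **Positive controls** (`gen_positive_controls()`): replicates of one
  fixed composition with log10 noise
  `sigma(m) = 0.05 + 0.1 · max(0, -2 - m)`, i.e. a floor of 0.05 for
  abundant taxa rising as abundance falls below 1%, plus multinomial
  counting noise — giving the calibration a recoverable target.

A consequence worth stating: with the default within-pair noise, a
planted log10 ratio of 0.35 at n = 6 is *estimated* accurately (the
posterior mean lands within ±0.15 in the recovery tests) but typically
does not reach q < 0.01 — the honest power of that design at that noise
level. Comparisons on quieter data (per-sample noise ≲ 0.05 log10, as in
several end-to-end tests) do cross the 1% FDR line. Passing tests
therefore demonstrate parameter recovery, calibration and specificity
under the stated noise model, not that any particular real dataset would
yield significant taxa.

## Problem sizes and numerical choices

The test suite and the acceptance script scale the Monte-Carlo work to
what the statistics require rather than to the full study: null
calibration uses 200 replicate 382-protein studies; power checks use
500-2,000 replicates; model-recovery checks use 20 seeded fits at the
fast MCMC profile; FDR behaviour under the null uses 50 replicate
6-taxon panels; the end-to-end crossover run uses 40 taxa across the
24 h comparisons. Degenerate inputs are rejected loudly rather than
patched: zero-variance paired differences, zero-total samples, constant
median profiles, all-zero arms, and Shannon inputs that do not sum to 1
all raise errors naming the offender (the one deliberate exception:
all-zero *ratios* in a comparison report p = 1, since "nothing changed"
is a valid finding). Ties in BH adjustment follow the step-up definition
exactly; quantiles use R's default type 7; all seeds flow through
function arguments, and generation and inference are deterministic given
a seed.

## Known limitations

* The diversity model is fitted as displayed, with per-pair free means;
  its arm-level scales are informed mostly by their priors at n = 6.
  This is faithful to the described model, not a modelling
  recommendation.
* The measurement-error law is linear in `log10 v` vs `m`; strongly
  curved variance profiles would be mis-fit (the calibration table and
  `autoplot()` make this visible).
* The posterior-tail p-value below the empirical resolution leans on a
  normal approximation of the effect's posterior; for 6 pairs this is
  mildly anti-conservative in the extreme tail, which is where it is
  only used to order already-overwhelming effects.
* The proteomics stage starts from a protein-level intensity table;
  spectral processing, identification and protein inference are upstream
  and out of scope, as are functional-enrichment analyses that require
  external databases.
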
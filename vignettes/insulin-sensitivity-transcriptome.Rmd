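---
title: "Discovering and validating an insulin-sensitivity transcriptome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating an insulin-sensitivity transcriptome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreis)
```

# The problem

Fasting insulin sensitivity (IS) varies continuously across people and sits
at the centre of metabolic disease. Finding the genes whose skeletal-muscle
expression tracks IS is hard for two compounding reasons: expression arrays
quantify transcripts through probes that may be stale (mis-mapped, dim, or
chemically awkward), and IS itself is entangled with covariates such as age
and adiposity, so the association model and the order of its terms change
the answer. This package implements, as reusable and tested functions, a
pipeline that addresses both: probe-level filtering feeding a custom chip
definition, covariate-adjusted per-cohort association, cross-cohort
meta-analysis with a directional filter (the *CORE-IS* list), and an
intervention layer asking whether per-subject expression changes track
per-subject IS changes (the *Delta-IS* selection). Every stage runs on
synthetic data with planted truth, so the whole chain is verifiable without
any external download.

# Quantification: probe filters, chip definition, summarization

Probes are dropped by three independent criteria, and the retained ones are
regrouped into probe-sets:

1. **Genomic uniqueness** — a probe must align to exactly one genomic
   location (`map_count == 1`); probes aligning nowhere or to several loci
   cannot be attributed to a single transcript.
2. **Signal** — across the arrays of the experiment at hand, a probe must
   show a mean linear intensity of at least 10 units with a coefficient of
   variation of at most 25%. Both thresholds are tissue- and
   experiment-dependent knobs (`min_mean`, `max_cv`), which is why the chip
   definition is rebuilt per study rather than taken from the vendor.
3. **GC content** — probes with a GC fraction outside [0.20, 0.80] are
   removed because intensity-correction models behave nonlinearly at the
   extremes. The boundaries are inclusive-retain: exactly 0.20 or 0.80
   survives, since removal is specified by strict inequalities.

The filters are pure set intersections, so their order is immaterial (a
property the tests exercise). Surviving probes are grouped by target
transcript; only groups of `min_probes >= 3` become probe-sets. Expression is
then quantified by quantile normalization (every array is mapped onto the
mean sorted profile) followed by median polish of each probe-set's log2
intensities — the RMA-style robust additive fit
`value ~ overall + probe + sample`, iterated row/column median sweeps with
tolerance 1e-8 and at most 20 iterations. The probe-set expression of sample
*j* is `overall + sample_j`; residuals feed array QC. A plain mean
summarizer is available behind `method = "mean"` for comparison. Background
correction is deliberately not modelled: the filter cascade removes the
probes for which it would matter most, and the synthetic chips have no
spatial or optical structure.

Array quality is scored by NUSE (normalized unscaled standard error): each
probe-set's per-sample SE is estimated from the median-polish residuals,
scaled to a cross-sample median of 1, and each array is summarized by its
median scaled SE. The outlier cutoff of 1.05 is common practice for
PLM-based QC; it is a package default, not a published constant, and is
configurable. With few probe-sets (hundreds rather than tens of thousands)
the NUSE distribution is noticeably wider, so small simulations can flag a
few healthy arrays; the pipeline simply drops flagged arrays.

When one gene is represented by several probe-sets, the gene-level matrix
keeps the probe-set with the highest mean expression (ties break to the
lexicographically smallest id, for determinism).

# The IS phenotype

IS is quantified as `log10(S%)`, where S% is the insulin-sensitivity
percentile from homeostasis-model assessment of fasting insulin
(pmol/l) and glucose (mmol/l). The genuine second-generation HOMA model is
an iterative computer program that has never been published in closed form,
so the package uses the classical closed-form stand-in

\[ \mathrm{HOMA} = \frac{(I/6.945)\,G}{22.5}, \qquad S\% = 100/\mathrm{HOMA},
   \qquad \mathrm{IS} = \log_{10} S\%, \]

documented as such, with an override (`s_percent_column`) so that values
computed with the real HOMA2 software can be injected. The stand-in is
monotone in both inputs and rank-equivalent to the real model over the
physiological range, which is what the downstream rank- and
correlation-based analyses consume; its absolute values differ from HOMA2
(the model's nonlinear corrections are the point of HOMA2), and no test
asserts agreement. Records outside the model's operating range (defaults
insulin 20--400 pmol/l, glucose 3--25 mmol/l, mirroring the published
calculator's accepted ranges) are excluded from association with a logged
reason rather than winsorized.

# Association and meta-analysis

Per cohort and per gene, the package fits the two bivariate sequential
(Type I) ANOVA models `expression ~ IS*age` and `expression ~ IS*BMI` — the
interaction is always included, its p-value reported but not used for
selection. Sequential decomposition means the variance shared between IS and
the covariate is credited to whichever enters first; `order = "cov_first"`
exposes the covariate-first variant because that order dependence is itself
a finding worth reproducing (see below). The genome-wide scan
(`fit_bivariate_scan`) orthonormalises the design once by QR in column
order, which reproduces the sequential decomposition exactly; it is verified
against both `anova(lm(...))` and a naive normal-equations implementation to
1e-10.

Per-study IS p-values are combined across cohorts per model with the
unweighted Stouffer method, \(Z = \sum_i \Phi^{-1}(1-p_i)/\sqrt{k}\) (a
weighted variant is available but off by default: no weighting scheme is
specified by the design being emulated), and each model's meta p-values are
BH-adjusted. A gene is **CORE-IS** when it passes the FDR threshold (default
10%) in *both* models and its univariate correlation with IS keeps one
strict sign across the required studies (default: the four largest by sample
count). The both-model requirement is the stricter of the two readings and
is the default; `both_models_required = FALSE` gives the other. The
directional filter uses univariate Pearson correlations, not model
coefficients; a zero correlation in any required study breaks consistency.
F-test p-values are direction-blind, so directionality is enforced entirely
by this second stage.

# Intervention layer

For each paired pre/post study, per-subject log2 fold changes of the
candidate genes are computed, paired-t differential expression is run
(per-study p-values meta-analysed by Stouffer + BH), and each gene's fold
change is Spearman-correlated with the subject's change in log-IS. A gene is
**Delta-IS** when that correlation's sign is strictly nonzero and concordant
with the gene's baseline direction in *every* study — the weakest, sign-only
reading of "consistently correlated"; a `min_abs_rho` knob adds a magnitude
threshold when wanted. The count *k* of selected genes among *n* tested
across *s* studies is scored by the upper cumulative binomial tail with null
per-gene probability \(p_0 = (1/2)^s\): under no association each study
contributes an independent fair sign. That null is the package's own,
documented choice; other nulls (e.g. requiring per-study significance before
counting) would give different tails, and the package makes no claim to
reproduce any particular published probability.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every property above is checked.

* **Chips** (`chip_design`, `simulate_chip`): live probes measure
  `gain x abundance x affinity x noise`, with a fixed per-probe log-normal
  affinity (sequence-dependent binding) and log-normal measurement noise
  (CV 10%). Planted violations: *dead* probes draw from background only
  (linear mean 5, below the 10-unit floor); *multi-mapping* probes
  cross-hybridise, adding the abundance of the other loci they map to;
  *GC-extreme* probes respond with a compressed dynamic range. Default
  planted fractions 0.15/0.10/0.10 put roughly a third of probes in
  violation, the scale of attrition seen when such filters are applied to
  real high-density arrays.
* **Cohorts** (`cohort_params`, `simulate_cohorts`): per subject, log-IS is
  drawn from a truncated normal (mean 1.8, sd 0.25 on the log10 S% scale — a
  median S% near 80 with a several-fold range, typical of mixed-fitness
  adult cohorts) inside the window compatible with the insulin/glucose
  operating ranges; glucose is uniform in 4.0--6.5 mmol/l and insulin is
  back-solved through the stand-in formula, so the phenotype module
  reproduces the planted IS exactly and no record falls outside range. BMI
  couples to log-IS through a bivariate Gaussian with correlation -0.4
  (heavier, less sensitive); age is independent. Planted genes follow
  `y = alpha + d * r * sigma * z_IS + sigma * sqrt(1-r^2) * eps` with
  per-gene residual sd 0.25 log2 units — typical array-scale biological
  variation, and coherent with the 25% linear-CV probe filter. `effect_r`
  may be a scalar or a range; a range draws each planted gene's |r|
  uniformly, emulating a continuous effect-size distribution.
* **Interventions** (`intervention_params`, `simulate_intervention`):
  per-subject IS change is normal (mean 0.15, sd 0.20 — interventions help
  on average, some subjects worsen). Planted delta genes' fold changes load
  on the standardized IS change with Pearson coupling \(2\sin(\pi\rho_S/6)\),
  so the population Spearman correlation equals the requested `delta_rho`
  under the Gaussian copula; the sign matches the gene's baseline direction.
  The planted fraction defaults to 0.25 of the directional pool: neither a
  published design fraction exists nor is one recoverable from reported
  outcomes, and a quarter keeps both precision and recall of the
  sign-consistency selector estimable against its \((1/2)^s\) chance
  background.

What the generator does **not** emulate: batch and site effects, array
spatial artifacts, assay-specific insulin calibration differences,
non-Gaussian expression tails, and correlation *between* genes. Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the stated model — not that real cohorts are free of the
confounders the generator omits.

# Numerical and design choices

* Probe CVs are computed on the linear intensity scale (matching the filter
  definition); the signal filter is computed from the sample set being
  analysed, and the chip definition records it in its provenance.
* Duplicate probe-to-target assignments are an ingest error, never silently
  resolved.
* Stouffer inputs are clamped to [1e-300, 1-1e-16] with a warning; exact 0/1
  p-values otherwise break the quantile transform.
* Degenerate fits (zero-variance response, numerically perfect fit) are
  flagged; p-values are forced to 1 and 0 respectively rather than NA.
* The binomial tail uses `pbinom`'s log-space-stable machinery rather than
  term summation; tests compare it against exhaustive enumeration.
* All randomness flows through explicit seed arguments; generators save and
  restore the caller's RNG state, and the pipeline derives per-stage seeds
  from one master seed, making a run a pure function of (config, seed).

# Problem sizes used in the shipped analyses

The analysis drivers and the acceptance script run at desk scale, chosen so
each analysis completes in seconds-to-minutes on one CPU while keeping the
planted signal comfortably estimable: 2000 genes and six cohorts of 80--190
subjects for discovery (null calibration uses 12--20 replicates of the same
shape), 1000 genes with frac_is 0.15 and |r| ~ U(0.05, 0.25) for the
covariate-order experiment (the order effect lives on near-threshold genes;
with one strong common effect size nothing sits near the threshold and the
phenomenon vanishes), 200 candidate genes x 4 studies x 40 pairs for the
intervention layer, and a 200--400-gene probe-level chip for the end-to-end
pipeline. Real-scale inputs (tens of thousands of probe-sets) change memory
and time, not code paths.

# Known limitations

* The closed-form HOMA stand-in is rank-faithful but not value-faithful to
  the iterative HOMA2 model; absolute S% values should come from the real
  calculator when available.
* NUSE's 1.05 cutoff assumes thousands of probe-sets; small chips flag more
  healthy arrays.
* The sign-only Delta-IS null assumes independent studies and exchangeable
  signs; correlated interventions would need a permutation null.
* Cross-assay insulin calibration is carried as metadata only; cohorts are
  always analysed separately and combined at the p-value level, which is
  what makes that defensible.
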
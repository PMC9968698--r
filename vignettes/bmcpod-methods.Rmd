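---
title: "Methods: benchmark-concentration PODs from DIMS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark-concentration PODs from DIMS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `bmcpod`, in the order data flows through the workflow.

## What the synthetic generator emulates

Direct-infusion MS (DIMS) toxicometabolomics studies expose a cell line to
a chemical along a geometric dilution series and profile the metabolome at
one or more sampling times. `build_design()` reproduces the canonical
layout: seven concentrations at a 2.5× ratio (50 → 0.2048 µM, or 10 →
0.04096 µM for a more potent chemical), a vehicle control, 3 technical ×
3 biological treated replicates per concentration (9 samples per group),
27 vehicle controls per time point, pooled QC samples interleaved through
the run, and extraction blanks at the sequence edges. Batches are
contiguous acquisition blocks.

`simulate_intensities()` draws lognormal intensities around per-feature
curves planted on the **log-intensity scale**: responsive features follow a
Hill curve `b0 + v·d^n/(k^n + d^n)` or a saturating exponential
`b0 + v·(1 − e^{−d/k})`, null features are flat, and blank-only features
model extraction contaminants (present in blanks, at low level elsewhere).
Because multiplicative lognormal noise becomes additive Gaussian noise
after log transform, every responsive truth has an analytic 1 SD benchmark
concentration, recorded in the truth sheet. Defaults: noise `sdlog = 0.1`
(≈10% RSD, the mid-range of QC precision for well-behaved DIMS assays);
baseline abundances 10⁵–10⁷ counts; effect sizes 0.6–1.5 log units
(6–15 σ at the asymptote). These magnitudes are a modelling choice — the
kind of study this emulates reports only a ≤30% QC mRSD quality envelope,
not per-feature noise — and they are deliberately not revisited per test.

`apply_artifacts()` overlays what the cascade must remove: a ppm
mass-accuracy error curve over acquisition order (default linear +2 → −2
ppm) applied to the per-sample observed m/z, within-batch multiplicative
signal drift, intensity-threshold dropout (the DIMS detection mechanism,
hence missing-not-at-random; an MCAR fraction is available for tests), and
the spiked internal standard — tryptophan-d5 observed as [M+H]⁺, its m/z
derived from the formula `C11H7D5N2O2` through the annotation module
rather than hard-coded.

What the generator does **not** emulate: raw spectra (isotopologues,
centroiding, peak shape), chromatography, correlated feature blocks from
shared pathways, and adduct/fragment degeneracy of a single metabolite.
Passing tests therefore demonstrate correctness of the pipeline's
contracts on clean ground truth, not performance on any real dataset.

## The preprocessing cascade

Steps run in the order: mass-drift correction → IS outlier removal → blank
subtraction → presence filter → sparse-sample filter → QC presence filter
→ signal/batch drift correction → PQN → QC RSD filter → (kNN imputation →
glog → mean centring → PCA outlier removal). "Present" and "detected" mean
a non-missing value — in DIMS, missingness is the detection proxy — and
all keep/remove boundaries are inclusive on the keep side.

Decisions worth recording:

* **Mass-drift correction.** The internal standard's per-sample ppm error
  against its theoretical m/z is modelled over acquisition order with
  `smooth.spline(cv = TRUE)`, whose smoothing parameter minimises
  leave-one-out cross-validated error; all observed m/z in a sample are
  divided by the modelled relative error. Below five usable IS points the
  model degrades to a constant (median) correction, with a warning.
* **IS outlier rule.** Literal 3 × median absolute deviation, unscaled (no
  1.4826 consistency constant), applied separately to the study stratum
  (treated + controls) and the QC stratum; blanks are never scored. The
  rule is iterated to a fixed point, mirroring the practice of re-running
  processing without outliers; this also makes the step idempotent.
* **Blank subtraction.** A ratio rule: a feature detected in blanks
  survives only if its mean study intensity exceeds 20× its mean blank
  intensity (threshold configurable; `Inf` reduces it to presence-only).
* **Signal/batch drift.** Per feature and batch, the QC trend over
  acquisition order is fitted by a GCV smoothing spline whose equivalent
  df is capped at (n_QC − 2), with a straight line below five QC points,
  then divided out and batch levels aligned on QC medians. A locally
  weighted (lowess) fit was rejected: at realistic per-batch QC counts
  (~5–10) it nearly interpolates the QC points, collapsing the apparent
  technical variance to zero and corrupting the downstream
  maximum-likelihood glog λ. The df cap exists for the same reason.
* **PQN.** Reference = median spectrum of the QC samples (median of study
  samples when no QCs exist); each sample is divided by the median of its
  feature-wise quotients against the reference over shared features
  (minimum 10, otherwise the sample is left unnormalised and flagged).
  After normalisation every sample's median quotient is exactly 1.
* **glog.** `y = ln(x + √(x² + λ))`; λ is chosen by maximising the
  Jacobian-corrected Normal likelihood of the QC replicates (features as
  groups, shared variance), searched on a log scale; a fixed λ can be
  supplied. λ ≥ 0 is enforced.
* **PCA outliers.** Hotelling T² on the first two PCs with the
  F-distribution threshold at 95% confidence, computed on imputed,
  transformed, centred data; `conf = 1` removes nothing, and fewer than
  four samples is a warning no-op. One pass by default; when outliers are
  found the whole cascade re-runs once from scratch without them.
* **BMC sub-tables.** `prepare_bmc_groups()` keeps features present in at
  least 4 samples of every concentration group, tightening to 5 when the
  residual per-feature or per-sample missingness still exceeds 50% — the
  imputation that follows tolerates at most 50% missingness.

The cascade returns the **un-imputed** normalised table (missingness still
carries detection information for the group-presence rules) together with
the imputed/transformed PCA branch and an exact per-step filter log.

## Benchmark-concentration modelling

Seven continuous mean functions are fitted per feature by maximum
likelihood under Normal errors with constant variance σ²:

| model | mean function | constraints |
|-------|---------------|-------------|
| linear | γ + βd | — |
| power | γ + βd^δ | δ ≥ 1 |
| hill | γ + νdⁿ/(kⁿ + dⁿ) | n ≥ 1, k > 0 |
| exp2 | a·e^{sbd} | a, b > 0 |
| exp3 | a·e^{s(bd)^c} | c ≥ 1 |
| exp4 | a(c − (c−1)e^{−bd}) | c > 1 (increase), c < 1 (decrease) |
| exp5 | a(c − (c−1)e^{−(bd)^g}) | g ≥ 1 |

with s = ±1 set by the data trend. Fitting is multi-start `nlminb` in a
transformed space (log for positive scale parameters, boxed exponents),
with the Hill and power profiles reduced to low-dimensional searches via
inner least squares, and a 250-iteration cap per start; a fit that never
converges is flagged and excluded from selection. σ̂² = SSE/n is the ML
variance; AIC = 2p − 2ℓ counts the variance as a parameter.

Modelling consumes the glog-transformed, PQN-normalised sub-table
**without mean centring**: the exponential-family mean functions require
positive responses, and centring is only needed on the PCA branch. The BMR
is interpreted as an absolute shift from the modelled control mean,
|m(BMC) − m(0)| = k·σ̂, with m(0) the model's own intercept, not the
sample control mean. All seven mean functions are monotone in dose, so
this equation inverts in closed form for every model; the test suite keeps
an independent grid + bisection oracle to confirm each inversion to 10⁻⁶
relative. Doses beyond 10× the top tested concentration count as "no
solution" (BMC = ∞), which fails the retention criteria.

**BMCL/BMCU** are one-sided profile-likelihood bounds: the extreme BMC
over mean-parameter vectors whose profile log-likelihood is within
χ²₁(0.90)/2 of the maximum (σ profiled out), found by penalised
multi-start optimisation seeded from the MLE and from a randomized scan of
feasible profile points; individual optimiser failures are ignored and the
bound taken over successful points, a flat profile yields (0, ∞) with a
flag. A residual-bootstrap percentile alternative
(`bootstrap_bmc_bounds()`) exists purely as a cross-check.

**Lack of fit** is a likelihood-ratio test against the saturated
group-means model on n_groups − n_mean_params df. The 0.05 threshold gates
model *selection* (only fits with p > 0.05 compete on AIC, ties broken by
fewer parameters then fixed model order); the 10⁻⁴ threshold is the final
*retention* criterion. Hill fits with k below ⅓ of the lowest positive
dose are flagged and excluded from selection — such a k places the
half-maximal response below the tested range.

The screen fits each feature **once**: neither the fits, the AIC nor the
lack-of-fit p depend on the BMR, so the 3 SD and 1 SD passes share the
selected model and differ only in BMC/BMCL/BMCU. Retention requires, at
both BMRs: BMC < top tested concentration, p > 10⁻⁴, BMC/BMCL < 20.
Confidence bounds are computed only when the cheaper criteria can still
pass. The 1 SD BMC is the value carried into POD ranking (the analysis
pass); both are reported.

## POD derivation and annotation

Records are ranked ascending by the 1 SD BMC, ties broken by m/z then
feature id so ranking is canonical and permutation-invariant. Method 1
takes the first-ranked feature; method 2 the first-ranked feature with at
least one putative annotation (one match suffices; multiple matches still
count once); method 3 the n-th-ranked feature with n = 25 by default, a
convention imported from transcriptomics POD practice — annotation status
is ignored for method 3, since the rank list is defined over all retained
features. Unsatisfiable requests (no annotated feature, fewer than n
features, a time point with no retained features) produce an explicit
`undefined` status, and time-course summaries treat them as gaps. PODs
below the extrapolation floor — one third of the lowest tested
concentration — are flagged, never censored.

Annotation converts library formulas to monoisotopic masses from an
embedded IUPAC table (9+ significant figures; deuterium supported) and
derives each adduct shift from atomic and electron masses rather than
storing literals: a cation's m/z subtracts the electron mass, an anion's
adds it. The worked check: the [M+NH4]⁺ adduct of C59H106O6 gives
928.83277 Th, within 0.1 ppm of the observed 928.83266 — omitting the
electron shifts this to ≈0.7 ppm, so the convention is testable. Matching
is boundary-inclusive at the stated tolerance (±5 ppm default) and keeps
all isobaric matches (leucine/isoleucine cannot be separated on m/z
alone).

## Problem sizes and determinism

The bundled analysis and the test suite run a single-chemical,
single-assay study per dataset — 106 samples × ~70–80 features, with 35
responsive features in the analysis scripts — which exercises every code
path while keeping a full run in minutes on one core. Monte-Carlo checks
use 100 simulated features for BMC recovery and 200 replicates for BMCL
coverage. All generators and the pipeline are pure functions of their
seed; identical seeds give bit-identical tables and reports.

## Known limitations

* Constant-variance Normal errors only; no non-constant variance or
  model-averaged BMDs.
* Profile bounds use a soft-penalty search: bounds can be marginally
  conservative (BMCL slightly low) rather than exactly at the likelihood
  boundary.
* The dual p-value gating means a feature whose best-model p lies in
  (10⁻⁴, 0.05] has no selectable model and is excluded via selection
  rather than via the retention criterion; the retained set is identical
  either way.
* kNN imputation uses features as neighbours on the raw intensity scale;
  with very few shared samples the distance degrades to the feature-median
  fallback.
* Annotation is putative by construction: m/z match only, no MS²
  evidence, no adduct deconvolution.
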
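---
title: "Inter-brain synchronization analysis of dyadic joint-attention fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-brain synchronization analysis of dyadic joint-attention fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In hyperscanning fMRI, two interacting participants are scanned
simultaneously, and the question is whether — and where — their brain
activity becomes coupled *because* they are interacting, over and above the
coupling induced by performing the same task at the same times. `dyadsync`
implements the two complementary measures of such coupling for verbally
cued joint-attention (JA) experiments, together with the resampling null
that separates pair-specific synchrony from task-locked synchrony:

1. **Beta-series correlation.** A trial-wise GLM models every trial as its
   own regressor, yielding one amplitude estimate per trial per voxel. The
   ordered per-trial amplitudes form a "beta series"; the Pearson
   correlation between the two partners' series at the same voxel
   coordinates measures trial-by-trial co-fluctuation of task-evoked
   activity.
2. **Residual time-series correlation.** After removing every modelled
   event from the time series (with serial-correlation modelling switched
   off so residual autocorrelation is preserved), the remaining
   "background" signals are correlated per run and averaged (Fisher z)
   within condition type. This captures state-like shared fluctuation that
   is not locked to trials.

Both measures are computed for the real pairs and for every **pseudo
pair** — partner A of pair *i* with partner B of pair *j*, *i* ≠ *j*, all
`P(P-1)` of them (462 for 22 pairs). Pseudo pairs did the same tasks in
the same trial order (all series are reordered to a canonical task order:
first fJA run, second fJA run, first sJA run, second sJA run), so they
share everything except the live interaction. Pair-specific synchrony is
then the contrast *real > pseudo*, tested voxelwise with Welch's
unequal-variance t and corrected at cluster level by permutation.

## The experiment the generator emulates

A session has six runs of 175 volumes at TR 2.5 s — two feature-based JA
(fJA), two spatial JA (sJA), two solo control — in a counterbalanced order,
32 contiguous 12.5 s trials per run (fixation 2.5 s, role assignment
2.5 s, cue–response 2.5 s, fixation 2.5 s, verify 2.5 s), 192 trials in
total. In JA runs the partners swap initiator/responder roles
pseudo-randomly but evenly (16/16); control runs alternate feature and
spatial solo trials in blocks of four (16 fCTRL + 16 sCTRL). Condition
labels are complementary within a pair: when A is the feature-task
initiator (fIJA), B is the feature-task responder (fRJA), and so on;
control trials are identical for both.

Because no raw data accompany the design, `simulate_pair()` provides a
forward model with *known* coupling ground truth:

* per-voxel signal = HRF-convolved 5 s boxcars (role + cue phases) scaled
  by per-trial amplitudes, plus an HRF-convolved verify-phase response,
  plus slow cosine drift (periods > 128 s), plus stationary AR(1) noise;
* inside `task_sync_mask`, and only in JA runs, the partners' trial
  amplitudes share a latent component carrying a fraction `coupling_task`
  of the amplitude variance — so the expected inter-partner amplitude
  correlation equals `coupling_task`;
* inside a disjoint `residual_sync_mask`, again only in JA runs, a shared
  low-frequency (< 0.1 Hz, low-pass-filtered Gaussian) background series
  carries a fraction `coupling_residual` of the noise variance —
  emulating resting-state-like shared fluctuation;
* control runs receive *no* shared components: any synchrony detected
  there is a false positive by construction.

Defaults are the study conditions: 22 pairs, 24×24×24 voxels of 3 mm
(a desk-scale stand-in for a whole brain resliced to 3 mm), amplitude mean
1 and SD 0.5, unit noise SD, AR(1) φ = 0.3, drift component SD 1,
verify-phase amplitude 0.5, couplings 0.6 (task) and 0.5 (residual) in
50-voxel compact blobs. All randomness flows from one master seed through
a counter-based splitter (`split_seed()`), so each participant, run and
component has its own reproducible stream.

What the generator does **not** emulate: head motion, physiological
noise, spatial heterogeneity of the HRF, scanner drift nonstationarity,
inter-regional correlation structure, and anatomical geometry. Passing
tests therefore demonstrate the statistical machinery — estimator
correctness, null calibration, power to recover injected coupling — not
robustness to the full artefact spectrum of real recordings.

## First-level model

`build_design()` produces two designs. The *condition* design concatenates
the six runs: six regressors of interest (fIJA, fRJA, sIJA, sRJA, fCTRL,
sCTRL), events modelled as 5 s boxcars from role-assignment onset
convolved with the canonical double-gamma HRF (delays 6/16 s, unit
dispersions, undershoot ratio 1/6; unit peak, maximum near 5 s), one
verify-phase covariate of no interest, and one intercept per run. The
*trial-wise* design models a single run with 32 individual trial
regressors plus the verify covariate and intercept — 33 task-related
columns, matching the 33 betas (32 of interest + 1 of no interest)
consumed per run by the beta-series analysis.

`fit_glm()` high-pass filters data and design by projection onto the
orthogonal complement of a discrete cosine basis (cutoff period 128 s;
`floor(2·N·TR/cutoff) + 1` columns including the constant — 7 for a
175-volume run). Because the basis contains the constant, intercept
columns are annihilated by the filter and dropped; their effect is
absorbed by the projector (tested against fitting with DCT nuisance
columns appended). With `whiten = "ar1"`, a single AR(1) coefficient is
estimated by restricted maximum likelihood on a pooled voxel set — voxels
exceeding an omnibus-F threshold (p < 0.001) from a first-pass OLS fit,
capped at `pool_max` voxels by deterministic thinning — and both sides are
premultiplied by the exact AR(1) inverse-covariance Cholesky factor
(y*₁ = √(1−φ²)·y₁, y*ₜ = yₜ − φ·yₜ₋₁), making whitened OLS identical to
GLS under the fitted covariance (tested against an explicit-inverse
oracle). No global scaling is applied. `whiten = "none"` preserves
residual autocorrelation and is the setting used for residual-series
extraction.

Design choices worth recording:

* **Concatenated condition fits.** A single run only contains two of the
  six conditions, so the condition GLM must span the session; trial-wise
  fits are per-run. (Both granularities are exposed; the session fit is
  the default for contrasts.)
* **ReML pooling set.** The restricted-likelihood procedure is defined on
  a pooled voxel population; the omnibus-F rule (p < 0.001) selects
  task-responsive voxels, falling back to all non-degenerate voxels in
  tiny simulations. A coarse optimiser tolerance (1e-3 in φ) is used:
  φ precision far below the ±0.05 recovery tolerance costs nothing.
* **Degenerate voxels** (zero variance) get zero betas, are flagged, and
  are excluded from pooling.

## Inter-brain correlation

`assemble_beta_series()` drops control runs, reorders the four JA runs
canonically, discards the no-interest beta and concatenates 4 × 32 = 128
ordered trial betas per voxel. Beta series are *not* re-standardised per
run by default (the betas are already per-trial amplitude estimates);
residual series are demeaned per run, and residual correlations are
computed per run and Fisher-z-averaged within condition type rather than
after concatenation, to avoid spurious correlation from run-boundary
level shifts. "Same coordinates" means identical voxel indices on the
shared grid. The Fisher transform is applied to both analyses (a flag can
disable it); correlations at |r| ≥ 1−ε are clipped at ε = 1e-7.

`enumerate_pseudo_pairs()` pairs the A-role-sequence member of each pair
with the B-member of every other pair. Full enumeration is used (no
subsampling). Within a real pair the role sequences are complementary by
construction, so real and pseudo series align trial-for-trial.

## Group inference

`welch_two_sample_t()` compares real against pseudo Fisher-z maps with
Satterthwaite degrees of freedom; measurements are treated as independent
between groups (participants recur across pseudo pairs — the induced
dependence is deliberately ignored here, as exact dependence-respecting
inference is out of scope). `one_sample_t()` serves the session contrasts
(six-condition weight vectors; the main effect of JA is
(1, 1, 1, 1, −2, −2) over fIJA, fRJA, sIJA, sRJA, fCTRL, sCTRL).
`conjunction()` implements the minimum-statistic conjunction null: a voxel
passes iff every component map exceeds its own height threshold.

`cluster_fwe()` thresholds at height p < 0.001 (t quantile at the map's
df, per-voxel df for Welch maps), labels 26-connected components, and
assigns each cluster the proportion of permutations — observed labelling
included, so the smallest attainable p is 1/n_perm — whose *maximum*
cluster size reaches the cluster's size. Sign flipping serves one-sample
maps, group-label shuffling two-sample maps; fewer than 10 distinct
permutations is refused. Permutation was chosen over random-field theory
as the default and only method: RFT's smoothness estimation is fragile on
small synthetic grids, while permutation is exact under exchangeability at
any grid size. Ties in cluster size are broken by peak t in the report
ordering.

## Numerical and calibration choices

* The 128 s DCT filter annihilates stop-band *basis* components exactly
  (verified to < 1e-10); frequencies between basis lines (e.g. a 256 s
  cosine on a 437.5 s run, which is not a basis frequency of that grid)
  are strongly but not exactly attenuated (> 98% power removal). This is a
  property of any finite cosine basis, not an implementation artefact.
* Cluster-FWE calibration is assessed on spatially smoothed noise
  (FWHM 6 mm at 3 mm voxels): with unsmoothed independent voxels at
  height p < 0.001 the max-cluster-size distribution is nearly degenerate
  at sizes 0–2, making the permutation p heavily tied and very
  conservative; smoothed noise is also the realistic null for cluster
  inference.
* Simulation sizes in the test suite are chosen to keep the whole suite
  runnable on a single CPU in minutes: estimator and calibration checks
  run at 8³–12³ grids; the cohort-level recovery check runs 10 cohorts of
  12 pairs on a 16³ grid with 30-voxel masks and 200 permutations, with
  couplings at the defaults (0.6/0.5). The acceptance script additionally
  runs one cohort at the full default scale (22 pairs, 24³, 50-voxel
  masks, 462 pseudo pairs). Power at both scales is high: the injected
  couplings produce real-pair z-values an order of magnitude above the
  pseudo-pair null.
* Amplitude-coupling leakage: a shared background series inflates
  trial-amplitude estimates' errors in its own mask, so the beta-series
  analysis can show (genuine) secondary sensitivity inside the residual
  mask. The recovery check therefore requires each analysis to detect
  its *own* mask, and requires the control-run residual analysis — a pure
  null by construction — to stay empty.

## Known limitations

* A single pooled AR(1) coefficient per fit (the cited implementation's
  convention); voxelwise or higher-order noise models are not provided.
* The Welch test ignores the dependence among pseudo pairs sharing a
  participant; its per-voxel type-I calibration under independent nulls is
  verified, but the effective null distribution on real data with heavy
  participant reuse may be wider.
* Homotopic ("same coordinates") correlation assumes both partners are on
  a common grid; no spatial normalisation of real data is included.
* The generator's coupling is stationary within runs; time-varying
  synchrony is outside the model.
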
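---
title: "Methods and conventions in restkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in restkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restkit)
```

restkit computes the classical resting-state fMRI measures — seed-based
functional connectivity, regional homogeneity (ReHo), and the amplitude of
low-frequency fluctuation (ALFF/fALFF) — together with the preprocessing
they assume and voxel-wise group inference. This vignette records the
models, the conventions the package pins down where the field's informal
descriptions are ambiguous, and the limits of what the synthetic test data
can demonstrate.

## Signal model and preprocessing

A resting-state series is treated as

y(t) = baseline + drift·t + Σ nuisance loadings + band-limited signal + noise.

`detrend()` removes the least-squares line and adds the original mean back,
so the baseline level (used by e.g. PET-style normalisation downstream)
survives. Detrending is idempotent and mean-preserving by construction.

`ideal_bandpass()` is an ideal rectangle-window filter: each series is
zero-padded to the smallest length ≥ T whose prime factors are all in
{2, 3, 5} (`good_fft_length()`), transformed with the DFT, and every bin
whose frequency lies outside the closed interval [low, high] Hz is zeroed
before the inverse transform. Conventions:

* **Band edges.** A bin at exactly `low` or `high` is retained (closed
  interval, matching the "0.01–0.08 Hz" notation). `low = 0` gives a pure
  low-pass; `high` above the Nyquist frequency 1/(2·TR) a pure high-pass.
  A band narrower than the frequency resolution 1/(N_pad·TR) is an error
  that reports the achievable resolution.
* **Retrend.** The least-squares *line* (not only the mean) is removed
  before the transform and restored afterwards, and the DC bin is always
  zeroed inside the transform. This full-line choice follows the ideal
  filter's usual trend handling in the AFNI lineage; the alternative
  (mean-only restoration) was considered and rejected for symmetry with
  `detrend()`. One measurable consequence: a sinusoid whose phase makes it
  non-orthogonal to a linear ramp exchanges a small amount of energy with
  the restored trend. The filter's pass/stop contracts are therefore
  stated — and tested, to < 1e-6 relative RMS — with window-symmetric
  (trend-orthogonal) exact-bin sinusoids.
* **Padding.** The padded region is filled with zeros after trend removal,
  so the series is approximately zero-mean when padded, avoiding a step
  edge at the junction.

`regress_covariates()` fits, per in-mask voxel, OLS on an intercept plus
the covariate columns (canonically: six head-motion series, global mean,
white matter, CSF) and keeps residuals plus the voxel's original mean.
Residuals are orthogonal to every covariate column to < 1e-8. A
rank-deficient design is refused with the collinear columns named;
all-zero covariate columns are refused outright.

## The three metrics

**Functional connectivity.** Pearson correlation between a seed series and
every in-mask voxel; partial correlation (both sides residualised on
[1 | covariates]) when covariates are given. The optional Fisher transform
z = atanh(r) clips |r| at 1 − 1e-7 first; clipped and constant-series
voxels are counted in QC fields rather than producing NaN or ±Inf in
written maps — a toolkit-wide policy.

**ReHo.** Kendall's W over the voxel plus its 6, 18 or 26 nearest
neighbours. Ranks are computed per series across time with *average ranks
on ties* and no tie-correction term in the denominator: BOLD data are
continuous, so ties have measure zero, and a genuinely constant series
simply lowers W through its flat ranks. At the mask or grid edge, absent
neighbours are dropped and K reduced (minimum 2, else the voxel gets 0);
the per-voxel effective K is returned in `$params$effective_k`. The
implementation accumulates shifted rank arrays, which makes it exactly
block-decomposable: `block_apply()` with a 1-voxel overlap reproduces the
whole-volume map bit for bit.

**ALFF and fALFF.** Per voxel the series (mean removed — padding a
nonzero-mean series would smear the DC level across every bin) is
zero-padded as in the filter, and amplitude is defined as
√(|X_k|²/N_pad). ALFF is the *mean* amplitude over in-band bins; the
alternative reading (sum divided by bandwidth in Hz) differs only by a
constant for a fixed band and padding, and the absolute ALFF scale is
declared arbitrary-up-to-constant anyway: only mask-mean-standardized maps
and fALFF ratios are contract-stable across FFT normalisations. fALFF is
the ratio of summed in-band amplitude to the summed amplitude over
(0, Nyquist]; the DC bin is excluded from both numerator and denominator
because the mean is not a fluctuation. Constant series give 0 with a QC
count. `alff_map()` requires `high` ≤ Nyquist; `falff_map()` expects
*unfiltered* input (a caller contract that cannot be verified from the
data).

`power_spectrum()` returns the one-sided periodogram on the padded length,
scaled so the total power equals the centred sum of squares (interior bins
doubled, DC and Nyquist not): Parseval's identity is the test.

## Group statistics

All tests are ordinary GLMs evaluated per voxel. The two-sample t uses the
pooled (equal-variance) formula — the classical SPM-style model — not
Welch. Image covariates ("voxel-dependent EVs", e.g. gray-matter density)
are mean-centred per voxel before entering the design so the group
contrast keeps its interpretation; with them the fit is per voxel, without
them one shared QR factorisation serves all voxels. ANOVA F comes from
full-versus-reduced model comparison (group dummies + covariates vs
covariates only). Maps store the signed statistic; sidedness is applied
only at thresholding (`stat_to_p()`, `fdr_threshold()`).

Degenerate voxels never produce NaN: a zero-variance one-sample voxel
yields 0 when its mean equals the null value and a sign-preserving value
capped at ±1e6 otherwise. The cap is applied uniformly, which also
regularises the near-degenerate case where differences are constant up to
floating-point rounding and the raw statistic would be ~1/ε. Capped and
rank-deficient voxels are QC-counted.

One subtlety: adding a covariate orthogonal to the whole design still
consumes one residual degree of freedom, so the group t rescales by
√(df_new/df_old) even though the contrast estimate and RSS are identical.
The tests assert that sharp form rather than naive invariance.

## Multiple-comparison correction

`fdr_threshold()` is Benjamini–Hochberg step-up on the in-mask p-values;
two-tailed mode converts a signed t map to two-sided p first. `alphasim()`
estimates cluster-extent false-positive rates by Monte Carlo: unit
Gaussian noise on the grid, separable Gaussian smoothing at the given FWHM
(a user input — smoothness estimation from residuals is out of scope),
re-standardisation within the mask, thresholding at the *empirical*
(1 − p) within-mask quantile — so the per-voxel rate is exact by
construction rather than distorted by smoothing — then 6/18/26-connected
labelling and the maximum cluster size per iteration. Corrected alpha for
size s is the fraction of iterations whose largest cluster reaches s,
non-increasing in s by construction. The seed is a named parameter recorded
in the output header. Exact bit-compatibility with other AlphaSim
implementations is not claimed; the statistical properties (binomial
suprathreshold rate at FWHM = 0, monotone alpha, seed-to-seed agreement
within Monte-Carlo error) are the contract.

Default connectivity is 26 (faces, edges, corners), consistent with the
27-voxel ReHo cluster convention; 6 and 18 are available. Cluster volumes
are voxel count × |det| of the spatial affine block; peaks are the
maximum-|intensity| member, reported in mm via the affine with 0-based
voxel indices.

## File formats and memory

Volumes are read and written through RNifti (NIfTI-1 `.nii`/`.nii.gz`,
`.hdr`/`.img` pairs, ANALYZE 7.5 input). ANALYZE carries no full affine;
the transform synthesised from voxel sizes and origin is taken RAS-positive.
TR precedence is explicit argument > header time step; because the NIfTI
library normalises a zero on-disk time step to 1 while loading, the reader
inspects the raw header field and refuses a 4D file with a non-positive
stored time step unless the caller supplies `tr`. Probabilistic masks are
binarised at nonzero by default with an optional threshold.

Very long acquisitions are handled by trading time for space:
`block_plan()` / `block_apply()` cut the spatial grid into boxes under a
voxel budget, run the metric per box, and reassemble. Voxel-independent
metrics are invariant to the plan by construction; neighbourhood metrics
use an overlap margin equal to the stencil radius, and the contract —
bit-identity with the whole-volume result — is what the tests check.

## Synthetic data: what it shows and what it does not

`make_rs_volume()` emulates a short resting acquisition on a 16³ grid of
3 mm voxels, T = 120, TR = 2 s — large enough that the padded frequency
resolution (~0.004 Hz) resolves the 0.01–0.08 Hz band, small enough for
seconds-scale tests (group simulations use up to 2000 voxels and n = 20
subjects; AlphaSim checks run 1000 iterations on a 20³ mask). It plants:
a two-blob "network" sharing a 0.04 Hz sinusoid of amplitude 3 (noise SD
1) with one random phase per network, so cross-network correlation is ~0
by construction; a compact high-concordance region (shared 0.05 Hz
sinusoid plus shared noise); uniform drift slopes in ±0.05 per volume; and
nine smooth nuisance series (global, WM-like, CSF-like, six motion-like)
with loading 0.3. Everything derives from one seed and is recorded in a
ground-truth object.

What passing recovery tests demonstrates: the metrics detect the planted
structure in the direction and ordering expected, at realistic SNR. What
they do not demonstrate: behaviour under real hemodynamics, spatially
correlated physiological noise, motion artefacts beyond smooth confound
series, registration error, or real anatomy. Group-level simulations use
independent Gaussian voxels, so they calibrate error rates, not spatial
cluster behaviour of real data.

## Known limitations

* No spatial preprocessing (slice timing, realignment, normalisation,
  reslicing, smoothing of input data): these are delegated to SPM/AFNI/FSL
  upstream, as in the classical pipeline.
* No ICA-based connectivity, Granger causality, scrubbing, or
  mixed-effects/repeated-measures models.
* The absolute ALFF scale depends on the FFT normalisation convention;
  compare only standardized maps or fALFF across implementations.
* AlphaSim smoothness is user-specified, not estimated; corrected
  cluster-size/alpha pairings depend on the mask and assumed FWHM and are
  not transferable between studies.
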
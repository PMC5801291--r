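---
title: "Classical and Bayesian second-level inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical and Bayesian second-level inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A second-level (group) fMRI analysis takes one contrast image per subject —
a 3-D map of an effect estimate produced by each subject's first-level GLM —
and asks, voxel by voxel, whether the group-mean effect is positive. With
tens of thousands of voxels, the decision rule matters as much as the test
statistic. This package implements and compares two families of rules on a
one-sample design:

* **Classical**: a per-voxel one-sample t-test, corrected for familywise
  error (FWE) either by a random-field-theory (RFT) height threshold
  (voxelwise) or by cluster-extent inference above an uncorrected
  cluster-forming threshold (clusterwise).
* **Bayesian**: an empirical-Bayes posterior probability map with a global
  shrinkage prior, thresholded jointly on an effect-size criterion and on
  the log posterior odds ("logBF") that the effect exceeds it.

Because real scanner data offer no ground truth, the package evaluates the
rules the way the underlying study design does: by survived-voxel counts,
by robustness to injected noise (false-alarm and hit rates against the
unperturbed analysis), and by the behaviour of the statistics as subjects
are added incrementally.

# Models

## Group GLM

At voxel $v$ with subject values $y_{1v},\dots,y_{nv}$:
$\hat\beta_v = \bar y_v$, $s_v^2$ the unbiased sample variance, and
$t_v = \hat\beta_v / \sqrt{s_v^2/n}$ with $\nu = n-1$ degrees of freedom.
Zero-variance voxels get $t_v = 0$ when the mean is also zero, and a
flagged $\pm\infty$ otherwise; flagged voxels are excluded from smoothness
and prior estimation.

## Random-field FWE

The voxelwise threshold $t^\*$ solves $E[\mathrm{EC}(u)] = \alpha$, where
the expected Euler characteristic of the thresholded t field is
$\sum_{d=0}^3 R_d\,\rho_d(u,\nu)$ with the standard t-field EC densities
and $R_d$ the resel counts of the search region. The package takes
$t^\* = \min(t_{\mathrm{RFT}}, t_{\mathrm{Bonf}})$, as SPM does, and never
below the uncorrected one-sided threshold. $E[\mathrm{EC}]$ is unimodal in
$u$ (the 3-D density is negative near 0), so the root is bracketed from
the last grid point where $E[\mathrm{EC}] > \alpha$ and then bisected on
$[0, 50]$ to $10^{-8}$; when $E[\mathrm{EC}]$ never reaches $\alpha$ the
RFT branch abstains and Bonferroni rules.

Cluster-extent inference forms clusters above the one-sided
cluster-defining threshold (default $p < 0.001$ uncorrected) and computes
each cluster's corrected p from the Gaussian-random-field extent
distribution: with $E[m] = E[\mathrm{EC}(u)]$, $E[N] = R_3 P(T>u)$,
$\beta = (\Gamma(5/2)\,E[m]/E[N])^{2/3}$ and extent $k$ in resels,
$P(\text{size} \ge k) = e^{-\beta k^{2/3}}$ and
$p_{\mathrm{FWE}} = 1 - \exp(-E[m]\,e^{-\beta k^{2/3}})$. Clusters with
$p_{\mathrm{FWE}} < \alpha$ survive.

**Smoothness.** FWHM per axis comes from the variance of forward spatial
differences of the per-voxel-standardized residual fields:
$\lambda_a = \widehat{\mathrm{Var}}(\partial e/\partial a)$, pooled over
subjects and in-mask neighbour pairs, and
$\mathrm{FWHM}_a = \sqrt{4\ln 2/\lambda_a}$. On unsmoothed white noise the
forward-difference estimator floors at $\sqrt{2\ln 2} \approx 1.18$
voxels. This estimator tracks the one SPM uses but is not line-for-line
identical (SPM additionally applies small-df corrections), which is a
known source of discrepancy when chasing externally reported voxel counts.

**Resels.** $R_0$–$R_2$ use the standard lattice counting of in-mask
points, edges and faces; $R_3$ is the mask volume in FWHM-cubes,
$V\prod_a \mathrm{FWHM}_a^{-1}$ (the convention FSL's `smoothest` uses;
SPM's cube counting differs at the boundary by order surface/FWHM). A
10×10×10 box at FWHM 2 therefore has $R_3 = 125$ exactly.

## Empirical-Bayes posterior maps

The hierarchical model is
$\hat\beta_v \mid \beta_v \sim N(\beta_v, s_v^2/n)$,
$\beta_v \sim N(0, c_B)$ with one global prior variance $c_B$. The
moments estimator is
$\hat c_B = \max\{0,\ \mathrm{Var}_v(\hat\beta_v) - \overline{s_v^2}/n\}$
over usable in-mask voxels. The conjugate posterior at each voxel has
precision $1/c_B + n/s_v^2$, hence
$\mathrm{post\_var} \le \min(c_B, s_v^2/n)$ and
$|\mathrm{post\_mean}| \le |\hat\beta_v|$ (shrinkage toward zero). The
voxel's own variance is used in the posterior; pooling enters only through
$c_B$. A `reml` method tag is reserved but unimplemented — the moments
form is transparent, deterministic, and recovers the generating $c_B$
within a few percent at study scale (V = 50,000, n = 16).

**Thresholding.** The effect-size threshold is $\gamma = d\sqrt{c_B}$:
the prior SD plays the role of Cohen's d = 1.0, so $d = 0.5$ requests half
of it. The evidence statistic is the log posterior odds
$\log \frac{P(\beta_v > \gamma \mid y)}{P(\beta_v \le \gamma \mid y)}$,
which equals the log Bayes factor under the implicit equal prior odds —
hence the "logBF" name used in reports. Odds are computed in log-space
from the normal CDF and clipped at ±40, beyond double-precision resolution
of $\Phi$ and far past any threshold in use. Defaults follow the guideline
pairing $d = 0.5$ (medium effect) with $\tau = 5$ (very strong evidence);
$\tau = 3$ and the stricter tool default 10 are also first-class. The
voxel extent threshold defaults to 0 because no corrected cluster
criterion exists on the Bayesian side.

# The synthetic generator

`generate_subject_images()` stands in for first-level outputs. Subject $i$
gets $M + E_i$: a mean map $M$ equal to $d_{\mathrm{true}}\sigma_B$ inside
hard-edged spherical blobs (voxel centre in sphere ⇒ active, no
partial-volume feathering, so the truth map is unambiguous), plus Gaussian
white noise smoothed with an isotropic kernel and rescaled to marginal SD
$\sigma_B$. Noise is generated on a grid padded by the kernel half-width
and cropped, so the field is exactly stationary and the closed-form
rescale $(\sum w^2)^{-3/2}$ is exact; rescaling happens *after* smoothing
so the smoothness knob does not change power. "Mean signal strength" for
the noise-injection protocol is the mean *absolute* in-mask value, since
contrast images are signed and a plain mean can sit near zero; the
injected SD is `fraction` (study value 0.25) times that, drawn iid per
voxel within the mask, independently per image.

Defaults are the study conditions: 16 subjects, a 40×48×34 grid at 2 mm
(65,280 voxels) with an inscribed-ellipsoid mask (≈31,700 in-mask voxels),
noise FWHM 3 voxels, $\sigma_B = 1$. The default affine places the origin
at (−40, −44, −24) mm so that the tracked frontal coordinate
(−4, 48, 12) mm lies inside the volume. What the generator does *not*
emulate: anatomical structure, spatially varying variance, physiological
artifacts, inter-subject misregistration, or heavy-tailed outlier
subjects. Tests passing on this generator therefore certify the
inferential machinery under its stated assumptions, not performance on
real scanner data.

# Evaluation harness

`noise_robustness_experiment()` analyses the original images once, then R
(default 10) independently perturbed copies at `fraction = 0.25`; one
perturbed dataset per replicate is shared across methods, giving paired
comparisons. False-alarm rate is
$|A_{\mathrm{noise}} \setminus A_{\mathrm{orig}}| / |A_{\mathrm{noise}}|$
and hit rate
$|A_{\mathrm{noise}} \cap A_{\mathrm{orig}}| / |A_{\mathrm{orig}}|$;
empty denominators yield NA, reported as missing and excluded from
summaries rather than silently zeroed. Group-level model comparison of
the rates (Bayesian ANCOVA and the like) is deliberately out of scope:
the harness emits tidy per-replicate tables for external analysis.

`sample_size_sweep()` draws P (default 10) random subject orders and, for
each order and each $n = 2..N$, refits everything — smoothness, $c_B$,
$\gamma$ — from the first $n$ subjects, recording per-method survived
counts and the t and log-odds values at the voxel nearest a target mm
coordinate (default (−4, 48, 12)). The sweep starts at $n = 2$ even
though df = 1 makes classical inference wildly unstable; classical
methods that cannot run (smoothness needs $n \ge 3$) return NA counts
rather than aborting, so the instability is visible, not suppressed.

# Numerical and design notes

* Cluster connectivity defaults to 18 (faces + edges), the convention of
  SPM-style cluster reporting; 6 and 26 are available. Labeling order is
  deterministic: descending size, ties by smallest linear index.
* Voxel indices are 0-based with mm coordinates through the NIfTI affine;
  mm→voxel conversion rounds half away from zero and refuses coordinates
  outside the grid. Peaks are reported in mm.
* On-disk payloads are float32 (the field's convention); in-memory
  arithmetic is double. NaN is the out-of-mask value on written maps.
* All randomness flows through explicit integer seeds; replicate r of the
  noise experiment uses `seed + r`, and the sweep's subject orders come
  from a single seeded draw, so every result is reproducible from the run
  log.
* Problem sizes used in the shipped tests (100 null datasets for FWE
  calibration, 20 seeds for the method-ordering scenario, 100 simulations
  at V = 50,000 for prior recovery, P = 10 sweeps) are the study-scale
  settings; they complete in minutes on one core.

# Known limitations

* One-sample designs only: no covariates, two-sample or paired tests,
  nonstationary cluster inference, permutation/TFCE, or FDR.
* The RFT and smoothness implementations follow the published formulas,
  not SPM's code; externally reported voxel counts from SPM runs should be
  expected to match in pattern (clusterwise ≥ Bayes at moderate
  thresholds ≥ voxelwise) rather than digit-for-digit.
* The Bayesian branch assumes the global-shrinkage hierarchical model;
  when true effects are rare and strong, $\hat c_B$ is small and the
  posterior shrinks hard, which is a property of the model, not a bug of
  the estimator.
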
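# bayesppm

Classical and Bayesian second-level inference for group fMRI, side by side.

Second-level fMRI analysis takes one contrast image per subject and asks,
at every voxel, whether the group-mean effect is positive. `bayesppm` is
for methodologists and analysts who want to compare the two standard
answers on equal footing:

* **Classical**: a mass-univariate one-sample t-test with familywise error
  (FWE) control — either a random-field-theory (RFT) voxelwise height
  threshold `t* = min(t_RFT, t_Bonf)` solving `E[EC(u)] = alpha`, or
  cluster-extent inference (cluster-forming `p < 0.001` uncorrected,
  cluster-level FWE `p < 0.05` from the Gaussian-random-field extent
  distribution).
* **Bayesian**: an empirical-Bayes posterior probability map under the
  global shrinkage prior `beta_v ~ N(0, cB)`, with conjugate per-voxel
  posteriors, thresholded jointly on an effect size `gamma = d * sqrt(cB)`
  (the prior SD plays Cohen's d = 1.0) and on the log posterior odds
  `logBF = log P(beta_v > gamma | y) / P(beta_v <= gamma | y)` — guideline
  defaults d = 0.5, logBF > 5.

Because group data carry no ground truth, the package also ships the
study-style evaluation harness: survived-voxel counts, noise-injection
robustness (Gaussian noise at 25% of each image's mean absolute signal,
false-alarm and hit rates over replicates), and incremental sample-size
sweeps tracking t and logBF at a target voxel. A synthetic contrast-image
generator (smooth between-subject noise plus planted Cohen's-d blobs)
stands in for first-level outputs.

## Worked example

Sixteen synthetic subjects on the default 40x48x34 grid (2 mm voxels,
ellipsoid mask), one planted blob of radius 5 voxels at Cohen's d = 0.8,
noise smoothness 3 voxels FWHM:

```r
library(bayesppm)

spec <- synthetic_spec(
  n_subjects = 16, smooth_fwhm_voxels = 3,
  blobs = list(activation_blob(c(19, 23, 16), radius_voxels = 5,
                               d_true = 0.8)),
  seed = 2001)
ds <- generate_subject_images(spec)

fit <- run_inference(ds, list(
  method_clusterwise(alpha = 0.05, cdt_p = 0.001),
  method_voxelwise(alpha = 0.05),
  method_bayes(d = 0.5, tau = 5)))
sapply(fit$results, survived_count)
#>     clusterwise   voxelwise_fwe bayes_d0.5_tau5
#>             279              16              66
```

The estimated smoothness is FWHM (3.02, 3.01, 3.01) voxels — the
generator's kernel recovered — and the Bayesian branch reports
`cB = 0.0163`, i.e. prior SD 0.1276, so the d = 0.5 effect-size threshold
is `gamma = 0.0638` in contrast units. The counts show the characteristic
ordering: cluster-extent inference is the most liberal (one cluster of
279 voxels, peak t = 9.06 at (-4, 6, 2) mm), voxelwise FWE the most
conservative (16 voxels), and the Bayesian map with moderate thresholds
sits between (66 voxels).

Robustness of the Bayesian decision to the study's perturbation:

```r
noise_robustness_experiment(ds, list(method_bayes(d = 0.5, tau = 5)),
                            R = 3, fraction = 0.25, seed = 9)
#>   replicate          method false_alarm       hit seed
#> 1         1 bayes_d0.5_tau5   0.1454545 0.7121212   10
#> 2         2 bayes_d0.5_tau5   0.1346154 0.6818182   11
#> 3         3 bayes_d0.5_tau5   0.1538462 0.8333333   12
```

so roughly 14% of voxels active under perturbation are new, and 68-83% of
the original activation survives each perturbation.

End-to-end runs are also driven by a YAML config
(`load_run_config()` / `run_comparison()` / `run_evaluation()`), which
writes `report.csv`, per-method activation masks and cluster tables, tidy
`noise_eval.csv` / `sweep.csv` / `orders.csv`, and a `run_log.jsonl`
capturing every data-dependent threshold (FWHM, t*, CDT, cB, gamma) and
seed. See the vignette `vignettes/group-inference-methods.Rmd` for the
models, estimators and design choices.

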
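# pace

Voxel-based Normal Tissue Complication Probability (NTCP) modelling for
radiation oncology: an R implementation of the **PACE** formalism
(Probabilistic Atlas for Complication Estimation), together with the
classical Lyman–Kutcher–Burman (LKB) benchmark, a full in-silico
validation suite, and a radio-sensitivity (RS) map inference tool.

## Who this is for

Researchers in radiotherapy outcome modelling who want an NTCP model that
uses the *spatial arrangement* of dose, not just the dose-volume histogram
(DVH). DVH-based models such as LKB are blind to inhomogeneous organ
radio-sensitivity by construction: two plans with identical DVHs get
identical predictions no matter which subregion they irradiate.

## The model

Given N spatially co-registered dose maps `D_i(x_j)` on a grid of M ROI
voxels with binary outcomes `O_i`:

1. **Voxelwise backbone** — one logistic regression per voxel of outcome
   on local dose (plus optional scalar covariates). For a test map this
   yields a probability map `P(x_j)` and a reliability map
   `W(x_j) = 1 / CI(x_j)` (reciprocal width of the 95% CI of P; `W = 0`
   where the fitted dose odds ratio is < 1).
2. **Aggregation** — the generalized equivalent uniform probability

       gEUp = [ Σ_j P(x_j)^(1/ν) W(x_j) / Σ_j W(x_j) ]^ν

3. **Sigmoid** — `PACE = Φ( (gEUp − Tp50) / (μ · Tp50) )`.

The parameters (ν, μ, Tp50) are estimated by maximum likelihood (seeded
multi-start over bounded boxes) with Wilks profile-likelihood confidence
intervals. The LKB reference (`gEUD = [mean D^(1/n)]^n`,
`NTCP = Φ((gEUD − TD50)/(m·TD50))`) is fitted with identical machinery for
like-for-like comparison.

The package also ships the synthetic study kit used to validate the
method end to end: Gaussian-peak dose-map simulation, a DVH-equalizing
rank transform (all maps share one DVH, so DVH-based models are provably
uninformative), RS-weighted gEUD outcome labelling, learning curves,
ROC/calibration/LOO evaluation, and single-hot-spot probe sets that
reconstruct the level sets of the RS map a trained model has absorbed
(scored by the Dice index between equal-size superlevel sets, DI_V).

## Worked example

```r
library(pace)

g  <- grid_spec(c(32, 32))
rs <- make_rs_map(g, "s2g")                     # two-bump RS ground truth
cohort <- simulate_cohort(400, g, rs = rs, n_exp = 0.1,
                          event_rate = 0.25, seed = 1)

fit <- fit_pace(cohort, conf_int = FALSE)
tidy(fit)
#> # A tibble: 3 × 6
#>   term  estimate conf.low conf.high at_lower_bound at_upper_bound
#>   <chr>    <dbl>    <dbl>     <dbl> <lgl>          <lgl>
#> 1 nu      0.0705       NA        NA NA             NA
#> 2 mu      0.0505       NA        NA NA             NA
#> 3 tp50    0.593        NA        NA NA             NA

preds <- predict(fit, cohort)
evaluate_predictions(preds$.pred, cohort$outcome)
#> <pace_eval> N = 400 patients
#>   AUC 0.996 (SE 0.005, 95% CI 0.965-0.999)
#>   calibration slope 0.997 +/- 0.017, intercept 0.002 +/- 0.008, R2 0.998
#>   accuracy 0.975, balanced accuracy 0.967, F1 0.950
```

`nu` plays the role of the volume-effect exponent on the probability map
(small values = serial behaviour, prediction driven by the most reliable
high-risk voxels); `tp50` is the gEUp level at which predicted risk
crosses 50%. The AUC/calibration/accuracy block is the in-sample training
report; honest out-of-sample numbers come from `loo_cv(cohort, "pace")`.

Probing the trained model recovers the RS pattern it absorbed:

```r
probes <- make_probe_set(g, amplitude = median(sapply(cohort$dose, max)))
est <- infer_rs_map(fit, probes)
di_v_auc(di_v_curve(rs, est))   # 1 = perfect level-set recovery
autoplot(est)
```

A config-driven driver (`run_experiment()`) and a thin CLI
(`inst/cli/pace`) string the stages into reproducible experiments
(`simulate`, `fit`, `evaluate`, `learning-curve`, `rs-map`), each writing
a provenance JSON.

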
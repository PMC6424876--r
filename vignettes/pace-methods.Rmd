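---
title: "Voxel-based NTCP modelling with PACE: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based NTCP modelling with PACE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(pace)
```

## The problem

Classical Normal Tissue Complication Probability (NTCP) models such as
Lyman–Kutcher–Burman (LKB) reduce a 3D dose distribution to its
dose-volume histogram (DVH) before relating it to a binary toxicity
outcome. The DVH discards *where* dose is deposited, so any spatial
inhomogeneity in organ radio-sensitivity (RS) is invisible to such models:
two dose plans with identical DVHs receive identical LKB predictions even
when one irradiates a sensitive subregion and the other does not.

PACE (Probabilistic Atlas for Complication Estimation) keeps the LKB
architecture — a scalar "generalized equivalent uniform" summary pushed
through a probit sigmoid — but replaces the dose distribution with a
voxelwise collection of outcome odds, so the spatial arrangement of dose
enters the model.

## The model

**Backbone.** Given $N$ spatially co-registered dose maps $D_i(x_j)$ on a
common grid of $M$ ROI voxels and binary outcomes $O_i$, one logistic
regression per voxel ties the $N$ outcomes to the $N$ local doses (plus
any global scalar covariates):
$$\mathrm{logit}\, \Pr(O = 1 \mid D(x_j)) = \beta_{0j} + \beta_{1j} D(x_j)
  + \textstyle\sum_k \gamma_{kj} V_k .$$
The $M$ fitted models form the atlas. For a test dose map the backbone
yields a probability map $P(x_j)$ and a reliability map
$W(x_j) = 1/\mathrm{CI}(x_j)$, where $\mathrm{CI}(x_j)$ is the width of
the 95% confidence interval of $P(x_j)$; wherever the fitted dose odds
ratio is below 1 (dose locally "protective") the voxel is considered
uninformative and $W(x_j) = 0$.

**Aggregation.** The maps are condensed into the generalized equivalent
uniform probability
$$\mathrm{gEUp} = \left[
  \frac{\sum_j P(x_j)^{1/\nu}\, W(x_j)}{\sum_j W(x_j)}
  \right]^{\nu},$$
a reliability-weighted power mean: $\nu = 1$ is the weighted arithmetic
mean; $\nu \to 0$ makes the summary serial, dominated by the most reliable
high-risk voxels. The final prediction is the probit sigmoid
$$\mathrm{PACE} = \Phi\!\left(\frac{\mathrm{gEUp} - Tp_{50}}
  {\mu\, Tp_{50}}\right),$$
with tolerance probability $Tp_{50}$ (the gEUp at which predicted risk
crosses 0.5) and slope $\mu$. The three free parameters
$(\nu, \mu, Tp_{50})$ are estimated by maximum likelihood; confidence
intervals come from inverting the likelihood-ratio test (Wilks), profiling
each parameter with the other two re-optimised.

The reference LKB model is the exact structural analogue on dose:
$\mathrm{gEUD} = [\frac1M \sum_j D(x_j)^{1/n}]^n$ and
$\mathrm{NTCP} = \Phi((\mathrm{gEUD} - TD_{50})/(m\,TD_{50}))$, fitted
with the same machinery, which makes model comparisons like-for-like.

## Parameters that matter

| parameter | meaning | default / bounds |
|---|---|---|
| $\nu$ | volume effect on the probability map (dimensionless) | bounds $[0.01, 1]$ |
| $\mu$ | PACE sigmoid slope (dimensionless) | bounds $[0.01, 2]$ |
| $Tp_{50}$ | tolerance probability (probability units) | bounds $[0.01, 0.99]$ |
| $n, m, TD_{50}$ | LKB analogues ($TD_{50}$ in dose units) | $n, m \in [0.01, 1]$; $TD_{50} \in [\min D, 10 \max D]$ |
| `w_max` | reliability cap for degenerate zero-width CIs | $10^6$ |
| `threshold` | classification threshold on predicted probability | 0.5 |

The sigmoid in the final stage is the standard LKB probit
$\Phi(t) = \tfrac12[1 + \mathrm{erf}(t/\sqrt2)]$; the exponent in the gEUp
power mean is read as $P^{1/\nu}$, mirroring $D^{1/n}$ in the gEUD.

## Numerical strategy

Both likelihoods share one structure: an expensive per-patient power-mean
summary that depends only on the volume-effect exponent, followed by a
two-parameter sigmoid that is cheap once the summaries are known. The
fitter exploits this: the exponent is profiled on a seeded Latin-hypercube
grid over its bounds (each profile point re-optimising slope and midpoint
from several starts), the best bracket is refined by golden-section
search, and the joint solution receives a final Nelder–Mead polish on the
exact three-parameter likelihood. The multi-start design guards against
the multi-modality these likelihoods can exhibit; every fit is
deterministic given its seed. Probabilities are clipped to
$[10^{-12}, 1 - 10^{-12}]$ inside the Bernoulli log-likelihood.

All $M$ voxel regressions are fitted in one batched Newton–Raphson sweep
(matrix operations across voxels, closed-form $2\times2$ solves in the
covariate-free case). Voxelwise fits at cohort sizes of order 100 with
minority events frequently (quasi-)separate; flagged voxels (divergent
slope, saturated linear predictor, or non-convergence) are refitted with a
Firth-type bias-reduced penalised likelihood, implemented in the same
batched form via the per-observation leverages. Voxels whose dose has zero
variance across the cohort get an intercept-only model, a dose slope fixed
at 0 with infinite variance, and reliability 0.

Degenerate inputs are handled explicitly: constant dose maps cannot be
DVH-equalized (error); a degenerate g2EUD distribution admits no outcome
threshold (error); a test patient whose W map is identically zero receives
the training-prevalence fallback probability with a warning; ties in rank
constructions (DVH equalization, superlevel sets) are broken by stable
voxel index order.

## What the synthetic generator emulates

The in-silico cohorts mimic the geometry of a 2D dose-painting study on a
square ROI (default $32 \times 32$ voxels):

* **Dose maps** are sums of 1–4 Gaussian peaks, widths uniform between 10%
  and 30% of the ROI linear size $L$, heights uniform on $[0.5, 1.5]$
  arbitrary dose units, centers uniform over the ROI.
* **Identical-DVH families** apply to each map the monotone rank transform
  sending its empirical dose distribution to the uniform distribution on
  $(0, d_{\max}]$ (plotting positions $r/M$, stable ties). All maps then
  share exactly one DVH while keeping their spatial patterns — the
  construction that blinds any DVH-based model by design.
* **Radio-sensitivity ground truths** are either homogeneous or the sum of
  two shifted Gaussians (S2G). The S2G default places equal-amplitude
  bumps of width $0.12\,L$ at fractional positions $(0.3, 0.3)$ and
  $(0.7, 0.7)$: clearly separated peaks that still leave most of the ROI
  at low sensitivity, a deliberately hard but resolvable target at the
  default grid size.
* **Outcomes** threshold the RS-weighted generalized EUD,
  $\mathrm{g^2EUD} = [\sum_j D^{1/n}(x_j) RS(x_j) / \sum_j RS(x_j)]^n$,
  strictly at $D_{th}$; $D_{th}$ is set as the empirical quantile matching
  a target event rate (default 25%, a realistic toxicity incidence; a
  balanced 50% rate is used where a chance-level reference of 0.5 is the
  point of the experiment).

What this generator does *not* emulate: registration error and anatomical
variability between patients, dose-fractionation effects, label noise in
outcome scoring, non-dosimetric confounders, and 3D organ geometry.
Passing the in-silico suite therefore demonstrates that the estimation
machinery recovers the data-generating structure under ideal spatial
normalisation — not that the model is clinically validated.

## Radio-sensitivity inference

A trained PACE model can be interrogated about the RS pattern it has
absorbed: probe it with synthetic dose maps carrying a single narrow
Gaussian hot spot (default $\sigma = 1.5$ voxels, stride 1) and read the
PACE probability as a function of hot-spot position. The readout is
meaningful up to a monotone transform, so agreement with a ground truth is
scored on superlevel sets: for each volume fraction $v$, the Dice index
between the two maps' top $v \cdot M$ voxels (rank-based, equal sizes by
construction), summarised by the trapezoidal area under the
$\mathrm{DI}_V$-versus-$v$ curve, normalised to the $v$ range
(grid 0.05–0.95, step 0.05).

**Probe amplitude.** PACE is nonlinear in dose, so the probe dose level is
a real design choice. An amplitude sensitivity sweep (easily reproduced by
varying `amplitude` in `make_probe_set()`) shows a plateau of recovery
quality for probes near a *typical single-peak dose* and a marked
degradation for probes at the cohort-wide maximum dose: at off-centre
voxels the maximum dose lies far outside the locally observed training
doses, the Wald intervals inflate, $W \to 0$, and the readout becomes
biased toward the grid centre. The default amplitude is therefore the
median over training maps of their maximum dose.

**Known limitation.** The voxelwise dose–outcome association inherits the
spatial correlation length of the dose field (peaks up to $0.3\,L$ wide).
The inferred RS map is effectively the ground truth blurred at that scale:
the global value ordering and the large-$v$ superlevel sets are recovered
well, but closely spaced RS peaks are smeared toward each other, which
depresses $\mathrm{DI}_V$ at small $v$. Sharper dose textures or coarser
RS structure would raise it; the shipped experiments report what the
stated generator conditions give.

## Evaluation toolbox

Discrimination is the Mann–Whitney AUC with the Hanley–McNeil standard
error and a logit-scale Wald CI; two models on the same patients are
compared by a Z-test whose correlation term is approximated by the average
Spearman correlation of the two prediction vectors within events and
within non-events (the tabulated Hanley–McNeil correction is unavailable
in closed form). Calibration regresses observed event fractions on mean
predicted probabilities over 10 equal-count bins (OLS slope, intercept,
$R^2$; ideal 1, 0, 1). Classification metrics (accuracy, balanced
accuracy, F1) use threshold 0.5 unless stated. Leave-one-out
cross-validation refits the *entire* model — backbone included — in every
fold by default; a fast mode keeping the backbone fixed is provided and
labelled optimistic, because the held-out patient then contributes to its
own voxel models. Learning curves simulate a fresh cohort per replicate,
share one labelling threshold between training pool and validation set,
and resample (with an incremented seed, counted) if a training subset
degenerates to a single class.

## Problem sizes used in the shipped experiments

The packaged validation experiments run at desk scale, chosen as the
smallest sizes at which the qualitative contrasts stabilise: $32\times32$
grids; 400–800 training and 500 validation maps with 10 seeds for the
learning-curve contrasts; 1,000-map cohorts for the four RS-inference
models; $N = 500$ with 20 replicates for parameter-recovery coverage
(P/W maps with 64 voxels for PACE, $16\times16$ dose grids for LKB).
Parameter-recovery outcomes are drawn Bernoulli from the model's own
sigmoid probabilities, the well-specified reading of "recovery"; the
LKB unit tests additionally exercise threshold-plus-label-noise outcomes.

## Worked example

```{r example, eval = FALSE}
g <- grid_spec(c(32, 32))
rs <- make_rs_map(g, "s2g")
cohort <- simulate_cohort(400, g, rs = rs, n_exp = 0.1,
                          event_rate = 0.25, seed = 1)

fit <- fit_pace(cohort)          # backbone + (nu, mu, Tp50) with Wilks CIs
tidy(fit)
glance(fit)

lkb <- fit_lkb(cohort)
preds <- predict(fit, cohort)
evaluate_predictions(preds$.pred, cohort$outcome)

probes <- make_probe_set(g, amplitude = median(sapply(cohort$dose, max)))
est <- infer_rs_map(fit, probes)
di_v_auc(di_v_curve(rs, est))
autoplot(est)
```

## Design choices made where the design was open

* **CI scale for W.** The reliability is the reciprocal *width* of the 95%
  interval of $P(x_j)$, computed Wald on the logit scale and mapped through
  the inverse logit (keeps intervals inside $[0,1]$). A logit-scale width
  is an equally defensible reading of "the CI"; the probability-scale one
  is kept because $W$ weights a mean of probabilities, so its units should
  match.
* **Zero-width CIs** (degenerate certainty) cap $W$ at $10^6$ so no single
  voxel can dominate the gEUp sum.
* **Separation handling** uses Firth's bias-reduced likelihood rather than
  an ad-hoc ridge, because it needs no tuning constant and its estimates
  are finite under separation by construction.
* **Superlevel sets by rank** (top $v \cdot M$ voxels) rather than by value
  threshold guarantee the equal-size sets the Dice construction requires,
  and make the score invariant under monotone transforms of either map.
* **In-sample training protocol**: backbone and $(\nu,\mu,Tp_{50})$ are fit
  on the same cohort; honest assessment is delegated to LOO.
* **LKB on voxels, not binned DVHs**: the gEUD is computed from the ROI
  voxels directly (the exact differential DVH), so the homogeneous-RS
  identity $\mathrm{g^2EUD} \equiv \mathrm{gEUD}$ holds to machine
  precision; a binned DVH export is provided separately for inspection.

## Limitations

Voxel models are fitted independently (no spatial regularisation); the
atlas is honest about that through $W$, but neighbouring voxels share most
of their information. The Wald-based $W$ degrades gracefully but is not a
posterior. The RS probe readout confounds radio-sensitivity with the
spatial distribution of training dose support — probes outside the locally
observed dose range are extrapolations, which is why the probe amplitude
default is conservative. Clinical covariate maps (per-voxel covariates)
are accepted through the same interface but have no dedicated synthetic
generator.
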
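---
title: "Split LBI for voxel-level gray-matter classification: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split LBI for voxel-level gray-matter classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitlbi)
```

## The problem

Voxel-based morphometry reduces a structural MRI to one gray-matter (GM)
volume value per voxel on a common template grid. At a coarse 8 mm
resolution a whole brain is ~2,500 in-mask voxels, and a case-control study
(here: Alzheimer's disease vs normal controls, 57/47 subjects) becomes a
high-dimensional logistic classification problem with two kinds of
predictive voxels:

* **lesion features** — disease-related atrophy, spatially contiguous
  (hippocampus, temporal lobe), the voxels one wants to *select and
  interpret*; and
* **procedural bias** — GM volume mistakenly enlarged near tissue
  boundaries during registration/segmentation. These voxels genuinely carry
  class information and help prediction, but they are not lesions and
  should not dominate an interpretable support.

A plain L2-penalized logistic model uses everything and explains nothing; a
plain L1 model selects a sparse support in which lesion features and
procedural bias compete head-on. The estimator implemented here separates
the two roles by *variable splitting*: one dense parameter predicts, one
sparse parameter selects.

## Model and algorithm

The loss is

$$
\mathcal{L}(\beta, \beta_0, \gamma) \;=\;
-\sum_{i=1}^N \big[ y_i \log \sigma(x_i\beta + \beta_0) +
(1-y_i)\log(1-\sigma(x_i\beta + \beta_0)) \big]
\;+\; \frac{1}{2\nu}\,\lVert D\beta - \gamma \rVert_2^2 ,
$$

where $\beta$ is the dense voxel-weight vector (with unpenalized intercept
$\beta_0$), $\gamma$ is the sparse splitting parameter, and $D$ stacks an
identity block (voxel-level sparsity) over a $\rho$-weighted 6-neighborhood
incidence block (one row $\rho(\beta_a - \beta_b)$ per face-adjacent in-mask
voxel pair; spatially fused sparsity). With $\rho = 0$ the edge block is
omitted and the penalty reduces to pure voxel sparsity.

The regularization path is generated by the Split Linearized Bregman
Iteration, a three-line scheme:

$$
\beta_{k+1} = \beta_k - \kappa\alpha\,\nabla_\beta\mathcal{L}, \qquad
z_{k+1} = z_k - \alpha\,\nabla_\gamma\mathcal{L}, \qquad
\gamma_{k+1} = \kappa\,\mathrm{soft}(z_{k+1}, 1),
$$

with regularization time $t_k = \kappa\alpha k$. The dual variable $z$
integrates the (sign-reversed) gradient of the splitting residual; a
coordinate enters the support exactly when $|z| > 1$. The path starts from
the fully-null model and sparsity *decreases* along it — early checkpoints
are heavily regularized, late checkpoints approach the unpenalized dense
fit. Two estimators live at every checkpoint:

* the **dense estimator** $\beta$, used for prediction (it can exploit
  procedural bias and everything else); and
* the **sparse estimator** $\tilde\beta$ (`sparse_projection()`), which
  keeps $\beta_j$ only where the identity-block $\gamma_j \ne 0$, used for
  interpretation and feature selection. Because scattered voxels entering
  alone pay fusion penalties that contiguous clusters share, lesion
  clusters tend to enter $\gamma$'s support before isolated boundary
  voxels.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `nu` ($\nu$) | 0.2 | balance between loss and splitting penalty |
| `kappa` ($\kappa$) | 10 | damping; larger = sharper sparse path, smaller stable step |
| `rho` ($\rho$) | 1 | weight of the fused (edge) block of $D$ |
| `alpha` ($\alpha$) | auto | step size, $0.9 / (\kappa(\lVert X\rVert_2^2/4 + \lVert D\rVert_2^2/\nu))$ |
| `t_max` | 20 | path horizon in time units $t=\kappa\alpha k$ |
| `stride` | 20 | iterations between stored checkpoints |
| `patience` | 5 | consecutive rising validation checkpoints before stopping |

On the choice of $\nu$: at stationarity of the dense block the splitting
gap satisfies $(D\beta - \gamma)/\nu \approx -\nabla$ (logistic), so the
dual $z$ accumulates at rate $\alpha\,\nabla$ only when $\nu$ is small
enough for the gap to track the gradient. With $\nu = 1$ on standardized
cohort-sized designs, support entry times inflate by more than an order of
magnitude (we measured single-voxel support after $10^5$ iterations);
$\nu = 0.2$ puts the iteration in the strong-splitting regime where entry
times are governed by the logistic gradient itself, which is both the
statistically intended behavior and computationally practical. $\nu$
remains exposed for sensitivity analysis.

The step-size rule uses the sum-form logistic Lipschitz constant
$\lVert X\rVert_2^2/4$ plus the penalty curvature $\lVert D\rVert_2^2/\nu$,
estimated by power iteration (tolerance $10^{-8}$, deterministic start);
the 0.9 safety factor absorbs the unpenalized intercept column. Under this
rule the recorded full loss is non-increasing (checked over 50-step windows
in the tests), and a divergence guard aborts if the loss ever grows more
than 10-fold over 100 steps.

## Cross-validation protocol

`run_cv()` implements one repeat of stratified 10-fold cross-validation:
per fold, standardization statistics (per-voxel z-scoring) come from the
nine training folds only; the path is fit on a stratified 80% of the
training subjects while the remaining 20% drive early stopping and
checkpoint selection (minimum validation deviance, earliest time on ties);
the held-out fold is predicted with the selected dense estimator. Folds are
stratified — the protocol only requires random division, but with 57/47
subjects unstratified folds can produce single-class training anomalies —
and the two classes are dealt in opposite fold orders so fold sizes stay
within one subject of balance. Out-of-fold predictions are pooled into one
prediction per subject ("full" cross-validation); `repeat_cv()` repeats the
whole protocol (default R = 10) under fresh fold assignments and reports
per-metric means with 95% t-intervals,
$\bar m \pm t_{R-1,0.975}\, s/\sqrt R$. A bootstrap of the pooled
predictions is deliberately *not* the default: with R repeats available the
across-repeat interval is the simpler, assumption-lighter summary.

With validation data the path always runs to `t_max` and is then
auto-extended until the validation deviance has risen for `patience`
consecutive checkpoints (cap: `extend_factor * t_max`). Requiring `t_max`
first matters: the validation deviance has a shallow transient minimum
during the early dense phase (before any support enters), and a pure
patience rule would stop there.

## Interpretation

* **Key voxels** — weights of a single interpretation model (refit on the
  full cohort at the median of the fold-selected times; fold-averaging is
  available as `mode = "fold_average"`) are ranked by $|\beta|$. Ranking by
  magnitude rather than signed value is deliberate: atrophy carries
  negative weights yet plainly belongs among the most influential voxels;
  signed ranking sits behind `signed = TRUE`. `topn_accuracy_curve()`
  re-evaluates the pooled out-of-fold accuracy while keeping only the top-n
  weights of each fold model (no refitting — the curve asks how much of the
  *fitted* model's signal its largest weights carry), and `find_plateau()`
  returns the smallest n whose accuracy stays at the sustained maximum
  (tolerance `eps`, default exact; if the tail never returns to the
  maximum, the start of the terminal constant run is returned so that
  accuracy at `n_key` always reproduces the full-model accuracy).
* **Atlas aggregation** — the coarse weight map is brought to atlas
  resolution by nearest-neighbor upsampling (corner-aligned grids, each
  fine voxel takes the physically nearest coarse center) and summed as
  $|w|$ within each labeled region; signed sums can cancel inside a region,
  so the signed variant is opt-in. Region percentages are normalized to
  100.
* **Clinical correlation** — `partial_correlation()` residualizes both
  variables on an intercept plus nuisance covariates (age, sex, education)
  by OLS and applies the t transform with $df = n - k - 2$. A variable
  explained exactly by the covariates has residual norm at rounding level;
  its partial correlation is defined as 0 rather than left to numerical
  noise.
* **Demographics tables** — `ttest_from_summary()` implements both the
  pooled and the Welch variant because published tables rarely state which
  was used (the classical pooled test reproduces a printed age p-value of
  0.46 at these group sizes, while the education row matches the Welch
  variant); `chisq_2x2()` defaults to the uncorrected Pearson statistic
  with Yates behind a flag. No single convention reproduces every printed
  value, so both are first-class.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis
assumes, with ground truth retained:

* a centered ellipsoid mask (fraction 0.67 of the grid half-dimensions,
  tuned so the 24×28×24 grid at 8 mm holds ~2,500 in-mask voxels);
* features $x_{ij} = 0.5 + \text{group}_i\,\text{effect}_j + u_i +
  \varepsilon_{ij}$ truncated to $[0,1]$, with subject intercept
  $u_i \sim N(0, 0.02^2)$ and voxel noise
  $\varepsilon_{ij} \sim N(0, 0.05^2)$. The subject intercept is kept small:
  it is shared across all voxels, so it sets the inter-voxel correlation
  (and with it $\lVert X \rVert_2$); 0.02 against 0.05 voxel noise gives a
  mild ~14% correlation, which we consider realistic for
  template-normalized GM proportions;
* lesion clusters: 6-connected blobs grown from interior seed centers,
  either as radius-r Euclidean balls or to an exact voxel count
  (`lesion_cluster_voxels`), with effect $-0.2$ GM units in cases;
* procedural-bias voxels: scattered draws from the outermost mask shell
  with effect $+0.1$ in cases. The magnitude of procedural bias is a free
  parameter of the generator — no empirical value exists for it;
* group-matched covariates (age $N(65,9)$, education $N(11,5)$ truncated at
  0, sex Bernoulli(0.46)) and MMSE $= 27 - 65\,\text{load}_i + N(0,4^2)$,
  rounded and clamped to $[0,30]$, where load is the subject's mean planted
  lesion-effect magnitude — at the default effect this puts cases near
  MMSE 14 and controls near 27, emulating a typical AD/NC contrast.

Everything is reproducible from `config$seed` and the caller's RNG state is
restored. What the generator does **not** emulate: registration artifacts
beyond the planted bias, spatially varying templates and noise, covariate
effects on GM, site/scanner effects, or any longitudinal structure. Tests
passing on these cohorts certify the estimator's mechanics and
support-recovery behavior under the stated noise model, not clinical
performance on real MRI.

## Problem sizes used in tests

The test suite and the acceptance script run at deliberately desk-sized
conditions: support recovery uses an 8×10×8 full-ellipsoid mask (P = 344
voxels, 852 lattice edges) with 10 planted lesion voxels and 57/47
subjects; mechanics tests use a 6×6×6 mask (P = 136). At these sizes a full
path fit takes on the order of a second and the complete 10×10-fold
repeated cross-validation a few minutes on one core. The full 24×28×24
(P ≈ 2,500) geometry is exercised for the generator and IO but not for
repeated cross-validation.

## Numerical choices and degenerate inputs

* Logistic terms are evaluated through the softplus identity
  $\log(1+e^\eta) - y\eta$; no probability is ever formed by
  exponentiation.
* Zero-variance feature columns standardize to exact zero (scale 1), so
  constant columns are inert rather than NaN.
* Decision threshold 0.5 with ties assigned to class 0 (controls).
* Predicted-label ties, ranking ties and plateau ties all break toward the
  lower index / earlier time, making every reported selection
  deterministic.
* The iteration itself contains no randomness; seeds only enter fold
  shuffling, selection splits and data simulation.

## Known limitations

* The fused penalty uses face (6-)connectivity only; 18/26-neighborhoods
  are out of scope.
* Downsampling is mean pooling; no trilinear or spline resampling. The
  fine-to-coarse dimension bookkeeping is a convention
  (`round(d·s_f/s_c)+1` by default) — conventions differ between tools and
  the alternatives are selectable.
* `n_key` from `find_plateau()` is a descriptive quantity: when
  classification saturates with very few voxels (as it does at strong
  planted effects), the key-voxel set is much smaller than the full planted
  support, and overlap metrics against the full lesion set are bounded by
  `n_key` itself.
* Cross-cohort testing enforces an identical mask contract; no
  harmonization or site correction is attempted.
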
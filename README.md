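# splitlbi

Voxel-level gray-matter classification with structured sparsity, for
researchers analyzing voxel-based morphometry (VBM) data in case-control
neuroimaging studies (the motivating setting is Alzheimer's disease vs
normal controls). The package provides the estimator, the evaluation
protocol, the interpretation tooling, and a seeded synthetic-cohort
generator for benchmarking support recovery.

## The model

Each subject contributes one gray-matter volume value per in-mask voxel on
a coarse template grid (~2,500 voxels at 8 mm). The classifier minimizes a
logistic loss with a variable-splitting penalty:

```
L(beta, beta0, gamma) = -sum_i [ y_i log sigma(x_i beta + beta0)
                               + (1 - y_i) log(1 - sigma(x_i beta + beta0)) ]
                        + ||D beta - gamma||^2 / (2 nu)
```

`D` stacks an identity block over a rho-weighted 6-neighborhood incidence
block on the in-mask lattice, so `gamma` is sparse both voxel-wise and
across spatial edges. The Split Linearized Bregman Iteration

```
beta  <- beta - kappa * alpha * grad_beta
z     <- z    - alpha * grad_gamma
gamma <- kappa * soft_threshold(z, 1)
```

traces a full regularization path indexed by time `t = kappa * alpha * k`.
Every checkpoint carries two estimators: the **dense** `beta` used for
prediction (it may exploit procedural bias — gray matter mistakenly
enlarged near tissue boundaries during preprocessing), and the **sparse**
`beta_tilde` (`beta` restricted to `gamma`'s support) used for
interpretation, in which spatially contiguous lesion clusters are favored
over scattered boundary voxels. Checkpoints are selected by validation
deviance; evaluation is stratified 10-fold full cross-validation, repeated
10 times, with accuracy/sensitivity/specificity/AUC and 95% t-intervals.

## Worked example

Simulate a cohort with 10 planted atrophy voxels (two 6-connected clusters
of five, effect −0.2 gray-matter units in cases), evaluate it by repeated
cross-validation, and ask the sparse estimator which voxels matter:

```r
library(splitlbi)

cfg <- simulation_config(grid_dims = c(8, 10, 8), mask_semi_axes = 1,
                         n_lesion_clusters = 2, lesion_cluster_voxels = 5,
                         n_bias_voxels = 0, seed = 7)
sim <- simulate_cohort(cfg)
sim$dataset
#> cohort_dataset: 104 subjects (57 cases / 47 controls) x 344 voxels

repeat_cv(sim$dataset, lbi_control(seed = 1), R = 3, K = 10, seed = 1)
#> repeat_cv_result over 3 repeats
#>   accuracy     1.0000  [95% CI 1.0000 - 1.0000]
#>   sensitivity  1.0000  [95% CI 1.0000 - 1.0000]
#>   specificity  1.0000  [95% CI 1.0000 - 1.0000]
#>   auc          1.0000  [95% CI 1.0000 - 1.0000]

model <- train_full(sim$dataset, lbi_control(seed = 1))
model
#> splitlbi_model: P = 344 voxels, t = 75.96, sparse support 10

op <- build_difference_operator(sim$dataset$mask, 1)
st <- lbi_state(model$beta, model$intercept, model$gamma, model$z)
sparse_projection(st, op)$support
#>  [1]  42  83  90  91  92 216 268 275 276 277
sim$truth$lesion
#>  [1]  42  83  90  91  92 216 268 275 276 277
```

At this planted effect size the cohort is cleanly separable (all metrics
1.0), and the sparse support recovers exactly the ten planted lesion
voxels. Weaker effects, subject/voxel noise levels, procedural-bias voxels
and null (zero-effect) cohorts are all one `simulation_config()` call away;
`topn_accuracy_curve()`/`find_plateau()` give the key-voxel count,
`aggregate_by_atlas()` the per-region weight table, and
`external_test()` the train-on-one-cohort/test-on-another transfer metrics.

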
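test_that("weight ranking orders by |beta| with stable ties", {
  expect_identical(rank_weights(c(0.1, -0.9, 0.5)), c(2L, 3L, 1L))
  expect_identical(rank_weights(rep(0, 4)), 1:4)
  set.seed(3)
  b <- rnorm(50)
  expect_identical(rank_weights(b), order(-abs(b), seq_along(b)))
  expect_identical(rank_weights(b, signed = TRUE),
                   order(-b, seq_along(b)))
})

test_that("plateau detection returns the earliest sustained maximum", {
  expect_identical(find_plateau(c(0.6, 0.8, 0.9, 0.9, 0.9)), 3L)
  # strictly increasing curve: the full model is needed
  expect_identical(find_plateau(c(0.5, 0.6, 0.7, 0.8)), 4L)
  expect_identical(find_plateau(c(0.9, 0.9, 0.9)), 1L)
  # no exact return to the max: fall back to the terminal constant run
  expect_identical(find_plateau(c(0.6, 0.95, 0.9, 0.9, 0.9)), 3L)
  # tolerance admits near-plateaus
  expect_identical(find_plateau(c(0.6, 0.89, 0.9, 0.9, 0.9), eps = 0.011), 2L)
  expect_error(find_plateau(numeric(0)), "empty")
})

test_that("nearest-neighbor upsampling matches brute-force nearest centers", {
  # identical grids: identity map
  set.seed(5)
  vol <- array(rnorm(27), c(3, 3, 3))
  expect_equal(upsample_nearest(vol, 8, c(3, 3, 3), 8), vol)
  # one coarse voxel: constant fine volume
  one <- array(2.5, c(1, 1, 1))
  expect_equal(upsample_nearest(one, 8, c(8, 8, 8), 1),
               array(2.5, c(8, 8, 8)))
  # 2-coarse-voxel line upsampled x8: step function at the midpoint
  line <- array(c(1, 2), c(2, 1, 1))
  fine <- upsample_nearest(line, 8, c(16, 1, 1), 1)
  expect_equal(as.numeric(fine), c(rep(1, 8), rep(2, 8)))
  # brute-force oracle voxel by voxel on an asymmetric case
  coarse <- array(rnorm(12), c(3, 2, 2))
  fr <- upsample_nearest(coarse, c(6, 4, 4), c(9, 4, 4), c(2, 2, 2))
  for (i in 1:9) for (j in 1:4) for (k in 1:4) {
    cf <- c((i - 0.5) * 2, (j - 0.5) * 2, (k - 0.5) * 2)
    best <- c(which.min(abs((seq_len(3) - 0.5) * 6 - cf[1])),
              which.min(abs((seq_len(2) - 0.5) * 4 - cf[2])),
              which.min(abs((seq_len(2) - 0.5) * 4 - cf[3])))
    expect_equal(fr[i, j, k], coarse[best[1], best[2], best[3]])
  }
  expect_error(upsample_nearest(coarse, 8, c(50, 4, 4), 1), "extents")
})

test_that("atlas aggregation computes volumes, centroids and percentages", {
  w <- array(0, c(4, 4, 2))
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  w[1, 1, 1] <- -2; w[2, 1, 1] <- 1   # region 1: |w| sum = 3
  w[3, 1, 1] <- 1                     # region 2: |w| sum = 1
  tab <- aggregate_by_atlas(w, atlas, voxel_mm = c(1, 1, 1))
  expect_identical(tab$id, c(1L, 2L))
  expect_equal(tab$weight, c(3, 1))
  expect_equal(tab$weight_percent, c(75, 25))
  expect_equal(tab$volume_mm3, c(16, 16))
  expect_equal(tab$centroid_x[1], 1)   # mean of centers 0.5 and 1.5
  # single region: one row at 100%
  tab1 <- aggregate_by_atlas(w, array(1L, dim(w)))
  expect_identical(nrow(tab1), 1L)
  expect_equal(tab1$weight_percent, 100)
  # percentages always sum to 100 (within 1e-9) for nonzero totals
  set.seed(8)
  wr <- array(rnorm(32), c(4, 4, 2))
  ar <- array(sample(1:5, 32, replace = TRUE), c(4, 4, 2))
  tr <- aggregate_by_atlas(wr, ar)
  expect_lt(abs(sum(tr$weight_percent) - 100), 1e-9)
  # signed aggregation can differ from absolute
  ts <- aggregate_by_atlas(w, atlas, absolute = FALSE)
  expect_equal(ts$weight[ts$id == 1], -1)
  expect_error(aggregate_by_atlas(w, array(0L, dim(w))), "no positive labels")
})

test_that("the top-n accuracy curve reproduces the full model at n = P", {
  sim <- simulate_cohort(small_config(720))
  op <- build_difference_operator(sim$dataset$mask, 1)
  cv <- run_cv(sim$dataset, lbi_control(seed = 4), op = op)
  im <- interpretation_model(cv, sim$dataset, lbi_control(seed = 4))
  rk <- rank_weights(im$beta / im$std$scale)
  curve <- topn_accuracy_curve(cv, sim$dataset, rk)
  P <- nrow(curve)
  expect_equal(curve$accuracy[P], cv$metrics[["accuracy"]])
  n_key <- attr(curve, "n_key")
  expect_lte(n_key, P)
  # accuracy at the plateau point reproduces the full-model accuracy
  expect_equal(curve$accuracy[n_key], curve$accuracy[P])
  # the curve reaches its maximum well before the full feature count
  expect_lt(n_key, P / 2)
  # key voxels concentrate on the planted lesions
  k <- min(n_key, length(sim$truth$lesion))
  expect_true(all(rk[seq_len(k)] %in% sim$truth$lesion))
})

test_that("a model with one nonzero weight yields a flat curve", {
  sim <- simulate_cohort(small_config(721))
  op <- build_difference_operator(sim$dataset$mask, 1)
  cv <- run_cv(sim$dataset, lbi_control(seed = 4), op = op)
  # overwrite fold models with a single shared nonzero weight
  for (f in seq_along(cv$models)) {
    b <- numeric(ncol(sim$dataset$features)); b[3] <- 1.2
    cv$models[[f]]$state$beta <- b
    cv$models[[f]]$state$intercept <- 0.1
  }
  curve <- topn_accuracy_curve(cv, sim$dataset, ranking = NULL)
  expect_equal(stats::var(curve$accuracy), 0)
})

test_that("partial correlation reduces to Pearson and nulls exact fits", {
  set.seed(10)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  pc <- partial_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value)
  # y an exact linear function of the covariates: r = 0
  Z <- cbind(rnorm(40), rnorm(40))
  ylin <- 2 + Z %*% c(1.5, -0.7)
  pc0 <- partial_correlation(x, as.numeric(ylin), Z)
  expect_lt(abs(pc0$r), 1e-12)
  # inverse-correlation-matrix oracle for the general case
  y2 <- 0.4 * x + Z %*% c(1, 0.5) + rnorm(40)
  pc2 <- partial_correlation(x, as.numeric(y2), Z)
  Rm <- stats::cor(cbind(x, as.numeric(y2), Z))
  Km <- solve(Rm)
  r_oracle <- -Km[1, 2] / sqrt(Km[1, 1] * Km[2, 2])
  expect_equal(pc2$r, r_oracle, tolerance = 1e-10)
  expect_error(partial_correlation(x, as.numeric(y2), cbind(Z, Z[, 1])),
               "rank deficient")
  expect_error(partial_correlation(1:3, 1:3, Z[1:3, ]), "need n")
})

test_that("summary t-tests reproduce the demographics-table comparisons", {
  # age: 65.21 +/- 9.14 (n = 57) vs 63.94 +/- 8.06 (n = 47), pooled variance
  age <- ttest_from_summary(65.21, 9.14, 57, 63.94, 8.06, 47)
  expect_identical(age$df, 102)
  expect_equal(round(age$p, 2), 0.46)
  # identical groups: t = 0, p = 1
  same <- ttest_from_summary(5, 1, 20, 5, 1, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # education: pooled ~0.45, Welch variant reproduces the printed 0.43
  edu_p <- ttest_from_summary(10.56, 6.47, 57, 11.36, 3.59, 47)
  expect_equal(round(edu_p$p, 2), 0.45)
  edu_w <- ttest_from_summary(10.56, 6.47, 57, 11.36, 3.59, 47, welch = TRUE)
  expect_equal(round(edu_w$p, 2), 0.43)
  expect_error(ttest_from_summary(1, 0, 5, 2, 1, 5), "sd")
})

test_that("2x2 chi-square matches the expected-counts oracle", {
  # perfectly proportional table: statistic 0, p = 1
  prop <- chisq_2x2(matrix(c(20, 10, 40, 20), 2, 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  # sex table 25/32 vs 23/24 against the definitional sum((O-E)^2/E)
  tab <- rbind(c(25, 32), c(23, 24))
  got <- chisq_2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E))
  expect_equal(round(got$statistic, 3), 0.267)
  expect_equal(round(got$p, 2), 0.61)
  expect_equal(got$df, 1)
  # swapping rows leaves the statistic unchanged
  expect_equal(chisq_2x2(tab[2:1, ])$statistic, got$statistic)
  # Yates correction shrinks the statistic
  expect_lt(chisq_2x2(tab, yates = TRUE)$statistic, got$statistic)
  expect_error(chisq_2x2(rbind(c(0, 0), c(1, 2))), "marginal")
})
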
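test_that("constant-dose voxel reduces to the intercept-only event rate", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 0)
  f <- fit_voxel_glm(rep(2, 8), y)
  expect_true(f$zero_variance)
  expect_equal(unname(f$coefficients["dose"]), 0)
  expect_equal(unname(plogis(f$coefficients["(Intercept)"])), mean(y))
  expect_equal(f$vcov[2, 2], Inf)
})

test_that("complete separation is flagged and penalised to a finite slope", {
  f <- fit_voxel_glm(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_true(f$separation_flag)
  expect_true(is.finite(f$coefficients["dose"]))
  expect_gt(f$coefficients["dose"], 0)
})

test_that("single-voxel MLE matches glm() on a clean logistic sample", {
  set.seed(7)
  d <- runif(120, 0, 3)
  y <- rbinom(120, 1, plogis(-1 + 0.9 * d))
  f <- fit_voxel_glm(d, y)
  ref <- glm(y ~ d, family = binomial())
  expect_false(f$separation_flag)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f$vcov, unname(vcov(ref)), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("slope is recovered within 3 SE at N = 200", {
  set.seed(31)
  d <- runif(200, 0, 4)
  y <- rbinom(200, 1, plogis(-2 + 0.8 * d))
  f <- fit_voxel_glm(d, y)
  se <- sqrt(f$vcov[2, 2])
  expect_lt(abs(f$coefficients["dose"] - 0.8), 3 * se)
})

test_that("covariates enter the voxel model and match glm()", {
  set.seed(12)
  d <- runif(80); v <- rnorm(80)
  y <- rbinom(80, 1, plogis(-0.5 + d + 0.5 * v))
  f <- fit_voxel_glm(d, y, covariates = cbind(v))
  ref <- glm(y ~ d + v, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
})

test_that("fit_backbone keeps one model per ROI voxel and is permutation-equivariant", {
  roi <- matrix(FALSE, 3, 3); roi[c(2, 5)] <- TRUE
  g <- grid_spec(c(3, 3), roi = roi)
  set.seed(5)
  maps <- replicate(12, matrix(runif(9), 3, 3), simplify = FALSE)
  co <- tibble::tibble(id = as.character(1:12), dose = maps,
                       outcome = rep(c(0L, 1L), 6))
  bb <- fit_backbone(co, grid = g)
  expect_equal(nrow(bb$coef), 2)
  perm <- sample(12)
  bb2 <- fit_backbone(co[perm, ], grid = g)
  expect_equal(bb$coef, bb2$coef, tolerance = 1e-9)
})

test_that("planted informative voxel out-scores a noise voxel", {
  zsig <- zno <- numeric(6)
  for (s in 1:6) {
    co <- planted_cohort(n = 80, signal_voxel = 6, seed = s)
    bb <- fit_backbone(co)
    z <- abs(bb$coef[, 2]) / sqrt(bb$vcov[, 2, 2])
    zsig[s] <- z[6]; zno[s] <- z[11]
  }
  expect_gt(mean(zsig), mean(zno))
})

test_that("null dose-effect calibration: ~5% of voxels reach p < 0.05", {
  set.seed(99)
  frac <- numeric(12)
  g <- grid_spec(c(6, 6))
  for (s in seq_along(frac)) {
    maps <- replicate(60, matrix(runif(36), 6, 6), simplify = FALSE)
    co <- tibble::tibble(id = as.character(1:60), dose = maps,
                         outcome = sample(rep(0:1, 30)))
    bb <- fit_backbone(co, grid = g)
    z <- bb$coef[, 2] / sqrt(bb$vcov[, 2, 2])
    frac[s] <- mean(2 * pnorm(-abs(z)) < 0.05)
  }
  expect_lt(abs(mean(frac) - 0.05), 0.03)
})

test_that("prediction maps obey the P/W contracts", {
  co <- tiny_s2g_cohort(n = 50, seed = 3)
  bb <- fit_backbone(co)
  pm <- predict_maps(bb, co$dose[[1]])
  roi <- bb$grid$roi
  expect_true(all(pm$p_map[roi] >= 0 & pm$p_map[roi] <= 1))
  expect_true(all(pm$w_map[roi] >= 0))
  # W = 1/width where OR >= 1; W = 0 where the dose slope is negative
  neg <- roi_mat <- matrix(FALSE, 8, 8)
  neg[roi][bb$coef[, 2] < 0] <- TRUE
  expect_true(all(pm$w_map[neg] == 0))
  pos <- roi & !neg
  expect_equal(pm$w_map[pos], 1 / pm$ci_width_map[pos])
})

test_that("intercept-zero voxel model predicts exactly one half", {
  # hand-built single-voxel backbone: coefficients (0, 0) -> P = 0.5
  bb <- structure(list(
    coef = matrix(c(0, 0), 1, 2),
    vcov = array(c(0.04, 0, 0, 0.01), dim = c(1, 2, 2)),
    converged = TRUE, separated = FALSE, zero_var = FALSE,
    grid = grid_spec(2), covariate_names = character(),
    n_train = 10, event_rate = 0.5
  ), class = "pace_backbone")
  pw <- pace:::predict_pw(bb, matrix(5, 1, 1))
  expect_equal(pw$p[1, 1], 0.5)
})

test_that("Wald CI width on P agrees with a direct logit-interval oracle", {
  # coefficients (-1, 1), dose 1 -> eta = 0, P = 0.5
  V <- matrix(c(0.09, -0.02, -0.02, 0.04), 2, 2)
  bb <- structure(list(
    coef = matrix(c(-1, 1), 1, 2),
    vcov = array(V, dim = c(1, 2, 2)),
    converged = TRUE, separated = FALSE, zero_var = FALSE,
    grid = grid_spec(2), covariate_names = character(),
    n_train = 10, event_rate = 0.5
  ), class = "pace_backbone")
  pw <- pace:::predict_pw(bb, matrix(1, 1, 1))
  expect_equal(pw$p[1, 1], 0.5)
  x <- c(1, 1)
  se <- sqrt(drop(t(x) %*% V %*% x))
  width <- plogis(1.959964 * se) - plogis(-1.959964 * se)
  expect_equal(pw$ci_width[1, 1], width, tolerance = 1e-6)
  expect_equal(pw$w[1, 1], 1 / width, tolerance = 1e-6)
})

test_that("backbone converges to generative probabilities at large N", {
  # well-specified single-peak generative model, 3 probe voxels
  set.seed(17)
  g <- grid_spec(c(4, 4))
  n <- 600
  maps <- replicate(n, matrix(runif(16, 0, 2), 4, 4), simplify = FALSE)
  b0 <- -1.2; b1 <- 1.1; vox <- c(1, 6, 16)
  dsig <- vapply(maps, function(m) m[6], numeric(1))
  y <- rbinom(n, 1, plogis(b0 + b1 * dsig))
  co <- tibble::tibble(id = as.character(1:n), dose = maps, outcome = y)
  bb <- fit_backbone(co, grid = g)
  pm <- predict_maps(bb, maps[[1]])
  # at the signal voxel the fitted P must be within 3 SE of the truth
  eta_hat <- bb$coef[6, 1] + bb$coef[6, 2] * maps[[1]][6]
  x <- c(1, maps[[1]][6])
  se <- sqrt(drop(t(x) %*% bb$vcov[6, , ] %*% x))
  eta_true <- b0 + b1 * maps[[1]][6]
  expect_lt(abs(eta_hat - eta_true), 3 * se)
  expect_equal(pm$p_map[6], plogis(eta_hat))
})

test_that("missing covariate values are rejected at prediction time", {
  co <- tiny_s2g_cohort(n = 30, seed = 6)
  co$age <- rnorm(30, 60, 8)
  bb <- fit_backbone(co, covariates = "age")
  expect_error(predict_maps(bb, co$dose[[1]]), "covariates")
  pm <- predict_maps(bb, co$dose[[1]], test_covariates = c(age = 61))
  expect_true(all(pm$p_map[bb$grid$roi] >= 0))
})
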
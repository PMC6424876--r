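test_that("gEUp fixed points, hand value and exponent identity", {
  w <- c(2, 1, 5)
  for (nu in c(0.05, 0.5, 1)) {
    expect_equal(geup(rep(0.3, 3), w, nu), 0.3)
  }
  expect_equal(geup(c(0.04, 0.36), c(1, 3), 0.5), sqrt(0.0976))
  p <- c(0.2, 0.5, 0.9)
  expect_equal(geup(p, w, 1), sum(p * w) / sum(w))
  expect_error(geup(p, c(0, 0, 0), 0.5), "zero")
  expect_error(geup(p, w, 0), "nu")
})

test_that("gEUp is invariant under positive rescaling of W", {
  set.seed(3)
  p <- runif(50); w <- rexp(50)
  for (nu in c(0.1, 0.7)) {
    expect_equal(geup(p, w, nu), geup(p, 1000 * w, nu))
    expect_equal(geup(p, w, nu), geup(p, w / 17, nu))
  }
})

test_that("gEUp stays between min and max P over positive-W voxels", {
  set.seed(8)
  for (i in 1:10) {
    p <- runif(30); w <- rexp(30) * rbinom(30, 1, 0.7)
    if (sum(w) == 0) next
    nu <- runif(1, 0.02, 1)
    g <- geup(p, w, nu)
    expect_gte(g, min(p[w > 0]) - 1e-12)
    expect_lte(g, max(p[w > 0]) + 1e-12)
  }
})

test_that("small nu drives gEUp toward the high-P voxel", {
  p <- c(0.9, rep(0.1, 9)); w <- rep(1, 10)
  g <- vapply(c(1, 0.5, 0.2, 0.05), function(nu) geup(p, w, nu), numeric(1))
  expect_true(all(diff(g) > 0))  # gEUp increases as nu decreases
  expect_lt(max(g), 0.9 + 1e-12)
})

test_that("the PACE sigmoid hits its midpoint, slope point and monotonicity", {
  expect_equal(pace_probability(0.4, 0.35, 0.4), 0.5)
  expect_equal(pace_probability(0.4 * 1.35, 0.35, 0.4), pnorm(1))
  g <- seq(0.01, 0.99, length.out = 25)
  expect_true(all(diff(pace_probability(g, 0.3, 0.5)) > 0))
})

test_that("pace_loglik matches a hand-summed Bernoulli log-likelihood", {
  # 3 patients, single voxel with W = 1 so gEUp = P exactly
  P <- matrix(c(0.2, 0.6, 0.8), 3, 1)
  W <- matrix(1, 3, 1)
  y <- c(0, 1, 1)
  mu <- 0.4; tp50 <- 0.5
  pi <- pnorm((c(0.2, 0.6, 0.8) - tp50) / (mu * tp50))
  hand <- sum(y * log(pi) + (1 - y) * log(1 - pi))
  expect_equal(pace_loglik(c(0.5, mu, tp50), P, W, y), hand)
  # flat-probability parameters give -N log 2
  Ph <- matrix(0.5, 4, 2); Wh <- matrix(1, 4, 2)
  expect_equal(pace_loglik(c(1, 0.5, 0.5), Ph, Wh, c(0, 1, 0, 1)),
               -4 * log(2))
})

test_that("fitting a duplicated cohort doubles the log-likelihood exactly", {
  co <- tiny_s2g_cohort(n = 40, seed = 13)
  g <- attr(co, "grid")
  co2 <- dplyr::bind_rows(co, co)
  co2$id <- as.character(seq_len(nrow(co2)))
  attr(co2, "grid") <- g
  f1 <- fit_pace(co, conf_int = FALSE)
  # duplicate the P/W maps instead of refitting the (different) backbone
  bb <- f1$backbone
  D <- pace:::roi_matrix(co$dose, g)
  pw <- pace:::predict_pw(bb, D)
  fa <- fit_pace_maps(pw$p, pw$w, co$outcome, conf_int = FALSE)
  fb <- fit_pace_maps(rbind(pw$p, pw$p), rbind(pw$w, pw$w),
                      rep(co$outcome, 2), conf_int = FALSE)
  expect_equal(fa$params$estimate, fb$params$estimate, tolerance = 1e-3)
  expect_equal(2 * fa$loglik, fb$loglik, tolerance = 1e-4)
})

test_that("fitted model dominates the prevalence-only likelihood", {
  co <- tiny_s2g_cohort(n = 50, seed = 19)
  f <- fit_pace(co, conf_int = FALSE)
  prev <- mean(co$outcome)
  ll0 <- sum(co$outcome * log(prev) + (1 - co$outcome) * log(1 - prev))
  expect_gte(f$loglik, ll0 - 1e-6)
})

test_that("predict() composes the three stages exactly", {
  co <- tiny_s2g_cohort(n = 40, seed = 23)
  f <- fit_pace(co, conf_int = FALSE)
  est <- setNames(f$params$estimate, f$params$term)
  test_map <- co$dose[[5]]
  pm <- predict_maps(f$backbone, test_map)
  roi <- f$grid$roi
  manual_ge <- geup(pm$p_map[roi], pm$w_map[roi], est["nu"])
  manual <- pace_probability(manual_ge, est["mu"], est["tp50"])
  auto <- predict(f, test_map)
  expect_equal(auto$.pred, unname(manual), tolerance = 1e-10)
  expect_equal(auto$geup, unname(manual_ge), tolerance = 1e-10)
  # scaling all W by a positive constant leaves the prediction unchanged
  expect_equal(manual,
               pace_probability(geup(pm$p_map[roi], 7.3 * pm$w_map[roi],
                                     est["nu"]),
                                est["mu"], est["tp50"]))
})

test_that("a test gEUp equal to Tp50 predicts exactly one half", {
  est <- c(nu = 0.3, mu = 0.4, tp50 = 0.6)
  expect_equal(pace_probability(est["tp50"], est["mu"], est["tp50"]),
               c(tp50 = 0.5))
})

test_that("all-zero reliability falls back to the training prevalence", {
  co <- tiny_s2g_cohort(n = 40, seed = 29)
  f <- fit_pace(co, conf_int = FALSE)
  # a backbone whose slopes are all negative yields W = 0 everywhere
  f2 <- f
  f2$backbone$coef[, 2] <- -abs(f2$backbone$coef[, 2]) - 0.1
  expect_warning(pr <- predict(f2, co$dose[[1]]), "fallback")
  expect_equal(pr$.pred, f$fallback_probability)
})

test_that("parameters are recovered from the true generative maps", {
  # simulate from a PACE model with known parameters using exact P/W maps
  true <- c(nu = 0.1, mu = 0.35, tp50 = 0.5)
  hits <- logical(10)
  for (s in seq_along(hits)) {
    set.seed(300 + s)
    N <- 500; M <- 64
    P <- matrix(runif(N * M), N, M)
    W <- matrix(rexp(N * M), N, M)
    ge <- vapply(seq_len(N), function(i) geup(P[i, ], W[i, ], true["nu"]),
                 numeric(1))
    y <- rbinom(N, 1, pace_probability(ge, true["mu"], true["tp50"]))
    if (length(unique(y)) < 2) next
    f <- fit_pace_maps(P, W, y, conf_int = TRUE)
    hits[s] <- all(f$params$conf.low <= true & true <= f$params$conf.high)
  }
  expect_gte(mean(hits), 0.7)  # joint 3-parameter coverage, 10 replicates
})
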
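test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    p <- round(runif(n), 2)  # rounded to force ties
    expect_equal(roc_auc(p, y)$auc, auc_pairs(p, y))
  }
})

test_that("AUC edge cases and invariances", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), y)$auc, 1)
  set.seed(1)
  yb <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(runif(2000), yb)$auc - 0.5), 0.05)
  # invariant under strictly monotone transforms of the score
  p <- runif(60); yy <- rbinom(60, 1, 0.3); yy[1:2] <- c(0, 1)
  expect_equal(roc_auc(p, yy)$auc, roc_auc(qlogis(p), yy)$auc)
  expect_equal(roc_auc(p, yy)$auc, roc_auc(p^3, yy)$auc)
  expect_error(roc_auc(p, rep(1, 60)), "single class")
})

test_that("Hanley-McNeil SE and CI agree with pROC's DeLong to first order", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(120, 1, 0.3); y[1:2] <- c(0, 1)
  p <- plogis(rnorm(120) + y)
  r <- roc_auc(p, y)
  ref <- pROC::roc(y, p, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
  expect_equal(r$se, sqrt(pROC::var(ref)), tolerance = 0.25)
  expect_true(r$conf.low < r$auc && r$auc < r$conf.high)
})

test_that("compare_auc: identical predictions give Z = 0, p = 1", {
  set.seed(2)
  y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  p <- runif(40)
  cmp <- compare_auc(p, p, y)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p.value, 1)
  expect_error(compare_auc(p, p[-1], y), "same patients")
})

test_that("compare_auc has power: generator model beats noise at N = 200", {
  wins <- logical(10)
  for (s in seq_along(wins)) {
    set.seed(600 + s)
    n <- 200
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 2 * x))
    if (length(unique(y)) < 2) next
    pa <- plogis(-1 + 2 * x)        # generator probabilities
    pb <- runif(n)                  # random predictor
    wins[s] <- compare_auc(pa, pb, y)$p.value < 0.05
  }
  expect_gte(mean(wins), 0.8)
})

test_that("calibration recovers a hand-computed binned OLS", {
  # 3 bins with hand-set predictions and outcomes
  probs <- c(rep(0.1, 4), rep(0.5, 4), rep(0.9, 4))
  out <- c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1, 1, 0)
  cal <- calibration(probs, out, n_bins = 3)
  x <- c(0.1, 0.5, 0.9); yb <- c(0.25, 0.5, 0.75)
  ref <- lm(yb ~ x)
  sm <- suppressWarnings(summary(ref))
  expect_equal(cal$slope, unname(coef(ref)[2]))
  expect_equal(cal$intercept, unname(coef(ref)[1]))
  expect_equal(cal$r_squared, sm$r.squared)
  expect_equal(cal$slope_se, sm$coefficients[2, 2])
})

test_that("perfectly calibrated bins give slope 1, intercept 0, R2 1", {
  probs <- rep(c(0.2, 0.4, 0.8), each = 10)
  set.seed(3)
  out <- unlist(lapply(c(0.2, 0.4, 0.8), function(p) {
    v <- rep(0, 10); v[seq_len(round(10 * p))] <- 1; sample(v)
  }))
  cal <- calibration(probs, out, n_bins = 3)
  expect_equal(cal$slope, 1)
  expect_equal(abs(cal$intercept), 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_error(calibration(rep(0.3, 30), out, n_bins = 3), "constant")
  expect_error(calibration(probs, out, n_bins = 2), "n_bins")
})

test_that("classification metrics match hand confusion-matrix arithmetic", {
  m <- classification_metrics(c(0.9, 0.2), c(1, 0))
  expect_equal(m$accuracy, 1); expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$f1, 1)
  # all predicted negative at prevalence 0.2
  m2 <- classification_metrics(rep(0.1, 10), c(rep(1, 2), rep(0, 8)))
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$balanced_accuracy, 0.5)
  expect_equal(m2$f1, 0)
  # TP=10 FP=5 TN=70 FN=15
  y <- c(rep(1, 10), rep(0, 5), rep(0, 70), rep(1, 15))
  p <- c(rep(0.9, 10), rep(0.9, 5), rep(0.1, 70), rep(0.1, 15))
  m3 <- classification_metrics(p, y)
  expect_equal(m3$accuracy, 0.80)
  expect_equal(m3$balanced_accuracy, (10 / 25 + 70 / 75) / 2)
  expect_equal(m3$f1, 0.5)
})

test_that("balanced accuracy equals accuracy on balanced classes", {
  y <- rep(c(0, 1), 20)
  set.seed(6)
  p <- ifelse(y == 1, 0.7, 0.35) + rnorm(40, 0, 0.05)
  m <- classification_metrics(p, y)
  # constructed so that errors are symmetric across classes
  if (m$tp / (m$tp + m$fn) == m$tn / (m$tn + m$fp)) {
    expect_equal(m$balanced_accuracy, m$accuracy)
  }
  m0 <- classification_metrics(ifelse(y == 1, 0.9, 0.1), y)
  expect_equal(m0$balanced_accuracy, m0$accuracy)
})

test_that("LOO with the prevalence model predicts the majority class", {
  co <- tiny_s2g_cohort(n = 20, shape = c(4, 4), seed = 41, event_rate = 0.3)
  res <- loo_cv(co, model = "prevalence")
  maj <- mean(co$outcome == as.integer(mean(co$outcome) > 0.5))
  expect_equal(res$report$metrics$accuracy, maj)
  # each held-out prediction is the event rate of the other N-1 patients
  expect_equal(res$predictions$.pred,
               vapply(seq_len(20), function(i) mean(co$outcome[-i]),
                      numeric(1)))
})

test_that("LOO prediction for a patient ignores that patient's outcome", {
  co <- tiny_s2g_cohort(n = 14, shape = c(4, 4), seed = 43, event_rate = 0.5)
  i <- 3
  res1 <- loo_cv(co, model = "lkb", n_starts = 4)
  co_flip <- co
  co_flip$outcome[i] <- 1L - co_flip$outcome[i]
  attr(co_flip, "grid") <- attr(co, "grid")
  res2 <- loo_cv(co_flip, model = "lkb", n_starts = 4)
  expect_equal(res1$predictions$.pred[i], res2$predictions$.pred[i])
})

test_that("learning_curve returns seeded, well-formed accuracy rows", {
  rs <- make_rs_map(c(6, 6), "s2g")
  lc <- learning_curve(train_sizes = c(20, 30), models = "lkb",
                       n_replicates = 2, validation_size = 40,
                       grid = grid_spec(c(6, 6)), rs = rs, n_exp = 0.5,
                       event_rate = 0.4, n_starts = 4, seed = 3)
  expect_s3_class(lc, "pace_learning_curve")
  expect_equal(nrow(lc), 4)
  expect_true(all(lc$validation_accuracy >= 0 & lc$validation_accuracy <= 1))
  lc2 <- learning_curve(train_sizes = c(20, 30), models = "lkb",
                        n_replicates = 2, validation_size = 40,
                        grid = grid_spec(c(6, 6)), rs = rs, n_exp = 0.5,
                        event_rate = 0.4, n_starts = 4, seed = 3)
  expect_equal(lc$validation_accuracy, lc2$validation_accuracy)
  s <- summarize_learning_curve(lc)
  expect_equal(nrow(s), 2)
  expect_error(learning_curve(train_sizes = 10), ">= 20")
})
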
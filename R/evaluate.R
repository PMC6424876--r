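#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC by the Mann-Whitney construction (probability that a random event
#' patient receives a higher prediction than a random non-event patient,
#' ties counted half), standard error by the Hanley-McNeil formula, and a
#' 95% CI from a Wald interval on the logit of the AUC (which keeps the
#' interval inside \[0, 1\]).
#'
#' @param probs Numeric predictions (any monotone score).
#' @param outcomes Binary outcomes, both classes present.
#' @param level CI level (default 0.95).
#' @return A tibble with `auc`, `se`, `conf.low`, `conf.high`, `n_events`,
#'   `n_nonevents`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(probs, outcomes, level = 0.95) {
  y <- check_outcomes(outcomes)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(probs)
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (a <= 0 || a >= 1 || se == 0) {
    ci <- c(max(0, a - z * se), min(1, a + z * se))
  } else {
    la <- stats::qlogis(a)
    sel <- se / (a * (1 - a))
    ci <- stats::plogis(c(la - z * sel, la + z * sel))
  }
  tibble::tibble(auc = a, se = se, conf.low = ci[1], conf.high = ci[2],
                 n_events = n1, n_nonevents = n0)
}

#' Z-test comparison of two correlated AUCs
#'
#' Compares two models' AUCs measured on the same patients:
#' \eqn{Z = (AUC_a - AUC_b)/SE_{diff}} with
#' \eqn{SE_{diff}^2 = SE_a^2 + SE_b^2 - 2 r\, SE_a SE_b}, where the
#' between-model correlation `r` is approximated by the average of the
#' Spearman correlations of the two prediction vectors within events and
#' within non-events.
#'
#' @param probs_a,probs_b Prediction vectors of the two models on the same
#'   patients.
#' @param outcomes Shared binary outcomes.
#' @return A tibble with `auc_a`, `auc_b`, `z`, `p.value`, `r`.
#' @export
compare_auc <- function(probs_a, probs_b, outcomes) {
  if (length(probs_a) != length(probs_b) ||
      length(probs_a) != length(outcomes)) {
    stop("prediction vectors and outcomes must describe the same patients",
         call. = FALSE)
  }
  y <- check_outcomes(outcomes)
  ra <- roc_auc(probs_a, y)
  rb <- roc_auc(probs_b, y)
  cor_in <- function(cls) {
    pa <- probs_a[y == cls]; pb <- probs_b[y == cls]
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(0)
    stats::cor(pa, pb, method = "spearman")
  }
  r <- mean(c(cor_in(1), cor_in(0)))
  se_diff <- sqrt(max(ra$se^2 + rb$se^2 - 2 * r * ra$se * rb$se, 0))
  z <- if (se_diff > 0) (ra$auc - rb$auc) / se_diff else 0
  tibble::tibble(auc_a = ra$auc, auc_b = rb$auc, z = z,
                 p.value = 2 * stats::pnorm(-abs(z)), r = r)
}

#' Calibration slope, intercept and R-squared
#'
#' Patients are grouped into equal-count bins by predicted probability; the
#' observed event fraction per bin is regressed (ordinary least squares) on
#' the mean predicted probability per bin. A well-calibrated model has
#' slope 1 and intercept 0 (calibration-in-the-large).
#'
#' @inheritParams roc_auc
#' @param n_bins Number of equal-count bins (default 10, minimum 3); bins
#'   emptied by ties are merged with their neighbour.
#' @return A tibble with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared`, `n_bins`, plus the binned table in attribute `"bins"`.
#' @export
calibration <- function(probs, outcomes, n_bins = 10) {
  if (n_bins < 3) stop("n_bins must be >= 3", call. = FALSE)
  y <- check_outcomes(outcomes)
  n <- length(y)
  n_bins <- min(n_bins, n)
  # equal-count assignment by prediction order (stable under ties)
  ord <- order(probs)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  tab <- tibble::tibble(bin = bin, pred = probs, obs = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(pred = mean(.data$pred), obs = mean(.data$obs),
                     n = dplyr::n(), .groups = "drop")
  if (stats::sd(tab$pred) == 0) {
    stop("constant predictions: calibration slope undefined", call. = FALSE)
  }
  fit <- stats::lm(obs ~ pred, data = tab)
  # exact fits (R2 = 1) are legitimate here; silence summary.lm's caveat
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  out <- tibble::tibble(
    slope = cf["pred", "Estimate"], slope_se = cf["pred", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared,
    n_bins = nrow(tab)
  )
  attr(out, "bins") <- tab
  out
}

#' Threshold classification metrics
#'
#' Accuracy, balanced accuracy and F1 score of the binarised predictions:
#' accuracy = (TP+TN)/(P+N), balanced accuracy = (TP/P + TN/N)/2,
#' F1 = 2TP / (2TP + FP + FN).
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold on the probabilities
#'   (default 0.5; predictions strictly above it are called events).
#' @return A tibble with `accuracy`, `balanced_accuracy`, `f1` and the
#'   confusion counts.
#' @export
classification_metrics <- function(probs, outcomes, threshold = 0.5) {
  y <- as.integer(outcomes)
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  p <- tp + fn; n <- tn + fp
  sens <- if (p > 0) tp / p else NA_real_
  spec <- if (n > 0) tn / n else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tibble::tibble(
    accuracy = (tp + tn) / (p + n),
    balanced_accuracy = mean(c(sens, spec)),
    f1 = f1,
    tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold
  )
}

#' Assemble a full evaluation report from predictions
#'
#' Bundles discrimination (AUC with SE and CI), calibration
#' (slope/intercept/R-squared over equal-count bins) and threshold
#' classification metrics for one vector of predicted probabilities.
#'
#' @inheritParams roc_auc
#' @inheritParams calibration
#' @inheritParams classification_metrics
#' @param ids Optional patient identifiers for the per-patient table.
#' @return An object of class `pace_eval`: list with `auc`, `calibration`,
#'   `metrics`, `predictions`.
#' @export
evaluate_predictions <- function(probs, outcomes, ids = NULL, n_bins = 10,
                                 threshold = 0.5) {
  cal <- tryCatch(calibration(probs, outcomes, n_bins = n_bins),
                  error = function(e) {
                    warning("calibration undefined: ", conditionMessage(e))
                    NULL
                  })
  structure(list(
    auc = roc_auc(probs, outcomes),
    calibration = cal,
    metrics = classification_metrics(probs, outcomes, threshold),
    predictions = tibble::tibble(
      id = ids %||% sprintf("P%04d", seq_along(probs)),
      outcome = as.integer(outcomes), .pred = probs
    )
  ), class = "pace_eval")
}

#' @export
print.pace_eval <- function(x, ...) {
  cat("<pace_eval> N =", nrow(x$predictions), "patients\n")
  cat(sprintf("  AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$auc$auc, x$auc$se, x$auc$conf.low, x$auc$conf.high))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration slope %.3f +/- %.3f, intercept %.3f +/- %.3f, R2 %.3f\n",
                x$calibration$slope, x$calibration$slope_se,
                x$calibration$intercept, x$calibration$intercept_se,
                x$calibration$r_squared))
  }
  cat(sprintf("  accuracy %.3f, balanced accuracy %.3f, F1 %.3f\n",
              x$metrics$accuracy, x$metrics$balanced_accuracy, x$metrics$f1))
  invisible(x)
}

#' Leave-one-out cross-validation of PACE or LKB
#'
#' For each patient the full model is refit on the remaining N - 1 patients
#' and applied to the held-out one; the N out-of-sample probabilities are
#' then scored. For PACE the honest default refits the voxel backbone
#' inside every fold; `refit_backbone = FALSE` keeps the full-data backbone
#' fixed and refits only `(nu, mu, tp50)` — faster but optimistic, since
#' the held-out patient then contributes to its own voxel models.
#'
#' @inheritParams fit_pace
#' @param model `"pace"`, `"lkb"`, or `"prevalence"` (constant predictor
#'   baseline).
#' @param refit_backbone PACE only: refit the backbone per fold
#'   (default `TRUE`).
#' @param n_bins,threshold Passed to [evaluate_predictions()].
#' @return A list with `predictions` (tibble id/outcome/.pred) and
#'   `report` (a `pace_eval`).
#' @export
loo_cv <- function(cohort, model = c("pace", "lkb", "prevalence"),
                   covariates = character(), grid = NULL,
                   refit_backbone = TRUE, n_starts = 8, seed = 1,
                   n_bins = 10, threshold = 0.5, w_max = 1e6) {
  model <- match.arg(model)
  n <- nrow(cohort)
  if (n < 10) stop("LOO needs at least 10 patients", call. = FALSE)
  if (is.null(grid)) grid <- attr(cohort, "grid")
  if (is.null(grid)) grid <- as_grid(cohort$dose[[1]])
  y <- check_outcomes(cohort$outcome)
  preds <- rep(NA_real_, n)
  fixed_bb <- NULL
  if (model == "pace" && !refit_backbone) {
    fixed_bb <- fit_backbone(cohort, covariates = covariates, grid = grid)
  }
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    attr(train, "grid") <- grid
    if (length(unique(train$outcome)) < 2) {
      warning("fold ", i, " lost all events; skipped")
      next
    }
    test <- cohort[i, , drop = FALSE]
    preds[i] <- switch(
      model,
      prevalence = mean(train$outcome),
      lkb = {
        f <- fit_lkb(train, grid = grid, n_starts = n_starts, seed = seed,
                     conf_int = FALSE)
        predict(f, test)$.pred
      },
      pace = {
        if (refit_backbone) {
          f <- fit_pace(train, covariates = covariates, grid = grid,
                        n_starts = n_starts, seed = seed, conf_int = FALSE,
                        w_max = w_max)
        } else {
          Dt <- roi_matrix(train$dose, grid)
          Vt <- cov_matrix(train, covariates)
          pw <- predict_pw(fixed_bb, Dt, Vt, w_max = w_max)
          f <- fit_pace_maps(pw$p, pw$w, train$outcome, n_starts = n_starts,
                             seed = seed, conf_int = FALSE)
          f$backbone <- fixed_bb
          f$covariate_names <- covariates
          f$grid <- grid
          f$w_max <- w_max
        }
        suppressWarnings(predict(f, test)$.pred)
      }
    )
  }
  keep <- !is.na(preds)
  report <- evaluate_predictions(preds[keep], y[keep],
                                 ids = (cohort$id %||% as.character(seq_len(n)))[keep],
                                 n_bins = n_bins, threshold = threshold)
  list(predictions = report$predictions, report = report)
}

cov_matrix <- function(cohort, covariates) {
  if (!length(covariates)) return(NULL)
  v <- as.matrix(cohort[, covariates, drop = FALSE])
  storage.mode(v) <- "double"
  v
}

#' Learning curves of PACE and LKB on synthetic cohorts
#'
#' For each training size and replicate, a fresh synthetic cohort (training
#' pool plus a disjoint validation set, labelled with a common threshold)
#' is simulated, each requested model is fitted on the first `size` maps,
#' and the classification accuracy at the stated threshold is recorded on
#' both the training subset and the validation set.
#'
#' @inheritParams simulate_cohort
#' @param train_sizes Integer vector of training-set sizes (each >= 20).
#' @param models Character subset of `c("pace", "lkb")`.
#' @param n_replicates Replicates per size (default 10).
#' @param validation_size Disjoint validation-set size (default 500).
#' @param threshold Classification threshold (default 0.5).
#' @param n_starts Multi-start count for the fits.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`. Degenerate
#'   single-class training subsets are resampled with an incremented seed
#'   (count reported in the `resampled` column).
#' @return A tibble of class `pace_learning_curve` with one row per
#'   (model, size, replicate): train and validation accuracy, seeds used.
#' @export
learning_curve <- function(train_sizes, models = c("pace", "lkb"),
                           n_replicates = 10, validation_size = 500,
                           grid = grid_spec(c(32, 32)), rs = NULL,
                           n_exp = 0.1, event_rate = 0.25, d_th = NULL,
                           equalize = FALSE, threshold = 0.5,
                           n_starts = 8, seed = 1, ...) {
  if (any(train_sizes < 20)) stop("train_sizes must be >= 20", call. = FALSE)
  models <- match.arg(models, c("pace", "lkb"), several.ok = TRUE)
  grid <- as_grid(grid)
  n_pool <- max(train_sizes) + validation_size
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- seed * 1000 + r
    resampled <- 0L
    repeat {
      cohort <- simulate_cohort(n_pool, grid = grid, rs = rs, n_exp = n_exp,
                                event_rate = event_rate, d_th = d_th,
                                equalize = equalize, seed = rseed + resampled * 100000L,
                                ...)
      val <- cohort[(n_pool - validation_size + 1):n_pool, ]
      ok <- all(vapply(train_sizes, function(s) {
        length(unique(cohort$outcome[seq_len(s)])) == 2
      }, logical(1)))
      if (ok || resampled >= 20L) break
      resampled <- resampled + 1L
    }
    for (s in train_sizes) {
      train <- cohort[seq_len(s), ]
      attr(train, "grid") <- grid
      for (m in models) {
        fit <- if (m == "pace") {
          fit_pace(train, grid = grid, conf_int = FALSE,
                   n_starts = n_starts, seed = 1)
        } else {
          fit_lkb(train, grid = grid, conf_int = FALSE,
                  n_starts = n_starts, seed = 1)
        }
        ptr <- suppressWarnings(predict(fit, train)$.pred)
        pva <- suppressWarnings(predict(fit, val)$.pred)
        rows[[length(rows) + 1]] <- tibble::tibble(
          model = m, train_size = s, replicate = r,
          train_accuracy = mean((ptr > threshold) == (train$outcome == 1)),
          validation_accuracy = mean((pva > threshold) == (val$outcome == 1)),
          resampled = resampled, seed = rseed
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pace_learning_curve", class(out))
  out
}

#' Summarise a learning curve over replicates
#'
#' @param curve A [learning_curve()] tibble.
#' @return One row per (model, train_size) with mean and SD of train and
#'   validation accuracy.
#' @export
summarize_learning_curve <- function(curve) {
  dplyr::group_by(curve, .data$model, .data$train_size) |>
    dplyr::summarise(
      train_mean = mean(.data$train_accuracy),
      train_sd = stats::sd(.data$train_accuracy),
      validation_mean = mean(.data$validation_accuracy),
      validation_sd = stats::sd(.data$validation_accuracy),
      n = dplyr::n(), .groups = "drop"
    )
}
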
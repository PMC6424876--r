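#' Generalized equivalent uniform probability (gEUp)
#'
#' Aggregates a per-voxel probability map P and reliability map W into one
#' scalar through the reliability-weighted power mean
#' \deqn{gEUp = \left[\frac{\sum_j P(x_j)^{1/\nu} W(x_j)}{\sum_j W(x_j)}\right]^\nu,}
#' the probability-space analogue of the gEUD: small \eqn{\nu} makes the
#' summary serial (dominated by the most reliable high-risk voxels),
#' \eqn{\nu = 1} gives the W-weighted arithmetic mean. The value is
#' invariant under positive rescaling of W and lies between the min and max
#' of P over voxels with positive reliability.
#'
#' @param p Probabilities in \[0, 1\] (vector, or matrix map).
#' @param w Nonnegative reliability weights, same length; must not sum to 0.
#' @param nu Volume-effect exponent, > 0.
#' @return A scalar in \[0, 1\].
#' @examples
#' geup(c(0.04, 0.36), c(1, 3), nu = 0.5)  # sqrt(0.0976)
#' @export
geup <- function(p, w, nu) {
  p <- as.numeric(p); w <- as.numeric(w)
  ok <- is.finite(p) & is.finite(w)
  p <- p[ok]; w <- w[ok]
  if (nu <= 0) stop("nu must be > 0", call. = FALSE)
  if (any(w < 0)) stop("reliability weights must be nonnegative", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("reliability weights sum to zero", call. = FALSE)
  power_mean(p, w / sw, nu)
}

#' PACE sigmoid: complication probability from a gEUp value
#'
#' Maps the gEUp summary through the probit (LKB-style) sigmoid
#' \eqn{\Phi\!\left((gEUp - Tp_{50}) / (\mu\, Tp_{50})\right)}: `tp50` is
#' the tolerance probability at which the predicted risk crosses 0.5 and
#' `mu` controls the sigmoid slope.
#'
#' @param geup_value gEUp value(s) in \[0, 1\].
#' @param mu Slope parameter, > 0.
#' @param tp50 Tolerance probability in (0, 1).
#' @return Complication probabilities.
#' @examples
#' pace_probability(0.5, mu = 0.35, tp50 = 0.5)        # 0.5 at midpoint
#' pace_probability(0.5 * 1.35, mu = 0.35, tp50 = 0.5) # pnorm(1)
#' @export
pace_probability <- function(geup_value, mu, tp50) {
  stats::pnorm((geup_value - tp50) / (mu * tp50))
}

#' PACE log-likelihood for fixed parameters
#'
#' Bernoulli log-likelihood of the outcomes under the PACE probabilities
#' computed from per-patient P/W maps at parameters `(nu, mu, tp50)`;
#' probabilities are clipped to \eqn{[\epsilon, 1-\epsilon]},
#' \eqn{\epsilon = 10^{-12}}. Patients whose W map is identically zero get
#' the fallback probability.
#'
#' @param params Numeric vector `c(nu, mu, tp50)`.
#' @param p_maps,w_maps N x M matrices (rows = patients, columns = ROI
#'   voxels) of per-voxel probabilities and reliabilities.
#' @param outcomes Binary outcome vector of length N.
#' @param fallback Probability used for all-zero-W patients (default: the
#'   event rate of `outcomes`).
#' @return The scalar log-likelihood.
#' @export
pace_loglik <- function(params, p_maps, w_maps, outcomes, fallback = NULL) {
  y <- as.integer(outcomes)
  if (is.null(fallback)) fallback <- mean(y)
  nll <- make_pace_nll(p_maps, w_maps, y, fallback)
  -nll(params)
}

# Build the negative log-likelihood closure over precomputed P/W matrices.
# Columns with zero reliability for every patient are dropped up front; the
# exp(log(P)/nu) form keeps the power mean cheap and stable (P = 0 maps to
# -Inf and contributes exactly 0).
make_pace_parts <- function(P, W) {
  P <- rbind(P); W <- rbind(W)
  keep <- colSums(W) > 0
  P <- P[, keep, drop = FALSE]
  W <- W[, keep, drop = FALSE]
  rs <- rowSums(W)
  fb_rows <- rs <= 0
  Wn <- W / ifelse(rs > 0, rs, 1)
  logP <- log(P)
  list(
    ge_fun = function(nu) rowSums(Wn * exp(logP / nu))^nu,
    fb_rows = fb_rows
  )
}

make_pace_nll <- function(P, W, y, fallback, eps = 1e-12) {
  parts <- make_pace_parts(P, W)
  function(theta) {
    nu <- theta[1]; mu <- theta[2]; tp50 <- theta[3]
    if (nu <= 0 || mu <= 0 || tp50 <= 0 || tp50 >= 1) return(Inf)
    ge <- parts$ge_fun(nu)
    pi <- stats::pnorm((ge - tp50) / (mu * tp50))
    pi[parts$fb_rows] <- fallback
    -bernoulli_loglik(pi, y, eps)
  }
}

#' Fit the PACE model on a cohort
#'
#' Full training pipeline: fits the voxelwise logistic backbone
#' ([fit_backbone()]), populates in-sample P/W maps for every training
#' patient, and estimates `(nu, mu, tp50)` by maximum likelihood over a
#' bounded box with a seeded Latin-hypercube multi-start (the PACE
#' likelihood can be multi-modal). Profile-likelihood 95% confidence
#' intervals (Wilks) are computed unless `conf_int = FALSE`.
#'
#' @inheritParams fit_backbone
#' @param bounds 2 x 3 matrix of lower/upper bounds for `(nu, mu, tp50)`;
#'   default `rbind(c(0.01, 0.01, 0.01), c(1, 2, 0.99))`.
#' @param n_starts Number of multi-start points (default 8).
#' @param seed Seed for the multi-start design (default 1; the fit is
#'   deterministic given the seed).
#' @param conf_int Compute Wilks profile CIs (default `TRUE`; switch off in
#'   tight loops such as learning curves).
#' @param level CI level.
#' @param w_max Reliability cap passed to the P/W map computation.
#' @return An object of class `pace_fit` with elements `backbone`, `params`
#'   (tibble with estimates and CIs), `loglik`, `fallback_probability`,
#'   and the training `grid`. Supports [predict()][predict.pace_fit],
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' rs <- make_rs_map(c(8, 8), "s2g")
#' co <- simulate_cohort(60, grid_spec(c(8, 8)), rs = rs,
#'                       event_rate = 0.4, seed = 2)
#' fit <- fit_pace(co, conf_int = FALSE)
#' fit$params
#' @export
fit_pace <- function(cohort, covariates = character(), grid = NULL,
                     bounds = NULL, n_starts = 8, seed = 1,
                     conf_int = TRUE, level = 0.95, w_max = 1e6) {
  backbone <- fit_backbone(cohort, covariates = covariates, grid = grid)
  y <- as.integer(cohort$outcome)
  Dt <- roi_matrix(cohort$dose, backbone$grid)
  Vt <- if (length(covariates)) {
    v <- as.matrix(cohort[, covariates, drop = FALSE]); storage.mode(v) <- "double"; v
  } else NULL
  pw <- predict_pw(backbone, Dt, Vt, level = level, w_max = w_max)
  fit <- fit_pace_maps(pw$p, pw$w, y, bounds = bounds, n_starts = n_starts,
                       seed = seed, conf_int = conf_int, level = level)
  fit$backbone <- backbone
  fit$covariate_names <- covariates
  fit$grid <- backbone$grid
  fit$w_max <- w_max
  fit
}

#' Fit PACE parameters from precomputed P/W maps
#'
#' Lower-level entry point taking per-patient probability and reliability
#' matrices directly (e.g. the generative per-voxel probabilities in a
#' simulation study), bypassing the backbone fit.
#'
#' @inheritParams pace_loglik
#' @inheritParams fit_pace
#' @return A `pace_fit` object without a backbone.
#' @export
fit_pace_maps <- function(p_maps, w_maps, outcomes, bounds = NULL,
                          n_starts = 8, seed = 1, conf_int = TRUE,
                          level = 0.95) {
  y <- check_outcomes(outcomes)
  if (is.null(bounds)) bounds <- rbind(c(0.01, 0.01, 0.01), c(1, 2, 0.99))
  fallback <- mean(y)
  parts <- make_pace_parts(p_maps, w_maps)
  nll <- make_pace_nll(p_maps, w_maps, y, fallback)
  opt <- fit_power_sigmoid(parts$ge_fun, y,
                           outer_bounds = bounds[, 1],
                           inner_lower = bounds[1, 2:3],
                           inner_upper = bounds[2, 2:3],
                           full_nll = nll, n_starts = n_starts, seed = seed,
                           fallback = fallback, fb_rows = parts$fb_rows)
  params <- tibble::tibble(
    term = c("nu", "mu", "tp50"),
    estimate = opt$par,
    conf.low = NA_real_, conf.high = NA_real_,
    at_lower_bound = NA, at_upper_bound = NA
  )
  if (conf_int) {
    params <- profile_ci_all(nll, opt$par, opt$value, bounds[1, ],
                             bounds[2, ], level = level,
                             names_par = c("nu", "mu", "tp50"))
  }
  structure(list(
    model = "pace",
    params = params,
    loglik = -opt$value,
    fallback_probability = fallback,
    n_train = length(y),
    bounds = bounds,
    seed = seed,
    level = level
  ), class = "pace_fit")
}

#' @export
print.pace_fit <- function(x, ...) {
  cat("<pace_fit> PACE model, N =", x$n_train,
      " logLik =", signif(x$loglik, 6), "\n")
  print(x$params)
  invisible(x)
}

#' Predict complication probabilities for new patients
#'
#' Composes the three PACE stages for each new dose map: per-voxel P/W maps
#' from the backbone, gEUp aggregation at the fitted `nu`, and the probit
#' sigmoid at the fitted `(mu, tp50)`. Patients whose reliability map is
#' identically zero receive the training-prevalence fallback probability
#' (with a warning).
#'
#' @param object A `pace_fit` from [fit_pace()].
#' @param newdata A cohort tibble with a `dose` list-column (covariate
#'   columns as in training), or a single dose matrix.
#' @param ... Unused.
#' @return A tibble with columns `id`, `geup` and `.pred`.
#' @export
predict.pace_fit <- function(object, newdata, ...) {
  if (is.null(object$backbone)) {
    stop("this pace_fit has no backbone; predict from P/W maps instead",
         call. = FALSE)
  }
  if (!is.data.frame(newdata)) {
    newdata <- tibble::tibble(id = "test", dose = list(newdata))
  }
  grid <- object$grid
  Dt <- roi_matrix(newdata$dose, grid)
  Vt <- if (length(object$covariate_names)) {
    v <- as.matrix(newdata[, object$covariate_names, drop = FALSE])
    storage.mode(v) <- "double"; v
  } else NULL
  pw <- predict_pw(object$backbone, Dt, Vt, level = object$level,
                   w_max = object$w_max %||% 1e6)
  est <- stats::setNames(object$params$estimate, object$params$term)
  rs <- rowSums(pw$w)
  ge <- rep(NA_real_, nrow(Dt))
  ok <- rs > 0
  if (any(ok)) {
    Wn <- pw$w[ok, , drop = FALSE] / rs[ok]
    ge[ok] <- rowSums(Wn * exp(log(pw$p[ok, , drop = FALSE]) / est["nu"]))^est["nu"]
  }
  pred <- pace_probability(ge, est["mu"], est["tp50"])
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) had an all-zero reliability map; ",
            "fallback probability applied")
    pred[!ok] <- object$fallback_probability
  }
  tibble::tibble(
    id = newdata$id %||% sprintf("T%04d", seq_len(nrow(Dt))),
    geup = ge,
    .pred = unname(pred)
  )
}
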
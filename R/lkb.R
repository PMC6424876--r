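#' Generalized equivalent uniform dose (gEUD)
#'
#' The classical power-mean dose summary
#' \eqn{gEUD = [\frac{1}{M}\sum_j D(x_j)^{1/n}]^n} over the ROI voxels:
#' `n = 1` gives the mean dose, small `n` approaches the maximum dose
#' (serial organ behaviour). Identical to [g2eud()] with a homogeneous
#' radio-sensitivity map.
#'
#' @param dose Dose matrix (nonnegative over the ROI).
#' @param n Volume-effect exponent, > 0.
#' @param grid Grid; defaults to the map's dimensions with a full ROI.
#' @return A scalar in dose units, between the min and max ROI dose.
#' @examples
#' geud(matrix(c(4, 16), 1, 2), n = 0.5)  # sqrt(136)
#' @export
geud <- function(dose, n, grid = NULL) {
  if (is.null(grid)) grid <- as_grid(dose)
  if (n <= 0) stop("volume-effect exponent n must be > 0", call. = FALSE)
  check_map(dose, grid, "dose map")
  d <- dose[grid$roi]
  power_mean(d, rep(1 / length(d), length(d)), n)
}

#' LKB sigmoid: complication probability from a gEUD value
#'
#' Probit dose-response \eqn{\Phi\!\left((gEUD - TD_{50})/(m\, TD_{50})\right)}:
#' `td50` is the uniform dose giving 50% complication probability and `m`
#' the relative slope.
#'
#' @param geud_value gEUD value(s), dose units.
#' @param m Slope parameter, > 0.
#' @param td50 Tolerance dose, > 0.
#' @return Complication probabilities.
#' @export
lkb_probability <- function(geud_value, m, td50) {
  stats::pnorm((geud_value - td50) / (m * td50))
}

# Negative log-likelihood closure over the cohort's ROI dose matrix.
# Row-wise max scaling keeps D^(1/n) finite down to n = 0.01.
make_lkb_nll <- function(D, y, eps = 1e-12) {
  dmax <- apply(D, 1, max)
  dmax[dmax <= 0] <- 1
  Z <- log(D / dmax)  # -Inf at zero-dose voxels; exp() maps those to 0
  function(theta) {
    n <- theta[1]; m <- theta[2]; td50 <- theta[3]
    if (n <= 0 || m <= 0 || td50 <= 0) return(Inf)
    g <- dmax * rowMeans(exp(Z / n))^n
    pi <- stats::pnorm((g - td50) / (m * td50))
    -bernoulli_loglik(pi, y, eps)
  }
}

#' Fit the reference LKB model on a cohort
#'
#' DVH-based benchmark: the three LKB parameters `(n, m, td50)` are
#' estimated by maximum likelihood with the same bounded multi-start and
#' Wilks profile-CI machinery as [fit_pace()]. The gEUD is computed
#' directly from the ROI voxels of each dose map (equivalent to using the
#' exact differential DVH).
#'
#' @inheritParams fit_pace
#' @param bounds 2 x 3 matrix of bounds for `(n, m, td50)`; by default
#'   `n` in \[0.01, 1\], `m` in \[0.01, 1\], `td50` from the smallest
#'   observed ROI dose (at least 1e-6) to 10x the largest.
#' @return An object of class `lkb_fit` (same layout as `pace_fit`).
#' @examples
#' co <- simulate_cohort(60, grid_spec(c(8, 8)), n_exp = 0.5,
#'                       event_rate = 0.4, seed = 3)
#' fit <- fit_lkb(co, conf_int = FALSE)
#' fit$params
#' @export
fit_lkb <- function(cohort, grid = NULL, bounds = NULL, n_starts = 8,
                    seed = 1, conf_int = TRUE, level = 0.95) {
  if (is.null(grid)) grid <- attr(cohort, "grid")
  if (is.null(grid)) grid <- as_grid(cohort$dose[[1]])
  y <- check_outcomes(cohort$outcome)
  D <- roi_matrix(cohort$dose, grid)
  if (is.null(bounds)) {
    dmin <- max(min(D), 1e-6)
    dmax <- max(D)
    bounds <- rbind(c(0.01, 0.01, dmin), c(1, 1, 10 * dmax))
  }
  nll <- make_lkb_nll(D, y)
  dmax <- apply(D, 1, max)
  dmax[dmax <= 0] <- 1
  Z <- log(D / dmax)
  ge_fun <- function(n) dmax * rowMeans(exp(Z / n))^n
  opt <- fit_power_sigmoid(ge_fun, y,
                           outer_bounds = bounds[, 1],
                           inner_lower = bounds[1, 2:3],
                           inner_upper = bounds[2, 2:3],
                           full_nll = nll, n_starts = n_starts, seed = seed)
  params <- tibble::tibble(
    term = c("n", "m", "td50"),
    estimate = opt$par,
    conf.low = NA_real_, conf.high = NA_real_,
    at_lower_bound = NA, at_upper_bound = NA
  )
  if (conf_int) {
    params <- profile_ci_all(nll, opt$par, opt$value, bounds[1, ],
                             bounds[2, ], level = level,
                             names_par = c("n", "m", "td50"))
  }
  structure(list(
    model = "lkb",
    params = params,
    loglik = -opt$value,
    fallback_probability = mean(y),
    n_train = length(y),
    bounds = bounds,
    seed = seed,
    level = level,
    grid = grid
  ), class = "lkb_fit")
}

#' @export
print.lkb_fit <- function(x, ...) {
  cat("<lkb_fit> LKB model, N =", x$n_train,
      " logLik =", signif(x$loglik, 6), "\n")
  print(x$params)
  invisible(x)
}

#' @rdname predict.pace_fit
#' @export
predict.lkb_fit <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) {
    newdata <- tibble::tibble(id = "test", dose = list(newdata))
  }
  est <- stats::setNames(object$params$estimate, object$params$term)
  g <- vapply(newdata$dose, geud, numeric(1), n = est["n"],
              grid = object$grid)
  tibble::tibble(
    id = newdata$id %||% sprintf("T%04d", seq_along(g)),
    geud = unname(g),
    .pred = unname(lkb_probability(g, est["m"], est["td50"]))
  )
}

#' Dose-volume histogram of a dose map
#'
#' Utility export for DVH-level inspection: cumulative (volume fraction
#' receiving at least each dose) and differential (fraction per bin) DVHs
#' over the ROI.
#'
#' @param dose Dose matrix.
#' @param bins Number of dose bins (default 100) or a vector of bin edges.
#' @param grid Grid; defaults to the full map.
#' @return A tibble with columns `dose` (bin lower edge), `differential`
#'   and `cumulative` volume fractions.
#' @export
dvh <- function(dose, bins = 100, grid = NULL) {
  if (is.null(grid)) grid <- as_grid(dose)
  v <- dose[grid$roi]
  edges <- if (length(bins) == 1) {
    seq(0, max(v) * (1 + 1e-9), length.out = bins + 1)
  } else bins
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  diff_frac <- h$counts / length(v)
  tibble::tibble(
    dose = utils::head(edges, -1),
    differential = diff_frac,
    cumulative = rev(cumsum(rev(diff_frac)))
  )
}
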
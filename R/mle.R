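# Shared maximum-likelihood machinery: seeded multi-start bounded
# optimisation and Wilks profile-likelihood confidence intervals. Both the
# PACE fit (nu, mu, Tp50) and the reference LKB fit (n, m, TD50) go through
# these; their likelihoods can be multi-modal, hence the Latin-hypercube
# multi-start.

# Minimise nll over a box. Starts: the box midpoint plus n_starts - 1
# Latin-hypercube points (seeded). Returns the best converged solution.
mle_multistart <- function(nll, lower, upper, n_starts = 8, seed = 1,
                           start = NULL) {
  p <- length(lower)
  starts <- matrix((lower + upper) / 2, nrow = 1)
  if (n_starts > 1) {
    lh <- with_preserved_seed(seed, lhs::randomLHS(n_starts - 1, p))
    starts <- rbind(starts, sweep(sweep(lh, 2, upper - lower, `*`),
                                  2, lower, `+`))
  }
  if (!is.null(start)) starts <- rbind(matrix(start, nrow = 1), starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 300, factr = 1e7)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("optimizer failed to converge from every start", call. = FALSE)
  }
  # polish with a derivative-free pass (L-BFGS-B can stall on likelihood
  # kinks created by probability clipping)
  pol <- try(stats::optim(best$par, nll, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && is.finite(pol$value) &&
      pol$value <= best$value) {
    pol$par <- pmin(pmax(pol$par, lower), upper)
    if (nll(pol$par) <= best$value) best <- pol
  }
  list(par = best$par, value = best$value)
}

# Profiled optimisation for power-mean + probit-sigmoid likelihoods.
#
# Both PACE and LKB have the same shape: an expensive power-mean summary
# per patient that depends only on the volume-effect exponent, followed by
# a two-parameter sigmoid that is cheap given the summaries. Exploiting
# that, the exponent is profiled on a seeded Latin-hypercube grid (each
# profile point re-optimising slope and midpoint from multiple starts),
# the best bracket is refined by golden-section search, and the full
# three-parameter solution receives a final Nelder-Mead polish on the
# exact joint likelihood.
fit_power_sigmoid <- function(ge_fun, y, outer_bounds, inner_lower,
                              inner_upper, full_nll, n_starts = 8,
                              seed = 1, fallback = mean(y),
                              fb_rows = NULL) {
  if (is.null(fb_rows)) fb_rows <- rep(FALSE, length(y))

  inner_nll <- function(ge) {
    function(q) {
      slope <- q[1]; center <- q[2]
      if (slope <= 0 || center <= 0) return(Inf)
      pi <- stats::pnorm((ge - center) / (slope * center))
      pi[fb_rows] <- fallback
      -bernoulli_loglik(pi, y)
    }
  }
  inner_opt <- function(ge) {
    f <- inner_nll(ge)
    starts <- rbind((inner_lower + inner_upper) / 2,
                    sweep(sweep(with_preserved_seed(seed + 1,
                                                    lhs::randomLHS(5, 2)),
                                2, inner_upper - inner_lower, `*`),
                          2, inner_lower, `+`))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- try(stats::optim(starts[i, ], f, method = "L-BFGS-B",
                              lower = inner_lower, upper = inner_upper,
                              control = list(maxit = 100, factr = 1e7)),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) return(list(par = starts[1, ], value = Inf))
    best
  }

  lo <- outer_bounds[1]; hi <- outer_bounds[2]
  grid <- sort(c((lo + hi) / 2,
                 lo + (hi - lo) * as.vector(
                   with_preserved_seed(seed, lhs::randomLHS(max(n_starts - 1, 2), 1)))))
  prof_cache <- new.env()
  prof <- function(nu) {
    key <- format(nu, digits = 12)
    if (!is.null(prof_cache[[key]])) return(prof_cache[[key]])
    res <- inner_opt(ge_fun(nu))
    out <- list(value = res$value, par = res$par)
    prof_cache[[key]] <- out
    out
  }
  vals <- vapply(grid, function(nu) prof(nu)$value, numeric(1))
  k <- which.min(vals)
  bracket <- c(if (k > 1) grid[k - 1] else lo,
               if (k < length(grid)) grid[k + 1] else hi)
  refine <- stats::optimize(function(nu) prof(nu)$value,
                            interval = bracket, tol = (hi - lo) * 1e-4)
  cand <- if (refine$objective < vals[k]) refine$minimum else grid[k]
  inner <- prof(cand)
  par0 <- c(cand, inner$par)
  # exact-joint polish
  pol <- try(stats::optim(par0, full_nll, method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-9)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && is.finite(pol$value) &&
      pol$value <= inner$value) {
    par <- pmin(pmax(pol$par, c(lo, inner_lower)), c(hi, inner_upper))
    if (full_nll(par) <= inner$value) {
      return(list(par = par, value = full_nll(par)))
    }
  }
  list(par = par0, value = inner$value)
}

# Evaluate the RNG-consuming expression under `seed` without disturbing the
# caller's random stream.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Wilks profile-likelihood confidence interval
#'
#' Inverts the likelihood-ratio test for one parameter of a fitted
#' three-parameter model: the interval is the set of values whose profile
#' deviance 2\[lnL_max - lnL_profile\] stays below the chi-square(1)
#' quantile at the requested level (3.841 at 95%), with the remaining
#' parameters re-optimised at every probed value. Endpoints that run into
#' the parameter box are reported at the bound and flagged.
#'
#' @param nll Negative log-likelihood taking the full parameter vector.
#' @param par_hat MLE parameter vector.
#' @param nll_min Minimised negative log-likelihood.
#' @param lower,upper Parameter box.
#' @param index Which parameter to profile.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, and logical flags
#'   `at_lower_bound` / `at_upper_bound`.
#' @export
wilks_profile_ci <- function(nll, par_hat, nll_min, lower, upper, index,
                             level = 0.95) {
  crit <- stats::qchisq(level, df = 1)
  free <- setdiff(seq_along(par_hat), index)
  warm <- new.env()
  warm$par <- par_hat[free]

  prof_dev <- function(theta) {
    if (length(free) == 0) {
      return(2 * (nll(theta) - nll_min))
    }
    f <- function(q) {
      p <- numeric(length(par_hat))
      p[index] <- theta
      p[free] <- q
      nll(p)
    }
    # warm-started refit of the free parameters; Nelder-Mead only as a
    # fallback when the quasi-Newton step fails
    fit <- try(stats::optim(warm$par, f, method = "L-BFGS-B",
                            lower = lower[free], upper = upper[free],
                            control = list(maxit = 100, factr = 1e8)),
               silent = TRUE)
    val <- if (inherits(fit, "try-error")) Inf else fit$value
    if (!is.finite(val)) {
      pol <- try(stats::optim(warm$par, f, method = "Nelder-Mead",
                              control = list(maxit = 200, reltol = 1e-9)),
                 silent = TRUE)
      if (!inherits(pol, "try-error") && is.finite(pol$value)) {
        fit <- pol; val <- pol$value
      }
    }
    if (is.finite(val) && !inherits(fit, "try-error")) {
      warm$par <- pmin(pmax(fit$par, lower[free]), upper[free])
    }
    2 * (val - nll_min)
  }

  g <- function(theta) prof_dev(theta) - crit
  solve_side <- function(bound) {
    warm$par <- par_hat[free]
    gb <- g(bound)
    if (!is.finite(gb) || gb <= 0) {
      return(list(value = bound, at_bound = TRUE))
    }
    root <- try(stats::uniroot(g, lower = min(bound, par_hat[index]),
                               upper = max(bound, par_hat[index]),
                               tol = max(abs(upper[index] - lower[index]), 1) * 1e-3),
                silent = TRUE)
    if (inherits(root, "try-error")) {
      return(list(value = bound, at_bound = TRUE))
    }
    list(value = root$root, at_bound = FALSE)
  }
  lo <- solve_side(lower[index])
  hi <- solve_side(upper[index])
  list(lower = lo$value, upper = hi$value,
       at_lower_bound = lo$at_bound, at_upper_bound = hi$at_bound)
}

profile_ci_all <- function(nll, par_hat, nll_min, lower, upper,
                           level = 0.95, names_par = NULL) {
  ci <- lapply(seq_along(par_hat), function(k) {
    wilks_profile_ci(nll, par_hat, nll_min, lower, upper, k, level)
  })
  out <- tibble::tibble(
    term = names_par %||% paste0("par", seq_along(par_hat)),
    estimate = par_hat,
    conf.low = vapply(ci, `[[`, numeric(1), "lower"),
    conf.high = vapply(ci, `[[`, numeric(1), "upper"),
    at_lower_bound = vapply(ci, `[[`, logical(1), "at_lower_bound"),
    at_upper_bound = vapply(ci, `[[`, logical(1), "at_upper_bound")
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bernoulli log-likelihood with probability clipping
bernoulli_loglik <- function(pi, y, eps = 1e-12) {
  pi <- pmin(pmax(pi, eps), 1 - eps)
  sum(y * log(pi) + (1 - y) * log(1 - pi))
}
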
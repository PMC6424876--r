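#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted PACE or LKB model
#'
#' @param x A `pace_fit` or `lkb_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `conf.low`,
#'   `conf.high` (Wilks profile CIs where computed) and bound flags.
#' @export
tidy.pace_fit <- function(x, ...) x$params

#' @rdname tidy.pace_fit
#' @export
tidy.lkb_fit <- function(x, ...) x$params

#' One-row model summary for a fitted PACE or LKB model
#'
#' @param x A `pace_fit` or `lkb_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `nobs`, `fallback_probability`.
#' @export
glance.pace_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = 2 * nrow(x$params) - 2 * x$loglik,
    nobs = x$n_train,
    fallback_probability = x$fallback_probability
  )
}

#' @rdname glance.pace_fit
#' @export
glance.lkb_fit <- glance.pace_fit

#' @export
logLik.pace_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$params), nobs = object$n_train,
            class = "logLik")
}

#' @export
logLik.lkb_fit <- logLik.pace_fit

#' Tidy an evaluation report
#'
#' @param x A `pace_eval`.
#' @param ... Unused.
#' @return A long tibble of metric/value pairs.
#' @export
tidy.pace_eval <- function(x, ...) {
  rows <- list(
    tibble::tibble(metric = c("auc", "auc_se"),
                   value = c(x$auc$auc, x$auc$se)),
    tibble::tibble(metric = c("accuracy", "balanced_accuracy", "f1"),
                   value = c(x$metrics$accuracy, x$metrics$balanced_accuracy,
                             x$metrics$f1))
  )
  if (!is.null(x$calibration)) {
    rows[[3]] <- tibble::tibble(
      metric = c("calibration_slope", "calibration_intercept",
                 "calibration_r_squared"),
      value = c(x$calibration$slope, x$calibration$intercept,
                x$calibration$r_squared))
  }
  dplyr::bind_rows(rows)
}
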
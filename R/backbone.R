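#' Fit the voxelwise logistic backbone of a PACE model
#'
#' For every ROI voxel, a logistic regression ties the N patients' binary
#' outcomes to the N local dose values at that voxel (plus any global scalar
#' covariates, which enter every voxel model identically). The M fitted
#' models form the "backbone" from which per-patient probability (P) and
#' reliability (W) maps are later populated.
#'
#' All M regressions are fitted simultaneously by a batched Newton-Raphson
#' (IRLS) sweep. Voxels showing (quasi-)separation — a frequent event at
#' cohort sizes of order 100 with rare events — are refitted with a
#' Firth-type bias-reduced penalised likelihood and flagged; voxels whose
#' dose has zero variance across the cohort get an intercept-only model
#' with the dose slope fixed at 0 and an infinite slope CI (reliability 0).
#'
#' @param cohort A cohort tibble with a `dose` list-column and an `outcome`
#'   column in \{0, 1\} (see [simulate_cohort()] / [read_cohort()]).
#' @param covariates Character vector of cohort columns to include as
#'   non-dosimetric covariates (default none).
#' @param grid Grid; defaults to the cohort's `"grid"` attribute.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return An object of class `pace_backbone`: per-voxel coefficients and
#'   covariance matrices, convergence/separation/zero-variance flags, the
#'   grid, covariate names, training size and event rate.
#' @examples
#' co <- simulate_cohort(40, grid_spec(c(6, 6)), event_rate = 0.4, seed = 1)
#' bb <- fit_backbone(co)
#' bb
#' @export
fit_backbone <- function(cohort, covariates = character(), grid = NULL,
                         maxit = 50, tol = 1e-8) {
  if (is.null(grid)) grid <- attr(cohort, "grid")
  if (is.null(grid)) grid <- as_grid(cohort$dose[[1]])
  y <- check_outcomes(cohort$outcome)
  D <- roi_matrix(cohort$dose, grid)
  V <- NULL
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(cohort))
    if (length(missing_cov)) {
      stop("covariates not found in cohort: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    V <- as.matrix(cohort[, covariates, drop = FALSE])
    storage.mode(V) <- "double"
  }
  fit <- batch_logistic(D, y, V, maxit = maxit, tol = tol)
  structure(
    c(fit, list(grid = grid, covariate_names = covariates,
                n_train = length(y), event_rate = mean(y))),
    class = "pace_backbone"
  )
}

#' @export
print.pace_backbone <- function(x, ...) {
  cat("<pace_backbone> ", nrow(x$coef), " voxel models, N = ", x$n_train,
      " patients (event rate ", signif(x$event_rate, 3), ")\n", sep = "")
  cat("  separation-flagged voxels: ", sum(x$separated),
      "; zero-variance voxels: ", sum(x$zero_var), "\n", sep = "")
  if (length(x$covariate_names)) {
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a single-voxel logistic model
#'
#' Convenience wrapper around the batched engine for one voxel: logistic
#' regression of the outcomes on the local doses (plus optional covariates),
#' with the same separation handling as [fit_backbone()].
#'
#' @param local_doses Numeric vector of length N.
#' @param outcomes Binary vector of length N containing both classes.
#' @param covariates Optional N x K numeric matrix.
#' @return A list with `coefficients` (intercept, dose slope, covariate
#'   slopes), `vcov`, `converged`, `separation_flag`, `zero_variance`.
#' @export
fit_voxel_glm <- function(local_doses, outcomes, covariates = NULL) {
  y <- check_outcomes(outcomes)
  D <- matrix(as.numeric(local_doses), ncol = 1)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  f <- batch_logistic(D, y, covariates)
  nm <- c("(Intercept)", "dose",
          if (!is.null(covariates)) paste0("V", seq_len(ncol(covariates))))
  co <- stats::setNames(f$coef[1, ], nm)
  list(coefficients = co,
       vcov = f$vcov[1, , ],
       converged = f$converged[1],
       separation_flag = f$separated[1],
       zero_variance = f$zero_var[1])
}

check_outcomes <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("outcomes must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("outcomes contain a single class; cannot fit", call. = FALSE)
  }
  y
}

# --- batched per-voxel logistic regression ---------------------------------
#
# D: N x M local dose matrix (one column per voxel); y: N binary outcomes;
# V: optional N x K covariate matrix shared across voxels.
# Returns coef (M x P), vcov (M x P x P), flags.
batch_logistic <- function(D, y, V = NULL, maxit = 50, tol = 1e-8) {
  N <- nrow(D); M <- ncol(D)
  K <- if (is.null(V)) 0L else ncol(V)
  P <- 2L + K
  sdD <- apply(D, 2, stats::sd)
  zero_var <- sdD == 0

  coef <- matrix(0, M, P)
  vcov <- array(NA_real_, dim = c(M, P, P))
  converged <- rep(FALSE, M)
  separated <- rep(FALSE, M)

  active <- which(!zero_var)
  if (length(active)) {
    res <- irls_sweep(D[, active, drop = FALSE], y, V,
                      maxit = maxit, tol = tol, firth = FALSE)
    # Separation heuristics: non-convergence, or a slope driving the linear
    # predictor into saturation over the observed dose range.
    sep <- !res$converged |
      abs(res$coef[2, ]) * sdD[active] > 15 |
      res$max_abs_eta > 30
    if (any(sep)) {
      idx <- which(sep)
      fr <- irls_sweep(D[, active[idx], drop = FALSE], y, V,
                       maxit = maxit * 2, tol = tol, firth = TRUE)
      res$coef[, idx] <- fr$coef
      res$vcov[idx, , ] <- fr$vcov
      res$converged[idx] <- fr$converged
    }
    coef[active, ] <- t(res$coef)
    vcov[active, , ] <- res$vcov
    converged[active] <- res$converged
    separated[active] <- sep
  }
  if (any(zero_var)) {
    # intercept-only MLE; dose slope pinned at 0 with infinite variance
    p0 <- mean(y)
    b0 <- stats::qlogis(p0)
    for (j in which(zero_var)) {
      coef[j, 1] <- b0
      v <- matrix(0, P, P)
      v[1, 1] <- 1 / (N * p0 * (1 - p0))
      v[2, 2] <- Inf
      vcov[j, , ] <- v
      converged[j] <- TRUE
    }
  }
  list(coef = coef, vcov = vcov, converged = converged,
       separated = separated, zero_var = zero_var)
}

# One batched IRLS run over the columns of D. Coefficients are P x m here
# (transposed relative to the caller). With firth = TRUE the score is given
# Firth's bias-reducing adjustment based on the per-observation leverages.
irls_sweep <- function(D, y, V, maxit, tol, firth) {
  N <- nrow(D); m <- ncol(D)
  K <- if (is.null(V)) 0L else ncol(V)
  P <- 2L + K
  b <- matrix(0, P, m)
  p0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
  b[1, ] <- stats::qlogis(p0)
  done <- rep(FALSE, m)
  max_abs_eta <- rep(NA_real_, m)
  Yc <- y  # recycles down columns of N x m matrices

  lin_pred <- function(b, D, V) {
    eta <- matrix(b[1, ], nrow(D), ncol(D), byrow = TRUE) +
      D * matrix(b[2, ], nrow(D), ncol(D), byrow = TRUE)
    if (!is.null(V)) eta <- eta + V %*% b[-(1:2), , drop = FALSE]
    eta
  }

  for (it in seq_len(maxit)) {
    act <- which(!done)
    if (!length(act)) break
    Da <- D[, act, drop = FALSE]
    ba <- b[, act, drop = FALSE]
    eta <- lin_pred(ba, Da, V)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (K == 0L) {
      S11 <- colSums(w); S1D <- colSums(w * Da); SDD <- colSums(w * Da * Da)
      det <- S11 * SDD - S1D^2
      det[det <= 0] <- NA_real_
      r <- Yc - p
      if (firth) {
        # leverage h_ij = w_ij x_i' (X'WX)^{-1} x_i, closed form for P = 2
        i11 <- SDD / det; i12 <- -S1D / det; i22 <- S11 / det
        h <- w * (matrix(i11, N, length(act), byrow = TRUE) +
                  2 * Da * matrix(i12, N, length(act), byrow = TRUE) +
                  Da * Da * matrix(i22, N, length(act), byrow = TRUE))
        r <- r + h * (0.5 - p)
      }
      g1 <- colSums(r); g2 <- colSums(Da * r)
      d1 <- (SDD * g1 - S1D * g2) / det
      d2 <- (-S1D * g1 + S11 * g2) / det
      step <- rbind(d1, d2)
    } else {
      step <- matrix(NA_real_, P, length(act))
      r <- Yc - p
      for (jj in seq_along(act)) {
        X <- cbind(1, Da[, jj], V)
        A <- crossprod(X, X * w[, jj])
        Ai <- try(solve(A), silent = TRUE)
        if (inherits(Ai, "try-error")) next
        rj <- r[, jj]
        if (firth) {
          h <- w[, jj] * rowSums((X %*% Ai) * X)
          rj <- rj + h * (0.5 - p[, jj])
        }
        step[, jj] <- Ai %*% crossprod(X, rj)
      }
    }
    bad <- !is.finite(colSums(step))
    step[, bad] <- 0
    # damp exploding steps (separation divergence control)
    sn <- apply(abs(step), 2, max)
    big <- sn > 5
    if (any(big)) step[, big] <- sweep(step[, big, drop = FALSE], 2,
                                       sn[big] / 5, `/`)
    b[, act] <- ba + step
    conv <- apply(abs(step), 2, max) < tol
    newly <- act[conv | bad]
    done[newly] <- TRUE
  }
  converged <- done
  eta_all <- lin_pred(b, D, V)
  max_abs_eta <- apply(abs(eta_all), 2, max)

  # observed-information covariance at the final coefficients
  p <- stats::plogis(eta_all)
  w <- p * (1 - p)
  vcov <- array(NA_real_, dim = c(m, P, P))
  if (K == 0L) {
    S11 <- colSums(w); S1D <- colSums(w * D); SDD <- colSums(w * D * D)
    det <- S11 * SDD - S1D^2
    det[det <= 0] <- NA_real_
    vcov[, 1, 1] <- SDD / det
    vcov[, 1, 2] <- vcov[, 2, 1] <- -S1D / det
    vcov[, 2, 2] <- S11 / det
  } else {
    for (jj in seq_len(m)) {
      X <- cbind(1, D[, jj], V)
      A <- crossprod(X, X * w[, jj])
      Ai <- try(solve(A), silent = TRUE)
      if (!inherits(Ai, "try-error")) vcov[jj, , ] <- Ai
    }
  }
  list(coef = b, vcov = vcov, converged = converged,
       max_abs_eta = max_abs_eta)
}

# --- prediction maps --------------------------------------------------------

#' Per-voxel prediction and reliability maps for a test patient
#'
#' Evaluates every voxel model of the backbone at the test patient's local
#' dose (and covariates), producing the probability map P, the width of the
#' 95% confidence interval of P (Wald on the logit scale, mapped through the
#' inverse logit so the interval stays inside \[0, 1\]) and the reliability
#' map W = 1/CI-width. Where the fitted dose odds ratio is below 1 (dose
#' locally protective) or the voxel is uninformative (zero dose variance in
#' training), W is set to 0; a numerically zero CI width is capped at
#' `w_max`.
#'
#' @param backbone A [fit_backbone()] object.
#' @param test_dose Dose matrix on the backbone grid.
#' @param test_covariates Named numeric vector/list matching the backbone's
#'   covariates.
#' @param level Confidence level (default 0.95).
#' @param w_max Reliability cap for degenerate zero-width intervals.
#' @return An object of class `pace_maps`: list of full-grid matrices
#'   `p_map`, `ci_width_map`, `w_map` (NA outside the ROI).
#' @export
predict_maps <- function(backbone, test_dose, test_covariates = NULL,
                         level = 0.95, w_max = 1e6) {
  grid <- backbone$grid
  check_map(test_dose, grid, "test dose map")
  V <- covariate_row(backbone, test_covariates)
  pw <- predict_pw(backbone, matrix(test_dose[grid$roi], nrow = 1), V,
                   level = level, w_max = w_max)
  structure(list(
    p_map = roi_unvec(pw$p[1, ], grid),
    ci_width_map = roi_unvec(pw$ci_width[1, ], grid),
    w_map = roi_unvec(pw$w[1, ], grid),
    grid = grid
  ), class = "pace_maps")
}

covariate_row <- function(backbone, test_covariates) {
  cn <- backbone$covariate_names
  if (!length(cn)) return(NULL)
  if (is.null(test_covariates)) {
    stop("model uses covariates (", paste(cn, collapse = ", "),
         ") but none supplied", call. = FALSE)
  }
  tc <- as.list(test_covariates)
  miss <- setdiff(cn, names(tc))
  if (length(miss)) {
    stop("missing covariate value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  matrix(as.numeric(tc[cn]), nrow = 1)
}

# Batched P/W computation: Dt is Nt x M test doses (ROI order), Vt is
# Nt x K covariates (or NULL). Returns Nt x M matrices p, ci_width, w.
predict_pw <- function(backbone, Dt, Vt = NULL, level = 0.95, w_max = 1e6) {
  M <- nrow(backbone$coef)
  Nt <- nrow(Dt)
  P <- ncol(backbone$coef)
  b0 <- backbone$coef[, 1]; b1 <- backbone$coef[, 2]
  eta <- matrix(b0, Nt, M, byrow = TRUE) + Dt * matrix(b1, Nt, M, byrow = TRUE)
  if (P > 2L) eta <- eta + Vt %*% t(backbone$coef[, -(1:2), drop = FALSE])
  # delta-method variance of the linear predictor: x' Vcov x with
  # x = (1, dose, covariates); accumulated term by term.
  Xa <- vector("list", P)
  Xa[[1]] <- 1; Xa[[2]] <- Dt
  if (P > 2L) for (k in 3:P) Xa[[k]] <- Vt[, k - 2]
  v <- matrix(0, Nt, M)
  for (a in seq_len(P)) for (bidx in seq_len(P)) {
    vab <- backbone$vcov[, a, bidx]
    term <- matrix(vab, Nt, M, byrow = TRUE)
    if (!identical(Xa[[a]], 1)) term <- term * Xa[[a]]
    if (!identical(Xa[[bidx]], 1)) term <- term * Xa[[bidx]]
    v <- v + term
  }
  v[v < 0 | !is.finite(v)] <- Inf
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- stats::plogis(eta)
  ci_width <- stats::plogis(eta + z * se) - stats::plogis(eta - z * se)
  w <- 1 / ci_width
  w[!is.finite(w) | w > w_max] <- w_max
  # protective dose (odds ratio < 1) or uninformative voxel: zero reliability
  drop_w <- b1 < 0 | backbone$zero_var
  if (any(drop_w)) w[, drop_w] <- 0
  list(p = p, ci_width = ci_width, w = w)
}
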
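#' Build a single-hot-spot probe set
#'
#' Generates one synthetic dose map per (strided) ROI position, each
#' carrying a single narrow Gaussian hot spot centred on that position.
#' Probing a trained PACE model with these maps and reading its probability
#' as a function of hot-spot position reconstructs the level sets of the
#' underlying radio-sensitivity map.
#'
#' @param grid A [grid_spec()] or shape vector.
#' @param sigma_probe Hot-spot standard deviation in voxels (default 1.5).
#' @param amplitude Hot-spot peak dose (default 1; in practice set to the
#'   maximum training dose, since PACE is nonlinear in dose).
#' @param stride Spacing between probed positions in voxels (default 1 =
#'   every ROI voxel).
#' @return A tibble of class `pace_probe_set` with one row per probed
#'   position: `id`, voxel coordinates, `boundary` flag (hot spot clipped
#'   by the ROI edge, within 2 sigma), and the `dose` list-column.
#' @export
make_probe_set <- function(grid, sigma_probe = 1.5, amplitude = 1,
                           stride = 1) {
  grid <- as_grid(grid)
  if (sigma_probe < 1) stop("sigma_probe must be >= 1 voxel", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (stride >= max(grid$shape)) {
    stop("stride larger than the roi extent", call. = FALSE)
  }
  coords <- grid_coords(grid)
  in_roi <- as.vector(grid$roi)
  on_stride <- rowSums((coords - 1) %% stride) == 0
  pos <- coords[in_roi & on_stride, , drop = FALSE]
  if (nrow(pos) == 0) stop("stride leaves no probed positions", call. = FALSE)
  roi_pts <- coords[in_roi, , drop = FALSE]
  lo <- apply(roi_pts, 2, min); hi <- apply(roi_pts, 2, max)
  boundary <- apply(pos, 1, function(p) {
    any(p - lo < 2 * sigma_probe | hi - p < 2 * sigma_probe)
  })
  maps <- lapply(seq_len(nrow(pos)), function(k) {
    gaussian_sum_map(grid, pos[k, , drop = FALSE], sigma_probe, amplitude)
  })
  out <- tibble::tibble(
    id = sprintf("probe%05d", seq_len(nrow(pos))),
    dose = maps,
    boundary = boundary
  )
  for (ax in seq_len(ncol(pos))) out[[paste0("x", ax)]] <- pos[, ax]
  attr(out, "grid") <- grid
  attr(out, "sigma_probe") <- sigma_probe
  attr(out, "amplitude") <- amplitude
  attr(out, "stride") <- stride
  class(out) <- c("pace_probe_set", class(out))
  out
}

#' Infer the radio-sensitivity map of a trained PACE model
#'
#' Evaluates the model on every probe map and assigns the resulting PACE
#' probability to the probed position; positions between strides are filled
#' by nearest-neighbour interpolation. The estimate is meaningful up to a
#' monotone transform (its level sets are the object of interest, scored
#' with [di_v_curve()]).
#'
#' @param fit A `pace_fit` with a backbone.
#' @param probe_set A [make_probe_set()] tibble on the model's grid.
#' @return An object of class `pace_rs_estimate`: list with `values`
#'   (full-grid matrix, arbitrary units), `grid`, `predictions` (per-probe
#'   tibble) and `n_fallback` (probes that hit the all-zero-W fallback).
#' @export
infer_rs_map <- function(fit, probe_set) {
  grid <- attr(probe_set, "grid")
  if (!identical(grid$shape, fit$grid$shape)) {
    stop("probe set and model grids differ", call. = FALSE)
  }
  withCallingHandlers(
    pr <- predict(fit, probe_set),
    warning = function(w) invokeRestart("muffleWarning")
  )
  n_fb <- sum(!is.finite(pr$geup))
  axes <- grep("^x\\d+$", names(probe_set), value = TRUE)
  pos <- as.matrix(probe_set[, axes])
  vals <- rep(NA_real_, prod(grid$shape))
  roi_idx <- which(as.vector(grid$roi))
  coords <- grid_coords(grid)[roi_idx, , drop = FALSE]
  # nearest probed position per ROI voxel (exact assignment at stride 1)
  nn <- apply(coords, 1, function(p) {
    which.min(colSums((t(pos) - p)^2))
  })
  vals[roi_idx] <- pr$.pred[nn]
  structure(list(
    values = array(vals, dim = grid$shape),
    grid = grid,
    predictions = dplyr::bind_cols(probe_set[, c("id", axes, "boundary")],
                                   pr[, c("geup", ".pred")]),
    n_fallback = n_fb
  ), class = "pace_rs_estimate")
}

#' @export
print.pace_rs_estimate <- function(x, ...) {
  cat("<pace_rs_estimate> ", paste(x$grid$shape, collapse = " x "),
      " grid, ", nrow(x$predictions), " probes",
      if (x$n_fallback > 0) paste0(" (", x$n_fallback, " fallback)"),
      "\n", sep = "")
  invisible(x)
}

#' Dice index of two voxel sets
#'
#' \eqn{DI(A, B) = 2|A \cap B| / (|A| + |B|)}; two empty sets score 1.
#'
#' @param set_a,set_b Logical maps on the same grid.
#' @return A value in \[0, 1\].
#' @export
dice_index <- function(set_a, set_b) {
  if (!identical(dim(set_a), dim(set_b)) ||
      length(set_a) != length(set_b)) {
    stop("sets must share one grid", call. = FALSE)
  }
  a <- as.logical(set_a); b <- as.logical(set_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Top round(v * M) ROI voxels by value; ties broken by voxel index (stable).
superlevel_set <- function(values, grid, v) {
  M <- n_roi(grid)
  k <- round(v * M)
  vec <- values[grid$roi]
  sel <- order(vec, decreasing = TRUE)[seq_len(k)]
  out <- array(FALSE, dim = grid$shape)
  idx <- which(grid$roi)[sel]
  out[idx] <- TRUE
  out
}

#' Dice-index curve between superlevel sets of two maps
#'
#' For each volume fraction v, takes the v*M highest-valued ROI voxels of
#' each map (rank-based superlevel sets of equal size, ties broken by voxel
#' index) and computes their Dice index; the curve is summarised by its
#' trapezoidal integral over v, normalised by the v range. Because the sets
#' depend only on value ordering, the score is invariant under monotone
#' transforms of either map — exactly what an arbitrary-units RS estimate
#' requires.
#'
#' @param rs_true Ground-truth RS map (matrix).
#' @param rs_est Estimated map: matrix or a [infer_rs_map()] result.
#' @param v_fractions Volume fractions in (0, 1)
#'   (default `seq(0.05, 0.95, by = 0.05)`).
#' @param grid Grid; defaults to the estimate's grid or the map dimensions.
#' @return A tibble of class `pace_div_curve` with columns `v` and `dice`,
#'   and the normalised AUC in attribute `"auc"` (see [di_v_auc()]).
#' @export
di_v_curve <- function(rs_true, rs_est, v_fractions = seq(0.05, 0.95, by = 0.05),
                       grid = NULL) {
  if (length(v_fractions) == 0) stop("empty v_fractions", call. = FALSE)
  if (any(v_fractions <= 0 | v_fractions >= 1)) {
    stop("v_fractions must lie in (0, 1)", call. = FALSE)
  }
  if (inherits(rs_est, "pace_rs_estimate")) {
    if (is.null(grid)) grid <- rs_est$grid
    rs_est <- rs_est$values
  }
  if (is.null(grid)) grid <- as_grid(rs_true)
  v_fractions <- sort(v_fractions)
  dice <- vapply(v_fractions, function(v) {
    dice_index(superlevel_set(rs_true, grid, v),
               superlevel_set(rs_est, grid, v))
  }, numeric(1))
  out <- tibble::tibble(v = v_fractions, dice = dice)
  auc <- if (length(v_fractions) > 1) {
    sum(diff(v_fractions) * (utils::head(dice, -1) + utils::tail(dice, -1)) / 2) /
      diff(range(v_fractions))
  } else dice
  attr(out, "auc") <- auc
  class(out) <- c("pace_div_curve", class(out))
  out
}

#' @rdname di_v_curve
#' @param curve A `pace_div_curve`.
#' @export
di_v_auc <- function(curve) attr(curve, "auc")
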
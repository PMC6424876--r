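#' Generate one synthetic Gaussian-peak dose map
#'
#' Dose maps are built as the sum of a random number of isotropic Gaussian
#' peaks: the peak count is uniform on `n_peaks`, the peak width (standard
#' deviation) uniform between `sigma_frac[1]` and `sigma_frac[2]` times the
#' linear size of the region of interest, the peak height uniform on
#' `height` (arbitrary dose units), and the peak centers uniform over the
#' ROI. Draws come from the current R random-number stream, so a fixed
#' `set.seed()` makes the map bit-reproducible.
#'
#' @param grid A [grid_spec()] (or a shape vector).
#' @param n_peaks Integer vector of admissible peak counts (default 1:4).
#' @param sigma_frac Range of peak standard deviations as a fraction of the
#'   ROI linear size (default `c(0.10, 0.30)`).
#' @param height Range of peak heights in arbitrary dose units
#'   (default `c(0.5, 1.5)`).
#'
#' @return A numeric matrix/array of dimension `grid$shape` with nonnegative
#'   dose values (zero outside the ROI).
#' @examples
#' set.seed(1)
#' d <- generate_dose_map(grid_spec(c(16, 16)))
#' range(d)
#' @export
generate_dose_map <- function(grid, n_peaks = 1:4,
                              sigma_frac = c(0.10, 0.30),
                              height = c(0.5, 1.5)) {
  grid <- as_grid(grid)
  k <- if (length(n_peaks) == 1) n_peaks else sample(n_peaks, 1)
  L <- roi_linear_size(grid)
  sig <- stats::runif(k, sigma_frac[1] * L, sigma_frac[2] * L)
  h <- stats::runif(k, height[1], height[2])
  roi_idx <- which(grid$roi)
  centers <- grid_coords(grid)[sample(roi_idx, k, replace = TRUE), , drop = FALSE]
  centers <- centers + matrix(stats::runif(k * ncol(centers), -0.5, 0.5),
                              nrow = k)
  gaussian_sum_map(grid, centers, sig, h)
}

# Linear size L of the ROI: side of the (square) bounding box of the mask,
# in voxels.
roi_linear_size <- function(grid) {
  idx <- which(grid$roi, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  max(apply(idx, 2, function(v) diff(range(v)) + 1))
}

# Sum of isotropic Gaussian bumps evaluated on the grid; zero outside ROI.
gaussian_sum_map <- function(grid, centers, sigmas, amplitudes) {
  centers <- matrix(centers, ncol = length(grid$shape))
  xy <- grid_coords(grid)
  vals <- numeric(nrow(xy))
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums((xy - matrix(centers[k, ], nrow(xy), ncol(xy), byrow = TRUE))^2)
    vals <- vals + amplitudes[k] * exp(-d2 / (2 * sigmas[k]^2))
  }
  out <- array(vals, dim = grid$shape)
  out[!grid$roi] <- 0
  out
}

#' Simulate a cohort of synthetic dose maps
#'
#' Draws `n` independent Gaussian-peak dose maps (see [generate_dose_map()])
#' and returns them as a tibble with one row per synthetic patient and a
#' list-column of dose matrices.
#'
#' @inheritParams generate_dose_map
#' @param n Number of maps.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `id` (character) and `dose` (list of
#'   matrices), carrying the grid in attribute `"grid"`.
#' @examples
#' maps <- simulate_dose_maps(3, grid_spec(c(8, 8)), seed = 1)
#' maps
#' @export
simulate_dose_maps <- function(n, grid = grid_spec(c(32, 32)), n_peaks = 1:4,
                               sigma_frac = c(0.10, 0.30),
                               height = c(0.5, 1.5), seed = NULL) {
  grid <- as_grid(grid)
  if (!is.null(seed)) set.seed(seed)
  maps <- replicate(
    n, generate_dose_map(grid, n_peaks, sigma_frac, height),
    simplify = FALSE
  )
  out <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    dose = maps
  )
  attr(out, "grid") <- grid
  out
}

#' Transform a cohort so every dose map shares one flat DVH
#'
#' Applies to each map the monotone rank transform that sends its empirical
#' dose distribution over the ROI to the uniform distribution on
#' `(0, d_max]`: voxel with rank r (out of M ROI voxels, ties broken by
#' stable voxel order) receives dose `d_max * r / M`. After the transform
#' every map has exactly the same differential DVH (the same sorted value
#' multiset) while its spatial ordering of voxels by dose is preserved —
#' the construction that makes any DVH-based model blind to the outcome.
#'
#' @param cohort A cohort tibble with a `dose` list-column, or a bare list
#'   of dose matrices.
#' @param d_max Upper edge of the equalized dose support (default 1).
#' @param grid Grid; defaults to the cohort's `"grid"` attribute.
#' @return The cohort with the `dose` column replaced by equalized maps.
#' @export
equalize_dvh <- function(cohort, d_max = 1, grid = NULL) {
  is_tbl <- is.data.frame(cohort)
  maps <- if (is_tbl) cohort$dose else cohort
  if (length(maps) < 1) stop("need at least one dose map", call. = FALSE)
  if (is.null(grid)) grid <- attr(cohort, "grid")
  if (is.null(grid)) grid <- as_grid(maps[[1]])
  M <- n_roi(grid)
  eq <- lapply(maps, function(d) {
    check_map(d, grid, "dose map")
    v <- d[grid$roi]
    if (diff(range(v)) == 0) {
      stop("constant dose map: rank transform undefined", call. = FALSE)
    }
    r <- rank(v, ties.method = "first")
    out <- d
    out[grid$roi] <- d_max * r / M
    out[!grid$roi] <- 0
    out
  })
  if (is_tbl) {
    cohort$dose <- eq
    cohort
  } else {
    eq
  }
}

#' Build a radio-sensitivity (RS) map
#'
#' The RS map expresses how strongly each voxel's dose drives the outcome.
#' Two synthetic ground truths are supported: a spatially homogeneous map
#' (constant 1 over the ROI) and the sum of two shifted Gaussian bumps
#' ("S2G"), the canonical inhomogeneous case.
#'
#' @param grid A [grid_spec()] or shape vector.
#' @param kind `"homogeneous"` or `"s2g"`.
#' @param centers For `"s2g"`: a 2-row matrix of peak centers in fractional
#'   grid coordinates (each row in (0,1) per axis). Default: peaks at 0.3
#'   and 0.7 of each axis.
#' @param sigmas Peak standard deviations as fractions of the ROI linear
#'   size (default `c(0.12, 0.12)`).
#' @param amplitudes Peak amplitudes (default `c(1, 1)`).
#' @return A nonnegative matrix of weights on the grid (zero outside ROI).
#' @export
make_rs_map <- function(grid, kind = c("homogeneous", "s2g"),
                        centers = NULL, sigmas = c(0.12, 0.12),
                        amplitudes = c(1, 1)) {
  grid <- as_grid(grid)
  kind <- match.arg(kind)
  if (kind == "homogeneous") {
    out <- array(0, dim = grid$shape)
    out[grid$roi] <- 1
    return(out)
  }
  nd <- length(grid$shape)
  if (is.null(centers)) {
    centers <- rbind(rep(0.3, nd), rep(0.7, nd))
  }
  centers <- matrix(centers, ncol = nd)
  if (nrow(centers) != 2) stop("s2g needs exactly two centers", call. = FALSE)
  L <- roi_linear_size(grid)
  # fractional coordinates -> voxel coordinates
  cvox <- sweep(centers, 2, grid$shape, `*`) + 0.5
  gaussian_sum_map(grid, cvox, sigmas * L, amplitudes)
}

#' Radio-sensitivity-weighted generalized equivalent uniform dose
#'
#' The g2EUD summarises a dose map through a power mean in which every
#' voxel's dose term is weighted by the local radio-sensitivity:
#' \deqn{g^2EUD = \left[\frac{\sum_j D(x_j)^{1/n} RS(x_j)}{\sum_j RS(x_j)}\right]^n}
#' With a homogeneous RS map this reduces exactly to the standard gEUD
#' (see [geud()]); `n` is the usual volume-effect exponent (small `n` makes
#' the summary serial, i.e. dominated by the hottest sensitive voxels).
#'
#' @param dose A dose matrix (nonnegative over the ROI).
#' @param rs An RS weight matrix on the same grid (nonnegative, positive sum).
#' @param n Volume-effect exponent, > 0.
#' @param grid Grid; defaults to the maps' dimensions with a full ROI.
#' @return A scalar in dose units.
#' @examples
#' d <- matrix(c(4, 16), 1, 2)
#' r <- matrix(c(1, 3), 1, 2)
#' g2eud(d, r, n = 0.5)  # sqrt(197)
#' @export
g2eud <- function(dose, rs, n, grid = NULL) {
  if (is.null(grid)) grid <- as_grid(dose)
  if (n <= 0) stop("volume-effect exponent n must be > 0", call. = FALSE)
  check_map(dose, grid, "dose map")
  check_map(rs, grid, "RS map")
  w <- rs[grid$roi]
  sw <- sum(w)
  if (sw <= 0) stop("RS weights sum to zero over the ROI", call. = FALSE)
  d <- dose[grid$roi]
  power_mean(d, w / sw, n)
}

# Weighted power mean [sum(w d^(1/n))]^n with weights summing to 1,
# overflow-safe via scaling by the max dose (handles 1/n up to ~100).
power_mean <- function(d, w, n) {
  dmax <- max(d[w > 0])
  if (dmax == 0) return(0)
  x <- d / dmax
  dmax * sum(w * x^(1 / n))^n
}

#' Threshold g2EUD values into binary outcomes
#'
#' The synthetic radiation-induced-morbidity outcome is the indicator that a
#' map's g2EUD strictly exceeds a dose threshold.
#'
#' @param g2euds Numeric vector of g2EUD values.
#' @param d_th Dose threshold.
#' @return Integer 0/1 vector.
#' @export
label_outcomes <- function(g2euds, d_th) {
  as.integer(g2euds > d_th)
}

#' Pick the dose threshold that yields a target event rate
#'
#' Returns the empirical (1 - rate)-quantile (inverse-ECDF convention) of
#' the g2EUD values, so that strict thresholding by it produces an event
#' fraction within 1/N of the target.
#'
#' @param g2euds Numeric vector of g2EUD values.
#' @param target_event_rate Desired event fraction, in (0, 1).
#' @return The dose threshold.
#' @export
choose_threshold <- function(g2euds, target_event_rate) {
  if (target_event_rate <= 0 || target_event_rate >= 1) {
    stop("target_event_rate must be in (0, 1)", call. = FALSE)
  }
  if (diff(range(g2euds)) == 0) {
    stop("degenerate g2EUD distribution: all values equal", call. = FALSE)
  }
  unname(stats::quantile(g2euds, 1 - target_event_rate, type = 1))
}

#' Simulate a fully labelled synthetic cohort
#'
#' End-to-end generator for the in-silico experiments: draws Gaussian-peak
#' dose maps, optionally applies the DVH-equalizing transform, computes each
#' map's g2EUD under the supplied radio-sensitivity map and volume-effect
#' exponent, and labels outcomes by strict thresholding. The threshold is
#' either given (`d_th`) or chosen to hit a target event rate.
#'
#' @inheritParams simulate_dose_maps
#' @param rs RS map matrix (default: homogeneous over the grid).
#' @param n_exp Volume-effect exponent used in the g2EUD (default 0.1).
#' @param event_rate Target event fraction used to pick the threshold
#'   (default 0.25); ignored when `d_th` is given.
#' @param d_th Optional fixed dose threshold.
#' @param equalize If `TRUE`, maps are DVH-equalized (to `d_max`) before
#'   computing g2EUDs, so all maps share one DVH.
#' @param d_max Equalized dose support upper edge (default 1).
#' @return A tibble with columns `id`, `dose` (list of matrices), `g2eud`,
#'   `outcome`, plus attributes `grid`, `rs_map`, `n_exp`, `d_th`, `seed`.
#' @examples
#' rs <- make_rs_map(c(16, 16), "s2g")
#' co <- simulate_cohort(20, grid_spec(c(16, 16)), rs = rs, seed = 7)
#' table(co$outcome)
#' @export
simulate_cohort <- function(n, grid = grid_spec(c(32, 32)), rs = NULL,
                            n_exp = 0.1, event_rate = 0.25, d_th = NULL,
                            equalize = FALSE, d_max = 1,
                            n_peaks = 1:4, sigma_frac = c(0.10, 0.30),
                            height = c(0.5, 1.5), seed = NULL) {
  grid <- as_grid(grid)
  if (is.null(rs)) rs <- make_rs_map(grid, "homogeneous")
  cohort <- simulate_dose_maps(n, grid, n_peaks, sigma_frac, height,
                               seed = seed)
  if (equalize) cohort <- equalize_dvh(cohort, d_max = d_max, grid = grid)
  g2 <- vapply(cohort$dose, g2eud, numeric(1), rs = rs, n = n_exp,
               grid = grid)
  if (is.null(d_th)) d_th <- choose_threshold(g2, event_rate)
  cohort$g2eud <- g2
  cohort$outcome <- label_outcomes(g2, d_th)
  attr(cohort, "grid") <- grid
  attr(cohort, "rs_map") <- rs
  attr(cohort, "n_exp") <- n_exp
  attr(cohort, "d_th") <- d_th
  attr(cohort, "seed") <- seed
  cohort
}
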
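#' Define the voxel grid a cohort lives on
#'
#' All dose maps, radio-sensitivity maps and probe sets in a study share one
#' grid: a 2D (or single-slice 3D) array of voxels with a physical spacing and
#' a region-of-interest (ROI) mask. Spatial normalisation of clinical maps to
#' this common grid is assumed done upstream.
#'
#' @param shape Integer vector of voxel extents per axis (each >= 2).
#' @param spacing Physical voxel size, one value per axis or a scalar
#'   (arbitrary length units; only recorded in file headers).
#' @param roi Logical array of dimension `shape` selecting the region of
#'   interest, or `NULL` for the full grid.
#'
#' @return An object of class `pace_grid`: a list with `shape`, `spacing`
#'   and `roi`.
#' @examples
#' g <- grid_spec(c(32, 32))
#' sum(g$roi)  # number of ROI voxels M
#' @export
grid_spec <- function(shape, spacing = 1, roi = NULL) {
  shape <- as.integer(shape)
  if (length(shape) < 1 || any(shape < 2)) {
    stop("all grid extents must be >= 2", call. = FALSE)
  }
  if (length(spacing) == 1) spacing <- rep(spacing, length(shape))
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (is.null(roi)) {
    roi <- array(TRUE, dim = shape)
  } else {
    roi <- array(as.logical(roi), dim = dim(roi))
    if (!identical(as.integer(dim(roi)), shape)) {
      stop("roi mask dimensions do not match grid shape", call. = FALSE)
    }
    if (!any(roi)) stop("roi mask must contain at least one voxel", call. = FALSE)
    if (anyNA(roi)) stop("roi mask must not contain NA", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, roi = roi),
            class = "pace_grid")
}

#' @export
print.pace_grid <- function(x, ...) {
  cat("<pace_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = " x "),
      ", ", sum(x$roi), " ROI voxels\n", sep = "")
  invisible(x)
}

# Coerce shape / grid arguments uniformly; accepts a pace_grid, an integer
# shape vector, or a matrix whose dim defines the grid.
as_grid <- function(x) {
  if (inherits(x, "pace_grid")) return(x)
  if (is.array(x) || is.matrix(x)) {
    d <- dim(x)
    roi <- NULL
    if (any(d == 1) && sum(d > 1) >= 1) {
      # tolerate row/column-vector toy maps: treat as a 1D grid
      d <- d[d > 1]
    }
    g <- grid_spec(d)
    return(g)
  }
  grid_spec(x)
}

# Number of ROI voxels
n_roi <- function(grid) sum(grid$roi)

check_map <- function(map, grid, what = "map") {
  if (!is.array(map) && !is.matrix(map)) {
    if (is.numeric(map) && length(map) == prod(grid$shape)) {
      map <- array(map, dim = grid$shape)
    } else {
      stop(what, " must be a matrix/array", call. = FALSE)
    }
  }
  d <- as.integer(dim(map))
  if (!identical(d, grid$shape)) {
    if (identical(d[d > 1L], grid$shape) && prod(d) == prod(grid$shape)) {
      map <- array(map, dim = grid$shape)  # drop singleton axes
    } else {
      stop(what, " dimensions do not match the grid", call. = FALSE)
    }
  }
  v <- map[grid$roi]
  if (any(!is.finite(v))) stop(what, " has non-finite ROI values", call. = FALSE)
  if (any(v < 0)) stop(what, " has negative ROI values", call. = FALSE)
  invisible(map)
}

# Stack the ROI voxels of a list of maps into an N x M matrix (one row per
# map, columns in fixed ROI voxel order). The workhorse layout for the
# voxelwise backbone and the EUD-type power means.
roi_matrix <- function(maps, grid) {
  if (is.matrix(maps) && !is.list(maps)) maps <- list(maps)
  m <- vapply(maps, function(d) {
    check_map(d, grid, "dose map")
    as.numeric(d[grid$roi])
  }, numeric(n_roi(grid)))
  t(m)
}

# Scatter a length-M ROI vector back into a full-grid array (NA outside ROI)
roi_unvec <- function(values, grid, fill = NA_real_) {
  out <- array(fill, dim = grid$shape)
  out[grid$roi] <- values
  out
}

# Fractional voxel coordinates of every grid point, one row per voxel,
# in the same linear order as array indexing.
grid_coords <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), .dim = grid$shape)
  idx
}
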
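#' Write and read dose/RS maps as NIfTI
#'
#' Maps live in NIfTI volumes (2D grids stored as single-slice 3D), with
#' the voxel spacing in the header. Voxel-index space only; no world
#' coordinate math is applied.
#'
#' @param map Numeric matrix/array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing recorded in the header.
#' @return `path`, invisibly (`write_map`); the map matrix (`read_map`).
#' @export
write_map <- function(map, path, spacing = 1) {
  arr <- as.array(map)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  img <- RNifti::asNifti(arr)
  sp <- rep(spacing, length.out = 3)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) == 3 && d[3] == 1) d <- d[1:2]
  # strip NIfTI header attributes: callers expect a plain numeric array
  array(as.numeric(arr), dim = d)
}

#' Persist a cohort as NIfTI maps plus a CSV manifest
#'
#' Writes one NIfTI file per dose map, the ROI mask, and `manifest.csv`
#' with columns `id`, `dose_path`, `outcome` and any covariate columns.
#'
#' @param cohort Cohort tibble (`id`, `dose`, `outcome`, covariates).
#' @param dir Output directory (created if missing).
#' @param grid Grid; defaults to the cohort's attribute.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, grid = NULL) {
  if (is.null(grid)) grid <- attr(cohort, "grid")
  if (is.null(grid)) grid <- as_grid(cohort$dose[[1]])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(cohort)), function(i) {
    p <- file.path(dir, paste0(cohort$id[i], ".nii.gz"))
    write_map(cohort$dose[[i]], p, spacing = grid$spacing[1])
    basename(p)
  }, character(1))
  write_map(grid$roi * 1, file.path(dir, "roi_mask.nii.gz"),
            spacing = grid$spacing[1])
  man <- dplyr::select(tibble::as_tibble(cohort), -"dose")
  man <- dplyr::mutate(man, dose_path = paths, .after = "id")
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from a CSV manifest
#'
#' The manifest must hold columns `id` (unique), `dose_path` (relative to
#' the manifest's directory or absolute) and `outcome` (strictly 0/1);
#' remaining columns are treated as covariates. All maps must share one
#' grid; a `roi_mask.nii.gz` next to the manifest, if present, defines the
#' ROI.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A cohort tibble with the grid in attribute `"grid"`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  req <- c("id", "dose_path", "outcome")
  miss <- setdiff(req, names(man))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$id)) stop("duplicate patient ids", call. = FALSE)
  if (!all(man$outcome %in% c(0, 1))) {
    bad <- man$id[!man$outcome %in% c(0, 1)][1]
    stop("non-binary outcome for id '", bad, "'", call. = FALSE)
  }
  base <- dirname(manifest_path)
  maps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$dose_path[i]
    if (!file.exists(p)) p <- file.path(base, man$dose_path[i])
    if (!file.exists(p)) {
      stop("dose map missing for id '", man$id[i], "': ", man$dose_path[i],
           call. = FALSE)
    }
    maps[[i]] <- read_map(p)
    if (i > 1 && !identical(dim(maps[[i]]), dim(maps[[1]]))) {
      stop("grid mismatch at id '", man$id[i], "'", call. = FALSE)
    }
  }
  roi_path <- file.path(base, "roi_mask.nii.gz")
  roi <- if (file.exists(roi_path)) read_map(roi_path) > 0 else NULL
  grid <- grid_spec(dim(maps[[1]]), roi = roi)
  out <- dplyr::mutate(dplyr::select(man, -"dose_path"),
                       dose = maps, .after = "id")
  out$outcome <- as.integer(out$outcome)
  attr(out, "grid") <- grid
  out
}

#' Serialise a fitted backbone to a plain-text archive directory
#'
#' Writes per-voxel coefficients and covariances as CSV and the metadata
#' (grid, covariates, flags, training size) as JSON, so a backbone can be
#' stored and reloaded without binary formats.
#'
#' @param backbone A [fit_backbone()] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_backbone <- function(backbone, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- ncol(backbone$coef)
  co <- tibble::as_tibble(backbone$coef, .name_repair = ~ paste0("b", seq_len(P) - 1))
  readr::write_csv(co, file.path(dir, "coefficients.csv"))
  vc <- do.call(cbind, lapply(seq_len(P), function(a)
    vapply(seq_len(P), function(b) backbone$vcov[, a, b],
           numeric(nrow(backbone$coef)))))
  colnames(vc) <- as.vector(outer(seq_len(P), seq_len(P),
                                  function(a, b) paste0("v", a - 1, b - 1)))
  readr::write_csv(tibble::as_tibble(vc), file.path(dir, "vcov.csv"))
  meta <- list(
    shape = backbone$grid$shape, spacing = backbone$grid$spacing,
    roi = which(backbone$grid$roi),
    covariate_names = backbone$covariate_names,
    n_train = backbone$n_train, event_rate = backbone$event_rate,
    converged = which(!backbone$converged),
    separated = which(backbone$separated),
    zero_var = which(backbone$zero_var)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_backbone
#' @export
read_backbone <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  roi <- array(FALSE, dim = meta$shape)
  roi[meta$roi] <- TRUE
  grid <- grid_spec(meta$shape, spacing = meta$spacing, roi = roi)
  co <- as.matrix(readr::read_csv(file.path(dir, "coefficients.csv"),
                                  show_col_types = FALSE))
  vc <- as.matrix(readr::read_csv(file.path(dir, "vcov.csv"),
                                  show_col_types = FALSE))
  P <- ncol(co); M <- nrow(co)
  vcov <- array(NA_real_, dim = c(M, P, P))
  for (a in seq_len(P)) for (b in seq_len(P)) {
    vcov[, a, b] <- vc[, paste0("v", a - 1, b - 1)]
  }
  converged <- rep(TRUE, M); converged[as.integer(unlist(meta$converged))] <- FALSE
  separated <- rep(FALSE, M); separated[as.integer(unlist(meta$separated))] <- TRUE
  zero_var <- rep(FALSE, M); zero_var[as.integer(unlist(meta$zero_var))] <- TRUE
  structure(list(
    coef = unname(co), vcov = vcov, converged = converged,
    separated = separated, zero_var = zero_var, grid = grid,
    covariate_names = meta$covariate_names %||% character(),
    n_train = meta$n_train, event_rate = meta$event_rate
  ), class = "pace_backbone")
}

#' Write fitted model parameters as JSON
#'
#' @param fit A `pace_fit` or `lkb_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_params <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$model,
    params = fit$params,
    loglik = fit$loglik,
    fallback_probability = fit$fallback_probability,
    n_train = fit$n_train,
    bounds = fit$bounds,
    seed = fit$seed,
    level = fit$level
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
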
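#' Run a configured end-to-end experiment
#'
#' Config-driven driver stringing the package stages into the standard
#' workflows: `simulate` (write a synthetic cohort), `fit` (PACE or LKB on
#' a cohort manifest), `evaluate` (training metrics plus optional LOO
#' cross-validation), `learning_curve`, and `rs_map` (probe a fitted PACE
#' model and score the inferred radio-sensitivity map). Every run writes a
#' `provenance.json` (config, seed, package version) into the output
#' directory; all outputs are plain text or NIfTI.
#'
#' @param config A named list, or the path of a YAML/JSON config file. Must
#'   contain `experiment` (one of the kinds above); remaining entries are
#'   kind-specific (see the package vignette).
#' @param out_dir Output directory.
#' @param seed Integer seed; mandatory for stochastic experiments
#'   (overrides `config$seed`).
#' @return A list of the produced artifacts, invisibly.
#' @export
run_experiment <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$experiment)) {
    stop("config must name an 'experiment'", call. = FALSE)
  }
  seed <- seed %||% config$seed
  kind <- match.arg(config$experiment,
                    c("simulate", "fit", "evaluate", "learning_curve",
                      "rs_map"))
  if (is.null(seed) && kind %in% c("simulate", "learning_curve")) {
    stop("a seed is mandatory for stochastic experiments", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(kind,
    simulate = exp_simulate(config, out_dir, seed),
    fit = exp_fit(config, out_dir, seed),
    evaluate = exp_evaluate(config, out_dir, seed),
    learning_curve = exp_learning_curve(config, out_dir, seed),
    rs_map = exp_rs_map(config, out_dir, seed)
  )
  jsonlite::write_json(list(
    experiment = kind, config = config, seed = seed,
    package_version = as.character(utils::packageVersion("pace")),
    r_version = R.version.string,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), file.path(out_dir, "provenance.json"), auto_unbox = TRUE, force = TRUE)
  invisible(res)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_grid <- function(config) {
  grid_spec(config$grid %||% c(32, 32))
}

config_rs <- function(config, grid) {
  rs <- config$rs %||% list(kind = "homogeneous")
  make_rs_map(grid, kind = rs$kind %||% "homogeneous",
              centers = if (!is.null(rs$centers)) matrix(unlist(rs$centers), ncol = length(grid$shape), byrow = TRUE),
              sigmas = rs$sigmas %||% c(0.12, 0.12),
              amplitudes = rs$amplitudes %||% c(1, 1))
}

sim_from_config <- function(config, seed) {
  grid <- config_grid(config)
  rs <- config_rs(config, grid)
  simulate_cohort(
    n = config$n %||% 100,
    grid = grid, rs = rs,
    n_exp = config$n_exp %||% 0.1,
    event_rate = config$event_rate %||% 0.25,
    d_th = config$d_th,
    equalize = isTRUE(config$equalize),
    seed = seed
  )
}

exp_simulate <- function(config, out_dir, seed) {
  cohort <- sim_from_config(config, seed)
  man <- write_cohort(cohort, file.path(out_dir, "cohort"))
  write_map(attr(cohort, "rs_map"), file.path(out_dir, "rs_map.nii.gz"))
  list(manifest = man, cohort = cohort)
}

load_or_sim <- function(config, seed) {
  if (!is.null(config$manifest)) read_cohort(config$manifest)
  else sim_from_config(config, seed)
}

exp_fit <- function(config, out_dir, seed) {
  cohort <- load_or_sim(config, seed)
  model <- config$model %||% "pace"
  fit <- if (model == "pace") {
    fit_pace(cohort, covariates = config$covariates %||% character(),
             n_starts = config$n_starts %||% 8,
             conf_int = !isFALSE(config$conf_int))
  } else {
    fit_lkb(cohort, n_starts = config$n_starts %||% 8,
            conf_int = !isFALSE(config$conf_int))
  }
  write_params(fit, file.path(out_dir, paste0(model, "_params.json")))
  if (model == "pace") {
    write_backbone(fit$backbone, file.path(out_dir, "backbone"))
  }
  list(fit = fit)
}

exp_evaluate <- function(config, out_dir, seed) {
  cohort <- load_or_sim(config, seed)
  model <- config$model %||% "pace"
  fit <- if (model == "pace") {
    fit_pace(cohort, covariates = config$covariates %||% character(),
             conf_int = FALSE)
  } else fit_lkb(cohort, conf_int = FALSE)
  pr <- suppressWarnings(predict(fit, cohort))
  train_rep <- evaluate_predictions(pr$.pred, cohort$outcome, ids = cohort$id)
  readr::write_csv(train_rep$predictions,
                   file.path(out_dir, "train_predictions.csv"))
  out <- list(training = report_json(train_rep))
  if (isTRUE(config$loo)) {
    loo <- loo_cv(cohort, model = model,
                  covariates = config$covariates %||% character(),
                  refit_backbone = !isTRUE(config$fast_loo))
    readr::write_csv(loo$predictions, file.path(out_dir, "loo_predictions.csv"))
    out$loo <- report_json(loo$report)
  }
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(fit = fit, report = train_rep)
}

report_json <- function(rep) {
  list(auc = as.list(rep$auc),
       calibration = if (!is.null(rep$calibration)) as.list(rep$calibration),
       metrics = as.list(rep$metrics[, c("accuracy", "balanced_accuracy", "f1")]))
}

exp_learning_curve <- function(config, out_dir, seed) {
  grid <- config_grid(config)
  curve <- learning_curve(
    train_sizes = config$train_sizes %||% c(50, 100, 200),
    models = config$models %||% c("pace", "lkb"),
    n_replicates = config$n_replicates %||% 10,
    validation_size = config$validation_size %||% 500,
    grid = grid, rs = config_rs(config, grid),
    n_exp = config$n_exp %||% 0.1,
    event_rate = config$event_rate %||% 0.25,
    equalize = isTRUE(config$equalize),
    seed = seed
  )
  readr::write_csv(curve, file.path(out_dir, "learning_curve.csv"))
  readr::write_csv(summarize_learning_curve(curve),
                   file.path(out_dir, "learning_curve_summary.csv"))
  list(curve = curve)
}

exp_rs_map <- function(config, out_dir, seed) {
  cohort <- load_or_sim(config, seed)
  fit <- fit_pace(cohort, conf_int = FALSE)
  grid <- fit$grid
  amp <- config$probe_amplitude %||% max(vapply(cohort$dose, max, numeric(1)))
  probes <- make_probe_set(grid,
                           sigma_probe = config$sigma_probe %||% 1.5,
                           amplitude = amp,
                           stride = config$stride %||% 1)
  est <- infer_rs_map(fit, probes)
  write_map(est$values, file.path(out_dir, "rs_estimate.nii.gz"))
  out <- list(estimate = est)
  rs_true <- attr(cohort, "rs_map")
  if (!is.null(rs_true)) {
    curve <- di_v_curve(rs_true, est)
    readr::write_csv(curve, file.path(out_dir, "di_v_curve.csv"))
    jsonlite::write_json(list(di_v_auc = di_v_auc(curve)),
                         file.path(out_dir, "di_v_auc.json"),
                         auto_unbox = TRUE, digits = NA)
    out$di_v <- curve
  }
  out
}
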
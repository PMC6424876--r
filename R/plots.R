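# ggplot2 display methods. Maps are drawn voxelwise with geom_raster;
# curves carry mean +/- SD ribbons over replicates.

map_df <- function(map, grid = NULL) {
  if (is.null(grid)) grid <- as_grid(map)
  xy <- grid_coords(grid)
  tibble::tibble(x = xy[, 1], y = xy[, 2],
                 value = as.vector(map),
                 roi = as.vector(grid$roi))
}

#' Plot a voxel map
#'
#' @param map Numeric matrix (dose, RS, P, W, ...).
#' @param grid Optional [grid_spec()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_map <- function(map, grid = NULL, title = NULL) {
  df <- dplyr::filter(map_df(map, grid), .data$roi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pace_maps <- function(object, ...) {
  dfs <- dplyr::bind_rows(
    dplyr::mutate(map_df(object$p_map, object$grid), panel = "P map"),
    dplyr::mutate(map_df(object$w_map, object$grid), panel = "W map")
  )
  dfs <- dplyr::filter(dfs, .data$roi)
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pace_rs_estimate <- function(object, ...) {
  plot_map(object$values, object$grid,
           title = "Inferred radio-sensitivity (arbitrary units)")
}

#' @export
autoplot.pace_learning_curve <- function(object, ...) {
  s <- summarize_learning_curve(object)
  long <- tidyr::pivot_longer(
    s, cols = c("train_mean", "validation_mean"),
    names_to = "set", values_to = "accuracy"
  )
  long$sd <- ifelse(long$set == "train_mean", s$train_sd[match(
    paste(long$model, long$train_size),
    paste(s$model, s$train_size))],
    s$validation_sd[match(paste(long$model, long$train_size),
                          paste(s$model, s$train_size))])
  long$set <- ifelse(long$set == "train_mean", "train", "validation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$train_size,
                                     y = .data$accuracy,
                                     colour = .data$model,
                                     linetype = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$sd,
                                      ymax = .data$accuracy + .data$sd,
                                      fill = .data$model), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training-set size", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pace_div_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v, y = .data$dice)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "volume fraction V", y = expression(DI[V]),
      subtitle = sprintf("normalized AUC = %.3f", di_v_auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pace_eval <- function(object, type = c("roc", "calibration"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    y <- object$predictions$outcome
    p <- object$predictions$.pred
    th <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
    roc <- tibble::tibble(
      tpr = vapply(th, function(t) mean(p[y == 1] >= t), numeric(1)),
      fpr = vapply(th, function(t) mean(p[y == 0] >= t), numeric(1))
    )
    ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(linetype = 2, colour = "grey") +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "false positive rate", y = "true positive rate",
        subtitle = sprintf("AUC = %.3f (SE %.3f)", object$auc$auc,
                           object$auc$se)
      ) +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$calibration)) {
      stop("calibration undefined for this report", call. = FALSE)
    }
    bins <- attr(object$calibration, "bins")
    ggplot2::ggplot(bins, ggplot2::aes(x = .data$pred, y = .data$obs)) +
      ggplot2::geom_abline(linetype = 2, colour = "grey") +
      ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "steelblue") +
      ggplot2::labs(
        x = "mean predicted probability", y = "observed event fraction",
        subtitle = sprintf("slope %.2f, intercept %.3f, R2 %.2f",
                           object$calibration$slope,
                           object$calibration$intercept,
                           object$calibration$r_squared)
      ) +
      ggplot2::theme_minimal()
  }
}
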
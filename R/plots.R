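#' Plot a free-energy profile
#'
#' 1D grids are drawn as a free-energy curve; 2D grids as a filled surface
#' with masked bins left blank, the convention used for collective-variable
#' free-energy maps.
#'
#' @param object a [pmf_grid].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pmf_grid
#' @export
autoplot.pmf_grid <- function(object, ...) {
  nm <- attr(object, "cv_names")
  df <- tibble::as_tibble(object)
  if (length(nm) == 1) {
    ggplot2::ggplot(df[!df$masked, ],
                    ggplot2::aes(x = .data[[nm[1]]], y = .data$free_energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = paste0(nm[1], " (A)"),
                    y = "free energy (kcal/mol)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df[!df$masked, ],
                    ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                 fill = .data$free_energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
      ggplot2::labs(x = paste0(nm[1], " (A)"), y = paste0(nm[2], " (A)")) +
      ggplot2::theme_minimal()
  }
}

#' Plot trajectory time courses
#'
#' Coordinate of the first particle, potential energy and boost energy
#' against time, stacked as facets.
#'
#' @param object a `gamd_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gamd_trajectory
#' @export
autoplot.gamd_trajectory <- function(object, ...) {
  nf <- n_frames(object)
  t_ps <- seq_len(nf) * object$period_ps
  df <- dplyr::bind_rows(
    tibble::tibble(time_ps = t_ps, value = traj_x(object), what = "x (A)"),
    tibble::tibble(time_ps = t_ps, value = object$energies$V_total,
                   what = "V (kcal/mol)"),
    tibble::tibble(time_ps = t_ps, value = object$boost$dV_sum,
                   what = "dV (kcal/mol)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a time-course tibble
#'
#' Works on the outputs of [distance_timecourse()], [rmsd_timecourse()] and
#' [com_distance_timecourse()].
#'
#' @param df tibble with `time_ps` and one value column.
#' @param value name of the value column (default: last column).
#' @return a ggplot object.
#' @export
plot_timecourse <- function(df, value = NULL) {
  if (is.null(value)) value <- names(df)[ncol(df)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data[[value]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ps)", y = paste0(value, " (A)")) +
    ggplot2::theme_minimal()
}

#' Plot per-particle RMSF profiles
#'
#' @param ... named tibbles from [rmsf()] (names become the legend).
#' @return a ggplot object.
#' @export
plot_rmsf <- function(...) {
  inputs <- list(...)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("traj", seq_along(inputs))
  }
  df <- dplyr::bind_rows(inputs, .id = "trajectory")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$particle, y = .data$rmsf,
                                   colour = .data$trajectory)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "particle", y = "RMSF (A)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
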
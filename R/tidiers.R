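#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-cell table of a polar benchmark
#'
#' @param x a [run_polar_benchmark()] result.
#' @param ... unused.
#' @return Tibble with one row per (direction, speed) cell: `angle_deg`,
#'   `speed`, `mean_ae_deg`, `mean_epe`, `n`, `detected_frac`, `aliased`.
#' @export
tidy.polar_benchmark <- function(x, ...) {
  dplyr::transmute(x$cells,
                   angle_deg = .data$angle_deg, speed = .data$speed_true,
                   mean_ae_deg = .data$mean_ae_deg,
                   mean_epe = .data$mean_epe, n = .data$n,
                   detected_frac = .data$detected_frac,
                   aliased = .data$aliased)
}

#' One-row summary of a polar benchmark
#'
#' Cell-averaged AE/EPE over the unaliased speeds, worst cell values, and
#' the overall average including aliased cells.
#'
#' @inheritParams tidy.polar_benchmark
#' @return One-row tibble.
#' @export
glance.polar_benchmark <- function(x, ...) {
  ok <- !x$cells$aliased
  tibble::tibble(
    mean_ae_deg = mean(x$cells$mean_ae_deg[ok], na.rm = TRUE),
    mean_epe = mean(x$cells$mean_epe[ok], na.rm = TRUE),
    max_cell_ae_deg = max(x$cells$mean_ae_deg[ok], na.rm = TRUE),
    max_cell_epe = max(x$cells$mean_epe[ok], na.rm = TRUE),
    mean_ae_deg_all = mean(x$cells$mean_ae_deg, na.rm = TRUE),
    detected_frac = mean(x$cells$detected_frac),
    n_cells = nrow(x$cells))
}

#' Tidy the per-level table of a cascade benchmark
#'
#' @param x a [run_cascade_benchmark()] result.
#' @param ... unused.
#' @return Tibble with one row per brightness level.
#' @export
tidy.cascade_benchmark <- function(x, ...) x$levels

#' One-row summary of a cascade benchmark
#'
#' @inheritParams tidy.cascade_benchmark
#' @return One-row tibble: worst-level detection fraction and AE.
#' @export
glance.cascade_benchmark <- function(x, ...) {
  tibble::tibble(gain_variant = x$config$gain_variant,
                 n_levels = nrow(x$levels),
                 min_detected_frac = min(x$levels$detected_frac),
                 max_level_ae_deg = max(x$levels$mean_ae_deg, na.rm = TRUE),
                 mean_ae_deg = mean(x$levels$mean_ae_deg, na.rm = TRUE))
}

#' Steady-state response curves of the gain-control DNP
#'
#' Evaluates the closed-form steady-state output over an intensity grid for
#' the feedforward and local-feedback variants.
#'
#' @param params a [dnp_params()].
#' @param I intensity grid (default 8 decades, log-spaced).
#' @param variants subset of `c("ff", "local_fb")`.
#' @return Tibble (class `dnp_response`) with `I`, `log10_I`, `variant`,
#'   `v`.
#' @export
dnp_response_curve <- function(params, I = 10^seq(-2, 6, length.out = 200),
                               variants = c("ff", "local_fb")) {
  out <- purrr::map_dfr(variants, function(vr) {
    v <- switch(vr, ff = steady_state_ff(I, params),
                local_fb = steady_state_fb(I, params, method = "cardano"))
    tibble::tibble(I = I, log10_I = log10(I), variant = vr, v = v)
  })
  class(out) <- c("dnp_response", class(out))
  out
}

#' @rdname plot_dnpflow
#' @export
autoplot.dnp_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log10_I, .data$v,
                                       colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.1, 0.9), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(log[10](I)), y = "steady-state output v",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plots for dnpflow result objects
#'
#' `autoplot()` methods: polar error maps for [run_polar_benchmark()]
#' results, per-level detection/AE profiles for [run_cascade_benchmark()]
#' results, steady-state curves for [dnp_response_curve()] tables, and
#' arrow fields for [detect_motion()] estimates.
#'
#' @param object a result object.
#' @param metric which error to map (`"ae"` or `"epe"`).
#' @param ... unused.
#' @return A ggplot object.
#' @name plot_dnpflow
NULL

#' @rdname plot_dnpflow
#' @export
autoplot.polar_benchmark <- function(object, metric = c("ae", "epe"), ...) {
  metric <- match.arg(metric)
  cells <- object$cells
  cells$value <- if (metric == "ae") cells$mean_ae_deg else cells$mean_epe
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$angle_deg,
                               y = factor(.data$speed_true),
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_fill_viridis_c(
      name = if (metric == "ae") "AE (deg)" else "EPE (px/frame)") +
    ggplot2::labs(x = "motion direction (deg)", y = "speed (px/frame)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dnpflow
#' @export
autoplot.cascade_benchmark <- function(object, ...) {
  lv <- tidyr::pivot_longer(object$levels,
                            c("detected_frac", "mean_ae_deg"),
                            names_to = "measure")
  ggplot2::ggplot(lv, ggplot2::aes(factor(.data$level), .data$value,
                                   group = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "brightness level (decades)", y = NULL,
                  title = sprintf("cascade: gain_variant = \"%s\"",
                                  object$config$gain_variant)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_dnpflow
#' @export
autoplot.motion_estimates <- function(object, ...) {
  d <- dplyr::filter(object, .data$t == min(.data$t), .data$detected)
  sc <- 4 / max(d$speed, 0.1)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + sc * .data$vx,
                                       yend = .data$y + sc * .data$vy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px, image coordinates)") +
    ggplot2::theme_minimal()
}
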
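#' Plot a simulated trajectory
#'
#' Cell populations and cytokines on free y scales, with shaded spans for
#' active input pulses.
#'
#' @param object A `sarco_trajectory` from [simulate_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sarco_trajectory <- function(object, ...) {
  vn <- intersect(c(state_names()), names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(vn),
                              names_to = "variable", values_to = "density")
  long$variable <- factor(long$variable, levels = state_names())
  scn <- attr(object, "scenario")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                           y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (model units)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(scn) && length(scn$pulses)) {
    spans <- purrr::map_dfr(scn$pulses, function(p) {
      tibble::tibble(channel = p$channel, xmin = p$t_on, xmax = p$t_off)
    })
    gg <- gg + ggplot2::geom_rect(
      data = spans, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$channel),
      alpha = 0.12)
  }
  gg
}

#' Plot the steady-state branches of the minimal model
#'
#' The classic S-shaped curve of the Th1 steady state against the
#' activation drive: stable low and high branches connected by the
#' unstable middle branch, with the bistable drive range between the
#' folds.
#'
#' @param params A [minimal_params()] object.
#' @param f_range Length-2 drive range to trace.
#' @param n Number of drive values.
#' @return A ggplot object.
#' @export
plot_steady_state_curve <- function(params, f_range = c(0.5, 15),
                                    n = 300) {
  grid <- seq(f_range[1], f_range[2], length.out = n)
  curve <- purrr::map_dfr(grid, steady_states_minimal, params = params)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$f_T, y = .data$T_s,
                                      group = .data$branch,
                                      linetype = .data$stable)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   labels = c("unstable", "stable"),
                                   name = NULL) +
    ggplot2::labs(x = expression(f[T]), y = expression(T[s])) +
    ggplot2::theme_minimal()
}

#' Heat map of a combination-therapy dose plane
#'
#' @param dose_map Output of [titrate_combination()].
#' @return A ggplot object.
#' @export
plot_dose_plane <- function(dose_map) {
  ggplot2::ggplot(dose_map,
                  ggplot2::aes(x = .data$I_delta, y = .data$I_gamma,
                               fill = .data$verdict)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::labs(x = "anti-IL2 dose", y = "anti-IFNγ dose",
                  fill = "outcome") +
    ggplot2::theme_minimal()
}
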
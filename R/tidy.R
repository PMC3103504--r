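#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trajectory into long format
#'
#' @param x A `sarco_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `variable`, `density`.
#' @export
tidy.sarco_trajectory <- function(x, ...) {
  vn <- intersect(state_names(), names(x))
  if (!length(vn)) vn <- "T"
  tidyr::pivot_longer(tibble::as_tibble(x)[c("time", vn)],
                      dplyr::all_of(vn),
                      names_to = "variable", values_to = "density")
}

#' One-row summary of a simulated trajectory
#'
#' @param x A `sarco_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `t_end`, `n_pulses`, `settled`,
#'   terminal state values, and (for a settled detailed-model run) the
#'   coarse phenotype `state` and `label`.
#' @export
glance.sarco_trajectory <- function(x, ...) {
  scn <- attr(x, "scenario")
  st <- terminal_state(x)
  settled <- is_settled(x, window = min(20, diff(range(x$time)) / 2))
  out <- tibble::tibble(model = scn$model, t_end = max(x$time),
                        n_pulses = length(scn$pulses), settled = settled)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(st)))
  if (scn$model == "detailed" && settled) {
    cls <- classify_state(st)
    out$state <- cls$state
    out$label <- cls$label
  }
  out
}
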
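#' A time-windowed square input pulse
#'
#' A constant input applied to one channel over a half-open window
#' `[t_on, t_off)`: either the antigen channel `A` or one of the cytokine
#' inhibitor channels `I_delta` (anti-IL2), `I_gamma` (anti-IFN-gamma),
#' `I_alpha` (anti-TNF-alpha). Outside the window the channel contributes
#' nothing.
#'
#' @param channel One of `"A"`, `"I_delta"`, `"I_gamma"`, `"I_alpha"`.
#' @param amplitude Pulse level, >= 0.
#' @param t_on,t_off Window bounds in model time, `t_on < t_off`.
#' @return An object of class `square_pulse`.
#' @export
#' @examples
#' square_pulse("A", 100, 20, 70)
square_pulse <- function(channel, amplitude, t_on, t_off) {
  channel <- match.arg(channel, pulse_channels())
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0) {
    stop("pulse amplitude must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(t_on) || !is.numeric(t_off) || t_on >= t_off) {
    stop(sprintf("pulse on channel %s: t_on (%s) must be < t_off (%s)",
                 channel, format(t_on), format(t_off)), call. = FALSE)
  }
  structure(list(channel = channel, amplitude = amplitude,
                 t_on = t_on, t_off = t_off),
            class = "square_pulse")
}

pulse_channels <- function() c("A", "I_delta", "I_gamma", "I_alpha")

#' @export
print.square_pulse <- function(x, ...) {
  cat(sprintf("<square_pulse> %s = %g on [%g, %g)\n",
              x$channel, x$amplitude, x$t_on, x$t_off))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario is the unit of every experiment: a model choice, a parameter
#' set, an initial state, an ordered list of square pulses and a time
#' horizon. The shared protocol of the perturbation experiments is encoded
#' by `settle = TRUE`: the system is first relaxed to its drive-free low
#' steady state before the schedule starts.
#'
#' @param model `"minimal"` or `"detailed"`.
#' @param params A [minimal_params()] or [detailed_params()] object
#'   matching `model`; defaults to the base constants.
#' @param initial_state For the detailed model a named state vector
#'   (default [default_initial_state()]); for the minimal model a single
#'   number `T` (default 0.34, the published switching demonstration).
#' @param pulses A list of [square_pulse()] objects (may be empty). Stored
#'   sorted by `t_on`.
#' @param horizon End time of the simulation; must exceed the last
#'   `t_off`.
#' @param settle If `TRUE`, relax to the low steady state before running
#'   the schedule.
#' @return An object of class `sarco_scenario`.
#' @export
#' @examples
#' scn <- scenario("detailed", detailed_params(k_2a = 2.1),
#'                 pulses = list(square_pulse("A", 100, 20, 70)),
#'                 horizon = 300)
scenario <- function(model = c("detailed", "minimal"),
                     params = NULL,
                     initial_state = NULL,
                     pulses = list(),
                     horizon = 300,
                     settle = TRUE) {
  model <- match.arg(model)
  if (is.null(params)) {
    params <- if (model == "detailed") detailed_params() else minimal_params()
  }
  expected <- if (model == "detailed") "detailed_params" else "minimal_params"
  if (!inherits(params, expected)) {
    stop("params must be a ", expected, " object for model = '", model, "'",
         call. = FALSE)
  }
  if (is.null(initial_state)) {
    initial_state <- if (model == "detailed") default_initial_state() else
      c(T = 0.34)
  }
  if (model == "detailed") {
    initial_state <- as_state(initial_state)
  } else {
    initial_state <- c(T = as.numeric(initial_state)[1])
    if (initial_state < 0 || !is.finite(initial_state)) {
      stop("initial T must be a finite number >= 0", call. = FALSE)
    }
  }
  if (!is.list(pulses)) pulses <- list(pulses)
  ok <- vapply(pulses, inherits, logical(1), "square_pulse")
  if (!all(ok)) stop("pulses must be square_pulse objects", call. = FALSE)
  if (model == "minimal") {
    chans <- vapply(pulses, `[[`, "", "channel")
    if (any(chans != "A")) {
      stop("the minimal model only has the antigen channel A", call. = FALSE)
    }
  }
  if (length(pulses)) {
    pulses <- pulses[order(vapply(pulses, `[[`, 0, "t_on"))]
    last_off <- max(vapply(pulses, `[[`, 0, "t_off"))
    if (horizon <= last_off) {
      stop("horizon (", horizon, ") must exceed the last pulse t_off (",
           last_off, ")", call. = FALSE)
    }
  }
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be a positive number", call. = FALSE)
  }
  structure(list(model = model, params = params,
                 initial_state = initial_state, pulses = pulses,
                 horizon = horizon, settle = settle),
            class = "sarco_scenario")
}

#' @export
print.sarco_scenario <- function(x, ...) {
  cat(sprintf("<sarco_scenario> %s model, horizon %g, settle=%s, %d pulse(s)\n",
              x$model, x$horizon, x$settle, length(x$pulses)))
  for (p in x$pulses) {
    cat(sprintf("  %s = %g on [%g, %g)\n", p$channel, p$amplitude,
                p$t_on, p$t_off))
  }
  invisible(x)
}

#' Channel levels implied by a pulse schedule at time t
#' @keywords internal
channel_levels <- function(pulses, t) {
  lv <- c(A = 0, I_delta = 0, I_gamma = 0, I_alpha = 0)
  for (p in pulses) {
    if (t >= p$t_on && t < p$t_off) lv[p$channel] <- lv[p$channel] + p$amplitude
  }
  lv
}

#' Modify one pulse of a scenario
#'
#' Convenience for threshold scans: returns a copy of the scenario with
#' the `i`-th pulse's amplitude or end time replaced.
#'
#' @param scn A [scenario()].
#' @param i Pulse index (in `t_on` order).
#' @param amplitude,t_off New value (give exactly one).
#' @return A new `sarco_scenario`.
#' @export
set_pulse <- function(scn, i, amplitude = NULL, t_off = NULL) {
  stopifnot(inherits(scn, "sarco_scenario"))
  if (i < 1 || i > length(scn$pulses)) {
    stop("no pulse with index ", i, call. = FALSE)
  }
  p <- scn$pulses[[i]]
  if (!is.null(amplitude)) p$amplitude <- amplitude
  if (!is.null(t_off)) p$t_off <- t_off
  scn$pulses[[i]] <- square_pulse(p$channel, p$amplitude, p$t_on, p$t_off)
  scenario(scn$model, scn$params, scn$initial_state, scn$pulses,
           horizon = max(scn$horizon, p$t_off + 1), settle = scn$settle)
}

#' Override parameters of a scenario
#'
#' @param scn A [scenario()].
#' @param ... Named parameter overrides applied on top of the scenario's
#'   current parameter set.
#' @return A new `sarco_scenario`.
#' @export
set_params <- function(scn, ...) {
  stopifnot(inherits(scn, "sarco_scenario"))
  over <- list(...)
  p <- unclass(scn$params)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  params <- if (scn$model == "detailed") do.call(detailed_params, p) else
    do.call(minimal_params, p)
  scenario(scn$model, params, scn$initial_state, scn$pulses, scn$horizon,
           scn$settle)
}
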
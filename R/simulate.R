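#' @importFrom deSolve ode
NULL

# Default integrator settings: stiff-capable adaptive method, tight
# tolerances (threshold brackets as sharp as 0.1 in pulse amplitude demand
# accurate transients), pulse edges handled by segmenting the integration.
integrator_defaults <- function() {
  list(method = "lsoda", rtol = 1e-8, atol = 1e-10, maxsteps = 100000L)
}

# Integrate one constant-input segment; returns the deSolve matrix.
integrate_segment <- function(model, y0, times, params, levels, control) {
  if (model == "detailed") {
    fn <- function(t, y, parms) {
      y <- pmax(y, 0)
      list(detailed_rhs_raw(y, levels[["A"]], levels[["I_delta"]],
                            levels[["I_gamma"]], levels[["I_alpha"]], parms))
    }
  } else {
    f <- params$eta1 * levels[["A"]] + params$eta2 * params$c
    fn <- function(t, y, parms) {
      y <- pmax(y, 0)
      list(parms$beta_T - parms$eps_T * y +
             f * y^2 / (parms$theta_T^2 + y^2))
    }
  }
  out <- deSolve::ode(y = y0, times = times, func = fn, parms = params,
                      method = control$method, rtol = control$rtol,
                      atol = control$atol, maxsteps = control$maxsteps)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop(sprintf("integrator failure at t = %.4g (state: %s)",
                 out[nrow(out), 1],
                 paste(signif(out[nrow(out), -1], 4), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Relax a model to its low steady state
#'
#' Integrates with all input channels at zero until the right-hand side
#' falls below `tol` in the infinity norm. From the default initial state
#' under base parameters this is the low ("healthy") branch, the starting
#' point of every perturbation experiment.
#'
#' @param params A [detailed_params()] or [minimal_params()] object.
#' @param initial_state Starting state; defaults to
#'   [default_initial_state()] (detailed) or `T = 0.34` (minimal).
#' @param model `"detailed"` or `"minimal"`; inferred from `params` when
#'   missing.
#' @param tol Steady-state tolerance on the RHS infinity norm.
#' @param budget Maximum settling time before non-convergence is reported
#'   as an error (a non-converging settle signals oscillation or runaway,
#'   both diagnostically meaningful).
#' @return The settled state (named numeric vector) with attribute
#'   `"settle_time"`.
#' @export
#' @examples
#' settle(detailed_params())
settle <- function(params, initial_state = NULL, model = NULL,
                   tol = 1e-7, budget = 500) {
  if (is.null(model)) {
    model <- if (inherits(params, "detailed_params")) "detailed" else "minimal"
  }
  if (is.null(initial_state)) {
    initial_state <- if (model == "detailed") default_initial_state() else
      c(T = 0.34)
  }
  y <- if (model == "detailed") as_state(initial_state) else
    c(T = as.numeric(initial_state)[1])
  control <- integrator_defaults()
  levels <- c(A = 0, I_delta = 0, I_gamma = 0, I_alpha = 0)
  rhs_norm <- function(y) {
    d <- if (model == "detailed") {
      detailed_rhs_raw(y, 0, 0, 0, 0, params)
    } else {
      minimal_rhs(y, 0, params)
    }
    max(abs(d))
  }
  t_done <- 0
  chunk <- 50
  while (t_done < budget) {
    out <- integrate_segment(model, y, c(0, chunk), params, levels, control)
    y <- pmax(out[nrow(out), -1, drop = TRUE], 0)
    names(y) <- if (model == "detailed") state_names() else "T"
    t_done <- t_done + chunk
    if (rhs_norm(y) < tol) {
      attr(y, "settle_time") <- t_done
      return(y)
    }
  }
  stop(sprintf(
    "settle() did not converge within %g time units (RHS norm %.3g); %s",
    budget, rhs_norm(y),
    "the system may be oscillating or running away"), call. = FALSE)
}

#' Run a scenario
#'
#' Integrates the scenario's model under its square-pulse schedule. The
#' integration is restarted at every pulse edge so channel switching is
#' located exactly, making runs reproducible to integrator tolerance.
#'
#' @param scn A [scenario()].
#' @param dt Output grid spacing (model time units).
#' @param control Integrator settings; see source of
#'   `integrator_defaults()` (`method`, `rtol`, `atol`, `maxsteps`).
#' @return A `sarco_trajectory`: a tibble with columns `time`, the state
#'   variables (`T`, `R`, `M`, `delta`, `gamma`, `alpha` for the detailed
#'   model; `T` for the minimal one) and the channel levels `A`,
#'   `I_delta`, `I_gamma`, `I_alpha`. The scenario is attached as
#'   attribute `"scenario"`.
#' @export
#' @examples
#' scn <- scenario("minimal", minimal_params(), horizon = 50,
#'                 pulses = list(square_pulse("A", 4, 5, 10)),
#'                 settle = FALSE)
#' traj <- simulate_scenario(scn)
#' tail(traj)
simulate_scenario <- function(scn, dt = 0.5, control = list()) {
  stopifnot(inherits(scn, "sarco_scenario"))
  control <- utils::modifyList(integrator_defaults(), control)
  y0 <- if (scn$settle) {
    settle(scn$params, scn$initial_state, scn$model)
  } else if (scn$model == "detailed") {
    as_state(scn$initial_state)
  } else {
    scn$initial_state
  }
  edges <- sort(unique(c(0, unlist(lapply(scn$pulses, function(p)
    c(p$t_on, p$t_off))), scn$horizon)))
  edges <- edges[edges >= 0 & edges <= scn$horizon]
  if (edges[length(edges)] < scn$horizon) edges <- c(edges, scn$horizon)

  rows <- list()
  y <- as.numeric(y0)
  vn <- if (scn$model == "detailed") state_names() else "T"
  for (i in seq_len(length(edges) - 1)) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    lv <- channel_levels(scn$pulses, (t0 + t1) / 2)
    times <- unique(c(seq(t0, t1, by = dt), t1))
    out <- integrate_segment(scn$model, y, times, scn$params, lv, control)
    seg <- as.data.frame(out)
    names(seg) <- c("time", vn)
    seg[vn] <- lapply(seg[vn], pmax, 0)
    for (ch in names(lv)) seg[[ch]] <- unname(lv[[ch]])
    if (i > 1) seg <- seg[-1, , drop = FALSE]  # avoid duplicate edge rows
    rows[[i]] <- seg
    y <- pmax(out[nrow(out), -1, drop = TRUE], 0)
  }
  traj <- tibble::as_tibble(do.call(rbind, rows))
  attr(traj, "scenario") <- scn
  class(traj) <- c("sarco_trajectory", class(traj))
  traj
}

#' Terminal state of a trajectory
#' @param traj A `sarco_trajectory`.
#' @return Named numeric state vector at the final time point.
#' @export
terminal_state <- function(traj) {
  vn <- intersect(state_names(), names(traj))
  if (!length(vn)) vn <- "T"
  s <- unlist(traj[nrow(traj), vn])
  names(s) <- vn
  s
}

#' Extract the settled final steady state of a trajectory
#'
#' Checks that the trajectory has actually settled: the maximum time
#' derivative over the trailing `window` must be below `tol`. A still
#' moving (transient) trajectory yields an *indeterminate* result rather
#' than a misleading snapshot.
#'
#' @param traj A `sarco_trajectory` from [simulate_scenario()].
#' @param window Trailing window length (model time units) over which
#'   stationarity is checked; must not exceed the trajectory span.
#' @param tol Tolerance on the RHS infinity norm over the window.
#' @return The terminal state vector, or `NULL` (with a warning) if the
#'   trajectory has not settled. Use [is_settled()] for a predicate.
#' @export
final_steady_state <- function(traj, window = 20, tol = 1e-6) {
  scn <- attr(traj, "scenario")
  span <- diff(range(traj$time))
  if (window > span) {
    stop("window (", window, ") exceeds the trajectory span (", span, ")",
         call. = FALSE)
  }
  if (length(scn$pulses)) {
    last_off <- max(vapply(scn$pulses, `[[`, 0, "t_off"))
    if (max(traj$time) - last_off < window) {
      stop("trajectory must extend at least `window` beyond the last pulse",
           call. = FALSE)
    }
  }
  tail_rows <- which(traj$time >= max(traj$time) - window)
  minimal <- !is.null(scn) && scn$model == "minimal"
  vn <- if (minimal) "T" else intersect(state_names(), names(traj))
  worst <- 0
  for (i in tail_rows) {
    s <- unlist(traj[i, vn])
    d <- if (minimal) {
      minimal_rhs(s[["T"]], traj$A[i], scn$params)
    } else {
      detailed_rhs_raw(s, traj$A[i], traj$I_delta[i], traj$I_gamma[i],
                       traj$I_alpha[i], scn$params)
    }
    worst <- max(worst, max(abs(d)))
  }
  if (worst >= tol) {
    warning(sprintf(
      "trajectory has not settled (max |d/dt| = %.3g over the last %g units)",
      worst, window), call. = FALSE)
    return(NULL)
  }
  terminal_state(traj)
}

#' Has a trajectory settled to a steady state?
#' @inheritParams final_steady_state
#' @return `TRUE`/`FALSE`.
#' @export
is_settled <- function(traj, window = 20, tol = 1e-6) {
  !is.null(suppressWarnings(final_steady_state(traj, window, tol)))
}

#' Write a trajectory to a delimited text file
#'
#' Writes the standard 11-column table (`time`, six state variables, four
#' channel levels) as comma-separated values. Minimal-model trajectories
#' are padded with `NA` state columns so the header is uniform.
#'
#' @param traj A `sarco_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time", state_names(), "A", "I_delta", "I_gamma", "I_alpha")
  out <- as.data.frame(traj)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA_real_
  utils::write.csv(out[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
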
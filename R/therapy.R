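#' In-silico therapy experiments
#'
#' @description
#' Therapies are modeled as square pulses of a neutralizing inhibitor
#' applied to one cytokine channel of an established sarcoid state:
#' anti-IL2 (`I_delta`), anti-IFN-gamma (`I_gamma`) or anti-TNF-alpha
#' (`I_alpha`). The inhibitor removes its target by mass action while the
#' pulse is on. Doses are abstract pulse amplitudes; no pharmacokinetics.
#'
#' The verdict of a therapy compares the coarse phenotype before and
#' after:
#' * `remission` — all three populations low afterwards;
#' * `partial` — at least one population newly low but Teff still high;
#' * `no_effect` — coarse state unchanged;
#' * `paradoxical` — some population flipped low-to-high (therapy
#'   promoted the disease phenotype).
#'
#' @name therapy
NULL

#' The standard sarcoid induction scenario
#'
#' Settle to the low state, then challenge with antigen amplitude 100
#' over the window 20-70 under elevated Treg IL-2 sensitivity
#' (`k_2a = 2.1` unless overridden). This is the common pre-state of all
#' therapy experiments.
#'
#' @param horizon Simulation end time (therapy pulses are added within
#'   it).
#' @param ... Parameter overrides on top of `k_2a = 2.1` base values
#'   (for example `k_2b = 0.2`).
#' @return A [scenario()].
#' @export
sarcoid_scenario <- function(horizon = 700, ...) {
  over <- utils::modifyList(list(k_2a = 2.1), list(...))
  scenario("detailed", do.call(detailed_params, over),
           pulses = list(square_pulse("A", 100, 20, 70)),
           horizon = horizon)
}

#' Verdict of a therapy from pre/post coarse states
#'
#' A pure function of the two [classify_state()] rows.
#'
#' @param pre,post One-row classification tibbles.
#' @return One of `"remission"`, `"partial"`, `"no_effect"`,
#'   `"paradoxical"`.
#' @export
therapy_verdict <- function(pre, post) {
  pre_f <- unlist(pre[c("T_high", "R_high", "M_high")])
  post_f <- unlist(post[c("T_high", "R_high", "M_high")])
  if (any(!pre_f & post_f)) return("paradoxical")
  if (!any(post_f)) return("remission")
  if (all(pre_f == post_f)) return("no_effect")
  if (any(pre_f & !post_f) && post_f[["T_high"]]) return("partial")
  # a population dropped and T dropped with it, but not all are low
  "partial"
}

run_therapy <- function(channels, amplitudes, windows, base_scn = NULL,
                        reference = NULL, ...) {
  if (is.null(base_scn)) base_scn <- sarcoid_scenario(...)
  stopifnot(inherits(base_scn, "sarco_scenario"))
  if (is.null(reference)) reference <- coarse_reference(base_scn$params)
  pre_traj <- simulate_scenario(base_scn, dt = 2)
  pre_state <- final_steady_state(pre_traj)
  if (is.null(pre_state)) {
    stop("protocol error: pre-therapy scenario does not settle",
         call. = FALSE)
  }
  pre_cls <- classify_state(pre_state, reference)
  pulses <- base_scn$pulses
  last_end <- 0
  for (i in seq_along(channels)) {
    if (amplitudes[i] > 0) {
      pulses <- c(pulses, list(square_pulse(channels[i], amplitudes[i],
                                            windows[[i]][1],
                                            windows[[i]][2])))
    }
    last_end <- max(last_end, windows[[i]][2])
  }
  scn <- scenario("detailed", base_scn$params, base_scn$initial_state,
                  pulses, horizon = max(base_scn$horizon, last_end + 400),
                  settle = base_scn$settle)
  traj <- simulate_scenario(scn, dt = 2)
  post_state <- final_steady_state(traj)
  if (is.null(post_state)) {
    stop("post-therapy trajectory did not settle", call. = FALSE)
  }
  post_cls <- classify_state(post_state, reference)
  list(pre = pre_cls, post = post_cls,
       verdict = therapy_verdict(pre_cls, post_cls),
       post_state = post_state, trajectory = traj)
}

#' Run a single-inhibitor therapy on an established sarcoid state
#'
#' Induces the sarcoid state (antigen 100, window 20-70, `k_2a = 2.1` by
#' default), applies one inhibitor pulse, and classifies the settled
#' outcome. The published windows are 100-120 for anti-IL2, 100-150 for
#' anti-IFN-gamma and 100-140 for anti-TNF-alpha.
#'
#' @param channel `"I_delta"`, `"I_gamma"` or `"I_alpha"`.
#' @param amplitude Pulse amplitude, >= 0.
#' @param window Length-2 numeric, pulse on/off times; defaults to the
#'   published window for the channel.
#' @param base_scn Optional pre-built sarcoid [scenario()]; it must
#'   settle to a high-Teff state, otherwise a protocol error is raised.
#' @param reference Optional precomputed [coarse_reference()].
#' @param ... Parameter overrides passed to [sarcoid_scenario()] when
#'   `base_scn` is not supplied.
#' @return A one-row tibble: `channel`, `amplitude`, `pre_state`,
#'   `post_state` (phenotype indices), `verdict`, plus the post-therapy
#'   flags `T_high`, `R_high`, `M_high`.
#' @export
#' @examples
#' \donttest{
#' run_monotherapy("I_delta", 30)
#' }
run_monotherapy <- function(channel = c("I_delta", "I_gamma", "I_alpha"),
                            amplitude, window = NULL, base_scn = NULL,
                            reference = NULL, ...) {
  channel <- match.arg(channel)
  if (is.null(window)) {
    window <- switch(channel, I_delta = c(100, 120), I_gamma = c(100, 150),
                     I_alpha = c(100, 140))
  }
  res <- run_therapy(channel, amplitude, list(window), base_scn, reference,
                     ...)
  if (!res$pre$T_high) {
    stop("protocol error: pre-therapy state is not sarcoid (Teff low)",
         call. = FALSE)
  }
  tibble::tibble(channel = channel, amplitude = amplitude,
                 pre_state = res$pre$state, post_state = res$post$state,
                 verdict = res$verdict, T_high = res$post$T_high,
                 R_high = res$post$R_high, M_high = res$post$M_high)
}

#' Titrate an anti-IL2 / anti-IFN-gamma combination over a dose grid
#'
#' Applies simultaneous square pulses of both inhibitors (shared window,
#' published default 100-120) to the established sarcoid state, one run
#' per grid cell, and records the outcome verdict and post-state.
#'
#' @param I_delta_grid,I_gamma_grid Numeric dose grids (>= 0).
#' @param window Shared pulse window.
#' @param base_scn Optional pre-built sarcoid scenario.
#' @param reference Optional precomputed [coarse_reference()].
#' @param ... Parameter overrides passed to [sarcoid_scenario()] (for
#'   example `k_2a = 2.0`).
#' @return A tibble with one row per `(I_delta, I_gamma)` cell: doses,
#'   `verdict`, `post_state` and the post-therapy flags — ready for
#'   heat-map plotting (see [plot_dose_plane()]).
#' @export
titrate_combination <- function(I_delta_grid, I_gamma_grid,
                                window = c(100, 120), base_scn = NULL,
                                reference = NULL, ...) {
  if (is.null(base_scn)) base_scn <- sarcoid_scenario(...)
  if (is.null(reference)) reference <- coarse_reference(base_scn$params)
  cells <- tidyr::expand_grid(I_delta = I_delta_grid,
                              I_gamma = I_gamma_grid)
  purrr::pmap_dfr(cells, function(I_delta, I_gamma) {
    res <- run_therapy(c("I_delta", "I_gamma"), c(I_delta, I_gamma),
                       list(window, window), base_scn, reference)
    tibble::tibble(I_delta = I_delta, I_gamma = I_gamma,
                   verdict = res$verdict, post_state = res$post$state,
                   T_high = res$post$T_high, R_high = res$post$R_high,
                   M_high = res$post$M_high)
  })
}

#' Scan anti-TNF-alpha monotherapy over a dose grid
#'
#' The anti-TNF-alpha experiment runs under a Treg compartment that is
#' both more IL-2-sensitive and more strongly TNF-alpha-suppressed than
#' base (`k_2a = 2.1`, `k_2b = 0.2`). Below a threshold dose the pulse
#' changes nothing; at the threshold the long-term coarse state flips —
#' the in-silico counterpart of anti-TNF-alpha therapy paradoxically
#' promoting the disease phenotype in susceptible patients.
#'
#' @param amplitudes Dose grid (>= 0).
#' @param window Pulse window (published: 100-140).
#' @param base_scn Optional pre-built scenario; defaults to
#'   [sarcoid_scenario()] with `k_2a = 2.1, k_2b = 0.2`.
#' @param reference Optional precomputed [coarse_reference()].
#' @return A tibble with one row per dose: `I_alpha`, `verdict`,
#'   `post_state` and post-therapy flags, where `verdict` compares
#'   against the untreated (zero-dose) outcome of the same protocol.
#' @export
anti_tnf_scan <- function(amplitudes, window = c(100, 140),
                          base_scn = NULL, reference = NULL) {
  if (is.null(base_scn)) base_scn <- sarcoid_scenario(k_2b = 0.2)
  if (is.null(reference)) reference <- coarse_reference(base_scn$params)
  base_res <- run_therapy("I_alpha", 0, list(window), base_scn, reference)
  base_flags <- unlist(base_res$post[c("T_high", "R_high", "M_high")])
  purrr::map_dfr(amplitudes, function(a) {
    res <- run_therapy("I_alpha", a, list(window), base_scn, reference)
    flags <- unlist(res$post[c("T_high", "R_high", "M_high")])
    changed <- any(flags != base_flags)
    verdict <- if (!changed) "no_effect" else
      therapy_verdict(base_res$post, res$post)
    tibble::tibble(I_alpha = a, verdict = verdict,
                   post_state = res$post$state,
                   changed = changed,
                   T_high = flags[["T_high"]], R_high = flags[["R_high"]],
                   M_high = flags[["M_high"]])
  })
}
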
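#' Model equations
#'
#' @description
#' The two models share one building block: each cell population `x` obeys
#'
#' \deqn{dx/dt = \beta_x - \epsilon_x x + f_x \frac{x^2}{\theta_x^2 + x^2}}
#'
#' a net basal flux plus an autocatalytic Hill-type activation whose rate
#' saturates at the instantaneous drive `f_x`. The squared-Hill form is the
#' minimal sigmoidal rate yielding a cubic steady-state equation and hence
#' a bistable (low/high) branch structure with hysteresis.
#'
#' Minimal model (one variable, Th1 activity `T`):
#' \deqn{f_T = \eta_1 A + \eta_2 c}
#'
#' Detailed model (six variables) drives:
#' \deqn{f_T = \frac{k_{1a} A M + k_{1b}\delta + k_{1c}\gamma}
#'             {1 + k_{1d} R + k_{1e} \alpha M}}
#' \deqn{f_R = \delta \,\max(k_{2a} - k_{2b}\alpha,\, 0)}
#' \deqn{f_M = \frac{k_6 \gamma + k_{6b}\alpha}{1 + k_{6c} R}}
#'
#' `A*M` is antigen presentation by macrophages (macrophages are the only
#' antigen-presenting cells here). Treg inhibition of Teff proliferation
#' sits in the denominator of the Teff drive (`k_1d R`), together with the
#' macrophage-mediated TNF-alpha suppression of Teffs (`k_1e alpha M`).
#' The Treg drive encodes IL-2-dependent activation by Teffs whose sign is
#' flipped by TNF-alpha: for `alpha > k_2a / k_2b` the Teff-to-Treg edge
#' has turned from an arrow into a hammerhead and the drive is clamped at
#' zero. Cytokines follow linear production/clearance kinetics; an active
#' inhibitor pulse `I_x` removes its target cytokine by mass action
#' (`- I_x x`).
#'
#' @name model-equations
NULL

#' Activation drive of the minimal Th1 model
#'
#' `f_T = eta1 * A + eta2 * c`: the linear combination of antigen density
#' and the constant lumped cytokine level that feeds the autocatalytic
#' activation term.
#'
#' @param A Antigen density (scalar or vector), must be >= 0.
#' @param params A [minimal_params()] object.
#' @return Drive value(s), same length as `A`.
#' @export
#' @examples
#' minimal_drive(4, minimal_params()) # 4 + 3 = 7
minimal_drive <- function(A, params) {
  stopifnot(inherits(params, "minimal_params"))
  if (any(A < 0)) stop("antigen density A must be >= 0", call. = FALSE)
  params$eta1 * A + params$eta2 * params$c
}

#' Hill-type autocatalytic activation rate
#'
#' `f * x^2 / (theta^2 + x^2)`: zero without a seed population (`x = 0`),
#' nondecreasing in `x`, saturating at the drive `f` as `x` grows, and
#' linear in `f`.
#'
#' @param x Population density, >= 0.
#' @param f Activation drive, >= 0.
#' @param theta Activation threshold, > 0.
#' @return Activation rate(s).
#' @export
#' @examples
#' hill_activation(1, f = 3, theta = 1) # half-maximal: 1.5
hill_activation <- function(x, f, theta) {
  if (any(theta <= 0)) stop("theta must be > 0", call. = FALSE)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (any(f < 0)) stop("f must be >= 0", call. = FALSE)
  f * x^2 / (theta^2 + x^2)
}

#' Right-hand side of the minimal Th1 model
#'
#' `dT/dt = beta_T - eps_T * T + hill_activation(T, minimal_drive(A), theta_T)`.
#' With zero drive the unique steady state is the basal level
#' `beta_T / eps_T`.
#'
#' @param T Th1 activity, >= 0.
#' @param A Antigen density, >= 0.
#' @param params A [minimal_params()] object.
#' @return `dT/dt`.
#' @export
minimal_rhs <- function(T, A, params) {
  stopifnot(inherits(params, "minimal_params"))
  if (any(T < 0)) stop("T must be >= 0", call. = FALSE)
  f <- minimal_drive(A, params)
  params$beta_T - params$eps_T * T +
    hill_activation(T, f, params$theta_T)
}

#' Instantaneous activation drives of the detailed model
#'
#' Evaluates the three cell-population drives `f_T`, `f_R`, `f_M` at a
#' given state and antigen level (see [model-equations] for the algebra).
#'
#' @param state Named state vector (or one-row data frame) over
#'   `T, R, M, delta, gamma, alpha`, componentwise >= 0.
#' @param A Antigen density, >= 0.
#' @param params A [detailed_params()] object.
#' @return A one-row tibble with columns `f_T`, `f_R`, `f_M`.
#' @export
#' @examples
#' detailed_drives(default_initial_state(), A = 0, detailed_params())
detailed_drives <- function(state, A, params) {
  stopifnot(inherits(params, "detailed_params"))
  s <- as_state(state)
  if (A < 0) stop("antigen density A must be >= 0", call. = FALSE)
  p <- params
  f_T <- (p$k_1a * A * s[["M"]] + p$k_1b * s[["delta"]] +
            p$k_1c * s[["gamma"]]) /
    (1 + p$k_1d * s[["R"]] + p$k_1e * s[["alpha"]] * s[["M"]])
  f_R <- s[["delta"]] * max(p$k_2a - p$k_2b * s[["alpha"]], 0)
  f_M <- (p$k_6 * s[["gamma"]] + p$k_6b * s[["alpha"]]) /
    (1 + p$k_6c * s[["R"]])
  tibble::tibble(f_T = f_T, f_R = f_R, f_M = f_M)
}

#' Right-hand side of the detailed six-variable model
#'
#' Each cell population follows basal influx minus clearance plus the
#' Hill-type activation of its own density under its drive; each cytokine
#' follows basal influx plus production from cell densities minus
#' clearance minus first-order neutralization by any active inhibitor.
#'
#' @param state Named state vector over `T, R, M, delta, gamma, alpha`.
#' @param A Antigen density, >= 0.
#' @param inhibitors Named vector/list of inhibitor levels with any of
#'   `I_delta`, `I_gamma`, `I_alpha` (missing entries are 0).
#' @param params A [detailed_params()] object.
#' @return Named numeric vector of the six time derivatives.
#' @export
#' @examples
#' detailed_rhs(default_initial_state(), A = 0, c(I_delta = 0),
#'              detailed_params())
detailed_rhs <- function(state, A, inhibitors = NULL, params) {
  stopifnot(inherits(params, "detailed_params"))
  s <- as_state(state)
  inh <- c(I_delta = 0, I_gamma = 0, I_alpha = 0)
  if (!is.null(inhibitors)) {
    inhibitors <- unlist(inhibitors)
    unknown <- setdiff(names(inhibitors), names(inh))
    if (length(unknown)) {
      stop("unknown inhibitor channel(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(inhibitors < 0)) stop("inhibitor levels must be >= 0",
                                  call. = FALSE)
    inh[names(inhibitors)] <- inhibitors
  }
  d <- detailed_rhs_raw(s, A, inh[["I_delta"]], inh[["I_gamma"]],
                        inh[["I_alpha"]], params)
  names(d) <- state_names()
  d
}

# Unchecked fast path shared by detailed_rhs() and the integrator.
detailed_rhs_raw <- function(s, A, I_delta, I_gamma, I_alpha, p) {
  T <- s[[1L]]; R <- s[[2L]]; M <- s[[3L]]
  delta <- s[[4L]]; gamma <- s[[5L]]; alpha <- s[[6L]]
  f_T <- (p$k_1a * A * M + p$k_1b * delta + p$k_1c * gamma) /
    (1 + p$k_1d * R + p$k_1e * alpha * M)
  f_R <- delta * max(p$k_2a - p$k_2b * alpha, 0)
  f_M <- (p$k_6 * gamma + p$k_6b * alpha) / (1 + p$k_6c * R)
  c(p$beta_T - p$eps_T * T + f_T * T^2 / (p$theta_T^2 + T^2),
    p$beta_R - p$eps_R * R + f_R * R^2 / (p$theta_R^2 + R^2),
    p$beta_M - p$eps_M * M + f_M * M^2 / (p$theta_M^2 + M^2),
    p$beta_delta + p$k_3 * T - p$eps_delta * delta - I_delta * delta,
    p$beta_gamma + p$k_4a * T + p$k_4b * M - p$eps_gamma * gamma -
      I_gamma * gamma,
    p$beta_alpha + p$k_5a * T + p$k_5b * M - p$eps_alpha * alpha -
      I_alpha * alpha)
}
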
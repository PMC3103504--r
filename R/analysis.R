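#' Steady states of the minimal model at a fixed drive
#'
#' Solves `beta_T - eps_T*T + f_T * T^2/(theta_T^2 + T^2) = 0`, i.e. the
#' cubic
#' `-eps_T T^3 + (beta_T + f_T) T^2 - eps_T theta_T^2 T + beta_T theta_T^2 = 0`,
#' and returns all real nonnegative roots. Inside the bistable range there
#' are three (low, middle, high); outside, one.
#'
#' @param f_T Activation drive, >= 0.
#' @param params A [minimal_params()] object.
#' @return A tibble with columns `f_T`, `T_s` (root, ascending), `branch`
#'   (`"low"`, `"middle"`, `"high"`; a unique root is labelled by its
#'   stability-side: `"low"` below the fold region, `"high"` above) and
#'   `stable`.
#' @export
#' @examples
#' steady_states_minimal(3, minimal_params())
steady_states_minimal <- function(f_T, params) {
  stopifnot(inherits(params, "minimal_params"))
  if (f_T < 0) stop("f_T must be >= 0", call. = FALSE)
  p <- params
  # polyroot takes ascending coefficients: a0 + a1 z + a2 z^2 + a3 z^3
  co <- c(p$beta_T * p$theta_T^2,
          -p$eps_T * p$theta_T^2,
          p$beta_T + f_T,
          -p$eps_T)
  z <- polyroot(co)
  re <- Re(z)[abs(Im(z)) < 1e-8]
  re <- sort(re[re >= -1e-12])
  re <- pmax(re, 0)
  # Polish by Newton and verify by substitution.
  g <- function(T) p$beta_T - p$eps_T * T +
    f_T * T^2 / (p$theta_T^2 + T^2)
  gp <- function(T) -p$eps_T +
    f_T * 2 * T * p$theta_T^2 / (p$theta_T^2 + T^2)^2
  for (i in seq_along(re)) {
    for (it in 1:50) {
      step <- g(re[i]) / gp(re[i])
      if (!is.finite(step)) break
      re[i] <- re[i] - step
      if (abs(step) < 1e-14) break
    }
  }
  re <- sort(unique(round(re, 12)))
  re <- re[abs(vapply(re, g, 0)) < 1e-10 & re >= 0]
  # De-duplicate near-tangent roots
  if (length(re) > 1) re <- re[c(TRUE, diff(re) > 1e-8)]
  branch <- switch(as.character(length(re)),
    "3" = c("low", "middle", "high"),
    "2" = c("low", "high"),  # fold tangency; endpoints count as monostable
    "1" = if (re[1] < p$theta_T) "low" else "high",
    character(0))
  stable <- vapply(re, function(T) gp(T) < 0, logical(1))
  tibble::tibble(f_T = f_T, T_s = re, branch = branch, stable = stable)
}

count_roots <- function(f_T, params) nrow(steady_states_minimal(f_T, params))

#' Bistable drive range of the minimal model
#'
#' Locates the interval of the drive `f_T` over which the steady-state
#' equation has three roots (coexisting low and high branches). Endpoints
#' are found by bisection on the root count to an absolute tolerance of
#' `1e-8`; by convention the endpoints themselves (where two roots merge
#' in a fold) belong to the monostable side.
#'
#' @param params A [minimal_params()] object.
#' @param f_max Upper limit of the search.
#' @return A tibble with columns `f_lo`, `f_hi` and `bistable`. For
#'   parameters admitting no bistability (for example overwhelming
#'   clearance) `bistable` is `FALSE` and the endpoints are `NA` — an
#'   empty-range marker, not an error.
#' @export
#' @examples
#' bistable_range(minimal_params(beta_T = 0.05))
bistable_range <- function(params, f_max = 1000) {
  stopifnot(inherits(params, "minimal_params"))
  # coarse scan for a drive with three roots
  grid <- exp(seq(log(1e-3), log(f_max), length.out = 400))
  n3 <- vapply(grid, count_roots, 0L, params = params)
  idx <- which(n3 == 3)
  if (!length(idx)) {
    return(tibble::tibble(f_lo = NA_real_, f_hi = NA_real_,
                          bistable = FALSE))
  }
  bisect_edge <- function(lo, hi, want_three_at_hi) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      three <- count_roots(mid, params) == 3
      if (three == want_three_at_hi) hi <- mid else lo <- mid
      if (hi - lo < 1e-8) break
    }
    (lo + hi) / 2
  }
  f_in <- grid[idx[1]]
  lo_start <- if (idx[1] > 1) grid[idx[1] - 1] else 0
  f_lo <- bisect_edge(lo_start, f_in, want_three_at_hi = TRUE)
  f_in2 <- grid[idx[length(idx)]]
  hi_end <- if (idx[length(idx)] < length(grid))
    grid[idx[length(idx)] + 1] else f_max
  # here "three" holds at the lower end of the bracket
  lo <- f_in2; hi <- hi_end
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_roots(mid, params) == 3) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  f_hi <- (lo + hi) / 2
  tibble::tibble(f_lo = f_lo, f_hi = f_hi, bistable = TRUE)
}

#' Quasi-static hysteresis sweep of the minimal model
#'
#' Sweeps the drive `f_T` up through a grid and back down, at each step
#' continuing from the branch reached previously (state continuation by
#' nearest stable root). Crossing the upper fold on the way up jumps the
#' state to the high branch; the high branch is then retained down to the
#' lower fold — the hysteresis loop of a bistable switch.
#'
#' @param params A [minimal_params()] object.
#' @param f_seq Ascending drive grid; swept up then down.
#' @return A tibble with columns `step`, `direction` (`"up"`/`"down"`),
#'   `f_T` and `T_s`.
#' @export
sweep_hysteresis <- function(params, f_seq = seq(0.5, 15, by = 0.05)) {
  stopifnot(inherits(params, "minimal_params"))
  f_seq <- sort(f_seq)
  path <- c(f_seq, rev(f_seq))
  dir <- rep(c("up", "down"), each = length(f_seq))
  T_cur <- NULL
  out <- numeric(length(path))
  for (i in seq_along(path)) {
    ss <- steady_states_minimal(path[i], params)
    stab <- ss[ss$stable, , drop = FALSE]
    if (is.null(T_cur)) {
      T_cur <- min(stab$T_s)
    } else {
      T_cur <- stab$T_s[which.min(abs(stab$T_s - T_cur))]
    }
    out[i] <- T_cur
  }
  tibble::tibble(step = seq_along(path), direction = dir, f_T = path,
                 T_s = out)
}

# ---------------------------------------------------------------------------
# Coarse-state classification (the eight low/high phenotypes)

coarse_state_table <- function() {
  tibble::tibble(
    state = 1:8,
    T_high = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    R_high = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    M_high = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    label = c("healthy", "unlikely", "unlikely", "unlikely", "unlikely",
              "sarcoid, lymphopenia", "sarcoid", "sarcoid, lymphopenia")
  )
}

#' Reference scales for coarse-state classification
#'
#' The classifier needs, per population, a low reference (the basal level
#' `beta/eps`) and a high-branch scale. The high scale is measured once
#' from the settled outcome of the standard supra-threshold antigen
#' challenge (amplitude 100, window 20-70, Treg IL-2 sensitivity
#' `k_2a = 2.1`), which drives all three populations to their high
#' branches. Each population is then called high when it exceeds the
#' geometric mean of its two references; because the branches are orders
#' of magnitude apart, any mid-gap cut is stable, and this one is anchored
#' in the model rather than hand-picked.
#'
#' @param params Parameter set used for the basal references (the high
#'   scale is always measured under the standard challenge above).
#' @return A tibble with columns `population`, `low_ref`, `high_ref`,
#'   `cut`.
#' @export
coarse_reference <- function(params = detailed_params()) {
  stopifnot(inherits(params, "detailed_params"))
  low_ref <- c(T = params$beta_T / params$eps_T,
               R = params$beta_R / params$eps_R,
               M = params$beta_M / params$eps_M)
  high <- the$high_ref
  if (is.null(high)) {
    scn <- scenario("detailed", detailed_params(k_2a = 2.1),
                    pulses = list(square_pulse("A", 100, 20, 70)),
                    horizon = 700)
    st <- final_steady_state(simulate_scenario(scn, dt = 5))
    high <- st[c("T", "R", "M")]
    the$high_ref <- high
  }
  tibble::tibble(population = c("T", "R", "M"),
                 low_ref = unname(low_ref),
                 high_ref = unname(high),
                 cut = sqrt(unname(low_ref) * unname(high)))
}

# package-local cache environment
the <- new.env(parent = emptyenv())

#' Classify a settled state onto the eight coarse phenotypes
#'
#' Flags each of `T`, `R`, `M` low (0) or high (+) against the
#' [coarse_reference()] cuts and maps the triple to its phenotype index
#' 1-8: state 1 is healthy (all low); 7 is the classic sarcoid state
#' (Teff and macrophages high, Tregs low); 6 and 8 combine a sarcoid
#' lesion with high Tregs, the in-model correlate of the peripheral
#' anergy/lymphopenia seen in active disease; the four remaining
#' combinations are not reachable in this network.
#'
#' @param state Named state vector (at least `T`, `R`, `M`), a one-row
#'   data frame, or a `sarco_trajectory` (its settled final state is
#'   used; a non-settled trajectory is an error).
#' @param reference Optional precomputed [coarse_reference()] tibble.
#' @return A one-row tibble: `T_high`, `R_high`, `M_high`, `state`
#'   (1-8), `label`.
#' @export
#' @examples
#' \donttest{
#' classify_state(c(T = 0.05, R = 0.05, M = 0.05))
#' }
classify_state <- function(state, reference = NULL) {
  if (inherits(state, "sarco_trajectory")) {
    st <- final_steady_state(state)
    if (is.null(st)) {
      stop("trajectory has not settled; cannot classify a transient",
           call. = FALSE)
    }
    state <- st
  }
  if (is.data.frame(state)) state <- unlist(state[1, ])
  need <- c("T", "R", "M")
  if (!all(need %in% names(state))) {
    stop("state must contain components T, R and M", call. = FALSE)
  }
  if (is.null(reference)) reference <- coarse_reference()
  cuts <- stats::setNames(reference$cut, reference$population)
  flags <- c(T_high = unname(state["T"] > cuts["T"]),
             R_high = unname(state["R"] > cuts["R"]),
             M_high = unname(state["M"] > cuts["M"]))
  tab <- coarse_state_table()
  row <- tab[tab$T_high == flags["T_high"] & tab$R_high == flags["R_high"] &
               tab$M_high == flags["M_high"], ]
  tibble::tibble(T_high = flags[["T_high"]], R_high = flags[["R_high"]],
                 M_high = flags[["M_high"]], state = row$state,
                 label = row$label)
}

#' Coarse states reached by a set of scenarios
#'
#' Runs each scenario to its settled end state and classifies it. In this
#' network only phenotypes 1, 6, 7 and 8 are dynamically reachable; the
#' "unlikely" states 2-5 never appear.
#'
#' @param fixtures Named list of [scenario()] objects (for example a
#'   subset of [paper_fixtures()]).
#' @param reference Optional precomputed [coarse_reference()].
#' @return A tibble with one row per fixture: `fixture`, `state`,
#'   `label`, plus the three flags. Scenarios that fail to settle are
#'   reported with `state = NA`.
#' @export
reachable_states <- function(fixtures, reference = NULL) {
  if (!length(fixtures)) {
    return(tibble::tibble(fixture = character(), T_high = logical(),
                          R_high = logical(), M_high = logical(),
                          state = integer(), label = character()))
  }
  if (is.null(reference)) reference <- coarse_reference()
  fixtures <- Filter(function(s) s$model == "detailed", fixtures)
  purrr::map_dfr(names(fixtures), function(nm) {
    traj <- simulate_scenario(fixtures[[nm]], dt = 2)
    st <- suppressWarnings(final_steady_state(traj))
    if (is.null(st)) {
      return(tibble::tibble(fixture = nm, T_high = NA, R_high = NA,
                            M_high = NA, state = NA_integer_,
                            label = "indeterminate"))
    }
    cls <- classify_state(st, reference)
    dplyr::bind_cols(tibble::tibble(fixture = nm), cls)
  })
}

# ---------------------------------------------------------------------------
# Threshold finding

#' Find the switching threshold of a scenario knob
#'
#' Scans a scalar knob of a template scenario — a pulse amplitude, a pulse
#' end time, or a named model parameter — over `[lo, hi]` on a fixed grid
#' and returns the smallest knob value at which `predicate` (a function of
#' the settled final state's [classify_state()] row) becomes `TRUE`. The
#' published figures report thresholds on coarse grids (0.5 for antigen
#' amplitude, 1 for pulse end times and inhibitor doses, 0.1 for the
#' anti-TNF-alpha dose), so a grid scan keeps results comparable to the
#' captions; pass a smaller `step` to refine.
#'
#' @param scn Template [scenario()].
#' @param knob A list describing what to vary:
#'   `list(type = "pulse_amplitude", pulse = i)`,
#'   `list(type = "pulse_end", pulse = i)`, or
#'   `list(type = "param", name = "k_2a")`.
#' @param lo,hi Bracket; `predicate` must differ between the two ends.
#' @param predicate Function of a one-row classification tibble returning
#'   `TRUE`/`FALSE` (for example `function(s) s$T_high`).
#' @param step Grid step.
#' @param reference Optional precomputed [coarse_reference()].
#' @return A one-row tibble: `threshold` (smallest value with
#'   `predicate == TRUE`), `below` (largest grid value failing it), and
#'   the predicate values at the bracket ends.
#' @export
find_threshold <- function(scn, knob, lo, hi, predicate, step = 1,
                           reference = NULL) {
  stopifnot(inherits(scn, "sarco_scenario"))
  if (lo >= hi) stop("degenerate bracket: lo must be < hi", call. = FALSE)
  if (is.null(reference)) {
    reference <- if (scn$model == "detailed") coarse_reference(scn$params)
    else minimal_reference(scn$params)
  }
  apply_knob <- function(value) {
    switch(knob$type,
      pulse_amplitude = set_pulse(scn, knob$pulse, amplitude = value),
      pulse_end = set_pulse(scn, knob$pulse, t_off = value),
      param = do.call(set_params,
                      c(list(scn), stats::setNames(list(value), knob$name))),
      stop("unknown knob type: ", knob$type, call. = FALSE))
  }
  eval_at <- function(value) {
    traj <- simulate_scenario(apply_knob(value), dt = 2)
    st <- suppressWarnings(final_steady_state(traj))
    if (is.null(st)) {
      stop("scenario did not settle at knob value ", value, call. = FALSE)
    }
    cls <- if (scn$model == "detailed") classify_state(st, reference) else
      classify_minimal(st, reference)
    isTRUE(predicate(cls))
  }
  p_lo <- eval_at(lo); p_hi <- eval_at(hi)
  if (p_lo == p_hi) {
    stop("bracket error: predicate is ", p_lo, " at both lo and hi",
         call. = FALSE)
  }
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  # binary search on the grid (outcome is monotone along the published
  # scan axes; a full scan would find the same first TRUE)
  lo_i <- 1L; hi_i <- length(grid)
  while (hi_i - lo_i > 1L) {
    mid <- (lo_i + hi_i) %/% 2L
    if (eval_at(grid[mid]) == p_hi) hi_i <- mid else lo_i <- mid
  }
  if (p_hi) {
    tibble::tibble(threshold = grid[hi_i], below = grid[lo_i],
                   predicate_lo = p_lo, predicate_hi = p_hi)
  } else {
    # predicate TRUE at lo: smallest value where it is TRUE is lo itself;
    # report the transition pair anyway
    tibble::tibble(threshold = grid[lo_i], below = grid[hi_i],
                   predicate_lo = p_lo, predicate_hi = p_hi)
  }
}

# Minimal-model analogue of the coarse reference: low branch vs high
# branch of the baseline drive.
minimal_reference <- function(params) {
  ss <- steady_states_minimal(minimal_drive(0, params), params)
  lo <- min(ss$T_s)
  hi <- if (nrow(ss) >= 2) max(ss$T_s) else lo * 100
  tibble::tibble(population = "T", low_ref = lo, high_ref = hi,
                 cut = sqrt(lo * hi))
}

classify_minimal <- function(state, reference) {
  hi <- unname(state["T"] > reference$cut[1])
  tibble::tibble(T_high = hi, R_high = NA, M_high = NA,
                 state = if (hi) 5L else 1L,
                 label = if (hi) "high Th1 activity" else "low Th1 activity")
}
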
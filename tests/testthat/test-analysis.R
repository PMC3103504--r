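test_that("zero drive gives the single basal root", {
  p <- minimal_params()
  ss <- steady_states_minimal(0, p)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$T_s, p$beta_T / p$eps_T, tolerance = 1e-10)
  expect_equal(ss$branch, "low")
})

test_that("analytic roots agree with the dense-grid oracle over random draws", {
  set.seed(7)
  p0 <- minimal_params()
  for (i in 1:100) {
    f <- stats::runif(1, 0, 15)
    theta <- stats::runif(1, 0.3, 2)
    p <- minimal_params(theta_T = theta, beta_T = stats::runif(1, 0.01, 0.2))
    got <- steady_states_minimal(f, p)$T_s
    want <- oracle_roots(f, p)
    expect_equal(length(got), length(want))
    expect_equal(got, want, tolerance = 1e-6)
    # every reported root satisfies the steady-state equation
    resid <- abs(vapply(got, function(T) minimal_rhs(
      T, 0, minimal_params(theta_T = p$theta_T, beta_T = p$beta_T,
                           eps_T = p$eps_T, c = f, eta1 = 0, eta2 = 1)),
      0))
    expect_true(all(resid < 1e-10))
  }
})

test_that("bistable range matches a root-count scan and moves with theta_T", {
  p1 <- minimal_params(beta_T = 0.05, theta_T = 1)
  p05 <- minimal_params(beta_T = 0.05, theta_T = 0.5)
  r1 <- bistable_range(p1)
  r05 <- bistable_range(p05)
  expect_true(r1$bistable && r05$bistable)
  # a stronger threshold (more Treg-like suppression) pushes the
  # switch-on drive higher
  expect_gt(r1$f_hi, r05$f_hi)

  # endpoints agree with a brute-force scan of the root count
  grid <- seq(r1$f_lo - 0.05, r1$f_hi + 0.05, by = 1e-3)
  counts <- vapply(grid, function(f) length(oracle_roots(f, p1, n = 20001)),
                   0L)
  inside <- grid[counts == 3]
  expect_lt(abs(min(inside) - r1$f_lo), 2e-3)
  expect_lt(abs(max(inside) - r1$f_hi), 2e-3)

  # overwhelming clearance: no bistability, empty-range marker
  rdeg <- bistable_range(minimal_params(eps_T = 500))
  expect_false(rdeg$bistable)
  expect_true(is.na(rdeg$f_lo))
})

test_that("the quasi-static sweep shows hysteresis", {
  p <- minimal_params(beta_T = 0.05)
  rng <- bistable_range(p)
  sw <- sweep_hysteresis(p, f_seq = seq(1, 8, by = 0.02))
  up <- sw[sw$direction == "up", ]
  down <- sw[sw$direction == "down", ]
  mid_f <- (rng$f_lo + rng$f_hi) / 2
  up_mid <- up$T_s[which.min(abs(up$f_T - mid_f))]
  down_mid <- down$T_s[which.min(abs(down$f_T - mid_f))]
  # path dependence: low branch on the way up, high branch coming down
  expect_lt(up_mid, 0.5)
  expect_gt(down_mid, 1)
  # the jump up happens only past the fold
  jump_f <- up$f_T[which(diff(up$T_s) > 0.5)[1] + 1]
  expect_gt(jump_f, rng$f_hi - 0.05)
  # the high state is retained down to the lower fold
  drop_f <- down$f_T[which(-diff(down$T_s) > 0.5)[1] + 1]
  expect_lt(drop_f, rng$f_lo + 0.05)
})

test_that("classification maps flag triples onto the published state table", {
  ref <- coarse_reference()
  lo <- c(T = 0.05, R = 0.05, M = 0.05)
  expect_equal(classify_state(lo, ref)$state, 1L)
  s7 <- c(T = 12, R = 0.06, M = 2)
  c7 <- classify_state(s7, ref)
  expect_equal(c7$state, 7L)
  expect_equal(c7$label, "sarcoid")
  s8 <- c(T = 12, R = 1.9, M = 2)
  expect_equal(classify_state(s8, ref)$state, 8L)
  s6 <- c(T = 12, R = 1.9, M = 0.06)
  expect_equal(classify_state(s6, ref)$label, "sarcoid, lymphopenia")

  # rescaling both references and the state by a common factor changes
  # nothing
  ref2 <- ref
  ref2$low_ref <- ref$low_ref * 10
  ref2$high_ref <- ref$high_ref * 10
  ref2$cut <- sqrt(ref2$low_ref * ref2$high_ref)
  expect_equal(classify_state(s7 * 10, ref2)$state, 7L)
})

test_that("classify_state refuses unsettled trajectories", {
  scn <- scenario("detailed", detailed_params(k_2a = 2.1),
                  pulses = list(square_pulse("A", 100, 5, 30)),
                  horizon = 51)
  traj <- simulate_scenario(scn, dt = 0.5)
  expect_error(suppressWarnings(classify_state(traj)), "not settled")
})

test_that("threshold finder demands an informative bracket and is stable to widening", {
  scn <- scenario("minimal", minimal_params(), initial_state = 0.34,
                  pulses = list(square_pulse("A", 1, 5, 10)),
                  horizon = 150, settle = FALSE)
  knob <- list(type = "pulse_amplitude", pulse = 1)
  pred <- function(s) s$T_high
  expect_error(find_threshold(scn, knob, 5, 5, pred), "degenerate")
  expect_error(find_threshold(scn, knob, 6, 8, pred, step = 0.5),
               "bracket error")
  narrow <- find_threshold(scn, knob, 3, 5, pred, step = 0.5)
  wide <- find_threshold(scn, knob, 0.5, 8, pred, step = 0.5)
  expect_equal(narrow$threshold, wide$threshold)
  expect_equal(narrow$threshold - narrow$below, 0.5)
})

test_that("reachable states of fixture subsets and the empty set", {
  expect_equal(nrow(reachable_states(list())), 0)
  got <- reachable_states(paper_fixtures(c("fig3_CD", "fig6_B")))
  expect_equal(got$state[got$fixture == "fig3_CD"], 8L)
  expect_equal(got$state[got$fixture == "fig6_B"], 1L)
})
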
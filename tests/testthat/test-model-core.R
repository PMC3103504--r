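test_that("minimal drive combines antigen and cytokine linearly", {
  p <- minimal_params() # eta1 = eta2 = 1, c = 3
  expect_equal(minimal_drive(4, p), 7)
  p0 <- minimal_params(c = 0)
  expect_equal(minimal_drive(0, p0), 0)
  pz <- minimal_params(eta1 = 0, eta2 = 0)
  expect_equal(minimal_drive(123, pz), 0)
  expect_error(minimal_drive(-1, p), ">= 0")
})

test_that("Hill activation vanishes without drive or seed and saturates at f", {
  expect_equal(hill_activation(5, f = 0, theta = 1), 0)
  expect_equal(hill_activation(0, f = 9, theta = 1), 0)
  expect_equal(hill_activation(1e9, f = 3, theta = 1), 3, tolerance = 1e-6)
  x <- seq(0, 10, by = 0.1)
  expect_true(all(diff(hill_activation(x, 2, 1)) >= 0))
  expect_error(hill_activation(1, 1, theta = 0), "theta")
})

test_that("minimal RHS has the basal fixed point and pure influx at T = 0", {
  p <- minimal_params(c = 0) # zero drive
  expect_equal(minimal_rhs(p$beta_T / p$eps_T, 0, p), 0)
  p2 <- minimal_params()
  expect_equal(minimal_rhs(0, 50, p2), p2$beta_T)
})

test_that("minimal RHS changes sign across the three bistable roots", {
  p <- minimal_params()
  roots <- oracle_roots(minimal_drive(0, p), p) # baseline drive 3
  expect_length(roots, 3)
  probes <- c(roots[1] / 2, mean(roots[1:2]), mean(roots[2:3]),
              roots[3] * 1.5)
  signs <- sign(vapply(probes, minimal_rhs, 0, A = 0, params = p))
  expect_equal(signs, c(1, -1, 1, -1))
})

test_that("detailed drives vanish at the zero state and obey monotonicity", {
  p <- detailed_params()
  zero <- c(T = 0, R = 0, M = 0, delta = 0, gamma = 0, alpha = 0)
  d0 <- detailed_drives(zero, 0, p)
  expect_equal(unlist(d0), c(f_T = 0, f_R = 0, f_M = 0))

  s <- c(T = 1, R = 0.5, M = 0.8, delta = 0.3, gamma = 0.4, alpha = 0.2)
  base <- detailed_drives(s, 2, p)
  # f_T rises with antigen, IL-2 and IFN-gamma ...
  expect_gt(detailed_drives(s, 4, p)$f_T, base$f_T)
  up <- function(nm, by = 2) { s2 <- s; s2[nm] <- s2[nm] * by; s2 }
  expect_gt(detailed_drives(up("delta"), 2, p)$f_T, base$f_T)
  expect_gt(detailed_drives(up("gamma"), 2, p)$f_T, base$f_T)
  # ... and falls when Tregs or TNF-alpha double
  expect_lt(detailed_drives(up("R"), 2, p)$f_T, base$f_T)
  expect_lt(detailed_drives(up("alpha"), 2, p)$f_T, base$f_T)
  # Treg drive: nondecreasing in IL-2, suppressed by TNF-alpha
  expect_gt(detailed_drives(up("delta"), 2, p)$f_R, base$f_R)
  expect_lt(detailed_drives(up("alpha"), 2, p)$f_R, base$f_R)
  # TNF-alpha dominance clamps the Treg drive at zero
  s_hi_a <- s; s_hi_a["alpha"] <- 1000
  expect_equal(detailed_drives(s_hi_a, 2, p)$f_R, 0)
})

test_that("without inhibition terms the Teff drive is linear in its inputs", {
  p <- detailed_params(k_1d = 0, k_1e = 0)
  s1 <- c(T = 1, R = 2, M = 0.5, delta = 0.2, gamma = 0.3, alpha = 0.9)
  s2 <- s1; s2[c("delta", "gamma")] <- 2 * s1[c("delta", "gamma")]
  f1 <- detailed_drives(s1, 1, p)$f_T
  f2 <- detailed_drives(s2, 2, p)$f_T
  expect_equal(f2, 2 * f1) # doubling (A*M, delta, gamma) doubles f_T
  expect_equal(f1, p$k_1a * 1 * 0.5 + p$k_1b * 0.2 + p$k_1c * 0.3)
})

test_that("cytokine kinetics have the expected basal roots and quasi-steady states", {
  p <- detailed_params()
  # with T = 0 the IL-2 equation root is beta_delta / eps_delta = 0.001
  s <- c(T = 0, R = 0, M = 0, delta = 0.001, gamma = 0, alpha = 0)
  expect_equal(detailed_rhs(s, 0, NULL, p)[["delta"]], 0)
  # at the all-zero state each derivative equals its basal influx
  zero <- c(T = 0, R = 0, M = 0, delta = 0, gamma = 0, alpha = 0)
  d <- detailed_rhs(zero, 0, NULL, p)
  expect_equal(unname(d), c(p$beta_T, p$beta_R, p$beta_M, p$beta_delta,
                            p$beta_gamma, p$beta_alpha))
  # settled cytokines equal (beta + production) / eps at the settled cells
  st <- settle(p)
  expect_equal(st[["delta"]],
               (p$beta_delta + p$k_3 * st[["T"]]) / p$eps_delta,
               tolerance = 1e-5)
  expect_equal(st[["gamma"]],
               (p$beta_gamma + p$k_4a * st[["T"]] + p$k_4b * st[["M"]]) /
                 p$eps_gamma, tolerance = 1e-5)
})

test_that("inhibitor levels act as first-order removal on their channel", {
  p <- detailed_params()
  s <- c(T = 1, R = 1, M = 1, delta = 0.5, gamma = 0.5, alpha = 0.5)
  d0 <- detailed_rhs(s, 0, NULL, p)
  d1 <- detailed_rhs(s, 0, c(I_delta = 2), p)
  expect_equal(d1[["delta"]], d0[["delta"]] - 2 * 0.5)
  expect_equal(d1[["gamma"]], d0[["gamma"]])
  expect_error(detailed_rhs(s, 0, c(I_zeta = 1), p), "unknown inhibitor")
  expect_error(detailed_rhs(s, 0, c(I_delta = -1), p), ">= 0")
})

test_that("detailed T equation reduces to the minimal model when the rest is frozen", {
  p <- detailed_params()
  M <- 0.7; delta <- 0.4; gamma <- 0.6 # frozen context, R = alpha = 0
  pm <- minimal_params(theta_T = p$theta_T, beta_T = p$beta_T,
                       eps_T = p$eps_T,
                       c = p$k_1b * delta + p$k_1c * gamma,
                       eta1 = p$k_1a * M, eta2 = 1)
  for (T in c(0, 0.1, 1, 5)) {
    for (A in c(0, 2, 10)) {
      s <- c(T = T, R = 0, M = M, delta = delta, gamma = gamma, alpha = 0)
      expect_equal(detailed_rhs(s, A, NULL, p)[["T"]],
                   minimal_rhs(T, A, pm))
    }
  }
})

test_that("trajectories stay nonnegative from random nonnegative starts", {
  set.seed(42)
  p <- detailed_params(k_2a = 2.1)
  for (i in 1:5) {
    y0 <- stats::runif(6, 0, 5)
    names(y0) <- c("T", "R", "M", "delta", "gamma", "alpha")
    scn <- scenario("detailed", p, initial_state = y0,
                    pulses = list(square_pulse("A", stats::runif(1, 0, 100),
                                               5, 20)),
                    horizon = 120, settle = FALSE)
    traj <- simulate_scenario(scn, dt = 1)
    expect_true(all(as.matrix(traj[c("T","R","M","delta","gamma","alpha")]) >= 0))
  }
})
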
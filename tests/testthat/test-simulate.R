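test_that("with all drives off, settle reaches beta/eps componentwise", {
  p <- zero_drive_params()
  st <- settle(p)
  expect_equal(unclass(st)[names(basal_state(p))], basal_state(p),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("settle under base parameters is a fixed point on the healthy branch", {
  p <- detailed_params()
  st <- settle(p)
  cls <- classify_state(st)
  expect_equal(cls$state, 1L)
  # re-integrating from the settled state moves essentially nowhere
  scn <- scenario("detailed", p, initial_state = st, horizon = 100,
                  settle = FALSE)
  traj <- simulate_scenario(scn, dt = 1)
  drift <- abs(terminal_state(traj) - st)
  expect_true(all(drift < 1e-6))
})

test_that("a zero-amplitude pulse leaves the trajectory unchanged", {
  p <- detailed_params(k_2a = 2.1)
  base <- scenario("detailed", p, horizon = 150, settle = FALSE)
  with0 <- scenario("detailed", p,
                    pulses = list(square_pulse("A", 0, 20, 70)),
                    horizon = 150, settle = FALSE)
  t1 <- simulate_scenario(base, dt = 1)
  t2 <- simulate_scenario(with0, dt = 1)
  shared <- intersect(t1$time, t2$time)
  m1 <- as.matrix(t1[t1$time %in% shared, c("T", "R", "M")])
  m2 <- as.matrix(t2[t2$time %in% shared, c("T", "R", "M")])
  expect_equal(m1, m2, tolerance = 1e-7)
})

test_that("identical scenarios integrate to identical trajectories", {
  scn <- paper_fixtures("fig3_CD")[[1]]
  t1 <- simulate_scenario(scn, dt = 5)
  t2 <- simulate_scenario(scn, dt = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("disjoint pulses commute in the schedule description", {
  p <- detailed_params()
  p1 <- square_pulse("A", 50, 10, 20)
  p2 <- square_pulse("I_delta", 5, 40, 50)
  s12 <- scenario("detailed", p, pulses = list(p1, p2), horizon = 100,
                  settle = FALSE)
  s21 <- scenario("detailed", p, pulses = list(p2, p1), horizon = 100,
                  settle = FALSE)
  expect_identical(as.data.frame(simulate_scenario(s12, dt = 1)),
                   as.data.frame(simulate_scenario(s21, dt = 1)))
})

test_that("final_steady_state returns the constant for a settled run and refuses transients", {
  p <- detailed_params()
  st <- settle(p)
  scn <- scenario("detailed", p, initial_state = st, horizon = 100,
                  settle = FALSE)
  traj <- simulate_scenario(scn, dt = 1)
  got <- final_steady_state(traj)
  expect_equal(got, st, tolerance = 1e-6, ignore_attr = TRUE)

  # truncated mid-transient: cut the run right after a strong pulse
  scn2 <- scenario("detailed", detailed_params(k_2a = 2.1),
                   pulses = list(square_pulse("A", 100, 5, 30)),
                   horizon = 31, settle = TRUE)
  traj2 <- simulate_scenario(scn2, dt = 0.5)
  expect_warning(out <- final_steady_state(traj2, window = 0.9),
                 "not settled")
  expect_null(out)
  expect_error(final_steady_state(traj, window = 1e5), "span")
})

test_that("halving integrator tolerances does not change fixture outcomes", {
  ref <- coarse_reference()
  for (nm in c("fig3_AB", "fig5_B")) {
    scn <- paper_fixtures(nm)[[1]]
    a <- simulate_scenario(scn, dt = 2)
    b <- simulate_scenario(scn, dt = 2,
                           control = list(rtol = 5e-9, atol = 5e-11))
    ca <- classify_state(final_steady_state(a), ref)
    cb <- classify_state(final_steady_state(b), ref)
    expect_equal(ca$state, cb$state)
  }
})

test_that("trajectory files carry the standard 11-column table", {
  scn <- scenario("minimal", minimal_params(), initial_state = 0.34,
                  pulses = list(square_pulse("A", 4, 5, 10)),
                  horizon = 50, settle = FALSE)
  traj <- simulate_scenario(scn)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  tab <- utils::read.csv(f)
  expect_named(tab, c("time", "T", "R", "M", "delta", "gamma", "alpha",
                      "A", "I_delta", "I_gamma", "I_alpha"))
  expect_true(all(diff(tab$time) > 0))
})
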
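test_that("the verdict is a pure function of the two coarse states", {
  row <- function(T, R, M) tibble::tibble(T_high = T, R_high = R, M_high = M)
  s8 <- row(TRUE, TRUE, TRUE); s7 <- row(TRUE, FALSE, TRUE)
  s1 <- row(FALSE, FALSE, FALSE)
  expect_equal(therapy_verdict(s8, s8), "no_effect")
  expect_equal(therapy_verdict(s8, s1), "remission")
  expect_equal(therapy_verdict(s8, s7), "partial")
  expect_equal(therapy_verdict(s7, s8), "paradoxical")
})

test_that("zero-dose therapy has no effect and reproduces the untreated outcome", {
  ref <- coarse_reference()
  out <- run_monotherapy("I_delta", 0, reference = ref)
  expect_equal(out$verdict, "no_effect")
  expect_equal(out$pre_state, out$post_state)

  # the untreated sarcoid protocol itself
  untreated <- classify_state(
    final_steady_state(simulate_scenario(sarcoid_scenario(), dt = 2)), ref)
  expect_equal(out$post_state, untreated$state)
})

test_that("anti-IL2 above threshold silences Tregs but neither Teffs nor macrophages", {
  ref <- coarse_reference()
  out <- run_monotherapy("I_delta", 30, reference = ref)
  expect_equal(out$verdict, "partial")
  expect_false(out$R_high)
  expect_true(out$T_high)
  expect_true(out$M_high)
  expect_equal(out$post_state, 7L)
})

test_that("anti-IFN-gamma above threshold silences macrophages but neither Teffs nor Tregs", {
  ref <- coarse_reference()
  out <- run_monotherapy("I_gamma", 16, reference = ref)
  expect_equal(out$verdict, "partial")
  expect_false(out$M_high)
  expect_true(out$T_high)
  expect_true(out$R_high)
  expect_equal(out$post_state, 6L)
})

test_that("monotherapy response has a single transition along the dose axis", {
  ref <- coarse_reference()
  doses <- c(0, 2, 4, 8, 16, 30, 45)
  eff <- vapply(doses, function(d) {
    run_monotherapy("I_delta", d, reference = ref)$verdict != "no_effect"
  }, logical(1))
  # no effect ... effect, with one switch
  expect_equal(sum(diff(eff) != 0), 1L)
  expect_false(eff[1])
  expect_true(eff[length(eff)])
})

test_that("a non-sarcoid pre-state raises a protocol error", {
  benign <- scenario("detailed", detailed_params(), horizon = 300)
  expect_error(run_monotherapy("I_delta", 30, base_scn = benign),
               "protocol error")
})

test_that("anti-TNF-alpha scan flags outcome changes against the untreated run", {
  ref <- coarse_reference()
  scan <- anti_tnf_scan(c(0, 2, 30), reference = ref)
  expect_equal(scan$verdict[scan$I_alpha == 0], "no_effect")
  expect_equal(scan$verdict[scan$I_alpha == 2], "no_effect")
  expect_true(scan$changed[scan$I_alpha == 30])
  # the flip promotes the lymphopenic phenotype: Tregs newly high
  expect_true(scan$R_high[scan$I_alpha == 30])
  expect_equal(scan$verdict[scan$I_alpha == 30], "paradoxical")
})
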
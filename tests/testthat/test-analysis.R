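# Dose-response machinery is exercised here in its cheap single-exposure
# modes; the chronic-protocol results are covered by the acceptance suite.

test_that("dose-response curves behave at the boundaries", {
  p <- default_params()
  curve <- dose_response(p, ppm_grid = c(1e-6, 0.5, 2),
                         dpx_protocol = "single", dg_protocol = "single")
  # exogenous series vanish with the exposure, endogenous stay positive
  expect_lt(curve$exogDPX[1L], 1e-6)
  expect_lt(curve$exogDG[1L], 1e-9)
  expect_true(all(curve$endoDG > 0))
  expect_true(all(curve$endoDPX > 0))
  # exogenous series increase with dose
  expect_true(all(diff(curve$exogDPX) > 0))
  expect_true(all(diff(curve$exogDG) > 0))
  expect_error(dose_response(p, ppm_grid = c(2, 1)), "increasing")
  long <- tidy_dose_response(curve)
  expect_equal(nrow(long), 3L * 4L)
})

test_that("no crossover is reported when the curves never meet", {
  p <- default_params()
  curve <- dose_response(p, ppm_grid = c(0.01, 0.02),
                         dpx_protocol = "single", dg_protocol = "single")
  cx <- find_crossover(curve, "DPX")
  expect_false(cx$found)
  expect_true(is.na(cx$ppm))
  expect_match(cx$message, "no crossover")
})

test_that("crossover refinement brackets a sign change on the grid", {
  p <- default_params()
  curve <- dose_response(p, ppm_grid = c(2, 4, 8, 16),
                         dpx_protocol = "single", dg_protocol = "single")
  cx <- find_crossover(curve, "DG", rel_tol = 0.01)
  if (cx$found) {
    expect_gt(cx$ppm, 2)
    expect_lt(cx$ppm, 16)
    expect_lt(cx$bracket[2L] / cx$bracket[1L], 1.011)
  } else {
    expect_match(cx$message, "no crossover")
  }
})

test_that("steady-state DPX:DG ratio equals the closed form", {
  p <- default_params()
  ss <- endogenous_steady_state(p)
  closed <- (p$kDNA_DPX / p$krep_DPX) / (p$kDNA_DG / p$krep_DG)
  expect_equal(ss[["endoDPX"]] / ss[["endoDG"]], closed, tolerance = 1e-6)
  # doubling the DPX formation constant doubles the ratio
  p2 <- kinetic_parameters(kDNA_DPX = 2 * p$kDNA_DPX)
  ss2 <- endogenous_steady_state(p2)
  expect_equal(ss2[["endoDPX"]] / ss2[["endoDG"]], 2 * closed,
               tolerance = 1e-4)
})

test_that("ratio minima exclude zero-DG grid points with a warning", {
  p <- default_params()
  curve <- dose_response(p, ppm_grid = c(0.5, 1),
                         dpx_protocol = "single", dg_protocol = "single")
  r <- dpx_dg_ratio(curve)
  expect_gt(r$endo, 1)
  expect_gt(r$exog, 1)
  expect_equal(r$overall, min(r$endo, r$exog))
  broken <- curve
  broken$exogDG[1L] <- 0
  expect_warning(r2 <- dpx_dg_ratio(broken), "zero DG")
  expect_equal(r2$exog, broken$exogDPX[2L] / broken$exogDG[2L])
})

test_that("the 2 ppm time course shows a rising exogenous sawtooth", {
  p <- default_params()
  tr <- timecourse_2ppm(p, n_days = 28, post_days = 7, dt = 1)
  expect_equal(tr$exogDG[tr$time_h == 0], 0)
  # exogenous DG builds toward a plateau across the weeks
  expect_gt(tr$exogDG[tr$time_h == 679], tr$exogDG[tr$time_h == 175])
  # at 2 ppm exogenous DG stays below endogenous DG throughout
  expect_true(all(tr$exogDG < tr$endoDG))
  # endogenous DG stays near its fixed point
  ss <- endogenous_steady_state(p)
  expect_lt(max(abs(tr$endoDG / ss[["endoDG"]] - 1)), 0.15)
})

test_that("the base model predicts detectable adducts at 0.3 ppm", {
  p <- default_params()
  base <- leng_lod_check(p)
  expect_true(base$detectable)
  expect_gt(base$exogDG, 10 * base$lod)
  zero <- leng_lod_check(p, ppm = 0)
  expect_false(zero$detectable)
  expect_equal(zero$exogDG, 0)
  # the zero-order extracellular clearance variant suppresses the
  # prediction by more than an order of magnitude
  pz <- kinetic_parameters(ec_mode = "zero_order", ec_rate = 2.02e3)
  varz <- leng_lod_check(pz)
  expect_lt(varz$exogDG, base$exogDG / 10)
})
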
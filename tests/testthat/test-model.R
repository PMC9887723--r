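test_that("uptake converts site flux to a volumetric source term", {
  expect_equal(uptake_rate(site_flux("DG"), 0.1138, 1), 776.6 / 0.1138,
               tolerance = 1e-12)
  expect_equal(uptake_rate(site_flux("DPX"), 0.1138, 15.8),
               800.3 * 15.8 / 0.1138, tolerance = 1e-12)
  expect_equal(uptake_rate(site_flux("DPX"), 0.2, 0), 0)
  # linear in ppm
  expect_equal(uptake_rate("DG", 0.1138, c(1, 2, 4)),
               uptake_rate("DG", 0.1138, 1) * c(1, 2, 4))
  expect_error(uptake_rate("DG", 0, 1), "positive")
  expect_error(uptake_rate("DG", -0.1, 1), "positive")
})

test_that("only the endogenous source survives at an empty state", {
  p <- default_params()
  d <- derivatives(mucosal_state(), p, 0)
  expect_equal(unname(d["endoF"]), p$kp)
  expect_equal(unname(d[names(d) != "endoF"]), rep(0, 8))
  # with uptake, the exogenous source appears symmetrically
  d2 <- derivatives(mucosal_state(), p, 500)
  expect_equal(unname(d2["exogF"]), 500)
})

test_that("derivatives agree with an independent transcription of the model", {
  p <- default_params()
  set.seed(42)
  for (i in 1:25) {
    y <- mucosal_state(
      endoF = runif(1, 0, 500), exogF = runif(1, 0, 5000),
      GSH = runif(1, 0, 5000), endoF_GSH = runif(1, 0, 2000),
      exogF_GSH = runif(1, 0, 2000), endoDG = runif(1, 0, 1e-2),
      exogDG = runif(1, 0, 1e-2), endoDPX = runif(1, 0, 1),
      exogDPX = runif(1, 0, 1))
    uptake <- runif(1, 0, 1e5)
    expect_equal(derivatives(y, p, uptake), ref_rhs(y, p, uptake),
                 tolerance = 1e-12)
    # glutathione moiety is conserved by construction
    d <- derivatives(y, p, uptake)
    expect_equal(unname(d["GSH"] + d["endoF_GSH"] + d["exogF_GSH"]), 0,
                 tolerance = 1e-9 * abs(d[["GSH"]]) + 1e-12)
  }
})

test_that("negative state components are rejected by name", {
  p <- default_params()
  y <- mucosal_state(GSH = 4506)
  y["exogDG"] <- -1e-6
  expect_error(derivatives(y, p, 0), "exogDG")
})

test_that("endogenous fixed point matches the independent algebraic oracle", {
  p <- default_params()
  ss <- endogenous_steady_state(p)
  oracle <- grid_fixed_point(p)
  for (nm in names(oracle))
    expect_equal(unname(ss[nm]), unname(oracle[nm]), tolerance = 1e-5)
  # exogenous pools are empty, every rate vanishes
  expect_equal(unname(ss[c("exogF", "exogF_GSH", "exogDG", "exogDPX")]),
               rep(0, 4))
  expect_lt(max(abs(derivatives(ss, p, 0))), 1e-6 * p$kp)
  # burn-in lands on the same fixed point
  ss_b <- endogenous_steady_state(p, method = "burnin")
  expect_equal(ss_b, ss, tolerance = 1e-6)
})

test_that("the fixed point is insensitive to the starting adduct levels", {
  for (dpx0 in c(0, 0.01, 1.0)) {
    p <- kinetic_parameters(endoDPX_init = dpx0, endoDG_init = 1e-5)
    ss <- endogenous_steady_state(p, method = "burnin")
    ref <- endogenous_steady_state(default_params(), method = "burnin")
    expect_equal(ss, ref, tolerance = 1e-4)
  }
})

test_that("the free formaldehyde fixed point rises with production", {
  p1 <- default_params()
  p2 <- kinetic_parameters(kp = 2 * p1$kp)
  expect_gt(endogenous_steady_state(p2)[["endoF"]],
            endogenous_steady_state(p1)[["endoF"]])
})

test_that("parameter constructor validates inputs", {
  expect_error(kinetic_parameters(kp = -1), "strictly positive")
  expect_error(kinetic_parameters(thick = 0), "strictly positive")
  expect_error(kinetic_parameters(endoDG_init = -1e-4), "non-negative")
  expect_error(kinetic_parameters(kP = 1), "unknown parameter")
  expect_error(kinetic_parameters(ec_mode = "on"), "ec_mode")
  expect_error(kinetic_parameters(ec_mode = "saturable"), "ec_Vmax")
  p <- kinetic_parameters(kp = 4200)
  expect_equal(p$kp, 4200)
  expect_equal(p$k21, default_params()$k21)
})
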
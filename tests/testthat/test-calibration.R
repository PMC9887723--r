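# Calibration tests run on synthetic observations from the compact recovery
# protocol set (single exposures plus a 7-day daily design), which keeps each
# cost evaluation cheap while probing both the linear and enzyme-saturated
# dose range.

truth <- kinetic_parameters()
syn0 <- generate_synthetic_observations(truth, noise_cv = 0)

test_that("the cost vanishes at the generating parameters", {
  expect_lt(as.numeric(adduct_cost(truth, syn0)), 1e-8)
})

test_that("uniformly doubled observations cost one unit per observation", {
  half <- syn0
  half$value_pmol_mm3 <- half$value_pmol_mm3 / 2  # predictions = 2 * obs
  expect_equal(as.numeric(adduct_cost(truth, half)), nrow(half),
               tolerance = 1e-6)
  # and the log-residual variant gives n * log(2)^2
  expect_equal(as.numeric(adduct_cost(truth, half, residual = "log")),
               nrow(half) * log(2)^2, tolerance = 1e-6)
})

test_that("the cost is invariant to row order and drops unusable rows", {
  shuffled <- syn0[sample.int(nrow(syn0)), , drop = FALSE]
  attr(shuffled, "protocol_builders") <- attr(syn0, "protocol_builders")
  expect_equal(as.numeric(adduct_cost(truth, shuffled)),
               as.numeric(adduct_cost(truth, syn0)), tolerance = 1e-10)
  # a below-LOD row and a DPC row leave the cost untouched
  extra <- rbind(syn0,
                 data.frame(study = "syn_single_dg", ppm = 2, time_h = 7,
                            species = c("exogDG", "endoDPC"),
                            value_pmol_mm3 = c(NA, 1e-5),
                            below_lod = c(TRUE, FALSE)))
  attr(extra, "protocol_builders") <- attr(syn0, "protocol_builders")
  expect_equal(as.numeric(adduct_cost(truth, extra)),
               as.numeric(adduct_cost(truth, syn0)), tolerance = 1e-10)
})

test_that("unmappable studies are reported by name", {
  bad <- data.frame(study = "Nope2020", ppm = 1, time_h = 7,
                    species = "exogDG", value_pmol_mm3 = 1e-4,
                    below_lod = FALSE)
  expect_error(adduct_cost(truth, bad), "Nope2020")
})

test_that("synthetic generation is reproducible and noise-free at cv = 0", {
  a <- generate_synthetic_observations(truth, noise_cv = 0.2, seed = 11)
  b <- generate_synthetic_observations(truth, noise_cv = 0.2, seed = 11)
  expect_equal(a$value_pmol_mm3, b$value_pmol_mm3)
  c2 <- generate_synthetic_observations(truth, noise_cv = 0.2, seed = 12)
  expect_false(identical(a$value_pmol_mm3, c2$value_pmol_mm3))
  # zero noise reproduces the model predictions exactly
  pred <- predict_observations(truth, syn0)
  expect_equal(syn0$value_pmol_mm3, pred$predicted)
  expect_error(generate_synthetic_observations(truth, noise_cv = -0.1),
               "non-negative")
})

test_that("fit spec validation enforces bounds and known names", {
  expect_error(fit_spec("nope", lower = c(nope = 0), upper = c(nope = 1)),
               "unknown")
  expect_error(fit_spec("kp", lower = c(kp = 1), upper = c(kp = Inf)),
               "finite")
  expect_error(fit_spec("kp", lower = c(kp = 2), upper = c(kp = 1)),
               "lower bound")
  expect_error(fit_spec("kp", lower = c(kp = 20000), upper = c(kp = 30000)),
               "within the bounds")
})

test_that("an empty free set returns the starting parameters unchanged", {
  spec <- fit_spec(character())
  res <- fit_parameters(spec, syn0)
  expect_true(res$converged)
  expect_equal(res$cost, res$initial_cost)
  expect_equal(unlist(res$params[1:16]), unlist(truth[1:16]))
})

test_that("bounded fits descend, stay in bounds, and recover parameters", {
  start <- kinetic_parameters(kp = 1.4 * truth$kp, thick = 1.3 * truth$thick)
  spec <- fit_spec(c("kp", "thick"),
                   lower = c(kp = truth$kp / 4, thick = truth$thick / 4),
                   upper = c(kp = truth$kp * 4, thick = truth$thick * 4),
                   init = start, maxit = 400)
  res <- fit_parameters(spec, syn0)
  expect_lte(res$cost, res$initial_cost)
  expect_lt(res$cost, 1e-4)
  expect_true(res$params$kp > truth$kp / 4 && res$params$kp < truth$kp * 4)
  expect_equal(res$params$kp, truth$kp, tolerance = 0.02)
  expect_equal(res$params$thick, truth$thick, tolerance = 0.02)
})

test_that("two-stage thickness calibration recovers a shared thickness", {
  start <- kinetic_parameters(thick = 0.15)
  ts <- two_stage_fit(syn0, free = "thick",
                      lower = c(thick = 0.05), upper = c(thick = 0.25),
                      init = start)
  # stage 1: per-site fits agree because the data come from one thickness
  expect_equal(ts$stage1$DG$params$thick, truth$thick, tolerance = 0.01)
  expect_equal(ts$stage1$DPX$params$thick, truth$thick, tolerance = 0.01)
  expect_lt(abs(ts$stage1$DG$params$thick / ts$stage1$DPX$params$thick - 1),
            0.01)
  # stage 2: shared thickness within bounds, near the truth
  expect_gt(ts$stage2$params$thick, 0.05)
  expect_lt(ts$stage2$params$thick, 0.25)
  expect_equal(ts$stage2$params$thick, truth$thick, tolerance = 0.01)
  # the constrained joint optimum cannot beat the per-site optima
  expect_gte(ts$stage2$cost + 1e-9,
             ts$stage1$DG$cost + ts$stage1$DPX$cost)
})

test_that("the published thickness is bracketed on the packaged dataset", {
  obs <- calibration_observations()
  expect_equal(nrow(obs), 30L)
  cost_mid <- as.numeric(adduct_cost(kinetic_parameters(), obs))
  cost_lo <- as.numeric(adduct_cost(kinetic_parameters(thick = 0.05), obs))
  cost_hi <- as.numeric(adduct_cost(kinetic_parameters(thick = 0.25), obs))
  expect_lt(cost_mid, cost_lo)
  expect_lt(cost_mid, cost_hi)
})
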
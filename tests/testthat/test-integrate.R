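test_that("exogenous species stay identically zero without exposure", {
  p <- default_params()
  sched <- exposure_schedule(NULL, horizon = 48, label = "null")
  tr <- integrate_model(p, "DG", sched, output_times = seq(0, 48, by = 4))
  expect_equal(tr$exogF, rep(0, nrow(tr)))
  expect_equal(tr$exogF_GSH, rep(0, nrow(tr)))
  expect_equal(tr$exogDG, rep(0, nrow(tr)))
  expect_equal(tr$exogDPX, rep(0, nrow(tr)))
})

test_that("glutathione moiety is conserved and states stay non-negative", {
  p <- default_params()
  sched <- daily_schedule(15, n_exposure_days = 3, sample_days = 3L)
  tr <- integrate_model(p, "DG", sched,
                        output_times = seq(0, sched$horizon, by = 0.5))
  total <- tr$GSH + tr$endoF_GSH + tr$exogF_GSH
  expect_lt(max(abs(total / total[1L] - 1)), 1e-6)
  expect_true(all(as.matrix(tr[, -1L]) >= 0))
})

test_that("post-exposure DPX decay follows the first-order repair half-life", {
  p <- default_params()
  sched <- single_exposure(2, sample_at_h = 14)
  tr <- integrate_model(p, "DPX", sched, output_times = c(10, 12, 14))
  # free exogenous formaldehyde has long since washed out
  expect_lt(tr$exogF[1L], 1e-3)
  ratio <- tr$exogDPX[3L] / tr$exogDPX[2L]
  expect_equal(ratio, exp(-p$krep_DPX * 2), tolerance = 1e-4)
  # half-life ln 2 / krep_DPX = 1.777 h
  expect_equal(log(2) / p$krep_DPX, 1.7772, tolerance = 1e-3)
})

test_that("adaptive solution matches a brute-force fixed-step RK4 run", {
  p <- default_params()
  ss <- endogenous_steady_state(p)
  out_times <- c(3, 6, 7, 12, 24)
  sched <- single_exposure(2, sample_at_h = 24)
  tr <- integrate_model(p, "DG", sched, output_times = out_times,
                        initial = ss)
  oracle <- rk4_single_exposure(p, ss,
                                uptake_on = uptake_rate("DG", p$thick, 2),
                                t_off = 6, h = 1e-4, out_times = out_times)
  for (sp in c("endoF", "exogF", "GSH", "endoF_GSH", "exogF_GSH",
               "endoDG", "exogDG", "endoDPX", "exogDPX")) {
    expect_equal(tr[[sp]], unname(oracle[, sp]), tolerance = 1e-3,
                 label = sp)
  }
})

test_that("endogenous and exogenous kinetics differ only in their source", {
  p <- default_params()
  gsh0 <- p$GSH_init + p$endoF_GSH_init
  y0 <- mucosal_state(GSH = gsh0)
  times <- seq(0, 24, by = 2)
  # baseline: endogenous production only
  sched0 <- exposure_schedule(NULL, horizon = 24, label = "base")
  base <- integrate_model(p, "DG", sched0, output_times = times,
                          initial = y0)
  # swapped: negligible endogenous production, constant uptake equal to kp
  p_swap <- kinetic_parameters(kp = 1e-9, GSH_init = gsh0,
                               endoF_GSH_init = 0)
  ppm_eq <- p$kp * p$thick / site_flux("DG")$flux_per_ppm
  sched1 <- exposure_schedule(
    data.frame(start_h = 0, end_h = 24, ppm = ppm_eq),
    horizon = 24, label = "swap")
  swap <- integrate_model(p_swap, "DG", sched1, output_times = times,
                          initial = y0)
  expect_equal(swap$exogF, base$endoF, tolerance = 1e-6)
  expect_equal(swap$exogF_GSH, base$endoF_GSH, tolerance = 1e-6)
  expect_equal(swap$exogDG, base$endoDG, tolerance = 1e-6)
  expect_equal(swap$exogDPX, base$endoDPX, tolerance = 1e-6)
})

test_that("output times outside the schedule horizon are rejected", {
  p <- default_params()
  expect_error(integrate_model(p, "DG", single_exposure(2),
                               output_times = 10),
               "horizon")
  expect_error(integrate_model(p, "DG", single_exposure(2),
                               output_times = numeric()),
               "no output times")
})

test_that("trajectories carry provenance and tidy to long format", {
  p <- default_params()
  tr <- integrate_model(p, "DPX", single_exposure(2),
                        output_times = c(3, 7))
  expect_s3_class(tr, "mucosal_trajectory")
  expect_match(attr(tr, "param_hash"), "^[0-9a-f]+$")
  expect_equal(attr(tr, "site_label"), "DPX_high_tumor")
  long <- tidy_trajectory(tr)
  expect_equal(nrow(long), 2L * 9L)
  expect_setequal(unique(long$species),
                  c("endoF", "exogF", "GSH", "endoF_GSH", "exogF_GSH",
                    "endoDG", "exogDG", "endoDPX", "exogDPX"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  lines <- readLines(path)
  expect_match(lines[1L], "param_hash")
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#")
  expect_equal(nrow(back), 18L)
})
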
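test_that("reference subtraction handles identity and zero references", {
  a <- toy_trace()
  r <- toy_trace(flow_cell = "reference")
  expect_equal(subtract_reference(a, r)$response_RU, rep(0, 6))
  r0 <- r; r0$response_RU <- 0
  expect_equal(subtract_reference(a, r0)$response_RU, a$response_RU)
  r_bad <- r; r_bad$time_s <- r$time_s + 0.5
  expect_error(subtract_reference(a, r_bad),
               class = "sprbind_validation_error")
})

test_that("reference subtraction removes a shared bulk offset", {
  cs <- quick_cycle_set(noise_sd = 0.2, bulk_shift = 20, seed = 5)
  act <- dplyr::filter(cs, flow_cell == "active", concentration_M == 0)
  ref <- dplyr::filter(cs, flow_cell == "reference",
                       cycle_id %in% act$cycle_id)
  sub <- subtract_reference(act, ref)
  # blanks carry only the bulk term: after referencing only noise remains
  expect_lt(abs(mean(sub$response_RU)), 0.2)
  expect_lt(max(abs(sub$response_RU)), 5 * 0.2 * sqrt(2))
})

test_that("blank subtraction averages blanks and removes shared drift", {
  s <- toy_trace()
  expect_equal(subtract_blanks(s, dplyr::mutate(s, concentration_M = 0)
                               )$response_RU, rep(0, 6))
  # two blanks that are negatives of each other: mean is zero
  b1 <- dplyr::mutate(toy_trace(cycle_id = "b1"), concentration_M = 0)
  b2 <- dplyr::mutate(b1, cycle_id = "b2", response_RU = -response_RU)
  expect_equal(subtract_blanks(s, dplyr::bind_rows(b1, b2))$response_RU,
               s$response_RU)
  expect_error(subtract_blanks(s, b1[0, ]), class = "sprbind_config_error")
  # a drifting blank removes the same drift from the sample
  slope <- 0.05
  drifting <- dplyr::mutate(b1, response_RU = slope * time_s)
  sample <- dplyr::mutate(s, response_RU = response_RU + slope * time_s)
  fixed <- subtract_blanks(sample, drifting)
  expect_equal(fixed$response_RU, s$response_RU, tolerance = 1e-12)
})

test_that("subtraction is linear in its first argument", {
  r <- quick_cycle_set(noise_sd = 0.3, seed = 9) |>
    dplyr::filter(flow_cell == "reference", cycle_id == "quick_c01")
  a <- dplyr::mutate(r, flow_cell = "active")
  shift <- 7.5
  a_shift <- dplyr::mutate(a, response_RU = response_RU + shift)
  expect_equal(subtract_reference(a_shift, r)$response_RU,
               subtract_reference(a, r)$response_RU + shift,
               tolerance = 1e-12)
})

test_that("solvent correction recovers an exactly linear calibration", {
  truth <- c(3, -0.002, 0)
  cyc <- simulate_solvent_cycles(coefficients = truth, noise_sd = 0)
  curve <- fit_solvent_correction(cyc)
  expect_equal(curve$coefficients[1:2], truth[1:2], tolerance = 1e-9)
  expect_lt(abs(curve$coefficients[3]), 1e-10)
  expect_equal(curve$valid_range, range(seq(1200, 1900, length.out = 8)),
               tolerance = 1e-9)
})

test_that("solvent correction recovers a noisy quadratic within 3 SE", {
  truth <- c(2, -0.004, 1.5e-6)
  cyc <- simulate_solvent_cycles(coefficients = truth, noise_sd = 0.2,
                                 seed = 21)
  curve <- fit_solvent_correction(cyc)
  fit <- lm(correction_RU ~ poly(reference_RU, 2, raw = TRUE),
            data = curve$calibration_points)
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(curve$coefficients - truth) <= 3 * se))
})

test_that("fewer than eight calibration cycles is a configuration error", {
  cyc <- simulate_solvent_cycles(bulk_RU = seq(1200, 1900, length.out = 7))
  expect_error(fit_solvent_correction(cyc), class = "sprbind_config_error")
})

test_that("applying bracketing curves interpolates and flags extrapolation", {
  mk_curve <- function(intercept, at) {
    fit_solvent_correction(
      simulate_solvent_cycles(coefficients = c(intercept, 0, 0)),
      acquired_at_cycle = at)
  }
  zero <- mk_curve(0, 0)
  s <- quick_cycle_set(noise_sd = 0, bulk_shift = 1500)
  ref <- dplyr::filter(s, flow_cell == "reference")
  act <- subtract_reference(dplyr::filter(s, flow_cell == "active"), ref)
  # before == after with a zero-valued curve: unchanged
  same <- apply_solvent_correction(act, ref, zero, zero)
  expect_equal(same$response_RU, act$response_RU, tolerance = 1e-9)
  # midway between two constant curves c1 and c2: (c1 + c2) / 2 applied
  c1 <- mk_curve(4, 0)
  c2 <- mk_curve(10, 60)
  mid <- apply_solvent_correction(act, ref, c1, c2, cycle_index = 30)
  expect_equal(mid$response_RU, act$response_RU - 7, tolerance = 1e-9)
  # bulk outside the calibrated range is flagged
  s_out <- quick_cycle_set(noise_sd = 0, bulk_shift = 3000)
  ref_out <- dplyr::filter(s_out, flow_cell == "reference")
  act_out <- subtract_reference(
    dplyr::filter(s_out, flow_cell == "active"), ref_out)
  flagged <- apply_solvent_correction(act_out, ref_out, c1, c2)
  expect_true(attr(flagged, "solvent_extrapolated"))
})

test_that("double referencing noise-free data returns the ideal curve", {
  k_on <- 1e5; k_off <- 0.5; R_max <- 200
  cs <- quick_cycle_set(k_on = k_on, k_off = k_off, R_max = R_max,
                        noise_sd = 0, drift = 0.03, bulk_shift = 25)
  prep <- preprocess_cycles(cs)
  one <- dplyr::filter(prep, cycle_id == "quick_c04",
                       phase != "baseline")
  ideal <- sprbind:::langmuir_vec(
    one$time_s - min(one$time_s), one$concentration_M[1], k_on, k_off,
    R_max, diff(range(one$time_s[one$phase == "association"])))
  expect_lt(max(abs(one$response_RU - ideal)), 1e-9)
})

test_that("solvent correction repairs an injected DMSO mismatch", {
  k_on <- 1e5; k_off <- 0.5; R_max <- 200
  truth <- c(0, -0.004, 0)
  clean <- quick_cycle_set(k_on = k_on, k_off = k_off, R_max = R_max,
                           noise_sd = 0, bulk_shift = 1500)
  # mismatch: the active cell reads an extra DMSO-dependent offset that the
  # reference cell does not share
  mismatch <- sum(truth * 1500^(0:2))
  biased <- clean |>
    dplyr::mutate(response_RU = response_RU +
                    ifelse(flow_cell == "active" & phase == "association",
                           mismatch, 0))
  curve <- fit_solvent_correction(
    simulate_solvent_cycles(coefficients = truth))
  ref <- dplyr::filter(biased, flow_cell == "reference")
  act <- subtract_reference(dplyr::filter(biased, flow_cell == "active"),
                            ref)
  fixed <- apply_solvent_correction(act, ref, curve, curve)
  clean_ref <- subtract_reference(
    dplyr::filter(clean, flow_cell == "active"),
    dplyr::filter(clean, flow_cell == "reference"))
  req_fixed <- sprbind:::plateau_value(
    dplyr::filter(fixed, cycle_id == "quick_c07"))
  req_clean <- sprbind:::plateau_value(
    dplyr::filter(clean_ref, cycle_id == "quick_c07"))
  expect_lt(abs(req_fixed - req_clean) / abs(req_clean), 0.02)
})
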
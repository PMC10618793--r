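test_that("identical seed and spec give bit-identical output", {
  a <- simulate_cycle_set("x", 1e5, 0.5, 200, noise_sd = 0.5, seed = 101)
  b <- simulate_cycle_set("x", 1e5, 0.5, 200, noise_sd = 0.5, seed = 101)
  expect_identical(a, b)
  c <- simulate_cycle_set("x", 1e5, 0.5, 200, noise_sd = 0.5, seed = 102)
  expect_false(identical(a$response_RU, c$response_RU))
  # seeding does not disturb the session RNG
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_cycle_set("x", 1e5, 0.5, 200, seed = 7))
  expect_identical(runif(1), before)
})

test_that("noise-free traces equal the closed-form model exactly", {
  cs <- simulate_cycle_set("x", 1e5, 0.5, 200, noise_sd = 0,
                           t_baseline = 30, t_assoc = 180, t_diss = 420)
  act <- dplyr::filter(cs, flow_cell == "active", concentration_M > 0,
                       cycle_id == "x_c05")
  C <- act$concentration_M[1]
  expected <- ifelse(
    act$time_s < 30, 0,
    sprbind:::langmuir_vec(act$time_s - 30, C, 1e5, 0.5, 200, 180))
  expect_equal(act$response_RU, expected, tolerance = 1e-12)
  # reference traces carry no binding signal
  ref <- dplyr::filter(cs, flow_cell == "reference")
  expect_true(all(ref$response_RU == 0))
})

test_that("generated sets validate and carry blanks and both channels", {
  cs <- simulate_cycle_set("x", 1e5, 0.5, 200, noise_sd = 0.3, seed = 2)
  expect_silent(validate_sensorgrams(cs))
  expect_setequal(unique(cs$flow_cell), c("active", "reference"))
  blanks <- dplyr::filter(cs, concentration_M == 0,
                          flow_cell == "active")
  expect_length(unique(blanks$cycle_id), 2)
})

test_that("non-competitive generation is exactly additive, competitive sub-additive", {
  ncm <- probe_mechanism("noncompetitive_independent_sites")
  e <- simulate_competition_experiment(ncm, 1e-6, 1e-6, noise_sd = 0)
  expect_equal(e$RU_ab, e$RU_a + e$RU_b, tolerance = 1e-12)
  cm <- probe_mechanism("competitive_shared_site")
  for (ca in c(2e-7, 1e-6, 1e-5)) for (cb in c(5e-7, 5e-6)) {
    ec <- simulate_competition_experiment(cm, ca, cb, noise_sd = 0)
    expect_lt(ec$RU_ab, ec$RU_a + ec$RU_b)
  }
})

test_that("classifying noise-free experiments recovers the mechanism", {
  for (kind in c("competitive_shared_site",
                 "noncompetitive_independent_sites")) {
    e <- simulate_competition_experiment(probe_mechanism(kind), 1e-6, 1e-6,
                                         noise_sd = 0)
    want <- if (kind == "competitive_shared_site") "competitive"
            else "non_competitive"
    expect_identical(classify_competition(e)$label, want)
  }
})

test_that("ODE trajectories reduce to the single-analyte model at C_b = 0", {
  mech <- probe_mechanism("competitive_shared_site")
  traj <- simulate_competition_odes(mech, 1e-6, 0, t_end = 120)
  single <- association_response(traj$time_s, 1e-6, 1.099e5, 0.4947,
                                 1) # R_max 1 gives occupancy directly
  expect_lt(max(abs(traj$theta_a - single)), 1e-6)
  expect_true(all(traj$theta_b == 0))
  expect_error(
    simulate_competition_odes(
      probe_mechanism("noncompetitive_independent_sites"), 1e-6, 1e-6),
    class = "sprbind_usage_error")
})

test_that("panel generator labels binders and non-binders faithfully", {
  pan <- simulate_panel(n_compounds = 6, n_binders = 3, seed = 31,
                        noise_sd = 0.4)
  expect_equal(nrow(pan$truth), 6)
  expect_equal(sum(pan$truth$is_binder), 3)
  expect_setequal(unique(pan$sensorgrams$analyte_id),
                  pan$panel$compound_name)
  expect_true(all(pan$truth$K_D[pan$truth$is_binder] >= 1e-6 &
                    pan$truth$K_D[pan$truth$is_binder] <= 3.4e-4))
  # non-binder cycles are artifact-free noise around zero
  nb <- dplyr::filter(pan$sensorgrams,
                      analyte_id == pan$truth$compound_name[6],
                      flow_cell == "active")
  expect_lt(max(abs(nb$response_RU)), 5 * 0.4)
  expect_error(simulate_panel(n_compounds = 3, n_binders = 5),
               class = "sprbind_config_error")
})
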
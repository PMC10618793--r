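test_that("occupancy reduces to the single-ligand isotherm when C_b = 0", {
  fo <- fractional_occupancy(4.5e-6, 0, 4.5e-6, 7.795e-6)
  expect_equal(fo$fo_a, 0.5)
  expect_equal(fo$fo_b, 0)
  # saturation limit: excess A fills the surface and excludes B
  fo_sat <- fractional_occupancy(1, 1e-6, 4.5e-6, 7.795e-6)
  expect_gt(fo_sat$fo_a, 0.999)
  expect_lt(fo_sat$fo_b, 1e-3)
  expect_error(fractional_occupancy(1e-6, 1e-6, -1, 1e-6),
               class = "sprbind_domain_error")
})

test_that("occupancy equals the shared-site ODE steady state", {
  # the probe pair at 1 uM each (the validation experiment's design)
  mech <- probe_mechanism("competitive_shared_site")
  traj <- simulate_competition_odes(mech, 1e-6, 1e-6)
  fo <- fractional_occupancy(1e-6, 1e-6,
                             compute_kd(1.099e5, 0.4947),
                             compute_kd(2.882e4, 0.2246))
  expect_lt(abs(tail(traj$theta_a, 1) - fo$fo_a), 1e-9)
  expect_lt(abs(tail(traj$theta_b, 1) - fo$fo_b), 1e-9)
  # at the reported probe KDs the occupancies take their reference values
  fo_ref <- fractional_occupancy(1e-6, 1e-6, 4.500e-6, 7.795e-6)
  expect_equal(fo_ref$fo_a, 0.1646, tolerance = 5e-4)
  expect_equal(fo_ref$fo_b, 0.0950, tolerance = 5e-4)
  # and across a log-grid of rate parameters
  for (ka in c(1e4, 1e6)) for (kb in c(1e3, 1e5)) {
    for (koffa in c(0.01, 0.5)) for (koffb in c(0.05, 1)) {
      m <- competition_mechanism(
        "competitive_shared_site",
        c(k_on = ka, k_off = koffa, R_max = 100),
        c(k_on = kb, k_off = koffb, R_max = 100))
      tr <- simulate_competition_odes(m, 2e-6, 5e-6)
      f <- fractional_occupancy(2e-6, 5e-6, koffa / ka, koffb / kb)
      expect_lt(abs(tail(tr$theta_a, 1) - f$fo_a), 1e-9)
      expect_lt(abs(tail(tr$theta_b, 1) - f$fo_b), 1e-9)
      expect_true(all(tr$theta_a + tr$theta_b <= 1 + 1e-12))
    }
  }
})

test_that("occupancy is monotone and the fractions never exceed one", {
  Ca <- 10^seq(-8, -3, length.out = 12)
  Cb <- 10^seq(-8, -3, length.out = 12)
  for (cb in Cb) {
    fo <- fractional_occupancy(Ca, cb, 4.5e-6, 7.795e-6)
    expect_true(all(diff(fo$fo_a) > 0))     # nondecreasing in C_a
    expect_true(all(fo$fo_a + fo$fo_b <= 1))
  }
  for (ca in Ca) {
    fo <- fractional_occupancy(ca, Cb, 4.5e-6, 7.795e-6)
    expect_true(all(diff(fo$fo_a) < 0))     # nonincreasing in C_b
  }
})

test_that("competitive RU is the occupancy-weighted capacity sum", {
  expect_equal(theoretical_competitive_ru(0, 0, 100, 100), 0)
  expect_equal(theoretical_competitive_ru(1, 0, 123, 100), 123)
  fo <- fractional_occupancy(1e-6, 1e-6, compute_kd(1.099e5, 0.4947),
                             compute_kd(2.882e4, 0.2246))
  expect_equal(theoretical_competitive_ru(fo$fo_a, fo$fo_b, 100, 100),
               25.95, tolerance = 2e-3)
  expect_error(theoretical_competitive_ru(1.2, 0, 100, 100),
               class = "sprbind_domain_error")
})

test_that("non-competitive RU is exact addition of the measured pair", {
  expect_equal(theoretical_noncompetitive_ru(22.5, 34.9), 57.4)
  expect_equal(theoretical_noncompetitive_ru(6.9, 5.8), 12.7)
  expect_equal(theoretical_noncompetitive_ru(0.9, 6.4), 7.3)
  expect_error(theoretical_noncompetitive_ru(-1, 2),
               class = "sprbind_domain_error")
})

test_that("classifier reproduces the published P2X4 verdicts", {
  verdicts <- classify_competition(p2x4_competition())
  expect_identical(verdicts$label, verdicts$reported_label)
  expect_equal(verdicts$theoretical_noncompetitive, c(57.4, 12.7, 7.3))
})

test_that("classifier margin yields inconclusive on exact ties", {
  tie <- tibble::tibble(analyte_a = "A", analyte_b = "B",
                        RU_a = 10, RU_b = 10, RU_ab = 15,
                        theoretical_competitive = 10)
  # RU_ab exactly midway between 10 and 20
  expect_identical(classify_competition(tie)$label, "inconclusive")
  expect_identical(classify_competition(tie, margin = 0)$label,
                   "inconclusive")
  expect_error(classify_competition(tie, margin = 1),
               class = "sprbind_domain_error")
})

test_that("classifier computes the competitive prediction when not given", {
  m <- simulate_competition_experiment(
    probe_mechanism("competitive_shared_site"), 1e-6, 1e-6, noise_sd = 0)
  v <- classify_competition(m)
  fo <- fractional_occupancy(1e-6, 1e-6, m$KD_a_M, m$KD_b_M)
  expect_equal(v$theoretical_competitive,
               theoretical_competitive_ru(fo$fo_a, fo$fo_b, 100, 100))
  expect_identical(v$label, "competitive")
})
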
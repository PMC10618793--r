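# Independent oracle: numerical integration of dR/dt = kon*C*(Rmax - R)
# - koff*R with deSolve, against which the closed forms are checked.
ode_association <- function(t, C, k_on, k_off, R_max) {
  sol <- deSolve::ode(
    y = c(R = 0), times = c(0, t),
    func = function(t, y, p) list(k_on * C * (R_max - y) - k_off * y),
    parms = NULL, rtol = 1e-12, atol = 1e-12)
  unname(sol[nrow(sol), "R"])
}

test_that("association closed form matches ODE integration", {
  # reported P2X4 probe kinetics as a worked case
  expect_lt(abs(association_response(60, 1e-6, 1.099e5, 0.4947, 200) -
                ode_association(60, 1e-6, 1.099e5, 0.4947, 200)), 1e-6)
  # log-grid of parameters
  for (k_on in c(1e3, 1e5, 1e7)) {
    for (k_off in c(1e-3, 0.05, 0.5)) {
      for (C in c(1e-7, 1e-5)) {
        expect_lt(abs(association_response(120, C, k_on, k_off, 150) -
                      ode_association(120, C, k_on, k_off, 150)), 1e-6)
      }
    }
  }
})

test_that("association limits: zero concentration and half saturation", {
  expect_equal(association_response(c(0, 10, 1e4), 0, 1e5, 0.5, 200),
               c(0, 0, 0))
  K_D <- 0.5 / 1e5
  expect_equal(association_response(1e6, K_D, 1e5, 0.5, 200), 100,
               tolerance = 1e-9)
  # t -> Inf limit equals the steady-state isotherm identically
  C <- 3e-6
  expect_equal(association_response(1e7, C, 1e5, 0.5, 200),
               steady_state_response(C, K_D, 200), tolerance = 1e-12)
})

test_that("dissociation decay: initial value, half life, continuity", {
  expect_equal(dissociation_response(0, 57.3, 0.1), 57.3)
  expect_equal(dissociation_response(log(2) / 0.1, 57.3, 0.1), 57.3 / 2,
               tolerance = 1e-12)
  expect_error(dissociation_response(-1, 10, 0.1),
               class = "sprbind_domain_error")
  # piecewise trace is continuous at the association/dissociation boundary
  R_end <- association_response(180, 1e-6, 1e5, 0.5, 200)
  expect_equal(dissociation_response(0, R_end, 0.5), R_end)
  tr <- sprbind:::langmuir_vec(c(180, 180 + 1e-9), 1e-6, 1e5, 0.5, 200, 180)
  expect_lt(abs(diff(tr)), 1e-6)
})

test_that("steady state is monotone in C and bounded by R_max", {
  grid <- c(0.4, 1.2, 3.6, 10.8, 32.4, 97.2, 300) * 1e-6
  r <- steady_state_response(grid, K_D = 1e-5, R_max = 180)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 180))
  expect_equal(steady_state_response(1e-5, 1e-5, 180), 90)
  expect_equal(steady_state_response(0, 1e-5, 180), 0)
  expect_error(steady_state_response(1e-6, -1, 180),
               class = "sprbind_domain_error")
})

test_that("KD equals koff/kon for the published panel rows", {
  panel <- dplyr::filter(p2x4_panel(), !not_detectable)
  kd <- compute_kd(panel$k_on, panel$k_off)
  expect_equal(kd, panel$K_D, tolerance = 1e-3)
  expect_equal(compute_kd(1e5, 0), 0)
  expect_error(compute_kd(0, 0.1), class = "sprbind_domain_error")
})

test_that("theoretical Rmax scales as MW ratio times immobilization", {
  expect_equal(theoretical_rmax(300, 300, 17000), 17000)
  expect_equal(theoretical_rmax(300, 29000, 2 * 17000),
               2 * theoretical_rmax(300, 29000, 17000))
  # cannabinoid MWs and 16-18 kRU immobilization are consistent with a
  # 158-205 RU capacity span for one ligand MW near the ~29 kDa
  # ectodomain construct
  implied_mw <- c(286 * 16000 / 158, 330 * 18000 / 205)
  expect_true(any(implied_mw > 27000 & implied_mw < 31000))
  lo <- theoretical_rmax(286, 29000, 16000)
  hi <- theoretical_rmax(330, 29000, 18000)
  expect_lt(lo, 205); expect_gt(hi, 158)
})

test_that("free energy and inhibition constant convert consistently", {
  expect_equal(inhibition_constant_from_energy(0, 298.15), 1)
  ki <- inhibition_constant_from_energy(-7.14, 298.15)
  expect_lt(abs(ki - 5.84e-6) / 5.84e-6, 0.01)
  # round trip identity
  for (k in c(1e-9, 5.84e-6, 1e-3)) {
    expect_equal(
      inhibition_constant_from_energy(energy_from_inhibition_constant(k)),
      k, tolerance = 1e-12)
  }
  expect_error(inhibition_constant_from_energy(-7, temperature = 0),
               class = "sprbind_domain_error")
})
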
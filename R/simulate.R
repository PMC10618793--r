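# Synthetic Biacore-style data generator: 1:1 binding sensorgrams with
# noise, drift and bulk refractive-index artifacts, DMSO calibration cycle
# pairs, and competition experiments under known competitive and
# non-competitive mechanisms. The generator is the ground-truth side of
# every parameter-recovery and classifier-validation study in the package.

# Run code under a temporary RNG state seeded with `seed`; NULL leaves the
# global RNG alone. Identical (seed, arguments) give bit-identical output.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Default concentration ladder: 3-fold dilutions from 300 uM down to
# 0.4 uM, the broad-range design used when analyte affinity is unknown.
default_concentration_series <- function() {
  c(0.4, 1.2, 3.6, 10.8, 32.4, 97.2, 300) * 1e-6
}

#' Simulate a full concentration-series cycle set for one analyte
#'
#' Generates Biacore-style raw traces: for each concentration an active
#' trace (1:1 Langmuir binding + bulk shift during the injection + linear
#' drift + i.i.d. Gaussian noise) and a matched reference trace carrying
#' the same bulk and drift artifacts with independent noise, plus
#' zero-concentration blank cycle pairs. Time runs from cycle start
#' (baseline), the injection occupies `[t_baseline, t_baseline + t_assoc]`,
#' and dissociation follows for `t_diss` seconds.
#'
#' @param analyte_id Analyte name carried into every trace.
#' @param k_on,k_off True rate constants (1/(M s), 1/s).
#' @param R_max True surface capacity, RU. `0` produces a non-binding
#'   analyte (flat traces up to artifacts), used for screen negatives.
#' @param concentrations Molar concentration series (default 3-fold,
#'   0.4-300 uM).
#' @param t_baseline,t_assoc,t_diss Phase durations in seconds (defaults
#'   30, 180, 420).
#' @param noise_sd Gaussian noise sd per time point, RU (default 0.5).
#' @param drift Linear baseline drift, RU/s (default 0), common to both
#'   flow cells.
#' @param bulk_shift Bulk refractive-index jump during the injection, RU
#'   (default 0), common to both flow cells.
#' @param sample_rate Sampling rate, Hz (default 1).
#' @param n_blanks Number of zero-concentration blank cycles (default 2).
#' @param seed Integer seed; identical seed and arguments give bit-identical
#'   output. `NULL` draws from the session RNG.
#'
#' @return A raw sensorgram tibble (both flow cells, samples + blanks)
#'   suitable for [preprocess_cycles()].
#' @export
simulate_cycle_set <- function(analyte_id = "analyte",
                               k_on, k_off, R_max,
                               concentrations = default_concentration_series(),
                               t_baseline = 30, t_assoc = 180, t_diss = 420,
                               noise_sd = 0.5, drift = 0, bulk_shift = 0,
                               sample_rate = 1, n_blanks = 2, seed = NULL) {
  check_positive(k_on = k_on, k_off = k_off, sample_rate = sample_rate,
                 t_assoc = t_assoc, t_diss = t_diss)
  check_nonnegative(R_max = R_max, noise_sd = noise_sd,
                    t_baseline = t_baseline,
                    concentrations = concentrations)
  with_sim_seed(seed, {
    t <- seq(0, t_baseline + t_assoc + t_diss, by = 1 / sample_rate)
    phase <- dplyr::case_when(
      t < t_baseline ~ "baseline",
      t <= t_baseline + t_assoc ~ "association",
      TRUE ~ "dissociation")
    injection <- as.numeric(phase == "association")

    one_trace <- function(cycle_id, conc, flow_cell, with_binding) {
      binding <- if (with_binding && conc > 0 && R_max > 0) {
        langmuir_vec(pmax(t - t_baseline, 0), conc, k_on, k_off, R_max,
                     t_assoc) * as.numeric(t >= t_baseline)
      } else 0
      resp <- binding + bulk_shift * injection + drift * t +
        if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
      tibble(cycle_id = cycle_id, flow_cell = flow_cell,
             analyte_id = analyte_id, concentration_M = conc,
             phase = phase, time_s = t, response_RU = resp)
    }

    cycles <- purrr::imap(concentrations, function(conc, i) {
      id <- sprintf("%s_c%02d", analyte_id, i)
      dplyr::bind_rows(one_trace(id, conc, "active", TRUE),
                       one_trace(id, conc, "reference", FALSE))
    })
    blanks <- purrr::map(seq_len(n_blanks), function(i) {
      id <- sprintf("%s_b%02d", analyte_id, i)
      dplyr::bind_rows(one_trace(id, 0, "active", FALSE),
                       one_trace(id, 0, "reference", FALSE))
    })
    dplyr::bind_rows(cycles, blanks)
  })
}

#' Simulate DMSO solvent-correction calibration cycles
#'
#' Produces `length(bulk_RU)` calibration cycle pairs emulating the
#' DMSO-only injections of a correction set (the conventional design spans
#' 2.5-3.8 % DMSO, i.e. a range of bulk responses around the running
#' buffer). The reference trace plateaus at `bulk_RU`; the active trace
#' plateaus at `bulk_RU + correction(bulk_RU)` where the true correction is
#' the polynomial with the supplied `coefficients` (intercept first).
#'
#' @param bulk_RU Reference-cell bulk responses of the calibration points
#'   (default 8 points spanning 1200-1900 RU).
#' @param coefficients True correction polynomial coefficients, intercept
#'   first (default a mild quadratic).
#' @param noise_sd Gaussian noise sd, RU (default 0).
#' @param t_baseline,t_assoc,t_diss,sample_rate As in
#'   [simulate_cycle_set()].
#' @param seed Integer seed.
#' @param prefix Cycle-id prefix (default "dmso").
#' @return Raw sensorgram tibble of calibration cycle pairs (analyte
#'   "DMSO", concentration 0).
#' @export
simulate_solvent_cycles <- function(bulk_RU = seq(1200, 1900,
                                                  length.out = 8),
                                    coefficients = c(2, -0.004, 1e-6),
                                    noise_sd = 0, t_baseline = 10,
                                    t_assoc = 60, t_diss = 30,
                                    sample_rate = 1, seed = NULL,
                                    prefix = "dmso") {
  with_sim_seed(seed, {
    t <- seq(0, t_baseline + t_assoc + t_diss, by = 1 / sample_rate)
    phase <- dplyr::case_when(
      t < t_baseline ~ "baseline",
      t <= t_baseline + t_assoc ~ "association",
      TRUE ~ "dissociation")
    injection <- as.numeric(phase == "association")
    purrr::imap_dfr(bulk_RU, function(b, i) {
      corr <- sum(coefficients * b^(seq_along(coefficients) - 1))
      mk <- function(flow_cell, level) {
        tibble(cycle_id = sprintf("%s_%02d", prefix, i),
               flow_cell = flow_cell, analyte_id = "DMSO",
               concentration_M = 0, phase = phase, time_s = t,
               response_RU = level * injection +
                 if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0)
      }
      dplyr::bind_rows(mk("reference", b), mk("active", b + corr))
    })
  })
}

#' Define a two-analyte binding mechanism for simulation
#'
#' @param kind `"competitive_shared_site"` (both analytes bind one site)
#'   or `"noncompetitive_independent_sites"` (fully independent sites, the
#'   additive null made generative).
#' @param params_a,params_b Named numeric vectors with elements `k_on`,
#'   `k_off`, `R_max` for each analyte.
#' @return A `competition_mechanism` object.
#' @export
competition_mechanism <- function(kind = c("competitive_shared_site",
                                           "noncompetitive_independent_sites"),
                                  params_a, params_b) {
  kind <- match.arg(kind)
  for (p in list(params_a, params_b)) {
    if (!all(c("k_on", "k_off", "R_max") %in% names(p))) {
      abort("params need named elements k_on, k_off, R_max.",
            class = "sprbind_config_error")
    }
    check_positive(k_on = p[["k_on"]], k_off = p[["k_off"]],
                   R_max = p[["R_max"]])
  }
  structure(list(kind = kind, params_a = params_a, params_b = params_b),
            class = "competition_mechanism")
}

#' Integrate the two-analyte shared-site occupancy ODEs
#'
#' The kinetic scheme for two analytes competing for one site:
#' `d theta_a/dt = k_on_a * C_a * (1 - theta_a - theta_b) - k_off_a *
#' theta_a` and symmetrically for B, from empty surface. Integrated with an
#' adaptive stiff-capable solver at oracle-grade tolerances; the long-time
#' limit is the closed-form [fractional_occupancy()].
#'
#' @param mech A [competition_mechanism()] of kind
#'   `"competitive_shared_site"`.
#' @param C_a,C_b Analyte concentrations, molar.
#' @param t_end Integration end time, seconds; default long enough to relax
#'   to steady state (40 / slowest rate).
#' @param n_out Number of output time points (default 200).
#' @param rtol,atol Solver tolerances (defaults 1e-10, 1e-12).
#' @return A tibble with columns `time_s`, `theta_a`, `theta_b`.
#' @export
simulate_competition_odes <- function(mech, C_a, C_b, t_end = NULL,
                                      n_out = 200, rtol = 1e-10,
                                      atol = 1e-12) {
  if (!inherits(mech, "competition_mechanism") ||
      mech$kind != "competitive_shared_site") {
    abort("simulate_competition_odes() needs a competitive_shared_site mechanism.",
          class = "sprbind_usage_error")
  }
  check_nonnegative(C_a = C_a, C_b = C_b)
  pa <- mech$params_a; pb <- mech$params_b
  if (is.null(t_end)) {
    # the occupancy system is linear; relax past its slowest eigenmode
    A <- matrix(c(-(pa[["k_on"]] * C_a + pa[["k_off"]]),
                  -pb[["k_on"]] * C_b,
                  -pa[["k_on"]] * C_a,
                  -(pb[["k_on"]] * C_b + pb[["k_off"]])), 2, 2)
    lam_min <- min(abs(Re(eigen(A, only.values = TRUE)$values)))
    t_end <- 40 / lam_min
  }
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) {
    free <- 1 - y[1] - y[2]
    list(c(pa[["k_on"]] * C_a * free - pa[["k_off"]] * y[1],
           pb[["k_on"]] * C_b * free - pb[["k_off"]] * y[2]))
  }
  sol <- deSolve::ode(y = c(0, 0), times = times, func = deriv,
                      parms = NULL, rtol = rtol, atol = atol)
  tibble(time_s = sol[, 1], theta_a = sol[, 2], theta_b = sol[, 3])
}

#' Simulate one competition experiment under a known mechanism
#'
#' Emulates the single-analyte and combined injections of a competitive
#' SPR assay. `RU_a` and `RU_b` are single-analyte equilibrium responses
#' (Langmuir isotherm times `R_max`) plus noise. Under the competitive
#' mechanism `RU_ab` comes from the steady state of the shared-site ODE
#' system; under the non-competitive mechanism it is the sum of the two
#' independent single-site occupancies. KD and Rmax columns are filled from
#' the generating truth.
#'
#' @param mech A [competition_mechanism()].
#' @param C_a,C_b Mixture concentrations, molar (per-component).
#' @param noise_sd Gaussian noise sd added to each measured RU (default
#'   0.5).
#' @param seed Integer seed for reproducibility.
#' @param analyte_a,analyte_b Analyte names (defaults "A", "B").
#' @return A one-row tibble in the competition-measurement schema plus a
#'   `true_mechanism` column.
#' @export
simulate_competition_experiment <- function(mech, C_a, C_b, noise_sd = 0.5,
                                            seed = NULL, analyte_a = "A",
                                            analyte_b = "B") {
  if (!inherits(mech, "competition_mechanism")) {
    abort("`mech` must be a competition_mechanism.",
          class = "sprbind_usage_error")
  }
  check_positive(C_a = C_a, C_b = C_b)
  pa <- mech$params_a; pb <- mech$params_b
  KD_a <- pa[["k_off"]] / pa[["k_on"]]
  KD_b <- pb[["k_off"]] / pb[["k_on"]]
  theta_a1 <- C_a / (C_a + KD_a)  # single-analyte occupancies
  theta_b1 <- C_b / (C_b + KD_b)
  if (mech$kind == "competitive_shared_site") {
    traj <- simulate_competition_odes(mech, C_a, C_b)
    th <- tail(traj, 1)
    ru_ab_true <- th$theta_a * pa[["R_max"]] + th$theta_b * pb[["R_max"]]
  } else {
    ru_ab_true <- theta_a1 * pa[["R_max"]] + theta_b1 * pb[["R_max"]]
  }
  with_sim_seed(seed, {
    eps <- if (noise_sd > 0) rnorm(3, 0, noise_sd) else c(0, 0, 0)
    tibble(
      analyte_a = analyte_a, analyte_b = analyte_b,
      C_a_M = C_a, C_b_M = C_b, KD_a_M = KD_a, KD_b_M = KD_b,
      Rmax_a_RU = pa[["R_max"]], Rmax_b_RU = pb[["R_max"]],
      RU_a = theta_a1 * pa[["R_max"]] + eps[1],
      RU_b = theta_b1 * pb[["R_max"]] + eps[2],
      RU_ab = ru_ab_true + eps[3],
      true_mechanism = mech$kind)
  })
}

#' Simulate a screening panel with known binder status
#'
#' Emulates a compound screen: `n_binders` compounds get true 1:1 kinetics
#' with log-uniform KD in `kd_range` (and log-uniform `k_off`), the rest
#' are non-binders producing artifact-plus-noise traces only. Returns the
#' raw sensorgrams, panel metadata and a truth table for end-to-end
#' recovery studies.
#'
#' @param n_compounds Panel size (default 28).
#' @param n_binders Number of true binders (default 13).
#' @param kd_range True-KD envelope in molar (default `c(1e-6, 3.4e-4)`).
#' @param koff_range True `k_off` envelope in 1/s (default
#'   `c(0.05, 0.5)`).
#' @param R_max True surface capacity for binders, RU (default 100).
#' @param noise_sd,drift,bulk_shift,concentrations,sample_rate Passed to
#'   [simulate_cycle_set()].
#' @param seed Integer seed.
#' @return A list with elements `sensorgrams` (raw tibble for all
#'   compounds), `panel` (metadata tibble) and `truth` (per-compound true
#'   parameters and binder status).
#' @export
simulate_panel <- function(n_compounds = 28, n_binders = 13,
                           kd_range = c(1e-6, 3.4e-4),
                           koff_range = c(0.05, 0.5), R_max = 100,
                           noise_sd = 0.5, drift = 0, bulk_shift = 0,
                           concentrations = default_concentration_series(),
                           sample_rate = 1, seed = NULL) {
  if (n_binders > n_compounds) {
    abort("n_binders must not exceed n_compounds.",
          class = "sprbind_config_error")
  }
  with_sim_seed(seed, {
    compounds <- sprintf("cmpd%02d", seq_len(n_compounds))
    is_binder <- seq_len(n_compounds) <= n_binders
    KD <- exp(runif(n_compounds, log(kd_range[1]), log(kd_range[2])))
    k_off <- exp(runif(n_compounds, log(koff_range[1]), log(koff_range[2])))
    k_on <- k_off / KD
    mw <- runif(n_compounds, 286, 330)
    cycle_seeds <- sample.int(.Machine$integer.max, n_compounds)

    truth <- tibble(
      compound_name = compounds, is_binder = is_binder,
      k_on = ifelse(is_binder, k_on, NA_real_),
      k_off = ifelse(is_binder, k_off, NA_real_),
      K_D = ifelse(is_binder, KD, NA_real_),
      R_max = ifelse(is_binder, R_max, 0))
    panel <- tibble(compound_name = compounds,
                    molecular_weight_gmol = mw, role = "cannabinoid")
    sensorgrams <- purrr::map_dfr(seq_len(n_compounds), function(i) {
      simulate_cycle_set(
        analyte_id = compounds[i],
        k_on = if (is_binder[i]) k_on[i] else 1e3,
        k_off = if (is_binder[i]) k_off[i] else 0.1,
        R_max = if (is_binder[i]) R_max else 0,
        concentrations = concentrations, noise_sd = noise_sd,
        drift = drift, bulk_shift = bulk_shift, sample_rate = sample_rate,
        seed = cycle_seeds[i])
    })
    list(sensorgrams = sensorgrams, panel = panel, truth = truth)
  })
}
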
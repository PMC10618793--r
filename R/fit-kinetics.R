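# Global kinetic fitting of the 1:1 Langmuir model across a concentration
# series, steady-state affinity analysis and QC flagging.
#
# Optimization runs in log-parameter space (log kon, log koff, log Rmax),
# which keeps the rate constants positive and conditions the problem across
# their many orders of magnitude. Bounds: kon in [1e2, 1e9] 1/(M s),
# koff in [1e-5, 1] 1/s, Rmax bounded above by 10x the theoretical
# (or observed) capacity. The start point is deterministic, so fits are
# reproducible without a random seed: koff from a log-linear regression of
# the dissociation tail at the highest concentration, KD and Rmax from a
# steady-state prefit of plateau responses, kon = koff / KD.

default_fit_bounds <- function(rmax_upper) {
  list(lower = log(c(k_on = 1e2, k_off = 1e-5, R_max = 1e-6)),
       upper = log(c(k_on = 1e9, k_off = 1, R_max = rmax_upper)))
}

# Pooled noise sd from baseline-phase scatter (per-cycle mean removed);
# falls back to a high-frequency difference estimate on the association
# phase when no baseline samples exist.
estimate_noise_sd <- function(data) {
  base <- data[data$phase == "baseline", ]
  if (nrow(base) >= 8) {
    resid <- base |>
      dplyr::group_by(.data$cycle_id) |>
      dplyr::mutate(r = .data$response_RU - mean(.data$response_RU)) |>
      dplyr::pull(.data$r)
    return(max(sd(resid), 1e-12))
  }
  a <- data[data$phase == "association", ]
  if (nrow(a) < 4) return(1e-12)
  d <- a |>
    dplyr::group_by(.data$cycle_id) |>
    dplyr::summarise(s = sd(diff(.data$response_RU)) / sqrt(2),
                     .groups = "drop")
  max(median(d$s), 1e-12)
}

# Per-cycle geometry needed by the piecewise model.
cycle_geometry <- function(data) {
  data |>
    dplyr::filter(.data$phase != "baseline") |>
    dplyr::group_by(.data$cycle_id, .data$concentration_M) |>
    dplyr::summarise(
      t0 = min(.data$time_s[.data$phase == "association"]),
      t_assoc_end = max(.data$time_s[.data$phase == "association"]),
      .groups = "drop")
}

predict_cycles <- function(data, geom, k_on, k_off, R_max) {
  g <- geom[match(data$cycle_id, geom$cycle_id), ]
  langmuir_vec(data$time_s - g$t0, g$concentration_M, k_on, k_off, R_max,
               g$t_assoc_end - g$t0)
}

# Vectorised piecewise cycle model (t relative to association start;
# per-row concentration and association duration).
langmuir_vec <- function(t, C, k_on, k_off, R_max, t_assoc) {
  K_D <- k_off / k_on
  Req <- C * R_max / (C + K_D)
  r_assoc <- Req * (1 - exp(-(k_on * C + k_off) * pmin(t, t_assoc)))
  ifelse(t <= t_assoc, r_assoc, r_assoc * exp(-k_off * (t - t_assoc)))
}

#' Global 1:1 Langmuir kinetic fit of a preprocessed cycle set
#'
#' Fits shared `k_on`, `k_off` and `R_max` across every non-zero
#' concentration cycle of one analyte by bounded nonlinear least squares on
#' the piecewise association/dissociation model, minimising the summed
#' squared residuals over both phases. Parameters are optimised on the log
#' scale; standard errors come from the Jacobian at the optimum (delta
#' method back to the natural scale). A flat or sub-noise response set is
#' returned as a `not_detectable` result rather than an error.
#'
#' @param data Preprocessed (double-referenced) sensorgram tibble for one
#'   analyte; see [preprocess_cycles()].
#' @param rmax_theoretical Optional theoretical surface capacity in RU,
#'   used for the `R_max` upper bound and the `matrix_binding` QC flag.
#' @param noise_multiplier Detection threshold in units of baseline noise
#'   sd (default 3): below it the analyte is flagged `not_detectable`.
#' @param slow_dissociation_retention Retained fraction of a cycle's peak at
#'   the end of dissociation above which `slow_dissociation` is flagged
#'   (default 0.5).
#' @param max_iter Maximum optimizer iterations (default 200).
#'
#' @return An object of class `spr_kinetic_fit`. Use [tidy()] for the
#'   parameter table, [glance()] for a one-row summary, [augment()] for
#'   fitted values and residuals, and [autoplot()] for an overlay plot.
#' @export
fit_kinetics <- function(data, rmax_theoretical = NULL,
                         noise_multiplier = 3,
                         slow_dissociation_retention = 0.5,
                         max_iter = 200) {
  data <- as_tibble(data)
  analyte <- unique(data$analyte_id)
  if (length(analyte) != 1) {
    abort("fit_kinetics() expects cycles from a single analyte.",
          class = "sprbind_validation_error")
  }
  fitdat <- dplyr::filter(data, .data$concentration_M > 0,
                          .data$phase != "baseline")
  noise_sd <- estimate_noise_sd(data)
  concs <- sort(unique(fitdat$concentration_M))

  nd_result <- function(flags) {
    new_kinetic_fit(
      analyte_id = analyte,
      params = tibble(term = c("k_on", "k_off", "R_max"),
                      estimate = NA_real_, std.error = NA_real_),
      K_D = NA_real_, ssr = NA_real_, noise_sd = noise_sd,
      flags = union("not_detectable", flags),
      n_cycles_used = 0L, data = data, fitted = NULL, converged = FALSE)
  }
  if (length(concs) < 2) {
    return(nd_result(character()))
  }
  # detection on plateau reads (median of late association), which are
  # robust to single-point noise excursions
  plateaus <- fitdat |>
    dplyr::group_by(.data$cycle_id) |>
    dplyr::group_map(~ plateau_value(
      dplyr::mutate(.x, cycle_id = .y$cycle_id)))
  if (max(abs(unlist(plateaus))) < noise_multiplier * noise_sd) {
    return(nd_result(character()))
  }

  geom <- cycle_geometry(fitdat)
  obs <- fitdat$response_RU
  max_obs <- max(abs(obs))
  rmax_upper <- 10 * (rmax_theoretical %||% max_obs)
  bounds <- default_fit_bounds(rmax_upper)

  start <- kinetics_start(fitdat, geom, max_obs, bounds)

  residual_fun <- function(p) {
    predict_cycles(fitdat, geom, exp(p[1]), exp(p[2]), exp(p[3])) - obs
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = residual_fun,
    lower = unname(bounds$lower), upper = unname(bounds$upper),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-10, ptol = 1e-10))

  p <- fit$par
  est <- exp(p)
  names(est) <- c("k_on", "k_off", "R_max")
  # SE on the log scale from the Jacobian; delta method to natural scale.
  se_log <- tryCatch({
    dof <- max(length(obs) - 3L, 1L)
    s2 <- fit$deviance / dof
    covm <- s2 * solve(fit$hessian)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 3))
  se <- est * se_log

  at_bound <- any(
    abs(p - unname(bounds$lower)) < 1e-6 |
    abs(p - unname(bounds$upper)) < 1e-6)
  converged <- fit$info %in% 1:4

  params <- tibble(term = names(est), estimate = unname(est),
                   std.error = unname(se))
  flags <- qc_flags(data, rmax_theoretical = rmax_theoretical,
                    noise_sd = noise_sd, noise_multiplier = noise_multiplier,
                    slow_dissociation_retention = slow_dissociation_retention)
  if (at_bound) flags <- union(flags, "at_bound")
  if (!converged) flags <- union(flags, "not_detectable")

  fitted_tbl <- fitdat
  fitted_tbl$.fitted <- predict_cycles(fitdat, geom, est[1], est[2], est[3])
  fitted_tbl$.resid <- fitted_tbl$response_RU - fitted_tbl$.fitted

  new_kinetic_fit(
    analyte_id = analyte, params = params,
    K_D = unname(est["k_off"] / est["k_on"]),
    ssr = fit$deviance, noise_sd = noise_sd, flags = flags,
    n_cycles_used = nrow(geom), data = data, fitted = fitted_tbl,
    converged = converged)
}

new_kinetic_fit <- function(analyte_id, params, K_D, ssr, noise_sd, flags,
                            n_cycles_used, data, fitted, converged) {
  structure(
    list(analyte_id = analyte_id, params = params, K_D = K_D, ssr = ssr,
         noise_sd = noise_sd, flags = flags, n_cycles_used = n_cycles_used,
         data = data, fitted = fitted, converged = converged),
    class = "spr_kinetic_fit")
}

# Deterministic start point in log space (see header comment).
kinetics_start <- function(fitdat, geom, max_obs, bounds) {
  hi <- geom$cycle_id[which.max(geom$concentration_M)]
  diss <- fitdat[fitdat$cycle_id == hi & fitdat$phase == "dissociation", ]
  k_off0 <- 0.05
  pos <- diss[diss$response_RU > 0.05 * max_obs, ]
  if (nrow(pos) >= 4) {
    sl <- coef(lm(log(response_RU) ~ time_s, data = pos))[2]
    if (is.finite(sl) && sl < 0) k_off0 <- -sl
  }
  ss <- tryCatch(
    fit_steady_state(fitdat, min_concentrations = 2),
    error = function(e) NULL)
  if (!is.null(ss) && is.finite(ss$K_D) && ss$K_D > 0) {
    K_D0 <- ss$K_D
    R_max0 <- ss$R_max
  } else {
    K_D0 <- median(geom$concentration_M)
    R_max0 <- 2 * max_obs
  }
  p <- log(c(k_off0 / K_D0, k_off0, R_max0))
  pmin(pmax(p, unname(bounds$lower)), unname(bounds$upper))
}

#' Steady-state (equilibrium) affinity analysis
#'
#' Extracts the plateau response of each non-zero concentration cycle
#' (median of the final fraction of the association window) and fits the
#' Langmuir isotherm `Req = C * R_max / (C + K_D)` by nonlinear least
#' squares, the affinity branch used when kinetics are too fast to resolve.
#'
#' @param data Preprocessed sensorgram tibble for one analyte.
#' @param plateau_fraction Fraction of the association window read as the
#'   plateau (default 0.2).
#' @param min_concentrations Minimum number of distinct non-zero
#'   concentrations required (default 3).
#'
#' @return A one-row tibble: `K_D`, `R_max`, `ssr`, `n_concentrations`,
#'   `saturation_warning` (`TRUE` when the top concentration is far below
#'   the fitted `K_D`, so the plateau is unconstrained).
#' @export
fit_steady_state <- function(data, plateau_fraction = 0.2,
                             min_concentrations = 3) {
  data <- dplyr::filter(as_tibble(data), .data$concentration_M > 0)
  plate <- data |>
    dplyr::group_by(.data$cycle_id, .data$concentration_M) |>
    dplyr::group_modify(~ tibble(Req = plateau_value(
      dplyr::mutate(.x, cycle_id = .y$cycle_id), plateau_fraction))) |>
    dplyr::ungroup()
  concs <- unique(plate$concentration_M)
  if (length(concs) < min_concentrations) {
    abort(sprintf(
      "Steady-state fit needs >= %d distinct concentrations, got %d.",
      min_concentrations, length(concs)),
      class = "sprbind_config_error")
  }
  start <- list(K_D = median(concs), R_max = 1.2 * max(abs(plate$Req)))
  fit <- minpack.lm::nlsLM(
    Req ~ concentration_M * R_max / (concentration_M + K_D),
    data = plate, start = start,
    lower = c(K_D = 1e-12, R_max = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  tibble(
    K_D = unname(est["K_D"]), R_max = unname(est["R_max"]),
    ssr = sum(stats::resid(fit)^2), n_concentrations = length(concs),
    saturation_warning = max(concs) < unname(est["K_D"]) / 10)
}

#' Quality-control flags for a fitted cycle set
#'
#' Screens a preprocessed cycle set for the failure modes seen in
#' small-molecule SPR panels: `not_detectable` when no concentration rises
#' above `noise_multiplier` times the baseline noise sd; `matrix_binding`
#' when the observed response exceeds the theoretical surface capacity
#' (signal from the dextran matrix, not the ligand); `slow_dissociation`
#' when a cycle still retains more than `slow_dissociation_retention` of
#' its peak response at the end of the dissociation window (compound not
#' washed out).
#'
#' @inheritParams fit_kinetics
#' @param noise_sd Baseline noise sd in RU; estimated from the data when
#'   `NULL`.
#' @return Character vector of flags (possibly empty), never an error.
#' @export
qc_flags <- function(data, rmax_theoretical = NULL, noise_sd = NULL,
                     noise_multiplier = 3,
                     slow_dissociation_retention = 0.5) {
  data <- as_tibble(data)
  noise_sd <- noise_sd %||% estimate_noise_sd(data)
  flags <- character()
  samp <- dplyr::filter(data, .data$concentration_M > 0)
  if (nrow(samp) == 0) return("not_detectable")
  peak <- max(abs(samp$response_RU))
  plateaus <- samp |>
    dplyr::group_by(.data$cycle_id) |>
    dplyr::group_map(~ tryCatch(plateau_value(
      dplyr::mutate(.x, cycle_id = .y$cycle_id)), error = function(e) 0))
  if (max(abs(unlist(plateaus))) < noise_multiplier * noise_sd) {
    flags <- c(flags, "not_detectable")
  }
  if (!is.null(rmax_theoretical) && peak > rmax_theoretical) {
    flags <- c(flags, "matrix_binding")
  }
  retention <- samp |>
    dplyr::filter(.data$phase != "baseline") |>
    dplyr::group_by(.data$cycle_id) |>
    dplyr::group_map(~ {
      d <- .x[.x$phase == "dissociation", ]
      pk <- max(.x$response_RU)
      if (nrow(d) < 3 || pk < noise_multiplier * noise_sd) return(NA_real_)
      n_end <- max(3L, ceiling(0.05 * nrow(d)))
      median(tail(d$response_RU, n_end)) / pk
    })
  retention <- unlist(retention)
  if (any(!is.na(retention) &
          retention > slow_dissociation_retention)) {
    flags <- c(flags, "slow_dissociation")
  }
  flags
}

# --- methods ---------------------------------------------------------------

#' @export
print.spr_kinetic_fit <- function(x, ...) {
  cat(sprintf("<spr_kinetic_fit> analyte %s (%d cycles)\n", x$analyte_id,
              x$n_cycles_used))
  if (all(is.na(x$params$estimate))) {
    cat("  not detectable\n")
  } else {
    est <- setNames(x$params$estimate, x$params$term)
    cat(sprintf("  k_on  = %.4g 1/(M s)\n  k_off = %.4g 1/s\n", est["k_on"],
                est["k_off"]))
    cat(sprintf("  K_D   = %.4g M\n  R_max = %.4g RU\n", x$K_D,
                est["R_max"]))
  }
  if (length(x$flags) > 0) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a kinetic fit into a parameter table
#'
#' @param x An `spr_kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, including
#'   the derived `K_D` row.
#' @method tidy spr_kinetic_fit
#' @export
tidy.spr_kinetic_fit <- function(x, ...) {
  kd_se <- NA_real_
  est <- setNames(x$params$estimate, x$params$term)
  se <- setNames(x$params$std.error, x$params$term)
  if (all(is.finite(se[c("k_on", "k_off")])) &&
      all(is.finite(est[c("k_on", "k_off")]))) {
    # independent-rates delta method on the ratio
    kd_se <- x$K_D * sqrt((se["k_on"] / est["k_on"])^2 +
                          (se["k_off"] / est["k_off"])^2)
  }
  dplyr::bind_rows(
    x$params,
    tibble(term = "K_D", estimate = x$K_D, std.error = unname(kd_se)))
}

#' One-row summary of a kinetic fit
#'
#' @param x An `spr_kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `analyte_id`, `k_on`, `k_off`, `K_D`, `R_max`,
#'   `ssr`, `noise_sd`, `n_cycles_used`, `converged`, `flags` (comma
#'   separated, empty string when clean).
#' @method glance spr_kinetic_fit
#' @export
glance.spr_kinetic_fit <- function(x, ...) {
  est <- setNames(x$params$estimate, x$params$term)
  tibble(
    analyte_id = x$analyte_id,
    k_on = unname(est["k_on"]), k_off = unname(est["k_off"]), K_D = x$K_D,
    R_max = unname(est["R_max"]), ssr = x$ssr, noise_sd = x$noise_sd,
    n_cycles_used = x$n_cycles_used, converged = x$converged,
    flags = paste(x$flags, collapse = ","))
}

#' Observed data with fitted values and residuals
#'
#' @param x An `spr_kinetic_fit`.
#' @param ... Unused.
#' @return The fitted cycles with `.fitted` and `.resid` columns, or the
#'   input data unchanged for a not-detectable fit.
#' @method augment spr_kinetic_fit
#' @export
augment.spr_kinetic_fit <- function(x, ...) {
  x$fitted %||% x$data
}

#' Sensorgram overlay plot of a kinetic fit
#'
#' @param object An `spr_kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot: observed traces (points) and fitted curves (lines),
#'   coloured by concentration.
#' @method autoplot spr_kinetic_fit
#' @export
autoplot.spr_kinetic_fit <- function(object, ...) {
  d <- augment(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time_s, y = .data$response_RU,
    colour = factor(signif(.data$concentration_M * 1e6, 3)),
    group = .data$cycle_id)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  colour = expression("Concentration (" * mu * "M)"),
                  title = sprintf("1:1 kinetic fit: %s", object$analyte_id))
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(
      data = object$fitted,
      ggplot2::aes(y = .data$.fitted), linewidth = 0.6)
  }
  p
}
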
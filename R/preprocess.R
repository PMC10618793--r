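# Double referencing and DMSO solvent correction.
#
# Order of operations in preprocess_cycles(): reference-cell subtraction,
# then solvent correction (when calibration curves are supplied), then
# blank (zero-concentration) subtraction, with blanks processed through the
# same upstream steps. This is the standard double-referencing order.

#' Subtract the reference flow cell from active-cell traces
#'
#' Pointwise subtraction `active - reference`, matching cycles by `cycle_id`
#' and requiring identical time grids. Removes bulk refractive-index shifts
#' and drift common to both flow cells. Metadata (analyte, concentration,
#' phases) is carried from the active trace.
#'
#' @param active Sensorgram tibble of active-cell traces.
#' @param reference Sensorgram tibble of matched reference-cell traces
#'   (same `cycle_id`s, identical `time_s` grids).
#' @return A sensorgram tibble like `active` with referenced responses and
#'   `flow_cell = "active"`.
#' @export
subtract_reference <- function(active, reference) {
  active <- as_tibble(active)
  reference <- as_tibble(reference)
  out <- dplyr::group_split(active, .data$cycle_id)
  out <- purrr::map(out, function(a) {
    r <- dplyr::filter(reference, .data$cycle_id == a$cycle_id[1])
    if (nrow(r) != nrow(a) || any(r$time_s != a$time_s)) {
      abort(sprintf(
        "Cycle %s: reference trace missing or time grid mismatch.",
        a$cycle_id[1]), class = "sprbind_validation_error")
    }
    a$response_RU <- a$response_RU - r$response_RU
    a
  })
  dplyr::bind_rows(out)
}

#' Subtract averaged blank (zero-concentration) cycles
#'
#' Pointwise subtraction of the mean of the blank traces from each sample
#' trace, removing systematic per-cycle disturbances that survive reference
#' subtraction. All traces must share one time grid.
#'
#' @param sample Sensorgram tibble of sample traces.
#' @param blanks Sensorgram tibble of zero-concentration traces (one or
#'   more cycles), preprocessed identically to `sample`.
#' @return `sample` with the mean blank subtracted.
#' @export
subtract_blanks <- function(sample, blanks) {
  blanks <- as_tibble(blanks)
  if (nrow(blanks) == 0) {
    abort("At least one blank (zero-concentration) cycle is required.",
          class = "sprbind_config_error")
  }
  if (any(blanks$concentration_M != 0)) {
    abort("Blank cycles must have concentration_M == 0.",
          class = "sprbind_validation_error")
  }
  blank_mean <- blanks |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(blank_RU = mean(.data$response_RU), .groups = "drop")
  out <- dplyr::group_split(as_tibble(sample), .data$cycle_id)
  out <- purrr::map(out, function(s) {
    m <- match(s$time_s, blank_mean$time_s)
    if (any(is.na(m))) {
      abort(sprintf("Cycle %s: blank time grid does not match sample.",
                    s$cycle_id[1]), class = "sprbind_validation_error")
    }
    s$response_RU <- s$response_RU - blank_mean$blank_RU[m]
    s
  })
  dplyr::bind_rows(out)
}

# Plateau response of one trace: median of the final `fraction` of the
# association window (robust to noise).
plateau_value <- function(trace, fraction = 0.2) {
  a <- trace[trace$phase == "association", ]
  if (nrow(a) == 0) {
    abort(sprintf("Cycle %s: no association phase.", trace$cycle_id[1]),
          class = "sprbind_validation_error")
  }
  t0 <- min(a$time_s)
  t1 <- max(a$time_s)
  keep <- a$time_s >= t1 - fraction * (t1 - t0)
  median(a$response_RU[keep])
}

#' Fit a DMSO solvent-correction curve
#'
#' Solvent correction compensates the bulk refractive-index mismatch caused
#' by small differences in DMSO content between samples and running buffer.
#' Calibration cycles inject DMSO-only buffers spanning the assay's DMSO
#' design range (eight points, 2.5-3.8 % DMSO); for each cycle the plateau
#' response of the reference cell (x) and the plateau of active minus
#' reference (y, the required correction) are extracted, and a low-order
#' polynomial of y on x is fitted by least squares.
#'
#' @param cycles Sensorgram tibble holding the calibration cycles for one
#'   correction set: both flow cells for each of (at least) 8 cycles.
#' @param degree Polynomial degree (default 2, the conventional low-order
#'   fit).
#' @param plateau_fraction Fraction of the association window used for the
#'   plateau read (default 0.2).
#' @param acquired_at_cycle Run-order index of this calibration set, used
#'   for temporal interpolation between bracketing sets (default 0).
#'
#' @return An object of class `solvent_curve`: calibration points,
#'   polynomial coefficients (intercept first), valid reference-RU range and
#'   acquisition index.
#' @export
fit_solvent_correction <- function(cycles, degree = 2, plateau_fraction = 0.2,
                                   acquired_at_cycle = 0) {
  cycles <- as_tibble(cycles)
  ids <- unique(cycles$cycle_id)
  if (length(ids) < 8) {
    abort(sprintf(
      "Solvent correction needs >= 8 calibration cycles, got %d.",
      length(ids)), class = "sprbind_config_error")
  }
  pts <- purrr::map_dfr(ids, function(id) {
    cyc <- cycles[cycles$cycle_id == id, ]
    ref <- cyc[cyc$flow_cell == "reference", ]
    act <- cyc[cyc$flow_cell == "active", ]
    if (nrow(ref) == 0 || nrow(act) == 0) {
      abort(sprintf("Calibration cycle %s needs both flow cells.", id),
            class = "sprbind_config_error")
    }
    r <- plateau_value(ref, plateau_fraction)
    tibble(cycle_id = id, reference_RU = r,
           correction_RU = plateau_value(act, plateau_fraction) - r)
  })
  if (diff(range(pts$reference_RU)) < sqrt(.Machine$double.eps)) {
    abort("Degenerate calibration: all reference plateaus equal.",
          class = "sprbind_fit_error")
  }
  fit <- lm(correction_RU ~ poly(reference_RU, degree, raw = TRUE),
            data = pts)
  structure(
    list(calibration_points = pts,
         coefficients = unname(coef(fit)),
         degree = degree,
         valid_range = range(pts$reference_RU),
         acquired_at_cycle = acquired_at_cycle),
    class = "solvent_curve")
}

#' @export
print.solvent_curve <- function(x, ...) {
  cat(sprintf(
    "<solvent_curve> degree %d, valid range [%.2f, %.2f] RU, cycle %s\n",
    x$degree, x$valid_range[1], x$valid_range[2],
    format(x$acquired_at_cycle)))
  invisible(x)
}

# Evaluate a solvent_curve at reference responses x; attribute
# "extrapolated" marks evaluations outside the calibrated range.
eval_solvent_curve <- function(curve, x) {
  co <- curve$coefficients
  y <- rep(co[1], length(x))
  for (k in seq_len(curve$degree)) y <- y + co[k + 1] * x^k
  attr(y, "extrapolated") <- x < curve$valid_range[1] |
    x > curve$valid_range[2]
  y
}

#' Apply solvent correction to a referenced sensorgram
#'
#' Evaluates the bracketing calibration curves at the cycle's reference-cell
#' bulk response (the plateau of the matched reference trace), interpolates
#' linearly between the two curves by run-order cycle index, and subtracts
#' the resulting correction from the trace. Evaluation outside either
#' curve's calibrated range is flagged on the result via the
#' `solvent_extrapolated` attribute.
#'
#' @param s Reference-subtracted sensorgram tibble (one or more cycles).
#' @param reference The matched raw reference-cell traces for `s` (used for
#'   the bulk-response read).
#' @param before,after `solvent_curve` objects bracketing `s` in run order.
#' @param cycle_index Run-order index of `s` for temporal interpolation;
#'   default halfway between the two calibration sets.
#' @param plateau_fraction Plateau read fraction (default 0.2).
#' @return `s` with corrected responses; attribute `solvent_extrapolated`
#'   is `TRUE` if any bulk read fell outside a curve's valid range.
#' @export
apply_solvent_correction <- function(s, reference, before, after,
                                     cycle_index = NULL,
                                     plateau_fraction = 0.2) {
  if (!inherits(before, "solvent_curve") || !inherits(after, "solvent_curve")) {
    abort("`before` and `after` must be solvent_curve objects.",
          class = "sprbind_config_error")
  }
  span <- after$acquired_at_cycle - before$acquired_at_cycle
  if (is.null(cycle_index)) {
    w <- 0.5
  } else if (span <= 0) {
    w <- 0.5
  } else {
    w <- (cycle_index - before$acquired_at_cycle) / span
    w <- min(max(w, 0), 1)
  }
  out <- dplyr::group_split(as_tibble(s), .data$cycle_id)
  extrapolated <- FALSE
  out <- purrr::map(out, function(cyc) {
    ref <- dplyr::filter(as_tibble(reference),
                         .data$cycle_id == cyc$cycle_id[1])
    if (nrow(ref) == 0) {
      abort(sprintf("Cycle %s: no matched reference trace.",
                    cyc$cycle_id[1]), class = "sprbind_config_error")
    }
    bulk <- plateau_value(ref, plateau_fraction)
    c1 <- eval_solvent_curve(before, bulk)
    c2 <- eval_solvent_curve(after, bulk)
    extrapolated <<- extrapolated || any(attr(c1, "extrapolated")) ||
      any(attr(c2, "extrapolated"))
    corr <- (1 - w) * as.numeric(c1) + w * as.numeric(c2)
    cyc$response_RU <- cyc$response_RU - corr
    cyc
  })
  res <- dplyr::bind_rows(out)
  attr(res, "solvent_extrapolated") <- extrapolated
  res
}

#' Full double referencing of a raw cycle set
#'
#' Runs the standard preprocessing chain on the raw traces of one analyte:
#' reference-cell subtraction, optional solvent correction, then subtraction
#' of the (identically processed) zero-concentration blank cycles. Returns
#' the corrected non-blank active traces, ready for kinetic fitting.
#'
#' @param data Raw sensorgram tibble holding both flow cells, sample cycles
#'   and at least one zero-concentration blank cycle.
#' @param solvent_before,solvent_after Optional bracketing
#'   [fit_solvent_correction()] curves; both or neither.
#' @return Corrected sensorgram tibble (active channel, non-blank cycles).
#' @export
preprocess_cycles <- function(data, solvent_before = NULL,
                              solvent_after = NULL) {
  data <- validate_sensorgrams(data)
  active <- dplyr::filter(data, .data$flow_cell == "active")
  reference <- dplyr::filter(data, .data$flow_cell == "reference")
  refd <- subtract_reference(active, reference)
  if (!is.null(solvent_before) || !is.null(solvent_after)) {
    if (is.null(solvent_before) || is.null(solvent_after)) {
      abort("Supply both bracketing solvent curves or neither.",
            class = "sprbind_config_error")
    }
    refd <- apply_solvent_correction(refd, reference, solvent_before,
                                     solvent_after)
  }
  blanks <- dplyr::filter(refd, .data$concentration_M == 0)
  samples <- dplyr::filter(refd, .data$concentration_M > 0)
  subtract_blanks(samples, blanks)
}
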
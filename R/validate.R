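# Input validation helpers shared across the package.

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("`%s` must be finite and > 0.", nm),
            class = "sprbind_domain_error")
    }
  }
  invisible(TRUE)
}

check_nonnegative <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort(sprintf("`%s` must be finite and >= 0.", nm),
            class = "sprbind_domain_error")
    }
  }
  invisible(TRUE)
}

check_fraction <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm),
            class = "sprbind_domain_error")
    }
  }
  invisible(TRUE)
}

# The canonical sensorgram-table columns (also the TSV dialect field order).
SENSORGRAM_COLS <- c("cycle_id", "flow_cell", "analyte_id", "concentration_M",
                     "phase", "time_s", "response_RU")
PHASE_LEVELS <- c("baseline", "association", "dissociation")
FLOW_CELLS <- c("reference", "active")

#' Validate a sensorgram table
#'
#' Checks that a tibble of sensorgram samples satisfies the data-model
#' invariants: all canonical columns present; within each
#' `(cycle_id, flow_cell)` trace, time strictly increasing, responses finite,
#' concentration a single value >= 0, and phases appearing in run order
#' (baseline, association, dissociation).
#'
#' @param data A data frame with columns `cycle_id`, `flow_cell`,
#'   `analyte_id`, `concentration_M`, `phase`, `time_s`, `response_RU`.
#'
#' @return `data` invisibly (as a tibble), for use in pipes. Errors with a
#'   message naming the offending column or cycle otherwise.
#' @export
validate_sensorgrams <- function(data) {
  data <- as_tibble(data)
  missing <- setdiff(SENSORGRAM_COLS, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Sensorgram table is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  bad_phase <- setdiff(unique(data$phase), PHASE_LEVELS)
  if (length(bad_phase) > 0) {
    abort(sprintf("Unknown phase value(s): %s.",
                  paste(bad_phase, collapse = ", ")),
          class = "sprbind_format_error")
  }
  bad_fc <- setdiff(unique(data$flow_cell), FLOW_CELLS)
  if (length(bad_fc) > 0) {
    abort(sprintf("Unknown flow_cell value(s): %s.",
                  paste(bad_fc, collapse = ", ")),
          class = "sprbind_format_error")
  }
  traces <- dplyr::group_split(data, .data$cycle_id, .data$flow_cell)
  for (tr in traces) {
    id <- sprintf("%s/%s", tr$cycle_id[1], tr$flow_cell[1])
    if (any(diff(tr$time_s) <= 0)) {
      abort(sprintf("Cycle %s: time_s must be strictly increasing.", id),
            class = "sprbind_validation_error")
    }
    if (any(!is.finite(tr$response_RU))) {
      abort(sprintf("Cycle %s: non-finite response_RU.", id),
            class = "sprbind_validation_error")
    }
    conc <- unique(tr$concentration_M)
    if (length(conc) != 1 || !is.finite(conc) || conc < 0) {
      abort(sprintf(
        "Cycle %s: concentration_M must be a single finite value >= 0.", id),
        class = "sprbind_validation_error")
    }
    ph <- as.integer(factor(tr$phase, levels = PHASE_LEVELS))
    if (any(diff(ph) < 0)) {
      abort(sprintf(
        "Cycle %s: phases must run baseline -> association -> dissociation.",
        id), class = "sprbind_validation_error")
    }
  }
  invisible(data)
}

#' Phase boundaries of each sensorgram trace
#'
#' Summarises a sensorgram table into one row per `(cycle_id, flow_cell)`
#' with the association start/end and dissociation end times taken from the
#' `phase` column transitions.
#'
#' @inheritParams validate_sensorgrams
#' @return A tibble with columns `cycle_id`, `flow_cell`, `analyte_id`,
#'   `concentration_M`, `t_assoc_start`, `t_assoc_end`, `t_diss_end`.
#' @export
phase_boundaries <- function(data) {
  validate_sensorgrams(data)
  data |>
    dplyr::group_by(.data$cycle_id, .data$flow_cell, .data$analyte_id,
                    .data$concentration_M) |>
    dplyr::summarise(
      t_assoc_start = min(.data$time_s[.data$phase == "association"]),
      t_assoc_end = max(.data$time_s[.data$phase == "association"]),
      t_diss_end = max(.data$time_s[.data$phase == "dissociation"]),
      .groups = "drop"
    )
}
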
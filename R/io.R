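# Readers and writers for the project's tabular formats. All files are
# tab-separated, UTF-8, '.' decimal separator, one header line, trailing
# newline, fixed column order; write_* and read_* are exact inverses on
# valid data (numeric fields carried at full double precision via %.12g).

#' Read a sensorgram table
#'
#' Reads the tab-separated sensorgram dialect: columns `cycle_id`,
#' `flow_cell`, `analyte_id`, `concentration_M`, `phase`, `time_s`,
#' `response_RU`, one row per time point. Phase boundaries are carried by
#' the categorical `phase` column (baseline | association | dissociation);
#' time is seconds from cycle start. The result is validated against the
#' sensorgram invariants; files with missing columns or non-monotone time
#' are rejected, never repaired.
#'
#' @param path Path to a sensorgram TSV file.
#' @return A validated sensorgram tibble.
#' @seealso [write_sensorgram_tsv()], [validate_sensorgrams()]
#' @export
read_sensorgram_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SENSORGRAM_COLS, header)
  if (length(missing) > 0) {
    abort(sprintf("File %s is missing column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  data <- readr::read_tsv(
    path,
    col_types = readr::cols(
      cycle_id = readr::col_character(),
      flow_cell = readr::col_character(),
      analyte_id = readr::col_character(),
      concentration_M = readr::col_double(),
      phase = readr::col_character(),
      time_s = readr::col_double(),
      response_RU = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(SENSORGRAM_COLS, names(data))
  if (length(missing) > 0) {
    abort(sprintf("File %s is missing column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  validate_sensorgrams(data[SENSORGRAM_COLS])
  data[SENSORGRAM_COLS]
}

#' Write a sensorgram table
#'
#' Writes the tab-separated sensorgram dialect with deterministic column
#' order and `%.12g` numeric formatting, so that
#' `read_sensorgram_tsv(write_sensorgram_tsv(x))` round-trips numeric fields
#' to 12 significant digits. An empty table produces a header-only file.
#'
#' @param data A sensorgram tibble (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_tsv <- function(data, path) {
  if (nrow(data) > 0) validate_sensorgrams(data)
  data <- as_tibble(data)[SENSORGRAM_COLS]
  write_tsv_12g(data, path)
}

#' Read panel metadata
#'
#' Panel TSV: columns `compound_name`, `molecular_weight_gmol`, `role`
#' (control | cannabinoid).
#'
#' @param path Path to a panel TSV file.
#' @return A tibble of panel records; molecular weights must be positive.
#' @export
read_panel_tsv <- function(path) {
  data <- readr::read_tsv(
    path,
    col_types = readr::cols(
      compound_name = readr::col_character(),
      molecular_weight_gmol = readr::col_double(),
      role = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("compound_name", "molecular_weight_gmol", "role")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("File %s is missing column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  if (any(!is.finite(data$molecular_weight_gmol) |
          data$molecular_weight_gmol <= 0)) {
    abort("molecular_weight_gmol must be positive.",
          class = "sprbind_validation_error")
  }
  data[need]
}

#' Write panel metadata
#' @param data A tibble with columns `compound_name`,
#'   `molecular_weight_gmol`, `role`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(data, path) {
  write_tsv_12g(
    as_tibble(data)[c("compound_name", "molecular_weight_gmol", "role")],
    path)
}

COMPETITION_COLS <- c("analyte_a", "analyte_b", "C_a_M", "C_b_M", "KD_a_M",
                      "KD_b_M", "Rmax_a_RU", "Rmax_b_RU", "RU_a", "RU_b",
                      "RU_ab")

#' Read competition measurements
#'
#' Competition input TSV: one row per analyte pair with the mixture
#' concentrations, single-analyte KD and Rmax values, the single-analyte
#' experimental responses `RU_a`, `RU_b` and the combined-injection response
#' `RU_ab`.
#'
#' @param path Path to a competition TSV file.
#' @return A tibble with the competition measurement columns.
#' @export
read_competition_tsv <- function(path) {
  data <- readr::read_tsv(path, col_types = readr::cols(
    analyte_a = readr::col_character(),
    analyte_b = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(COMPETITION_COLS, names(data))
  if (length(missing) > 0) {
    abort(sprintf("File %s is missing column(s): %s.", path,
                  paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  data[union(COMPETITION_COLS, names(data))]
}

#' Write competition measurements
#'
#' The optional `theoretical_competitive` column (an externally supplied
#' competitive prediction, see [classify_competition()]) is preserved when
#' present.
#'
#' @param data A tibble with the competition measurement columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_competition_tsv <- function(data, path) {
  keep <- c(COMPETITION_COLS,
            intersect("theoretical_competitive", names(data)))
  write_tsv_12g(as_tibble(data)[keep], path)
}

# Shared TSV writer: tabs, '.' decimals, %.12g numerics, trailing newline.
write_tsv_12g <- function(data, path) {
  out <- data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- sprintf("%.12g", out[[nm]])
    }
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out) > 0) do.call(paste, c(unname(as.list(out)),
                                                 sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
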
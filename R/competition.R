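# Competitive-SPR analysis: fractional occupancy of two ligands sharing one
# binding site, theoretical combined responses under the competitive and
# non-competitive (additive) hypotheses, and the nearest-value classifier.
#
# For analytes A and B competing for a single site at equilibrium, the
# occupied fractions are
#
#   FO_A = 1 / (1 + (K_DA / C_A) * (1 + C_B / K_DB))
#   FO_B = 1 / (1 + (K_DB / C_B) * (1 + C_A / K_DA))
#
# which is the steady state of the shared-site kinetic scheme (see
# simulate_competition_odes()). The predicted combined response under
# competition is FO_A * Rmax_A + FO_B * Rmax_B; under independent
# (non-competitive) binding it is simply RU_A + RU_B, the sum of the
# single-analyte experimental responses.

#' Equilibrium fractional occupancy of two ligands competing for one site
#'
#' Closed-form occupied fractions for a shared single site. By convention
#' an absent analyte (`C = 0`, where the formula is singular) has occupancy
#' 0, recovering the single-ligand isotherm for the other analyte. All
#' arguments are vectorised and recycled.
#'
#' @param C_a,C_b Free concentrations of analytes A and B in the mixture,
#'   molar (>= 0).
#' @param K_Da,K_Db Equilibrium dissociation constants, molar (> 0).
#'
#' @return A tibble with columns `fo_a`, `fo_b` (fractions in [0, 1],
#'   `fo_a + fo_b <= 1`).
#'
#' @examples
#' # the two P2X4 antagonist probes at 1 uM each
#' fractional_occupancy(1e-6, 1e-6, K_Da = 4.5e-6, K_Db = 7.795e-6)
#' @export
fractional_occupancy <- function(C_a, C_b, K_Da, K_Db) {
  check_positive(K_Da = K_Da, K_Db = K_Db)
  check_nonnegative(C_a = C_a, C_b = C_b)
  n <- max(length(C_a), length(C_b), length(K_Da), length(K_Db))
  C_a <- rep_len(C_a, n); C_b <- rep_len(C_b, n)
  K_Da <- rep_len(K_Da, n); K_Db <- rep_len(K_Db, n)
  fo_a <- ifelse(C_a == 0, 0,
                 1 / (1 + (K_Da / C_a) * (1 + C_b / K_Db)))
  fo_b <- ifelse(C_b == 0, 0,
                 1 / (1 + (K_Db / C_b) * (1 + C_a / K_Da)))
  tibble(fo_a = fo_a, fo_b = fo_b)
}

#' Theoretical combined response under shared-site competition
#'
#' `RU = FO_a * R_max_a + FO_b * R_max_b`: the equilibrium response
#' predicted for a combined injection if both analytes compete for the same
#' site.
#'
#' @param fo_a,fo_b Fractional occupancies in [0, 1], typically from
#'   [fractional_occupancy()].
#' @param R_max_a,R_max_b Surface capacities of the two analytes, RU (> 0).
#' @return Predicted combined response in RU.
#' @export
theoretical_competitive_ru <- function(fo_a, fo_b, R_max_a, R_max_b) {
  check_fraction(fo_a = fo_a, fo_b = fo_b)
  check_positive(R_max_a = R_max_a, R_max_b = R_max_b)
  fo_a * R_max_a + fo_b * R_max_b
}

#' Theoretical combined response under independent (non-competitive) binding
#'
#' The additive null: if the analytes bind independent sites, the combined
#' response is the exact sum of the single-analyte experimental responses.
#'
#' @param RU_a,RU_b Single-analyte experimental responses, RU (>= 0).
#' @return `RU_a + RU_b`.
#' @export
theoretical_noncompetitive_ru <- function(RU_a, RU_b) {
  check_nonnegative(RU_a = RU_a, RU_b = RU_b)
  RU_a + RU_b
}

#' Classify analyte pairs as competitive or non-competitive binders
#'
#' Compares each pair's combined-injection response `RU_ab` against the two
#' theoretical predictions and assigns the nearer one, with a relative
#' margin guarding against ties: competitive when
#' `|RU_ab - RU_comp| < |RU_ab - RU_noncomp| * (1 - margin)`, symmetric for
#' non-competitive, otherwise inconclusive.
#'
#' The non-competitive prediction is always `RU_a + RU_b`. The competitive
#' prediction is taken from a `theoretical_competitive` column when present
#' (e.g. values from an external evaluation), otherwise computed from the
#' pair's concentrations, KD and Rmax values via [fractional_occupancy()].
#'
#' @param data A tibble with columns `analyte_a`, `analyte_b`, `RU_a`,
#'   `RU_b`, `RU_ab`, plus either `theoretical_competitive` or all of
#'   `C_a_M`, `C_b_M`, `KD_a_M`, `KD_b_M`, `Rmax_a_RU`, `Rmax_b_RU`.
#' @param margin Relative decision margin (default 0.1); 0 reduces the rule
#'   to plain nearest value.
#'
#' @return The input with verdict columns appended:
#'   `theoretical_competitive`, `theoretical_noncompetitive`,
#'   `distance_competitive`, `distance_noncompetitive`, `label`
#'   (competitive | non_competitive | inconclusive) and `margin`.
#'
#' @examples
#' classify_competition(tibble::tibble(
#'   analyte_a = "BX430", analyte_b = "5-BDBD",
#'   RU_a = 22.5, RU_b = 34.9, RU_ab = 39.3,
#'   theoretical_competitive = 17.2))
#' @export
classify_competition <- function(data, margin = 0.1) {
  data <- as_tibble(data)
  if (margin < 0 || margin >= 1) {
    abort("`margin` must lie in [0, 1).", class = "sprbind_domain_error")
  }
  need <- c("RU_a", "RU_b", "RU_ab")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")),
          class = "sprbind_format_error")
  }
  if (!"theoretical_competitive" %in% names(data)) {
    data$theoretical_competitive <- NA_real_
  }
  fill <- is.na(data$theoretical_competitive)
  if (any(fill)) {
    kin <- c("C_a_M", "C_b_M", "KD_a_M", "KD_b_M", "Rmax_a_RU", "Rmax_b_RU")
    bad <- kin[vapply(kin, function(cn) {
      !cn %in% names(data) || any(!is.finite(data[[cn]][fill]))
    }, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf(
        "Cannot compute the competitive prediction: missing field(s) %s.",
        paste(bad, collapse = ", ")), class = "sprbind_format_error")
    }
    fo <- fractional_occupancy(data$C_a_M[fill], data$C_b_M[fill],
                               data$KD_a_M[fill], data$KD_b_M[fill])
    data$theoretical_competitive[fill] <- theoretical_competitive_ru(
      fo$fo_a, fo$fo_b, data$Rmax_a_RU[fill], data$Rmax_b_RU[fill])
  }
  data |>
    dplyr::mutate(
      theoretical_noncompetitive = theoretical_noncompetitive_ru(
        .data$RU_a, .data$RU_b),
      distance_competitive = abs(.data$RU_ab -
                                   .data$theoretical_competitive),
      distance_noncompetitive = abs(.data$RU_ab -
                                      .data$theoretical_noncompetitive),
      label = dplyr::case_when(
        .data$distance_competitive <
          .data$distance_noncompetitive * (1 - margin) ~ "competitive",
        .data$distance_noncompetitive <
          .data$distance_competitive * (1 - margin) ~ "non_competitive",
        TRUE ~ "inconclusive"),
      margin = margin)
}

#' Verdict-table plot for competition experiments
#'
#' Dot plot of the experimental combined response against the two
#' theoretical predictions for each analyte pair, the visual form of the
#' nearest-value decision.
#'
#' @param verdicts Output of [classify_competition()].
#' @return A ggplot object.
#' @export
plot_competition <- function(verdicts) {
  long <- verdicts |>
    dplyr::mutate(pair = paste(.data$analyte_a, .data$analyte_b,
                               sep = " + ")) |>
    tidyr::pivot_longer(
      c("RU_ab", "theoretical_competitive", "theoretical_noncompetitive"),
      names_to = "quantity", values_to = "RU")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$RU,
                                     shape = .data$quantity,
                                     colour = .data$quantity)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(16, 4, 3)) +
    ggplot2::labs(x = NULL, y = "Response (RU)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
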
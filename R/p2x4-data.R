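# Published reference datasets for the P2X4 cannabinoid screen, built in
# code so they ship as plain source. These printed tables are inputs to the
# analysis (consistency checks, worked examples), not reproduced results.

#' Reported binding parameters of the P2X4 cannabinoid screening panel
#'
#' The published screen of twenty-eight cannabinoids plus the two control
#' antagonists BX430 and 5-BDBD against the immobilized P2X4 receptor
#' ectodomain: association rate `k_on` (1/(M s)), dissociation rate `k_off`
#' (1/s) and equilibrium constant `K_D` (M) from 1:1 kinetic analysis.
#' Thirteen cannabinoids are binders; the fifteen compounds with no
#' measurable concentration-dependent response carry `NA` rates and
#' `not_detectable = TRUE` (reported as "n.d.").
#'
#' @return A tibble with columns `compound_name`, `role`
#'   (control | cannabinoid), `k_on`, `k_off`, `K_D`, `not_detectable`.
#' @seealso [p2x4_competition()] for the competition measurements.
#' @export
p2x4_panel <- function() {
  binders <- tibble(
    compound_name = c("BX430", "5-BDBD", "CBD", "THCV", "CBGVA",
                      "D8-THCA-A", "CBV", "CBGA", "CBGV", "CBGOA",
                      "THCA-A", "CBND", "CBDV", "11-OH-THC", "6a-OH-CBD"),
    role = c("control", "control", rep("cannabinoid", 13)),
    k_on = c(1.099e5, 2.882e4, 1.922e4, 2175, 1892, 1063, 2474, 823.5,
             8446, 2725, 865.5, 1522, 1.209e4, 1.176e4, 1267),
    k_off = c(0.4947, 0.2246, 0.01998, 0.03374, 0.1741, 0.08122, 0.04054,
              0.1186, 0.02626, 0.3746, 0.1009, 0.1282, 0.1198, 0.07422,
              0.4273),
    K_D = c(4.500e-6, 7.795e-6, 1.039e-6, 1.552e-5, 9.200e-5, 7.640e-5,
            1.638e-5, 1.441e-4, 3.110e-6, 1.375e-4, 1.166e-4, 8.420e-5,
            9.908e-6, 6.311e-6, 3.374e-4),
    not_detectable = FALSE)
  nonbinders <- tibble(
    compound_name = c("CBDAME", "THCB", "CBN", "CBT",
                      "11-nor-9-carboxy-THC", "CBC", "CBDA", "CBCV",
                      "Varinolic acid", "CBL", "CBGM", "CBG", "CBDB",
                      "CBDP", "THCP"),
    role = "cannabinoid",
    k_on = NA_real_, k_off = NA_real_, K_D = NA_real_,
    not_detectable = TRUE)
  dplyr::bind_rows(binders, nonbinders)
}

#' Reported competition measurements on P2X4
#'
#' The three fully quantified competitive-binding experiments from the
#' published P2X4 study: single-analyte responses `RU_a`, `RU_b`, the
#' combined-injection response `RU_ab`, and the reported theoretical
#' competitive prediction for each pair (all analytes at 1 uM per
#' component, per-pair reported values). `reported_label` is the published
#' verdict.
#'
#' @return A tibble ready for [classify_competition()], one row per pair.
#' @export
p2x4_competition <- function() {
  tibble(
    analyte_a = c("BX430", "CBD", "CBV"),
    analyte_b = c("5-BDBD", "5-BDBD", "5-BDBD"),
    C_a_M = 1e-6, C_b_M = 1e-6,
    KD_a_M = c(4.500e-6, 1.039e-6, 1.638e-5),
    KD_b_M = 7.795e-6,
    RU_a = c(22.5, 6.9, 0.9),
    RU_b = c(34.9, 5.8, 6.4),
    RU_ab = c(39.3, 6.9, 2.1),
    theoretical_competitive = c(17.2, 6.7, 4.37),
    reported_label = c("non_competitive", "competitive", "competitive"))
}
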
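# S-index scoring: EFF, S, delta-S, delta-pAC50, delta-pAUC.
#
# All logarithms are base 10: the deposited LAC50 is log10 molar, and the
# 0.5 / 0.3 prioritization thresholds read as ~3-fold and ~2-fold arithmetic
# changes only in base 10.

#' Curve effectiveness: span between the response asymptotes
#'
#' `EFF = ZERO - INF`, the asymptote maximum (response extrapolated to zero
#' concentration) minus the asymptote minimum (extrapolated to infinite
#' concentration), in % of DMSO control. Positive for inhibitory curves;
#' zero means no concentration-response and negative means a rising
#' (stimulatory) curve — both leave the S index undefined.
#'
#' @param asym_zero,asym_inf Numeric vectors of asymptotes, % control.
#' @return Numeric vector `asym_zero - asym_inf` (`NA` where either side is
#'   missing).
#' @examples
#' effectiveness(100, 0) # 100
#' effectiveness(95, 20) # 75
#' @export
effectiveness <- function(asym_zero, asym_inf) {
  out <- ifelse(is.finite(asym_zero) & is.finite(asym_inf),
    asym_zero - asym_inf, NA_real_)
  as.numeric(out)
}

#' The S index: log10 of effectiveness over potency
#'
#' `S = log10(EFF / AC50)` combines effectiveness (% control) and potency
#' (AC50 in uM) into one value per compound per cell line. S is undefined
#' (returned `NA`, never -Inf) when `EFF <= 0` or `AC50 <= 0`. The magnitude
#' of S depends on the units of response and concentration, but differences
#' of S between cell lines do not.
#'
#' @param eff Effectiveness, % control (from [effectiveness()]).
#' @param ac50_um AC50 in uM (from [lac50_to_ac50()]).
#' @return Numeric vector of S values; `NA` where undefined.
#' @examples
#' s_score(100, 1)    # 2
#' s_score(75, 0.5)   # log10(150)
#' @export
s_score <- function(eff, ac50_um) {
  ok <- is.finite(eff) & is.finite(ac50_um) & eff > 0 & ac50_um > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log10(eff[ok] / ac50_um[ok])
  out
}

#' Pairwise reference-minus-test differences
#'
#' `delta_s()` is `S_ref - S_test`: positive when the test line responds
#' less than the reference (drug resistant), negative when it responds more
#' (drug sensitive). `delta_pac50()` returns the relative potency
#' `delta_ac50 = log10(AC50_ref / AC50_test)` and its negative `delta_pac50`;
#' `delta_pauc()` is the analogous `-log10(AUC_ref / AUC_test)`. All three
#' share the orientation that negative values mean the test line is the more
#' affected one. `NA` propagates for undefined inputs (nonpositive AUC or
#' AC50, undefined S).
#'
#' @param s_ref,s_test S indices of the reference and test lines.
#' @return Numeric vector.
#' @examples
#' delta_s(2, 2.5) # -0.5: test line sensitive, ~3.16-fold
#' @export
delta_s <- function(s_ref, s_test) {
  as.numeric(ifelse(is.finite(s_ref) & is.finite(s_test), s_ref - s_test, NA_real_))
}

#' @rdname delta_s
#' @param ac50_ref_um,ac50_test_um AC50 values in uM, positive.
#' @return For `delta_pac50()`: a tibble with columns `delta_ac50` and
#'   `delta_pac50 = -delta_ac50`.
#' @export
delta_pac50 <- function(ac50_ref_um, ac50_test_um) {
  ok <- is.finite(ac50_ref_um) & is.finite(ac50_test_um) &
    ac50_ref_um > 0 & ac50_test_um > 0
  d <- as.numeric(ifelse(ok, log10(ac50_ref_um / ac50_test_um), NA_real_))
  tibble::tibble(delta_ac50 = d, delta_pac50 = -d)
}

#' @rdname delta_s
#' @param auc_ref,auc_test Areas under the response curve, positive.
#' @export
delta_pauc <- function(auc_ref, auc_test) {
  ok <- is.finite(auc_ref) & is.finite(auc_test) & auc_ref > 0 & auc_test > 0
  as.numeric(ifelse(ok, -log10(auc_ref / auc_test), NA_real_))
}

#' Score each (compound, cell line) record of a pre-fitted table
#'
#' Adds effectiveness, AC50 in uM, the S index and quality flags to a
#' pre-fitted screen table. Flags (comma-joined in the `flags` column):
#' `missing` (absent LAC50 or asymptote), `no_response` (EFF = 0),
#' `stimulatory` (EFF < 0). S is present exactly when EFF > 0, AC50 > 0 and
#' no disqualifying flag is set.
#'
#' @param data Pre-fitted tibble with columns `compound`, `cell_line`,
#'   `lac50`, `asym_zero`, `asym_inf` (e.g. from [read_screen()] or
#'   [fit_screen()]).
#' @return The input with added columns `eff`, `ac50_um`, `s`, `flags`.
#' @export
score_lines <- function(data) {
  stopifnot(all(c("compound", "cell_line", "lac50", "asym_zero", "asym_inf")
    %in% names(data)))
  data |>
    dplyr::mutate(
      eff = effectiveness(.data$asym_zero, .data$asym_inf),
      ac50_um = lac50_to_ac50(.data$lac50),
      flags = "",
      flags = add_flag(.data$flags, "missing",
        !is.finite(.data$lac50) | is.na(.data$eff)),
      flags = add_flag(.data$flags, "no_response",
        !is.na(.data$eff) & .data$eff == 0),
      flags = add_flag(.data$flags, "stimulatory",
        !is.na(.data$eff) & .data$eff < 0),
      s = ifelse(.data$flags == "", s_score(.data$eff, .data$ac50_um), NA_real_)
    )
}

#' Score a screen against a designated reference cell line
#'
#' Produces one row per (compound, test cell line) pair with the pairwise
#' differences delta-S, delta-pAC50 and delta-pAUC against the reference,
#' plus the sensitivity call: `resistant` when delta-S > 0, `sensitive` when
#' delta-S < 0, `indeterminate` when delta-S is exactly 0 or undefined
#' (with the reason recorded: `ref_no_response`, `test_no_response`, `both`,
#' or `missing` when a side has no record or no fit).
#'
#' @param data Pre-fitted tibble (scored on the fly with [score_lines()] if
#'   the `s` column is absent). Needs a `tauc` column for delta-pAUC;
#'   otherwise that endpoint is `NA`.
#' @param reference Name of the reference cell line; must be present.
#' @return A tibble, one row per compound x test line, with columns
#'   `compound`, `target`, `reference_cell_line`, `test_cell_line`,
#'   `eff_ref`, `eff_test`, `ac50_ref_um`, `ac50_test_um`, `s_ref`, `s_test`,
#'   `r2_ref`, `r2_test`, `delta_s`, `delta_ac50`, `delta_pac50`,
#'   `delta_pauc`, `call`, `reason`, `flags`.
#' @export
score_screen <- function(data, reference) {
  if (!"s" %in% names(data)) data <- score_lines(data)
  if (!"tauc" %in% names(data)) data$tauc <- NA_real_
  if (!"target" %in% names(data)) data$target <- NA_character_
  if (!"r2" %in% names(data)) data$r2 <- NA_real_
  if (!reference %in% data$cell_line) {
    abort(sprintf("Reference cell line '%s' not present in the table.", reference),
      class = "sindex_reference_error")
  }
  keep <- c("compound", "target", "eff", "ac50_um", "s", "r2", "tauc", "flags")
  ref <- data |>
    dplyr::filter(.data$cell_line == reference) |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::rename_with(~ paste0(.x, "_ref"), -c("compound", "target"))
  test <- data |>
    dplyr::filter(.data$cell_line != reference) |>
    dplyr::rename(test_cell_line = "cell_line") |>
    dplyr::select(dplyr::all_of(c("compound", "test_cell_line", keep[-(1:2)]))) |>
    dplyr::rename_with(~ paste0(.x, "_test"), -c("compound", "test_cell_line"))
  # full join so compounds missing on either side stay visible as indeterminate
  pairs <- tidyr::expand_grid(
    compound = unique(data$compound),
    test_cell_line = setdiff(unique(data$cell_line), reference)
  ) |>
    dplyr::left_join(dplyr::distinct(data[, c("compound", "target")]),
      by = "compound") |>
    dplyr::left_join(ref |> dplyr::select(-"target"), by = "compound") |>
    dplyr::left_join(test, by = c("compound", "test_cell_line"))

  pairs |>
    dplyr::mutate(
      delta_s = delta_s(.data$s_ref, .data$s_test),
      delta_ac50 = delta_pac50(.data$ac50_um_ref, .data$ac50_um_test)$delta_ac50,
      delta_pac50 = -.data$delta_ac50,
      delta_pauc = delta_pauc(.data$tauc_ref, .data$tauc_test),
      call = dplyr::case_when(
        is.na(.data$delta_s) ~ "indeterminate",
        .data$delta_s > 0 ~ "resistant",
        .data$delta_s < 0 ~ "sensitive",
        TRUE ~ "indeterminate"
      ),
      reason = dplyr::case_when(
        !is.na(.data$delta_s) ~ NA_character_,
        (is.na(.data$s_ref) & has_flag(.data$flags_ref, "no_response")) &
          (is.na(.data$s_test) & has_flag(.data$flags_test, "no_response")) ~ "both",
        is.na(.data$s_ref) & has_flag(.data$flags_ref, "no_response") ~ "ref_no_response",
        is.na(.data$s_test) & has_flag(.data$flags_test, "no_response") ~ "test_no_response",
        TRUE ~ "missing"
      ),
      flags = paste0(
        ifelse(is.na(.data$flags_ref) | .data$flags_ref == "", "",
          paste0("ref:", gsub(",", ",ref:", .data$flags_ref))),
        ifelse(
          (is.na(.data$flags_ref) | .data$flags_ref == "") |
            (is.na(.data$flags_test) | .data$flags_test == ""), "", ","),
        ifelse(is.na(.data$flags_test) | .data$flags_test == "", "",
          paste0("test:", gsub(",", ",test:", .data$flags_test)))
      )
    ) |>
    dplyr::rename(
      eff_ref = "eff_ref", eff_test = "eff_test",
      ac50_ref_um = "ac50_um_ref", ac50_test_um = "ac50_um_test",
      r2_ref = "r2_ref", r2_test = "r2_test"
    ) |>
    dplyr::mutate(reference_cell_line = reference, .after = "target") |>
    dplyr::select(-dplyr::any_of(c("tauc_ref", "tauc_test", "flags_ref", "flags_test")))
}
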
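# Per-compound aggregation across test cell lines, prioritization filters,
# endpoint correlations and rank comparison.

#' Aggregate pairwise delta-S into per-compound summaries
#'
#' Computes, per compound across test cell lines, the delta-S mean (a simple
#' arithmetic mean over the lines where delta-S is defined), the sample
#' variance of those delta-S values, and the variance of the mean
#' (variance / n). Indeterminate lines are excluded from `n_lines` and
#' counted in `n_indeterminate`. Per-endpoint means of delta-pAC50 and
#' delta-pAUC are computed the same way for rank comparison.
#'
#' @param deltas Pairwise tibble from [score_screen()].
#' @return A tibble, one row per compound: `compound`, `target`, `n_lines`,
#'   `n_indeterminate`, `ds_mean`, `ds_variance`, `ds_variance_of_mean`,
#'   `dpac50_mean`, `dpauc_mean`, `min_r2_test`, `ref_no_response`,
#'   `r2_ref`. Variance fields are `NA` when fewer than 2 lines are defined;
#'   `ds_mean` is `NA` when none are.
#' @examples
#' # four test lines:
#' d <- tibble::tibble(
#'   compound = "a", target = NA_character_, test_cell_line = letters[1:4],
#'   delta_s = c(-0.5, -0.7, -0.6, -0.8), delta_pac50 = 0, delta_pauc = 0,
#'   r2_ref = 1, r2_test = 1, flags = ""
#' )
#' summarize_compounds(d)$ds_mean # -0.65
#' @export
summarize_compounds <- function(deltas) {
  stopifnot(all(c("compound", "delta_s") %in% names(deltas)))
  for (col in c("target", "delta_pac50", "delta_pauc", "r2_test", "r2_ref", "reason")) {
    if (!col %in% names(deltas)) deltas[[col]] <- NA
  }
  deltas |>
    dplyr::group_by(.data$compound, .data$target) |>
    dplyr::summarise(
      n_lines = sum(is.finite(.data$delta_s)),
      n_indeterminate = sum(!is.finite(.data$delta_s)),
      ds_mean = if (n_lines >= 1) mean(.data$delta_s, na.rm = TRUE) else NA_real_,
      ds_variance = if (n_lines >= 2) var(.data$delta_s[is.finite(.data$delta_s)]) else NA_real_,
      ds_variance_of_mean = ds_variance / n_lines,
      dpac50_mean = if (any(is.finite(.data$delta_pac50)))
        mean(.data$delta_pac50[is.finite(.data$delta_pac50)]) else NA_real_,
      dpauc_mean = if (any(is.finite(.data$delta_pauc)))
        mean(.data$delta_pauc[is.finite(.data$delta_pauc)]) else NA_real_,
      min_r2_test = if (any(is.finite(.data$r2_test)))
        min(.data$r2_test[is.finite(.data$r2_test)]) else NA_real_,
      n_r2_test = sum(is.finite(.data$r2_test)),
      mean_r2_test = if (any(is.finite(.data$r2_test)))
        mean(.data$r2_test[is.finite(.data$r2_test)]) else NA_real_,
      r2_ref = .data$r2_ref[1],
      ref_no_response = any(.data$reason %in% c("ref_no_response", "both")),
      .groups = "drop"
    )
}

#' Apply the prioritization filters to compound summaries
#'
#' A compound is prioritized when all of the following hold, with every
#' predicate recorded in the returned audit columns:
#'
#' 1. **Fit quality**: R^2 >= `r2_threshold` in every test cell line, and in
#'    the reference line — except reference records with no
#'    concentration-response, which are exempt. With `r2_mode = "mean"` the
#'    test-line requirement is on the mean R^2 instead.
#' 2. **Effect size**: |delta-S mean| > `ds_mean_threshold` (0.5 ~ 3-fold on
#'    an arithmetic scale); the sign sets the verdict direction.
#' 3. **Non-inferiority**: |delta-S mean| - sqrt(variance of the mean) >=
#'    `variance_floor` (0.3 ~ 2-fold), so the lower bound of the effect
#'    clears the margin.
#'
#' Compounds with delta-S defined in fewer than `n_required_lines` test
#' lines are excluded with reason `missing_fit` (compounds dropped for a
#' single missing or inconsistent cell line, rather than failing a filter).
#'
#' @param summaries Tibble from [summarize_compounds()].
#' @param r2_threshold Minimum R^2 (default 0.8).
#' @param ds_mean_threshold Threshold on |delta-S mean| (default 0.5).
#' @param variance_floor Non-inferiority margin (default 0.3).
#' @param n_required_lines Number of test lines that must have a defined
#'   delta-S; defaults to the maximum `n_lines + n_indeterminate` observed.
#' @param r2_mode `"per_line"` (default) or `"mean"` for the test-line R^2
#'   requirement.
#' @return `summaries` with added logical audit columns `complete_ok`,
#'   `r2_ok`, `effect_ok`, `noninferiority_ok` and a `verdict` column in
#'   `{sensitive_prioritized, resistant_prioritized, not_prioritized,
#'   excluded}` plus `verdict_reason`.
#' @export
prioritize_compounds <- function(summaries, r2_threshold = 0.8,
                                 ds_mean_threshold = 0.5, variance_floor = 0.3,
                                 n_required_lines = NULL,
                                 r2_mode = c("per_line", "mean")) {
  r2_mode <- match.arg(r2_mode)
  assert_scalar_number(r2_threshold, "r2_threshold", positive = TRUE)
  assert_scalar_number(ds_mean_threshold, "ds_mean_threshold", positive = TRUE)
  assert_scalar_number(variance_floor, "variance_floor", positive = TRUE)
  n_required_lines <- n_required_lines %||%
    max(summaries$n_lines + summaries$n_indeterminate, 0L)

  summaries |>
    dplyr::mutate(
      complete_ok = .data$n_lines >= n_required_lines,
      r2_test_ok = dplyr::case_when(
        .data$n_r2_test < .data$n_lines ~ FALSE,
        r2_mode == "per_line" ~ is.finite(.data$min_r2_test) &
          .data$min_r2_test >= r2_threshold,
        TRUE ~ is.finite(.data$mean_r2_test) & .data$mean_r2_test >= r2_threshold
      ),
      r2_ref_ok = .data$ref_no_response |
        (is.finite(.data$r2_ref) & .data$r2_ref >= r2_threshold),
      r2_ok = .data$r2_test_ok & .data$r2_ref_ok,
      effect_ok = is.finite(.data$ds_mean) & abs(.data$ds_mean) > ds_mean_threshold,
      noninferiority_ok = is.finite(.data$ds_mean) &
        is.finite(.data$ds_variance_of_mean) &
        (abs(.data$ds_mean) - sqrt(.data$ds_variance_of_mean)) >= variance_floor,
      verdict = dplyr::case_when(
        .data$n_lines == 0 ~ "excluded",
        !.data$complete_ok ~ "excluded",
        !(.data$r2_ok & .data$effect_ok & .data$noninferiority_ok) ~ "not_prioritized",
        .data$ds_mean < 0 ~ "sensitive_prioritized",
        TRUE ~ "resistant_prioritized"
      ),
      verdict_reason = dplyr::case_when(
        .data$n_lines == 0 ~ "no_data",
        !.data$complete_ok ~ "missing_fit",
        .data$verdict != "not_prioritized" ~ NA_character_,
        !.data$r2_ok ~ "r2_below_threshold",
        !.data$effect_ok ~ "effect_below_threshold",
        TRUE ~ "non_inferiority"
      )
    )
}

#' Difference of group delta-S means (multiple controls)
#'
#' With several control and tumor cell lines scored against one common
#' reference, `delta_delta_s()` is the unweighted difference of the group
#' delta-S means: `ddS = dS_mean(tumor) - dS_mean(control)`.
#'
#' @param ds_mean_tumor,ds_mean_control Delta-S means (numeric vectors).
#' @return `ds_mean_tumor - ds_mean_control`.
#' @examples
#' delta_delta_s(-1.0, -0.2) # -0.8
#' @export
delta_delta_s <- function(ds_mean_tumor, ds_mean_control) {
  as.numeric(ifelse(is.finite(ds_mean_tumor) & is.finite(ds_mean_control),
    ds_mean_tumor - ds_mean_control, NA_real_))
}

#' @rdname delta_delta_s
#' @param deltas Pairwise tibble from [score_screen()] (all lines scored
#'   against the same reference).
#' @param tumor_lines,control_lines Character vectors of test cell-line
#'   names forming the two groups.
#' @return For `delta_delta_s_groups()`: a tibble per compound with
#'   `ds_mean_tumor`, `ds_mean_control` (unweighted means of the member
#'   lines' delta-S) and `delta_delta_s`.
#' @export
delta_delta_s_groups <- function(deltas, tumor_lines, control_lines) {
  bad <- setdiff(c(tumor_lines, control_lines), deltas$test_cell_line)
  if (length(bad) > 0) {
    abort(paste0("Cell lines not in the scored table: ", paste(bad, collapse = ", ")))
  }
  if ("reference_cell_line" %in% names(deltas) &&
      dplyr::n_distinct(deltas$reference_cell_line) > 1) {
    abort("All rows must share one designated reference cell line.")
  }
  grp_mean <- function(d, lines) {
    d |>
      dplyr::filter(.data$test_cell_line %in% lines, is.finite(.data$delta_s)) |>
      dplyr::group_by(.data$compound, .data$test_cell_line) |>
      dplyr::summarise(ds = mean(.data$delta_s), .groups = "drop") |>
      dplyr::group_by(.data$compound) |>
      dplyr::summarise(m = mean(.data$ds), .groups = "drop")
  }
  dplyr::full_join(
    grp_mean(deltas, tumor_lines) |> dplyr::rename(ds_mean_tumor = "m"),
    grp_mean(deltas, control_lines) |> dplyr::rename(ds_mean_control = "m"),
    by = "compound"
  ) |>
    dplyr::mutate(delta_delta_s = delta_delta_s(.data$ds_mean_tumor,
      .data$ds_mean_control))
}

#' Squared Pearson correlations between scoring endpoints
#'
#' Pairwise r^2 (square of the Pearson product-moment correlation) between
#' delta-S, delta-pAC50 and delta-pAUC across compounds, per test cell line
#' or pooled. Incomplete pairs are dropped listwise within each cell of the
#' matrix and the remaining n is reported; cells with fewer than `min_n`
#' complete pairs or zero variance are `NA`.
#'
#' @param deltas Pairwise tibble from [score_screen()].
#' @param by `"cell_line"` (default) or `"pooled"`.
#' @param min_n Minimum complete pairs per cell (default 3).
#' @return A tibble with `cell_line` (or `"pooled"`), `endpoint_x`,
#'   `endpoint_y`, `r2`, `n`.
#' @export
endpoint_correlation <- function(deltas, by = c("cell_line", "pooled"), min_n = 3) {
  by <- match.arg(by)
  endpoints <- c(delta_s = "delta_s", delta_pac50 = "delta_pac50",
    delta_pauc = "delta_pauc")
  stopifnot(all(endpoints %in% names(deltas)))
  groups <- if (by == "cell_line") split(deltas, deltas$test_cell_line)
    else list(pooled = deltas)
  purrr::imap(groups, function(d, nm) {
    combos <- utils::combn(names(endpoints), 2, simplify = FALSE)
    purrr::map(combos, function(pr) {
      x <- d[[endpoints[pr[1]]]]
      y <- d[[endpoints[pr[2]]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      r2 <- if (n >= min_n && var(x[ok]) > 0 && var(y[ok]) > 0) {
        cor(x[ok], y[ok])^2
      } else {
        NA_real_
      }
      tibble::tibble(cell_line = nm, endpoint_x = pr[1], endpoint_y = pr[2],
        r2 = r2, n = n)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Rank compounds under the three endpoint means
#'
#' Ranks compounds ascending under each of the delta-S mean, delta-pAC50
#' mean and delta-pAUC mean (rank 1 = most negative = most sensitising;
#' ties get average ranks; undefined endpoints get `NA` ranks).
#'
#' @param summaries Tibble from [summarize_compounds()] (needs `ds_mean`,
#'   `dpac50_mean`, `dpauc_mean`).
#' @return A tibble with `compound`, the three endpoint means and
#'   `rank_ds_mean`, `rank_dpac50_mean`, `rank_dpauc_mean`.
#' @export
rank_endpoints <- function(summaries) {
  stopifnot(nrow(summaries) >= 2)
  rk <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- is.finite(x)
    out[ok] <- rank(x[ok], ties.method = "average")
    out
  }
  summaries |>
    dplyr::select(dplyr::all_of(c("compound", "ds_mean", "dpac50_mean", "dpauc_mean"))) |>
    dplyr::mutate(
      rank_ds_mean = rk(.data$ds_mean),
      rank_dpac50_mean = rk(.data$dpac50_mean),
      rank_dpauc_mean = rk(.data$dpauc_mean)
    )
}

#' @rdname rank_endpoints
#' @param ranks Tibble from `rank_endpoints()`.
#' @return For `rank_concordance()`: a tibble of pairwise Spearman rank
#'   correlations between the endpoints (complete pairs only).
#' @export
rank_concordance <- function(ranks) {
  cols <- c(ds_mean = "rank_ds_mean", dpac50_mean = "rank_dpac50_mean",
    dpauc_mean = "rank_dpauc_mean")
  combos <- utils::combn(names(cols), 2, simplify = FALSE)
  purrr::map(combos, function(pr) {
    x <- ranks[[cols[pr[1]]]]
    y <- ranks[[cols[pr[2]]]]
    ok <- is.finite(x) & is.finite(y)
    rho <- if (sum(ok) >= 2 && var(x[ok]) > 0 && var(y[ok]) > 0) {
      cor(x[ok], y[ok], method = "spearman")
    } else {
      NA_real_
    }
    tibble::tibble(endpoint_x = pr[1], endpoint_y = pr[2],
      spearman = rho, n = sum(ok))
  }) |> purrr::list_rbind()
}

#' Ordered delta-S values and threshold exceedance counts for one test line
#'
#' Sorts the delta-S values of one test cell line from low to high and
#' counts how many fall below `-threshold`, within `[-threshold, threshold]`
#' and above `threshold` — the waterfall summary used to mark biologically
#' meaningful sensitivity/resistance.
#'
#' @param deltas Pairwise tibble from [score_screen()].
#' @param cell_line Test cell line to summarise; `NULL` (default) pools all.
#' @param threshold Symmetric delta-S threshold (default 0.5).
#' @return A list with `values` (sorted finite delta-S), `n_below`,
#'   `n_within`, `n_above` (summing to `length(values)`), `threshold`.
#' @export
ds_distribution <- function(deltas, cell_line = NULL, threshold = 0.5) {
  d <- deltas
  if (!is.null(cell_line)) {
    d <- dplyr::filter(d, .data$test_cell_line == cell_line)
  }
  if (nrow(d) == 0) abort("No delta-S rows for the requested cell line.")
  v <- sort(d$delta_s[is.finite(d$delta_s)])
  list(
    values = v,
    n_below = sum(v < -threshold),
    n_within = sum(v >= -threshold & v <= threshold),
    n_above = sum(v > threshold),
    threshold = threshold
  )
}
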
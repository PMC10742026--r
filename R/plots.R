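# ggplot2 views of fits, delta-S distributions and rank comparisons.

#' @export
autoplot.fit4pl <- function(object, ...) {
  if (!isTRUE(object$converged)) {
    abort("Cannot plot a non-converged 4PL fit.")
  }
  d <- object$data
  grid <- tibble::tibble(
    conc_um = 10^seq(log10(min(d$conc_um)), log10(max(d$conc_um)),
      length.out = 200)
  )
  grid$response <- predict(object, grid$conc_um)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_um, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (µM)", y = "Response (% DMSO control)",
      subtitle = sprintf("AC50 = %.3g µM, EFF = %.1f, R² = %.3f",
        10^(object$lac50 + 6), object$asym_zero - object$asym_inf, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of ordered delta-S values for one test line
#'
#' Orders delta-S from low to high and marks the symmetric threshold beyond
#' which differences are treated as biologically meaningful (~3-fold at
#' 0.5).
#'
#' @param deltas Pairwise tibble from [score_screen()].
#' @param cell_line Test cell line to plot; `NULL` pools all lines.
#' @param threshold Symmetric delta-S threshold (default 0.5).
#' @return A ggplot object.
#' @export
plot_ds_distribution <- function(deltas, cell_line = NULL, threshold = 0.5) {
  dist <- ds_distribution(deltas, cell_line = cell_line, threshold = threshold)
  d <- tibble::tibble(rank = seq_along(dist$values), delta_s = dist$values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$delta_s)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
      linetype = "dotted") +
    ggplot2::labs(
      x = "Compounds, ordered by ΔS", y = "ΔS",
      subtitle = sprintf("%d sensitive (< -%.1f), %d within, %d resistant (> %.1f)",
        dist$n_below, threshold, dist$n_within, dist$n_above, threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Bump plot comparing compound ranks across endpoints
#'
#' Shows each compound's rank under the delta-S mean, delta-pAC50 mean and
#' delta-pAUC mean (rank 1 = most sensitising), connecting the same
#' compound across endpoints so rank displacement is visible.
#'
#' @param ranks Tibble from [rank_endpoints()].
#' @return A ggplot object.
#' @export
plot_rank_comparison <- function(ranks) {
  long <- ranks |>
    dplyr::select(dplyr::all_of(c("compound", "rank_ds_mean",
      "rank_dpac50_mean", "rank_dpauc_mean"))) |>
    tidyr::pivot_longer(-"compound", names_to = "endpoint",
      values_to = "rank") |>
    dplyr::mutate(endpoint = factor(.data$endpoint,
      levels = c("rank_dpac50_mean", "rank_dpauc_mean", "rank_ds_mean"),
      labels = c("ΔpAC50 mean", "ΔpAUC mean", "ΔS mean")))
  ggplot2::ggplot(long,
    ggplot2::aes(x = .data$endpoint, y = .data$rank, group = .data$compound)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Rank (1 = most sensitising)") +
    ggplot2::theme_minimal()
}
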
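# Four-parameter logistic fitting in log10-concentration space.
#
# Model: R(x) = asym_inf + (asym_zero - asym_inf) / (1 + 10^(hill * (x - m)))
# with x = log10(concentration, uM) and m = log10(AC50, uM). The model has an
# exact mirror degeneracy (swap asymptotes, negate hill); fits are
# canonicalised to hill >= 0 so asym_zero is always the low-dose asymptote
# and rising (stimulatory) curves show asym_inf > asym_zero.

fourpl_response <- function(x, asym_zero, asym_inf, m, hill) {
  asym_inf + (asym_zero - asym_inf) / (1 + 10^(hill * (x - m)))
}

#' Coefficient of determination against the mean-response null
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, computed on
#' raw (untransformed) responses. May be negative for fits worse than the
#' mean; `NA` when the observed responses have zero total sum of squares
#' (no concentration-response to explain).
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return A single number, or `NA` if undefined.
#' @examples
#' r_squared(c(0, 10, 20), c(0, 0, 0)) # -1.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

fit4pl_failure <- function(reason, n_points) {
  structure(
    list(
      asym_zero = NA_real_, asym_inf = NA_real_, lac50 = NA_real_,
      hill = NA_real_, r2 = NA_real_, auc = NA_real_,
      converged = FALSE, reason = reason, n_points = n_points,
      stimulatory = FALSE, data = NULL
    ),
    class = "fit4pl"
  )
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Fits `R(C) = INF + (ZERO - INF) / (1 + 10^(hill * (log10 C - log10 AC50)))`
#' to one concentration-response series by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nls.lm()]) from a deterministic multi-start:
#' `asym_zero` starts at the maximum response, `asym_inf` at the minimum,
#' `log10 AC50` at the concentration nearest the half-range response, and the
#' Hill slope at each of 0.5, 1, 2 in both directions. The lowest residual
#' sum of squares wins; ties go to the smaller |slope|.
#'
#' Bounds: asymptotes in \[-50, 250\] % control, |hill| <= 10, and log10 AC50
#' within \[log10 Cmin - 3, log10 Cmax + 3\] so the midpoint cannot run away
#' from the tested range. Fewer than 5 distinct concentrations, or a series
#' with no response variation, returns a non-converged fit with a reason
#' rather than an error.
#'
#' @param conc_um Concentrations in uM, strictly positive.
#' @param response Matched responses, % of DMSO control.
#' @param n_grid Grid size for the trapezoidal AUC over the tested
#'   log10-concentration range (default 1001).
#' @return An object of class `fit4pl`: a list with `asym_zero`, `asym_inf`
#'   (% control), `lac50` (log10 molar AC50), `hill` (>= 0 by
#'   canonicalisation), `r2`, `auc` ((% control) x log10-concentration
#'   decades over the tested range), `converged`, `reason`, `n_points`,
#'   `stimulatory` (TRUE when the curve rises with concentration) and the
#'   fitted data. Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @examples
#' conc <- 10^seq(-3, 2, length.out = 11)
#' resp <- 100 / (1 + conc / 1) # ZERO=100, INF=0, AC50=1 uM, hill=1
#' fit <- fit_4pl(conc, resp)
#' glance(fit)
#' @export
fit_4pl <- function(conc_um, response, n_grid = 1001) {
  keep <- is.finite(conc_um) & is.finite(response) & conc_um > 0
  conc_um <- conc_um[keep]
  response <- response[keep]
  o <- order(conc_um)
  conc_um <- conc_um[o]
  response <- response[o]
  n <- length(conc_um)
  if (length(unique(conc_um)) < 5) {
    return(fit4pl_failure("too few points", n))
  }
  if (diff(range(response)) == 0) {
    return(fit4pl_failure("no concentration-response", n))
  }

  x <- log10(conc_um)
  lower <- c(asym_zero = -50, asym_inf = -50, m = min(x) - 3, hill = -10)
  upper <- c(asym_zero = 250, asym_inf = 250, m = max(x) + 3, hill = 10)

  half <- (max(response) + min(response)) / 2
  m0 <- x[which.min(abs(response - half))]
  starts <- purrr::map(c(0.5, -0.5, 1, -1, 2, -2), function(h) {
    c(asym_zero = max(response), asym_inf = min(response), m = m0, hill = h)
  })

  resid_fn <- function(p) {
    response - fourpl_response(x, p[1], p[2], p[3], p[4])
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14
        )
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12 ||
        (abs(ssr - best$ssr) <= 1e-12 && abs(res$par[4]) < abs(best$par[4]))) {
      best <- list(par = res$par, ssr = ssr, info = res$info)
    }
  }
  if (is.null(best)) {
    return(fit4pl_failure("non-convergence", n))
  }

  p <- best$par
  # canonical form: hill >= 0, asym_zero = low-dose asymptote
  if (p[4] < 0) {
    p <- c(p[2], p[1], p[3], -p[4])
  }
  r2 <- r_squared(response, fourpl_response(x, p[1], p[2], p[3], p[4]))
  fit <- structure(
    list(
      asym_zero = unname(p[1]), asym_inf = unname(p[2]),
      lac50 = unname(p[3]) - 6, hill = unname(p[4]),
      r2 = r2, auc = NA_real_,
      converged = TRUE, reason = NA_character_, n_points = n,
      stimulatory = unname(p[2] > p[1]),
      data = tibble::tibble(conc_um = conc_um, response = response)
    ),
    class = "fit4pl"
  )
  fit$auc <- auc_4pl(fit, min(x), max(x), n_grid = n_grid)
  fit
}

#' Area under a fitted 4PL curve over a log10-concentration range
#'
#' Trapezoidal integral of the fitted response against log10 concentration
#' (uM) on a uniform grid; converges to the analytic integral as `n_grid`
#' grows. Units: (% control) x log10-concentration decades.
#'
#' @param fit A `fit4pl` object.
#' @param log_c_min,log_c_max Integration range in log10 uM
#'   (`log_c_min < log_c_max`).
#' @param n_grid Number of grid points (>= 2, default 1001).
#' @return The AUC, or `NA` for a non-converged fit.
#' @export
auc_4pl <- function(fit, log_c_min, log_c_max, n_grid = 1001) {
  stopifnot(inherits(fit, "fit4pl"), n_grid >= 2)
  if (!isTRUE(fit$converged)) return(NA_real_)
  if (!(log_c_min < log_c_max)) {
    abort("`log_c_min` must be strictly less than `log_c_max`.")
  }
  xs <- seq(log_c_min, log_c_max, length.out = n_grid)
  ys <- fourpl_response(xs, fit$asym_zero, fit$asym_inf, fit$lac50 + 6, fit$hill)
  trapz_uniform(ys, xs[2] - xs[1])
}

#' @export
predict.fit4pl <- function(object, conc_um = NULL, ...) {
  if (!isTRUE(object$converged)) {
    abort("Cannot predict from a non-converged 4PL fit.")
  }
  conc_um <- conc_um %||% object$data$conc_um
  fourpl_response(log10(conc_um), object$asym_zero, object$asym_inf,
    object$lac50 + 6, object$hill)
}

#' @export
tidy.fit4pl <- function(x, ...) {
  tibble::tibble(
    term = c("asym_zero", "asym_inf", "lac50", "hill"),
    estimate = c(x$asym_zero, x$asym_inf, x$lac50, x$hill)
  )
}

#' @export
glance.fit4pl <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, auc = x$auc, n_points = x$n_points,
    converged = x$converged, reason = x$reason, stimulatory = x$stimulatory
  )
}

#' @export
print.fit4pl <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<fit4pl> not converged (%s), n = %d\n", x$reason, x$n_points))
    return(invisible(x))
  }
  cat(sprintf(
    "<fit4pl> ZERO = %.2f, INF = %.2f, AC50 = %.4g uM, hill = %.3f, R2 = %.4f, AUC = %.1f\n",
    x$asym_zero, x$asym_inf, 10^(x$lac50 + 6), x$hill, x$r2, x$auc
  ))
  invisible(x)
}

#' Fit every concentration-response series in a raw screen table
#'
#' Maps [fit_4pl()] over each (compound, cell line) series of a long-form
#' raw screen table (as returned by [read_screen()] in the raw dialect) and
#' returns one row of fitted parameters per series, in the pre-fitted
#' column layout so the scoring functions apply unchanged.
#'
#' @param data Tibble with columns `compound`, `cell_line`, optional
#'   `target`, `conc_um`, `response`.
#' @param n_grid Grid size passed to [auc_4pl()] for the per-series AUC.
#' @return A tibble with one row per (compound, cell line): `lac50`, `r2`,
#'   `tauc`, `asym_zero`, `asym_inf`, `hill`, `converged`, `reason`,
#'   `n_points`, `stimulatory`, `no_fit`.
#' @export
fit_screen <- function(data, n_grid = 1001) {
  stopifnot(all(c("compound", "cell_line", "conc_um", "response") %in% names(data)))
  if (!"target" %in% names(data)) data$target <- NA_character_
  data |>
    dplyr::group_by(.data$compound, .data$cell_line, .data$target) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_4pl(d$conc_um, d$response, n_grid = n_grid)
      tibble::tibble(
        lac50 = f$lac50, r2 = f$r2, tauc = f$auc,
        asym_zero = f$asym_zero, asym_inf = f$asym_inf, hill = f$hill,
        converged = f$converged, reason = f$reason, n_points = f$n_points,
        stimulatory = f$stimulatory, no_fit = !f$converged
      )
    }) |>
    dplyr::ungroup()
}
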
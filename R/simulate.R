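# Synthetic multi-compound, multi-cell-line screens with known 4PL ground
# truth, in both file dialects, so every downstream module is testable
# without external data.

# Closed-form integral of the 4PL over log10 concentration; used for the
# ground-truth TAUC so the sidecar is exact, not gridded.
auc_4pl_exact <- function(asym_zero, asym_inf, m, hill, a, b) {
  if (hill == 0) return((asym_zero + asym_inf) / 2 * (b - a))
  # antiderivative of 1/(1 + 10^(hill (x - m)))
  f <- function(x) x - log1p(10^(hill * (x - m))) / (hill * log(10))
  asym_inf * (b - a) + (asym_zero - asym_inf) * (f(b) - f(a))
}

#' Simulate a drug screen with known ground truth
#'
#' Generates an `n_compounds` x (1 reference + `n_test_lines`) screen on a
#' log-spaced concentration grid, emulating a proliferation qHTS: responses
#' in % of DMSO control, upper asymptote near 100, and a per-compound effect
#' class applied to every test line:
#'
#' * `null` — test lines identical to the reference (true delta-S = 0).
#' * `sensitive` — test AC50 shifted down by `shift_decades` decades at
#'   equal effectiveness, so true delta-S = -shift.
#' * `resistant` — AC50 shifted up, true delta-S = +shift.
#' * `partial` — same AC50 but test effectiveness reduced to 20-50 %
#'   control, so the pair separates under delta-S while delta-pAC50 is
#'   blind to it.
#' * `stimulatory` — test upper asymptote above 100 % control (low-dose
#'   growth stimulation) with unchanged potency.
#'
#' The raw-dialect table carries responses with additive homoscedastic
#' Gaussian noise (`noise_sd` % control); the pre-fitted table carries the
#' noiseless true parameters, so scoring can be tested independently of
#' fitting; the truth sidecar carries the hidden per-line parameters, EFF,
#' S, true delta-S and class labels. The seed fully determines the output.
#'
#' @param n_compounds Number of compounds (default 50).
#' @param n_test_lines Number of test cell lines (default 4).
#' @param conc_um Concentration grid in uM (default 11 log-spaced points,
#'   1e-3 to 1e2).
#' @param class_probs Named probabilities for the effect classes, summing
#'   to 1.
#' @param shift_decades Range (length 2) of the AC50 shift, in decades, for
#'   the sensitive/resistant classes; a single value pins the shift exactly.
#' @param noise_sd Gaussian response noise, % control (default 5).
#' @param seed Integer seed (required: the screen is a reproducible object).
#' @return A list of class `synthetic_screen` with tibbles `raw` (long
#'   form: `compound`, `cell_line`, `target`, `conc_um`, `response`),
#'   `prefitted` (`compound`, `cell_line`, `target`, `lac50`, `r2`, `tauc`,
#'   `asym_zero`, `asym_inf`, `no_fit`) and `truth` (per compound x line:
#'   true parameters, `eff`, `s`, `class`, `true_delta_s`), plus
#'   `reference`, `test_lines` and the generating parameters.
#' @export
simulate_screen <- function(n_compounds = 50, n_test_lines = 4,
                            conc_um = 10^seq(-3, 2, length.out = 11),
                            class_probs = c(null = 0.4, sensitive = 0.2,
                              resistant = 0.2, partial = 0.1, stimulatory = 0.1),
                            shift_decades = c(0.6, 1.4),
                            noise_sd = 5, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (length(conc_um) < 2) abort("Concentration grid needs at least 2 points.")
  if (abs(sum(class_probs) - 1) > 1e-8) abort("`class_probs` must sum to 1.")
  classes <- c("null", "sensitive", "resistant", "partial", "stimulatory")
  if (!setequal(names(class_probs), classes)) {
    abort(paste0("`class_probs` must be named: ", paste(classes, collapse = ", ")))
  }
  if (length(shift_decades) == 1) shift_decades <- rep(shift_decades, 2)
  conc_um <- sort(conc_um)
  x <- log10(conc_um)

  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  reference <- "REF-1"
  test_lines <- sprintf("TEST-%d", seq_len(n_test_lines))
  compounds <- sprintf("CPD-%03d", seq_len(n_compounds))
  cls <- sample(classes, n_compounds, replace = TRUE,
    prob = class_probs[classes])

  truth <- purrr::map(seq_len(n_compounds), function(i) {
    zero <- rnorm(1, 100, 5)
    # partial-class compounds get a full-responder reference so the pair is
    # separated by effectiveness alone (equal AC50s)
    inf <- if (cls[i] == "partial") runif(1, 0, 10) else runif(1, 0, 60)
    # midpoint in the grid interior so the curve is observable
    m <- runif(1, x[2], x[length(x) - 1])
    hill <- runif(1, 0.5, 3)
    shift <- runif(1, shift_decades[1], shift_decades[2])
    lines <- c(reference, test_lines)
    purrr::map(lines, function(ln) {
      p <- list(zero = zero, inf = inf, m = m, hill = hill)
      if (ln != reference) {
        p <- switch(cls[i],
          null = p,
          sensitive = modifyList(p, list(m = m - shift)),
          resistant = modifyList(p, list(m = m + shift)),
          partial = modifyList(p, list(inf = zero - runif(1, 20, 50))),
          stimulatory = modifyList(p, list(zero = runif(1, 105, 130)))
        )
      }
      tibble::tibble(
        compound = compounds[i], cell_line = ln,
        target = paste0("TGT-", toupper(cls[i])),
        class = cls[i],
        asym_zero = p$zero, asym_inf = p$inf,
        lac50 = p$m - 6, hill = p$hill
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  truth <- truth |>
    dplyr::mutate(
      eff = effectiveness(.data$asym_zero, .data$asym_inf),
      ac50_um = lac50_to_ac50(.data$lac50),
      s = s_score(.data$eff, .data$ac50_um)
    ) |>
    dplyr::group_by(.data$compound) |>
    dplyr::mutate(
      true_delta_s = ifelse(.data$cell_line == reference, NA_real_,
        .data$s[.data$cell_line == reference] - .data$s)
    ) |>
    dplyr::ungroup()

  prefitted <- truth |>
    dplyr::mutate(
      r2 = 1,
      tauc = purrr::pmap_dbl(
        list(.data$asym_zero, .data$asym_inf, .data$lac50 + 6, .data$hill),
        function(z, i2, m, h) auc_4pl_exact(z, i2, m, h, min(x), max(x))
      ),
      no_fit = FALSE
    ) |>
    dplyr::select(dplyr::all_of(c("compound", "cell_line", "target", "lac50",
      "r2", "tauc", "asym_zero", "asym_inf", "no_fit")))

  raw <- truth |>
    dplyr::select(dplyr::all_of(c("compound", "cell_line", "target",
      "asym_zero", "asym_inf", "lac50", "hill"))) |>
    dplyr::mutate(points = purrr::pmap(
      list(.data$asym_zero, .data$asym_inf, .data$lac50 + 6, .data$hill),
      function(z, i2, m, h) {
        tibble::tibble(
          conc_um = conc_um,
          response = fourpl_response(x, z, i2, m, h) +
            rnorm(length(x), 0, noise_sd)
        )
      }
    )) |>
    dplyr::select(dplyr::all_of(c("compound", "cell_line", "target", "points"))) |>
    tidyr::unnest("points")

  structure(
    list(
      raw = raw, prefitted = prefitted, truth = truth,
      reference = reference, test_lines = test_lines,
      conc_um = conc_um, noise_sd = noise_sd, seed = seed,
      class_probs = class_probs[classes]
    ),
    class = "synthetic_screen"
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_screen> %d compounds x (%s + %d test lines), %d-point grid, noise sd %.1f, seed %d\n",
    dplyr::n_distinct(x$truth$compound), x$reference, length(x$test_lines),
    length(x$conc_um), x$noise_sd, x$seed
  ))
  print(table(class = x$truth$class[x$truth$cell_line == x$reference]))
  invisible(x)
}

#' Write a synthetic screen to disk
#'
#' Emits `raw.csv` (wide C0../dat0.. raw dialect), `prefitted.csv`
#' (LAC50/R2/TAUC/ZERO/INF dialect) and `truth.csv` (the hidden ground
#' truth) into `dir`.
#'
#' @param screen A `synthetic_screen` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- screen$raw |>
    dplyr::group_by(.data$compound, .data$cell_line, .data$target) |>
    dplyr::mutate(.k = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      names_from = ".k",
      values_from = c("conc_um", "response"),
      names_glue = "{ifelse(.value == 'conc_um', 'C', 'dat')}{.k}"
    )
  readr::write_csv(wide, file.path(dir, "raw.csv"))
  write_screen_results(screen$prefitted, file.path(dir, "prefitted.csv"),
    layout = "prefitted", precision = 10)
  readr::write_csv(screen$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Run the full pipeline on a synthetic screen and compare to truth
#'
#' Fits the noisy raw data, scores against the reference, summarises,
#' prioritizes, and joins the verdicts back onto the hidden class labels:
#' the pipeline's integration check. A compound counts as recalled when its
#' verdict direction matches its class (`sensitive` ->
#' `sensitive_prioritized`, `resistant` -> `resistant_prioritized`).
#'
#' @param screen A `synthetic_screen` object.
#' @param use_prefitted Skip the fitting stage and score the noiseless true
#'   parameters instead (default `FALSE`).
#' @param r2_threshold,ds_mean_threshold,variance_floor Passed to
#'   [prioritize_compounds()].
#' @return A list of class `recovery_report`: `per_compound` (class, true
#'   and estimated delta-S mean, verdict, `recalled`), `confusion` (counts
#'   by class x verdict), `delta_s_error` (distribution summary of
#'   estimated minus true delta-S), `recall` (per prioritizable class).
#' @export
end_to_end_recovery <- function(screen, use_prefitted = FALSE,
                                r2_threshold = 0.8, ds_mean_threshold = 0.5,
                                variance_floor = 0.3) {
  stopifnot(inherits(screen, "synthetic_screen"))
  prefitted <- if (use_prefitted) {
    screen$prefitted
  } else {
    fit_screen(screen$raw)
  }
  deltas <- score_screen(prefitted, screen$reference)
  summaries <- summarize_compounds(deltas)
  verdicts <- prioritize_compounds(summaries,
    r2_threshold = r2_threshold, ds_mean_threshold = ds_mean_threshold,
    variance_floor = variance_floor,
    n_required_lines = length(screen$test_lines))

  truth_cpd <- screen$truth |>
    dplyr::filter(.data$cell_line != screen$reference) |>
    dplyr::group_by(.data$compound, .data$class) |>
    dplyr::summarise(true_ds_mean = mean(.data$true_delta_s), .groups = "drop")

  per_compound <- verdicts |>
    dplyr::select(dplyr::all_of(c("compound", "ds_mean", "ds_variance_of_mean",
      "n_lines", "verdict", "verdict_reason"))) |>
    dplyr::left_join(truth_cpd, by = "compound") |>
    dplyr::mutate(recalled = (.data$class == "sensitive" &
        .data$verdict == "sensitive_prioritized") |
      (.data$class == "resistant" & .data$verdict == "resistant_prioritized"))

  err <- deltas |>
    dplyr::left_join(
      screen$truth |>
        dplyr::select(dplyr::all_of(c("compound", "cell_line", "true_delta_s"))),
      by = c("compound", "test_cell_line" = "cell_line")
    ) |>
    dplyr::filter(is.finite(.data$delta_s), is.finite(.data$true_delta_s)) |>
    dplyr::mutate(error = .data$delta_s - .data$true_delta_s)

  recall <- per_compound |>
    dplyr::filter(.data$class %in% c("sensitive", "resistant")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), n_recalled = sum(.data$recalled),
      recall = n_recalled / n, .groups = "drop")

  structure(
    list(
      per_compound = per_compound,
      confusion = dplyr::count(per_compound, .data$class, .data$verdict),
      delta_s_error = tibble::tibble(
        n = nrow(err),
        mean_abs_error = mean(abs(err$error)),
        median_abs_error = median(abs(err$error)),
        max_abs_error = max(abs(err$error))
      ),
      recall = recall
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$recall)
  print(x$delta_s_error)
  invisible(x)
}
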
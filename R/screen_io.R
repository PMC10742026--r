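#' Convert log10 molar AC50 to AC50 in micromolar
#'
#' Screen deposits store potency as `LAC50`, the log10 of the AC50 in molar
#' units. Scoring works in micromolar, so the conversion is
#' `AC50_uM = 10^(lac50 + 6)`. Non-finite inputs (no-fit records) propagate
#' as `NA` rather than a numeric sentinel.
#'
#' @param lac50 Numeric vector of log10 molar AC50 values.
#' @return Numeric vector of AC50 values in uM; `NA` where `lac50` is not
#'   finite.
#' @examples
#' lac50_to_ac50(-6) # 1 uM
#' lac50_to_ac50(-9) # 1 nM = 0.001 uM
#' @export
lac50_to_ac50 <- function(lac50) {
  out <- ifelse(is.finite(lac50), 10^(lac50 + 6), NA_real_)
  as.numeric(out)
}

#' @rdname lac50_to_ac50
#' @param ac50_um Numeric vector of AC50 values in uM (strictly positive).
#' @export
ac50_to_lac50 <- function(ac50_um) {
  out <- ifelse(is.finite(ac50_um) & ac50_um > 0, log10(ac50_um) - 6, NA_real_)
  as.numeric(out)
}

# Canonical column synonyms, matched case-insensitively after squashing
# spaces/dots to underscores. The deposited files' exact header spelling is
# not fixed, so every canonical name can be remapped via `column_map`.
default_column_synonyms <- function() {
  list(
    compound  = c("compound", "drug", "drug_name", "compound_name", "name"),
    cell_line = c("cell_line", "cell_line_name", "cell", "cellline"),
    target    = c("target", "drug_target", "target_annotation"),
    lac50     = c("lac50", "log_ac50", "logac50"),
    r2        = c("r2", "rsq", "r_squared"),
    tauc      = c("tauc", "auc", "total_auc"),
    asym_zero = c("zero", "asym_zero", "asymptote_maximum"),
    asym_inf  = c("inf", "asym_inf", "asymptote_minimum")
  )
}

normalise_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ .\\-]+", "_", x)
}

resolve_columns <- function(headers, column_map = NULL) {
  norm <- normalise_header(headers)
  syn <- default_column_synonyms()
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), c(names(syn), "conc_prefix", "resp_prefix"))
    if (length(unknown) > 0) {
      abort(paste0("Unknown column_map keys: ", paste(unknown, collapse = ", ")))
    }
    for (nm in intersect(names(column_map), names(syn))) {
      syn[[nm]] <- normalise_header(column_map[[nm]])
    }
  }
  out <- list()
  for (nm in names(syn)) {
    hit <- which(norm %in% syn[[nm]])
    if (length(hit) > 0) out[[nm]] <- headers[hit[1]]
  }
  conc_prefix <- normalise_header((column_map[["conc_prefix"]] %||% "c"))
  resp_prefix <- normalise_header((column_map[["resp_prefix"]] %||% "dat"))
  out$conc_cols <- headers[grepl(paste0("^", conc_prefix, "[0-9]+$"), norm)]
  out$resp_cols <- headers[grepl(paste0("^", resp_prefix, "[0-9]+$"), norm)]
  # order C0..C10 numerically, not lexically
  ord <- function(cols, prefix) {
    cols[order(as.integer(sub(paste0("^", prefix), "", normalise_header(cols))))]
  }
  out$conc_cols <- ord(out$conc_cols, conc_prefix)
  out$resp_cols <- ord(out$resp_cols, resp_prefix)
  out
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  if (stringr::str_detect(first, "\t")) "\t" else ","
}

parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Read a screen table in the raw or pre-fitted dialect
#'
#' Reads delimited text (comma or tab, sniffed from the header line unless
#' `delim` is given) in one of two dialects:
#'
#' * **prefitted** — one row per (compound, cell line) carrying fitted
#'   4-parameter-logistic summaries: `LAC50` (log10 molar AC50), `R2`,
#'   `TAUC` (total area under the curve), `ZERO` (asymptote maximum, the
#'   response extrapolated to zero concentration) and `INF` (asymptote
#'   minimum, extrapolated to infinite concentration).
#' * **raw** — one row per (compound, cell line) with up to 11 matched
#'   concentration/response columns `C0..C10` (uM) and `dat0..dat10`
#'   (% of DMSO control). Returned in long form, one row per retained point.
#'
#' Column names are matched case-insensitively; `column_map` overrides any
#' canonical name (keys: `compound`, `cell_line`, `target`, `lac50`, `r2`,
#' `tauc`, `asym_zero`, `asym_inf`, `conc_prefix`, `resp_prefix`).
#'
#' Parsing never fabricates values: every unparsable number is recorded as a
#' warning with its row identity, points with a missing concentration or
#' response are dropped pairwise, and rows with no usable data are excluded
#' and counted, so `rows kept + rows rejected = data rows in`. Duplicate
#' (compound, cell line) keys are a hard error, never a silent overwrite.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect `"auto"` (default), `"raw"` or `"prefitted"`.
#' @param column_map Optional named list remapping canonical column names to
#'   the file's actual headers.
#' @param delim Optional field delimiter; sniffed when `NULL`.
#' @return A tibble. Prefitted dialect: columns `compound`, `cell_line`,
#'   `target`, `lac50`, `r2`, `tauc`, `asym_zero`, `asym_inf`, `no_fit`.
#'   Raw dialect: columns `compound`, `cell_line`, `target`, `conc_um`,
#'   `response` (long form, concentrations strictly increasing within each
#'   series). Attributes: `dialect`, and `parse_info` (a list with
#'   `rows_in`, `rows_kept`, `rows_rejected`, `warnings` — a character vector
#'   of row-identified anomalies).
#' @export
read_screen <- function(path, dialect = c("auto", "raw", "prefitted"),
                        column_map = NULL, delim = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "sindex_io_error")
  }
  delim <- delim %||% sniff_delim(path)
  raw_tbl <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  cols <- resolve_columns(names(raw_tbl), column_map)

  has_prefitted <- !is.null(cols$lac50)
  has_raw <- length(cols$conc_cols) > 0 && length(cols$resp_cols) > 0
  if (dialect == "auto") {
    if (has_prefitted) {
      dialect <- "prefitted"
    } else if (has_raw) {
      dialect <- "raw"
    } else {
      abort(paste0(
        "Cannot detect dialect: found neither an LAC50 column nor C0/dat0 ",
        "concentration-response columns in header: ",
        paste(names(raw_tbl), collapse = ", ")
      ), class = "sindex_dialect_error")
    }
  }
  if (dialect == "prefitted" && !has_prefitted) {
    abort("Dialect 'prefitted' requires an LAC50 column; none found.",
      class = "sindex_dialect_error")
  }
  if (dialect == "raw" && !has_raw) {
    abort("Dialect 'raw' requires C<k>/dat<k> concentration-response columns; none found.",
      class = "sindex_dialect_error")
  }
  for (req in c("compound", "cell_line")) {
    if (is.null(cols[[req]])) {
      abort(sprintf("Required column '%s' not found (use column_map to remap).", req),
        class = "sindex_dialect_error")
    }
  }

  warnings <- character()
  n_in <- nrow(raw_tbl)
  base <- tibble::tibble(
    compound = trimws(raw_tbl[[cols$compound]]),
    cell_line = trimws(raw_tbl[[cols$cell_line]]),
    target = if (!is.null(cols$target)) trimws(raw_tbl[[cols$target]]) else NA_character_,
    .row = seq_len(max(n_in, 0L))
  )

  dup <- base |>
    dplyr::count(.data$compound, .data$cell_line) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (compound, cell line) keys: ",
      paste(sprintf("%s/%s", dup$compound, dup$cell_line), collapse = "; ")
    ), class = "sindex_duplicate_error")
  }

  grab_num <- function(col, label) {
    if (is.null(col)) return(rep(NA_real_, n_in))
    chr <- raw_tbl[[col]]
    num <- parse_num(chr)
    bad <- !is.na(chr) & chr != "" & is.na(num)
    if (any(bad)) {
      warnings <<- c(warnings, sprintf(
        "row %d (%s/%s): unparsable %s value '%s'",
        which(bad), base$compound[bad], base$cell_line[bad], label, chr[bad]
      ))
    }
    num
  }

  if (dialect == "prefitted") {
    out <- base |>
      dplyr::mutate(
        lac50 = grab_num(cols$lac50, "LAC50"),
        r2 = grab_num(cols$r2, "R2"),
        tauc = grab_num(cols$tauc, "TAUC"),
        asym_zero = grab_num(cols$asym_zero, "ZERO"),
        asym_inf = grab_num(cols$asym_inf, "INF")
      ) |>
      dplyr::mutate(no_fit = !is.finite(.data$lac50))
    usable <- !(is.na(out$lac50) & is.na(out$r2) & is.na(out$tauc) &
      is.na(out$asym_zero) & is.na(out$asym_inf))
    rejected <- sum(!usable)
    if (rejected > 0) {
      warnings <- c(warnings, sprintf(
        "row %d (%s/%s): no usable data, excluded",
        out$.row[!usable], out$compound[!usable], out$cell_line[!usable]
      ))
    }
    out <- out[usable, , drop = FALSE]
    out$.row <- NULL
    kept <- nrow(out)
  } else {
    n_c <- length(cols$conc_cols)
    n_d <- length(cols$resp_cols)
    n_pts <- min(n_c, n_d)
    if (n_c != n_d) {
      warnings <- c(warnings, sprintf(
        "unequal concentration (%d) and response (%d) column counts; using first %d pairs",
        n_c, n_d, n_pts
      ))
    }
    conc_mat <- matrix(vapply(cols$conc_cols[seq_len(n_pts)],
      function(cc) grab_num(cc, cc), numeric(n_in)), nrow = n_in)
    resp_mat <- matrix(vapply(cols$resp_cols[seq_len(n_pts)],
      function(cc) grab_num(cc, cc), numeric(n_in)), nrow = n_in)
    series <- purrr::map(seq_len(n_in), function(i) {
      conc <- as.numeric(conc_mat[i, ])
      resp <- as.numeric(resp_mat[i, ])
      ok <- is.finite(conc) & is.finite(resp) & conc > 0
      conc <- conc[ok]; resp <- resp[ok]
      o <- order(conc)
      tibble::tibble(conc_um = conc[o], response = resp[o])
    })
    n_ok <- vapply(series, nrow, integer(1))
    usable <- n_ok >= 2
    rejected <- sum(!usable)
    if (rejected > 0) {
      warnings <- c(warnings, sprintf(
        "row %d (%s/%s): fewer than 2 usable concentration-response points, excluded",
        base$.row[!usable], base$compound[!usable], base$cell_line[!usable]
      ))
    }
    out <- base[usable, , drop = FALSE]
    out$points <- series[usable]
    out <- tidyr::unnest(out, "points")
    out$.row <- NULL
    kept <- sum(usable)
  }

  attr(out, "dialect") <- dialect
  attr(out, "parse_info") <- list(
    rows_in = n_in, rows_kept = kept, rows_rejected = n_in - kept,
    warnings = warnings
  )
  out
}

#' Write screen results to CSV
#'
#' Serialises scored or summarised tables with a deterministic column order
#' and fixed-precision rendering of floating-point columns.
#'
#' @param data A tibble: per-pair scores for `"per_cell_line"`, compound
#'   summaries for `"per_compound_summary"`, a rank table for
#'   `"rank_comparison"`, or fitted/pre-fitted records for `"prefitted"`
#'   (written with the deposit's LAC50/R2/TAUC/ZERO/INF headers).
#' @param path Output file path.
#' @param layout One of `"per_cell_line"`, `"per_compound_summary"`,
#'   `"rank_comparison"`, `"prefitted"`.
#' @param precision Decimal places for floating-point columns (default 2).
#' @param allow_empty Permit writing a header-only file from zero rows.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(data, path,
                                 layout = c("per_cell_line", "per_compound_summary",
                                            "rank_comparison", "prefitted"),
                                 precision = 2, allow_empty = FALSE) {
  layout <- match.arg(layout)
  if (nrow(data) == 0 && !allow_empty) {
    abort("Refusing to write an empty table (set allow_empty = TRUE).")
  }
  columns <- switch(layout,
    per_cell_line = c("compound", "target", "test_cell_line", "eff_ref", "eff_test",
      "ac50_ref_um", "ac50_test_um", "delta_s", "delta_pac50", "delta_pauc",
      "call", "flags"),
    per_compound_summary = c("compound", "target", "ds_mean", "ds_variance",
      "ds_variance_of_mean", "n_lines", "verdict"),
    rank_comparison = c("compound", "rank_ds_mean", "rank_dpac50_mean",
      "rank_dpauc_mean"),
    prefitted = c("cell_line", "compound", "target", "lac50", "r2", "tauc",
      "asym_zero", "asym_inf")
  )
  present <- intersect(columns, names(data))
  out <- dplyr::select(data, dplyr::all_of(present))
  is_dbl <- vapply(out, is.double, logical(1))
  out[is_dbl] <- lapply(out[is_dbl], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = precision))
  })
  if (layout == "prefitted") {
    names(out) <- dplyr::recode(names(out),
      lac50 = "LAC50", r2 = "R2", tauc = "TAUC",
      asym_zero = "ZERO", asym_inf = "INF"
    )
  }
  ok <- tryCatch({
    readr::write_csv(out, path, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Cannot write to '%s': %s", path, conditionMessage(ok)),
      class = "sindex_io_error")
  }
  invisible(path)
}

#' Parsing diagnostics from a read screen table
#'
#' @param data A tibble returned by [read_screen()].
#' @return A list with `rows_in`, `rows_kept`, `rows_rejected` and
#'   `warnings`.
#' @export
parse_info <- function(data) {
  attr(data, "parse_info") %||%
    list(rows_in = nrow(data), rows_kept = nrow(data), rows_rejected = 0L,
      warnings = character())
}
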
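# Internal helpers shared across modules.

# Comma-joined flag strings ("" = no flags). Flags travel as plain character
# columns so scored tables stay ordinary tibbles.
add_flag <- function(flags, flag, where) {
  ifelse(where,
    ifelse(flags == "", flag, paste(flags, flag, sep = ",")),
    flags
  )
}

has_flag <- function(flags, flag) {
  stringr::str_detect(flags %||% "", paste0("(^|,)", flag, "($|,)"))
}

# %||% re-exported from rlang for internal use only.

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Trapezoidal rule on a uniform grid.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}
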
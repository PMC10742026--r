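# Fixtures are built in code at test time; nothing is read from disk that a
# test did not itself write.

fourpl_curve <- function(conc_um, zero = 100, inf = 0, ac50_um = 1, hill = 1) {
  inf + (zero - inf) / (1 + 10^(hill * (log10(conc_um) - log10(ac50_um))))
}

default_grid <- function() 10^seq(-3, 2, length.out = 11)

# A tiny prefitted table: 2 compounds x (1 reference + 2 test lines).
tiny_prefitted <- function() {
  tibble::tibble(
    compound = rep(c("cpdA", "cpdB"), each = 3),
    cell_line = rep(c("ref", "t1", "t2"), 2),
    target = rep(c("MEK", "AKT"), each = 3),
    lac50 = c(-6, -7, -5, -6, -6, -6),
    r2 = c(0.95, 0.9, 0.85, 0.99, 0.97, 0.92),
    tauc = c(300, 200, 400, 300, 300, 300),
    asym_zero = c(100, 100, 100, 100, 100, 100),
    asym_inf = c(0, 0, 0, 0, 50, 80),
    no_fit = FALSE
  )
}

write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}
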
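test_that("effectiveness is the asymptote span with the inhibitory sign", {
  expect_equal(effectiveness(100, 0), 100)
  expect_equal(effectiveness(100, 100), 0)
  expect_equal(effectiveness(95, 20), 75)
  expect_true(is.na(effectiveness(NA, 0)))
})

test_that("s_score is log10(EFF/AC50) and undefined off-domain", {
  expect_equal(s_score(100, 1), 2)
  expect_equal(s_score(100, 100), 0)
  expect_equal(s_score(75, 0.5), log10(150))
  expect_true(is.na(s_score(0, 1)))
  expect_true(is.na(s_score(-5, 1)))
  expect_true(is.na(s_score(100, 0)))
})

test_that("pairwise deltas follow the reference-minus-test sign convention", {
  expect_equal(delta_s(2, 2), 0)
  expect_equal(delta_s(2, 2.5), -0.5)   # test line sensitive
  d <- delta_pac50(1, 0.1)              # test more potent
  expect_equal(d$delta_ac50, 1)
  expect_equal(d$delta_pac50, -1)
  expect_equal(delta_pac50(0.1, 1)$delta_ac50, -1)
  expect_equal(delta_pac50(2, 2)$delta_pac50, 0)
  expect_equal(delta_pauc(500, 500), 0)
  expect_equal(delta_pauc(500, 50), -1) # test curve lower -> sensitive
  expect_true(is.na(delta_pauc(-1, 50)))
})

test_that("deltas are antisymmetric under swapping reference and test", {
  withr::with_seed(3, {
    a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
  })
  expect_equal(delta_s(a, b), -delta_s(b, a), tolerance = 1e-12)
  expect_equal(delta_pac50(a, b)$delta_pac50, -delta_pac50(b, a)$delta_pac50,
    tolerance = 1e-12)
  expect_equal(delta_pauc(a, b), -delta_pauc(b, a), tolerance = 1e-12)
})

test_that("delta-S is invariant under joint unit rescaling while S is not", {
  withr::with_seed(4, {
    eff_ref <- runif(30, 10, 100); eff_test <- runif(30, 10, 100)
    ac_ref <- runif(30, 0.01, 50); ac_test <- runif(30, 0.01, 50)
    m <- 7.3; k <- 0.011  # response and concentration unit factors
  })
  s_ref <- s_score(eff_ref, ac_ref); s_test <- s_score(eff_test, ac_test)
  s_ref2 <- s_score(m * eff_ref, k * ac_ref)
  s_test2 <- s_score(m * eff_test, k * ac_test)
  expect_equal(s_ref2 - s_ref, rep(log10(m / k), 30), tolerance = 1e-12)
  expect_equal(delta_s(s_ref2, s_test2), delta_s(s_ref, s_test),
    tolerance = 1e-12)
})

test_that("with equal EFF, delta-S collapses to the relative potency exactly", {
  withr::with_seed(5, {
    eff <- runif(40, 5, 120)
    ac_ref <- runif(40, 0.01, 80); ac_test <- runif(40, 0.01, 80)
  })
  # S_ref - S_test = log10(AC50_test/AC50_ref) = -deltaAC50 = deltapAC50:
  # the potency-only comparison, with the shared sensitive-is-negative sign
  ds <- delta_s(s_score(eff, ac_ref), s_score(eff, ac_test))
  dp <- delta_pac50(ac_ref, ac_test)
  expect_equal(ds, dp$delta_pac50, tolerance = 1e-12)
  expect_equal(ds, -dp$delta_ac50, tolerance = 1e-12)
})

test_that("the sensitivity call is fully determined by the sign of delta-S", {
  withr::with_seed(6, {
    grid <- tiny_prefitted()[rep(1:6, 40), ]
    grid$compound <- paste0("c", rep(1:80, each = 3))
    grid$lac50 <- grid$lac50 + rnorm(240, 0, 1)
    grid$asym_inf <- pmin(runif(240, 0, 99), 99)
  })
  deltas <- score_screen(grid, "ref")
  ok <- is.finite(deltas$delta_s)
  expect_true(all(deltas$call[ok & deltas$delta_s > 0] == "resistant"))
  expect_true(all(deltas$call[ok & deltas$delta_s < 0] == "sensitive"))
  expect_true(all(deltas$call[!ok] == "indeterminate"))
})

test_that("score_lines flags missing, no-response and stimulatory records", {
  pre <- tibble::tibble(
    compound = c("a", "b", "c", "d"), cell_line = "x",
    lac50 = c(-6, NA, -6, -6), asym_zero = c(100, 100, 100, 90),
    asym_inf = c(0, 0, 100, 120)
  )
  sc <- score_lines(pre)
  expect_equal(sc$s, c(2, NA, NA, NA))
  expect_identical(sc$flags, c("", "missing", "no_response", "stimulatory"))
  expect_equal(sc$eff, c(100, 100, 0, -30))
})

test_that("score_screen yields one pair per test line with reasons for gaps", {
  pre <- tiny_prefitted()
  deltas <- score_screen(pre, "ref")
  expect_equal(nrow(deltas), 4) # 2 compounds x 2 test lines
  # cpdA: ref S = 2, t1 S = log10(100/0.1) = 3, t2 S = log10(100/10) = 1
  a <- deltas[deltas$compound == "cpdA", ]
  expect_equal(a$delta_s[a$test_cell_line == "t1"], -1)
  expect_equal(a$delta_s[a$test_cell_line == "t2"], 1)
  expect_identical(a$call, c("sensitive", "resistant"))

  expect_error(score_screen(pre, "nope"), class = "sindex_reference_error")

  # drop one test record -> that pair indeterminate with reason missing
  deltas2 <- score_screen(pre[-2, ], "ref")
  gap <- deltas2[deltas2$compound == "cpdA" & deltas2$test_cell_line == "t1", ]
  expect_identical(gap$call, "indeterminate")
  expect_identical(gap$reason, "missing")

  # reference with no concentration-response -> ref_no_response
  pre3 <- tiny_prefitted()
  pre3$asym_inf[1] <- 100
  d3 <- score_screen(pre3, "ref")
  expect_identical(unique(d3$reason[d3$compound == "cpdA"]), "ref_no_response")
})

test_that("synthetic truth delta-S is recovered from the prefitted dialect", {
  scr <- simulate_screen(n_compounds = 15, seed = 99)
  deltas <- score_screen(scr$prefitted, scr$reference)
  joined <- dplyr::inner_join(
    deltas, scr$truth[scr$truth$cell_line != scr$reference, ],
    by = c("compound", "test_cell_line" = "cell_line"))
  ok <- is.finite(joined$true_delta_s) & is.finite(joined$delta_s)
  expect_gt(sum(ok), 0)
  expect_equal(joined$delta_s[ok], joined$true_delta_s[ok], tolerance = 1e-12)
})
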
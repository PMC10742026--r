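make_deltas <- function(ds, compound = "a", r2_ref = 1, r2_test = 1) {
  tibble::tibble(
    compound = compound, target = NA_character_,
    test_cell_line = paste0("t", seq_along(ds)),
    delta_s = ds, delta_pac50 = ds / 2, delta_pauc = ds / 3,
    r2_ref = r2_ref, r2_test = r2_test, reason = NA_character_, flags = ""
  )
}

test_that("compound summaries match hand arithmetic and handle sparse data", {
  s <- summarize_compounds(make_deltas(c(-0.5, -0.7, -0.6, -0.8)))
  expect_equal(s$ds_mean, -0.65)
  expect_equal(s$ds_variance, 0.05 / 3, tolerance = 1e-12) # 0.016667
  expect_equal(s$ds_variance_of_mean, s$ds_variance / 4)
  expect_equal(s$n_lines, 4)

  one <- summarize_compounds(make_deltas(1.2))
  expect_equal(one$ds_mean, 1.2)
  expect_true(is.na(one$ds_variance))

  gap <- summarize_compounds(make_deltas(c(-1, NA, -2)))
  expect_equal(gap$n_lines, 2)
  expect_equal(gap$n_indeterminate, 1)
  expect_equal(gap$ds_mean, -1.5)

  none <- summarize_compounds(make_deltas(rep(NA_real_, 3)))
  expect_true(is.na(none$ds_mean))
})

test_that("summaries equal a naive two-pass oracle on fuzzed inputs", {
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(2:1000, 1)
      v <- rnorm(n, sd = 2)
      s <- summarize_compounds(make_deltas(v))
      expect_equal(s$ds_mean, sum(v) / n, tolerance = 1e-12)
      expect_equal(s$ds_variance, sum((v - sum(v) / n)^2) / (n - 1),
        tolerance = 1e-12)
    }
  })
})

test_that("prioritization applies the R2, effect-size and non-inferiority filters", {
  base <- function(ds, ...) {
    prioritize_compounds(summarize_compounds(make_deltas(ds, ...)),
      n_required_lines = 4)
  }
  # strong sensitivity, tight variance, good fits -> prioritized
  p <- base(c(-0.6, -0.7, -0.6, -0.7))
  expect_identical(p$verdict, "sensitive_prioritized")
  expect_true(all(p$r2_ok, p$effect_ok, p$noninferiority_ok))

  # |ds_mean| = 0.45 < 0.5 -> never prioritized, whatever the variance
  p2 <- base(rep(-0.45, 4))
  expect_identical(p2$verdict, "not_prioritized")
  expect_identical(p2$verdict_reason, "effect_below_threshold")

  # ds_mean 0.6 with sd of the mean 0.5: 0.6 - 0.5 = 0.1 < 0.3 -> fails
  d <- make_deltas(c(0.6, 0.6, 0.6, 0.6))
  s <- summarize_compounds(d)
  s$ds_variance_of_mean <- 0.25
  p3 <- prioritize_compounds(s, n_required_lines = 4)
  expect_identical(p3$verdict, "not_prioritized")
  expect_identical(p3$verdict_reason, "non_inferiority")

  # poor fit in one test line blocks prioritization
  p4 <- base(c(-0.9, -0.9, -0.9, -0.9), r2_test = c(0.95, 0.7, 0.9, 0.95))
  expect_identical(p4$verdict, "not_prioritized")
  expect_identical(p4$verdict_reason, "r2_below_threshold")

  # ...unless r2_mode = "mean" and the mean clears the bar
  p5 <- prioritize_compounds(
    summarize_compounds(make_deltas(rep(-0.9, 4), r2_test = c(0.95, 0.7, 0.9, 0.95))),
    n_required_lines = 4, r2_mode = "mean")
  expect_identical(p5$verdict, "sensitive_prioritized")

  # a missing line excludes the compound rather than filtering it
  p6 <- base(c(-2, -2, NA, -2))
  expect_identical(p6$verdict, "excluded")
  expect_identical(p6$verdict_reason, "missing_fit")

  # reference without concentration-response is exempt from the ref R2 bar
  d7 <- make_deltas(rep(-0.9, 4), r2_ref = NA_real_)
  d7$reason[1] <- "ref_no_response"
  p7 <- prioritize_compounds(summarize_compounds(d7), n_required_lines = 3)
  expect_true(p7$r2_ref_ok)

  expect_error(prioritize_compounds(summarize_compounds(d7),
    variance_floor = -1), "variance_floor")
})

test_that("prioritization is monotone in effect size and variance", {
  verdict_of <- function(ds_mean, vom) {
    s <- summarize_compounds(make_deltas(rep(ds_mean, 4)))
    s$ds_variance_of_mean <- vom
    prioritize_compounds(s, n_required_lines = 4)$verdict
  }
  withr::with_seed(9, {
    for (i in 1:50) {
      m <- runif(1, 0.1, 2) * sample(c(-1, 1), 1)
      v <- runif(1, 0, 0.5)
      v1 <- verdict_of(m, v)
      if (endsWith(v1, "prioritized") && v1 != "not_prioritized") {
        # shrinking the variance never demotes
        expect_identical(verdict_of(m, v / 2), v1)
        # growing |ds_mean| never demotes
        expect_identical(verdict_of(m * 1.5, v), v1)
      }
    }
  })
})

test_that("delta-delta-S is the difference of group means", {
  expect_equal(delta_delta_s(-1, -0.2), -0.8)
  expect_equal(delta_delta_s(0.4, 0.4), 0)
  expect_equal(delta_delta_s(0.3, -0.2), -delta_delta_s(-0.2, 0.3))

  scr <- simulate_screen(n_compounds = 6, n_test_lines = 4, seed = 21)
  deltas <- score_screen(scr$prefitted, scr$reference)
  g <- delta_delta_s_groups(deltas, tumor_lines = c("TEST-1", "TEST-2"),
    control_lines = c("TEST-3", "TEST-4"))
  manual <- deltas |>
    dplyr::filter(is.finite(delta_s)) |>
    dplyr::group_by(compound) |>
    dplyr::summarise(
      dd = mean(delta_s[test_cell_line %in% c("TEST-1", "TEST-2")]) -
        mean(delta_s[test_cell_line %in% c("TEST-3", "TEST-4")]))
  j <- dplyr::inner_join(g, manual, by = "compound")
  expect_equal(j$delta_delta_s, j$dd, tolerance = 1e-12)
  expect_error(delta_delta_s_groups(deltas, "TEST-1", "NOPE"), "NOPE")
})

test_that("endpoint r2 matches the covariance-formula oracle and its limits", {
  d <- make_deltas(seq(-1, 1, length.out = 10))
  d$delta_pac50 <- 2 * d$delta_s + 1          # exact linear -> r2 = 1
  d$delta_pauc <- c(1, -2, 1, rep(0, 7))
  d$delta_pauc <- d$delta_pauc - mean(d$delta_pauc)
  d$test_cell_line <- "t1"
  d$delta_pauc[4:10] <- rnorm(7)
  ec <- endpoint_correlation(d, by = "pooled")
  r2_sp <- ec$r2[ec$endpoint_x == "delta_s" & ec$endpoint_y == "delta_pac50"]
  expect_equal(r2_sp, 1, tolerance = 1e-12)

  # orthogonal example: x = {-1, 0, 1}, y = {1, -2, 1}
  d2 <- make_deltas(c(-1, 0, 1))
  d2$delta_pac50 <- c(1, -2, 1)
  d2$test_cell_line <- "t1"
  ec2 <- endpoint_correlation(d2, by = "cell_line")
  expect_equal(ec2$r2[ec2$endpoint_x == "delta_s" & ec2$endpoint_y == "delta_pac50"],
    0, tolerance = 1e-12)

  # brute-force formula on random vectors
  withr::with_seed(10, {
    x <- rnorm(50); y <- rnorm(50)
  })
  d3 <- make_deltas(x)
  d3$delta_pac50 <- y
  oracle <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ec3 <- endpoint_correlation(d3, by = "pooled")
  expect_equal(ec3$r2[ec3$endpoint_x == "delta_s" & ec3$endpoint_y == "delta_pac50"],
    oracle, tolerance = 1e-12)
  expect_true(all(ec3$n == 50))

  # zero variance or too few pairs -> NA, reported not errored
  d4 <- make_deltas(rep(0.5, 5))
  ec4 <- endpoint_correlation(d4, by = "pooled")
  expect_true(all(is.na(ec4$r2[ec4$endpoint_x == "delta_s"])))
})

test_that("endpoint ranks use average ties and conserve the rank sum", {
  s <- tibble::tibble(
    compound = c("a", "b", "c"),
    ds_mean = c(-1, 0, 1), dpac50_mean = c(-1, 0, 1), dpauc_mean = c(-1, 0, 1)
  )
  r <- rank_endpoints(s)
  expect_equal(r$rank_ds_mean, c(1, 2, 3))
  conc <- rank_concordance(r)
  expect_equal(conc$spearman, rep(1, 3))

  s2 <- tibble::tibble(compound = c("a", "b", "c", "d"),
    ds_mean = c(-2, -1, -1, 3), dpac50_mean = c(1, 2, 3, 4),
    dpauc_mean = c(NA, 1, 2, 3))
  r2 <- rank_endpoints(s2)
  expect_equal(r2$rank_ds_mean, c(1, 2.5, 2.5, 4))
  expect_equal(sum(r2$rank_ds_mean), 4 * 5 / 2)
  expect_true(is.na(r2$rank_dpauc_mean[1]))
  expect_equal(sum(r2$rank_dpauc_mean, na.rm = TRUE), 3 * 4 / 2)

  withr::with_seed(12, {
    s3 <- tibble::tibble(compound = paste0("c", 1:40),
      ds_mean = sample(c(rnorm(35), rep(0.3, 5))),
      dpac50_mean = rnorm(40), dpauc_mean = rnorm(40))
  })
  r3 <- rank_endpoints(s3)
  expect_equal(sum(r3$rank_ds_mean), 40 * 41 / 2) # ties conserve the sum
})

test_that("delta-S distributions count threshold exceedances conservatively", {
  d <- make_deltas(c(-1, -0.2, 0.7))
  d$test_cell_line <- "t1"
  dist <- ds_distribution(d, "t1")
  expect_equal(dist$values, c(-1, -0.2, 0.7))
  expect_equal(c(dist$n_below, dist$n_within, dist$n_above), c(1, 1, 1))

  z <- make_deltas(rep(0, 6))
  dz <- ds_distribution(z)
  expect_equal(c(dz$n_below, dz$n_within, dz$n_above), c(0, 6, 0))

  withr::with_seed(13, {
    v <- rnorm(200)
  })
  dv <- ds_distribution(make_deltas(v))
  expect_equal(dv$n_below + dv$n_within + dv$n_above, 200)
})
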
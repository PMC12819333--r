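test_that("time-to-onset requires day precision and a positive span", {
  r <- compute_tto("20200101", "20200131")
  expect_equal(r$tto_days, 30L)
  expect_equal(r$status, "valid")

  expect_equal(compute_tto("202006", "20200715")$status, "omission")
  expect_equal(compute_tto("20200310", "20200301")$status, "discrepancy")
  expect_equal(compute_tto("20200301", "20200301")$status, "same-day")
  expect_equal(compute_tto("", "20200301")$status, "omission")
})

test_that("every record falls in exactly one validity category", {
  cfg <- synthetic_config(n_reports = 2000L, seed = 13L)
  st <- build_report_store(generate_faers(cfg)$tables)
  ids <- as.character(st$reports$primaryid)
  tto <- extract_tto(st, ids)
  expect_equal(nrow(tto), length(ids))
  expect_true(all(tto$status %in% c("valid", "omission", "discrepancy",
                                    "same-day")))
  expect_equal(sum(table(tto$status)), length(ids))
  expect_true(all(tto$tto_days[tto$status == "valid"] >= 1))
  expect_true(all(is.na(tto$tto_days[tto$status != "valid"])))
})

test_that("onset summaries use type-7 interpolated quartiles", {
  s <- summarize_tto(5)
  expect_equal(unlist(s[c("median", "q1", "q3", "min", "max")]),
               c(median = 5, q1 = 5, q3 = 5, min = 5, max = 5))

  s <- summarize_tto(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)

  set.seed(3)
  for (i in 1:5) {
    x <- sample(1:500, 30, replace = TRUE)
    s <- summarize_tto(x)
    expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)
  }
  expect_error(summarize_tto(numeric(0)), "empty")
})

test_that("Weibull fit recovers the exponential special case", {
  set.seed(8)
  x <- rexp(5000, rate = 1 / 100)
  f <- fit_weibull(x, boot = 200, seed = 2)
  expect_gt(f$shape_beta, 0.95)
  expect_lt(f$shape_beta, 1.05)
  expect_equal(f$failure_type, "random")
  expect_lt(abs(f$scale_alpha - 100) / 100, 0.1)
})

test_that("Weibull MLE matches the independent fitdistrplus fit", {
  skip_if_not_installed("fitdistrplus")
  set.seed(14)
  x <- rweibull(400, shape = 0.8, scale = 250)
  f <- fit_weibull(x, boot = 50, seed = 3)
  ref <- fitdistrplus::fitdist(x, "weibull")
  # agreement at the reference optimizer's own convergence precision
  expect_equal(f$shape_beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$scale_alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("Weibull MLE is scale equivariant", {
  set.seed(9)
  x <- rweibull(200, shape = 0.7, scale = 120)
  f1 <- fit_weibull(x, boot = 20, seed = 4)
  f7 <- fit_weibull(7 * x, boot = 20, seed = 4)
  expect_equal(f7$shape_beta, f1$shape_beta, tolerance = 1e-6)
  expect_equal(f7$scale_alpha, 7 * f1$scale_alpha, tolerance = 1e-6)
})

test_that("Weibull fit refuses unusable samples", {
  expect_error(fit_weibull(1:5), "at least 10")
  expect_error(fit_weibull(rep(3, 20)), "degenerate")
})

test_that("Kaplan-Meier onset equals the empirical CDF without censoring", {
  k <- km_onset(10)
  expect_equal(k$time, 10)
  expect_equal(k$cumulative_onset, 1)

  k <- km_onset(c(10, 20, 20, 40))
  expect_equal(k$time, c(10, 20, 40))
  expect_equal(k$cumulative_onset, c(0.25, 0.75, 1))

  set.seed(4)
  x <- sample(1:1000, 200, replace = TRUE)
  k <- km_onset(x)
  ec <- ecdf(x)
  expect_equal(k$cumulative_onset, ec(k$time), tolerance = 1e-12)
  expect_error(km_onset(numeric(0)), "empty")
})

test_that("onset fractions cut at 30 and 180 days", {
  x <- c(rep(1, 10), rep(100, 5), rep(200, 5))
  fr <- onset_fractions(x)
  expect_equal(fr$within_first, 0.5)
  expect_equal(fr$after_second, 0.25)
  fr <- onset_fractions(rep(1, 7))
  expect_equal(fr$within_first, 1)
  expect_equal(fr$after_second, 0)
  # boundary: exactly 30 is "within the first month", exactly 180 is not
  # "after 6 months"
  fr <- onset_fractions(c(30, 180))
  expect_equal(fr$within_first, 0.5)
  expect_equal(fr$after_second, 0)
})

test_that("Mann-Whitney p-values match brute-force enumeration for small n", {
  r <- mann_whitney_bonferroni(list(a = c(1, 2), b = c(3, 4)),
                               list(c("a", "b")))
  oracle <- enumerate_mw(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, oracle$u)
  expect_equal(r$p_raw, oracle$p, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:5) {
    x <- sample(1:1000, sample(3:7, 1))
    y <- sample(1001:2000, sample(3:7, 1)) / 3  # no ties with x
    r <- mann_whitney_bonferroni(list(g1 = x, g2 = y), list(c("g1", "g2")))
    oracle <- enumerate_mw(x, y)
    expect_equal(r$u_statistic, oracle$u)
    expect_equal(r$p_raw, oracle$p, tolerance = 1e-12)
  }
})

test_that("identical groups give large p-values", {
  r <- mann_whitney_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                               list(c("a", "b")))
  expect_gt(r$p_raw, 0.9)
})

test_that("Bonferroni adjustment multiplies by m and caps at 1", {
  groups <- list(g1 = 1:10, g2 = 2:11, g3 = 3:12, g4 = 4:13)
  cmp <- utils::combn(names(groups), 2, simplify = FALSE)
  r <- mann_whitney_bonferroni(groups, cmp)
  expect_equal(nrow(r), 6L)
  expect_true(all(r$p_adjusted >= r$p_raw))
  expect_true(all(r$p_adjusted <= 1))
  expect_equal(r$p_adjusted, pmin(1, 6 * r$p_raw))
  expect_error(mann_whitney_bonferroni(groups, list(c("g1", "zz"))),
               "unknown group")
})
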
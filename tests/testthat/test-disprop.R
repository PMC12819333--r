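test_that("contingency tables count each report once in the right cell", {
  st <- make_four_cell_store()
  tab <- build_contingency(st, "nivolumab")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 1L, 1L))
  expect_equal(attr(tab, "N"), 4L)

  one <- make_store(make_reports(1),
                    drug = data.frame(PRIMARYID = "1", DRUG_SEQ = "1",
                                      DRUGNAME = "NIVOLUMAB", ROLE_COD = "PS"),
                    reac = data.frame(PRIMARYID = "1", PT = "Pemphigoid"))
  tab <- build_contingency(one, "nivolumab")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1L, 0L, 0L, 0L))

  expect_error(build_contingency(make_store(make_reports(0)), "nivolumab"),
               "empty")
})

test_that("ROR and Woolf interval match hand computation", {
  expect_equal(ror_stat(contingency_table(1, 1, 1, 1))$ror, 1)

  r <- ror_stat(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11, tolerance = 1e-12)
  # ln 11 +/- 1.96 * sqrt(1/10 + 1/90 + 1/100 + 1/9900)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$ci_low, exp(log(11) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(11) + 1.96 * se))
  expect_equal(r$ci_low, 5.56, tolerance = 0.002)
  expect_equal(r$ci_high, 21.77, tolerance = 0.002)
  expect_false(r$degenerate)
})

test_that("zero cells trigger the Haldane correction and a degenerate flag", {
  r <- ror_stat(contingency_table(0, 10, 10, 100))
  expect_true(r$degenerate)
  expect_true(is.finite(r$ror) && r$ror > 0)
  # corrected cells are (0.5, 10.5, 10.5, 100.5)
  expect_equal(r$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("PRR and chi-squared match the independent chisq.test oracle", {
  p <- prr_stat(contingency_table(1, 1, 1, 1))
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  p <- prr_stat(contingency_table(10, 90, 100, 9900))
  expect_equal(p$prr, 10, tolerance = 1e-12)
  m <- matrix(c(10, 90, 100, 9900), 2, 2, byrow = TRUE)
  expect_equal(p$chi2,
               unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic))
  expect_equal(round(p$chi2, 2), 74.45)
  py <- prr_stat(contingency_table(10, 90, 100, 9900), yates = TRUE)
  expect_equal(py$chi2,
               unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic))

  # equal reporting proportions give chi2 = 0 exactly
  expect_equal(prr_stat(contingency_table(10, 90, 20, 180))$chi2, 0)
})

test_that("ROR approximates PRR for rare events", {
  tabs <- list(c(10, 990, 400, 98600), c(3, 497, 50, 9450),
               c(25, 4975, 100, 94900))
  for (t in tabs) {
    stopifnot(t[1] + t[3] <= 0.01 * sum(t))
    r <- ror_stat(contingency_table(t[1], t[2], t[3], t[4]))$ror
    p <- prr_stat(contingency_table(t[1], t[2], t[3], t[4]))$prr
    expect_lt(abs(r - p) / p, 0.05)
  }
})

test_that("information component shrinks toward zero and flags independence", {
  ind <- bcpnn_ic(contingency_table(10, 90, 990, 8910))
  expect_lt(abs(ind$ic_expect), 0.15)
  expect_lt(ind$ic025, 0)

  sig <- bcpnn_ic(contingency_table(10, 90, 100, 9900))
  point_ic <- log2(10 * 10100 / (100 * 110))
  expect_equal(round(point_ic, 2), 3.2)
  expect_lt(sig$ic_expect, point_ic)  # shrinkage toward 0
  expect_gt(sig$ic_expect, 0)
  expect_lte(sig$ic025, sig$ic_expect)
})

test_that("information component converges to the point IC for large tables", {
  base <- c(20, 80, 100, 800)
  point_ic <- log2(base[1] * sum(base) / ((base[1] + base[2]) * (base[1] + base[3])))
  gaps <- vapply(c(10, 100, 1000), function(k) {
    t <- base * k
    abs(bcpnn_ic(contingency_table(t[1], t[2], t[3], t[4]))$ic_expect - point_ic)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("closed-form IC moments agree with the Monte-Carlo posterior", {
  # scaled-down spot check (the full 20-table sweep runs in the acceptance
  # suite): sample the Beta posteriors of p(x,y), p(x), p(y)
  mc_ic <- function(a, b, c, d, ndraw = 2e5) {
    C <- a + b + c + d; cx <- a + b; cy <- a + c
    g <- (C + 2) * (C + 2) / ((cx + 1) * (cy + 1))
    p11 <- rbeta(ndraw, a + 1, C - a + g - 1)
    px <- rbeta(ndraw, cx + 1, C - cx + 1)
    py <- rbeta(ndraw, cy + 1, C - cy + 1)
    ic <- log2(p11 / (px * py))
    c(mean = mean(ic), lo = mean(ic) - 1.96 * sd(ic))
  }
  set.seed(99)
  for (t in list(c(20, 20, 20, 80), c(12, 24, 12, 48), c(30, 60, 60, 120))) {
    cf <- bcpnn_ic(contingency_table(t[1], t[2], t[3], t[4]))
    mc <- mc_ic(t[1], t[2], t[3], t[4])
    expect_lt(abs(cf$ic_expect - mc["mean"]), 0.05)
    expect_lt(abs(cf$ic025 - mc["lo"]), 0.05)
  }
})

test_that("MGPS marginal likelihood is permutation invariant and guarded", {
  set.seed(5)
  E <- rlnorm(200, 0, 1)
  a <- rpois(200, E)
  h1 <- mgps_fit(a, E)
  perm <- sample(200)
  h2 <- mgps_fit(a[perm], E[perm])
  expect_equal(h1$loglik, h2$loglik, tolerance = 1e-8)
  expect_error(mgps_fit(1:5, rep(1, 5)), "at least 10")
  expect_error(mgps_fit(1:20, rep(0, 20)), "positive")
})

test_that("MGPS recovers a single-component gamma prior mean", {
  set.seed(11)
  E <- rlnorm(5000, 0, 1)
  lam <- rgamma(5000, shape = 2, rate = 4)
  a <- rpois(5000, lam * E)
  h <- mgps_fit(a, E)
  prior_mean <- h$mix_p * h$alpha1 / h$beta1 + (1 - h$mix_p) * h$alpha2 / h$beta2
  expect_lt(abs(prior_mean - 0.5) / 0.5, 0.2)
})

test_that("MGPS prior concentrates near 1 on a null-consistent grid", {
  set.seed(12)
  E <- rlnorm(2000, 1, 0.8)
  a <- round(E)
  h <- mgps_fit(a, E)
  prior_mean <- h$mix_p * h$alpha1 / h$beta1 + (1 - h$mix_p) * h$alpha2 / h$beta2
  expect_gt(prior_mean, 0.8)
  expect_lt(prior_mean, 1.25)
})

test_that("EBGM matches the digamma closed form on single-component priors", {
  # both mixture components identical => effectively a Gamma(1,1) prior;
  # posterior for a=10, E=1 is Gamma(11, 2)
  h <- list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, mix_p = 0.5)
  r <- mgps_ebgm(10, 1, h)
  expect_equal(r$ebgm, exp(digamma(11) - log(2)), tolerance = 1e-10)
  expect_equal(round(r$ebgm, 2), 5.25)
  # EB05 against the independent gamma quantile
  expect_equal(r$ebgm05, qgamma(0.05, 11, rate = 2), tolerance = 1e-7)

  # near-point-mass prior at lambda = 1 dominates any a
  hp <- list(alpha1 = 1e4, beta1 = 1e4, alpha2 = 1e4, beta2 = 1e4, mix_p = 0.5)
  for (a in c(0, 1, 10, 100)) {
    r <- mgps_ebgm(a, 1, hp)
    expect_gt(r$ebgm, 0.99)
    expect_lt(r$ebgm, 1.01)
  }
  expect_error(mgps_ebgm(1, 0, h), "positive")
})

test_that("EBGM orders correctly: eb05 < ebgm, monotone in a, shrinks toward 1", {
  set.seed(11)
  E <- rlnorm(2000, 0, 1)
  a <- rpois(2000, E)
  h <- mgps_fit(a, E)
  grid <- expand.grid(a = seq(0, 95, 5), E = seq(0.5, 10, 0.5))
  r <- mgps_ebgm(grid$a, grid$E, h)
  expect_true(all(r$ebgm05 < r$ebgm))
  for (e in unique(grid$E)) {
    expect_false(is.unsorted(r$ebgm[grid$E == e]))
  }
  hi <- grid$a / grid$E > 1
  expect_true(all(r$ebgm[hi] > 1))
  expect_true(all(r$ebgm[hi] < grid$a[hi] / grid$E[hi]))
})

test_that("positivity criteria use strict printed thresholds", {
  # published avelumab row: ROR/PRR positive, MGPS and BCPNN not
  fl <- evaluate_criteria(n_cases = 3, ror = 6.05, ror_low = 1.95,
                          prr = 6.05, chi2 = 12.64, ic025 = -0.1,
                          ebgm05 = 1.95)
  expect_true(fl$ror_pos)
  expect_true(fl$prr_pos)
  expect_false(fl$mgps_pos)
  expect_false(fl$bcpnn_pos)

  # fewer than three reports: all flags false regardless of magnitude
  fl <- evaluate_criteria(2, 50, 10, 50, 500, 3, 20)
  expect_false(any(unlist(fl)))

  # exact thresholds do not fire strict criteria
  fl <- evaluate_criteria(3, ror = 1, ror_low = 1, prr = 2, chi2 = 4,
                          ic025 = 0, ebgm05 = 2)
  expect_false(fl$ror_pos)
  expect_true(fl$prr_pos)   # PRR >= 2 and chi2 >= 4 are inclusive
  expect_false(fl$bcpnn_pos)
  expect_false(fl$mgps_pos)
})

test_that("planted signals are ranked concordantly by all four statistics", {
  agents <- c("nivolumab", "pembrolizumab", "atezolizumab", "ipilimumab")
  ok <- c(ROR = 0, PRR = 0, IC = 0, EBGM = 0)
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(
      n_reports = 30000L, agents = agents,
      exposure_probs = c(nivolumab = 0.10, pembrolizumab = 0.06,
                         atezolizumab = 0.04, ipilimumab = 0.03),
      rho = c(nivolumab = 2, pembrolizumab = 5, atezolizumab = 10,
              ipilimumab = 30),
      background_event_prob = 0.002, combo_fraction = 0,
      duplicate_rate = 0.02, seed = 400 + s)
    st <- build_report_store(generate_faers(cfg)$tables)
    sig <- signal_table(st, as.list(agents))
    for (stat in names(ok)) {
      if (!is.unsorted(sig[[stat]])) ok[stat] <- ok[stat] + 1
    }
  }
  for (stat in names(ok)) expect_gte(ok[[stat]], n_seeds - 1)
})
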
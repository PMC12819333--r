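# Time-to-onset: validity filtering, descriptive summaries, Weibull hazard
# typing, Kaplan-Meier cumulative onset, and pairwise rank tests.

#' Compute time-to-onset from partial dates
#'
#' Onset is the calendar-day difference between the event date and the
#' therapy start date.  A value is valid only when both dates have day
#' precision and the difference is at least one day; otherwise the record is
#' tagged with a reason: `omission` (either date missing or partial),
#' `discrepancy` (negative difference) or `same-day` (zero days — excluded
#' because a zero-day span is indistinguishable from a date-entry
#' duplication).  Vectorized; never throws.
#'
#' @param start,event parsed partial dates ([parse_partial_date()] frames)
#'   or raw date strings.
#' @return a `data.frame` with columns `tto_days` (integer, `NA` when
#'   invalid) and `status` (`valid`, `omission`, `discrepancy`, `same-day`).
#' @export
compute_tto <- function(start, event) {
  if (is.character(start)) start <- parse_partial_date(start)
  if (is.character(event)) event <- parse_partial_date(event)
  n <- nrow(start)
  stopifnot(nrow(event) == n)
  status <- rep("omission", n)
  days <- rep(NA_integer_, n)
  ok <- !is.na(start$precision) & start$precision == "day" &
        !is.na(event$precision) & event$precision == "day"
  if (any(ok)) {
    d0 <- as.Date(sprintf("%04d-%02d-%02d", start$year[ok], start$month[ok],
                          start$day[ok]))
    d1 <- as.Date(sprintf("%04d-%02d-%02d", event$year[ok], event$month[ok],
                          event$day[ok]))
    diff <- as.integer(d1 - d0)
    st <- ifelse(diff < 0, "discrepancy", ifelse(diff == 0, "same-day", "valid"))
    status[ok] <- st
    valid_idx <- which(ok)[st == "valid"]
    days[valid_idx] <- diff[st == "valid"]
  }
  data.frame(tto_days = days, status = status, stringsAsFactors = FALSE)
}

#' Extract per-report time-to-onset for a cohort
#'
#' For each cohort report, the therapy start is the earliest day-precision
#' `START_DT` among THER rows linked to the suspect ICI drug (by
#' drug-sequence key when both tables carry one, otherwise any THER row of
#' the report); the event date is the report's `EVENT_DT`.
#'
#' @param store a `faers_store`.
#' @param cohort_ids PRIMARYIDs of the cohort.
#' @param regimens optional [classify_regimens()] table for exposure labels.
#' @return a `data.table` with columns `primaryid`, `class`, `tto_days`,
#'   `status`.
#' @export
extract_tto <- function(store, cohort_ids, regimens = NULL) {
  if (is.null(regimens)) regimens <- classify_regimens(store$drug)
  rep_tab <- store$reports[as.character(store$reports$primaryid) %in% cohort_ids]
  ther <- store$ther[as.character(store$ther$PRIMARYID) %in% cohort_ids]

  # restrict to THER rows of the suspect ICI when the drug-sequence join exists
  seq_col <- intersect(c("DSG_DRUG_SEQ", "DRUG_SEQ"), names(ther))
  if (length(seq_col) > 0L && "DRUG_SEQ" %in% names(store$drug)) {
    dr <- store$drug
    ag <- map_drug(dr$DRUGNAME)$agent
    ici_seq <- unique(data.table::data.table(
      PRIMARYID = as.character(dr$PRIMARYID[!is.na(ag)]),
      seqkey = as.character(dr$DRUG_SEQ[!is.na(ag)])))
    th_key <- data.table::data.table(
      PRIMARYID = as.character(ther$PRIMARYID),
      seqkey = as.character(ther[[seq_col[1L]]]),
      START_DT = ther$START_DT)
    joined <- merge(th_key, ici_seq, by = c("PRIMARYID", "seqkey"))
    # fall back to all THER rows for reports with no joined row
    unmatched <- setdiff(unique(th_key$PRIMARYID), unique(joined$PRIMARYID))
    ther_use <- rbind(joined[, c("PRIMARYID", "START_DT")],
                      th_key[th_key$PRIMARYID %in% unmatched,
                             c("PRIMARYID", "START_DT")])
  } else {
    ther_use <- data.table::data.table(PRIMARYID = as.character(ther$PRIMARYID),
                                       START_DT = ther$START_DT)
  }

  # earliest day-precision start per report
  pd <- parse_partial_date(ther_use$START_DT)
  ther_use <- ther_use[!is.na(pd$precision) & pd$precision == "day"]
  starts <- if (nrow(ther_use) > 0L) {
    ther_use[, .(START_DT = min(START_DT)), by = "PRIMARYID"]
  } else {
    data.table::data.table(PRIMARYID = character(0), START_DT = character(0))
  }

  ids <- as.character(rep_tab$primaryid)
  start_raw <- starts$START_DT[match(ids, starts$PRIMARYID)]
  start_raw[is.na(start_raw)] <- ""
  tto <- compute_tto(start_raw, as.character(rep_tab$event_dt))
  cls <- regimens$class[match(ids, regimens$primaryid)]
  data.table::data.table(primaryid = ids, class = cls,
                         tto_days = tto$tto_days, status = tto$status)
}

#' Descriptive time-to-onset summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7); min and max exact.
#'
#' @param x positive onset values (days), `n >= 1`.
#' @return list with `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_tto <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("summarize_tto: empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       min = min(x), max = max(x))
}

# Weibull maximum likelihood via the profile score equation: for shape k the
# profile scale is (mean(x^k))^(1/k), and k solves
#   1/k + mean(log x) - sum(x^k log x) / sum(x^k) = 0,
# whose left side is strictly decreasing in k.
.weibull_mle <- function(x) {
  lx <- log(x)
  mlx <- mean(lx)
  g <- function(k) {
    xk <- exp(k * lx)
    1 / k + mlx - sum(xk * lx) / sum(xk)
  }
  sol <- stats::uniroot(g, interval = c(0.02, 50), extendInt = "downX",
                        tol = 1e-10)
  k <- sol$root
  scale <- mean(exp(k * lx))^(1 / k)
  c(shape = k, scale = scale)
}

#' Fit a Weibull onset-time model with hazard typing
#'
#' Maximum-likelihood fit of a Weibull distribution (scale `alpha` in days,
#' shape `beta`) to uncensored onset times, with seeded nonparametric
#' bootstrap percentile confidence intervals.  The shape parameter types the
#' hazard: `beta < 1` (upper CI bound below 1) is *early failure* — onset
#' risk peaks just after treatment start and declines; lower CI bound above
#' 1 is *wear-out* (increasing hazard); otherwise *random* (roughly constant
#' hazard, the exponential special case).
#'
#' @param x positive onset values (days); at least 10, not all identical.
#' @param boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (0.95).
#' @return an object of class `weibull_fit`: list with `scale_alpha`,
#'   `shape_beta`, `alpha_ci`, `beta_ci`, `failure_type`, `n_used`, `boot`.
#' @export
fit_weibull <- function(x, boot = 1000L, seed = 1L, conf = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 10L) stop("fit_weibull: need at least 10 values")
  if (length(unique(x)) == 1L) stop("fit_weibull: degenerate sample (all values identical)")
  if (any(x <= 0)) stop("fit_weibull: values must be positive")
  est <- .weibull_mle(x)
  lo_p <- (1 - conf) / 2
  hi_p <- 1 - lo_p
  bs <- .with_seed(seed, {
    reps <- vapply(seq_len(boot), function(i) {
      xi <- x[sample.int(length(x), replace = TRUE)]
      if (length(unique(xi)) == 1L) return(c(NA_real_, NA_real_))
      .weibull_mle(xi)
    }, numeric(2))
    reps
  })
  beta_ci <- stats::quantile(bs[1, ], c(lo_p, hi_p), na.rm = TRUE, names = FALSE)
  alpha_ci <- stats::quantile(bs[2, ], c(lo_p, hi_p), na.rm = TRUE, names = FALSE)
  type <- if (beta_ci[2] < 1) "early" else if (beta_ci[1] > 1) "wear-out" else "random"
  structure(list(scale_alpha = unname(est["scale"]),
                 shape_beta = unname(est["shape"]),
                 alpha_ci = alpha_ci, beta_ci = beta_ci,
                 failure_type = type, n_used = length(x), boot = boot),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d): alpha = %.2f (%.2f, %.2f) days; beta = %.3f (%.3f, %.3f); %s failure\n",
              x$n_used, x$scale_alpha, x$alpha_ci[1], x$alpha_ci[2],
              x$shape_beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

# run expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Kaplan-Meier cumulative onset curve
#'
#' Product-limit estimate of the cumulative onset proportion.  Case-only
#' onset data carry no censoring, so the curve equals the empirical CDF; the
#' function accepts event times only and refuses censoring indicators by
#' construction.
#'
#' @param x positive onset values (days), `n >= 1`.
#' @return a `data.frame` with columns `time` (ascending event times) and
#'   `cumulative_onset` (nondecreasing, reaching 1 at the last time).
#' @export
km_onset <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("km_onset: empty sample")
  fit <- survival::survfit(survival::Surv(x, rep(1L, length(x))) ~ 1)
  data.frame(time = fit$time, cumulative_onset = 1 - fit$surv)
}

#' Onset fractions at cutpoints
#'
#' Fraction of cases with onset within the first cutpoint (`<= cut[1]`
#' days, "within the first month" for the default 30) and after the second
#' (`> cut[2]` days, "after 6 months" for the default 180).
#'
#' @param x positive onset values (days), `n >= 1`.
#' @param cutpoints two cutpoints in days, default `c(30, 180)`.
#' @return list with `within_first` and `after_second` (proportions in
#'   `[0, 1]`).
#' @export
onset_fractions <- function(x, cutpoints = c(30, 180)) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("onset_fractions: empty sample")
  list(within_first = mean(x <= cutpoints[1]),
       after_second = mean(x > cutpoints[2]))
}

#' Pairwise Mann-Whitney tests with Bonferroni adjustment
#'
#' Two-sided Mann-Whitney U test for each requested pair of groups: exact
#' enumeration when both groups have at most 8 observations and no ties,
#' tie-corrected normal approximation (no continuity correction) otherwise.
#' Raw p-values are Bonferroni-adjusted by the number of comparisons
#' (`p_adj = min(1, m * p_raw)`); significance at adjusted `p < 0.05`.
#' Overlapping-group contrasts (e.g. a pooled group against one of its
#' subgroups) are allowed but violate independence between tests; they are
#' computed as requested, fidelity over orthodoxy.
#'
#' @param groups named list of numeric vectors.
#' @param comparisons list of 2-element character vectors (group name
#'   pairs); defaults to all unordered pairs.
#' @return a `data.frame` with columns `group1`, `group2`, `u_statistic`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
mann_whitney_bonferroni <- function(groups, comparisons = NULL) {
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    g1 <- cmp[[1]]; g2 <- cmp[[2]]
    if (!g1 %in% names(groups)) stop("unknown group label: ", g1)
    if (!g2 %in% names(groups)) stop("unknown group label: ", g2)
    x <- groups[[g1]]; y <- groups[[g2]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 8 && length(y) <= 8 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    data.frame(group1 = g1, group2 = g2,
               u_statistic = unname(wt$statistic),
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$significant <- out$p_adjusted < 0.05
  out
}
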
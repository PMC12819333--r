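# Whole-database 2x2 disproportionality statistics: ROR, PRR/chi-squared,
# BCPNN information component, and MGPS empirical-Bayes shrinkage.

#' 2x2 contingency table for one drug-event pair
#'
#' Cell `a` counts reports with both the exposure and the event, `b`
#' exposure without the event, `c` event without the exposure, and `d`
#' neither; the unit of counting is the deduplicated report.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency_table: cells must be nonnegative integers")
  }
  if (sum(cells) < 1) stop("contingency_table: N must be >= 1")
  structure(as.list(cells), N = sum(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "not exposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build a contingency table from a report store
#'
#' Exposure membership follows the regimen classification: an `agent` spec
#' matches monotherapy reports of that agent; a `combo` spec matches that
#' combination label; a `class` or `all` spec matches any report whose
#' primary-suspect set intersects the class (or any ICI), pooling
#' monotherapy and combination reports.  The comparator (`c`, `d`) is the
#' whole remaining database, unstratified.
#'
#' @param store a `faers_store`.
#' @param exposure a spec from [exposure_spec()], or a string shorthand: an
#'   agent name, a class name, a combination label, or `"all"`.
#' @param term_list event preferred-term list.
#' @param regimens optional precomputed [classify_regimens()] table (computed
#'   from `store$drug` otherwise).
#' @param dict drug dictionary.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(store, exposure, term_list = default_pemphigoid_terms(),
                              regimens = NULL, dict = default_drug_dictionary()) {
  if (nrow(store$reports) == 0L) stop("build_contingency: empty report store")
  if (is.character(exposure)) exposure <- exposure_spec(exposure)
  if (is.null(regimens)) regimens <- classify_regimens(store$drug, dict)
  event_ids <- select_event_reports(store$reac, term_list)
  .contingency_from_sets(as.character(store$reports$primaryid),
                         exposed_reports(regimens, exposure), event_ids)
}

.contingency_from_sets <- function(all_ids, exposed_ids, event_ids) {
  exp_in <- all_ids %in% exposed_ids
  ev_in <- all_ids %in% event_ids
  contingency_table(a = sum(exp_in & ev_in), b = sum(exp_in & !ev_in),
                    c = sum(!exp_in & ev_in), d = sum(!exp_in & !ev_in))
}

#' Exposure specifications
#'
#' @param value agent name, class name, combination label, or `"all"`.
#' @param type one of `"agent"`, `"class"`, `"combo"`, `"all"`; inferred from
#'   `value` when omitted.
#' @return a list with elements `type` and `value`, class `exposure_spec`.
#' @export
exposure_spec <- function(value, type = NULL) {
  if (is.null(type)) {
    type <- if (tolower(value) %in% c("all", "all icis")) "all"
    else if (value %in% .ici_agents$agent) "agent"
    else if (value %in% unique(.ici_agents$class)) "class"
    else if (grepl("+", value, fixed = TRUE)) "combo"
    else stop("cannot infer exposure type for ", value,
              "; pass type explicitly")
  }
  structure(list(type = type, value = value), class = "exposure_spec")
}

#' Report ids matching an exposure spec
#'
#' @param regimens a [classify_regimens()] table.
#' @param spec an [exposure_spec()].
#' @return character vector of PRIMARYIDs.
#' @export
exposed_reports <- function(regimens, spec) {
  r <- regimens
  sel <- switch(spec$type,
    agent = r$regimen == "monotherapy" & r$agent == spec$value,
    combo = r$regimen == "combination" & r$combo_label == spec$value,
    class = {
      agents <- .ici_agents$agent[.ici_agents$class == spec$value]
      vapply(strsplit(r$agents_ps, ",", fixed = TRUE),
             function(a) any(a %in% agents), logical(1))
    },
    all = r$regimen != "none",
    stop("unknown exposure type: ", spec$type))
  sel[is.na(sel)] <- FALSE
  as.character(r$primaryid[sel])
}

.haldane <- function(tab) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (any(cells == 0)) list(cells = cells + 0.5, degenerate = TRUE)
  else list(cells = cells, degenerate = FALSE)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = ad / bc`; the 95% interval is
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  If any cell is zero,
#' 0.5 is added to all four cells (Haldane correction) and the result is
#' flagged degenerate.
#'
#' @param tab a [contingency_table()].
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return list with `ror`, `ci_low`, `ci_high`, `degenerate`.
#' @export
ror_stat <- function(tab, z = 1.96) {
  h <- .haldane(tab)
  a <- h$cells[1]; b <- h$cells[2]; c <- h$cells[3]; d <- h$cells[4]
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror,
       ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se),
       degenerate = h$degenerate)
}

#' Proportional reporting ratio and 2x2 chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is the Pearson
#' statistic on the 2x2 table, without continuity correction by default
#' (Yates-corrected available via `yates = TRUE`).  The zero-cell rule of
#' [ror_stat()] applies.
#'
#' @param tab a [contingency_table()].
#' @param yates apply the Yates continuity correction to the chi-squared.
#' @return list with `prr`, `chi2`, `degenerate`.
#' @export
prr_stat <- function(tab, yates = FALSE) {
  h <- .haldane(tab)
  a <- h$cells[1]; b <- h$cells[2]; c <- h$cells[3]; d <- h$cells[4]
  prr <- (a / (a + b)) / (c / (c + d))
  n <- a + b + c + d
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(prr = prr, chi2 = chi2, degenerate = h$degenerate)
}

#' BCPNN information component (closed-form posterior approximation)
#'
#' The information component is the Bayesian-shrunk `log2` ratio of the
#' observed to expected joint reporting probability.  With cell margins
#' `cx = a+b`, `cy = a+c`, `C = N`, prior constants
#' `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1` and
#' `gamma = gamma11 (C+alpha)(C+beta) / ((cx+alpha1)(cy+beta1))`:
#'
#' `IC = log2[ (a+gamma11)(C+alpha)(C+beta) / ((C+gamma)(cx+alpha1)(cy+beta1)) ]`
#'
#' with the standard closed-form variance, and `IC025 = IC - z * sqrt(V)`.
#' Defined for `a = 0`; no zero-cell correction is applied.
#'
#' @param tab a [contingency_table()].
#' @param z normal quantile for the lower bound (1.96).
#' @return list with `ic_expect`, `ic_var`, `ic025`.
#' @export
bcpnn_ic <- function(tab, z = 1.96) {
  a <- tab$a; C <- attr(tab, "N")
  cx <- tab$a + tab$b
  cy <- tab$a + tab$c
  if (C == 0) stop("bcpnn_ic: N must be positive")
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (C + al) * (C + be) / ((cx + a1) * (cy + b1))
  ic <- log2((a + g11) * (C + al) * (C + be) /
               ((C + g) * (cx + a1) * (cy + b1)))
  v <- (1 / log(2)^2) * (
    (C - a + g - g11) / ((a + g11) * (1 + C + g)) +
    (C - cx + al - a1) / ((cx + a1) * (1 + C + al)) +
    (C - cy + be - b1) / ((cy + b1) * (1 + C + be)))
  list(ic_expect = ic, ic_var = v, ic025 = ic - z * sqrt(v))
}

#' Fit MGPS gamma-mixture hyperparameters
#'
#' The multi-item gamma Poisson shrinker models observed pair counts
#' `a_ij ~ Poisson(lambda_ij * E_ij)` with relative reporting rates
#' `lambda` drawn from a two-component gamma mixture
#' `p * Gamma(alpha1, beta1) + (1-p) * Gamma(alpha2, beta2)`.  The marginal
#' of each count is then a mixture of negative binomials, and the
#' hyperparameters are the maximizers of the marginal likelihood over the
#' whole drug-by-event grid (zero cells included).  Optimization is
#' derivative-free (Nelder-Mead) on log-/logit-transformed parameters from
#' the customary start `(0.2, 0.1, 2.0, 4.0, 1/3)`.
#'
#' @param a integer vector of observed pair counts over the grid.
#' @param E positive baseline expected counts `(row total)(col total)/N`.
#' @return an object of class `mgps_hyperparams`: list with `alpha1`,
#'   `beta1`, `alpha2`, `beta2`, `mix_p`, `loglik`, `convergence`.
#' @export
mgps_fit <- function(a, E) {
  stopifnot(length(a) == length(E))
  if (length(a) < 10L) {
    stop("mgps_fit: need at least 10 grid cells to identify hyperparameters")
  }
  if (any(E <= 0)) stop("mgps_fit: all E must be positive")
  nll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    l1 <- log(p) + stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
    l2 <- log1p(-p) + stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
    m <- pmax(l1, l2)
    -sum(m + log(exp(l1 - m) + exp(l2 - m)))
  }
  start <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  structure(list(alpha1 = exp(fit$par[1]), beta1 = exp(fit$par[2]),
                 alpha2 = exp(fit$par[3]), beta2 = exp(fit$par[4]),
                 mix_p = stats::plogis(fit$par[5]),
                 loglik = -fit$value, convergence = fit$convergence),
            class = "mgps_hyperparams")
}

#' @export
print.mgps_hyperparams <- function(x, ...) {
  cat(sprintf("MGPS prior: %.3f * Gamma(%.4g, %.4g) + %.3f * Gamma(%.4g, %.4g); loglik %.2f\n",
              x$mix_p, x$alpha1, x$beta1, 1 - x$mix_p, x$alpha2, x$beta2,
              x$loglik))
  invisible(x)
}

#' Empirical-Bayes geometric mean and its 5th percentile
#'
#' Given fitted hyperparameters, the posterior of the relative reporting
#' rate for a cell with count `a` and baseline `E` is the gamma mixture
#' `Q * Gamma(alpha1+a, beta1+E) + (1-Q) * Gamma(alpha2+a, beta2+E)` with
#' `Q` the posterior component weight.  `EBGM = 2^(E[log2 lambda | a])` via
#' the digamma function; `EBGM05` is the 0.05 quantile of the posterior
#' mixture, found by bisection on the mixture CDF (absolute tolerance
#' 1e-8).  Vectorized over `a` and `E`.
#'
#' @param a observed count(s).
#' @param E baseline expected count(s), positive.
#' @param hyper an [mgps_fit()] object (or compatible list).
#' @param q lower quantile (0.05).
#' @return list with vectors `ebgm` and `ebgm05`.
#' @export
mgps_ebgm <- function(a, E, hyper, q = 0.05) {
  if (any(E <= 0)) stop("mgps_ebgm: E must be positive")
  a1 <- hyper$alpha1; b1 <- hyper$beta1
  a2 <- hyper$alpha2; b2 <- hyper$beta2
  p <- hyper$mix_p
  l1 <- log(p) + stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- log1p(-p) + stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  Q <- 1 / (1 + exp(l2 - l1))
  ebgm <- exp(Q * (digamma(a1 + a) - log(b1 + E)) +
                (1 - Q) * (digamma(a2 + a) - log(b2 + E)))
  # bisection on the mixture CDF
  mix_cdf <- function(x) {
    Q * stats::pgamma(x, shape = a1 + a, rate = b1 + E) +
      (1 - Q) * stats::pgamma(x, shape = a2 + a, rate = b2 + E)
  }
  lo <- rep(0, length(ebgm))
  hi <- pmax(stats::qgamma(1 - 1e-12, shape = a1 + a, rate = b1 + E),
             stats::qgamma(1 - 1e-12, shape = a2 + a, rate = b2 + E))
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    below <- mix_cdf(mid) < q
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-8) break
  }
  list(ebgm = ebgm, ebgm05 = (lo + hi) / 2)
}

#' Positivity criteria for the four algorithms
#'
#' Established thresholds: ROR-positive iff `ROR > 1`, lower 95% bound `> 1`
#' and at least three case reports; PRR-positive iff `PRR >= 2`,
#' `chi2 >= 4` and at least three reports; BCPNN-positive iff `IC025 > 0`;
#' MGPS-positive iff `EBGM05 > 2`.  An exposure with fewer than three case
#' reports is reported with all flags `FALSE` (the "False" annotation of
#' signal tables).
#'
#' @param n_cases number of case reports (`a`).
#' @param ror,ror_low ROR point estimate and lower 95% bound.
#' @param prr,chi2 PRR point estimate and chi-squared statistic.
#' @param ic025 lower 95% bound of the information component.
#' @param ebgm05 5th percentile of the EBGM posterior.
#' @return list of logical flags `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`.
#' @export
evaluate_criteria <- function(n_cases, ror, ror_low, prr, chi2, ic025, ebgm05) {
  enough <- n_cases >= 3
  list(ror_pos = enough & ror > 1 & ror_low > 1,
       prr_pos = enough & prr >= 2 & chi2 >= 4,
       bcpnn_pos = enough & ic025 > 0,
       mgps_pos = enough & ebgm05 > 2)
}

#' Full drug-by-event pair grid for MGPS fitting
#'
#' Counts, for every (primary-suspect drug, preferred term) pair in the
#' store, the number of reports carrying both, and the baseline expectation
#' `E_ij = (row_i total)(col_j total) / N` from the pair-count margins.
#' Drug names are dictionary-mapped to agents where possible (raw normalized
#' names otherwise); zero cells are included.
#'
#' @param store a `faers_store`.
#' @param dict drug dictionary.
#' @return a `data.table` with columns `drug`, `event`, `a`, `E`.
#' @export
build_pair_grid <- function(store, dict = default_drug_dictionary()) {
  dr <- store$drug
  ps <- dr[toupper(trimws(dr$ROLE_COD)) == "PS"]
  mapped <- map_drug(ps$DRUGNAME, dict)$agent
  key <- ifelse(is.na(mapped), normalize_drug_name(ps$DRUGNAME), mapped)
  pairs <- unique(data.table::data.table(
    primaryid = as.character(ps$PRIMARYID), drug = key))
  ev <- unique(data.table::data.table(
    primaryid = as.character(store$reac$PRIMARYID),
    event = tolower(trimws(store$reac$PT))))
  de <- merge(pairs, ev, by = "primaryid", allow.cartesian = TRUE)
  cnt <- de[, .(a = .N), by = c("drug", "event")]
  grid <- data.table::CJ(drug = unique(pairs$drug), event = unique(ev$event))
  grid <- merge(grid, cnt, by = c("drug", "event"), all.x = TRUE)
  grid[is.na(a), a := 0L]
  N <- sum(grid$a)
  grid[, row_tot := sum(a), by = "drug"]
  grid[, col_tot := sum(a), by = "event"]
  grid[, E := row_tot * col_tot / N]
  grid[, c("row_tot", "col_tot") := NULL]
  grid[]
}

#' Signal table across exposures
#'
#' Computes, for each exposure, the 2x2 table and all four statistics with
#' positivity flags, mirroring the layout of published signal tables:
#' columns `exposure`, `n`, `ROR`, `ROR_low`, `ROR_high`, `PRR`, `chi2`,
#' `EBGM`, `EBGM05`, `IC`, `IC025`, the four flags and `degenerate`.  The
#' MGPS baseline for an exposure uses `E = (a+b)(a+c)/N` from its own 2x2
#' margins; hyperparameters are fitted once on the full pair grid.
#'
#' @param store a `faers_store`.
#' @param exposures list of [exposure_spec()]s or strings.
#' @param term_list event preferred-term list.
#' @param dict drug dictionary.
#' @param hyper optional precomputed [mgps_fit()] result.
#' @param yates use Yates-corrected chi-squared.
#' @param z normal quantile for ROR/BCPNN bounds.
#' @return a `data.frame`, one row per exposure.
#' @export
signal_table <- function(store, exposures, term_list = default_pemphigoid_terms(),
                         dict = default_drug_dictionary(), hyper = NULL,
                         yates = FALSE, z = 1.96) {
  regimens <- classify_regimens(store$drug, dict)
  if (is.null(hyper)) {
    grid <- build_pair_grid(store, dict)
    hyper <- mgps_fit(grid$a, grid$E)
  }
  all_ids <- as.character(store$reports$primaryid)
  event_ids <- select_event_reports(store$reac, term_list)
  rows <- lapply(exposures, function(ex) {
    if (is.character(ex)) ex <- exposure_spec(ex)
    tab <- .contingency_from_sets(all_ids, exposed_reports(regimens, ex),
                                  event_ids)
    ror <- ror_stat(tab, z)
    prr <- prr_stat(tab, yates)
    ic <- bcpnn_ic(tab, z)
    N <- attr(tab, "N")
    E <- (tab$a + tab$b) * (tab$a + tab$c) / N
    eb <- if (E > 0) mgps_ebgm(tab$a, E, hyper)
          else list(ebgm = NA_real_, ebgm05 = NA_real_)
    fl <- evaluate_criteria(tab$a, ror$ror, ror$ci_low, prr$prr, prr$chi2,
                            ic$ic025, eb$ebgm05)
    data.frame(exposure = ex$value, n = tab$a,
               ROR = ror$ror, ROR_low = ror$ci_low, ROR_high = ror$ci_high,
               PRR = prr$prr, chi2 = prr$chi2,
               EBGM = eb$ebgm, EBGM05 = eb$ebgm05,
               IC = ic$ic_expect, IC025 = ic$ic025,
               ror_pos = fl$ror_pos, prr_pos = fl$prr_pos,
               mgps_pos = fl$mgps_pos, bcpnn_pos = fl$bcpnn_pos,
               degenerate = ror$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
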
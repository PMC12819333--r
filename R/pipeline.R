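# Config-driven orchestration: read -> dedup -> cohort -> disproportionality
# -> time-to-onset, with machine-readable outputs.

#' Pipeline run configuration
#'
#' @param quarter_dirs character vector of quarter directories to read.
#' @param out_dir output directory for the report bundle.
#' @param dictionary_path,term_path optional config-file paths (packaged
#'   defaults otherwise).
#' @param exposures exposure specs (strings) to evaluate; `NULL` evaluates
#'   `"all"`, the three classes, every agent with at least one case, and
#'   every combination label with at least one case.
#' @param yates,bcpnn_z chi-squared variant and BCPNN normal quantile.
#' @param boot,seed bootstrap replicates and master seed; all randomness
#'   (bootstraps, per-group) derives from `seed` via a fixed splitting
#'   scheme.
#' @param cutpoints onset-fraction cutpoints in days.
#' @param comparisons Mann-Whitney comparison pairs; default the six pairs
#'   among All-ICIs and the three classes.
#' @param delim FAERS field delimiter.
#' @return a list of class `run_config`.
#' @export
run_config <- function(quarter_dirs, out_dir,
                       dictionary_path = NULL, term_path = NULL,
                       exposures = NULL, yates = FALSE, bcpnn_z = 1.96,
                       boot = 1000L, seed = 17L, cutpoints = c(30, 180),
                       comparisons = NULL, delim = "$") {
  missing_dirs <- quarter_dirs[!dir.exists(quarter_dirs)]
  if (length(missing_dirs) > 0L) {
    stop("run_config: quarter directories not found: ",
         paste(missing_dirs, collapse = ", "))
  }
  if (is.null(comparisons)) {
    comparisons <- list(c("All ICIs", "CTLA-4i"), c("All ICIs", "PD-L1i"),
                        c("All ICIs", "PD-1i"), c("CTLA-4i", "PD-L1i"),
                        c("CTLA-4i", "PD-1i"), c("PD-L1i", "PD-1i"))
  }
  structure(list(quarter_dirs = quarter_dirs, out_dir = out_dir,
                 dictionary_path = dictionary_path, term_path = term_path,
                 exposures = exposures, yates = yates, bcpnn_z = bcpnn_z,
                 boot = as.integer(boot), seed = as.integer(seed),
                 cutpoints = cutpoints, comparisons = comparisons,
                 delim = delim),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# deterministic seed splitting: child k of master seed s
.split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 10007) %% 2147483647)
}

#' Run the full signal-detection and onset pipeline
#'
#' Executes read -> deduplication -> cohort construction -> per-exposure
#' disproportionality -> time-to-onset, and writes the report bundle to
#' `config$out_dir`: `cohort_summary.tsv`, `signals.tsv`, `tto_tests.tsv`,
#' `weibull.tsv`, `onset_curves.tsv`, `flow_counts.json` (counts at each
#' filtering step) and `run_log.txt`.  Machine TSVs keep full precision;
#' rounding for display is left to the caller.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with every computed artifact.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dict <- read_drug_dictionary(config$dictionary_path)
  terms <- read_term_list(config$term_path)
  stage <- "read"
  res <- tryCatch({
    quarters <- lapply(config$quarter_dirs, read_quarter, delim = config$delim)
    stage <- "dedup"
    store <- build_report_store(quarters)
    stage <- "cohort"
    regimens <- classify_regimens(store$drug, dict)
    event_ids <- select_event_reports(store$reac, terms)
    ici_ids <- as.character(regimens$primaryid[regimens$regimen != "none"])
    cohort_ids <- intersect(ici_ids, event_ids)
    cohort_reports <- store$reports[as.character(store$reports$primaryid) %in% cohort_ids]
    summary <- summarize_cohort(cohort_reports, indi = store$indi,
                                drug = store$drug, dict = dict)

    stage <- "disprop"
    exposures <- config$exposures
    if (is.null(exposures)) {
      in_cohort <- regimens[regimens$primaryid %in% cohort_ids]
      agents <- sort(unique(stats::na.omit(in_cohort$agent[in_cohort$regimen == "monotherapy"])))
      combos <- sort(unique(stats::na.omit(in_cohort$combo_label)))
      exposures <- c("all", unique(.ici_agents$class), agents, combos)
    }
    signals <- signal_table(store, as.list(exposures), terms, dict,
                            yates = config$yates, z = config$bcpnn_z)

    stage <- "tto"
    tto <- extract_tto(store, cohort_ids, regimens)
    valid <- tto[tto$status == "valid"]
    groups <- list("All ICIs" = valid$tto_days)
    for (cc in unique(.ici_agents$class)) {
      groups[[cc]] <- valid$tto_days[!is.na(valid$class) & valid$class == cc]
    }
    comparisons <- Filter(function(cmp) {
      length(groups[[cmp[1]]]) >= 1 && length(groups[[cmp[2]]]) >= 1
    }, config$comparisons)
    tto_tests <- if (length(comparisons) > 0L) {
      mann_whitney_bonferroni(groups, comparisons)
    } else {
      data.frame(group1 = character(0), group2 = character(0),
                 u_statistic = numeric(0), p_raw = numeric(0),
                 p_adjusted = numeric(0), significant = logical(0))
    }

    weib_rows <- list()
    curve_rows <- list()
    gi <- 0L
    for (g in names(groups)) {
      gi <- gi + 1L
      x <- groups[[g]]
      if (length(x) < 1L) next
      s <- summarize_tto(x)
      fr <- onset_fractions(x, config$cutpoints)
      w <- if (length(x) >= 10L && length(unique(x)) > 1L) {
        fit_weibull(x, boot = config$boot, seed = .split_seed(config$seed, gi))
      } else NULL
      weib_rows[[g]] <- data.frame(
        group = g, n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
        min = s$min, max = s$max,
        within_first_pct = 100 * fr$within_first,
        after_second_pct = 100 * fr$after_second,
        alpha = if (is.null(w)) NA_real_ else w$scale_alpha,
        alpha_low = if (is.null(w)) NA_real_ else w$alpha_ci[1],
        alpha_high = if (is.null(w)) NA_real_ else w$alpha_ci[2],
        beta = if (is.null(w)) NA_real_ else w$shape_beta,
        beta_low = if (is.null(w)) NA_real_ else w$beta_ci[1],
        beta_high = if (is.null(w)) NA_real_ else w$beta_ci[2],
        failure_type = if (is.null(w)) NA_character_ else w$failure_type,
        stringsAsFactors = FALSE)
      km <- km_onset(x)
      curve_rows[[g]] <- data.frame(group = g, time = km$time,
                                    cumulative_onset = km$cumulative_onset)
    }
    weibull <- do.call(rbind, weib_rows)
    curves <- do.call(rbind, curve_rows)

    flow <- list(
      demo_rows_read = store$dedup_report$rows_read,
      reports_after_dedup = store$dedup_report$reports_kept,
      ici_ps_reports = length(ici_ids),
      event_reports = length(intersect(event_ids,
                                       as.character(store$reports$primaryid))),
      cohort_reports = length(cohort_ids),
      tto_valid = nrow(valid))

    list(store = store, cohort_ids = cohort_ids, summary = summary,
         signals = signals, tto = tto, tto_tests = tto_tests,
         weibull = weibull, curves = curves, flow = flow)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out, f), sep = "\t")
  fw(as.data.frame(res$summary), "cohort_summary.tsv")
  fw(res$signals, "signals.tsv")
  fw(res$tto_tests, "tto_tests.tsv")
  if (!is.null(res$weibull)) fw(res$weibull, "weibull.tsv")
  if (!is.null(res$curves)) fw(res$curves, "onset_curves.tsv")
  jsonlite::write_json(res$flow, file.path(out, "flow_counts.json"),
                       auto_unbox = TRUE)
  log_lines <- c(
    paste0("pvsignal ", as.character(utils::packageVersion("pvsignal"))),
    R.version.string,
    paste0("seed: ", config$seed),
    paste0("quarters: ", paste(config$quarter_dirs, collapse = ", ")),
    paste0("boot: ", config$boot, "; yates: ", config$yates,
           "; bcpnn_z: ", config$bcpnn_z),
    paste0("cutpoints: ", paste(config$cutpoints, collapse = ",")),
    paste0("elapsed_s: ", round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(res)
}
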
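# Reading FAERS-style quarterly ASCII tables, partial dates, and the FDA
# deduplication rule.

.faers_tables <- c("demo", "drug", "reac", "ther", "outc", "indi")

# Required columns per table, after legacy-header mapping (ISR -> PRIMARYID,
# CASE -> CASEID).  SEX is special-cased: either SEX or GNDR_COD qualifies.
.required_cols <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE", "AGE_COD",
           "OCCR_COUNTRY", "OCCP_COD"),
  drug = c("PRIMARYID", "DRUGNAME", "ROLE_COD"),
  reac = c("PRIMARYID", "PT"),
  ther = c("PRIMARYID", "START_DT"),
  outc = c("PRIMARYID", "OUTC_COD"),
  indi = c("PRIMARYID", "INDI_PT")
)

#' Read one FAERS-style quarter
#'
#' Reads the six core tables (DEMO, DRUG, REAC, THER, OUTC, INDI) from a
#' directory of `"$"`-delimited ASCII files with a header row, as distributed
#' by the FDA.  Column-name matching is case-insensitive; `GNDR_COD` is
#' accepted as a synonym for `SEX`, and the legacy (pre-2012) headers `ISR`
#' and `CASE` are mapped to `PRIMARYID` and `CASEID`.  Raw field strings are
#' preserved verbatim; rows whose field count does not match the header are
#' skipped and counted in the read report.
#'
#' @param dir directory containing one file per table; files are located by
#'   name prefix (`demo*`, `drug*`, ... case-insensitively).
#' @param delim field delimiter, `"$"` by FAERS convention (`"|"` occurs in
#'   some older quarters).
#' @param quarter optional quarter label (e.g. `"2019Q3"`); defaults to the
#'   directory name.
#' @return an object of class `faers_tables`: a list with one `data.table`
#'   per table (character columns, upper-cased canonical names), the quarter
#'   label, and a `read_report` (rows read/skipped per table, orphan counts).
#' @export
read_quarter <- function(dir, delim = "$", quarter = basename(normalizePath(dir))) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  tables <- list()
  report <- list()
  for (tab in .faers_tables) {
    hit <- files[grepl(paste0("^", tab), tolower(basename(files)))]
    if (length(hit) == 0L) {
      stop("required FAERS file missing from ", dir, ": ", toupper(tab))
    }
    parsed <- .read_dollar_file(hit[[1L]], delim)
    dt <- .canonicalize_headers(parsed$data, tab)
    tables[[tab]] <- dt
    report[[tab]] <- list(rows_read = parsed$rows_read,
                          rows_skipped = parsed$rows_skipped)
  }
  # flag orphans: non-DEMO rows whose PRIMARYID does not join to DEMO
  demo_ids <- unique(tables$demo$PRIMARYID)
  for (tab in setdiff(.faers_tables, "demo")) {
    report[[tab]]$orphan_rows <- sum(!(tables[[tab]]$PRIMARYID %in% demo_ids))
  }
  structure(list(tables = tables, quarter = quarter, read_report = report),
            class = "faers_tables")
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("FAERS quarter", x$quarter, "\n")
  for (tab in .faers_tables) {
    skipped <- x$read_report[[tab]]$rows_skipped
    cat(sprintf("  %s: %d rows (%d skipped)\n", toupper(tab),
                nrow(x$tables[[tab]]),
                if (is.null(skipped)) 0L else skipped))
  }
  invisible(x)
}

# Line-level reader: FAERS files are plain "$"-delimited text with no quoting,
# so fields are split literally.  Rows with the wrong field count are dropped
# and counted rather than guessed at.
.read_dollar_file <- function(path, delim) {
  lines <- readLines(path, encoding = "latin1", warn = FALSE)
  if (length(lines) == 0L) stop("file has no header row: ", path)
  header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  header <- toupper(trimws(header))
  ncol <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    cols <- replicate(ncol, character(0), simplify = FALSE)
    names(cols) <- header
    return(list(data = data.table::as.data.table(cols),
                rows_read = 0L, rows_skipped = 0L))
  }
  parts <- strsplit(body, delim, fixed = TRUE)
  # strsplit drops the single empty field after a trailing delimiter; pad it
  # back so "a$b$" parses as three fields
  trailing <- endsWith(body, delim)
  parts[trailing] <- lapply(parts[trailing], function(p) c(p, ""))
  lens <- lengths(parts)
  good <- lens == ncol
  parts <- parts[good]
  if (length(parts) == 0L) {
    cols <- replicate(ncol, character(0), simplify = FALSE)
  } else {
    cols <- data.table::transpose(parts)
  }
  names(cols) <- header
  list(data = data.table::as.data.table(cols),
       rows_read = sum(good), rows_skipped = sum(!good))
}

# Map headers to canonical names and check required columns.
.canonicalize_headers <- function(dt, tab) {
  nm <- toupper(names(dt))
  nm[nm == "ISR"] <- "PRIMARYID"
  nm[nm == "CASE"] <- "CASEID"
  if (tab == "demo") nm[nm == "GNDR_COD"] <- "SEX"
  data.table::setnames(dt, nm)
  need <- .required_cols[[tab]]
  if (tab == "demo") need <- c(need, "SEX")
  missing <- setdiff(need, nm)
  if (length(missing) > 0L) {
    stop("table ", toupper(tab), " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dt
}

#' Parse FAERS partial date strings
#'
#' FAERS dates are 8-digit (`YYYYMMDD`), 6-digit (`YYYYMM`) or 4-digit
#' (`YYYY`) strings.  Anything else (empty, non-digit, out-of-range month or
#' day, or a day-precision string that is not a real calendar date) is
#' returned as missing; the parser never throws.
#'
#' @param x character vector of raw date strings.
#' @return a `data.frame` with columns `year`, `month`, `day` (integer, `NA`
#'   where absent) and `precision` (`"year"`, `"month"`, `"day"`, or `NA` for
#'   missing).
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)
  digits <- grepl("^[0-9]+$", x)
  len <- nchar(x)

  i4 <- digits & len == 4L
  year[i4] <- as.integer(x[i4])
  precision[i4] <- "year"

  i6 <- digits & len == 6L
  year[i6] <- as.integer(substr(x[i6], 1L, 4L))
  month[i6] <- as.integer(substr(x[i6], 5L, 6L))
  precision[i6] <- "month"

  i8 <- digits & len == 8L
  year[i8] <- as.integer(substr(x[i8], 1L, 4L))
  month[i8] <- as.integer(substr(x[i8], 5L, 6L))
  day[i8] <- as.integer(substr(x[i8], 7L, 8L))
  precision[i8] <- "day"

  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  # day precision must be a real calendar date (rules out e.g. Feb 30)
  i_day <- which(precision == "day" & !bad_month & !bad_day)
  if (length(i_day) > 0L) {
    d <- as.Date(sprintf("%04d-%02d-%02d", year[i_day], month[i_day], day[i_day]),
                 format = "%Y-%m-%d")
    bad_day[i_day[is.na(d)]] <- TRUE
  }
  bad <- bad_month | bad_day
  year[bad] <- NA_integer_
  month[bad] <- NA_integer_
  day[bad] <- NA_integer_
  precision[bad] <- NA_character_
  data.frame(year = year, month = month, day = day, precision = precision,
             stringsAsFactors = FALSE)
}

#' Deduplicate DEMO rows by the FDA rule
#'
#' Spontaneous-report databases carry several versions of the same case.  The
#' FDA rule keeps, for each `CASEID`, the record with the latest `FDA_DT`;
#' ties on `FDA_DT` are broken by the highest `PRIMARYID`.  Records with an
#' unparseable `FDA_DT` sort before any dated record (they deterministically
#' lose ties) and are noted in the drop log.
#'
#' @param demo a data.frame/data.table with columns `PRIMARYID`, `CASEID`,
#'   `FDA_DT`.
#' @return a list with `keep` (character vector of kept PRIMARYIDs) and
#'   `drops` (a `data.table` with columns `dropped_primaryid`, `caseid`,
#'   `reason`).
#' @export
deduplicate <- function(demo) {
  demo <- data.table::as.data.table(demo)
  need <- c("PRIMARYID", "CASEID", "FDA_DT")
  missing <- setdiff(need, names(demo))
  if (length(missing) > 0L) {
    stop("deduplicate: missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(demo) == 0L) {
    return(list(keep = character(0),
                drops = data.table::data.table(dropped_primaryid = character(0),
                                               caseid = character(0),
                                               reason = character(0))))
  }
  d <- demo[, .(PRIMARYID = as.character(PRIMARYID),
                CASEID = as.character(CASEID),
                FDA_DT = as.character(FDA_DT))]
  fda_key <- d$FDA_DT
  parseable <- grepl("^[0-9]{8}$", fda_key)
  if (any(!parseable)) {
    warning(sum(!parseable), " DEMO row(s) with unparseable FDA_DT treated as earliest date")
    fda_key[!parseable] <- "00000000"
  }
  d[, `:=`(fda_key = fda_key, pid_num = suppressWarnings(as.numeric(PRIMARYID)))]
  data.table::setorder(d, CASEID, -fda_key, -pid_num)
  keep_idx <- !duplicated(d$CASEID)
  kept <- d[keep_idx]
  dropped <- d[!keep_idx]
  # reason: lost on date, or lost the PRIMARYID tiebreak at equal date
  best_date <- kept$fda_key[match(dropped$CASEID, kept$CASEID)]
  reason <- ifelse(dropped$fda_key < best_date, "older_fda_dt", "lower_primaryid")
  list(keep = kept$PRIMARYID,
       drops = data.table::data.table(dropped_primaryid = dropped$PRIMARYID,
                                      caseid = dropped$CASEID,
                                      reason = reason))
}

# FAERS age-unit codes -> years.
.age_factor <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.14, DY = 1 / 365.25,
                 DEC = 10, HR = 1 / 8766)

.convert_age_years <- function(age, age_cod) {
  age_num <- suppressWarnings(as.numeric(age))
  f <- .age_factor[toupper(trimws(age_cod))]
  out <- age_num * as.numeric(f)
  out[is.na(f)] <- NA_real_
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

.parse_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unspecified", length(x))
  out[x == "M"] <- "male"
  out[x == "F"] <- "female"
  out
}

.hcp_codes <- c("MD", "PH", "OT", "RN", "HP")
.non_hcp_codes <- c("CN", "LW")

.parse_reporter <- function(x) {
  x <- toupper(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% .hcp_codes] <- "healthcare professional"
  out[x %in% .non_hcp_codes] <- "non-healthcare professional"
  out
}

.outcome_map <- c(HO = "hospitalization", LT = "life-threatening",
                  DS = "disability", DE = "death", OT = "other",
                  CA = "other", RI = "other")

#' Build a normalized report store from raw tables
#'
#' Applies [deduplicate()] to DEMO, drops orphan rows from the other tables,
#' and normalizes demographics: age to years via the FAERS age-unit codes
#' (`YR`, `MON`, `WK`, `DY`, `DEC`, `HR`; unknown codes give missing age,
#' ages outside 0-120 are set missing), sex to
#' male/female/unspecified, reporter occupation to healthcare /
#' non-healthcare professional, country from `OCCR_COUNTRY` (falling back to
#' `REPORTER_COUNTRY` when present and `OCCR_COUNTRY` is blank), and outcome
#' codes to category labels collected once per report.
#'
#' @param x a `faers_tables` object from [read_quarter()] (or a compatible
#'   list of tables), or a list of several such objects whose tables are
#'   concatenated before deduplication.
#' @return an object of class `faers_store`: list with `reports` (one row per
#'   deduplicated report), the filtered `drug`, `reac`, `ther`, `indi`
#'   tables, and a `dedup_report` list.
#' @export
build_report_store <- function(x) {
  if (inherits(x, "faers_tables")) x <- list(x)
  tabs <- list()
  for (tname in .faers_tables) {
    tabs[[tname]] <- data.table::rbindlist(
      lapply(x, function(q) q$tables[[tname]]), use.names = TRUE, fill = TRUE)
  }
  demo <- tabs$demo
  if (nrow(demo) == 0L) stop("report store: no DEMO rows")
  dd <- deduplicate(demo)
  demo <- demo[demo$PRIMARYID %in% dd$keep]
  # a PRIMARYID should be unique post-dedup; belt-and-braces against exact
  # duplicate DEMO rows
  demo <- demo[!duplicated(demo$PRIMARYID)]

  outc <- tabs$outc[tabs$outc$PRIMARYID %in% demo$PRIMARYID]
  outcomes <- character(nrow(demo))
  if (nrow(outc) > 0L) {
    oc <- .outcome_map[toupper(trimws(outc$OUTC_COD))]
    oc[is.na(oc)] <- "other"
    agg <- data.table::data.table(PRIMARYID = outc$PRIMARYID, cat = oc)
    agg <- agg[, .(out = paste(sort(unique(cat)), collapse = ",")), by = "PRIMARYID"]
    outcomes[match(agg$PRIMARYID, demo$PRIMARYID)] <- agg$out
  }

  country <- trimws(demo$OCCR_COUNTRY)
  if ("REPORTER_COUNTRY" %in% names(demo)) {
    fb <- trimws(demo$REPORTER_COUNTRY)
    country[!nzchar(country)] <- fb[!nzchar(country)]
  }
  country[!nzchar(country)] <- NA_character_

  reports <- data.table::data.table(
    primaryid = demo$PRIMARYID,
    caseid = demo$CASEID,
    fda_dt = demo$FDA_DT,
    event_dt = demo$EVENT_DT,
    sex = .parse_sex(demo$SEX),
    age_years = .convert_age_years(demo$AGE, demo$AGE_COD),
    country = country,
    reporter = .parse_reporter(demo$OCCP_COD),
    outcomes = outcomes
  )

  keep_ids <- reports$primaryid
  store <- list(
    reports = reports,
    drug = tabs$drug[tabs$drug$PRIMARYID %in% keep_ids],
    reac = tabs$reac[tabs$reac$PRIMARYID %in% keep_ids],
    ther = tabs$ther[tabs$ther$PRIMARYID %in% keep_ids],
    indi = tabs$indi[tabs$indi$PRIMARYID %in% keep_ids],
    dedup_report = list(
      rows_read = nrow(tabs$demo),
      duplicates_dropped = nrow(dd$drops),
      reports_kept = nrow(reports),
      drops = dd$drops
    )
  )
  class(store) <- "faers_store"
  store
}

#' @export
print.faers_store <- function(x, ...) {
  cat("faers_store:", nrow(x$reports), "deduplicated reports",
      sprintf("(%d raw DEMO rows, %d duplicates dropped)\n",
              x$dedup_report$rows_read, x$dedup_report$duplicates_dropped))
  invisible(x)
}

# Fixed column order of the serialized report store.
.store_columns <- c("primaryid", "caseid", "fda_dt", "event_dt", "sex",
                    "age_years", "country", "reporter", "outcomes")

#' Write / read a report store
#'
#' The store is serialized as tab-separated values with a fixed column order
#' (`primaryid`, `caseid`, `fda_dt`, `event_dt`, `sex`, `age_years`,
#' `country`, `reporter`, `outcomes`) plus the filtered DRUG/REAC/THER/INDI
#' tables and a JSON read/dedup report.
#'
#' @param store a `faers_store`.
#' @param dir output (input) directory.
#' @return `write_report_store` returns `dir` invisibly; `read_report_store`
#'   returns a `faers_store`.
#' @export
write_report_store <- function(store, dir) {
  stopifnot(inherits(store, "faers_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(store$reports[, .store_columns, with = FALSE],
                     file.path(dir, "reports.tsv"), sep = "\t")
  for (tab in c("drug", "reac", "ther", "indi")) {
    data.table::fwrite(store[[tab]], file.path(dir, paste0(tab, ".tsv")), sep = "\t")
  }
  rep <- store$dedup_report
  jsonlite::write_json(
    list(rows_read = rep$rows_read,
         duplicates_dropped = rep$duplicates_dropped,
         reports_kept = rep$reports_kept),
    file.path(dir, "dedup_report.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_report_store
#' @export
read_report_store <- function(dir) {
  reports <- data.table::fread(file.path(dir, "reports.tsv"), sep = "\t",
                               colClasses = list(character = setdiff(.store_columns, "age_years")))
  store <- list(reports = reports)
  for (tab in c("drug", "reac", "ther", "indi")) {
    store[[tab]] <- data.table::fread(file.path(dir, paste0(tab, ".tsv")),
                                      sep = "\t", colClasses = "character")
  }
  store$dedup_report <- jsonlite::read_json(file.path(dir, "dedup_report.json"))
  class(store) <- "faers_store"
  store
}
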
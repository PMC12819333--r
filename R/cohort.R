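# Drug-dictionary mapping, event-term selection, regimen classification and
# demographic summaries.

# Canonical agent -> class table (immune checkpoint inhibitors).
.ici_agents <- data.table::data.table(
  agent = c("nivolumab", "pembrolizumab", "cemiplimab", "dostarlimab",
            "tislelizumab", "atezolizumab", "avelumab", "durvalumab",
            "ipilimumab", "tremelimumab"),
  class = c(rep("PD-1i", 5), rep("PD-L1i", 3), rep("CTLA-4i", 2)),
  abbrev = c("Nivo", "Pemb", "Cemi", "Dost", "Tisl",
             "Atez", "Avel", "Durv", "Ipil", "Trem")
)

#' Canonical ICI agent table
#'
#' The ten immune-checkpoint-inhibitor agents and their target classes:
#' PD-1 inhibitors (nivolumab, pembrolizumab, cemiplimab, dostarlimab,
#' tislelizumab), PD-L1 inhibitors (atezolizumab, avelumab, durvalumab) and
#' CTLA-4 inhibitors (ipilimumab, tremelimumab).
#'
#' @return a `data.table` with columns `agent`, `class`, `abbrev`.
#' @export
ici_agents <- function() data.table::copy(.ici_agents)

#' Drug-name dictionary
#'
#' A dictionary maps normalized raw drug names (generic and brand synonyms)
#' to a standardized agent and its class.  The packaged default covers the
#' ten ICI agents; users can supply their own flat file (one
#' `raw_name<TAB>agent` entry per line) to extend the machinery to other
#' drug families.
#'
#' @param path optional path to a two-column tab-separated file; default is
#'   the packaged ICI dictionary.
#' @return an object of class `drug_dictionary` (a `data.table` with columns
#'   `raw`, `agent`, `class`).
#' @export
read_drug_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ici_dictionary.tsv", package = "pvsignal")
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("raw", "agent"), colClasses = "character")
  dt[, raw := normalize_drug_name(raw)]
  dt <- merge(dt, .ici_agents[, c("agent", "class")], by = "agent",
              all.x = TRUE, sort = FALSE)
  unknown <- unique(dt$agent[is.na(dt$class)])
  if (length(unknown) > 0L) {
    # non-ICI families get a class equal to the agent name
    dt[is.na(class), class := agent]
  }
  data.table::setcolorder(dt, c("raw", "agent", "class"))
  structure(dt, class = c("drug_dictionary", class(dt)))
}

#' @rdname read_drug_dictionary
#' @export
default_drug_dictionary <- function() read_drug_dictionary(NULL)

#' Normalize a raw drug name
#'
#' Upper-cases, trims, strips dosage/formulation suffixes (anything after the
#' first comma or opening parenthesis), collapses punctuation runs to single
#' spaces, and squeezes whitespace — so `"nivolumab."` and `"NIVOLUMAB"`
#' normalize identically.
#'
#' @param x character vector of raw drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- sub("[,(].*$", "", x)
  x <- gsub("[^A-Z0-9-]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("(^[ -]+)|([ -]+$)", "", x)
  x
}

#' Map raw drug names to standardized agents
#'
#' Total function: names absent from the dictionary map to `NA` (not an
#' error).  Matching is exact after [normalize_drug_name()].
#'
#' @param raw_name character vector of raw drug names.
#' @param dict a [read_drug_dictionary()] object.
#' @return a `data.frame` with columns `agent` and `class` (`NA` for
#'   unmapped names), one row per input.
#' @export
map_drug <- function(raw_name, dict = default_drug_dictionary()) {
  key <- normalize_drug_name(raw_name)
  i <- match(key, dict$raw)
  data.frame(agent = dict$agent[i], class = dict$class[i],
             stringsAsFactors = FALSE)
}

#' Read an event preferred-term list
#'
#' One preferred term per line; blank lines and lines starting with `#` are
#' ignored.  The packaged default is a pemphigoid PT list standing in for
#' the MedDRA standardized query "pemphigoid" (MedDRA itself is licensed and
#' not redistributable).
#'
#' @param path optional path; default the packaged pemphigoid list.
#' @return character vector of preferred terms.
#' @export
read_term_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pemphigoid_terms.txt", package = "pvsignal")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_term_list
#' @export
default_pemphigoid_terms <- function() read_term_list(NULL)

#' Select reports carrying an event of interest
#'
#' A report qualifies if any of its REAC preferred terms matches the term
#' list case-insensitively after whitespace trimming.
#'
#' @param reac REAC table (columns `PRIMARYID`, `PT`).
#' @param term_list character vector of preferred terms (non-empty).
#' @return character vector of qualifying PRIMARYIDs.
#' @export
select_event_reports <- function(reac, term_list) {
  if (length(term_list) == 0L) stop("select_event_reports: empty term list")
  terms <- tolower(trimws(term_list))
  hit <- tolower(trimws(reac$PT)) %in% terms
  unique(as.character(reac$PRIMARYID[hit]))
}

#' Classify therapy regimens per report
#'
#' A report is ICI *monotherapy* when exactly one ICI agent appears on it
#' (with role primary suspect, PS); *combination* when two or more ICI agents
#' appear with at least one PS; and unexposed (`none`) when no ICI is PS.
#' Combination reports get an ordered label built from agent abbreviations in
#' canonical class order (e.g. `"Nivo+Ipi"`).
#'
#' @param drug DRUG table (columns `PRIMARYID`, `DRUGNAME`, `ROLE_COD`).
#' @param dict drug dictionary.
#' @return a `data.table` with one row per PRIMARYID present in `drug`:
#'   columns `primaryid`, `regimen` (`monotherapy`/`combination`/`none`),
#'   `agent` (the single agent for monotherapy, else `NA`), `class` (class of
#'   the PS agent(s); `NA` if mixed-class PS or none), `combo_label`,
#'   `agents_ps`, `agents_any` (comma-joined).
#' @export
classify_regimens <- function(drug, dict = default_drug_dictionary()) {
  d <- data.table::data.table(
    primaryid = as.character(drug$PRIMARYID),
    agent = map_drug(drug$DRUGNAME, dict)$agent,
    role = toupper(trimws(drug$ROLE_COD))
  )
  ord <- stats::setNames(seq_len(nrow(.ici_agents)), .ici_agents$agent)
  cls <- stats::setNames(.ici_agents$class, .ici_agents$agent)
  abbr <- stats::setNames(.ici_agents$abbrev, .ici_agents$agent)
  d[!(agent %in% .ici_agents$agent), agent := NA_character_]

  all_ids <- unique(d$primaryid)
  per <- data.table::data.table(primaryid = all_ids,
                                regimen = "none", agent = NA_character_,
                                class = NA_character_,
                                combo_label = NA_character_,
                                agents_ps = "", agents_any = "")
  ia <- unique(d[!is.na(agent), c("primaryid", "agent")])
  if (nrow(ia) == 0L) return(per)
  ips <- unique(d[!is.na(agent) & role == "PS", c("primaryid", "agent")])
  if (nrow(ips) == 0L) return(per)

  # only reports with >=1 PS ICI are exposed; the heavy string assembly runs
  # on that subset alone
  ia <- ia[primaryid %in% ips$primaryid]
  ia[, ord_key := ord[agent]]
  data.table::setorder(ia, primaryid, ord_key)
  agg_any <- ia[, .(n_any = .N,
                    agents_any = paste(sort(agent), collapse = ","),
                    combo_label = paste(abbr[agent], collapse = "+"),
                    first_agent = agent[1L]), by = "primaryid"]
  data.table::setorder(ips, primaryid, agent)
  agg_ps <- ips[, .(agents_ps = paste(agent, collapse = ","),
                    ps_classes = length(unique(cls[agent])),
                    ps_class1 = cls[agent[1L]]), by = "primaryid"]
  agg <- merge(agg_any, agg_ps, by = "primaryid")

  i <- match(agg$primaryid, per$primaryid)
  mono <- agg$n_any == 1L
  per$regimen[i] <- ifelse(mono, "monotherapy", "combination")
  per$agent[i[mono]] <- agg$first_agent[mono]
  per$class[i] <- ifelse(agg$ps_classes == 1L, agg$ps_class1, NA_character_)
  per$combo_label[i[!mono]] <- agg$combo_label[!mono]
  per$agents_ps[i] <- agg$agents_ps
  per$agents_any[i] <- agg$agents_any
  per
}

#' Classify the regimen of a single report
#'
#' @param drug_rows DRUG rows for one report.
#' @param dict drug dictionary.
#' @return one-row result of [classify_regimens()] as a list.
#' @export
classify_regimen <- function(drug_rows, dict = default_drug_dictionary()) {
  as.list(classify_regimens(drug_rows, dict)[1L])
}

.age_band <- function(age) {
  band <- rep("missing", length(age))
  band[!is.na(age) & age < 18] <- "<18"
  band[!is.na(age) & age >= 18 & age <= 60] <- "18-60"
  band[!is.na(age) & age > 60] <- ">60"
  factor(band, levels = c("<18", "18-60", ">60", "missing"))
}

#' Summarize a cohort's clinical characteristics
#'
#' Produces Table-1-style breakdowns: counts by sex, by age band
#' (`<18`, `18-60`, `>60`, with 18 and 60 in the middle band), top reported
#' countries, reporter occupation, outcome categories (counted once per
#' report per category; a report can contribute to several, so outcome
#' counts may exceed the cohort size), top indications, and the median age
#' over non-missing ages (ordinary sample median).
#'
#' @param reports the `reports` table of a `faers_store`, restricted to the
#'   cohort of interest (deduplicated).
#' @param indi optional INDI table for the same reports (columns
#'   `PRIMARYID`, `INDI_PT`, optionally `INDI_DRUG_SEQ`).
#' @param drug optional DRUG table; when both `indi` and `drug` carry
#'   drug-sequence keys, indications are joined to the ICI drug sequence,
#'   otherwise all indication terms of a report are used.
#' @param dict drug dictionary (used only for the indication join).
#' @param top_k_countries,top_k_indications how many top categories to keep.
#' @return an object of class `cohort_summary`: a list of count tables plus
#'   `n` and `median_age`.
#' @export
summarize_cohort <- function(reports, indi = NULL, drug = NULL,
                             dict = default_drug_dictionary(),
                             top_k_countries = 3L, top_k_indications = 5L) {
  n <- nrow(reports)
  sex <- table(factor(reports$sex, levels = c("male", "female", "unspecified")))
  band <- table(.age_band(reports$age_years))
  ages <- reports$age_years[!is.na(reports$age_years)]
  median_age <- if (length(ages) > 0L) stats::median(ages) else NA_real_

  top_count <- function(x, k) {
    x[is.na(x) | !nzchar(x)] <- NA
    tab <- table(x, useNA = "no")
    if (length(tab) == 0L) {
      return(data.table::data.table(value = character(0), count = integer(0)))
    }
    df <- data.table::data.table(value = names(tab), count = as.integer(tab))
    data.table::setorder(df, -count, value)  # ties broken alphabetically
    utils::head(df, k)
  }

  countries <- top_count(reports$country, top_k_countries)

  reporter <- reports$reporter
  reporter[is.na(reporter)] <- "missing"
  rep_tab <- table(factor(reporter, levels = c("healthcare professional",
                                               "non-healthcare professional",
                                               "missing")))

  oc <- strsplit(reports$outcomes, ",", fixed = TRUE)
  oc_flat <- unlist(lapply(seq_along(oc), function(i) unique(oc[[i]])))
  oc_flat <- oc_flat[nzchar(oc_flat)]
  outcome_levels <- c("hospitalization", "life-threatening", "disability",
                      "death", "other")
  outcomes <- table(factor(oc_flat, levels = outcome_levels))

  indications <- NULL
  if (!is.null(indi) && nrow(indi) > 0L) {
    ind <- data.table::as.data.table(indi)
    ind <- ind[as.character(ind$PRIMARYID) %in% as.character(reports$primaryid)]
    seq_col <- intersect(c("INDI_DRUG_SEQ", "DRUG_SEQ"), names(ind))
    if (!is.null(drug) && length(seq_col) > 0L &&
        "DRUG_SEQ" %in% names(drug)) {
      # keep indications attached to the ICI drug sequence when the key exists
      dr <- data.table::as.data.table(drug)
      dr[, agent := map_drug(DRUGNAME, dict)$agent]
      ici_seq <- dr[!is.na(agent),
                    .(PRIMARYID = as.character(PRIMARYID),
                      seqkey = as.character(DRUG_SEQ))]
      ind_key <- data.table::data.table(PRIMARYID = as.character(ind$PRIMARYID),
                                        seqkey = as.character(ind[[seq_col[1L]]]),
                                        pt = trimws(ind$INDI_PT))
      joined <- merge(ind_key, ici_seq, by = c("PRIMARYID", "seqkey"))
      if (nrow(joined) > 0L) {
        indications <- top_count(joined$pt, top_k_indications)
      }
    }
    if (is.null(indications)) {
      indications <- top_count(trimws(ind$INDI_PT), top_k_indications)
    }
  }

  structure(list(n = n,
                 sex = sex,
                 age_band = band,
                 median_age = median_age,
                 countries = countries,
                 reporter = rep_tab,
                 outcomes = outcomes,
                 indications = indications),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "reports; median age",
      ifelse(is.na(x$median_age), "NA", format(x$median_age)), "years\n")
  cat("  sex:", paste(names(x$sex), as.integer(x$sex), collapse = ", "), "\n")
  cat("  age:", paste(names(x$age_band), as.integer(x$age_band), collapse = ", "), "\n")
  if (nrow(x$countries) > 0L) {
    cat("  top countries:",
        paste(x$countries$value, x$countries$count, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a cohort summary into a long table
#'
#' @param x a `cohort_summary`.
#' @param ... unused.
#' @return a `data.frame` with columns `characteristic`, `value`, `count`.
#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  out <- list(
    data.frame(characteristic = "n", value = "cohort", count = x$n),
    data.frame(characteristic = "sex", value = names(x$sex),
               count = as.integer(x$sex)),
    data.frame(characteristic = "age_band", value = names(x$age_band),
               count = as.integer(x$age_band)),
    data.frame(characteristic = "median_age", value = "years",
               count = x$median_age),
    data.frame(characteristic = "reporter", value = names(x$reporter),
               count = as.integer(x$reporter)),
    data.frame(characteristic = "outcome", value = names(x$outcomes),
               count = as.integer(x$outcomes))
  )
  if (nrow(x$countries) > 0L) {
    out <- c(out, list(data.frame(characteristic = "country",
                                  value = x$countries$value,
                                  count = x$countries$count)))
  }
  if (!is.null(x$indications) && nrow(x$indications) > 0L) {
    out <- c(out, list(data.frame(characteristic = "indication",
                                  value = x$indications$value,
                                  count = x$indications$count)))
  }
  do.call(rbind, out)
}
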
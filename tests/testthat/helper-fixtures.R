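# In-code fixtures: hand-built stores and table sets for unit tests.

empty_dt <- function(...) {
  cols <- c(...)
  out <- replicate(length(cols), character(0), simplify = FALSE)
  names(out) <- cols
  data.table::as.data.table(out)
}

# a minimal faers_store built directly from data.frames
make_store <- function(reports, drug = NULL, reac = NULL, ther = NULL,
                       indi = NULL) {
  if (is.null(drug)) drug <- empty_dt("PRIMARYID", "DRUG_SEQ", "DRUGNAME", "ROLE_COD")
  if (is.null(reac)) reac <- empty_dt("PRIMARYID", "PT")
  if (is.null(ther)) ther <- empty_dt("PRIMARYID", "DSG_DRUG_SEQ", "START_DT")
  if (is.null(indi)) indi <- empty_dt("PRIMARYID", "INDI_DRUG_SEQ", "INDI_PT")
  structure(list(reports = data.table::as.data.table(reports),
                 drug = data.table::as.data.table(drug),
                 reac = data.table::as.data.table(reac),
                 ther = data.table::as.data.table(ther),
                 indi = data.table::as.data.table(indi),
                 dedup_report = list(rows_read = nrow(reports),
                                     duplicates_dropped = 0L,
                                     reports_kept = nrow(reports))),
            class = "faers_store")
}

make_reports <- function(n, ids = as.character(seq_len(n))) {
  data.table::data.table(primaryid = ids, caseid = ids,
                         fda_dt = "20200101", event_dt = "",
                         sex = "unspecified", age_years = NA_real_,
                         country = NA_character_, reporter = NA_character_,
                         outcomes = "")
}

# a 4-report store covering each contingency cell once for exposure
# "nivolumab" (monotherapy) x event "Pemphigoid"
make_four_cell_store <- function() {
  reports <- make_reports(4)
  drug <- data.table::data.table(
    PRIMARYID = c("1", "2", "3", "4"),
    DRUG_SEQ = "1",
    DRUGNAME = c("NIVOLUMAB", "NIVOLUMAB", "ASPIRIN", "ASPIRIN"),
    ROLE_COD = "PS")
  reac <- data.table::data.table(
    PRIMARYID = c("1", "2", "3", "4"),
    PT = c("Pemphigoid", "Nausea", "Pemphigoid", "Nausea"))
  make_store(reports, drug = drug, reac = reac)
}

# brute-force two-sided exact Mann-Whitney p-value by enumerating all
# assignments of the pooled sample (no ties assumed)
enumerate_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_all <- apply(idx, 2, function(i) {
    xs <- pooled[i]; ys <- pooled[-i]
    sum(outer(xs, ys, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}
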
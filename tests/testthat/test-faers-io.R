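test_that("partial dates parse 8/6/4-digit strings and reject malformed input", {
  pd <- parse_partial_date(c("20200131", "202006", "2020", "2020-01", "",
                             "20200230", "202013", "abc"))
  expect_equal(pd$precision,
               c("day", "month", "year", NA, NA, NA, NA, NA))
  expect_equal(pd$year[1:3], c(2020L, 2020L, 2020L))
  expect_equal(pd$month[1:2], c(1L, 6L))
  expect_equal(pd$day[1], 31L)
  # day implies month present for every day-precision result
  ok <- !is.na(pd$precision) & pd$precision == "day"
  expect_true(all(!is.na(pd$month[ok])))
})

test_that("deduplication keeps latest FDA_DT then highest PRIMARYID per case", {
  one <- data.frame(PRIMARYID = "1", CASEID = "A", FDA_DT = "20200101")
  expect_equal(deduplicate(one)$keep, "1")

  later <- data.frame(PRIMARYID = c("1", "2"), CASEID = "A",
                      FDA_DT = c("20200101", "20200301"))
  dd <- deduplicate(later)
  expect_equal(dd$keep, "2")
  expect_equal(dd$drops$reason, "older_fda_dt")

  tie <- data.frame(PRIMARYID = c("5", "9"), CASEID = "A",
                    FDA_DT = "20200101")
  dd <- deduplicate(tie)
  expect_equal(dd$keep, "9")
  expect_equal(dd$drops$reason, "lower_primaryid")
})

test_that("deduplication is idempotent and keeps one report per case", {
  set.seed(42)
  for (i in 1:5) {
    n <- 200
    demo <- data.frame(
      PRIMARYID = as.character(sample(1e6, n)),
      CASEID = as.character(sample(50, n, replace = TRUE)),
      FDA_DT = format(as.Date("2019-01-01") + sample(0:900, n, TRUE), "%Y%m%d"))
    dd <- deduplicate(demo)
    expect_equal(length(dd$keep), length(unique(demo$CASEID)))
    expect_lte(length(dd$keep), nrow(demo))
    # applying again to the kept rows changes nothing
    dd2 <- deduplicate(demo[demo$PRIMARYID %in% dd$keep, ])
    expect_setequal(dd2$keep, dd$keep)
    expect_equal(nrow(dd2$drops), 0L)
  }
})

test_that("unparseable FDA_DT sorts first and loses deterministically", {
  demo <- data.frame(PRIMARYID = c("7", "3"), CASEID = "A",
                     FDA_DT = c("", "20200101"))
  expect_warning(dd <- deduplicate(demo), "unparseable")
  expect_equal(dd$keep, "3")
})

test_that("read_quarter tolerates dialects and reports malformed rows", {
  dir <- withr::local_tempdir()
  writeLines(c("ISR$CASE$FDA_DT$EVENT_DT$GNDR_COD$AGE$AGE_COD$OCCR_COUNTRY$OCCP_COD",
               "1$A$20200101$20200131$M$71$YR$US$MD",
               "2$B$20200102$$F$65$YR$JP$CN",
               "broken$row"),
             file.path(dir, "demo.txt"))
  writeLines(c("ISR$DRUGNAME$ROLE_COD", "1$OPDIVO$PS", "2$ASPIRIN$PS"),
             file.path(dir, "drug.txt"))
  writeLines(c("ISR$PT", "1$Pemphigoid", "2$Nausea", "99$Orphan term"),
             file.path(dir, "reac.txt"))
  writeLines("ISR$START_DT", file.path(dir, "ther.txt"))
  writeLines("ISR$OUTC_COD", file.path(dir, "outc.txt"))
  writeLines("ISR$INDI_PT", file.path(dir, "indi.txt"))

  q <- read_quarter(dir)
  # legacy ISR/CASE headers map to PRIMARYID/CASEID; GNDR_COD to SEX
  expect_equal(q$tables$demo$PRIMARYID, c("1", "2"))
  expect_equal(q$tables$demo$CASEID, c("A", "B"))
  expect_equal(q$tables$demo$SEX, c("M", "F"))
  expect_equal(q$read_report$demo$rows_skipped, 1L)
  expect_equal(q$read_report$reac$orphan_rows, 1L)

  st <- build_report_store(q)
  expect_equal(st$reports$sex, c("male", "female"))
  expect_equal(st$reports$age_years, c(71, 65))
  # orphan REAC row excluded from the store
  expect_false("99" %in% st$reac$PRIMARYID)
})

test_that("read_quarter fails loudly on missing files and columns", {
  dir <- withr::local_tempdir()
  expect_error(read_quarter(dir), "DEMO")
  writeLines("PRIMARYID$FDA_DT", file.path(dir, "demo.txt"))  # no CASEID etc.
  for (f in c("drug", "reac", "ther", "outc", "indi")) {
    writeLines("PRIMARYID$X", file.path(dir, paste0(f, ".txt")))
  }
  expect_error(read_quarter(dir), "DEMO.*CASEID")
})

test_that("empty data files give empty rowsets without error", {
  dir <- withr::local_tempdir()
  writeLines("PRIMARYID$CASEID$FDA_DT$EVENT_DT$SEX$AGE$AGE_COD$OCCR_COUNTRY$OCCP_COD",
             file.path(dir, "demo.txt"))
  writeLines("PRIMARYID$DRUGNAME$ROLE_COD", file.path(dir, "drug.txt"))
  writeLines("PRIMARYID$PT", file.path(dir, "reac.txt"))
  writeLines("PRIMARYID$START_DT", file.path(dir, "ther.txt"))
  writeLines("PRIMARYID$OUTC_COD", file.path(dir, "outc.txt"))
  writeLines("PRIMARYID$INDI_PT", file.path(dir, "indi.txt"))
  q <- read_quarter(dir)
  expect_equal(nrow(q$tables$demo), 0L)
  expect_equal(nrow(q$tables$reac), 0L)
})

test_that("synthetic quarters round-trip through write and read", {
  cfg <- synthetic_config(n_reports = 60L, seed = 9L)
  dir <- withr::local_tempdir()
  g <- generate_faers(cfg, dir = dir)
  q <- read_quarter(dir)
  for (tab in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    expect_equal(as.data.frame(q$tables[[tab]]),
                 as.data.frame(g$tables$tables[[tab]]),
                 info = tab)
  }
})

test_that("age units convert to years and implausible ages go missing", {
  demo <- data.table::data.table(
    PRIMARYID = as.character(1:6), CASEID = as.character(1:6),
    FDA_DT = "20200101", EVENT_DT = "",
    SEX = "M", AGE = c("71", "24", "730", "7", "500", "71"),
    AGE_COD = c("YR", "MON", "DY", "DEC", "YR", "XX"),
    OCCR_COUNTRY = "US", OCCP_COD = "MD")
  tabs <- structure(list(tables = list(
    demo = demo,
    drug = empty_dt("PRIMARYID", "DRUGNAME", "ROLE_COD"),
    reac = empty_dt("PRIMARYID", "PT"),
    ther = empty_dt("PRIMARYID", "START_DT"),
    outc = empty_dt("PRIMARYID", "OUTC_COD"),
    indi = empty_dt("PRIMARYID", "INDI_PT"))), class = "faers_tables")
  st <- build_report_store(tabs)
  expect_equal(st$reports$age_years[1], 71)
  expect_equal(st$reports$age_years[2], 2)
  expect_equal(st$reports$age_years[3], 730 / 365.25)
  expect_equal(st$reports$age_years[4], 70)
  expect_true(is.na(st$reports$age_years[5]))  # 500 years -> missing
  expect_true(is.na(st$reports$age_years[6]))  # unknown unit -> missing
})

test_that("report store serializes to TSV and back", {
  cfg <- synthetic_config(n_reports = 40L, seed = 5L)
  st <- build_report_store(generate_faers(cfg)$tables)
  dir <- withr::local_tempdir()
  write_report_store(st, dir)
  st2 <- read_report_store(dir)
  expect_equal(nrow(st2$reports), nrow(st$reports))
  expect_equal(st2$reports$primaryid, st$reports$primaryid)
  expect_equal(st2$dedup_report$reports_kept, st$dedup_report$reports_kept)
})
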
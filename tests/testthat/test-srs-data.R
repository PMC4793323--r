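write_fixture_tables <- function(dir,
                                 demo = NULL, drug = NULL, reac = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(demo)) {
    demo <- tibble::tibble(
      case_id = c("A", "B", "C"),
      report_date = c("2010-01-15", "2011-06-02", "2014-11-30"),
      age = c(34, 61, NA),
      sex = c("male", "female", "male")
    )
  }
  if (is.null(drug)) {
    drug <- tibble::tibble(
      case_id = c("A", "A", "B"),
      generic_name = c("Sitagliptin Phosphate Hydrate", "metformin hydrochloride",
                       "liraglutide"),
      role = c("suspected", "concomitant", "suspected")
    )
  }
  if (is.null(reac)) {
    reac <- tibble::tibble(case_id = c("A", "B", "B", "C"),
                           pt_code = c("P001", "P002", "P003", "P001"))
  }
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"))
  readr::write_csv(demo, paths$demo, na = "")
  readr::write_csv(drug, paths$drug, na = "")
  readr::write_csv(reac, paths$reac, na = "")
  paths
}

test_that("load_cases joins the three tables into one case per ID", {
  p <- write_fixture_tables(withr::local_tempdir())
  cases <- load_cases(p$demo, p$drug, p$reac)
  expect_s3_class(cases, "pv_cases")
  expect_equal(nrow(cases), 3)
  expect_equal(cases$case_id, c("A", "B", "C"))
  expect_equal(cases$age_decade, c(3L, 6L, NA))
  a <- cases$drug_mentions[[1]]
  expect_setequal(a$generic_name,
                  c("sitagliptin phosphate hydrate", "metformin hydrochloride"))
  expect_equal(sort(cases$event_pts[[2]]), c("P002", "P003"))
  expect_equal(cases$event_pts[[3]], "P001")
  expect_equal(nrow(cases$drug_mentions[[3]]), 0)
  expect_equal(cases$year, c(2010L, 2011L, 2014L))
  expect_equal(cases$quarter, c(1L, 2L, 4L))
})

test_that("load_cases accepts empty tables with valid headers", {
  dir <- withr::local_tempdir()
  p <- write_fixture_tables(
    dir,
    demo = tibble::tibble(case_id = character(0), report_date = character(0),
                          age = numeric(0), sex = character(0)),
    drug = tibble::tibble(case_id = character(0), generic_name = character(0),
                          role = character(0)),
    reac = tibble::tibble(case_id = character(0), pt_code = character(0))
  )
  expect_equal(nrow(load_cases(p$demo, p$drug, p$reac)), 0)
})

test_that("load_cases rejects structural and integrity violations", {
  dir1 <- withr::local_tempdir()
  p <- write_fixture_tables(
    dir1,
    demo = tibble::tibble(id_wrong = "A", report_date = "2010-01-01",
                          age = 30, sex = "male")
  )
  expect_error(load_cases(p$demo, p$drug, p$reac), class = "pv_format_error")

  dir2 <- withr::local_tempdir()
  p2 <- write_fixture_tables(
    dir2,
    demo = tibble::tibble(case_id = c("A", "A", "B"),
                          report_date = "2010-01-01", age = 30, sex = "male")
  )
  expect_error(load_cases(p2$demo, p2$drug, p2$reac),
               class = "pv_integrity_error")

  dir3 <- withr::local_tempdir()
  p3 <- write_fixture_tables(
    dir3,
    reac = tibble::tibble(case_id = c("A", "GHOST"), pt_code = c("P001", "P002"))
  )
  expect_error(load_cases(p3$demo, p3$drug, p3$reac), regexp = "GHOST",
               class = "pv_integrity_error")
})

test_that("quarter_of maps months to calendar quarters", {
  expect_equal(quarter_of("2010-01-15"), tibble::tibble(year = 2010L, quarter = 1L))
  expect_equal(quarter_of("2015-03-31")$quarter, 1L)
  expect_equal(quarter_of(as.Date("2013-10-01"))$quarter, 4L)
  expect_error(quarter_of("not-a-date"), regexp = "unparseable")
})

test_that("the default study window spans 21 quarters", {
  w <- study_window()
  expect_equal(w$n_quarters, 21L)
  wq <- window_quarters(w)
  expect_equal(nrow(wq), 21L)
  expect_equal(wq$label[1], "2010Q1")
  expect_equal(wq$label[21], "2015Q1")
  # ordinal strictly increases with (year, quarter)
  expect_true(all(diff(quarter_ordinal(wq$year, wq$quarter, w)) == 1))
  expect_error(study_window("2015Q1", "2010Q1"), regexp = "after")
})

test_that("filter_analyzable keeps complete cases inside the window", {
  fx <- make_fixture("tiny-join")
  kept <- filter_analyzable(fx$cases)
  expect_equal(nrow(kept), 3)
  expect_true(all(!is.na(kept$age_decade) & !is.na(kept$sex)))
  # idempotent
  expect_identical(filter_analyzable(kept), kept)
  # a 2009Q4 case falls outside the default window
  pre <- fx$cases
  pre$year[1] <- 2009L
  pre$quarter[1] <- 4L
  expect_false("T01" %in% filter_analyzable(pre)$case_id)
  # all-complete in-window input passes through unchanged
  expect_identical(filter_analyzable(kept), kept)
})

test_that("per-quarter case counts partition the retained total", {
  fx <- make_fixture("planted-signal")
  kept <- filter_analyzable(fx$cases)
  ord <- quarter_ordinal(kept$year, kept$quarter)
  expect_equal(sum(table(ord)), nrow(kept))
})

test_that("hlt_events unions HLT parents, including multi-parent PTs", {
  dict <- make_fixture("tiny-join")$dict
  # P001 is parented by both H001 and H002
  expect_setequal(hlt_events("P001", dict), c("H001", "H002"))
  expect_equal(hlt_events(c("P002", "P002"), dict), "H002")
  expect_length(hlt_events(character(0), dict), 0)
  # unmapped PTs are dropped with a warning, not an error
  expect_warning(out <- hlt_events(c("P001", "ZZZ"), dict), regexp = "ZZZ")
  expect_setequal(out, c("H001", "H002"))
  expect_equal(attr(out, "unmapped"), "ZZZ")
})

test_that("cases survive a write/load round trip", {
  fx <- make_fixture("tiny-join")
  cases <- filter_analyzable(fx$cases)
  dir <- withr::local_tempdir()
  p <- write_cases(cases, dir)
  back <- load_cases(p$demo, p$drug, p$reac)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cases))
})

test_that("drug-name normalization unifies case, width, and spacing", {
  expect_equal(normalize_drug_name("  Sitagliptin   Phosphate "),
               "sitagliptin phosphate")
  # full-width latin and ideographic space
  expect_equal(normalize_drug_name("ＳＩＴＡ　X"), "sita x")
  expect_equal(normalize_drug_name(c("A", "a")), c("a", "a"))
})

test_that("the JADER dialect parses band ages and Japanese codings", {
  d <- jader_dialect()
  expect_equal(pvmix:::parse_age_decade(c("30歳代", "", "9歳代"), d),
               c(3L, NA, NA))
  expect_equal(pvmix:::parse_sex(c("男性", "女性", ""), d),
               c("male", "female", NA))
  expect_equal(pvmix:::parse_role("被疑薬", d), "suspected")
})

test_that("shipped dialect and class configs load to the built-in defaults", {
  d <- read_dialect(system.file("extdata", "dialect-jader.yaml",
                                package = "pvmix"))
  expect_equal(d, jader_dialect())
  cl <- read_drug_classes(system.file("extdata", "classes-incretin.yaml",
                                      package = "pvmix"))
  expect_equal(cl, default_drug_classes())
})
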
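#' Load spontaneous case reports from the three-table CSV layout
#'
#' Joins the demographics, drug-mention, and reported-event tables on the
#' case-ID key into one row per case. Drug names are normalized
#' ([normalize_drug_name()]) and ages are reduced to decade indices, the
#' analysis unit of the age covariate.
#'
#' @param demo_table,drug_table,reac_table Paths to the three CSV files.
#' @param dialect A [pv_dialect()] naming their columns and encodings.
#' @return A `pv_cases` tibble with columns `case_id`, `year`, `quarter`,
#'   `age_decade`, `sex`, and list-columns `drug_mentions` (tibbles with
#'   `generic_name`, `role`) and `event_pts` (character vectors of PT codes).
#' @examples
#' paths <- simulate_srs(simulation_config(quarter_sizes = rep(20, 4),
#'                                         seed = 1))$paths
#' cases <- load_cases(paths$demo, paths$drug, paths$reac)
#' nrow(cases)
#' @export
load_cases <- function(demo_table, drug_table, reac_table,
                       dialect = default_dialect()) {
  read_tbl <- function(path, mapping, what) {
    tbl <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    missing <- setdiff(unlist(mapping), names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("%s table %s lacks required column(s): %s",
                    what, path, paste(missing, collapse = ", ")),
            class = "pv_format_error")
    }
    tbl
  }
  demo <- read_tbl(demo_table, dialect$demo, "demo")
  drug <- read_tbl(drug_table, dialect$drug, "drug")
  reac <- read_tbl(reac_table, dialect$reac, "reac")

  ids <- demo[[dialect$demo$case_id]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate case ID(s) in demo table: %s",
                  paste(head(dup, 5), collapse = ", ")),
          class = "pv_integrity_error")
  }
  check_ref <- function(tbl, key, what) {
    orphan <- setdiff(unique(tbl[[key]]), ids)
    if (length(orphan) > 0) {
      abort(sprintf("%s row(s) reference case ID(s) absent from demo table: %s",
                    what, paste(head(orphan, 5), collapse = ", ")),
            class = "pv_integrity_error")
    }
  }
  check_ref(drug, dialect$drug$case_id, "drug")
  check_ref(reac, dialect$reac$case_id, "reac")

  q <- quarter_of(demo[[dialect$demo$date]])

  mentions <- tibble::tibble(
    case_id = drug[[dialect$drug$case_id]],
    generic_name = normalize_drug_name(drug[[dialect$drug$name]]),
    role = parse_role(drug[[dialect$drug$role]], dialect)
  )
  if (any(mentions$generic_name == "", na.rm = TRUE)) {
    abort("drug table contains empty generic names after normalization",
          class = "pv_format_error")
  }
  mention_sets <- split(mentions[c("generic_name", "role")], mentions$case_id)
  pt_sets <- split(reac[[dialect$reac$pt]], reac[[dialect$reac$case_id]])
  pt_sets <- lapply(pt_sets, function(p) unique(as.character(p)))

  empty_mentions <- tibble::tibble(generic_name = character(0),
                                   role = character(0))
  out <- tibble::tibble(
    case_id = ids,
    year = q$year,
    quarter = q$quarter,
    age_decade = parse_age_decade(demo[[dialect$demo$age]], dialect),
    sex = parse_sex(demo[[dialect$demo$sex]], dialect),
    drug_mentions = lapply(ids, function(i) mention_sets[[i]] %||% empty_mentions),
    event_pts = lapply(ids, function(i) pt_sets[[i]] %||% character(0))
  )
  class(out) <- c("pv_cases", class(out))
  out
}

#' Write cases back to the three-table CSV layout
#'
#' The inverse of [load_cases()] for the default dialect: reloading the three
#' files reproduces the cases (round-trip property used by the test suite).
#'
#' @param cases A `pv_cases` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_cases <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mid_month <- c("02", "05", "08", "11")[cases$quarter]
  demo <- tibble::tibble(
    case_id = cases$case_id,
    report_date = sprintf("%04d-%s-15", cases$year, mid_month),
    age = ifelse(is.na(cases$age_decade), NA_integer_,
                 cases$age_decade * 10L + 5L),
    sex = cases$sex
  )
  drug <- tidyr::unnest(
    tibble::tibble(case_id = cases$case_id, m = cases$drug_mentions),
    "m"
  )
  names(drug) <- c("case_id", "generic_name", "role")
  reac <- tidyr::unnest(
    tibble::tibble(case_id = cases$case_id, pt_code = cases$event_pts),
    "pt_code"
  )
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"))
  readr::write_csv(demo, paths$demo, na = "")
  readr::write_csv(drug, paths$drug, na = "")
  readr::write_csv(reac, paths$reac, na = "")
  invisible(paths)
}

#' Restrict to analyzable cases
#'
#' Keeps the cases with non-missing age and sex whose reporting quarter lies
#' inside the closed study window, in their input order. This mirrors the
#' usual spontaneous-report analysis filter: demographic covariates must be
#' present for the regression phase.
#'
#' @param cases A `pv_cases` tibble.
#' @param window A [study_window()].
#' @return The retained subset, same columns, input order preserved.
#' @export
filter_analyzable <- function(cases, window = study_window()) {
  ord <- quarter_ordinal(cases$year, cases$quarter, window)
  keep <- !is.na(cases$age_decade) & !is.na(cases$sex) &
    ord >= 1L & ord <= window$n_quarters
  cases[keep, ]
}

#' Attach HLT event sets to cases
#'
#' Adds an `event_hlts` list-column: the union of the HLT parents of each
#' case's reported PTs (multi-parent PTs contribute every parent).
#'
#' @param cases A `pv_cases` tibble.
#' @param dict A term dictionary.
#' @return `cases` with an `event_hlts` list-column.
#' @export
add_hlt_events <- function(cases, dict) {
  ev <- hlt_events(cases$event_pts, dict)
  attr(ev, "unmapped") <- NULL
  cases$event_hlts <- ev
  cases
}
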
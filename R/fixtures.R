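#' Deterministic test fixtures
#'
#' Small, fully deterministic datasets with documented expected behavior,
#' used throughout the test suite and examples.
#'
#' * `"tiny-join"` — 5 cases (2 with missing age) across the three tables;
#'   [filter_analyzable()] retains 3.
#' * `"planted-signal"` — 2,000 cases, three drugs and ten HLTs, constructed
#'   so exactly three drug-HLT pairs pass the Fisher screen.
#' * `"null-screen"` — 300 cases with background drugs only: no incretin
#'   exposure, so no screened combination can be significant.
#' * `"aic-contrast"` — a seeded simulation in which the common HLTs carry
#'   quarter heterogeneity (`sigma > 0`) and the rare ones do not, the
#'   regime in which the AIC comparison separates the two models.
#'
#' @param name Preset name.
#' @param seed Seed for the `"aic-contrast"` simulation (unused by the fully
#'   deterministic presets).
#' @return A list with, depending on the preset: `cases`, `dict`, `drugs`,
#'   `classes`, `window`, `planted`, `truth`, `config`.
#' @export
make_fixture <- function(name = c("tiny-join", "planted-signal",
                                  "null-screen", "aic-contrast"),
                         seed = 20160308) {
  name <- match.arg(name)
  switch(name,
         "tiny-join" = fixture_tiny_join(),
         "planted-signal" = fixture_planted_signal(),
         "null-screen" = fixture_null_screen(),
         "aic-contrast" = fixture_aic_contrast(seed))
}

fixture_dict <- function(n_hlt = 10) {
  base <- tibble::tibble(
    pt_code = sprintf("P%03d", seq_len(n_hlt)),
    pt_name = sprintf("Preferred term %d", seq_len(n_hlt)),
    hlt_code = sprintf("H%03d", seq_len(n_hlt)),
    hlt_name = sprintf("High level term %d", seq_len(n_hlt)),
    hlgt_code = sprintf("G%03d", (seq_len(n_hlt) - 1) %/% 3 + 1),
    soc_code = "S001"
  )
  # one multi-parent PT: P001 also belongs to H002
  extra <- tibble::tibble(pt_code = "P001", pt_name = "Preferred term 1",
                          hlt_code = "H002", hlt_name = "High level term 2",
                          hlgt_code = "G001", soc_code = "S001")
  as_term_dictionary(dplyr::bind_rows(base, extra))
}

mk_cases <- function(case_id, year, quarter, age_decade, sex, drugs, pts) {
  out <- tibble::tibble(
    case_id = case_id, year = as.integer(year), quarter = as.integer(quarter),
    age_decade = as.integer(age_decade), sex = sex,
    drug_mentions = drugs, event_pts = pts
  )
  class(out) <- c("pv_cases", class(out))
  out
}

mention <- function(name, role = "suspected") {
  tibble::tibble(generic_name = normalize_drug_name(name), role = role)
}

fixture_tiny_join <- function() {
  dict <- fixture_dict(4)
  cases <- mk_cases(
    case_id = sprintf("T%02d", 1:5),
    year = c(2010, 2010, 2011, 2012, 2014),
    quarter = c(1, 2, 3, 4, 1),
    age_decade = c(3, NA, 6, NA, 7),
    sex = c("male", "female", "female", "male", "male"),
    drugs = list(mention("sitagliptin phosphate hydrate"),
                 mention("metformin hydrochloride", "concomitant"),
                 dplyr::bind_rows(mention("liraglutide"),
                                  mention("glimepiride", "concomitant")),
                 mention("voglibose"),
                 mention("sitagliptin phosphate hydrate")),
    pts = list(c("P001"), c("P002"), c("P001", "P003"), c("P004"), c("P002"))
  )
  list(cases = cases, dict = dict, window = study_window())
}

fixture_planted_signal <- function() {
  dict <- fixture_dict(10)
  drugs <- c("drug alpha", "drug beta", "drug gamma")
  n <- 2000
  drug_of <- rep("background drug 01", n)
  drug_of[1:100] <- drugs[1]
  drug_of[101:200] <- drugs[2]
  drug_of[201:300] <- drugs[3]
  pt_of <- rep("P010", n)
  pt_of[1:30] <- "P004"      # planted: drug alpha x H004
  pt_of[101:130] <- "P005"   # planted: drug beta  x H005
  pt_of[201:230] <- "P006"   # planted: drug gamma x H006
  pt_of[301:340] <- "P004"   # background rate of the planted events
  pt_of[341:380] <- "P005"
  pt_of[381:420] <- "P006"
  pt_of[421:460] <- "P007"   # events never co-reported with the drugs
  pt_of[461:500] <- "P008"
  wq <- window_quarters(study_window())
  qi <- ((seq_len(n) - 1) %% nrow(wq)) + 1
  cases <- mk_cases(
    case_id = sprintf("S%04d", seq_len(n)),
    year = wq$year[qi], quarter = wq$quarter[qi],
    age_decade = ((seq_len(n) - 1) %% 9),
    sex = ifelse(seq_len(n) %% 2 == 0, "male", "female"),
    drugs = lapply(drug_of, mention),
    pts = as.list(pt_of)
  )
  list(cases = cases, dict = dict, drugs = drugs,
       planted = tibble::tibble(drug = normalize_drug_name(drugs),
                                hlt_code = c("H004", "H005", "H006")),
       window = study_window())
}

fixture_null_screen <- function() {
  dict <- fixture_dict(10)
  n <- 300
  wq <- window_quarters(study_window())
  qi <- ((seq_len(n) - 1) %% nrow(wq)) + 1
  cases <- mk_cases(
    case_id = sprintf("N%03d", seq_len(n)),
    year = wq$year[qi], quarter = wq$quarter[qi],
    age_decade = ((seq_len(n) - 1) %% 9),
    sex = ifelse(seq_len(n) %% 3 == 0, "male", "female"),
    drugs = lapply(sprintf("background drug %02d", (seq_len(n) - 1) %% 5 + 1),
                   mention),
    pts = as.list(sprintf("P%03d", (seq_len(n) - 1) %% 10 + 1))
  )
  list(cases = cases, dict = dict,
       drugs = default_drug_classes()$dpp4, window = study_window())
}

fixture_aic_contrast <- function(seed) {
  hp <- tibble::tibble(
    hlt_code = c("H_BIG_RE1", "H_BIG_RE2", "H_SMALL_FIX1", "H_SMALL_FIX2"),
    n_pts = c(2, 2, 1, 1),
    beta0 = c(-1.6, -1.8, -3.6, -3.8),
    beta_dpp4 = 0, beta_glp1 = 0, beta_hypo = 0,
    beta_conc = 0.05, beta_age = 0.02, beta_sex = 0.1,
    sigma = c(0.8, 0.8, 0, 0)
  )
  # no incretin or hypoglycemic exposure: the contrast isolates the random
  # effect, and tiny exposed groups would only invite quasi-separation on
  # 2,000-case replicates
  cfg <- simulation_config(quarter_sizes = rep(100, 21),
                           dpp4_share = 0, glp1_share = 0, hypo_share = 0,
                           hlt_params = hp, seed = seed)
  sim <- simulate_srs(cfg)
  cases <- load_cases(sim$paths$demo, sim$paths$drug, sim$paths$reac)
  list(cases = filter_analyzable(cases), dict = sim$dict,
       classes = cfg$classes, truth = sim$truth, config = cfg,
       window = study_window())
}
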
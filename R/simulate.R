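# deterministic 32-bit stage seed from a master seed and a stage label, so
# the demography, exposure, and per-HLT event streams are independent and
# adding an HLT never perturbs the other draws
stage_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Describes a JADER-like reporting stream: quarterly report volumes, a drug
#' catalogue whose DPP-4 exposure share rises over the study window (the
#' uptake trend of a newly adopted drug class), demographic distributions
#' with realistic missingness, a small MedDRA-style dictionary including a
#' multi-parent PT, and per-HLT true model parameters (fixed effects and the
#' quarter-level random-intercept standard deviation).
#'
#' @param window A [study_window()]; defaults to the 21-quarter window
#'   2010Q1-2015Q1.
#' @param quarter_sizes Integer vector of per-quarter case counts (length
#'   `window$n_quarters`); the default grows linearly from 400 to 1,500
#'   (about 20,000 cases), mimicking a steadily growing reporting stream.
#' @param classes A [drug_classes()] configuration.
#' @param dpp4_share,glp1_share Per-quarter probabilities that a case mentions
#'   a drug of the class; defaults rise linearly (DPP-4 markedly, 1% to 10%).
#' @param hypo_share Per-quarter probability of a non-incretin hypoglycemic
#'   mention (default flat 6%).
#' @param n_background_drugs Size of the background drug catalogue.
#' @param background_mean Poisson mean of the number of distinct background
#'   drugs per case.
#' @param suspected_prob,background_suspected_prob Probability that a class /
#'   background drug mention carries the suspected role (otherwise
#'   concomitant).
#' @param age_weights Sampling weights of age decades 0-9 (default skewed to
#'   60s-70s, as in real pharmacovigilance data).
#' @param male_prob Probability of male sex.
#' @param missing_age,missing_sex Missingness rates of the two demographic
#'   fields.
#' @param hlt_params Per-HLT truth: a tibble with columns `hlt_code`,
#'   `n_pts`, `beta0`, `beta_dpp4`, `beta_glp1`, `beta_hypo`, `beta_conc`,
#'   `beta_age`, `beta_sex`, `sigma`. See [default_hlt_params()].
#' @param seed Master seed; all stage streams derive from it.
#' @return A `pv_sim_config` list.
#' @export
simulation_config <- function(window = study_window(),
                              quarter_sizes = NULL,
                              classes = default_drug_classes(),
                              dpp4_share = NULL, glp1_share = NULL,
                              hypo_share = NULL,
                              n_background_drugs = 30,
                              background_mean = 1.5,
                              suspected_prob = 0.7,
                              background_suspected_prob = 0.6,
                              age_weights = c(1, 1, 2, 3, 4, 6, 8, 9, 6, 2),
                              male_prob = 0.55,
                              missing_age = 0.06, missing_sex = 0.025,
                              hlt_params = default_hlt_params(),
                              seed = 20100101) {
  nq <- window$n_quarters
  if (is.null(quarter_sizes)) {
    quarter_sizes <- round(seq(400, 1500, length.out = nq))
  }
  if (length(quarter_sizes) != nq) {
    abort("quarter_sizes must have one entry per window quarter")
  }
  if (sum(quarter_sizes) < 1) abort("configuration yields zero cases")
  lin <- function(x, from, to) if (is.null(x)) seq(from, to, length.out = nq) else rep_len(x, nq)
  cfg <- list(
    window = window,
    quarter_sizes = as.integer(quarter_sizes),
    classes = classes,
    dpp4_share = lin(dpp4_share, 0.01, 0.10),
    glp1_share = lin(glp1_share, 0.002, 0.008),
    hypo_share = lin(hypo_share, 0.06, 0.06),
    n_background_drugs = n_background_drugs,
    background_mean = background_mean,
    suspected_prob = suspected_prob,
    background_suspected_prob = background_suspected_prob,
    age_weights = age_weights / sum(age_weights),
    male_prob = male_prob,
    missing_age = missing_age, missing_sex = missing_sex,
    hlt_params = tibble::as_tibble(hlt_params),
    seed = as.integer(seed)
  )
  stopifnot(all(cfg$dpp4_share >= 0 & cfg$dpp4_share <= 1),
            all(cfg$hlt_params$sigma >= 0))
  structure(cfg, class = "pv_sim_config")
}

#' @rdname simulation_config
#' @details `default_hlt_params()` defines eight HLTs: a strong DPP-4 signal
#'   with quarter heterogeneity (the pancreatitis-like target), a GLP-1
#'   signal, moderately common null events with and without heterogeneity,
#'   and rare null events — plus two catch-all noise HLTs that absorb the
#'   filler PT of otherwise event-free cases.
#' @export
default_hlt_params <- function() {
  tibble::tibble(
    hlt_code = c("H_PANC", "H_THYR", "H_COMMON_RE", "H_COMMON_FIX",
                 "H_MID_RE", "H_MID_FIX", "H_RARE1", "H_RARE2"),
    n_pts = c(3, 2, 3, 3, 2, 2, 1, 1),
    beta0 = c(-5.0, -6.5, -2.8, -2.8, -4.0, -4.0, -5.8, -5.8),
    beta_dpp4 = c(1.5, 0, 0, 0, 0, 0, 0, 0),
    beta_glp1 = c(0.8, 2.0, 0, 0, 0, 0, 0, 0),
    beta_hypo = c(0.4, 0.3, 0, 0, 0, 0, 0, 0),
    beta_conc = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    beta_age = c(0.05, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    beta_sex = c(0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    sigma = c(0.5, 0.3, 0.8, 0, 0.6, 0, 0, 0)
  )
}

# dictionary implied by a simulation config: each HLT owns n_pts PTs; the
# first PT of the second HLT is additionally parented by the first HLT
# (multi-parent realism), and two noise HLTs hold the filler PTs
sim_dictionary <- function(cfg) {
  hp <- cfg$hlt_params
  rows <- purrr::map2_dfr(hp$hlt_code, hp$n_pts, function(h, k) {
    tibble::tibble(
      pt_code = sprintf("PT_%s_%d", h, seq_len(k)),
      pt_name = sprintf("Preferred term %s %d", h, seq_len(k)),
      hlt_code = h, hlt_name = sprintf("High level term %s", h),
      hlgt_code = paste0("G_", h), soc_code = "SOC_1"
    )
  })
  if (nrow(hp) >= 2) {
    shared <- sprintf("PT_%s_1", hp$hlt_code[2])
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      pt_code = shared, pt_name = sprintf("Preferred term %s 1", hp$hlt_code[2]),
      hlt_code = hp$hlt_code[1],
      hlt_name = sprintf("High level term %s", hp$hlt_code[1]),
      hlgt_code = paste0("G_", hp$hlt_code[1]), soc_code = "SOC_1"
    ))
  }
  noise <- tibble::tibble(
    pt_code = sprintf("PT_NOISE_%d", 1:4),
    pt_name = sprintf("Noise term %d", 1:4),
    hlt_code = rep(c("H_NOISE1", "H_NOISE2"), each = 2),
    hlt_name = rep(c("Noise events A", "Noise events B"), each = 2),
    hlgt_code = rep(c("G_NOISE1", "G_NOISE2"), each = 2),
    soc_code = "SOC_2"
  )
  as_term_dictionary(dplyr::bind_rows(rows, noise))
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Draws cases quarter by quarter: demographics (with missingness), drug
#' exposures with the configured uptake trends and suspected/concomitant
#' roles, then — independently per HLT — one normal random intercept per
#' quarter and Bernoulli events from the logistic model, reported as PT codes
#' sampled from the HLT's children. Cases with no drawn event receive a
#' filler noise PT, so every report carries at least one event term. The
#' three tables are written in the default CSV dialect together with the
#' term dictionary and a ground-truth JSON record.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory for `demo.csv`, `drug.csv`, `reac.csv`,
#'   `dictionary.csv`, `truth.json` (default: a fresh temporary directory).
#' @return A list: `paths` (named file paths), `demo`, `drug`, `reac`
#'   (tibbles), `dict` (term dictionary), `truth` (ground-truth list).
#' @examples
#' sim <- simulate_srs(simulation_config(quarter_sizes = rep(30, 4), seed = 7))
#' nrow(sim$demo)
#' @export
simulate_srs <- function(config, dir = tempfile("pvmix_sim_")) {
  cfg <- config
  wq <- window_quarters(cfg$window)
  n_q <- cfg$quarter_sizes
  n <- sum(n_q)
  qidx <- rep(seq_len(nrow(wq)), n_q)

  # --- demography stream
  set.seed(stage_seed(cfg$seed, "demography"))
  age_dec <- sample(0:9, n, replace = TRUE, prob = cfg$age_weights)
  sex <- ifelse(runif(n) < cfg$male_prob, "male", "female")
  age_dec[runif(n) < cfg$missing_age] <- NA
  sex[runif(n) < cfg$missing_sex] <- NA

  # --- exposure stream
  set.seed(stage_seed(cfg$seed, "exposure"))
  dpp4_on <- runif(n) < cfg$dpp4_share[qidx]
  glp1_on <- runif(n) < cfg$glp1_share[qidx]
  hypo_on <- runif(n) < cfg$hypo_share[qidx]
  dpp4_pick <- sample(cfg$classes$dpp4, n, replace = TRUE)
  glp1_pick <- sample(cfg$classes$glp1, n, replace = TRUE)
  other_hypo <- setdiff(cfg$classes$hypoglycemic,
                        c(cfg$classes$dpp4, cfg$classes$glp1))
  if (length(other_hypo) == 0) other_hypo <- "metformin hydrochloride"
  hypo_pick <- sample(other_hypo, n, replace = TRUE)
  bg_names <- sprintf("background drug %02d", seq_len(cfg$n_background_drugs))
  n_bg <- pmin(rpois(n, cfg$background_mean), cfg$n_background_drugs)
  bg_sets <- lapply(n_bg, function(k) {
    if (k == 0) character(0) else sample(bg_names, k)
  })
  role_of <- function(on, p) ifelse(runif(n) < p, "suspected", "concomitant")
  dpp4_role <- role_of(dpp4_on, cfg$suspected_prob)
  glp1_role <- role_of(glp1_on, cfg$suspected_prob)
  hypo_role <- role_of(hypo_on, cfg$suspected_prob)
  bg_roles <- lapply(bg_sets, function(s) {
    ifelse(runif(length(s)) < cfg$background_suspected_prob,
           "suspected", "concomitant")
  })

  # true covariates (complete, pre-missingness) for the event models; the
  # concomitant count is distinct suspected non-incretin drugs, matching the
  # ungated build_design() coding
  n_conc_true <- vapply(seq_len(n), function(i) {
    sum(bg_roles[[i]] == "suspected")
  }, integer(1)) + as.integer(hypo_on & hypo_role == "suspected")
  age_full <- ifelse(is.na(age_dec), 0L, age_dec)  # placeholder; see below
  sex_full <- ifelse(is.na(sex), "female", sex)

  # --- event streams, one per HLT
  hp <- cfg$hlt_params
  dict <- sim_dictionary(cfg)
  pt_sets <- vector("list", n)
  u_record <- list()
  for (r in seq_len(nrow(hp))) {
    h <- hp$hlt_code[r]
    set.seed(stage_seed(cfg$seed, paste0("events:", h)))
    u_q <- rnorm(nrow(wq), 0, hp$sigma[r])
    eta <- hp$beta0[r] + hp$beta_dpp4[r] * dpp4_on + hp$beta_glp1[r] * glp1_on +
      hp$beta_hypo[r] * (hypo_on | dpp4_on | glp1_on) +
      hp$beta_conc[r] * n_conc_true + hp$beta_age[r] * age_full +
      hp$beta_sex[r] * (sex_full == "male") + u_q[qidx]
    yev <- runif(n) < plogis(eta)
    children <- dict$pt_code[dict$hlt_code == h]
    picks <- sample(children, n, replace = TRUE)
    for (i in which(yev)) pt_sets[[i]] <- c(pt_sets[[i]], picks[i])
    u_record[[h]] <- u_q
  }
  set.seed(stage_seed(cfg$seed, "filler"))
  noise_pts <- dict$pt_code[startsWith(dict$hlt_code, "H_NOISE")]
  filler <- sample(noise_pts, n, replace = TRUE)
  empty <- lengths(pt_sets) == 0
  pt_sets[empty] <- as.list(filler[empty])

  # --- assemble dialect-conformant tables
  ids <- sprintf("C%06d", seq_len(n))
  mid_month <- c("02", "05", "08", "11")[wq$quarter[qidx]]
  demo <- tibble::tibble(
    case_id = ids,
    report_date = sprintf("%04d-%s-15", wq$year[qidx], mid_month),
    age = ifelse(is.na(age_dec), NA_integer_, age_dec * 10L + 5L),
    sex = sex
  )
  drug <- dplyr::bind_rows(
    tibble::tibble(case_id = ids[dpp4_on], generic_name = dpp4_pick[dpp4_on],
                   role = dpp4_role[dpp4_on]),
    tibble::tibble(case_id = ids[glp1_on], generic_name = glp1_pick[glp1_on],
                   role = glp1_role[glp1_on]),
    tibble::tibble(case_id = ids[hypo_on], generic_name = hypo_pick[hypo_on],
                   role = hypo_role[hypo_on]),
    tibble::tibble(case_id = rep(ids, lengths(bg_sets)),
                   generic_name = as.character(unlist(bg_sets)),
                   role = as.character(unlist(bg_roles)))
  ) |> dplyr::arrange(.data$case_id, .data$generic_name)
  reac <- tibble::tibble(case_id = rep(ids, lengths(pt_sets)),
                         pt_code = unlist(pt_sets))

  truth <- list(
    hlt_params = hp,
    quarter_intercepts = u_record,
    dpp4_share = cfg$dpp4_share, glp1_share = cfg$glp1_share,
    quarter_sizes = cfg$quarter_sizes,
    n_cases = n, seed = cfg$seed
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"),
                dict = file.path(dir, "dictionary.csv"),
                truth = file.path(dir, "truth.json"))
  readr::write_csv(demo, paths$demo, na = "")
  readr::write_csv(drug, paths$drug, na = "")
  readr::write_csv(reac, paths$reac, na = "")
  readr::write_csv(tibble::as_tibble(dict), paths$dict, na = "")
  jsonlite::write_json(truth["hlt_params"], paths$truth, digits = NA)
  list(paths = paths, demo = demo, drug = drug, reac = reac,
       dict = dict, truth = truth)
}

#' Simulate a bare regression design from the random-intercept model
#'
#' Draws covariates and outcomes directly at the design-matrix level — no
#' CSV tables, dictionary, or PT coding — for calibration studies (bias,
#' CI coverage, type-I error) where thousands of replicates are fitted.
#' One normal random intercept is drawn per cluster; outcomes follow the
#' logistic model.
#'
#' @param n Number of cases.
#' @param n_clusters Number of quarterly clusters (cases are spread evenly).
#' @param beta Named true fixed effects: `intercept`, `dpp4`, `glp1`,
#'   `hypoglycemic`, `n_concomitant_suspected`, `age_decade`, `sex`.
#' @param sigma True random-intercept standard deviation.
#' @param dpp4_prob,glp1_prob,hypo_prob Exposure probabilities (DPP-4 drawn
#'   with a rising trend across clusters around `dpp4_prob`).
#' @param seed Seed.
#' @return A `pv_design` tibble (as [build_design()] returns) with the true
#'   cluster intercepts in the `u` attribute.
#' @export
simulate_design <- function(n = 5000, n_clusters = 21,
                            beta = c(intercept = -4.5, dpp4 = 1.5, glp1 = 0.8,
                                     hypoglycemic = 0.3,
                                     n_concomitant_suspected = 0.05,
                                     age_decade = 0.05, sex = 0.2),
                            sigma = 0.5,
                            dpp4_prob = 0.05, glp1_prob = 0.005,
                            hypo_prob = 0.06, seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(n_clusters), length.out = n)
  trend <- seq(0.4, 1.6, length.out = n_clusters)   # uptake trend
  dpp4 <- rbinom(n, 1, pmin(dpp4_prob * trend[cl], 1))
  glp1 <- rbinom(n, 1, glp1_prob)
  hypo_other <- rbinom(n, 1, hypo_prob)
  hypo <- as.integer(dpp4 | glp1 | hypo_other)
  n_conc <- rpois(n, 1)
  age <- sample(0:9, n, replace = TRUE,
                prob = c(1, 1, 2, 3, 4, 6, 8, 9, 6, 2))
  sex <- rbinom(n, 1, 0.55)
  u <- rnorm(n_clusters, 0, sigma)
  eta <- beta[["intercept"]] + beta[["dpp4"]] * dpp4 + beta[["glp1"]] * glp1 +
    beta[["hypoglycemic"]] * hypo +
    beta[["n_concomitant_suspected"]] * n_conc +
    beta[["age_decade"]] * age + beta[["sex"]] * sex + u[cl]
  y <- rbinom(n, 1, plogis(eta))
  out <- tibble::tibble(y = y, dpp4 = dpp4, glp1 = glp1, hypoglycemic = hypo,
                        n_concomitant_suspected = n_conc, age_decade = age,
                        sex = sex, cluster = cl)
  class(out) <- c("pv_design", class(out))
  attr(out, "u") <- u
  out
}
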
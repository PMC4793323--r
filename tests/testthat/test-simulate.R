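small_window <- study_window("2010Q1", "2011Q4")  # 8 quarters

test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(window = small_window,
                           quarter_sizes = rep(40, 8), seed = 101)
  s1 <- simulate_srs(cfg, dir = withr::local_tempdir())
  s2 <- simulate_srs(cfg, dir = withr::local_tempdir())
  expect_identical(s1$demo, s2$demo)
  expect_identical(s1$drug, s2$drug)
  expect_identical(s1$reac, s2$reac)
})

test_that("quarterly case counts are conserved", {
  cfg <- simulation_config(window = small_window,
                           quarter_sizes = c(10, 20, 30, 40, 50, 60, 70, 80),
                           seed = 102)
  sim <- simulate_srs(cfg, dir = withr::local_tempdir())
  q <- quarter_of(sim$demo$report_date)
  ord <- quarter_ordinal(q$year, q$quarter, small_window)
  expect_equal(as.integer(table(ord)), cfg$quarter_sizes)
  expect_equal(nrow(sim$demo), sum(cfg$quarter_sizes))
  # every report carries at least one event term
  expect_true(all(sim$demo$case_id %in% sim$reac$case_id))
})

test_that("exposure prevalence tracks the configured uptake within 3 SD", {
  cfg <- simulation_config(quarter_sizes = rep(400, 21), seed = 103)
  sim <- simulate_srs(cfg, dir = withr::local_tempdir())
  cases <- load_cases(sim$paths$demo, sim$paths$drug, sim$paths$reac)
  ord <- quarter_ordinal(cases$year, cases$quarter)
  dpp4 <- vapply(cases$drug_mentions,
                 function(m) any(m$generic_name %in% cfg$classes$dpp4),
                 logical(1))
  for (q in c(1, 11, 21)) {
    p <- cfg$dpp4_share[q]
    n_q <- sum(ord == q)
    expect_lt(abs(mean(dpp4[ord == q]) - p), 3 * sqrt(p * (1 - p) / n_q) + 1e-9)
  }
  # the uptake trend is visible end to end
  expect_gt(mean(dpp4[ord == 21]), mean(dpp4[ord == 1]))
})

test_that("null drug effects produce odds ratios centered on 1", {
  hp <- tibble::tibble(hlt_code = "H_NULL", n_pts = 2, beta0 = -2.5,
                       beta_dpp4 = 0, beta_glp1 = 0, beta_hypo = 0,
                       beta_conc = 0, beta_age = 0, beta_sex = 0, sigma = 0)
  log_ors <- vapply(1:200, function(r) {
    cfg <- simulation_config(window = small_window,
                             quarter_sizes = rep(50, 8),
                             dpp4_share = 0.2, hlt_params = hp,
                             missing_age = 0, missing_sex = 0,
                             seed = 20000 + r)
    sim <- simulate_srs(cfg, dir = withr::local_tempdir())
    exposed_ids <- unique(sim$drug$case_id[sim$drug$generic_name %in%
                                             cfg$classes$dpp4])
    event_ids <- unique(sim$reac$case_id[startsWith(sim$reac$pt_code, "PT_H_NULL")])
    e <- sim$demo$case_id %in% exposed_ids
    v <- sim$demo$case_id %in% event_ids
    log((sum(e & v) + 0.5) * (sum(!e & !v) + 0.5) /
          ((sum(e & !v) + 0.5) * (sum(!e & v) + 0.5)))
  }, numeric(1))
  expect_lt(abs(mean(log_ors)), 3 * sd(log_ors) / sqrt(length(log_ors)))
})

test_that("quarter heterogeneity appears iff sigma is positive", {
  var_of <- function(sigma, seed) {
    hp <- tibble::tibble(hlt_code = "H_X", n_pts = 1, beta0 = -2,
                         beta_dpp4 = 0, beta_glp1 = 0, beta_hypo = 0,
                         beta_conc = 0, beta_age = 0, beta_sex = 0,
                         sigma = sigma)
    cfg <- simulation_config(quarter_sizes = rep(300, 21), hlt_params = hp,
                             missing_age = 0, missing_sex = 0, seed = seed)
    sim <- simulate_srs(cfg, dir = withr::local_tempdir())
    q <- quarter_of(sim$demo$report_date)
    ord <- quarter_ordinal(q$year, q$quarter)
    ev <- sim$demo$case_id %in%
      sim$reac$case_id[startsWith(sim$reac$pt_code, "PT_H_X")]
    rates <- tapply(ev, ord, mean)
    var(qlogis(pmin(pmax(rates, 1e-3), 1 - 1e-3)))
  }
  v0 <- var_of(0, 104)
  v1 <- var_of(1, 104)
  expect_gt(v1, 4 * v0)
})

test_that("adding an HLT leaves all other streams untouched", {
  base_hp <- default_hlt_params()[1:3, ]
  more_hp <- default_hlt_params()[1:4, ]
  cfg1 <- simulation_config(window = small_window, quarter_sizes = rep(60, 8),
                            hlt_params = base_hp, seed = 105)
  cfg2 <- simulation_config(window = small_window, quarter_sizes = rep(60, 8),
                            hlt_params = more_hp, seed = 105)
  s1 <- simulate_srs(cfg1, dir = withr::local_tempdir())
  s2 <- simulate_srs(cfg2, dir = withr::local_tempdir())
  expect_identical(s1$demo, s2$demo)
  expect_identical(s1$drug, s2$drug)
  # the shared HLTs' event rows are identical
  own <- function(sim, h) {
    r <- sim$reac[startsWith(sim$reac$pt_code, paste0("PT_", h)), ]
    r[order(r$case_id, r$pt_code), ]
  }
  for (h in base_hp$hlt_code[1:3]) {
    expect_identical(own(s1, h), own(s2, h))
  }
})

test_that("fixture presets honor their documented contracts", {
  tj <- make_fixture("tiny-join")
  expect_equal(nrow(tj$cases), 5)
  expect_equal(sum(is.na(tj$cases$age_decade)), 2)
  expect_equal(nrow(filter_analyzable(tj$cases)), 3)

  ps <- make_fixture("planted-signal")
  expect_equal(nrow(ps$cases), 2000)
  expect_equal(nrow(ps$planted), 3)

  ac <- make_fixture("aic-contrast", seed = 106)
  hp <- ac$truth$hlt_params
  expect_true(all(hp$sigma[startsWith(hp$hlt_code, "H_BIG")] > 0))
  expect_true(all(hp$sigma[startsWith(hp$hlt_code, "H_SMALL")] == 0))
  # common HLTs really are reported more often than the rare ones
  ev <- hlt_events(ac$cases$event_pts, ac$dict)
  counts <- table(unlist(ev))
  expect_gt(min(counts[c("H_BIG_RE1", "H_BIG_RE2")]),
            max(counts[c("H_SMALL_FIX1", "H_SMALL_FIX2")]))

  expect_error(make_fixture("no-such-preset"))
})

test_that("the dictionary written by the generator is loadable and multi-parent", {
  cfg <- simulation_config(window = small_window, quarter_sizes = rep(20, 8),
                           seed = 107)
  sim <- simulate_srs(cfg, dir = withr::local_tempdir())
  dict <- load_term_dictionary(sim$paths$dict)
  parents <- table(unique(tibble::as_tibble(dict)[c("pt_code", "hlt_code")])$pt_code)
  expect_gte(max(parents), 2)
})
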
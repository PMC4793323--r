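test_that("build_table counts at case level", {
  dict <- make_fixture("tiny-join")$dict
  mk <- function(drugs, pts) {
    out <- tibble::tibble(
      case_id = sprintf("C%d", seq_along(drugs)),
      year = 2010L, quarter = 1L, age_decade = 5L, sex = "male",
      drug_mentions = drugs, event_pts = pts
    )
    class(out) <- c("pv_cases", class(out))
    out
  }
  m <- function(nm) tibble::tibble(generic_name = nm, role = "suspected")
  cases <- mk(
    drugs = list(m("drug x"), m(c("drug x", "drug x")), m("drug z"), m("drug z")),
    pts = list("P002", "P003", "P002", "P004")
  )
  # a case mentioning the drug twice counts once in the exposed margin
  tab <- build_table(cases, "drug x", "H003", dict)
  expect_equal(tab, c(a = 1L, b = 1L, c = 0L, d = 2L))
  # never co-reported
  expect_equal(build_table(cases, "drug z", "H003", dict)[["a"]], 0L)
  # multi-parent PT: P001 counts for both H001 and H002
  cases2 <- mk(drugs = list(m("drug x")), pts = list("P001"))
  expect_equal(build_table(cases2, "drug x", "H001", dict)[["a"]], 1L)
  expect_equal(build_table(cases2, "drug x", "H002", dict)[["a"]], 1L)
})

test_that("two-sided Fisher p matches frozen enumeration values", {
  # enumeration over margins (4,4)/(4,4): p = 0.485714285714...
  expect_equal(as.numeric(fisher_exact_two_sided(c(3, 1, 1, 3))),
               17 / 35, tolerance = 1e-12)
  # mode table: every table qualifies
  expect_equal(as.numeric(fisher_exact_two_sided(c(5, 5, 5, 5))), 1)
  # two extreme tables, each with probability 1/choose(20, 10)
  expect_equal(as.numeric(fisher_exact_two_sided(c(10, 0, 0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:200) {
    tab <- rpois(4, lambda = sample(c(1, 5, 20), 1))
    if (sum(tab) == 0) next
    ours <- as.numeric(fisher_exact_two_sided(tab))
    m <- matrix(tab, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      expect_equal(ours, 1)
    } else {
      expect_equal(ours, fisher.test(m)$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Fisher p is invariant under transpose and row/column swaps", {
  set.seed(12)
  for (i in 1:50) {
    t0 <- rpois(4, 6) + c(1, 0, 0, 1)
    p0 <- as.numeric(fisher_exact_two_sided(t0))
    expect_equal(as.numeric(fisher_exact_two_sided(t0[c(1, 3, 2, 4)])), p0,
                 tolerance = 1e-12)  # transpose
    expect_equal(as.numeric(fisher_exact_two_sided(t0[c(3, 4, 1, 2)])), p0,
                 tolerance = 1e-12)  # swap rows
    expect_equal(as.numeric(fisher_exact_two_sided(t0[c(2, 1, 4, 3)])), p0,
                 tolerance = 1e-12)  # swap columns
  }
})

test_that("degenerate margins give p = 1 with a flag", {
  p <- fisher_exact_two_sided(c(0, 0, 3, 5))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_false(attr(fisher_exact_two_sided(c(3, 1, 1, 3)), "degenerate"))
})

test_that("shifting mass onto the diagonal shrinks the upper tail", {
  # along tables (a, 10-a, 12-a, a+8) with fixed margins, the one-sided
  # upper tail must fall as a grows; our two-sided p must track the oracle
  tails <- ours <- numeric(0)
  for (a in 2:10) {
    tab <- c(a, 10 - a, 12 - a, a + 8)
    m <- tab[1] + tab[2]; n <- tab[3] + tab[4]; k <- tab[1] + tab[3]
    tails <- c(tails, sum(dhyper(a:min(k, m), m, n, k)))
    ours <- c(ours, as.numeric(fisher_exact_two_sided(tab)))
    expect_equal(ours[length(ours)],
                 oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(tails) < 0))
})

test_that("crude odds ratio handles finite, infinite, and undefined cases", {
  expect_equal(crude_odds_ratio(c(234, 7031, 804, 179112)),
               234 * 179112 / (7031 * 804), tolerance = 1e-12)
  expect_equal(round(crude_odds_ratio(c(234, 7031, 804, 179112)), 3), 7.414)
  expect_equal(crude_odds_ratio(c(5, 5, 5, 5)), 1)
  expect_identical(crude_odds_ratio(c(1, 5, 0, 100)), Inf)
  expect_true(is.nan(crude_odds_ratio(c(0, 5, 0, 100))))
})

test_that("row-swapped odds ratios are reciprocal", {
  set.seed(13)
  for (i in 1:25) {
    tab <- rpois(4, 8) + 1
    expect_equal(crude_odds_ratio(tab) * crude_odds_ratio(tab[c(3, 4, 1, 2)]),
                 1, tolerance = 1e-12)
  }
})

test_that("screen_all flags exactly the planted associations", {
  fx <- make_fixture("planted-signal")
  scr <- screen_all(fx$cases, fx$drugs, fx$dict)
  hits <- dplyr::filter(scr, significant)
  expect_equal(nrow(hits), 3)
  expect_equal(dplyr::arrange(hits[c("drug", "hlt_code")], drug),
               dplyr::arrange(fx$planted, drug), ignore_attr = TRUE)
  # screened tables carry consistent margins
  expect_true(all(scr$a + scr$b + scr$c + scr$d == nrow(fx$cases)))
})

test_that("a zero-exposure drug yields no significant results", {
  fx <- make_fixture("null-screen")
  scr <- screen_all(fx$cases, fx$drugs, fx$dict)
  expect_true(all(!scr$significant))
  expect_true(all(scr$a == 0))
})

test_that("screening is invariant to case order and deterministically sorted", {
  fx <- make_fixture("planted-signal")
  scr1 <- screen_all(fx$cases, fx$drugs, fx$dict)
  set.seed(14)
  shuffled <- fx$cases[sample(nrow(fx$cases)), ]
  scr2 <- screen_all(shuffled, fx$drugs, fx$dict)
  expect_equal(scr1, scr2)
  expect_identical(order(scr1$drug, scr1$hlt_code), seq_len(nrow(scr1)))
})

test_that("pooled class screening unions member exposure", {
  fx <- make_fixture("planted-signal")
  scr <- screen_all(fx$cases,
                    list("class:all" = fx$drugs, fx$drugs[1]),
                    fx$dict)
  pooled <- dplyr::filter(scr, drug == "class:all")
  single <- dplyr::filter(scr, drug != "class:all")
  expect_true(all(pooled$a + pooled$b == 300))
  expect_true(all(single$a + single$b == 100))
})
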
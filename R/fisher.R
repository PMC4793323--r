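#' Case-level 2x2 contingency table for one drug and one HLT
#'
#' Counts cases, not mentions: a case mentioning the drug twice contributes
#' once. Exposure is any mention of the drug (any role); the event is
#' membership of the HLT in the case's rolled-up event set.
#'
#' @param cases A `pv_cases` tibble, already restricted by
#'   [filter_analyzable()].
#' @param drug A generic drug name (normalized internally), or a character
#'   vector of names treated as a pooled class (exposure = any member).
#' @param hlt An HLT code.
#' @param dict A term dictionary.
#' @return A named integer vector `c(a, b, c, d)`: drug & HLT, drug only,
#'   HLT only, neither.
#' @examples
#' fx <- make_fixture("tiny-join")
#' build_table(fx$cases, "sitagliptin phosphate hydrate", "H001", fx$dict)
#' @export
build_table <- function(cases, drug, hlt, dict) {
  drug <- normalize_drug_name(drug)
  hlts <- if ("event_hlts" %in% names(cases)) cases$event_hlts else {
    ev <- hlt_events(cases$event_pts, dict)
    attr(ev, "unmapped") <- NULL
    ev
  }
  exposed <- vapply(cases$drug_mentions,
                    function(m) any(m$generic_name %in% drug), logical(1))
  event <- vapply(hlts, function(h) hlt %in% h, logical(1))
  c(a = sum(exposed & event), b = sum(exposed & !event),
    c = sum(!exposed & event), d = sum(!exposed & !event))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed table's (the point-probability convention, with the standard
#' relative slack of 1e-7 on the comparison). A degenerate margin (an empty
#' row or column) carries no evidence; the p-value is 1 by convention and the
#' result is flagged via the `degenerate` attribute.
#'
#' @param tab A length-4 vector `(a, b, c, d)` of non-negative counts.
#' @return The p-value in (0, 1], with attribute `degenerate`.
#' @examples
#' fisher_exact_two_sided(c(3, 1, 1, 3))
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.numeric(tab)
  stopifnot(length(tab) == 4, all(tab >= 0), all(tab == floor(tab)))
  a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
  if (a + b + c + d < 1) abort("empty table")
  m <- a + b      # exposed cases
  n <- c + d      # unexposed cases
  k <- a + c      # event cases
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(min(p, 1), degenerate = FALSE)
}

#' Crude (sample) odds ratio of a 2x2 table
#'
#' `ad / bc`, uncorrected. When `bc = 0` with `ad > 0` the ratio is
#' `+Inf`; when both products are zero the ratio is undefined (`NaN`), which
#' downstream screening treats as not significant.
#'
#' @param tab A length-4 vector `(a, b, c, d)`.
#' @return A non-negative number, `Inf`, or `NaN` when undefined.
#' @examples
#' crude_odds_ratio(c(234, 7031, 804, 179112))
#' @export
crude_odds_ratio <- function(tab) {
  tab <- as.numeric(tab)
  stopifnot(length(tab) == 4, all(tab >= 0))
  ad <- tab[1] * tab[4]
  bc <- tab[2] * tab[3]
  if (bc == 0) {
    if (ad == 0) NaN else Inf
  } else {
    ad / bc
  }
}

#' Phase-1 disproportionality screen over drug-HLT combinations
#'
#' Builds the case-level 2x2 table for every combination of the given drugs
#' (or pooled classes) with every HLT reported in at least one case, applies
#' Fisher's exact test, and flags the combinations with two-sided p < alpha
#' and crude odds ratio > 1. No multiple-testing correction is applied; the
#' stringent significance level stands in for one.
#'
#' @param cases A filtered `pv_cases` tibble.
#' @param drugs A character vector of generic names, and/or a named list
#'   mixing single names with character vectors (a vector screens the pooled
#'   class, exposure = any member; its name labels the rows).
#' @param dict A term dictionary.
#' @param alpha Screening significance level (default 0.01).
#' @return A tibble ordered by (drug, hlt_code) with columns `drug`,
#'   `hlt_code`, `hlt_name`, `a`, `b`, `c`, `d`, `crude_or`, `p_two_sided`,
#'   `significant`.
#' @examples
#' fx <- make_fixture("planted-signal")
#' scr <- screen_all(fx$cases, fx$drugs, fx$dict)
#' sum(scr$significant)
#' @export
screen_all <- function(cases, drugs, dict, alpha = 0.01) {
  if (length(drugs) == 0) abort("drugs must be non-empty")
  if (!is.list(drugs)) drugs <- as.list(drugs)
  labels <- names(drugs) %||% rep("", length(drugs))
  labels[labels == ""] <- vapply(drugs[labels == ""], function(d) {
    normalize_drug_name(d[1])
  }, character(1))
  drug_sets <- lapply(drugs, normalize_drug_name)

  hlts <- if ("event_hlts" %in% names(cases)) cases$event_hlts else {
    ev <- hlt_events(cases$event_pts, dict)
    attr(ev, "unmapped") <- NULL
    ev
  }
  n_total <- nrow(cases)
  # per-HLT case counts over all reported HLTs
  hlt_counts <- table(unlist(lapply(hlts, unique)))
  hlt_codes <- sort(names(hlt_counts))
  hlt_names <- dict |>
    dplyr::distinct(.data$hlt_code, .data$hlt_name) |>
    dplyr::group_by(.data$hlt_code) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  res <- purrr::map2_dfr(drug_sets, labels, function(set, lab) {
    exposed <- vapply(cases$drug_mentions,
                      function(m) any(m$generic_name %in% set), logical(1))
    n_exp <- sum(exposed)
    a_counts <- table(unlist(lapply(hlts[exposed], unique)))
    a <- as.integer(a_counts[hlt_codes])
    a[is.na(a)] <- 0L
    k <- as.integer(hlt_counts[hlt_codes])
    tabs <- cbind(a = a, b = n_exp - a, c = k - a,
                  d = n_total - n_exp - k + a)
    stats <- apply(tabs, 1, function(t) {
      c(or = crude_odds_ratio(t), p = as.numeric(fisher_exact_two_sided(t)))
    })
    tibble::tibble(
      drug = lab, hlt_code = hlt_codes,
      a = tabs[, "a"], b = tabs[, "b"], c = tabs[, "c"], d = tabs[, "d"],
      crude_or = stats["or", ], p_two_sided = stats["p", ]
    )
  })
  res |>
    dplyr::left_join(hlt_names, by = "hlt_code") |>
    dplyr::mutate(
      hlt_name = dplyr::coalesce(.data$hlt_name, .data$hlt_code),
      significant = !is.na(.data$crude_or) & is.finite(.data$p_two_sided) &
        .data$p_two_sided < alpha & !is.nan(.data$crude_or) &
        .data$crude_or > 1
    ) |>
    dplyr::select("drug", "hlt_code", "hlt_name", "a", "b", "c", "d",
                  "crude_or", "p_two_sided", "significant") |>
    dplyr::arrange(.data$drug, .data$hlt_code)
}
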
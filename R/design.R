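#' Per-case regression design for one HLT
#'
#' Codes the outcome and fixed covariates of the logistic models for a single
#' HLT: the binary outcome (HLT reported or not), indicators for use of a
#' DPP-4 inhibitor, a GLP-1 receptor agonist, and any hypoglycemic drug, the
#' count of concomitant suspected drugs, the age decade, sex (female 0,
#' male 1), and the quarterly reporting period as the cluster label.
#'
#' The concomitant-suspected count is the number of distinct suspected-role
#' drugs in the case, excluding the incretin (DPP-4/GLP-1) members, and — when
#' a phase-1 screen is supplied — restricted to drugs whose per-drug Fisher
#' screen for this HLT was significant, so the covariate only counts drugs
#' themselves disproportionally co-reported with the event.
#'
#' @param cases A filtered `pv_cases` tibble.
#' @param hlt HLT code defining the outcome.
#' @param classes A [drug_classes()] configuration.
#' @param dict A term dictionary.
#' @param screen Optional phase-1 screen tibble from [screen_all()] run at
#'   the generic-drug level; `NULL` disables the significance gate.
#' @param window A [study_window()] defining the cluster ordinals.
#' @param exposure_roles Drug roles counting as "use" of a class drug
#'   (default: any role, matching a mention-based exposure definition).
#' @return A `pv_design` tibble with columns `y`, `dpp4`, `glp1`,
#'   `hypoglycemic`, `n_concomitant_suspected`, `age_decade`, `sex`, and
#'   `cluster`.
#' @export
build_design <- function(cases, hlt, classes, dict, screen = NULL,
                         window = study_window(),
                         exposure_roles = NULL) {
  hlts <- if ("event_hlts" %in% names(cases)) cases$event_hlts else {
    ev <- hlt_events(cases$event_pts, dict)
    attr(ev, "unmapped") <- NULL
    ev
  }
  y <- vapply(hlts, function(h) as.integer(hlt %in% h), integer(1))
  if (sum(y) == 0) {
    abort(sprintf("HLT %s is absent from every case; model not estimable", hlt),
          class = "pv_estimability_error")
  }
  exposure_sets <- case_drug_sets(cases, roles = exposure_roles)
  incretin <- c(classes$dpp4, classes$glp1)
  gate <- NULL
  if (!is.null(screen)) {
    gate <- screen$drug[screen$hlt_code == hlt & screen$significant]
  }
  suspected_sets <- case_drug_sets(cases, roles = "suspected")
  n_conc <- vapply(suspected_sets, function(s) {
    s <- setdiff(s, incretin)
    if (!is.null(gate)) s <- intersect(s, gate)
    length(s)
  }, integer(1))
  out <- tibble::tibble(
    y = y,
    dpp4 = vapply(exposure_sets,
                  function(s) as.integer(any(s %in% classes$dpp4)), integer(1)),
    glp1 = vapply(exposure_sets,
                  function(s) as.integer(any(s %in% classes$glp1)), integer(1)),
    hypoglycemic = vapply(exposure_sets,
                          function(s) as.integer(any(s %in% classes$hypoglycemic)),
                          integer(1)),
    n_concomitant_suspected = n_conc,
    age_decade = as.integer(cases$age_decade),
    sex = as.integer(cases$sex == "male"),
    cluster = quarter_ordinal(cases$year, cases$quarter, window)
  )
  if (anyNA(out)) {
    abort("design has missing entries; run filter_analyzable() first",
          class = "pv_estimability_error")
  }
  # a covariate with no variation (e.g. a gated concomitant count that is
  # zero everywhere, or a class with no exposed case) is inestimable; drop
  # it rather than hand the fitters a singular information matrix
  covars <- setdiff(names(out), c("y", "cluster"))
  constant <- covars[vapply(out[covars],
                            function(v) length(unique(v)) == 1L, logical(1))]
  if (length(constant) > 0) out <- out[setdiff(names(out), constant)]
  class(out) <- c("pv_design", class(out))
  attr(out, "dropped_covariates") <- constant
  out
}

# Model matrix from a design tibble: intercept plus every column that is not
# the outcome or the cluster label, in their tibble order.
design_matrix <- function(design) {
  covars <- setdiff(names(design), c("y", "cluster", "case_id"))
  X <- cbind(`(Intercept)` = rep(1, nrow(design)),
             as.matrix(design[covars]))
  storage.mode(X) <- "double"
  X
}

design_response <- function(design) as.numeric(design$y)
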
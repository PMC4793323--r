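#' Drug-class configuration
#'
#' Names the three drug sets the regression phase conditions on: DPP-4
#' inhibitors, GLP-1 receptor agonists, and the wider set of hypoglycemic
#' drugs used as an indication proxy for hyperglycemia. The hypoglycemic set
#' includes the two incretin classes by default; exposure to a class means a
#' mention of any member drug.
#'
#' @param dpp4,glp1,hypoglycemic Character vectors of generic names; names are
#'   normalized with [normalize_drug_name()]. `dpp4` and `glp1` must be
#'   disjoint.
#' @param include_incretins_in_hypoglycemic Add the DPP-4 and GLP-1 members to
#'   the hypoglycemic set (default `TRUE`).
#' @return A `pv_drug_classes` list with elements `dpp4`, `glp1`,
#'   `hypoglycemic`.
#' @examples
#' cl <- default_drug_classes()
#' head(cl$dpp4)
#' @export
drug_classes <- function(dpp4, glp1, hypoglycemic = character(0),
                         include_incretins_in_hypoglycemic = TRUE) {
  dpp4 <- unique(normalize_drug_name(dpp4))
  glp1 <- unique(normalize_drug_name(glp1))
  hypoglycemic <- unique(normalize_drug_name(hypoglycemic))
  if (length(dpp4) == 0 || length(glp1) == 0) {
    abort("dpp4 and glp1 drug sets must be non-empty")
  }
  if (length(intersect(dpp4, glp1)) > 0) {
    abort("dpp4 and glp1 drug sets must be disjoint")
  }
  if (include_incretins_in_hypoglycemic) {
    hypoglycemic <- unique(c(hypoglycemic, dpp4, glp1))
  }
  structure(list(dpp4 = dpp4, glp1 = glp1, hypoglycemic = hypoglycemic),
            class = "pv_drug_classes")
}

#' @rdname drug_classes
#' @details `default_drug_classes()` lists the DPP-4 inhibitors and GLP-1
#'   receptor agonists approved in Japan during the 2010-2015 study window,
#'   plus common non-incretin hypoglycemic drugs for the indication proxy.
#' @export
default_drug_classes <- function() {
  drug_classes(
    dpp4 = c("sitagliptin phosphate hydrate", "vildagliptin",
             "alogliptin benzoate",
             "alogliptin benzoate/pioglitazone hydrochloride",
             "linagliptin", "teneligliptin hydrobromide hydrate",
             "anagliptin", "saxagliptin hydrate"),
    glp1 = c("exenatide", "liraglutide", "lixisenatide"),
    hypoglycemic = c("metformin hydrochloride", "glimepiride",
                     "glibenclamide", "gliclazide", "pioglitazone hydrochloride",
                     "voglibose", "miglitol", "acarbose", "nateglinide",
                     "mitiglinide calcium hydrate", "insulin human",
                     "insulin glargine", "insulin aspart", "insulin lispro",
                     "insulin detemir")
  )
}

#' @rdname drug_classes
#' @param path YAML or JSON file with fields `dpp4`, `glp1`, `hypoglycemic`,
#'   and optionally `include_incretins_in_hypoglycemic`.
#' @export
read_drug_classes <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(drug_classes, cfg)
}

# distinct normalized drug names mentioned by each case, optionally by role
case_drug_sets <- function(cases, roles = NULL) {
  lapply(cases$drug_mentions, function(m) {
    nm <- if (is.null(roles)) m$generic_name else m$generic_name[m$role %in% roles]
    unique(nm)
  })
}
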
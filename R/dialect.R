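#' CSV dialect for spontaneous-report tables
#'
#' A dialect names the columns of the three input tables (demographics, drug
#' mentions, reported adverse-event terms), how ages and sexes are encoded,
#' and which date column defines the reporting quarter. Real-world databases
#' (JADER, FAERS) differ in all of these, so the reader is configured rather
#' than hard-coded.
#'
#' @param demo,drug,reac Named lists mapping canonical column roles to the
#'   column names present in the corresponding CSV file. `demo` needs
#'   `case_id`, `date`, `age`, `sex`; `drug` needs `case_id`, `name`, `role`;
#'   `reac` needs `case_id`, `pt`.
#' @param age_format `"integer"` for plain ages (decade = `floor(age / 10)`)
#'   or `"band"` for 10-year band strings such as `"30歳代"`
#'   (thirties) used by JADER.
#' @param sex_levels Length-2 character vector giving the file values coding
#'   male and female, in that order.
#' @param role_levels Length-3 character vector giving the file values coding
#'   suspected, concomitant, and interacting drug roles, in that order.
#' @param na_strings Values treated as missing in the demographics table.
#' @return A `pv_dialect` list.
#' @examples
#' d <- default_dialect()
#' d$demo$date
#' @export
pv_dialect <- function(demo = list(case_id = "case_id", date = "report_date",
                                   age = "age", sex = "sex"),
                       drug = list(case_id = "case_id", name = "generic_name",
                                   role = "role"),
                       reac = list(case_id = "case_id", pt = "pt_code"),
                       age_format = c("integer", "band"),
                       sex_levels = c("male", "female"),
                       role_levels = c("suspected", "concomitant", "interacting"),
                       na_strings = c("", "NA")) {
  age_format <- match.arg(age_format)
  need <- function(x, nm, what) {
    missing <- setdiff(nm, names(x))
    if (length(missing) > 0) {
      abort(sprintf("dialect %s mapping lacks column role(s): %s",
                    what, paste(missing, collapse = ", ")))
    }
  }
  need(demo, c("case_id", "date", "age", "sex"), "demo")
  need(drug, c("case_id", "name", "role"), "drug")
  need(reac, c("case_id", "pt"), "reac")
  stopifnot(length(sex_levels) == 2, length(role_levels) == 3)
  structure(list(demo = demo, drug = drug, reac = reac,
                 age_format = age_format,
                 sex_levels = sex_levels, role_levels = role_levels,
                 na_strings = na_strings),
            class = "pv_dialect")
}

#' @rdname pv_dialect
#' @export
default_dialect <- function() pv_dialect()

#' @rdname pv_dialect
#' @details `jader_dialect()` pre-configures JADER-style column names,
#'   Japanese 10-year age bands, and Japanese sex / drug-role codings.
#' @export
jader_dialect <- function() {
  pv_dialect(
    demo = list(case_id = "識別番号", date = "報告年月日",
                age = "年齢", sex = "性別"),
    drug = list(case_id = "識別番号", name = "医薬品（一般名）",
                role = "医薬品の関与"),
    reac = list(case_id = "識別番号", pt = "有害事象"),
    age_format = "band",
    sex_levels = c("男性", "女性"),
    role_levels = c("被疑薬", "併用薬", "相互作用")
  )
}

#' Read a dialect from a YAML or JSON file
#'
#' @param path File path; format is inferred from the extension.
#' @return A `pv_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pv_dialect, cfg)
}

# Decade index from the configured age encoding; NA when unparseable.
parse_age_decade <- function(x, dialect) {
  x <- as.character(x)
  x[x %in% dialect$na_strings] <- NA_character_
  if (dialect$age_format == "integer") {
    age <- suppressWarnings(as.numeric(x))
    out <- ifelse(is.finite(age) & age >= 0, floor(age / 10), NA_real_)
  } else {
    m <- regmatches(x, regexec("^([0-9]+)歳代$", x))
    out <- vapply(m, function(g) {
      if (length(g) != 2) return(NA_real_)
      v <- as.numeric(g[2])
      if (v %% 10 == 0) v / 10 else NA_real_   # bands are decade multiples
    }, numeric(1))
  }
  as.integer(out)
}

parse_sex <- function(x, dialect) {
  x <- as.character(x)
  x[x %in% dialect$na_strings] <- NA_character_
  out <- rep(NA_character_, length(x))
  out[x == dialect$sex_levels[1]] <- "male"
  out[x == dialect$sex_levels[2]] <- "female"
  out
}

parse_role <- function(x, dialect) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x == dialect$role_levels[1]] <- "suspected"
  out[x == dialect$role_levels[2]] <- "concomitant"
  out[x == dialect$role_levels[3]] <- "interacting"
  out
}

#' Normalize a generic drug name
#'
#' Trims whitespace, case-folds, and unifies Unicode full-width characters to
#' half-width so that the same generic name always compares equal. Matching
#' thereafter is exact; no drug thesaurus is consulted.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drug_name(c("  Sitagliptin ", "SITAGLIPTIN"))
#' @export
normalize_drug_name <- function(x) {
  x <- stringr::str_squish(as.character(x))
  # full-width ASCII block (U+FF01..U+FF5E) -> half-width; ideographic space
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    cp <- utf8ToInt(s)
    wide <- cp >= 0xFF01 & cp <= 0xFF5E
    cp[wide] <- cp[wide] - 0xFEE0
    cp[cp == 0x3000] <- 0x20
    stringr::str_squish(stringr::str_to_lower(intToUtf8(cp)))
  }, character(1), USE.NAMES = FALSE)
}
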
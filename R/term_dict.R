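#' Adverse-event term dictionary (PT -> HLT -> HLGT -> SOC)
#'
#' Adverse events arrive coded as preferred terms (PTs); the analysis unit is
#' the high-level term (HLT) grouping them, so every stage needs the roll-up.
#' The hierarchy is MedDRA-style: a PT may belong to more than one HLT, each
#' HLT has one HLGT parent, and each HLGT one SOC parent.
#'
#' @param df A data frame with one row per PT-to-HLT link and columns
#'   `pt_code`, `pt_name`, `hlt_code`, `hlt_name`, `hlgt_code`, `soc_code`.
#' @return A `pv_term_dict` tibble (the validated link table).
#' @examples
#' d <- as_term_dictionary(data.frame(
#'   pt_code = c("p1", "p1"), pt_name = "Pancreatitis acute",
#'   hlt_code = c("h1", "h2"),
#'   hlt_name = c("Acute and chronic pancreatitis", "Pancreatic disorders NEC"),
#'   hlgt_code = "g1", soc_code = "s1"))
#' hlt_events(list("p1"), d)
#' @export
as_term_dictionary <- function(df) {
  cols <- c("pt_code", "pt_name", "hlt_code", "hlt_name", "hlgt_code", "soc_code")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("term dictionary lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  d <- tibble::as_tibble(df)[cols]
  d <- dplyr::mutate(d, dplyr::across(dplyr::everything(), as.character))
  if (anyNA(d$pt_code) || anyNA(d$hlt_code)) {
    abort("term dictionary has missing pt_code or hlt_code")
  }
  d <- dplyr::distinct(d)
  # each HLT must roll up to exactly one HLGT, each HLGT to one SOC
  bad_hlt <- d |>
    dplyr::distinct(.data$hlt_code, .data$hlgt_code) |>
    dplyr::count(.data$hlt_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_hlt) > 0) {
    abort(sprintf("HLT(s) with more than one HLGT parent: %s",
                  paste(bad_hlt$hlt_code, collapse = ", ")))
  }
  bad_hlgt <- d |>
    dplyr::distinct(.data$hlgt_code, .data$soc_code) |>
    dplyr::count(.data$hlgt_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_hlgt) > 0) {
    abort(sprintf("HLGT(s) with more than one SOC parent: %s",
                  paste(bad_hlgt$hlgt_code, collapse = ", ")))
  }
  class(d) <- c("pv_term_dict", class(d))
  d
}

#' @rdname as_term_dictionary
#' @param path CSV file with the columns listed above.
#' @export
load_term_dictionary <- function(path) {
  as_term_dictionary(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  )))
}

#' HLT event sets from reported PTs
#'
#' Rolls each case's reported PTs up to the set of HLTs they belong to; a PT
#' with two HLT parents contributes both. PTs absent from the dictionary are
#' dropped from the union and reported via the `unmapped` attribute (and a
#' warning), never an error: real dictionaries lag real data.
#'
#' @param pts A character vector of PT codes, or a list of such vectors (one
#'   element per case).
#' @param dict A [as_term_dictionary()] dictionary.
#' @return For a character vector, a character vector of distinct HLT codes;
#'   for a list, a list of such vectors. The `unmapped` attribute holds the
#'   distinct unmapped PT codes.
#' @export
hlt_events <- function(pts, dict) {
  single <- !is.list(pts)
  if (single) pts <- list(pts)
  all_pts <- unique(unlist(pts))
  unmapped <- setdiff(all_pts, dict$pt_code)
  if (length(unmapped) > 0) {
    warn(sprintf("%d PT code(s) not in the term dictionary were ignored: %s",
                 length(unmapped),
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  map <- split(dict$hlt_code, dict$pt_code)
  out <- lapply(pts, function(p) {
    unique(unlist(map[intersect(unique(p), names(map))], use.names = FALSE)) %||%
      character(0)
  })
  if (single) out <- out[[1]]
  if (length(unmapped) > 0) attr(out, "unmapped") <- unmapped
  out
}
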
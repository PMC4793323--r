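#' Quarterly report volumes by drug class
#'
#' The line-per-class view of reporting volume over the study window that
#' motivates treating the reporting quarter as a random effect: class shares
#' drift as drugs are adopted.
#'
#' @param cases A `pv_cases` tibble.
#' @param classes A [drug_classes()].
#' @param window A [study_window()].
#' @return A ggplot object.
#' @export
plot_quarter_volumes <- function(cases, classes = default_drug_classes(),
                                 window = study_window()) {
  sets <- case_drug_sets(cases)
  tab <- tibble::tibble(
    ordinal = quarter_ordinal(cases$year, cases$quarter, window),
    dpp4 = vapply(sets, function(s) any(s %in% classes$dpp4), logical(1)),
    glp1 = vapply(sets, function(s) any(s %in% classes$glp1), logical(1)),
    hypoglycemic = vapply(sets, function(s) any(s %in% classes$hypoglycemic),
                          logical(1))
  ) |>
    dplyr::group_by(.data$ordinal) |>
    dplyr::summarise(`all cases` = dplyr::n(),
                     `DPP-4 inhibitors` = sum(.data$dpp4),
                     `GLP-1 receptor agonists` = sum(.data$glp1),
                     `any hypoglycemic` = sum(.data$hypoglycemic),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"ordinal", names_to = "series", values_to = "n")
  ggplot2::ggplot(tab, ggplot2::aes(.data$ordinal, .data$n,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Quarter (ordinal within study window)",
                  y = "Reported cases", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of significant class odds ratios
#'
#' @param forest The `forest` tibble from [run_model_phase()] (columns
#'   `drug_class`, `hlt_code`, `or`, `ci_low`, `ci_high`).
#' @return A ggplot object with a log-scaled OR axis and a reference line at
#'   1.
#' @export
plot_forest <- function(forest) {
  ggplot2::ggplot(forest,
                  ggplot2::aes(x = .data$or, y = .data$hlt_code,
                               xmin = .data$ci_low, xmax = .data$ci_high,
                               colour = .data$drug_class)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (Wald CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' AIC-difference scatter against reporting volume
#'
#' Plots `AIC(mixed) - AIC(fixed)` against the number of cases reporting the
#' HLT; points below zero favor the random effect.
#'
#' @param aic_tbl The per-HLT tibble from [run_model_phase()] /
#'   [run_aic_comparison()].
#' @return A ggplot object.
#' @export
plot_aic_comparison <- function(aic_tbl) {
  det <- dplyr::filter(aic_tbl, .data$winner != "undetermined")
  ggplot2::ggplot(det, ggplot2::aes(.data$total_cases, .data$delta_aic,
                                    colour = .data$winner)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Cases reporting the HLT",
                  y = "AIC difference (mixed - fixed)", colour = NULL) +
    ggplot2::theme_minimal()
}
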
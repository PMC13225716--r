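PHENOTYPES <- c("disorganized", "organized_or_condensed", "none_reported")

#' Golgi phenotype a knockdown should reproduce under concordance
#'
#' Within a screened cell-line pair, the lower-expressing cell line's Golgi
#' phenotype is the phenotype that knocking the gene down should reproduce if
#' expression and phenotype are causally linked. A gene higher in the
#' organized line is lower in the disorganized line, so its concordant
#' knockdown phenotype is `"disorganized"`, and vice versa.
#'
#' @param direction Character vector, `"higher_in_organized"` or
#'   `"higher_in_disorganized"` (a screened DEG is never `"equal"`).
#' @return Character vector, `"disorganized"` or `"organized_or_condensed"`.
#' @examples
#' predicted_low_expression_phenotype("higher_in_organized")
#' @export
predicted_low_expression_phenotype <- function(direction) {
  ok <- direction %in% c("higher_in_organized", "higher_in_disorganized")
  if (!all(ok)) {
    rlang::abort("`direction` must be a strict inequality (higher_in_organized or higher_in_disorganized)",
                 class = "golgiscreen_invalid_context")
  }
  ifelse(direction == "higher_in_organized", "disorganized", "organized_or_condensed")
}

#' Literature knockdown-concordance score (0/1/2)
#'
#' Scores each gene's curated knockdown evidence against its expression
#' pattern in the screened pair:
#' * **2** - the reported knockdown phenotype matches the Golgi phenotype of
#'   the cell line in which the gene is expressed at the lower level
#'   (concordant).
#' * **1** - knockdown data exist but the phenotype is discordant with the
#'   expression pattern.
#' * **0** - no knockdown data reported.
#'
#' @param evidence Data frame with columns `gene`, `knockdown_phenotype`
#'   (`"disorganized"`, `"organized_or_condensed"`, or `"none_reported"`) and
#'   `golgi_involvement` (logical). Genes absent from `evidence` are treated
#'   as `none_reported`.
#' @param directions Data frame with columns `gene` and `direction` (e.g. the
#'   passed rows of a [screen_degs()] table).
#' @return A tibble with columns `gene`, `score1` and `rationale`
#'   (`"concordant"`, `"involved_discordant"`, `"discordant"`, `"no_data"`),
#'   one row per gene in `directions`.
#' @export
literature_score <- function(evidence, directions) {
  stopifnot(is.data.frame(evidence), is.data.frame(directions))
  check_columns(evidence, c("gene", "knockdown_phenotype", "golgi_involvement"), "evidence table")
  check_columns(directions, c("gene", "direction"), "directions table")
  bad <- !evidence$knockdown_phenotype %in% PHENOTYPES
  if (any(bad)) {
    rlang::abort(sprintf("unknown knockdown_phenotype value(s): %s",
                         paste(unique(evidence$knockdown_phenotype[bad]), collapse = ", ")),
                 class = "golgiscreen_parse_error")
  }
  ev <- evidence |>
    dplyr::mutate(gene = normalize_symbol(.data$gene)) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::select("gene", "knockdown_phenotype", "golgi_involvement")
  directions |>
    dplyr::mutate(gene = normalize_symbol(.data$gene)) |>
    dplyr::select("gene", "direction") |>
    dplyr::left_join(ev, by = "gene") |>
    dplyr::mutate(
      knockdown_phenotype = dplyr::coalesce(.data$knockdown_phenotype, "none_reported"),
      golgi_involvement = dplyr::coalesce(.data$golgi_involvement, FALSE),
      predicted = predicted_low_expression_phenotype(.data$direction),
      score1 = dplyr::case_when(
        .data$knockdown_phenotype == "none_reported" ~ 0L,
        .data$knockdown_phenotype == .data$predicted ~ 2L,
        TRUE ~ 1L
      ),
      rationale = dplyr::case_when(
        .data$score1 == 2L ~ "concordant",
        .data$score1 == 1L & .data$golgi_involvement ~ "involved_discordant",
        .data$score1 == 1L ~ "discordant",
        TRUE ~ "no_data"
      )
    ) |>
    dplyr::select("gene", "score1", "rationale")
}
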
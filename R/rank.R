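#' Combine score components and select candidate regulators
#'
#' Adds the literature knockdown score (0/1/2) and the Golgi-interactor count
#' for every gene passing the expression screen, keeps genes whose combined
#' score meets the cutoff (default 3), and ranks them by combined score, then
#' fold change, then symbol. Genes missing from either score table score 0 on
#' that component (with a warning), so partially curated inputs still run.
#'
#' @param degs A [screen_degs()] table (only `passed` rows are considered).
#' @param scores1 Data frame with columns `gene`, `score1` (from
#'   [literature_score()]).
#' @param scores2 Data frame with columns `gene`, `score2` (from
#'   [count_golgi_interactors()]).
#' @param cutoff Minimum combined score for selection (default 3).
#' @return A `candidate_ranking` tibble with columns `rank`, `gene`, `fc`,
#'   `direction`, `score1`, `score2`, `combined`, sorted by rank.
#' @export
combine_and_select <- function(degs, scores1, scores2, cutoff = 3L) {
  stopifnot(is.data.frame(degs), is.numeric(cutoff), length(cutoff) == 1L)
  check_columns(degs, c("gene", "fc", "direction", "passed"), "DEG table")
  check_columns(scores1, c("gene", "score1"), "literature score table")
  check_columns(scores2, c("gene", "score2"), "interactor score table")
  passed <- dplyr::filter(tibble::as_tibble(unclass_screen(degs)), .data$passed)

  s1 <- dplyr::distinct(tibble::as_tibble(scores1), .data$gene, .keep_all = TRUE)
  s2 <- dplyr::distinct(tibble::as_tibble(scores2), .data$gene, .keep_all = TRUE)
  out <- passed |>
    dplyr::select("gene", "fc", "direction") |>
    dplyr::left_join(dplyr::select(s1, "gene", "score1"), by = "gene") |>
    dplyr::left_join(dplyr::select(s2, "gene", "score2"), by = "gene")
  n_missing <- sum(is.na(out$score1)) + sum(is.na(out$score2))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d missing score component(s) treated as 0", n_missing))
  }
  out |>
    dplyr::mutate(
      score1 = as.integer(dplyr::coalesce(.data$score1, 0L)),
      score2 = as.integer(dplyr::coalesce(.data$score2, 0L)),
      combined = .data$score1 + .data$score2
    ) |>
    dplyr::filter(.data$combined >= cutoff) |>
    dplyr::arrange(dplyr::desc(.data$combined), dplyr::desc(.data$fc), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    structure(cutoff = as.integer(cutoff),
              cancer_type = attr(degs, "pair")$cancer_type,
              class = c("candidate_ranking", class(passed)))
}

#' Genes common to two candidate lists
#'
#' @param list_a,list_b Candidate rankings (or any data frame with a `gene`
#'   column, or bare character vectors).
#' @return Sorted character vector of shared gene symbols.
#' @export
intersect_candidates <- function(list_a, list_b) {
  get_genes <- function(x) {
    if (is.data.frame(x)) universe_genes(x) else unique(normalize_symbol(as.character(x)))
  }
  a <- if (is.data.frame(list_a) && nrow(list_a) == 0 || length(list_a) == 0) character() else get_genes(list_a)
  b <- if (is.data.frame(list_b) && nrow(list_b) == 0 || length(list_b) == 0) character() else get_genes(list_b)
  sort(intersect(a, b))
}

#' Top-ranked candidates
#'
#' @param candidates A [combine_and_select()] ranking.
#' @param n Number of top-ranked records to return (all if fewer).
#' @return The first `n` rows in rank order.
#' @export
top_candidates <- function(candidates, n = 3L) {
  stopifnot(is.data.frame(candidates), is.numeric(n), length(n) == 1L, n >= 1)
  utils::head(dplyr::arrange(candidates, .data$rank), n)
}

#' @method tidy candidate_ranking
#' @export
tidy.candidate_ranking <- function(x, ...) {
  out <- x
  attr(out, "cutoff") <- NULL
  attr(out, "cancer_type") <- NULL
  class(out) <- setdiff(class(out), "candidate_ranking")
  tibble::as_tibble(out)
}

#' @method glance candidate_ranking
#' @export
glance.candidate_ranking <- function(x, ...) {
  tibble::tibble(
    cancer_type = attr(x, "cancer_type") %||% NA_character_,
    cutoff = attr(x, "cutoff"),
    n_selected = nrow(x),
    max_combined = if (nrow(x)) max(x$combined) else NA_integer_
  )
}

#' Score-component plot of a candidate ranking
#'
#' @param object A [combine_and_select()] ranking.
#' @param ... Unused.
#' @return A ggplot of literature score vs interactor count, point size by
#'   fold change, labelled with gene symbols.
#' @method autoplot candidate_ranking
#' @export
autoplot.candidate_ranking <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score2, y = .data$score1,
                                   size = .data$fc, label = .data$gene)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::labs(x = "Golgi-associated interactors (score 2)",
                  y = "knockdown concordance (score 1)",
                  size = "fold change") +
    ggplot2::theme_minimal()
}
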
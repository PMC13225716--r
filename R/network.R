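#' Build an undirected interaction network from an edge list
#'
#' Normalizes gene symbols, drops self-loops, canonicalizes each undirected
#' pair, and merges duplicate pairs by taking the per-channel maximum
#' confidence. Channel columns on the 0-1000 integer convention (any value
#' greater than 1) are auto-detected and rescaled to [0, 1].
#'
#' @param edges Data frame with columns `protein1`, `protein2` and one numeric
#'   confidence column per evidence channel (e.g. `experimental`,
#'   `combined_score`).
#' @return A tibble with columns `protein1`, `protein2` (`protein1 <
#'   protein2`), and the channel columns, one row per unordered pair.
#' @examples
#' as_interaction_network(tibble::tibble(
#'   protein1 = c("A", "B"), protein2 = c("B", "A"),
#'   experimental = c(0.5, 0.7)
#' ))
#' @export
as_interaction_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  check_columns(edges, c("protein1", "protein2"), "edge list")
  channels <- setdiff(names(edges), c("protein1", "protein2"))
  channels <- channels[vapply(edges[channels], is.numeric, logical(1))]
  edges <- tibble::as_tibble(edges[c("protein1", "protein2", channels)])
  for (ch in channels) {
    v <- edges[[ch]]
    if (any(v < 0, na.rm = TRUE)) {
      rlang::abort(sprintf("negative confidence in channel '%s'", ch),
                   class = "golgiscreen_parse_error")
    }
    if (any(v > 1, na.rm = TRUE)) edges[[ch]] <- v / 1000
    if (any(edges[[ch]] > 1, na.rm = TRUE)) {
      rlang::abort(sprintf("channel '%s' has confidences outside [0, 1] after rescaling", ch),
                   class = "golgiscreen_parse_error")
    }
  }
  a <- normalize_symbol(edges$protein1)
  b <- normalize_symbol(edges$protein2)
  edges$protein1 <- pmin(a, b)
  edges$protein2 <- pmax(a, b)
  edges |>
    dplyr::filter(.data$protein1 != .data$protein2) |>
    dplyr::group_by(.data$protein1, .data$protein2) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(channels),
                    ~ if (all(is.na(.x))) NA_real_ else max(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein1, .data$protein2)
}

#' Filter network edges by channel confidence
#'
#' Retains exactly the edges whose confidence on the chosen evidence channel
#' meets the cutoff; edges lacking a score on that channel are dropped. The
#' defaults follow the screen's use of experimental-evidence interactions at
#' confidence >= 0.4.
#'
#' @param net An [as_interaction_network()] tibble.
#' @param channel Channel column to filter on (default `"experimental"`).
#' @param min_conf Minimum confidence in [0, 1] (default 0.4).
#' @return The filtered network tibble.
#' @export
filter_edges <- function(net, channel = "experimental", min_conf = 0.4) {
  stopifnot(is.data.frame(net), length(channel) == 1L,
            is.numeric(min_conf), min_conf >= 0, min_conf <= 1)
  if (!channel %in% names(net)) {
    rlang::warn(sprintf("channel '%s' not present in network; returning empty network", channel))
    return(net[0, , drop = FALSE])
  }
  dplyr::filter(net, !is.na(.data[[channel]]), .data[[channel]] >= min_conf)
}

#' Count Golgi-associated primary interactors
#'
#' For each query gene, counts its distinct first-shell neighbors in the
#' (already confidence-filtered) network that belong to the Golgi-associated
#' gene universe. This count is the network score component: it is uncapped,
#' since no restriction is placed on the number of interactors considered.
#' Genes absent from the network score 0; a gene never counts itself.
#'
#' @param net A filtered [as_interaction_network()] tibble.
#' @param genes Character vector of query gene symbols.
#' @param universe A [build_universe()] tibble or character vector.
#' @return A tibble with columns `gene`, `n_golgi_interactors`, `score2`
#'   (identical to the count), one row per query gene in input order.
#' @export
count_golgi_interactors <- function(net, genes, universe) {
  stopifnot(is.data.frame(net))
  genes <- normalize_symbol(genes)
  uni <- universe_genes(universe)
  incident <- dplyr::bind_rows(
    tibble::tibble(gene = net$protein1, neighbor = net$protein2),
    tibble::tibble(gene = net$protein2, neighbor = net$protein1)
  ) |>
    dplyr::filter(.data$gene %in% genes,
                  .data$neighbor %in% uni,
                  .data$neighbor != .data$gene) |>
    dplyr::distinct(.data$gene, .data$neighbor) |>
    dplyr::count(.data$gene, name = "n_golgi_interactors")
  tibble::tibble(gene = genes) |>
    dplyr::left_join(incident, by = "gene") |>
    dplyr::mutate(
      n_golgi_interactors = dplyr::coalesce(.data$n_golgi_interactors, 0L),
      score2 = .data$n_golgi_interactors
    )
}
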
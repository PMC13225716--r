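#' Normalize gene symbols
#'
#' Gene identities are compared as uppercase, whitespace-trimmed HGNC-style
#' tokens throughout the package. All user-facing functions normalize their
#' inputs through this helper, so `"Axl "` and `"AXL"` refer to the same gene.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_symbol(c("Axl ", " golga2"))
#' @export
normalize_symbol <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- toupper(trimws(x))
  bad <- is.na(out) | out == "" | grepl("\\s", out)
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "invalid gene symbol(s): %s",
        paste(utils::head(sprintf("'%s'", x[bad]), 5L), collapse = ", ")
      ),
      class = "golgiscreen_invalid_symbol"
    )
  }
  out
}

#' Select genes annotated with any of a set of terms
#'
#' Filters a gene-term annotation table (the stand-in for a flat GO query
#' result) to the distinct genes carrying at least one of the query terms.
#' Matching is exact on the term label/identifier after case-folding; no
#' ontology traversal is performed.
#'
#' @param annotation Data frame with columns `gene` and `term`.
#' @param terms Character vector of query terms (labels or identifiers).
#' @return Sorted character vector of distinct normalized gene symbols.
#' @examples
#' tab <- tibble::tibble(
#'   gene = c("A", "B", "C"),
#'   term = c("golgi organization", "golgi organization", "mitosis")
#' )
#' select_by_terms(tab, "Golgi organization")
#' @export
select_by_terms <- function(annotation, terms) {
  stopifnot(is.data.frame(annotation))
  check_columns(annotation, c("gene", "term"), "annotation table")
  if (length(terms) == 0L || all(trimws(terms) == "")) {
    rlang::abort("`terms` must contain at least one non-empty term")
  }
  if (nrow(annotation) == 0L) return(character())
  hit <- tolower(trimws(annotation$term)) %in% tolower(trimws(terms))
  sort(unique(normalize_symbol(annotation$gene[hit])))
}

#' Assemble the Golgi-associated gene universe
#'
#' Merges the annotation-derived gene set with a curated regulator list into
#' one universe, recording the provenance of each gene. This mirrors how the
#' screen's gene universe is built from a flat ontology query union a
#' literature-collated regulator list.
#'
#' @param annotation_genes Character vector of annotation-derived symbols.
#' @param curated Character vector of curated regulator symbols.
#' @return A tibble with columns `gene` (normalized symbol, unique, sorted)
#'   and `source` (one of `"annotation"`, `"curated"`, `"both"`).
#' @examples
#' build_universe(c("A", "B"), c("B", "C"))
#' @export
build_universe <- function(annotation_genes, curated = character()) {
  ann <- if (length(annotation_genes)) unique(normalize_symbol(annotation_genes)) else character()
  cur <- if (length(curated)) unique(normalize_symbol(curated)) else character()
  genes <- sort(union(ann, cur))
  tibble::tibble(
    gene = genes,
    source = dplyr::case_when(
      genes %in% ann & genes %in% cur ~ "both",
      genes %in% ann ~ "annotation",
      TRUE ~ "curated"
    )
  )
}

# Accept either a build_universe() tibble or a bare character vector wherever
# a universe is consumed.
universe_genes <- function(universe) {
  if (is.data.frame(universe)) {
    check_columns(universe, "gene", "universe")
    unique(normalize_symbol(universe$gene))
  } else {
    unique(normalize_symbol(universe))
  }
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(
      sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      class = "golgiscreen_parse_error"
    )
  }
  invisible(df)
}
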
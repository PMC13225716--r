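#' Read the five pipeline input formats
#'
#' Plain-text readers for the screen's inputs. Each validates the documented
#' header and basic invariants and reports the offending file (and row where
#' possible) on failure.
#'
#' * `read_annotation()`: TSV with columns `gene`, `term`; duplicate
#'   (gene, term) rows are collapsed.
#' * `read_gene_list()`: one symbol per line, `#` comments and blank lines
#'   ignored.
#' * `read_expression()`: TSV with first column `gene`, remaining columns
#'   cell-line RPKM; negative values and duplicate genes are rejected.
#' * `read_interactions()`: TSV edge list passed through
#'   [as_interaction_network()] (0-1000 scores auto-rescaled).
#' * `read_evidence()`: CSV with columns `gene`, `knockdown_phenotype`,
#'   `golgi_involvement`, optional `citation`.
#'
#' @param path Path to the input file.
#' @return A tibble (or character vector for `read_gene_list()`).
#' @name readers
NULL

#' @rdname readers
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(tab, c("gene", "term"), sprintf("annotation file '%s'", path))
  tab |>
    dplyr::mutate(gene = normalize_symbol(.data$gene), term = trimws(.data$term)) |>
    dplyr::distinct(.data$gene, tolower(.data$term), .keep_all = TRUE) |>
    dplyr::select("gene", "term")
}

#' @rdname readers
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  if (length(lines) == 0L) return(character())
  unique(normalize_symbol(lines))
}

#' @rdname readers
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  check_columns(tab, "gene", sprintf("expression file '%s'", path))
  if (ncol(tab) < 2L) {
    rlang::abort(sprintf("expression file '%s' has no cell-line columns", path),
                 class = "golgiscreen_parse_error")
  }
  tab$gene <- normalize_symbol(tab$gene)
  if (anyDuplicated(tab$gene)) {
    rlang::abort(sprintf("duplicate gene symbols in '%s': %s", path,
                         paste(utils::head(unique(tab$gene[duplicated(tab$gene)]), 5), collapse = ", ")),
                 class = "golgiscreen_parse_error")
  }
  vals <- as.matrix(tab[-1])
  if (anyNA(vals)) {
    rlang::abort(sprintf("non-numeric or missing RPKM in '%s' (first bad row: %d)",
                         path, which(rowSums(is.na(tab[-1])) > 0)[1]),
                 class = "golgiscreen_parse_error")
  }
  if (any(vals < 0)) {
    rlang::abort(sprintf("negative RPKM in '%s' (first bad row: %d)",
                         path, which(rowSums(tab[-1] < 0) > 0)[1]),
                 class = "golgiscreen_parse_error")
  }
  tab
}

#' @rdname readers
#' @export
read_interactions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein1 = readr::col_character(), protein2 = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  check_columns(tab, c("protein1", "protein2"), sprintf("edge list '%s'", path))
  as_interaction_network(tab)
}

#' @rdname readers
#' @export
read_evidence <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(),
    knockdown_phenotype = readr::col_character(),
    golgi_involvement = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  check_columns(tab, c("gene", "knockdown_phenotype", "golgi_involvement"),
                sprintf("evidence file '%s'", path))
  bad <- which(!tab$knockdown_phenotype %in% PHENOTYPES)
  if (length(bad)) {
    rlang::abort(sprintf("invalid knockdown_phenotype in '%s' at data row %d: '%s'",
                         path, bad[1], tab$knockdown_phenotype[bad[1]]),
                 class = "golgiscreen_parse_error")
  }
  tab$gene <- normalize_symbol(tab$gene)
  tab
}

#' Write pipeline inputs
#'
#' Writers mirroring the [readers]; `write(read(x))` round-trips content.
#'
#' @param x Object to write.
#' @param path Output path.
#' @name writers
NULL

#' @rdname writers
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname writers
#' @export
write_interactions <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
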
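#' Describe a cancer-type cell-line pair
#'
#' A screening comparison is defined by one cell line with a predominantly
#' organized Golgi and one with a predominantly disorganized Golgi, plus the
#' base fold-change threshold and the adaptive cap on the number of genes
#' carried forward. Defaults follow the study layout: breast uses a 10-fold
#' base threshold, lung a 5-fold one, both capped at the top 50.
#'
#' @param cancer_type Label for the comparison (e.g. `"breast"`).
#' @param organized_line,disorganized_line Cell-line column names in the
#'   expression matrix.
#' @param base_threshold Minimum symmetric fold-change ratio (>= 1) for a gene
#'   to count as differentially expressed.
#' @param cap Maximum number of genes retained after screening (>= 1). When
#'   more than `cap` genes pass the base threshold, the effective threshold is
#'   raised so only the top `cap` by fold change remain.
#' @return A `cell_line_pair` list.
#' @examples
#' cell_line_pair("breast", "MDAMB231", "MCF7", base_threshold = 10)
#' @export
cell_line_pair <- function(cancer_type, organized_line, disorganized_line,
                           base_threshold, cap = 50L) {
  stopifnot(
    is.character(cancer_type), length(cancer_type) == 1L,
    length(organized_line) == 1L, length(disorganized_line) == 1L,
    is.numeric(base_threshold), length(base_threshold) == 1L,
    is.numeric(cap), length(cap) == 1L
  )
  if (identical(organized_line, disorganized_line)) {
    rlang::abort("organized and disorganized cell lines must differ")
  }
  if (base_threshold < 1) rlang::abort("`base_threshold` must be >= 1")
  if (cap < 1) rlang::abort("`cap` must be >= 1")
  structure(
    list(
      cancer_type = cancer_type,
      organized_line = organized_line,
      disorganized_line = disorganized_line,
      base_threshold = as.numeric(base_threshold),
      cap = as.integer(cap)
    ),
    class = "cell_line_pair"
  )
}

# Relative tolerance for fold-change equality/threshold comparisons. Planted
# ratios are realized as (baseline * r) / baseline, which need not round-trip
# exactly in floating point.
FC_REL_TOL <- 1e-9

#' Symmetric fold change between two expression values
#'
#' Computes the symmetric (direction-free) expression ratio max/min between
#' two RPKM values, retaining which side was higher as metadata. The screen
#' must be direction-symmetric: a gene can be higher in the organized line of
#' one cancer pair and higher in the disorganized line of the other, yet count
#' as differentially expressed in both. When the smaller value is zero the
#' pseudocount is added to both sides of the ratio's denominator form,
#' `(max + pseudocount) / pseudocount`, keeping nonzero ratios exact.
#'
#' @param a,b Nonnegative RPKM values (vectorized, recycled to equal length).
#' @param pseudocount Nonnegative value used only when `min(a, b)` is zero
#'   (default 0.01 RPKM).
#' @return A tibble with columns `fc` (ratio >= 1) and `direction` (one of
#'   `"higher_in_first"`, `"higher_in_second"`, `"equal"`).
#' @examples
#' fold_change(30, 3)
#' fold_change(5, 0, pseudocount = 0.01)
#' @export
fold_change <- function(a, b, pseudocount = 0.01) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(pseudocount),
            length(pseudocount) == 1L, pseudocount >= 0)
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  if (any(a < 0 | b < 0, na.rm = TRUE)) {
    rlang::abort("RPKM values must be nonnegative")
  }
  mn <- pmin(a, b)
  mx <- pmax(a, b)
  if (pseudocount == 0 && any(mx == 0)) {
    rlang::abort("fold change undefined: both values zero and pseudocount is 0",
                 class = "golgiscreen_undefined_ratio")
  }
  fc <- ifelse(mn > 0, mx / mn, (mx + pseudocount) / pseudocount)
  direction <- dplyr::case_when(
    fc <= 1 + FC_REL_TOL ~ "equal",
    a > b ~ "higher_in_first",
    TRUE ~ "higher_in_second"
  )
  fc[direction == "equal"] <- pmax(fc[direction == "equal"], 1)
  tibble::tibble(fc = fc, direction = direction)
}

#' Screen a cell-line pair for differentially expressed genes
#'
#' Restricts the expression matrix to the Golgi-associated gene universe,
#' computes each gene's symmetric fold change between the organized and
#' disorganized cell line, applies the base threshold, and then the adaptive
#' cap: if more than `pair$cap` genes pass, the effective threshold is raised
#' so that exactly the top `cap` genes by fold change (ties at the boundary
#' broken by ascending symbol) remain flagged.
#'
#' @param expr Data frame with a `gene` column and one numeric RPKM column per
#'   cell line.
#' @param universe A [build_universe()] tibble or character vector of symbols.
#' @param pair A [cell_line_pair()].
#' @param pseudocount Passed to [fold_change()].
#' @return A `deg_screen` tibble with columns `gene`, `fc`, `direction`
#'   (`"higher_in_organized"`, `"higher_in_disorganized"`, `"equal"`) and
#'   `passed`, sorted by `fc` descending then symbol ascending. Attributes
#'   `pair` and `effective_threshold` record the screening parameters;
#'   [glance()] summarizes them.
#' @examples
#' expr <- tibble::tibble(gene = c("A", "B"), L1 = c(30, 4), L2 = c(2, 4))
#' pair <- cell_line_pair("toy", "L1", "L2", base_threshold = 5)
#' screen_degs(expr, c("A", "B"), pair)
#' @export
screen_degs <- function(expr, universe, pair, pseudocount = 0.01) {
  stopifnot(is.data.frame(expr), inherits(pair, "cell_line_pair"))
  check_columns(expr, "gene", "expression matrix")
  for (line in c(pair$organized_line, pair$disorganized_line)) {
    if (!line %in% names(expr)) {
      rlang::abort(sprintf("cell line '%s' not found in expression matrix", line),
                   class = "golgiscreen_config_error")
    }
  }
  genes <- normalize_symbol(expr$gene)
  if (anyDuplicated(genes)) {
    rlang::abort("duplicate gene symbols in expression matrix")
  }
  keep <- genes %in% universe_genes(universe)
  org <- expr[[pair$organized_line]][keep]
  dis <- expr[[pair$disorganized_line]][keep]

  fc_tab <- if (any(keep)) fold_change(org, dis, pseudocount) else
    tibble::tibble(fc = numeric(), direction = character())
  tab <- tibble::tibble(
    gene = genes[keep],
    fc = fc_tab$fc,
    direction = dplyr::recode(fc_tab$direction,
      higher_in_first = "higher_in_organized",
      higher_in_second = "higher_in_disorganized"
    )
  ) |>
    dplyr::arrange(dplyr::desc(.data$fc), .data$gene)

  thr <- pair$base_threshold
  passed <- tab$fc >= thr * (1 - FC_REL_TOL)
  effective <- thr
  if (sum(passed) > pair$cap) {
    # rows are already in (fc desc, symbol asc) order, so the first `cap`
    # passing rows are exactly the retained set under the tie-break rule
    keep_idx <- which(passed)[seq_len(pair$cap)]
    effective <- tab$fc[keep_idx[pair$cap]]
    passed <- seq_len(nrow(tab)) %in% keep_idx
  }
  tab$passed <- passed

  structure(
    tab,
    pair = pair,
    effective_threshold = effective,
    pseudocount = pseudocount,
    class = c("deg_screen", class(tab))
  )
}

#' @method tidy deg_screen
#' @export
tidy.deg_screen <- function(x, ...) {
  tibble::as_tibble(unclass_screen(x))
}

#' @method glance deg_screen
#' @export
glance.deg_screen <- function(x, ...) {
  pair <- attr(x, "pair")
  tibble::tibble(
    cancer_type = pair$cancer_type,
    organized_line = pair$organized_line,
    disorganized_line = pair$disorganized_line,
    base_threshold = pair$base_threshold,
    effective_threshold = attr(x, "effective_threshold"),
    cap = pair$cap,
    n_candidates = nrow(x),
    n_passed = sum(x$passed)
  )
}

#' Fold-change profile of a DEG screen
#'
#' @param object A `deg_screen` from [screen_degs()].
#' @param ... Unused.
#' @return A ggplot: genes ranked by fold change on a log scale, colored by
#'   pass/fail, with the base and effective thresholds drawn as dashed lines.
#' @method autoplot deg_screen
#' @export
autoplot.deg_screen <- function(object, ...) {
  df <- tidy(object)
  df$rank <- seq_len(nrow(df))
  pair <- attr(object, "pair")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$fc, colour = .data$passed)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = pair$base_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "effective_threshold"),
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "gene rank by fold change", y = "symmetric fold change (RPKM ratio)",
      colour = "passed",
      title = sprintf("%s: %s vs %s", pair$cancer_type,
                      pair$organized_line, pair$disorganized_line)
    ) +
    ggplot2::theme_minimal()
}

unclass_screen <- function(x) {
  attr(x, "pair") <- NULL
  attr(x, "effective_threshold") <- NULL
  attr(x, "pseudocount") <- NULL
  class(x) <- setdiff(class(x), "deg_screen")
  x
}
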
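#' Default study layout: two cancer-type cell-line pairs
#'
#' Breast (MDAMB231 organized vs MCF7 disorganized, 10-fold base threshold)
#' and lung (A549 organized vs CALU1 disorganized, 5-fold), both capped at the
#' top 50 genes.
#'
#' @return Named list of [cell_line_pair()] objects.
#' @export
default_pairs <- function() {
  list(
    breast = cell_line_pair("breast", "MDAMB231", "MCF7", base_threshold = 10, cap = 50L),
    lung = cell_line_pair("lung", "A549", "CALU1", base_threshold = 5, cap = 50L)
  )
}

#' Default planted-gene table for the synthetic bundle
#'
#' Three candidate genes shared by both cancer types (fold change above both
#' thresholds, concordant or involved-but-discordant evidence, and Golgi
#' interactors summing with the literature score to at least the cutoff) plus
#' three decoys, each violating exactly one selection criterion: `DECOYNOEV`
#' passes the screen but has no evidence and no Golgi interactors,
#' `DECOYLOWFC` has strong scores but a fold change below both thresholds, and
#' `DECOYLOWSC` passes the screen with concordant evidence but no interactors
#' (combined score 2 < 3).
#'
#' @return Tibble with columns `gene`, `cancer_type`, `fc_ratio`, `direction`,
#'   `score1_setup`, `n_golgi_neighbors`.
#' @export
default_planted <- function() {
  tibble::tribble(
    ~gene,        ~cancer_type, ~fc_ratio, ~direction,                ~score1_setup, ~n_golgi_neighbors,
    "CANDA",      "both",       20,        "higher_in_organized",     2L,            3L,
    "CANDB",      "both",       12,        "higher_in_organized",     2L,            1L,
    "CANDC",      "both",       8,         "higher_in_disorganized",  1L,            4L,
    "DECOYNOEV",  "both",       15,        "higher_in_organized",     0L,            0L,
    "DECOYLOWFC", "both",       3,         "higher_in_organized",     2L,            5L,
    "DECOYLOWSC", "both",       11,        "higher_in_organized",     2L,            0L
  )
}

#' Configuration for the synthetic input generators
#'
#' Bundles every parameter the three generators need and validates the
#' construction guarantees that make planted ground truth exactly
#' recoverable:
#' * `background_max_fc` must be strictly below every pair's base threshold,
#'   so no background gene can pass the expression screen;
#' * each planted gene's `n_golgi_neighbors` must fit inside the non-planted
#'   part of the universe.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of genes in the expression matrix (default 500).
#' @param n_universe Size of the Golgi-associated universe (default 60),
#'   comprising the planted genes plus background members.
#' @param planted Planted-gene table, see [default_planted()]. `cancer_type`
#'   is a pair name or `"both"`; `fc_ratio` is realized exactly between that
#'   pair's cell lines; `score1_setup` in 0/1/2 is realized through the
#'   generated evidence table; `n_golgi_neighbors` through the network.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters for
#'   baseline RPKM (defaults meanlog 1, sdlog 0.8).
#' @param background_max_fc Upper bound on any background gene's between-line
#'   expression ratio (default 3).
#' @param n_background_edges Number of random background interactions drawn
#'   (default 1500; 0 gives a planted-edges-only network).
#' @param background_score_shape Beta shape parameters for background
#'   experimental-channel confidences (default c(2, 5), mass mostly below
#'   0.4).
#' @param pairs Named list of [cell_line_pair()] (default [default_pairs()]).
#' @param cutoff Combined-score selection cutoff (default 3).
#' @param pseudocount Screen pseudocount (default 0.01).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_genes = 500L, n_universe = 60L,
                         planted = default_planted(),
                         baseline_log_mean = 1, baseline_log_sd = 0.8,
                         background_max_fc = 3,
                         n_background_edges = 1500L,
                         background_score_shape = c(2, 5),
                         pairs = default_pairs(),
                         cutoff = 3L, pseudocount = 0.01) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_genes >= 1, n_universe >= 1, n_universe <= n_genes,
            baseline_log_sd >= 0, background_max_fc >= 1,
            n_background_edges >= 0, length(background_score_shape) == 2L,
            all(background_score_shape > 0), cutoff >= 0, pseudocount >= 0)
  stopifnot(is.data.frame(planted))
  check_columns(planted, c("gene", "cancer_type", "fc_ratio", "direction",
                           "score1_setup", "n_golgi_neighbors"), "planted table")
  planted <- tibble::as_tibble(planted)
  planted$gene <- normalize_symbol(planted$gene)
  if (anyDuplicated(planted$gene)) rlang::abort("planted genes must be unique")
  if (!all(planted$fc_ratio >= 1)) rlang::abort("planted fc_ratio must be >= 1")
  if (!all(planted$direction %in% c("higher_in_organized", "higher_in_disorganized"))) {
    rlang::abort("planted direction must be higher_in_organized or higher_in_disorganized")
  }
  if (!all(planted$score1_setup %in% 0:2)) rlang::abort("score1_setup must be 0, 1 or 2")
  if (!all(planted$n_golgi_neighbors >= 0)) rlang::abort("n_golgi_neighbors must be >= 0")
  if (!all(planted$cancer_type %in% c("both", names(pairs)))) {
    rlang::abort("planted cancer_type must be 'both' or a pair name",
                 class = "golgiscreen_config_error")
  }
  if (nrow(planted) > n_universe) {
    rlang::abort("n_universe must accommodate all planted genes",
                 class = "golgiscreen_config_error")
  }
  min_thr <- min(vapply(pairs, function(p) p$base_threshold, numeric(1)))
  if (background_max_fc >= min_thr) {
    rlang::abort(sprintf(
      "background_max_fc (%.3g) must be below the smallest base threshold (%.3g) so background genes cannot pass the screen",
      background_max_fc, min_thr), class = "golgiscreen_config_error")
  }
  n_pool <- n_universe - nrow(planted)
  if (any(planted$n_golgi_neighbors > n_pool)) {
    rlang::abort(sprintf(
      "n_golgi_neighbors exceeds the %d non-planted universe members available", n_pool),
      class = "golgiscreen_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_universe = as.integer(n_universe), planted = planted,
         baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
         background_max_fc = background_max_fc,
         n_background_edges = as.integer(n_background_edges),
         background_score_shape = background_score_shape,
         pairs = pairs, cutoff = as.integer(cutoff), pseudocount = pseudocount),
    class = "synth_config"
  )
}

# Deterministic gene inventory: planted symbols first, then background G####.
synth_genes <- function(cfg) {
  n_bg <- cfg$n_genes - nrow(cfg$planted)
  if (n_bg < 0) rlang::abort("n_genes smaller than the planted table",
                             class = "golgiscreen_config_error")
  c(cfg$planted$gene, sprintf("G%04d", seq_len(n_bg)))
}

# Universe = planted genes plus the first background genes (deterministic, so
# ground truth is derivable from the config alone).
synth_universe_members <- function(cfg) {
  genes <- synth_genes(cfg)
  c(cfg$planted$gene, utils::head(setdiff(genes, cfg$planted$gene),
                                  cfg$n_universe - nrow(cfg$planted)))
}

cell_line_names <- function(cfg) {
  unique(unlist(lapply(cfg$pairs, function(p) c(p$organized_line, p$disorganized_line))))
}

planted_pairs <- function(cfg, row) {
  if (row$cancer_type == "both") cfg$pairs else cfg$pairs[row$cancer_type]
}

#' Simulate the gene-term annotation table
#'
#' Roughly the first 70% of the universe carries the `golgi organization`
#' term and the last 50% appears in the curated list, so the two sources
#' overlap but neither covers the universe alone. A handful of non-universe
#' genes are annotated with an unrelated term to exercise term filtering.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with columns `gene`, `term`.
#' @export
simulate_annotation <- function(cfg) {
  uni <- synth_universe_members(cfg)
  ann <- annotation_members(cfg)
  decoys <- utils::head(setdiff(synth_genes(cfg), uni), 10L)
  dplyr::bind_rows(
    tibble::tibble(gene = ann, term = "golgi organization"),
    tibble::tibble(gene = decoys, term = "mitosis")
  )
}

annotation_members <- function(cfg) {
  uni <- synth_universe_members(cfg)
  utils::head(uni, ceiling(0.7 * length(uni)))
}

curated_members <- function(cfg) {
  uni <- synth_universe_members(cfg)
  utils::tail(uni, ceiling(0.5 * length(uni)))
}

#' Simulate the expression matrix
#'
#' Background genes get a log-normal baseline shared across cell lines,
#' jittered per line by a factor bounded so that no background between-line
#' ratio can reach `background_max_fc`. Each planted gene's two target-line
#' values are set by multiplying its drawn baseline by `fc_ratio`, so the
#' realized symmetric ratio equals the configured one.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with a `gene` column and one RPKM column per cell line.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  genes <- synth_genes(cfg)
  n <- length(genes)
  lines <- cell_line_names(cfg)
  baseline <- stats::rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  half <- log(cfg$background_max_fc) / 2
  vals <- vapply(lines, function(l) baseline * exp(stats::runif(n, -half, half)),
                 numeric(n))
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, lines))
  for (i in seq_len(nrow(cfg$planted))) {
    row <- cfg$planted[i, ]
    gi <- match(row$gene, genes)
    for (p in planted_pairs(cfg, row)) {
      hi <- baseline[gi] * row$fc_ratio
      lo <- baseline[gi]
      if (row$direction == "higher_in_organized") {
        vals[gi, p$organized_line] <- hi
        vals[gi, p$disorganized_line] <- lo
      } else {
        vals[gi, p$organized_line] <- lo
        vals[gi, p$disorganized_line] <- hi
      }
    }
  }
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(vals))
}

#' Simulate the interaction edge list
#'
#' Each planted gene is wired to exactly its configured number of non-planted
#' universe members with experimental confidences drawn uniform on [0.4, 1],
#' so its Golgi-interactor count after filtering equals `n_golgi_neighbors`.
#' Background edges are drawn uniformly over remaining gene pairs with
#' Beta-distributed experimental confidences (mass mostly below 0.4);
#' background edges never join a planted gene to a universe member, keeping
#' the planted counts exact. Self-loops are never emitted.
#'
#' @param cfg A [synth_config()].
#' @return Edge tibble with columns `protein1`, `protein2`, `experimental`,
#'   `combined_score` (canonicalized via [as_interaction_network()]).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  genes <- synth_genes(cfg)
  uni <- synth_universe_members(cfg)
  planted <- cfg$planted$gene
  pool <- setdiff(uni, planted)

  planted_edges <- purrr::pmap_dfr(cfg$planted, function(gene, n_golgi_neighbors, ...) {
    k <- n_golgi_neighbors
    if (k == 0L) return(NULL)
    tibble::tibble(
      protein1 = gene,
      protein2 = sample(pool, k),
      experimental = stats::runif(k, 0.4, 1)
    )
  })

  n_bg <- cfg$n_background_edges
  if (n_bg > 0) {
    a <- sample(genes, n_bg, replace = TRUE)
    b <- sample(genes, n_bg, replace = TRUE)
    keep <- a != b &
      !((a %in% planted & b %in% uni) | (b %in% planted & a %in% uni))
    bg <- tibble::tibble(
      protein1 = a[keep], protein2 = b[keep],
      experimental = stats::rbeta(sum(keep), cfg$background_score_shape[1],
                                  cfg$background_score_shape[2])
    )
  } else {
    bg <- NULL
  }
  edges <- dplyr::bind_rows(planted_edges, bg)
  if (nrow(edges) == 0L) {
    return(tibble::tibble(protein1 = character(), protein2 = character(),
                          experimental = numeric(), combined_score = numeric()))
  }
  edges$combined_score <- pmin(1, edges$experimental + stats::runif(nrow(edges), 0, 0.2))
  as_interaction_network(edges)
}

#' Simulate the curated knockdown-evidence table
#'
#' Planted genes receive records that realize their requested literature
#' score under their planted expression direction: score 2 gets the phenotype
#' a concordant knockdown would show (the low-expression line's phenotype),
#' score 1 gets the opposite phenotype with Golgi involvement, and score 0
#' gets `none_reported`. Background universe genes all get `none_reported`.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with columns `gene`, `knockdown_phenotype`,
#'   `golgi_involvement`, `citation`.
#' @export
simulate_evidence <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  planted <- cfg$planted |>
    dplyr::mutate(
      predicted = predicted_low_expression_phenotype(.data$direction),
      knockdown_phenotype = dplyr::case_when(
        .data$score1_setup == 2L ~ .data$predicted,
        .data$score1_setup == 1L ~ ifelse(.data$predicted == "disorganized",
                                          "organized_or_condensed", "disorganized"),
        TRUE ~ "none_reported"
      ),
      golgi_involvement = .data$score1_setup > 0L
    ) |>
    dplyr::select("gene", "knockdown_phenotype", "golgi_involvement")
  background <- tibble::tibble(
    gene = setdiff(synth_universe_members(cfg), cfg$planted$gene),
    knockdown_phenotype = "none_reported",
    golgi_involvement = FALSE
  )
  dplyr::bind_rows(planted, background) |>
    dplyr::mutate(citation = "synthetic")
}

#' Ground truth implied by a synthetic configuration
#'
#' Derives, from the configuration alone (before any pipeline run), the genes
#' expected to pass each pair's screen (applying the same adaptive-cap rule,
#' with ties at the boundary broken by nominal ratio then symbol), their
#' expected score components, the expected selected set per pair, and the
#' expected cross-cancer intersection. Valid because background genes cannot
#' pass the screen by construction.
#'
#' @param cfg A [synth_config()].
#' @return List with `expected_degs`, `expected_selected` (named lists of
#'   character vectors per pair), `expected_scores` (tibble `gene`, `score1`,
#'   `score2`), and `common` (character vector).
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  per_pair <- purrr::imap(cfg$pairs, function(p, nm) {
    applicable <- dplyr::filter(cfg$planted, .data$cancer_type %in% c("both", nm))
    passing <- applicable |>
      dplyr::filter(.data$fc_ratio >= p$base_threshold) |>
      dplyr::arrange(dplyr::desc(.data$fc_ratio), .data$gene) |>
      utils::head(p$cap)
    selected <- passing |>
      dplyr::filter(.data$score1_setup + .data$n_golgi_neighbors >= cfg$cutoff)
    list(degs = passing$gene, selected = selected$gene)
  })
  selected_sets <- purrr::map(per_pair, "selected")
  list(
    expected_degs = purrr::map(per_pair, "degs"),
    expected_selected = selected_sets,
    expected_scores = tibble::tibble(
      gene = cfg$planted$gene,
      score1 = cfg$planted$score1_setup,
      score2 = cfg$planted$n_golgi_neighbors
    ),
    common = sort(purrr::reduce(selected_sets, intersect))
  )
}

#' Write a complete synthetic input bundle
#'
#' Generates all five input files, the ground-truth JSON, and a ready-to-run
#' pipeline configuration YAML in `dir`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths` (named file paths), `config`
#'   (the pipeline configuration list, see [run_golgi_screen()]), and `truth`
#'   (the [ground_truth()] list).
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    annotation = file.path(dir, "annotation.tsv"),
    curated = file.path(dir, "curated_regulators.txt"),
    expression = file.path(dir, "expression.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    evidence = file.path(dir, "evidence.csv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.yaml")
  )
  readr::write_tsv(simulate_annotation(cfg), paths$annotation)
  writeLines(c("# synthetic curated regulator list", curated_members(cfg)), paths$curated)
  write_expression(simulate_expression(cfg), paths$expression)
  write_interactions(simulate_network(cfg), paths$interactions)
  readr::write_csv(simulate_evidence(cfg), paths$evidence)
  truth <- ground_truth(cfg)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = FALSE, digits = NA, pretty = TRUE)

  config <- list(
    inputs = list(annotation = paths$annotation, curated = paths$curated,
                  expression = paths$expression, interactions = paths$interactions,
                  evidence = paths$evidence),
    terms = list("golgi organization"),
    pairs = purrr::map(cfg$pairs, function(p) {
      list(organized_line = p$organized_line, disorganized_line = p$disorganized_line,
           base_threshold = p$base_threshold, cap = p$cap)
    }),
    network = list(channel = "experimental", min_conf = 0.4),
    cutoff = cfg$cutoff,
    pseudocount = cfg$pseudocount
  )
  yaml::write_yaml(config, paths$config)
  invisible(list(dir = dir, paths = paths, config = config, truth = truth))
}
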
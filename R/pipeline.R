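#' Run the full candidate-regulator screen
#'
#' Orchestrates the whole pipeline for every configured cancer-type pair:
#' universe assembly (annotation terms union curated list), fold-change
#' screening with the adaptive cap, literature and interactor scoring,
#' combined-score selection, and cross-cancer intersection. All analysis
#' stages are deterministic; randomness lives only in the synthetic
#' generators.
#'
#' @param config Path to a YAML configuration file or an equivalent list with
#'   elements `inputs` (paths `annotation`, `curated`, `expression`,
#'   `interactions`, `evidence`), `terms` (annotation query terms), `pairs`
#'   (named list of `organized_line`, `disorganized_line`, `base_threshold`,
#'   `cap`), `network` (`channel`, `min_conf`), `cutoff`, `pseudocount`.
#'   [simulate_bundle()] writes a ready-made one.
#' @param out_dir Optional output directory; when given, `candidates.tsv` and
#'   `report.json` are written there.
#' @param quiet Suppress stage-by-stage count messages.
#' @return A `golgi_report`: list with `universe`, `degs` and `candidates`
#'   (named per cancer type), `common_genes`, and `parameters` (the full
#'   configuration echo). Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' bundle <- simulate_bundle(synth_config(seed = 1), tempfile("bundle"))
#' report <- run_golgi_screen(bundle$config, quiet = TRUE)
#' glance(report)
#' @export
run_golgi_screen <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("inputs", "pairs")) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("configuration is missing '%s'", key),
                   class = "golgiscreen_config_error")
    }
  }
  for (f in c("annotation", "curated", "expression", "interactions", "evidence")) {
    path <- config$inputs[[f]]
    if (is.null(path) || !file.exists(path)) {
      rlang::abort(sprintf("input file '%s' missing or not found: %s", f, path %||% "<unset>"),
                   class = "golgiscreen_config_error")
    }
  }
  terms <- unlist(config$terms %||% "golgi organization")
  channel <- config$network$channel %||% "experimental"
  min_conf <- config$network$min_conf %||% 0.4
  cutoff <- config$cutoff %||% 3L
  pseudocount <- config$pseudocount %||% 0.01

  say <- function(...) if (!quiet) message(sprintf(...))

  annotation <- read_annotation(config$inputs$annotation)
  curated <- read_gene_list(config$inputs$curated)
  ann_genes <- if (nrow(annotation)) select_by_terms(annotation, terms) else character()
  universe <- build_universe(ann_genes, curated)
  if (nrow(universe) == 0L) rlang::warn("gene universe is empty; report will be empty")
  say("universe: %d genes (%d annotation, %d curated, %d both)",
      nrow(universe), sum(universe$source == "annotation"),
      sum(universe$source == "curated"), sum(universe$source == "both"))

  expr <- read_expression(config$inputs$expression)
  net <- filter_edges(read_interactions(config$inputs$interactions),
                      channel = channel, min_conf = min_conf)
  evidence <- read_evidence(config$inputs$evidence)
  say("network: %d edges at %s >= %.2f", nrow(net), channel, min_conf)

  degs_by_type <- list()
  cand_by_type <- list()
  for (nm in names(config$pairs)) {
    pc <- config$pairs[[nm]]
    pair <- cell_line_pair(nm, pc$organized_line, pc$disorganized_line,
                           base_threshold = pc$base_threshold,
                           cap = pc$cap %||% 50L)
    degs <- screen_degs(expr, universe, pair, pseudocount = pseudocount)
    passed <- dplyr::filter(tidy(degs), .data$passed)
    s1 <- literature_score(evidence, passed)
    s2 <- count_golgi_interactors(net, passed$gene, universe)
    cand <- combine_and_select(degs, s1, s2, cutoff = cutoff)
    say("%s: %d candidates screened, %d DEGs, %d selected (combined >= %d)",
        nm, nrow(degs), nrow(passed), nrow(cand), cutoff)
    degs_by_type[[nm]] <- degs
    cand_by_type[[nm]] <- cand
  }

  common <- if (length(cand_by_type) >= 2L) {
    sort(purrr::reduce(purrr::map(cand_by_type, "gene"), intersect))
  } else if (length(cand_by_type) == 1L) {
    sort(cand_by_type[[1]]$gene)
  } else character()
  say("common to all cancer types: %d gene(s)", length(common))

  cand_by_type <- purrr::map(cand_by_type, function(cand) {
    cand$common_to_both <- cand$gene %in% common
    cand
  })

  report <- structure(
    list(universe = universe, degs = degs_by_type, candidates = cand_by_type,
         common_genes = common,
         parameters = list(
           inputs = config$inputs, terms = as.list(terms),
           pairs = config$pairs, network = list(channel = channel, min_conf = min_conf),
           cutoff = cutoff, pseudocount = pseudocount
         )),
    class = "golgi_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_table(report, file.path(out_dir, "candidates.tsv"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @method tidy golgi_report
#' @export
tidy.golgi_report <- function(x, ...) {
  purrr::imap_dfr(x$candidates, function(cand, nm) {
    dplyr::mutate(tidy(cand), cancer_type = nm, .before = 1)
  })
}

#' @method glance golgi_report
#' @export
glance.golgi_report <- function(x, ...) {
  tibble::tibble(
    n_universe = nrow(x$universe),
    n_cancer_types = length(x$candidates),
    n_degs_total = sum(purrr::map_int(x$degs, ~ sum(.x$passed))),
    n_candidates_total = sum(purrr::map_int(x$candidates, nrow)),
    n_common = length(x$common_genes)
  )
}

#' @export
print.golgi_report <- function(x, ...) {
  cat(sprintf("<golgi_report> %d-gene universe, %d cancer type(s)\n",
              nrow(x$universe), length(x$candidates)))
  for (nm in names(x$candidates)) {
    cat(sprintf("  %s: %d DEGs, %d selected\n", nm,
                sum(x$degs[[nm]]$passed), nrow(x$candidates[[nm]])))
  }
  cat(sprintf("  common genes: %s\n",
              if (length(x$common_genes)) paste(x$common_genes, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Score-component overview of a screen report
#'
#' @param object A `golgi_report` from [run_golgi_screen()].
#' @param ... Unused.
#' @return A ggplot faceted by cancer type: interactor count vs literature
#'   score, point size by fold change, shared candidates highlighted.
#' @method autoplot golgi_report
#' @export
autoplot.golgi_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score2, y = .data$score1,
                                   size = .data$fc, colour = .data$common_to_both,
                                   label = .data$gene)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(size = 3, vjust = -1, show.legend = FALSE) +
    ggplot2::facet_wrap(~cancer_type) +
    ggplot2::labs(x = "Golgi-associated interactors (score 2)",
                  y = "knockdown concordance (score 1)",
                  colour = "shared", size = "fold change") +
    ggplot2::theme_minimal()
}

#' Write the candidate table
#'
#' Writes the ranked candidates of every cancer type as TSV with columns
#' `cancer_type`, `rank`, `gene`, `fc`, `direction`, `score1`, `score2`,
#' `combined`, `common_to_both`, preceded by a `# parameters:` provenance
#' line carrying the full configuration as compact JSON.
#'
#' @param report A `golgi_report`.
#' @param path Output path.
#' @export
write_candidate_table <- function(report, path) {
  stopifnot(inherits(report, "golgi_report"))
  df <- tidy(report)
  cols <- c("cancer_type", "rank", "gene", "fc", "direction",
            "score1", "score2", "combined", "common_to_both")
  df <- if (nrow(df)) df[cols] else
    tibble::as_tibble(stats::setNames(rep(list(logical()), length(cols)), cols))
  header <- paste0("# parameters: ",
                   jsonlite::toJSON(report$parameters, auto_unbox = TRUE, digits = NA))
  body <- readr::format_tsv(df)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Write the JSON report
#'
#' Emits stage counts, per-type candidate tables, the cross-cancer
#' intersection, and a complete echo of every parameter that influenced the
#' result, so a run can be reproduced from its own report.
#'
#' @param report A `golgi_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "golgi_report"))
  out <- list(
    parameters = report$parameters,
    universe_size = nrow(report$universe),
    cancer_types = purrr::imap(report$candidates, function(cand, nm) {
      list(
        n_screened = nrow(report$degs[[nm]]),
        n_degs = sum(report$degs[[nm]]$passed),
        effective_threshold = attr(report$degs[[nm]], "effective_threshold"),
        n_selected = nrow(cand),
        candidates = tidy(cand)
      )
    }),
    common_genes = as.list(report$common_genes)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
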
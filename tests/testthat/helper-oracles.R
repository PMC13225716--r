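# Independent brute-force oracles, written as plain base-R loops so they share
# no code path with the package implementation.

oracle_fc <- function(a, b, pseudocount = 0.01) {
  mn <- min(a, b)
  mx <- max(a, b)
  if (mn > 0) mx / mn else (mx + pseudocount) / pseudocount
}

# Exhaustive screen: returns the passed gene symbols (any order).
oracle_screen <- function(expr, universe, organized, disorganized,
                          threshold, cap, pseudocount = 0.01) {
  genes <- character()
  fcs <- numeric()
  for (i in seq_len(nrow(expr))) {
    g <- toupper(trimws(expr$gene[i]))
    if (!(g %in% universe)) next
    genes <- c(genes, g)
    fcs <- c(fcs, oracle_fc(expr[[organized]][i], expr[[disorganized]][i], pseudocount))
  }
  pass <- fcs >= threshold * (1 - 1e-9)
  genes <- genes[pass]
  fcs <- fcs[pass]
  ord <- order(-fcs, genes)
  utils::head(genes[ord], cap)
}

# Exhaustive neighbor enumeration for one gene on a raw (deduplicated) edge
# table with confidences already on the [0, 1] scale.
oracle_golgi_count <- function(edges, gene, universe,
                               channel = "experimental", min_conf = 0.4) {
  nb <- character()
  for (i in seq_len(nrow(edges))) {
    s <- edges[[channel]][i]
    if (is.na(s) || s < min_conf) next
    a <- edges$protein1[i]
    b <- edges$protein2[i]
    if (a == b) next
    if (a == gene) nb <- c(nb, b)
    if (b == gene) nb <- c(nb, a)
  }
  length(unique(intersect(nb, setdiff(universe, gene))))
}

# Hand-written rubric truth table over the full input grid:
# knockdown phenotype x golgi involvement x expression direction.
oracle_rubric <- function(knockdown_phenotype, golgi_involvement, direction) {
  predicted <- if (direction == "higher_in_organized") "disorganized" else "organized_or_condensed"
  if (knockdown_phenotype == "none_reported") return(0L)
  if (knockdown_phenotype == predicted) return(2L)
  1L
}

# Exhaustive combined-score selection; returns genes in rank order.
oracle_select <- function(genes, fc, score1, score2, cutoff) {
  combined <- score1 + score2
  keep <- combined >= cutoff
  genes <- genes[keep]
  ord <- order(-combined[keep], -fc[keep], genes)
  genes[ord]
}

# Random small fixtures -------------------------------------------------------

random_expression <- function(n_genes, lines = c("L1", "L2", "L3", "L4")) {
  tibble::tibble(
    gene = sprintf("R%03d", seq_len(n_genes)),
    !!!stats::setNames(
      lapply(lines, function(l) round(stats::rlnorm(n_genes, 1, 1.2), 4)),
      lines
    )
  )
}

random_edges <- function(n_nodes, n_edges) {
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  tibble::tibble(
    protein1 = sample(nodes, n_edges, replace = TRUE),
    protein2 = sample(nodes, n_edges, replace = TRUE),
    experimental = round(stats::runif(n_edges), 3),
    combined_score = round(stats::runif(n_edges), 3)
  )
}
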
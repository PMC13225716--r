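`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

test_that("network construction canonicalizes pairs, max-merges duplicates, drops self-loops", {
  net <- as_interaction_network(tibble::tibble(
    protein1 = c("a", "B", "C", "D"),
    protein2 = c("B", "A", "C", "E"),
    experimental = c(0.5, 0.7, 0.9, 0.2)
  ))
  expect_equal(nrow(net), 2L)  # self-loop dropped, (A,B)/(B,A) merged
  expect_equal(net$experimental[net$protein1 == "A" & net$protein2 == "B"], 0.7)
  expect_true(all(net$protein1 < net$protein2))
})

test_that("STRING-style 0-1000 scores are auto-rescaled to [0,1]", {
  net <- as_interaction_network(tibble::tibble(
    protein1 = c("A", "B"), protein2 = c("B", "C"),
    experimental = c(400, 950)
  ))
  expect_equal(sort(net$experimental), c(0.4, 0.95))
  expect_error(
    as_interaction_network(tibble::tibble(protein1 = "A", protein2 = "B", experimental = -5)),
    class = "golgiscreen_parse_error"
  )
})

test_that("confidence filtering keeps >= min_conf and drops edges lacking the channel", {
  net <- as_interaction_network(tibble::tibble(
    protein1 = c("A", "A", "A", "A"), protein2 = c("B", "C", "D", "E"),
    experimental = c(0.39, 0.40, 0.41, NA)
  ))
  kept <- filter_edges(net, "experimental", 0.4)
  expect_setequal(kept$protein2, c("C", "D"))
  expect_warning(empty <- filter_edges(net, "textmining", 0.4), "textmining")
  expect_equal(nrow(empty), 0L)
  # idempotence
  expect_equal(filter_edges(kept, "experimental", 0.4), kept)
})

test_that("Golgi-interactor counting is over distinct in-universe neighbors, self excluded", {
  net <- as_interaction_network(tibble::tibble(
    protein1 = c("A", "A", "A", "A"),
    protein2 = c("B", "C", "D", "A"),
    experimental = rep(0.9, 4)
  ))
  sc <- count_golgi_interactors(net, c("A", "ZZ"), c("A", "B", "C"))
  expect_equal(sc$n_golgi_interactors, c(2L, 0L))  # B, C in universe; D not; self and absent gene excluded
  expect_equal(sc$score2, sc$n_golgi_interactors)
})

test_that("interactor counts match exhaustive enumeration and igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (i in 1:15) {
    raw <- random_edges(n_nodes = sample(10:100, 1), n_edges = sample(20:200, 1))
    net <- as_interaction_network(raw)
    universe <- sample(unique(c(net$protein1, net$protein2)), 10)
    genes <- sample(unique(c(net$protein1, net$protein2)), 8)
    got <- count_golgi_interactors(filter_edges(net, "experimental", 0.4), genes, universe)
    for (j in seq_along(genes)) {
      expect_equal(got$n_golgi_interactors[j],
                   oracle_golgi_count(net, genes[j], universe))
    }
    # cross-check with igraph neighborhoods on the filtered graph
    kept <- filter_edges(net, "experimental", 0.4)
    if (nrow(kept) > 0) {
      g <- igraph::graph_from_data_frame(kept[c("protein1", "protein2")], directed = FALSE)
      for (j in seq_along(genes)) {
        ig_count <- if (genes[j] %in% igraph::V(g)$name) {
          length(intersect(igraph::neighbors(g, genes[j])$name, setdiff(universe, genes[j])))
        } else 0L
        expect_equal(got$n_golgi_interactors[j], ig_count)
      }
    }
  }
})

test_that("interactor count never exceeds degree and is monotone in the cutoff", {
  set.seed(303)
  net <- as_interaction_network(random_edges(40, 150))
  genes <- unique(c(net$protein1, net$protein2))
  universe <- genes  # everything Golgi-associated: count equals in-universe degree
  prev <- NULL
  for (conf in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
    kept <- filter_edges(net, "experimental", conf)
    sc <- count_golgi_interactors(kept, genes, universe)
    deg <- table(c(kept$protein1, kept$protein2))
    expect_true(all(sc$n_golgi_interactors <= as.integer(deg[sc$gene] %|NA|% 0L)))
    if (!is.null(prev)) expect_true(all(sc$n_golgi_interactors <= prev))
    prev <- sc$n_golgi_interactors
  }
})
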
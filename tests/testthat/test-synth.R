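test_that("all three generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 5, n_genes = 100, n_universe = 30, n_background_edges = 200)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_network(cfg), simulate_network(cfg))
  expect_identical(simulate_evidence(cfg), simulate_evidence(cfg))
  # and a different seed changes the draw
  cfg2 <- synth_config(seed = 6, n_genes = 100, n_universe = 30, n_background_edges = 200)
  expect_false(identical(simulate_expression(cfg), simulate_expression(cfg2)))
})

test_that("planted fold-change ratios are realized exactly in the matrix", {
  cfg <- synth_config(seed = 2)
  expr <- simulate_expression(cfg)
  expect_equal(nrow(expr), 500L)
  expect_true(all(as.matrix(expr[-1]) > 0))
  for (i in seq_len(nrow(cfg$planted))) {
    row <- cfg$planted[i, ]
    for (p in default_pairs()) {
      vals <- expr[expr$gene == row$gene, c(p$organized_line, p$disorganized_line)]
      got <- fold_change(vals[[1]], vals[[2]])
      expect_equal(got$fc, row$fc_ratio, tolerance = 1e-12)
      expect_equal(got$direction,
                   sub("higher_in_organized", "higher_in_first",
                       sub("higher_in_disorganized", "higher_in_second", row$direction)))
    }
  }
})

test_that("background genes never reach the screening thresholds", {
  cfg <- synth_config(seed = 3)
  expr <- simulate_expression(cfg)
  bg <- expr[!expr$gene %in% cfg$planted$gene, ]
  for (p in default_pairs()) {
    fc <- fold_change(bg[[p$organized_line]], bg[[p$disorganized_line]])$fc
    expect_true(all(fc < cfg$background_max_fc))
    expect_true(all(fc < p$base_threshold))
  }
})

test_that("the network wires each planted gene to exactly its configured Golgi neighbors", {
  cfg <- synth_config(seed = 4)
  bundle <- simulate_bundle(cfg, withr::local_tempdir())
  uni <- build_universe(
    select_by_terms(read_annotation(bundle$paths$annotation), "golgi organization"),
    read_gene_list(bundle$paths$curated)
  )
  net <- filter_edges(read_interactions(bundle$paths$interactions), "experimental", 0.4)
  counts <- count_golgi_interactors(net, cfg$planted$gene, uni)
  expect_equal(counts$n_golgi_interactors, cfg$planted$n_golgi_neighbors)
  # no self-loops anywhere
  full <- simulate_network(cfg)
  expect_true(all(full$protein1 != full$protein2))
})

test_that("a zero-density network contains only the planted edges", {
  cfg <- synth_config(seed = 1, n_background_edges = 0)
  net <- simulate_network(cfg)
  expect_equal(nrow(net), sum(cfg$planted$n_golgi_neighbors))
  expect_true(all(net$experimental >= 0.4))
  expect_setequal(intersect(unique(c(net$protein1, net$protein2)), cfg$planted$gene),
                  cfg$planted$gene[cfg$planted$n_golgi_neighbors > 0])
})

test_that("generated evidence round-trips through the scoring rubric", {
  cfg <- synth_config(seed = 8)
  ev <- simulate_evidence(cfg)
  directions <- tibble::tibble(gene = cfg$planted$gene, direction = cfg$planted$direction)
  got <- literature_score(ev, directions)
  expect_equal(got$score1, cfg$planted$score1_setup)
  # background universe genes carry no knockdown data
  bg <- ev[!ev$gene %in% cfg$planted$gene, ]
  expect_true(all(bg$knockdown_phenotype == "none_reported"))
})

test_that("invalid configurations are rejected with construction errors", {
  # background spread reaching the smallest threshold would let decoys pass
  expect_error(synth_config(background_max_fc = 5), class = "golgiscreen_config_error")
  expect_error(synth_config(background_max_fc = 7), class = "golgiscreen_config_error")
  # more Golgi neighbors than non-planted universe members exist
  planted <- default_planted()
  planted$n_golgi_neighbors[1] <- 100L
  expect_error(synth_config(planted = planted, n_universe = 20),
               class = "golgiscreen_config_error")
  # unknown cancer type
  planted <- default_planted()
  planted$cancer_type[1] <- "kidney"
  expect_error(synth_config(planted = planted), class = "golgiscreen_config_error")
})

test_that("ground truth applies the adaptive cap to planted genes", {
  planted <- tibble::tibble(
    gene = sprintf("PL%02d", 1:10),
    cancer_type = "lung",
    fc_ratio = seq(6, 24, by = 2),
    direction = "higher_in_organized",
    score1_setup = 2L,
    n_golgi_neighbors = 2L
  )
  pairs <- default_pairs()
  pairs$lung$cap <- 4L
  cfg <- synth_config(planted = planted, pairs = pairs, n_universe = 30)
  truth <- ground_truth(cfg)
  expect_equal(truth$expected_degs$lung, sprintf("PL%02d", 10:7))
  expect_equal(truth$expected_selected$lung, sprintf("PL%02d", 10:7))
  expect_equal(truth$expected_degs$breast, character())
})
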
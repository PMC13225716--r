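toy_pair <- function(threshold = 5, cap = 50L) {
  cell_line_pair("toy", "ORG", "DIS", base_threshold = threshold, cap = cap)
}

test_that("fold change is the symmetric ratio with the pseudocount only at zero", {
  expect_equal(fold_change(30, 3)$fc, 10)
  expect_equal(fold_change(30, 3)$direction, "higher_in_first")
  expect_equal(fold_change(7, 7), tibble::tibble(fc = 1, direction = "equal"))
  # (5 + 0.01) / 0.01 when the minimum is zero
  expect_equal(fold_change(5, 0, pseudocount = 0.01)$fc, 501)
  expect_equal(fold_change(0, 5, pseudocount = 0.01)$direction, "higher_in_second")
  expect_equal(fold_change(0, 0, pseudocount = 0.01)$direction, "equal")
  expect_error(fold_change(0, 0, pseudocount = 0), class = "golgiscreen_undefined_ratio")
  expect_error(fold_change(-1, 2))
})

test_that("fold change is symmetric up to a direction flip", {
  set.seed(7)
  a <- round(stats::rlnorm(50, 1, 1.5), 3)
  b <- round(stats::rlnorm(50, 1, 1.5), 3)
  fwd <- fold_change(a, b)
  rev <- fold_change(b, a)
  expect_equal(fwd$fc, rev$fc)
  flip <- c(higher_in_first = "higher_in_second",
            higher_in_second = "higher_in_first", equal = "equal")
  expect_equal(unname(flip[fwd$direction]), rev$direction)
})

test_that("base-threshold screening keeps exactly the genes at or above it", {
  expr <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E", "F"),
    ORG = c(12, 8, 5, 4.9, 2, 1),
    DIS = rep(1, 6)
  )
  degs <- screen_degs(expr, expr$gene, toy_pair(threshold = 5))
  expect_equal(degs$gene[degs$passed], c("A", "B", "C"))
  expect_equal(attr(degs, "effective_threshold"), 5)
  expect_equal(degs$gene, c("A", "B", "C", "D", "E", "F"))  # fc descending
  expect_true(all(degs$direction[1:5] == "higher_in_organized"))
  expect_equal(degs$direction[6], "equal")
})

test_that("the adaptive cap raises the effective threshold to the top cap genes", {
  set.seed(11)
  n <- 120
  expr <- tibble::tibble(
    gene = sprintf("P%03d", 1:n),
    ORG = 5 + stats::runif(n, 0.01, 40),
    DIS = rep(1, n)
  )
  degs <- screen_degs(expr, expr$gene, toy_pair(threshold = 5, cap = 50L))
  expect_equal(sum(degs$passed), 50L)
  expect_true(attr(degs, "effective_threshold") >= 5)
  expect_true(all(degs$fc[degs$passed] >= attr(degs, "effective_threshold")))
  # the retained genes are exactly the 50 largest fold changes
  expect_equal(sort(degs$gene[degs$passed]),
               sort(expr$gene[order(-expr$ORG)][1:50]))
})

test_that("cap-boundary ties break by ascending symbol, deterministically", {
  expr <- tibble::tibble(
    gene = c("ZZZ", "AAA", "MMM", "BBB"),
    ORG = c(10, 10, 20, 10),
    DIS = rep(1, 4)
  )
  degs <- screen_degs(expr, expr$gene, toy_pair(threshold = 5, cap = 2L))
  expect_equal(degs$gene[degs$passed], c("MMM", "AAA"))
  rerun <- screen_degs(expr[sample(4), ], expr$gene, toy_pair(threshold = 5, cap = 2L))
  expect_equal(tidy(degs), tidy(rerun))  # invariant to input row order
})

test_that("screening handles missing lines, empty universes, and threshold monotonicity", {
  expr <- tibble::tibble(gene = c("A", "B"), ORG = c(30, 2), DIS = c(2, 2))
  expect_error(
    screen_degs(expr, "A", cell_line_pair("x", "ORG", "GONE", 5)),
    class = "golgiscreen_config_error"
  )
  expect_equal(nrow(screen_degs(expr, c("X", "Y"), toy_pair())), 0L)

  set.seed(3)
  expr <- random_expression(30)
  for (i in 1:10) {
    t1 <- stats::runif(1, 1, 5)
    t2 <- t1 + stats::runif(1, 0, 5)
    p1 <- screen_degs(expr, expr$gene, cell_line_pair("x", "L1", "L2", t1))
    p2 <- screen_degs(expr, expr$gene, cell_line_pair("x", "L1", "L2", t2))
    expect_true(all(p2$gene[p2$passed] %in% p1$gene[p1$passed]))
  }
})

test_that("screen matches the exhaustive oracle on random matrices", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    expr <- random_expression(n)
    universe <- sample(expr$gene, sample(seq_len(n), 1))
    threshold <- sample(c(1.5, 2, 5, 10), 1)
    cap <- sample(2:20, 1)
    pair <- cell_line_pair("x", "L1", "L2", threshold, cap)
    got <- screen_degs(expr, universe, pair)
    want <- oracle_screen(expr, universe, "L1", "L2", threshold, cap)
    expect_setequal(got$gene[got$passed], want)
  }
})
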
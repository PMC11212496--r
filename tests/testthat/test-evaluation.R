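test_that("ARI is 1 for identical partitions and 0 against all-singletons", {
  p <- c(a = 0, b = 0, c = 1, d = 1, e = 2)
  expect_equal(adjusted_rand_index(p, p), 1.0)
  relabelled <- c(a = "x", b = "x", c = "y", d = "y", e = "z")
  expect_equal(adjusted_rand_index(p, relabelled), 1.0)
  singles <- stats::setNames(seq_along(p), names(p))
  expect_equal(adjusted_rand_index(p, singles), 0.0)
})

test_that("ARI reproduces the hand-evaluated contingency-table value", {
  p <- c(e1 = 0, e2 = 0, e3 = 0, e4 = 1, e5 = 1, e6 = 1)
  r <- c(e1 = "A", e2 = "A", e3 = "B", e4 = "B", e5 = "C", e6 = "C")
  # n_ij rows {2,1,0},{0,1,2}: sum C(nij,2)=2, sum C(ai,2)=6, sum C(bj,2)=3,
  # E = 6*3/15 = 1.2 -> (2-1.2)/(4.5-1.2) = 8/33
  expect_equal(adjusted_rand_index(p, r), 8 / 33)
  expect_equal(adjusted_rand_index(p, r),
               mclust::adjustedRandIndex(unname(p), unname(r)))
})

test_that("ARI is symmetric, relabel-invariant, and matches mclust on random cases", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:40, 1)
    ids <- make_chain_ids(n)
    p <- stats::setNames(sample.int(4, n, replace = TRUE), ids)
    r <- stats::setNames(sample(c("u", "v", "w"), n, replace = TRUE), ids)
    a1 <- adjusted_rand_index(p, r)
    expect_equal(a1, adjusted_rand_index(r, p))
    p_relab <- stats::setNames(letters[p], ids)
    expect_equal(adjusted_rand_index(p_relab, r), a1)
    expect_equal(a1, mclust::adjustedRandIndex(unname(p[ids]), unname(r[ids])),
                 tolerance = 1e-12)
  }
})

test_that("ARI restricts to the shared chains and rejects degenerate overlap", {
  p <- c(a = 0, b = 0, c = 1, d = 1)
  r <- c(b = "x", c = "y", d = "y", zz = "q")
  expect_message(ari <- adjusted_rand_index(p, r), "omitted")
  expect_equal(ari, mclust::adjustedRandIndex(c(0, 1, 1), c("x", "y", "y")))
  expect_error(adjusted_rand_index(c(a = 1), c(a = 1, b = 2)),
               class = "cm_degenerate_error")
  expect_error(adjusted_rand_index(c(a = 1, b = 1), c(x = 1, y = 1)),
               class = "cm_degenerate_error")
})

test_that("module report conserves weight and flags disconnected modules", {
  # two disconnected cliques clustered as themselves
  pg <- generate_planted_graph(2, 3, w_in = 4, w_out = 1, p_out = 0, seed = 1)
  rep0 <- module_report(pg$graph, pg$truth)
  expect_equal(nrow(rep0$pairs), 0)
  expect_equal(rep0$intra_fraction, 1.0)
  expect_equal(sum(rep0$modules$intra_weight), total_weight(pg$graph))
  # single module over the whole graph
  whole <- stats::setNames(rep(0, length(pg$graph$vertices)),
                           pg$graph$vertices)
  rep1 <- module_report(pg$graph, whole)
  expect_equal(rep1$intra_fraction, 1.0)
  expect_equal(nrow(rep1$modules), 1)
})

test_that("planted cross-module weight shows up as the inter-module weight", {
  # barbell: bridge c-d carries weight 1 between the two cliques
  g <- barbell_graph()
  p <- c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1)
  rep <- module_report(g, p)
  expect_equal(rep$pairs$inter_weight, 1)
  expect_equal(rep$modules$intra_weight, c(3, 3))
  expect_equal(rep$modules$size, c(3, 3))
  expect_equal(rep$intra_fraction, 6 / 7)
  expect_equal(sum(rep$modules$intra_weight) + sum(rep$pairs$inter_weight),
               total_weight(g))
})

test_that("weight conservation holds for arbitrary graph/partition pairs", {
  for (seed in 1:10) {
    g <- random_small_graph(seed + 60)
    p <- random_partition(g, seed + 600, k = 3)
    rep <- module_report(g, p)
    expect_equal(sum(rep$modules$intra_weight) + sum(rep$pairs$inter_weight),
                 total_weight(g))
    expect_equal(sum(rep$modules$size), length(g$vertices))
  }
})

test_that("reference assignments round-trip through TSV", {
  r <- c(A = "N", B = "Q", C = "PP", D = "PD")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chain_id\tmodule_name",
               sprintf("%s\t%s", names(r), r)), f)
  expect_equal(read_reference(f), r)
  writeLines(c("chain_id\tmodule_name", "A\tN", "A\tQ"), f)
  expect_error(read_reference(f), class = "cm_input_error")
})

test_that("module report files contain both TSV blocks", {
  g <- barbell_graph()
  p <- c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1)
  f <- tempfile(fileext = ".tsv")
  write_module_report(module_report(g, p), f)
  lines <- readLines(f)
  expect_true(any(grepl("^# modules", lines)))
  expect_true(any(grepl("^# interfaces", lines)))
  expect_true(any(grepl("intra_fraction=0.857143", lines)))
})
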
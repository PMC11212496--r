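test_that("graph construction maps contact matrices faithfully", {
  m <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  g0 <- build_complex_graph(m)
  expect_equal(length(g0$vertices), 3)
  expect_equal(nrow(g0$edges), 0)
  m["A", "B"] <- m["B", "A"] <- 7L
  g1 <- build_complex_graph(m)
  expect_equal(nrow(g1$edges), 1)
  expect_equal(g1$edges$weight, 7L)
  expect_equal(g1$edges$from, "A")
  expect_equal(g1$edges$to, "B")
  # C stays as an isolated vertex
  expect_true("C" %in% g1$vertices)
})

test_that("graph invariants are enforced", {
  expect_error(complex_graph(c("A", "A")), class = "cm_input_error")
  expect_error(complex_graph(c("A", "B"),
                             data.frame(from = "A", to = "A", weight = 1)),
               class = "cm_input_error")
  expect_error(complex_graph(c("A", "B"),
                             data.frame(from = "A", to = "B", weight = 0)),
               class = "cm_input_error")
  expect_error(complex_graph(c("A", "B"),
                             data.frame(from = c("A", "B"), to = c("B", "A"),
                                        weight = c(1, 2))),
               class = "cm_input_error")
})

test_that("GML round-trip is the identity on the graph data model", {
  for (seed in c(2, 17, 31)) {
    g <- random_small_graph(seed)
    f <- tempfile(fileext = ".gml")
    write_gml(g, f)
    expect_identical(read_gml(f), g)
  }
  # graph with an isolated vertex survives too
  g <- complex_graph(c("A", "B", "C"),
                     data.frame(from = "A", to = "B", weight = 3))
  f <- tempfile(fileext = ".gml")
  write_gml(g, f)
  expect_identical(read_gml(f), g)
})

test_that("the documented GML dialect parses as written", {
  f <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    '  node [ id 0 label "A" ]',
    '  node [ id 1 label "B" ]',
    "  edge [ source 0 target 1 weight 42 ]",
    "]"
  ), f)
  g <- read_gml(f)
  expect_equal(g$vertices, c("A", "B"))
  expect_equal(g$edges$weight, 42L)
  # multi-line blocks and extra scalar keys are tolerated
  writeLines(c(
    'Creator "something else"',
    "graph [",
    "  directed 0",
    "  node [",
    "    id 0",
    '    label "X"',
    "  ]",
    "  node [",
    "    id 5",
    '    label "Y"',
    "  ]",
    "  edge [ source 5 target 0 weight 2 ]",
    "]"
  ), f)
  g2 <- read_gml(f)
  expect_equal(g2$vertices, c("X", "Y"))
  expect_equal(g2$edges$from, "X")
  expect_equal(g2$edges$weight, 2L)
})

test_that("malformed GML is rejected with a parse error", {
  f <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [",
    '  node [ id 0 label "A" ]',
    '  node [ id 0 label "B" ]',
    "]"
  ), f)
  expect_error(read_gml(f), "duplicate node id", class = "cm_input_error")
  writeLines(c(
    "graph [",
    '  node [ id 0 label "A" ]',
    "  edge [ source 0 target 3 weight 1 ]",
    "]"
  ), f)
  expect_error(read_gml(f), "unknown node id", class = "cm_input_error")
  writeLines(c("graph [", '  node [ id 0 label "A" ]'), f)
  expect_error(read_gml(f), class = "cm_input_error")
})

test_that("our GML is readable by igraph", {
  g <- random_small_graph(7)
  f <- tempfile(fileext = ".gml")
  write_gml(g, f)
  ig <- igraph::read_graph(f, format = "gml")
  expect_equal(igraph::vcount(ig), length(g$vertices))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  expect_equal(sum(igraph::E(ig)$weight), sum(g$edges$weight))
})

test_that("geometric centres are atom-coordinate means and translate rigidly", {
  fx <- generate_planted_structure(1, 2, 2)
  s <- fx$structure
  cen <- geometric_centers(s)
  # chain A: CA atoms at (0,0,0) and (3.8,0,0) -> centre (1.9, 0, 0)
  expect_equal(unname(cen["A", ]), c(1.9, 0, 0))
  s2 <- s
  s2$atoms$x <- s2$atoms$x + 5
  s2$atoms$y <- s2$atoms$y - 2
  cen2 <- geometric_centers(s2)
  expect_equal(unname(cen2[, "x"] - cen[, "x"]), rep(5, nrow(cen)))
  expect_equal(unname(cen2[, "y"] - cen[, "y"]), rep(-2, nrow(cen)))
})

test_that("centres of planted chains sit at the planted lattice sites", {
  fx <- generate_planted_structure(2, 2, 9, jitter = 0.2, seed = 6)
  cen <- geometric_centers(fx$structure)
  # planted site of each chain: x = mean of the residue line, y/z from gaps
  expect_equal(unname(cen["A", ]), c(8 * 3.8 / 2, 0, 0), tolerance = 0.5)
  expect_equal(unname(cen["B", ]), c(8 * 3.8 / 2, 3.5, 0), tolerance = 0.5)
  expect_equal(unname(cen["C", ]), c(8 * 3.8 / 2, 0, 12), tolerance = 0.5)
})

test_that("graphs from a structure and its rigid transform are identical", {
  fx <- generate_planted_structure(2, 2, 12, jitter = 1, seed = 10)
  s <- fx$structure
  g0 <- build_complex_graph(chain_contact_counts(s))
  set.seed(1)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rot
  s$atoms$x <- round(xyz[, 1] + 3, 3)
  s$atoms$y <- round(xyz[, 2] - 8, 3)
  s$atoms$z <- round(xyz[, 3] + 1, 3)
  expect_identical(build_complex_graph(chain_contact_counts(s)), g0)
})

test_that("layout and edge annotation exports have the documented columns", {
  fx <- generate_planted_structure(2, 2, 10)
  s <- fx$structure
  g <- build_complex_graph(chain_contact_counts(s))
  cen <- geometric_centers(s)
  f <- tempfile(fileext = ".tsv")
  write_layout_tsv(cen, f, partition = fx$truth)
  df <- read.delim(f)
  expect_equal(names(df), c("chain_id", "x", "y", "z", "module_id"))
  expect_equal(df$module_id, unname(fx$truth[df$chain_id]))
  fe <- tempfile(fileext = ".tsv")
  write_edge_tsv(g, fe, min_edge_label = 10)
  de <- read.delim(fe, colClasses = c("character", "character", "integer",
                                      "character"))
  expect_equal(names(de), c("from", "to", "weight", "label"))
  expect_true(all((de$weight >= 10) == (de$label != "")))
})
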
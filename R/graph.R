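# The complex graph: undirected, labelled, integer-weighted graph over
# chain identifiers, plus its GML serialization and the geometric-centre
# vertex layout used for plotting outside this package.

#' Construct a complex graph
#'
#' An undirected, labelled graph with positive integer edge weights (the
#' residue-contact counts). Vertices are stored in sorted order and each
#' edge with its endpoints in sorted order, so two graphs over the same data
#' are identical objects. Self-loops, parallel edges, duplicate vertex
#' labels, and weights below 1 are rejected.
#'
#' @param vertices character vector of vertex labels (chain IDs).
#' @param edges data.frame with columns `from`, `to`, `weight` (may have
#'   zero rows).
#' @return object of class `complex_graph`: list with `vertices` (sorted
#'   character) and `edges` (data.frame `from`, `to`, `weight`, sorted).
#' @export
complex_graph <- function(vertices, edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop_input("duplicate vertex labels")
  if (length(vertices) == 0) stop_input("graph needs at least one vertex")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        weight = edges$weight, stringsAsFactors = FALSE)
    if (!all(edges$from %in% vertices) || !all(edges$to %in% vertices)) {
      stop_input("edge endpoint not in vertex set")
    }
    if (any(edges$from == edges$to)) stop_input("self-loops are not allowed")
    w <- edges$weight
    if (any(is.na(w)) || any(w < 1) || any(w != round(w))) {
      stop_input("edge weights must be integers >= 1")
    }
    edges$weight <- as.integer(round(w))
    ord <- sort_c(vertices)
    flip <- match(edges$from, ord) > match(edges$to, ord)
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to, sep = "~"))) {
      stop_input("parallel edges are not allowed")
    }
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(vertices = sort_c(vertices), edges = edges),
            class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("complex_graph: %d vertices, %d edges, total weight %d\n",
              length(x$vertices), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' @export
format.complex_graph <- function(x, ...) {
  sprintf("complex_graph<%d vertices, %d edges>", length(x$vertices),
          nrow(x$edges))
}

#' Total edge weight of a complex graph
#' @param g a `complex_graph`.
#' @return numeric scalar (sum of edge weights).
#' @export
total_weight <- function(g) sum(as.numeric(g$edges$weight))

#' Build the complex graph from a contact matrix
#'
#' Every chain pair with at least one residue contact becomes an edge whose
#' weight is the contact count; chains without contacts remain as isolated
#' vertices.
#'
#' @param m symmetric integer contact matrix with chain-ID dimnames, as
#'   returned by [chain_contact_counts()].
#' @return a [complex_graph()].
#' @export
build_complex_graph <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m))) {
    stop_input("contact matrix must be square with chain-ID dimnames")
  }
  if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) || any(m < 0)) {
    stop_input("contact matrix must be symmetric, non-negative, zero-diagonal")
  }
  idx <- which(upper.tri(m) & m >= 1, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[idx[, 1]],
                      to = colnames(m)[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  complex_graph(rownames(m), edges)
}

#' Write a complex graph in GML
#'
#' Emits the minimal Graph Modelling Language dialect used by this package:
#' ```
#' graph [
#'   node [ id 0 label "A" ]
#'   edge [ source 0 target 1 weight 7 ]
#' ]
#' ```
#' Node ids are 0-based in vertex sort order; keys are lowercase; no
#' graphics blocks are written.
#'
#' @param g a `complex_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gml <- function(g, path) {
  stopifnot(inherits(g, "complex_graph"))
  id <- stats::setNames(seq_along(g$vertices) - 1L, g$vertices)
  lines <- c(
    "graph [",
    sprintf("  node [ id %d label \"%s\" ]", unname(id), g$vertices),
    if (nrow(g$edges) > 0) {
      sprintf("  edge [ source %d target %d weight %d ]",
              unname(id[g$edges$from]), unname(id[g$edges$to]),
              g$edges$weight)
    },
    "]"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a complex graph from GML
#'
#' Parses the dialect written by [write_gml()] (tolerating multi-line
#' node/edge blocks and other scalar keys, which are ignored). Duplicate
#' node ids, dangling edge endpoints, self-loops, and non-positive weights
#' are errors; parse errors report the offending line.
#'
#' @param path GML file path.
#' @return a [complex_graph()].
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("GML file not found: %s", path))
  toks <- gml_tokenize(readLines(path, warn = FALSE))
  p <- new.env(parent = emptyenv())
  p$i <- 1L
  peek <- function() if (p$i <= nrow(toks)) toks$tok[p$i] else NA_character_
  line <- function() if (p$i <= nrow(toks)) toks$line[p$i] else NA_integer_
  advance <- function() { t <- toks[p$i, ]; p$i <- p$i + 1L; t }
  expect <- function(what) {
    t <- peek()
    if (is.na(t) || t != what) {
      stop_input(sprintf("GML parse error at line %s: expected '%s', got '%s'",
                         line(), what, if (is.na(t)) "<eof>" else t))
    }
    advance()
  }
  # skip leading scalar keys (e.g. Creator "...") before the graph block
  while (!is.na(peek()) && peek() != "graph") {
    advance()
    if (!is.na(peek()) && !toks$quoted[p$i] && peek() == "[") {
      stop_input(sprintf("GML parse error at line %d: unexpected block", line()))
    }
    if (!is.na(peek())) advance()
  }
  expect("graph"); expect("[")
  nodes <- list(); edges <- list()
  repeat {
    t <- peek()
    if (is.na(t)) stop_input("GML parse error: unexpected end of file")
    if (t == "]") { advance(); break }
    kw_line <- line()
    kw <- advance()$tok
    if (!is.na(peek()) && peek() == "[" && !toks$quoted[p$i]) {
      advance()
      fields <- list()
      repeat {
        tt <- peek()
        if (is.na(tt)) stop_input("GML parse error: unterminated block")
        if (tt == "]" && !toks$quoted[p$i]) { advance(); break }
        key <- advance()$tok
        val_line <- line()
        if (is.na(peek())) {
          stop_input(sprintf("GML parse error at line %d: key '%s' has no value",
                             val_line, key))
        }
        fields[[key]] <- advance()$tok
      }
      if (kw == "node") nodes[[length(nodes) + 1L]] <- fields
      if (kw == "edge") edges[[length(edges) + 1L]] <- fields
    } else {
      # scalar graph-level key (e.g. directed 0): consume its value
      if (is.na(peek())) {
        stop_input(sprintf("GML parse error at line %d: key '%s' has no value",
                           kw_line, kw))
      }
      advance()
    }
  }
  if (length(nodes) == 0) stop_input("GML parse error: graph has no nodes")
  ids <- vapply(nodes, function(f) gml_int(f, "id"), numeric(1))
  labels <- vapply(nodes, function(f) {
    if (is.null(f$label)) stop_input("GML parse error: node without label")
    f$label
  }, character(1))
  if (anyDuplicated(ids)) stop_input("GML parse error: duplicate node id")
  if (anyDuplicated(labels)) stop_input("GML parse error: duplicate node label")
  lab_of <- stats::setNames(labels, as.character(ids))
  ed <- NULL
  if (length(edges) > 0) {
    src <- vapply(edges, function(f) gml_int(f, "source"), numeric(1))
    tgt <- vapply(edges, function(f) gml_int(f, "target"), numeric(1))
    wt <- vapply(edges, function(f) gml_int(f, "weight"), numeric(1))
    if (!all(as.character(src) %in% names(lab_of)) ||
        !all(as.character(tgt) %in% names(lab_of))) {
      stop_input("GML parse error: edge endpoint references unknown node id")
    }
    ed <- data.frame(from = unname(lab_of[as.character(src)]),
                     to = unname(lab_of[as.character(tgt)]),
                     weight = wt, stringsAsFactors = FALSE)
  }
  complex_graph(labels, ed)
}

gml_tokenize <- function(lines) {
  toks <- character(0); lns <- integer(0); quoted <- logical(0)
  for (i in seq_along(lines)) {
    s <- lines[i]
    # quoted strings or bare tokens (keys, numbers, brackets)
    m <- gregexpr('"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+', s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    pieces <- regmatches(lines[i], gregexpr('"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+', s, perl = TRUE))[[1]]
    isq <- startsWith(pieces, '"')
    pieces[isq] <- substr(pieces[isq], 2, nchar(pieces[isq]) - 1)
    toks <- c(toks, pieces)
    lns <- c(lns, rep(i, length(pieces)))
    quoted <- c(quoted, isq)
  }
  data.frame(tok = toks, line = lns, quoted = quoted, stringsAsFactors = FALSE)
}

gml_int <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop_input(sprintf("GML parse error: missing '%s'", key))
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n) || n != round(n)) {
    stop_input(sprintf("GML parse error: '%s' must be an integer, got '%s'",
                       key, v))
  }
  n
}

#' Geometric centres of the vertex chains
#'
#' Per vertex chain, the unweighted mean of its atom coordinates (polymer
#' and ligand atoms of that chain; solvent excluded). Used as the vertex
#' layout when drawing the complex graph over the structure.
#'
#' @param s a `complex_structure`.
#' @return numeric matrix, one row per vertex chain (rownames = chain IDs),
#'   columns `x`, `y`, `z` in Angstrom.
#' @export
geometric_centers <- function(s) {
  stopifnot(inherits(s, "complex_structure"))
  vch <- suppressWarnings(select_vertex_chains(s))
  a <- s$atoms[s$atoms$chain %in% vch & s$atoms$kind != "solvent", , drop = FALSE]
  out <- t(vapply(vch, function(cid) {
    aa <- a[a$chain == cid, , drop = FALSE]
    c(mean(aa$x), mean(aa$y), mean(aa$z))
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write a vertex layout as TSV
#'
#' Columns `chain_id`, `x`, `y`, `z`, and `module_id` when a partition is
#' supplied (`NA` for chains the partition does not cover).
#'
#' @param centers matrix from [geometric_centers()].
#' @param path output path.
#' @param partition optional named module assignment (names = chain IDs).
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(centers, path, partition = NULL) {
  df <- data.frame(chain_id = rownames(centers),
                   x = round(centers[, "x"], 3),
                   y = round(centers[, "y"], 3),
                   z = round(centers[, "z"], 3),
                   stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    df$module_id <- unname(partition[df$chain_id])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weighted edge list with presentation labels
#'
#' Companion annotation to the layout export: one row per edge with its
#' weight and a `label` column that repeats the weight only when it reaches
#' `min_edge_label` (the display threshold for edge labels in complex-graph
#' figures); smaller weights get an empty label. The graph itself is never
#' affected by this threshold.
#'
#' @param g a `complex_graph`.
#' @param path output path.
#' @param min_edge_label smallest weight that receives a printed label.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(g, path, min_edge_label = 30) {
  e <- g$edges
  e$label <- ifelse(e$weight >= min_edge_label, as.character(e$weight), "")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
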
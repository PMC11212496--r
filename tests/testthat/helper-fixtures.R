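# Shared fixtures, all built in code.

# two disjoint unit-weight edges: a-b, c-d
two_edge_graph <- function() {
  complex_graph(c("a", "b", "c", "d"),
                data.frame(from = c("a", "c"), to = c("b", "d"),
                           weight = c(1, 1)))
}

# two unit-weight triangles joined by one bridge edge (c-d)
barbell_graph <- function() {
  complex_graph(letters[1:6],
                data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                           to   = c("b", "c", "c", "e", "f", "f", "d"),
                           weight = rep(1, 7)))
}

# random weighted graph on 4..9 vertices (connected not guaranteed)
random_small_graph <- function(seed) {
  set.seed(seed)
  n <- sample(4:9, 1)
  ids <- make_chain_ids(n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < 0.5
  if (!any(keep)) keep[1] <- TRUE
  complex_graph(ids, data.frame(from = ids[pairs[keep, 1]],
                                to = ids[pairs[keep, 2]],
                                weight = sample(1:10, sum(keep), replace = TRUE)))
}

# random partition of a graph's vertices into <= k blocks
random_partition <- function(g, seed, k = 4) {
  set.seed(seed)
  stats::setNames(sample.int(k, length(g$vertices), replace = TRUE) - 1L,
                  g$vertices)
}

# direct double-sum modularity oracle: Q = (1/2m) * sum over ordered vertex
# pairs in the same module of (A_uv - gamma * k_u * k_v / (2m)); independent
# of the package implementation
modularity_oracle <- function(g, partition, gamma = 1) {
  v <- g$vertices
  n <- length(v)
  A <- matrix(0, n, n, dimnames = list(v, v))
  for (i in seq_len(nrow(g$edges))) {
    A[g$edges$from[i], g$edges$to[i]] <- g$edges$weight[i]
    A[g$edges$to[i], g$edges$from[i]] <- g$edges$weight[i]
  }
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m == 0) return(0)
  q <- 0
  for (u in v) for (w in v) {
    if (partition[u] == partition[w]) {
      q <- q + A[u, w] - gamma * k[u] * k[w] / (2 * m)
    }
  }
  as.numeric(q / (2 * m))
}

# mmCIF text with altlocs, a ligand, a water, and a detached ligand-only
# chain; used by the structure_io tests
write_mixed_cif <- function(path) {
  writeLines(c(
    "data_MIXED",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 0.00 2 GLY A CA 1",
    "ATOM 3 C CA A VAL A 1 3 ? 7.600 0.000 0.000 0.40 0.00 3 VAL A CA 1",
    "ATOM 4 C CA B VAL A 1 3 ? 7.700 0.000 0.000 0.60 0.00 3 VAL A CA 1",
    "ATOM 5 C CA . ALA B 2 1 ? 0.000 3.500 0.000 1.00 0.00 1 ALA B CA 1",
    "ATOM 6 C CA . GLY B 2 2 ? 3.800 3.500 0.000 1.00 0.00 2 GLY B CA 1",
    "HETATM 7 FE FE . HEM C 3 . ? 5.000 3.000 0.000 1.00 0.00 101 HEM B FE 1",
    "HETATM 8 O O . HOH D 4 . ? 9.000 9.000 9.000 1.00 0.00 201 HOH B O 1",
    "HETATM 9 P PA . ADP E 5 . ? 30.000 30.000 30.000 1.00 0.00 301 ADP Z PA 1",
    "#"
  ), path)
  path
}
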
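# Synthetic fixtures with planted module structure: multi-chain pseudo
# structures written as mmCIF, and weighted planted-partition graphs. Both
# return the ground-truth partition so recovery can be scored exactly.

#' Chain identifiers in deposition style
#'
#' `A`..`Z`, then `AA`, `AB`, ... — deterministic labels for generated
#' chains.
#'
#' @param n number of identifiers.
#' @return character vector of length `n`.
#' @export
make_chain_ids <- function(n) {
  stopifnot(n >= 1, n <= 26 + 26 * 26)
  one <- LETTERS
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(one, two)[seq_len(n)]
}

#' Generate a planted multi-chain structure
#'
#' Builds a synthetic quaternary structure whose chains form spatial
#' clusters: each chain is a linear run of CA-only pseudo-residues (ALA,
#' 3.8 A spacing along x), the chains of one module are stacked
#' side-by-side at `intra_gap` along y (producing one residue-residue
#' contact per residue between adjacent chains under the default 4.0 A
#' protein-protein threshold), and module blocks are separated by
#' `inter_gap` along z. With the defaults (`intra_gap = 3.5`,
#' `inter_gap = 12`) chains of different modules share zero contacts, so
#' the chain contact matrix is exactly block-diagonal with respect to the
#' returned truth partition. With `inter_gap` at or below the contact
#' threshold the blocks touch and the graph becomes connected.
#'
#' An optional uniform coordinate `jitter` (seeded) perturbs each
#' coordinate by up to +/- `jitter` Angstrom; the default 0 keeps the
#' planted contact counts exact.
#'
#' @param n_modules number of planted modules (>= 1).
#' @param chains_per_module chains in each module (>= 1).
#' @param residues_per_chain residues per chain (>= 1).
#' @param intra_gap spacing between adjacent chains within a module, A.
#' @param inter_gap spacing between module blocks, A.
#' @param jitter half-width of uniform coordinate noise, A (default 0).
#' @param seed integer seed for the jitter.
#' @param path optional output path; when given, the structure is written
#'   as mmCIF.
#' @return list with `structure` (a `complex_structure`), `truth` (named
#'   integer vector: 0-based module id per chain), and `path` (or `NULL`).
#' @examples
#' fx <- generate_planted_structure(2, 3, 20)
#' fx$truth
#' @export
generate_planted_structure <- function(n_modules, chains_per_module,
                                       residues_per_chain,
                                       intra_gap = 3.5, inter_gap = 12.0,
                                       jitter = 0, seed = 1, path = NULL) {
  if (n_modules < 1 || chains_per_module < 1 || residues_per_chain < 1) {
    stop_input("all counts must be >= 1")
  }
  if (intra_gap <= 0 || inter_gap <= 0 || jitter < 0) {
    stop_input("gaps must be positive and jitter non-negative")
  }
  n_chains <- n_modules * chains_per_module
  ids <- make_chain_ids(n_chains)
  truth <- stats::setNames(rep(seq_len(n_modules) - 1L,
                               each = chains_per_module), ids)

  chain <- rep(ids, each = residues_per_chain)
  resno <- rep(seq_len(residues_per_chain), times = n_chains)
  mod_i <- rep(truth, each = residues_per_chain)
  chain_in_mod <- rep(rep(seq_len(chains_per_module) - 1L,
                          times = n_modules), each = residues_per_chain)
  x <- (resno - 1) * 3.8
  y <- chain_in_mod * intra_gap
  z <- mod_i * inter_gap
  if (jitter > 0) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             sample.kind = "Rejection")
    x <- x + stats::runif(length(x), -jitter, jitter)
    y <- y + stats::runif(length(y), -jitter, jitter)
    z <- z + stats::runif(length(z), -jitter, jitter)
  }
  atoms <- data.frame(
    serial = seq_along(chain),
    chain = chain, resno = resno, insert = "",
    resid = "ALA", elety = "CA", elesy = "C", alt = "",
    x = round(x, 3), y = round(y, 3), z = round(z, 3),
    o = 1, is_hetero = FALSE, kind = "polymer",
    stringsAsFactors = FALSE
  )
  atoms$reskey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
                        sep = "|")
  s <- new_complex_structure("SYNTH", atoms, "mmcif")
  if (!is.null(path)) write_structure_cif(s, path)
  list(structure = s, truth = truth, path = path)
}

#' Generate a planted-partition weighted graph
#'
#' Builds a weighted graph with known module structure: every within-module
#' vertex pair is connected at weight `w_in`; every between-module pair is
#' connected independently with probability `p_out` at weight `w_out`.
#' Vertex labels are deposition-style chain IDs. Seeded and reproducible:
#' the same seed gives the same edge set, different seeds differ only in
#' the inter-module edges.
#'
#' @param n_modules number of modules.
#' @param sizes vertices per module: a scalar or a length-`n_modules`
#'   vector.
#' @param w_in intra-module edge weight (positive integer).
#' @param w_out inter-module edge weight (positive integer).
#' @param p_out inter-module edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `graph` (a [complex_graph()]) and `truth` (named
#'   integer vector: 0-based module id per vertex).
#' @examples
#' pg <- generate_planted_graph(4, 5, w_in = 10, w_out = 1, p_out = 0.1,
#'                              seed = 42)
#' pg$graph
#' @export
generate_planted_graph <- function(n_modules, sizes, w_in = 10, w_out = 1,
                                   p_out = 0.1, seed = 1) {
  if (length(sizes) == 1) sizes <- rep(sizes, n_modules)
  stopifnot(length(sizes) == n_modules, all(sizes >= 1))
  if (w_in < 1 || w_out < 1 || w_in != round(w_in) || w_out != round(w_out)) {
    stop_input("edge weights must be positive integers")
  }
  if (p_out < 0 || p_out > 1) stop_input("p_out must be in [0, 1]")
  n <- sum(sizes)
  ids <- make_chain_ids(n)
  truth <- stats::setNames(rep(seq_len(n_modules) - 1L, times = sizes), ids)

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- truth[pairs[, 1]] == truth[pairs[, 2]]
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  keep_out <- !same & stats::runif(nrow(pairs)) < p_out
  sel <- same | keep_out
  edges <- data.frame(
    from = ids[pairs[sel, 1]],
    to = ids[pairs[sel, 2]],
    weight = ifelse(same[sel], as.integer(w_in), as.integer(w_out)),
    stringsAsFactors = FALSE
  )
  list(graph = complex_graph(ids, edges), truth = truth)
}
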
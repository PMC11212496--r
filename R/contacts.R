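# Sphere-overlap contact model.
#
# Two atoms are in contact when their spheres overlap (distance <= sum of
# radii, boundary inclusive); two residues when they share >= 1 atom-atom
# contact; two chains when they share >= 1 residue-residue contact. Edge
# weights count residue pairs, not atom pairs. The production engine bins
# atoms into a uniform grid with cell edge 2*max(radius) so only the 27
# neighbouring cells need scanning; a quadratic all-pairs engine serves as
# the independent reference.

#' Contact model parameters
#'
#' Sphere radii of the contact model: 2.0 A for atoms of polymer (protein)
#' residues and 3.0 A for atoms of ligand residues. Two atoms are in contact
#' when their spheres overlap, so the protein-protein contact threshold is
#' 4.0 A and the protein-ligand threshold 5.0 A.
#'
#' @param r_protein sphere radius for polymer-residue atoms, Angstrom.
#' @param r_ligand sphere radius for ligand-residue atoms, Angstrom.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(r_protein = 2.0, r_ligand = 3.0) {
  if (!is.numeric(r_protein) || length(r_protein) != 1 || r_protein <= 0 ||
      !is.numeric(r_ligand) || length(r_ligand) != 1 || r_ligand <= 0) {
    stop_input("contact radii must be single positive numbers")
  }
  structure(list(r_protein = r_protein, r_ligand = r_ligand),
            class = "contact_params")
}

#' Sphere radius of an atom
#'
#' Returns the contact-model radius for atoms by residue kind: `r_protein`
#' for polymer residues, `r_ligand` for ligand residues. Solvent residues
#' must be filtered out before contact computation and are a contract
#' violation here.
#'
#' @param residue_kind character vector, each `"polymer"` or `"ligand"`.
#' @param params a [contact_params()] object.
#' @return numeric vector of radii, Angstrom.
#' @export
atom_radius <- function(residue_kind, params = contact_params()) {
  if (any(residue_kind == "solvent")) {
    stop("solvent residues must be excluded before contact computation")
  }
  if (!all(residue_kind %in% c("polymer", "ligand"))) {
    stop("residue_kind must be 'polymer' or 'ligand'")
  }
  ifelse(residue_kind == "polymer", params$r_protein, params$r_ligand)
}

#' Atom-atom sphere overlap test
#'
#' Two atoms are in contact iff the Euclidean distance between their centres
#' is at most the sum of their radii; tangency (distance exactly equal to
#' the sum) counts as contact.
#'
#' @param a,b numeric length-3 coordinate vectors, Angstrom.
#' @param ra,rb sphere radii, Angstrom.
#' @return logical.
#' @export
atoms_in_contact <- function(a, b, ra, rb) {
  d2 <- sum((a - b)^2)
  d2 <= (ra + rb)^2
}

#' Residue-residue contact test
#'
#' Two residues are in contact iff at least one atom pair between them is in
#' contact under the sphere model. Residues are given as atom tables (rows
#' of a `complex_structure`'s `atoms` slot) carrying `x`, `y`, `z`, and
#' `kind` columns; both must come from different chains and neither may be
#' solvent.
#'
#' @param p,q atom tables of the two residues.
#' @param params a [contact_params()] object.
#' @return logical.
#' @export
residue_pair_in_contact <- function(p, q, params = contact_params()) {
  stopifnot(all(c("x", "y", "z", "kind") %in% names(p)),
            all(c("x", "y", "z", "kind") %in% names(q)))
  rp <- atom_radius(p$kind, params)
  rq <- atom_radius(q$kind, params)
  pm <- as.matrix(p[, c("x", "y", "z")])
  qm <- as.matrix(q[, c("x", "y", "z")])
  for (i in seq_len(nrow(pm))) {
    d2 <- (qm[, 1] - pm[i, 1])^2 + (qm[, 2] - pm[i, 2])^2 +
      (qm[, 3] - pm[i, 3])^2
    if (any(d2 <= (rp[i] + rq)^2)) return(TRUE)
  }
  FALSE
}

# atoms participating in contact computation: polymer + ligand residues of
# vertex (polypeptide) chains; solvent and detached non-polypeptide chains
# are excluded
contact_atom_table <- function(s, params, exclude_ligands = FALSE) {
  vch <- suppressWarnings(select_vertex_chains(s))
  a <- s$atoms[s$atoms$chain %in% vch & s$atoms$kind != "solvent", , drop = FALSE]
  if (exclude_ligands) a <- a[a$kind != "ligand", , drop = FALSE]
  a$radius <- atom_radius(a$kind, params)
  list(atoms = a, chains = vch)
}

#' Chain-chain contact counts
#'
#' Computes the symmetric matrix of residue-residue contact counts between
#' all pairs of vertex chains of a structure: entry `[i, j]` is the number
#' of unordered residue pairs (one residue in chain i, one in chain j) that
#' share at least one atom-atom sphere overlap. Each residue pair is counted
#' once no matter how many of its atom pairs overlap. Ligand residues
#' attached to a vertex chain contribute to that chain's counts unless
#' `exclude_ligands` is set. Intra-chain pairs are never computed.
#'
#' The default engine bins atoms into a uniform spatial grid with cell edge
#' `2 * max(r_protein, r_ligand)` and scans only neighbouring cells;
#' `method = "brute"` evaluates all cross-chain atom pairs directly and is
#' the reference implementation used for validation.
#'
#' @param s a `complex_structure`.
#' @param params a [contact_params()] object.
#' @param exclude_ligands drop ligand residues before counting.
#' @param method `"grid"` (default) or `"brute"`.
#' @return symmetric integer matrix with zero diagonal; dimnames are the
#'   vertex chain IDs in sorted order.
#' @examples
#' f <- tempfile(fileext = ".cif")
#' generate_planted_structure(2, 2, 10, path = f)
#' chain_contact_counts(parse_structure(f))
#' @export
chain_contact_counts <- function(s, params = contact_params(),
                                 exclude_ligands = FALSE,
                                 method = c("grid", "brute")) {
  method <- match.arg(method)
  ct <- contact_atom_table(s, params, exclude_ligands)
  if (length(ct$chains) < 2) {
    stop_degenerate("contact computation needs at least 2 vertex chains")
  }
  pairs <- if (method == "grid") {
    contact_residue_pairs_grid(ct$atoms, params)
  } else {
    contact_residue_pairs_brute(ct$atoms)
  }
  m <- matrix(0L, length(ct$chains), length(ct$chains),
              dimnames = list(ct$chains, ct$chains))
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$chain_i, levels = ct$chains),
                 factor(pairs$chain_j, levels = ct$chains))
    m <- m + unclass(tab) + t(unclass(tab))
    storage.mode(m) <- "integer"
  }
  m
}

# Grid engine: cell lists joined over the 27 neighbouring offsets; candidate
# atom pairs deduplicated by requiring id1 < id2, then distance-tested and
# reduced to unique cross-chain residue pairs.
contact_residue_pairs_grid <- function(atoms, params) {
  cell <- 2 * max(params$r_protein, params$r_ligand)
  dt <- data.table(
    id = seq_len(nrow(atoms)),
    chain = atoms$chain, reskey = atoms$reskey, radius = atoms$radius,
    x = atoms$x, y = atoms$y, z = atoms$z,
    cx = as.integer(floor(atoms$x / cell)),
    cy = as.integer(floor(atoms$y / cell)),
    cz = as.integer(floor(atoms$z / cell))
  )
  setkey(dt, cx, cy, cz)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    shifted <- dt[, .(id2 = id, chain2 = chain, reskey2 = reskey,
                      radius2 = radius, x2 = x, y2 = y, z2 = z,
                      cx = cx + offs[k, 1L], cy = cy + offs[k, 2L],
                      cz = cz + offs[k, 3L])]
    j <- dt[shifted, on = c("cx", "cy", "cz"), nomatch = NULL,
            allow.cartesian = TRUE,
            .(id, id2, chain, chain2, reskey, reskey2,
              d2 = (x - x2)^2 + (y - y2)^2 + (z - z2)^2,
              rsum = radius + radius2)]
    j <- j[id < id2 & chain != chain2 & d2 <= rsum^2]
    out[[k]] <- j[, .(chain, chain2, reskey, reskey2)]
  }
  hits <- data.table::rbindlist(out)
  if (nrow(hits) == 0) {
    return(data.frame(chain_i = character(0), chain_j = character(0)))
  }
  # orient each residue pair so chain_i < chain_j, then deduplicate
  flip <- hits$chain > hits$chain2
  res <- data.table(
    chain_i = ifelse(flip, hits$chain2, hits$chain),
    chain_j = ifelse(flip, hits$chain, hits$chain2),
    res_i = ifelse(flip, hits$reskey2, hits$reskey),
    res_j = ifelse(flip, hits$reskey, hits$reskey2)
  )
  res <- unique(res, by = c("res_i", "res_j"))
  as.data.frame(res[, .(chain_i, chain_j)])
}

# Reference engine: full cross-chain atom-pair distance evaluation.
contact_residue_pairs_brute <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  hits_i <- character(0); hits_j <- character(0)
  res_i <- character(0); res_j <- character(0)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    js <- js[atoms$chain[js] != atoms$chain[i]]
    if (length(js) == 0) next
    d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
      (xyz[js, 3] - xyz[i, 3])^2
    ok <- js[d2 <= (atoms$radius[i] + atoms$radius[js])^2]
    if (length(ok) == 0) next
    flip <- atoms$chain[i] > atoms$chain[ok]
    hits_i <- c(hits_i, ifelse(flip, atoms$chain[ok], atoms$chain[i]))
    hits_j <- c(hits_j, ifelse(flip, atoms$chain[i], atoms$chain[ok]))
    res_i <- c(res_i, ifelse(flip, atoms$reskey[ok], atoms$reskey[i]))
    res_j <- c(res_j, ifelse(flip, atoms$reskey[i], atoms$reskey[ok]))
  }
  if (length(hits_i) == 0) {
    return(data.frame(chain_i = character(0), chain_j = character(0)))
  }
  keep <- !duplicated(paste(res_i, res_j, sep = "~"))
  data.frame(chain_i = hits_i[keep], chain_j = hits_j[keep],
             stringsAsFactors = FALSE)
}

#' Write a contact matrix as TSV
#'
#' Header row and first column hold the chain IDs; cells are integer
#' residue-contact counts.
#'
#' @param m matrix from [chain_contact_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(m, path) {
  df <- data.frame(chain_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
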
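# Structure parsing and vertex-chain selection.
#
# A parsed structure is held as a flat atom table (one row per atom), the
# idiom used by bio3d, rather than nested chain/residue objects: all
# downstream contact computations are vectorized over this table.

#' @importFrom data.table data.table as.data.table setkey setkeyv := .N .SD
NULL

# residues treated as water/solvent; never reach contact computation
.SOLVENT_RESIDUES <- c("HOH", "DOD", "WAT")

# the 20 standard amino acids (3-letter codes)
.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Error condition helpers
#'
#' Input errors (`cm_input_error`) signal unreadable or malformed inputs;
#' degenerate-input errors (`cm_degenerate_error`) signal structurally valid
#' inputs on which the requested computation is undefined (e.g. fewer than
#' two chains). The command-line wrapper maps these to exit codes 2 and 3.
#'
#' @param msg error message.
#' @name cm-conditions
#' @keywords internal
stop_input <- function(msg) {
  stop(structure(
    class = c("cm_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @rdname cm-conditions
#' @keywords internal
stop_degenerate <- function(msg) {
  stop(structure(
    class = c("cm_degenerate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# C-locale lexicographic sort, independent of the session locale
sort_c <- function(x) sort(x, method = "radix")

#' Parse a macromolecular structure file
#'
#' Reads an mmCIF (PDBx) or legacy PDB file into a `complex_structure`
#' object: a flat atom table plus a per-chain summary. Only the first model
#' of multi-model files is kept. Alternate locations are resolved per
#' residue by keeping the altloc code with the highest occupancy (ties:
#' lexicographically smallest code); atoms without an altloc code are always
#' kept. Water residues (HOH/DOD/WAT) are flagged `kind = "solvent"` and are
#' excluded from all contact computations downstream. Chain identifiers are
#' the author-assigned (`auth_asym_id`) IDs, preserved verbatim.
#'
#' Residue `kind` is `"polymer"` for ATOM records, `"solvent"` for waters,
#' and `"ligand"` for all other HETATM records. A chain is classified as
#' polypeptide when more than half of its polymer residues are standard
#' amino acids, which keeps chains with modified residues and excludes
#' nucleic-acid chains.
#'
#' @param path path to the structure file.
#' @param format `"auto"` (default, detected from extension then content),
#'   `"mmcif"`, or `"pdb"`.
#' @return An object of class `complex_structure`: a list with
#'   `structure_id`, `atoms` (data.frame with columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`, `kind`,
#'   `reskey`), `chains` (data.frame with `chain_id`, `is_polypeptide`,
#'   `n_residues`), and `source_format`.
#' @examples
#' f <- tempfile(fileext = ".cif")
#' generate_planted_structure(1, 2, 5, path = f)
#' s <- parse_structure(f)
#' s$chains
#' @export
parse_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_input(sprintf("structure file not found: %s", path))
  }
  if (format == "auto") format <- detect_structure_format(path)

  raw <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       rm.insert = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       rm.insert = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop_input(sprintf("failed to parse %s as %s: %s",
                         path, format, conditionMessage(e)))
    }
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) {
    stop_input(sprintf("no atom records found in %s", path))
  }

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    chain  = as.character(at$chain),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    alt    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(suppressWarnings(as.numeric(at$o))), 1,
               suppressWarnings(as.numeric(at$o))),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- ""

  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop_input(sprintf("non-finite coordinates for %d atoms (first serial: %s)",
                       sum(bad), atoms$serial[which(bad)[1]]))
  }
  atoms$o <- pmin(pmax(atoms$o, 0), 1)

  atoms$kind <- ifelse(atoms$resid %in% .SOLVENT_RESIDUES, "solvent",
                       ifelse(atoms$is_hetero, "ligand", "polymer"))
  atoms$reskey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
                        sep = "|")

  atoms <- resolve_altlocs(atoms)

  structure_id <- read_structure_id(path, format)
  s <- new_complex_structure(structure_id, atoms, format)
  if (!any(s$chains$is_polypeptide)) {
    stop_input(sprintf("no polypeptide chains in %s", path))
  }
  s
}

detect_structure_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("_atom_site\\.", head_lines))) {
    return("mmcif")
  }
  if (any(grepl("^(ATOM|HETATM|HEADER|MODEL)", head_lines))) {
    return("pdb")
  }
  stop_input(sprintf("cannot detect structure format of %s", path))
}

read_structure_id <- function(path, format) {
  if (format == "mmcif") {
    head_lines <- readLines(path, n = 20L, warn = FALSE)
    d <- grep("^data_", head_lines, value = TRUE)
    if (length(d) > 0) return(sub("^data_", "", d[1]))
  }
  toupper(tools::file_path_sans_ext(basename(path)))
}

# Per residue: keep atoms with blank altloc plus atoms of the winning altloc
# code (highest mean occupancy; ties -> lexicographically smallest code).
resolve_altlocs <- function(atoms) {
  if (!any(atoms$alt != "")) return(atoms)
  dt <- as.data.table(atoms)
  dt[, row_id := .I]
  altd <- dt[alt != "", .(occ = mean(o)), by = .(reskey, alt)]
  # order: by residue, then occupancy descending, then altloc code ascending
  altd <- altd[order(reskey, -occ, alt, method = "radix")]
  winner <- altd[, .SD[1L], by = reskey][, .(reskey, win_alt = alt)]
  dt <- merge(dt, winner, by = "reskey", all.x = TRUE, sort = FALSE)
  keep <- dt[alt == "" | alt == win_alt][order(row_id)]
  keep[, c("row_id", "win_alt") := NULL]
  as.data.frame(keep)
}

new_complex_structure <- function(structure_id, atoms, source_format) {
  rt <- unique(atoms[, c("chain", "reskey", "kind")])
  poly <- rt[rt$kind == "polymer", , drop = FALSE]
  chain_ids <- sort_c(unique(atoms$chain))
  is_poly <- vapply(chain_ids, function(cid) {
    r <- poly[poly$chain == cid, , drop = FALSE]
    if (nrow(r) == 0) return(FALSE)
    comp <- sub("^.*\\|", "", r$reskey)
    mean(comp %in% .STANDARD_AA) > 0.5
  }, logical(1))
  n_res <- vapply(chain_ids, function(cid) sum(rt$chain == cid), integer(1))
  chains <- data.frame(
    chain_id = chain_ids,
    is_polypeptide = unname(is_poly),
    n_residues = unname(n_res),
    stringsAsFactors = FALSE
  )
  structure(
    list(structure_id = structure_id, atoms = atoms, chains = chains,
         source_format = source_format),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf(
    "complex_structure '%s' (%s): %d chains (%d polypeptide), %d atoms\n",
    x$structure_id, x$source_format, nrow(x$chains),
    sum(x$chains$is_polypeptide), nrow(x$atoms)
  ))
  invisible(x)
}

#' Select the chains that become graph vertices
#'
#' Returns the polypeptide chain identifiers of a structure in deterministic
#' (C-locale lexicographic) order. Non-polymer residues that carry the
#' chain ID of a polypeptide chain stay attached to that chain as ligand
#' residues; chains without any polypeptide content (detached ligand-only
#' chains, nucleic-acid chains) are dropped from the vertex set with a
#' warning.
#'
#' @param s a `complex_structure`.
#' @return character vector of chain IDs.
#' @export
select_vertex_chains <- function(s) {
  stopifnot(inherits(s, "complex_structure"))
  keep <- s$chains$chain_id[s$chains$is_polypeptide]
  dropped <- s$chains$chain_id[!s$chains$is_polypeptide]
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d non-polypeptide chain(s) from vertex set: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  sort_c(keep)
}

#' Serialize a structure to mmCIF
#'
#' Writes the atom table back out as a minimal PDBx/mmCIF `atom_site` loop
#' (coordinates to 3 decimals, occupancies to 2). Round-tripping through
#' [parse_structure()] preserves chain IDs, residue counts, and coordinates.
#'
#' @param s a `complex_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(s, path) {
  stopifnot(inherits(s, "complex_structure"))
  a <- s$atoms
  rec <- ifelse(a$kind == "polymer", "ATOM", "HETATM")
  elesy <- ifelse(a$elesy == "", substr(a$elety, 1, 1), a$elesy)
  ins <- ifelse(a$insert == "", "?", a$insert)
  lines <- c(
    sprintf("data_%s", s$structure_id),
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
    sprintf("%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
            rec, seq_len(nrow(a)), elesy, a$elety, a$resid, a$chain,
            a$resno, ins, a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain,
            a$elety),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}
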
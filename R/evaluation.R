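# Evaluation of predicted module structures: chance-corrected agreement
# with a reference assignment (adjusted Rand index) and module-level
# interface statistics (intra-module vs inter-module contact weight, the
# proxy used to read relative rigidity/flexibility off the graph).

#' Adjusted Rand index between a partition and a reference assignment
#'
#' Builds the contingency table `n_ij` over the elements shared by the two
#' assignments (row sums `a_i`, column sums `b_j`, total `n`) and returns
#'
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#'
#' with `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`. The index is 1 for
#' identical partitions and 0 in expectation for independent ones. The
#' binomial terms are accumulated before any division, so the computation
#' is exact up to the final quotient. When the denominator is 0 (both
#' assignments all-singletons, or both a single block) the two assignments
#' are necessarily identical and 1.0 is returned.
#'
#' Evaluation is restricted to the intersection of the two name sets (a
#' reference may omit unassigned chains); the number of elements outside
#' the intersection is reported via a message.
#'
#' @param p named vector: predicted module per element.
#' @param r named vector: reference module per element (free-form labels).
#' @return numeric scalar in `[-1, 1]`.
#' @examples
#' p <- c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1)
#' r <- c(a = "x", b = "x", c = "y", d = "y", e = "z", f = "z")
#' adjusted_rand_index(p, r)
#' @export
adjusted_rand_index <- function(p, r) {
  shared <- intersect(names(p), names(r))
  omitted <- length(union(names(p), names(r))) - length(shared)
  if (length(shared) < 2) {
    stop_degenerate("adjusted Rand index needs >= 2 shared elements")
  }
  if (omitted > 0) {
    message(sprintf("adjusted_rand_index: %d element(s) outside the shared set omitted",
                    omitted))
  }
  tab <- table(as.character(p[shared]), as.character(r[shared]))
  n <- length(shared)
  c2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(c2(tab))
  sum_a <- sum(c2(rowSums(tab)))
  sum_b <- sum(c2(colSums(tab)))
  expected <- sum_a * sum_b / c2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1.0)
  (sum_ij - expected) / denom
}

#' Module-level interface statistics
#'
#' For a partition of a complex graph, reports per-module size and
#' intra-module contact weight, the contact weight between every module
#' pair that shares an interface, and the overall intra-module weight
#' fraction. Inter-module weight is the package's flexibility proxy: a
#' large weight between two modules indicates a strong (comparatively
#' rigid) inter-module connection, a small one a weakly coupled, putatively
#' flexible interface. The intra and inter weights always sum to the total
#' graph weight.
#'
#' @param g a [complex_graph()].
#' @param partition named module assignment covering every vertex of `g`.
#' @return object of class `module_report`: list with `modules` (data.frame
#'   `module_id`, `size`, `intra_weight`), `pairs` (data.frame `module_i`,
#'   `module_j`, `inter_weight`, only pairs with positive weight),
#'   `intra_fraction`, `total_weight`.
#' @export
module_report <- function(g, partition) {
  stopifnot(inherits(g, "complex_graph"))
  if (!all(g$vertices %in% names(partition))) {
    stop("partition must cover every vertex of the graph")
  }
  mods <- as.character(partition[g$vertices])
  mod_ids <- unique(mods[order(rank_of(mods, g$vertices))])
  e <- g$edges
  mf <- as.character(partition[e$from])
  mt <- as.character(partition[e$to])
  intra <- vapply(mod_ids, function(mm) {
    sum(as.numeric(e$weight[mf == mm & mt == mm]))
  }, numeric(1))
  sizes <- vapply(mod_ids, function(mm) sum(mods == mm), integer(1))
  cross <- which(mf != mt)
  pairs <- data.frame(module_i = character(0), module_j = character(0),
                      inter_weight = numeric(0), stringsAsFactors = FALSE)
  if (length(cross) > 0) {
    a <- mf[cross]; b <- mt[cross]
    flip <- match(a, mod_ids) > match(b, mod_ids)
    tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
    key <- paste(a, b, sep = "\r")
    w <- tapply(as.numeric(e$weight[cross]), key, sum)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    pairs <- data.frame(module_i = vapply(parts, `[`, "", 1),
                        module_j = vapply(parts, `[`, "", 2),
                        inter_weight = as.numeric(w),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(match(pairs$module_i, mod_ids),
                         match(pairs$module_j, mod_ids)), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  tw <- total_weight(g)
  structure(
    list(
      modules = data.frame(module_id = mod_ids, size = unname(sizes),
                           intra_weight = unname(intra),
                           stringsAsFactors = FALSE),
      pairs = pairs,
      intra_fraction = if (tw > 0) sum(intra) / tw else 1.0,
      total_weight = tw
    ),
    class = "module_report"
  )
}

# order key: module label by smallest member vertex label
rank_of <- function(mods, verts) {
  first <- tapply(seq_along(verts), mods, min)
  unname(first[mods])
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf("module_report: %d modules, total weight %g, intra fraction %.4f\n",
              nrow(x$modules), x$total_weight, x$intra_fraction))
  cat("\nPer-module:\n")
  print(x$modules, row.names = FALSE)
  if (nrow(x$pairs) > 0) {
    cat("\nInter-module interfaces (weight = contact count between modules):\n")
    print(x$pairs, row.names = FALSE)
  } else {
    cat("\nNo inter-module interfaces (modules are disconnected).\n")
  }
  invisible(x)
}

#' Write a module report as TSV blocks
#'
#' Two TSV blocks (`modules`, then `interfaces`) separated by comment
#' lines, mirroring the fields of [module_report()].
#'
#' @param report a `module_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_weight=%g intra_fraction=%.6f",
                     report$total_weight, report$intra_fraction), con)
  writeLines("# modules", con)
  utils::write.table(report$modules, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# interfaces", con)
  utils::write.table(report$pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference module assignment
#'
#' Two-column TSV `chain_id<TAB>module_name`; lines starting with `#` are
#' ignored. Module names are free-form strings (e.g. `"N"`, `"Q"`, `"PP"`,
#' `"PD"`).
#'
#' @param path TSV file path.
#' @return named character vector: module name per chain ID.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("reference file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2) stop_input("reference file needs two tab-separated columns")
  if (anyDuplicated(df[[1]])) stop_input("duplicate chain IDs in reference file")
  stats::setNames(df[[2]], df[[1]])
}
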
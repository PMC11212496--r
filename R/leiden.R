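# Leiden community detection on the complex graph, optimizing generalized
# (resolution-parameterized) weighted modularity:
#
#   Q = sum_c [ w_in(c)/m - gamma * (s(c) / (2m))^2 ]
#
# with m the total edge weight, w_in(c) the weight inside module c
# (including self-loops on aggregate graphs), and s(c) the summed vertex
# strengths of c. The algorithm iterates three phases: queue-based greedy
# local movement, randomized refinement within modules (merge probability
# proportional to exp(dQ/theta), restricted to well-connected candidates),
# and aggregation of the refined sub-communities. Aggregation preserves Q
# exactly, so Q is monotone non-decreasing across iterations.
#
# All randomness flows through R's Mersenne-Twister generator, seeded per
# run; the caller's RNG state is saved and restored.

# ---- internal graph representation -----------------------------------------
# Vertices 1..n; edges as index triples (a, b, w) with a < b and no
# self-loops; self-loop weight per vertex kept separately (arises on
# aggregate graphs only). Strength includes 2 * self-loop weight.
igr_new <- function(n, ea, eb, ew, selfw = numeric(n)) {
  k <- numeric(n)
  if (length(ea)) {
    tab <- rowsum(c(ew, ew), c(ea, eb))
    k[as.integer(rownames(tab))] <- tab[, 1]
  }
  k <- k + 2 * selfw
  adj_idx <- vector("list", n)
  adj_w <- vector("list", n)
  if (length(ea)) {
    nb_from <- c(ea, eb); nb_to <- c(eb, ea); nb_w <- c(ew, ew)
    o <- order(nb_from)
    nb_from <- nb_from[o]; nb_to <- nb_to[o]; nb_w <- nb_w[o]
    runs <- rle(nb_from)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      v <- runs$values[r]
      adj_idx[[v]] <- nb_to[starts[r]:ends[r]]
      adj_w[[v]] <- nb_w[starts[r]:ends[r]]
    }
  }
  list(n = n, ea = ea, eb = eb, ew = ew, selfw = selfw, k = k,
       m = sum(ew) + sum(selfw), adj_idx = adj_idx, adj_w = adj_w)
}

igr_from_graph <- function(g) {
  stopifnot(inherits(g, "complex_graph"))
  n <- length(g$vertices)
  ea <- match(g$edges$from, g$vertices)
  eb <- match(g$edges$to, g$vertices)
  igr_new(n, ea, eb, as.numeric(g$edges$weight))
}

# modularity on the internal representation
igr_modularity <- function(gr, memb, gamma) {
  if (gr$m == 0) return(0)
  same <- memb[gr$ea] == memb[gr$eb]
  w_in_edges <- sum(gr$ew[same])
  w_in_self <- sum(gr$selfw)
  s <- rowsum(gr$k, memb)[, 1]
  (w_in_edges + w_in_self) / gr$m - gamma * sum((s / (2 * gr$m))^2)
}

#' Generalized weighted modularity of a partition
#'
#' Computes `Q = sum_c [w_in(c)/m - gamma * (s(c)/(2m))^2]` over the modules
#' `c` of a partition: `m` is the total edge weight of the graph, `w_in(c)`
#' the summed weight of edges with both ends in `c`, and `s(c)` the summed
#' vertex strengths (weighted degrees) of `c`. `gamma` is the dimensionless
#' resolution parameter; at `gamma = 1` this is Newman-Girvan weighted
#' modularity. For an edgeless graph Q is 0 by convention.
#'
#' @param g a [complex_graph()].
#' @param partition named vector mapping every vertex label of `g` to a
#'   module id (any label type).
#' @param gamma resolution parameter, > 0.
#' @return numeric scalar.
#' @examples
#' g <- complex_graph(c("a", "b", "c", "d"),
#'                    data.frame(from = c("a", "c"), to = c("b", "d"),
#'                               weight = c(1, 1)))
#' modularity(g, c(a = 0, b = 0, c = 1, d = 1)) # 0.5
#' @export
modularity <- function(g, partition, gamma = 1) {
  stopifnot(inherits(g, "complex_graph"), gamma > 0)
  if (!all(g$vertices %in% names(partition))) {
    stop("partition must cover every vertex of the graph")
  }
  memb <- match(partition[g$vertices], unique(partition[g$vertices]))
  gr <- igr_from_graph(g)
  igr_modularity(gr, memb, gamma)
}

# ---- local movement --------------------------------------------------------
# Queue-based greedy local move: vertices visited in seeded random order;
# each is moved to the neighbouring (or empty) module with the largest
# positive dQ, ties broken uniformly at random; neighbours of a moved vertex
# re-enter the queue.
local_move <- function(gr, memb, gamma) {
  n <- gr$n
  comm_s <- numeric(n)
  cs <- rowsum(gr$k, memb)
  comm_s[as.integer(rownames(cs))] <- cs[, 1]
  queue <- sample.int(n)
  in_queue <- rep(TRUE, n)
  head <- 1L
  moved_any <- FALSE
  m <- gr$m
  eps <- 1e-12
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    in_queue[v] <- FALSE
    cv <- memb[v]
    nb <- gr$adj_idx[[v]]
    kv <- gr$k[v]
    s_old <- comm_s[cv] - kv
    if (length(nb) == 0) next
    nbc <- memb[nb]
    wsum <- rowsum(gr$adj_w[[v]], nbc)
    cand <- as.integer(rownames(wsum))
    k_to <- wsum[, 1]
    k_cur <- if (cv %in% cand) k_to[match(cv, cand)] else 0
    # candidate communities: neighbouring ones plus a fresh empty one
    empty <- which.max(comm_s == 0 & tabulate(memb, n) == 0)
    if (comm_s[empty] == 0 && !any(memb == empty)) {
      cand <- c(cand, empty)
      k_to <- c(k_to, 0)
    }
    keep <- cand != cv
    cand <- cand[keep]; k_to <- k_to[keep]
    if (length(cand) == 0) next
    dq <- (k_to - k_cur) / m -
      gamma * kv * (comm_s[cand] - ifelse(cand == cv, kv, 0) - s_old) /
        (2 * m^2)
    best <- max(dq)
    if (best <= eps) next
    ties <- which(dq >= best - eps)
    pick <- if (length(ties) == 1) ties else ties[sample.int(length(ties), 1)]
    d <- cand[pick]
    comm_s[cv] <- comm_s[cv] - kv
    comm_s[d] <- comm_s[d] + kv
    memb[v] <- d
    moved_any <- TRUE
    # re-queue neighbours now outside v's new community
    requeue <- nb[memb[nb] != d & !in_queue[nb]]
    if (length(requeue)) {
      queue <- c(queue, requeue)
      in_queue[requeue] <- TRUE
    }
  }
  list(memb = memb, moved = moved_any)
}

# ---- refinement ------------------------------------------------------------
# Within each community of partition `memb`, starting from singletons,
# still-singleton vertices that are well-connected within their community
# merge into a sub-community chosen among well-connected candidates with
# dQ >= 0, with probability proportional to exp(dQ / theta). Staying
# singleton (dQ = 0) is always a candidate.
refine <- function(gr, memb, gamma, theta) {
  n <- gr$n
  ref <- seq_len(n)                 # refined membership: singletons
  sub_s <- gr$k                     # strength per refined community
  m <- gr$m
  comm_s <- numeric(n)
  cs <- rowsum(gr$k, memb)
  comm_s[as.integer(rownames(cs))] <- cs[, 1]
  # edge weight from each vertex to the rest of its community
  k_within <- numeric(n)
  same <- memb[gr$ea] == memb[gr$eb]
  if (any(same)) {
    t1 <- rowsum(gr$ew[same], gr$ea[same])
    k_within[as.integer(rownames(t1))] <- t1[, 1]
    t2 <- rowsum(gr$ew[same], gr$eb[same])
    k_within[as.integer(rownames(t2))] <-
      k_within[as.integer(rownames(t2))] + t2[, 1]
  }
  # ext[s]: edge weight from refined community s to the rest of its parent
  ext <- k_within
  sub_size <- rep(1L, n)
  for (v in sample.int(n)) {
    if (sub_size[ref[v]] != 1L || ref[v] != v) next  # v no longer singleton
    cv <- memb[v]
    kv <- gr$k[v]
    if (k_within[v] < gamma * kv * (comm_s[cv] - kv) / (2 * m)) next
    nb <- gr$adj_idx[[v]]
    inside <- which(memb[nb] == cv)
    if (length(inside) == 0) next
    nbr_sub <- ref[nb[inside]]
    wsum <- rowsum(gr$adj_w[[v]][inside], nbr_sub)
    cand <- as.integer(rownames(wsum))
    k_to <- wsum[, 1]
    drop_self <- cand != ref[v]
    cand <- cand[drop_self]; k_to <- k_to[drop_self]
    # well-connectedness of candidate sub-communities within the parent
    ok <- ext[cand] >= gamma * sub_s[cand] * (comm_s[cv] - sub_s[cand]) / (2 * m)
    cand <- cand[ok]; k_to <- k_to[ok]
    if (length(cand) == 0) next
    dq <- k_to / m - gamma * kv * sub_s[cand] / (2 * m^2)
    keep <- dq >= -1e-12
    cand <- cand[keep]; dq <- dq[keep]
    if (length(cand) == 0) next
    # candidates plus "stay singleton" (dQ = 0)
    dq_all <- c(dq, 0) / theta
    pr <- exp(dq_all - max(dq_all))
    pick <- sample.int(length(pr), 1, prob = pr)
    if (pick > length(cand)) next   # stayed singleton
    target <- cand[pick]
    # merge v into target
    ext[target] <- ext[target] + k_within[v] - 2 * k_to[pick]
    sub_s[target] <- sub_s[target] + kv
    sub_size[target] <- sub_size[target] + sub_size[ref[v]]
    ref[v] <- target
  }
  ref
}

# ---- aggregation -----------------------------------------------------------
# Aggregate by refined membership; returns the new graph plus the vertex ->
# aggregate mapping and the induced (non-refined) membership.
aggregate_graph <- function(gr, ref, memb) {
  comm_ids <- sort(unique(ref))
  map <- match(ref, comm_ids)
  n2 <- length(comm_ids)
  selfw2 <- numeric(n2)
  if (length(gr$selfw)) {
    sw <- rowsum(gr$selfw, map)
    selfw2[as.integer(rownames(sw))] <- sw[, 1]
  }
  if (length(gr$ea)) {
    a2 <- map[gr$ea]; b2 <- map[gr$eb]
    internal <- a2 == b2
    if (any(internal)) {
      sw <- rowsum(gr$ew[internal], a2[internal])
      selfw2[as.integer(rownames(sw))] <-
        selfw2[as.integer(rownames(sw))] + sw[, 1]
    }
    aa <- pmin(a2[!internal], b2[!internal])
    bb <- pmax(a2[!internal], b2[!internal])
    ww <- gr$ew[!internal]
    if (length(aa)) {
      key <- (aa - 1) * n2 + bb
      agg <- rowsum(ww, key)
      k2 <- as.numeric(rownames(agg))
      ea2 <- as.integer((k2 - 1) %/% n2 + 1)
      eb2 <- as.integer((k2 - 1) %% n2 + 1)
      ew2 <- agg[, 1]
    } else {
      ea2 <- integer(0); eb2 <- integer(0); ew2 <- numeric(0)
    }
  } else {
    ea2 <- integer(0); eb2 <- integer(0); ew2 <- numeric(0)
  }
  memb2 <- memb[match(comm_ids, ref)]   # parent community of each aggregate
  list(graph = igr_new(n2, ea2, eb2, ew2, selfw2), map = map, memb = memb2)
}

# ---- single Leiden run -----------------------------------------------------

#' One Leiden run
#'
#' Runs a single pass of the Leiden algorithm from the singleton partition:
#' local movement (greedy best positive modularity gain, queue-based, random
#' tie-breaks), refinement (randomized merges within modules, probability
#' proportional to `exp(dQ/theta)`, restricted to well-connected
#' candidates), and aggregation (the aggregate graph starts from the
#' non-refined partition), iterated until no further improvement is
#' possible. Modularity never decreases across iterations.
#'
#' @param g a [complex_graph()].
#' @param gamma resolution parameter (> 0, default 1.0).
#' @param theta refinement randomness temperature (> 0, default 0.01).
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param check if `TRUE`, assert on every iteration that (i) modularity is
#'   non-decreasing and (ii) the aggregate graph's modularity under the
#'   induced partition equals the original graph's modularity under the
#'   flat partition (aggregation invariance). For validation; adds
#'   overhead.
#' @return named integer vector: module id (0-based, canonical) per vertex
#'   label, with attribute `"q"` holding the partition's modularity.
#' @export
leiden_once <- function(g, gamma = 1, theta = 0.01, seed = 1, check = FALSE) {
  stopifnot(inherits(g, "complex_graph"), gamma > 0, theta > 0)
  gr0 <- igr_from_graph(g)
  n0 <- gr0$n
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")

  gr <- gr0
  assign_map <- seq_len(n0)      # original vertex -> current-level vertex
  memb <- seq_len(gr$n)          # singleton partition at current level
  q_prev <- -Inf
  repeat {
    lm <- local_move(gr, memb, gamma)
    memb <- lm$memb
    flat <- memb[assign_map]
    if (check) {
      q_now <- igr_modularity(gr0, flat, gamma)
      stopifnot(q_now >= q_prev - 1e-9)
      q_prev <- q_now
    }
    if (length(unique(memb)) == gr$n) break   # every community is a vertex
    ref <- refine(gr, memb, gamma, theta)
    ag <- aggregate_graph(gr, ref, memb)
    if (ag$graph$n == gr$n) break             # refinement made no progress
    if (check) {
      q_agg <- igr_modularity(ag$graph, ag$memb, gamma)
      q_flat <- igr_modularity(gr0, memb[assign_map], gamma)
      stopifnot(abs(q_agg - q_flat) < 1e-9)
    }
    assign_map <- ag$map[assign_map]
    gr <- ag$graph
    # renumber induced membership to 1..k so it indexes level-local arrays
    memb <- match(ag$memb, unique(ag$memb))
  }
  flat <- memb[assign_map]
  p <- canonical_partition(stats::setNames(flat, g$vertices))
  attr(p, "q") <- igr_modularity(gr0, flat, gamma)
  p
}

#' Canonicalize a partition's module ids
#'
#' Renumbers modules 0..k-1 so that modules are ordered by their smallest
#' contained vertex label (C-locale lexicographic), making partitions
#' comparable across runs and platforms.
#'
#' @param partition named vector (names = vertex labels).
#' @return named integer vector with canonical 0-based module ids.
#' @export
canonical_partition <- function(partition) {
  labs <- sort_c(names(partition))
  first_seen <- unique(unname(partition[labs]))
  out <- stats::setNames(match(partition[labs], first_seen) - 1L, labs)
  out
}

#' Cluster a complex graph with the best-of-N Leiden protocol
#'
#' Performs `n_runs` independent Leiden runs with seeds `base_seed + 0 ...
#' base_seed + n_runs - 1` and keeps the partition with the highest
#' modularity (ties broken in favour of the earliest seed). Vertex
#' processing order is random per run, so independent runs explore
#' different local optima; the default protocol uses 2000 runs.
#'
#' @inheritParams leiden_once
#' @param n_runs number of independent runs (>= 1; default 2000).
#' @param base_seed seed of the first run.
#' @return object of class `clustering_result`: list with `best` (canonical
#'   partition, as in [leiden_once()]), `best_q`, `run_qs` (modularity of
#'   every run), `n_runs`, `base_seed`, `gamma`, `theta`.
#' @examples
#' pg <- generate_planted_graph(2, 4, w_in = 10, w_out = 1, p_out = 0)
#' res <- cluster_best_of(pg$graph, n_runs = 20, base_seed = 7)
#' res$best_q
#' @export
cluster_best_of <- function(g, gamma = 1, theta = 0.01, n_runs = 2000,
                            base_seed = 1, check = FALSE) {
  stopifnot(n_runs >= 1)
  run_qs <- numeric(n_runs)
  best <- NULL
  best_q <- -Inf
  for (i in seq_len(n_runs)) {
    p <- leiden_once(g, gamma = gamma, theta = theta,
                     seed = base_seed + i - 1, check = check)
    q <- attr(p, "q")
    run_qs[i] <- q
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  attr(best, "q") <- NULL   # best_q carries the value

  structure(
    list(best = best, best_q = best_q, run_qs = run_qs, n_runs = n_runs,
         base_seed = base_seed, gamma = gamma, theta = theta),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  k <- length(unique(x$best))
  cat(sprintf(
    "clustering_result: %d modules, best Q = %.6f (gamma = %g, %d runs, base seed %d)\n",
    k, x$best_q, x$gamma, x$n_runs, x$base_seed
  ))
  cat(sprintf("run Q: min %.6f / median %.6f / max %.6f\n",
              min(x$run_qs), stats::median(x$run_qs), max(x$run_qs)))
  invisible(x)
}

#' Exhaustive modularity maximization (test oracle)
#'
#' Enumerates every set partition of the vertex set (restricted-growth-
#' string enumeration over vertices in sorted label order) and returns the
#' global modularity maximizer; on ties, the lexicographically smallest
#' canonical form wins. Guarded to graphs with at most 10 vertices
#' (Bell(10) = 115975 partitions).
#'
#' @inheritParams modularity
#' @return named integer vector (canonical partition) with attribute `"q"`.
#' @export
exhaustive_best_partition <- function(g, gamma = 1) {
  stopifnot(inherits(g, "complex_graph"))
  n <- length(g$vertices)
  if (n > 10) stop("exhaustive enumeration is limited to 10 vertices")
  gr <- igr_from_graph(g)
  m <- gr$m
  if (m == 0) {
    # every partition of an edgeless graph scores 0; return singletons, the
    # same resolution of the tie that a Leiden run reaches
    out <- stats::setNames(seq_len(n) - 1L, sort_c(g$vertices))
    attr(out, "q") <- 0
    return(out)
  }
  P <- rgs_enumerate(n)           # partitions x n matrix of 0-based ids
  {
    w_in <- numeric(nrow(P))
    for (e in seq_along(gr$ea)) {
      w_in <- w_in + gr$ew[e] * (P[, gr$ea[e]] == P[, gr$eb[e]])
    }
    pen <- numeric(nrow(P))
    for (u in seq_len(n)) {
      pen <- pen + gr$k[u]^2      # same-module u,u term
      if (u < n) for (v in (u + 1):n) {
        pen <- pen + 2 * gr$k[u] * gr$k[v] * (P[, u] == P[, v])
      }
    }
    qs <- w_in / m - gamma * pen / (4 * m^2)
    best_i <- which.max(qs)       # first maximum = lex-smallest RGS
    best <- P[best_i, ]
    q <- qs[best_i]
  }
  out <- stats::setNames(as.integer(best), sort_c(g$vertices))
  attr(out, "q") <- q
  out
}

# all restricted growth strings of length n (0-based), in lexicographic
# order; each row is the canonical form of one set partition; cached per n
.rgs_cache <- new.env(parent = emptyenv())

rgs_enumerate <- function(n) {
  key <- as.character(n)
  if (!is.null(.rgs_cache[[key]])) return(.rgs_cache[[key]])
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 1024L)
  acc$cnt <- 0L
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      acc$cnt <- acc$cnt + 1L
      if (acc$cnt > length(acc$rows)) {
        acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
      }
      acc$rows[[acc$cnt]] <- prefix
      return()
    }
    for (v in 0:(maxv + 1L)) {
      rec(c(prefix, v), max(maxv, v))
    }
  }
  rec(integer(0), -1L)
  out <- do.call(rbind, acc$rows[seq_len(acc$cnt)])
  .rgs_cache[[key]] <- out
  out
}

# ---- partition file I/O ----------------------------------------------------

#' Write a partition file
#'
#' Two-column TSV `chain_id<TAB>module_id`, sorted by chain ID, preceded by
#' a `# Q=<value> gamma=<value> runs=<n> seed=<s>` comment header.
#'
#' @param partition named module assignment (names = chain IDs).
#' @param path output path.
#' @param q,gamma,runs,seed header metadata.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, q = NA, gamma = NA, runs = NA,
                            seed = NA) {
  labs <- sort_c(names(partition))
  lines <- c(
    sprintf("# Q=%s gamma=%s runs=%s seed=%s",
            format(q, digits = 15), format(gamma), format(runs), format(seed)),
    "chain_id\tmodule_id",
    sprintf("%s\t%s", labs, partition[labs])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a partition file
#'
#' @param path a file written by [write_partition()].
#' @return named vector of module ids with attributes `q`, `gamma`, `runs`,
#'   `seed` when present in the header.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("partition file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = c("character", "character"))
  vals <- suppressWarnings(as.integer(df$module_id))
  p <- stats::setNames(if (any(is.na(vals))) df$module_id else vals,
                       df$chain_id)
  if (length(hdr) > 0) {
    keys <- c(q = "Q", gamma = "gamma", runs = "runs", seed = "seed")
    for (a in names(keys)) {
      mm <- regmatches(hdr[1], regexec(paste0(keys[a], "=([^ ]+)"), hdr[1]))[[1]]
      if (length(mm) == 2) attr(p, a) <- suppressWarnings(as.numeric(mm[2]))
    }
  }
  p
}
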
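# Proportional thresholding and graph metrics, implemented directly on
# adjacency matrices (no graph library): participation coefficient, local
# and global efficiency, Louvain modularity.

# round-half-away-from-zero, the toolbox convention for round(p * K)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Proportional (density) thresholding of a connectivity matrix
#'
#' Retains the strongest positive Fisher-z edges at a fixed edge density.
#' Candidate edges are the unmasked, strictly positive off-diagonal cells;
#' the retained count is `round(density * K)` where `K` is the number of
#' unmasked off-diagonal unordered pairs (round-half-away-from-zero). Ties
#' at the retention boundary are broken by node-pair lexicographic order so
#' edge sets are bit-reproducible. Negative correlations are never retained.
#'
#' @param C A `connectivity_matrix`.
#' @param density Proportion of valid pairs to keep, in (0, 1]. The default
#'   analysis grid is `seq(0.02, 0.10, by = 0.01)`.
#' @param mode `"weighted"` (default; retained edges keep their z weight) or
#'   `"binary"` (retained edges set to 1).
#' @return A `thresholded_graph` with fields `adjacency` (N x N, zero
#'   diagonal), `mode`, `density`, `n_edges`, `node_ids`.
#' @export
proportional_threshold <- function(C, density,
                                   mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(C, "connectivity_matrix"))
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  z <- C$z
  n <- nrow(z)
  ut <- upper.tri(z)
  valid <- ut & !C$mask
  k_valid <- sum(valid)
  cand <- which(valid & z > 0)
  want <- as.integer(.round_half_away(density * k_valid))
  w <- z[cand]
  ij <- arrayInd(cand, dim(z))
  ord <- order(-w, ij[, 1], ij[, 2])
  if (length(cand) < want) {
    warning(sprintf("only %d positive candidate edges for %d requested; keeping all",
                    length(cand), want))
    want <- length(cand)
  }
  keep <- cand[ord[seq_len(want)]]
  adj <- matrix(0, n, n, dimnames = dimnames(z))
  adj[keep] <- if (mode == "binary") 1 else z[keep]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, mode = mode, density = density,
                 n_edges = want, node_ids = C$node_ids),
            class = "thresholded_graph")
}

#' Build a thresholded graph directly from an adjacency matrix
#'
#' Mainly for tests and toy examples; `adjacency` must be symmetric,
#' nonnegative, zero-diagonal.
#'
#' @param adjacency Symmetric numeric matrix.
#' @param mode `"weighted"` or `"binary"`.
#' @param node_ids Node ids (default `1:N`).
#' @return A `thresholded_graph`.
#' @export
as_thresholded_graph <- function(adjacency, mode = c("weighted", "binary"),
                                 node_ids = NULL) {
  mode <- match.arg(mode)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  stopifnot(ncol(adjacency) == n, all(adjacency >= 0),
            isTRUE(all.equal(adjacency, t(adjacency))),
            all(diag(adjacency) == 0))
  if (is.null(node_ids)) node_ids <- seq_len(n)
  structure(list(adjacency = adjacency, mode = mode, density = NA_real_,
                 n_edges = sum(adjacency[upper.tri(adjacency)] > 0),
                 node_ids = as.integer(node_ids)),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("thresholded_graph: %d nodes, %d edges (%s, density %s)\n",
              nrow(x$adjacency), x$n_edges, x$mode,
              ifelse(is.na(x$density), "-", format(x$density))))
  invisible(x)
}

#' Participation coefficient
#'
#' PC_i = 1 - sum_s (k_is / k_i)^2, where k_i is node strength (weighted
#' mode) or degree (binary mode) and k_is the part of it landing in module
#' s. Modules are the fixed atlas partition, not detected communities. A
#' node with k_i = 0 has PC 0. High PC = connectivity spread across foreign
#' networks; PC = 0 = all edges within the node's own module.
#'
#' @param G A `thresholded_graph`.
#' @param P A `network_partition` covering every graph node.
#' @return Named numeric vector of per-node PC values in [0, 1].
#' @export
participation_coefficient <- function(G, P) {
  stopifnot(inherits(G, "thresholded_graph"))
  pos <- match(G$node_ids, P$roi_id)
  if (anyNA(pos)) stop("graph node missing from partition")
  modules <- P$network[pos]
  A <- G$adjacency
  k <- rowSums(A)
  # k_is: strength of node i into module s
  kis <- t(rowsum(t(A), group = modules))
  pc <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, .Machine$double.eps))^2), 0)
  pc[k == 0] <- 0
  pc <- pmin(pmax(pc, 0), 1)   # guard fp drift at the 0 and 1 boundaries
  stats::setNames(as.numeric(pc), G$node_ids)
}

# all-pairs shortest path lengths; len = edge length matrix (Inf = absent)
.fw_distances <- function(len) .fw_distances_cpp(len)

# edge length convention: binary hop count; weighted 1/w
.edge_lengths <- function(G) {
  A <- G$adjacency
  len <- ifelse(A > 0, if (G$mode == "binary") 1 else 1 / A, Inf)
  diag(len) <- Inf
  len
}

.efficiency_from_adj <- function(A, mode) {
  n <- nrow(A)
  if (n < 2L) return(0)
  len <- ifelse(A > 0, if (mode == "binary") 1 else 1 / A, Inf)
  diag(len) <- Inf
  d <- .fw_distances(len)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all unordered node pairs.
#' Path lengths use hop counts in binary mode and edge lengths 1/weight in
#' weighted mode; disconnected pairs contribute 0. Empty graphs return 0.
#'
#' @param G A `thresholded_graph`.
#' @return Scalar efficiency (in [0, 1] for binary graphs).
#' @export
global_efficiency <- function(G) {
  stopifnot(inherits(G, "thresholded_graph"))
  .efficiency_from_adj(G$adjacency, G$mode)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (the node itself excluded). Nodes with fewer than two
#' neighbors score 0.
#'
#' @param G A `thresholded_graph`.
#' @return Named numeric vector of per-node local efficiencies.
#' @export
local_efficiency <- function(G) {
  stopifnot(inherits(G, "thresholded_graph"))
  A <- G$adjacency
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) next
    out[i] <- .efficiency_from_adj(A[nb, nb, drop = FALSE], G$mode)
  }
  stats::setNames(out, G$node_ids)
}

#' Newman modularity Q of a fixed partition
#'
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j), with
#' 2m = sum(A) and k the (weighted) degree. Q of a single all-in-one
#' community is 0 by construction.
#'
#' @param G A `thresholded_graph` with at least one edge.
#' @param membership Community labels, one per node (any atomic type).
#' @return Scalar Q in [-0.5, 1].
#' @export
evaluate_q <- function(G, membership) {
  stopifnot(inherits(G, "thresholded_graph"))
  .q_of(G$adjacency, as.integer(factor(membership)))
}

# Q on a raw adjacency (diagonal self-loop weights allowed; they count once
# per the aggregation convention B[c,c] = sum over both orders)
.q_of <- function(A, comm) {
  S <- sum(A)
  if (S <= 0) stop("modularity undefined on an edgeless graph")
  k <- rowSums(A)
  same <- outer(comm, comm, "==")
  sum((A - outer(k, k) / S)[same]) / S
}

# one Louvain level: local node moves until no gain; returns membership.
# Node order randomized once per phase (seeded upstream); moves implemented
# in compiled code.
.louvain_moves <- function(A) {
  .louvain_move_phase_cpp(A, sample.int(nrow(A)))
}

# full Louvain: move phase + aggregation until Q stops improving
.louvain_once <- function(A) {
  n0 <- nrow(A)
  assign_full <- seq_len(n0)
  B <- A
  q_prev <- -Inf
  repeat {
    comm <- .louvain_moves(B)
    comm <- as.integer(factor(comm))
    assign_full <- comm[assign_full]
    q_now <- .q_of(A, assign_full)
    if (q_now <= q_prev + 1e-12) break
    q_prev <- q_now
    # aggregate: B[c,d] = sum over both orders of member cells
    M <- outer(comm, sort(unique(comm)), "==") * 1
    B <- t(M) %*% B %*% M
    if (nrow(B) == n0) break
    n0 <- nrow(B)
    assign_full <- as.integer(factor(assign_full))
  }
  list(membership = as.integer(factor(assign_full)), q = .q_of(A, assign_full))
}

#' Louvain modularity maximization
#'
#' Greedy multi-level (Louvain) maximization of Newman Q on the weighted
#' thresholded graph. The node visiting order is randomized, so the search
#' is repeated `n_restarts` times with seeds `seed .. seed + n_restarts - 1`
#' and the best-Q partition kept; the result is deterministic given
#' `(seed, n_restarts)`. Community labels are canonicalized so community 1
#' contains the smallest node index.
#'
#' @param G A `thresholded_graph` with at least one edge.
#' @param seed Integer base seed.
#' @param n_restarts Number of randomized restarts (default 10).
#' @return List of class `modularity_result`: `q`, `membership` (named by
#'   node id), `n_communities`, `seed`, `n_restarts`, plus
#'   `global_efficiency` slot left `NULL` (filled by [graph_metrics()]).
#' @export
modularity_louvain <- function(G, seed = 1L, n_restarts = 10L) {
  stopifnot(inherits(G, "thresholded_graph"))
  A <- G$adjacency
  if (sum(A) <= 0) stop("modularity undefined on an edgeless graph")
  best <- NULL
  for (s in seq_len(n_restarts)) {
    res <- .with_seed(as.integer(seed) + s - 1L, .louvain_once(A))
    if (is.null(best) || res$q > best$q + 1e-15) best <- res
  }
  # canonical labels: order communities by their smallest member
  memb <- best$membership
  first <- tapply(seq_along(memb), memb, min)
  relabel <- rank(first, ties.method = "first")
  memb <- as.integer(relabel[as.character(memb)])
  structure(list(q = best$q,
                 membership = stats::setNames(memb, G$node_ids),
                 n_communities = length(unique(memb)),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts)),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("modularity: Q = %.4f in %d communities (seed %d, %d restarts)\n",
              x$q, x$n_communities, x$seed, x$n_restarts))
  invisible(x)
}

#' Average nodal metric values by network
#'
#' @param values Named numeric vector of per-node values (names = ROI ids).
#' @param P A `network_partition`; every partition node must have a value.
#' @return Named numeric vector of unweighted per-network means (`NA` for
#'   empty networks).
#' @export
network_average_nodal <- function(values, P) {
  pos <- match(P$roi_id, as.integer(names(values)))
  if (anyNA(pos)) stop("missing nodal value for partition node(s): ",
                       paste(P$roi_id[is.na(pos)], collapse = ", "))
  v <- values[pos]
  vapply(P$networks, function(k) {
    sel <- P$network == k
    if (!any(sel)) NA_real_ else mean(v[sel])
  }, numeric(1))
}

#' All graph metrics across the density grid
#'
#' Convenience driver: thresholds a connectivity matrix at each density and
#' computes participation coefficient, local efficiency (nodal, plus
#' network means), modularity Q and global efficiency.
#'
#' @param C A `connectivity_matrix`.
#' @param P A `network_partition`.
#' @param densities Density grid (default 2-10% in 1% steps).
#' @param mode `"weighted"` or `"binary"`.
#' @param seed Seed for Louvain restarts.
#' @param n_restarts Louvain restarts per density.
#' @return List with data frames `nodal` (node, density, mode, pc, le),
#'   `network` (network, density, metric, value) and `global`
#'   (density, mode, q, eglob).
#' @export
graph_metrics <- function(C, P, densities = seq(0.02, 0.10, by = 0.01),
                          mode = c("weighted", "binary"), seed = 1L,
                          n_restarts = 10L) {
  mode <- match.arg(mode)
  nodal <- list(); netm <- list(); glob <- list()
  for (d in densities) {
    G <- proportional_threshold(C, d, mode = mode)
    pc <- participation_coefficient(G, P)
    le <- local_efficiency(G)
    mod <- modularity_louvain(G, seed = seed, n_restarts = n_restarts)
    eg <- global_efficiency(G)
    key <- format(d)
    nodal[[key]] <- data.frame(node = G$node_ids, density = d, mode = mode,
                               pc = as.numeric(pc), le = as.numeric(le))
    pc_net <- network_average_nodal(pc, P)
    le_net <- network_average_nodal(le, P)
    netm[[key]] <- data.frame(network = rep(P$networks, 2L), density = d,
                              metric = rep(c("pc", "le"),
                                           each = length(P$networks)),
                              value = c(pc_net, le_net))
    glob[[key]] <- data.frame(density = d, mode = mode, q = mod$q, eglob = eg)
  }
  list(nodal = do.call(rbind, c(nodal, make.row.names = FALSE)),
       network = do.call(rbind, c(netm, make.row.names = FALSE)),
       global = do.call(rbind, c(glob, make.row.names = FALSE)))
}
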
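# Independent oracles and toy builders shared across the suite.
# Graph oracles go through igraph so they share no code with the package's
# adjacency-matrix implementations.

# random symmetric weighted adjacency with edge probability p
random_adjacency <- function(n, p = 0.4, weighted = TRUE) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- ut[stats::runif(length(ut)) < p]
  A[on] <- if (weighted) stats::runif(length(on), 0.1, 1) else 1
  A + t(A)
}

.oracle_igraph <- function(A, mode) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  w <- igraph::E(g)$weight
  list(g = g, lengths = if (mode == "binary") rep(1, length(w)) else 1 / w)
}

oracle_eglob <- function(A, mode = "weighted") {
  n <- nrow(A)
  if (n < 2L) return(0)
  o <- .oracle_igraph(A, mode)
  d <- igraph::distances(o$g, weights = o$lengths)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_local_efficiency <- function(A, mode = "weighted") {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    oracle_eglob(A[nb, nb, drop = FALSE], mode)
  }, numeric(1))
}

# direct double-loop participation coefficient
oracle_pc <- function(A, modules, mode = "weighted") {
  if (mode == "binary") A <- (A > 0) * 1
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    if (ki == 0) return(0)
    s <- 0
    for (m in unique(modules)) s <- s + (sum(A[i, modules == m]) / ki)^2
    1 - s
  }, numeric(1))
}

oracle_q <- function(A, membership) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_q <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) oracle_q(A, p), numeric(1)))
}

# tiny two-network connectivity toy: nets A = {1,2}, B = {3,4}
toy_connectivity <- function(z12 = 0.4, z34 = 0.2, zcross = 0.1) {
  z <- matrix(zcross, 4, 4)
  z[1, 2] <- z[2, 1] <- z12
  z[3, 4] <- z[4, 3] <- z34
  diag(z) <- 0
  apply_masks(z)
}

toy_partition <- function(networks = c("DMN", "DMN", "FP", "FP"),
                          roi_id = seq_along(networks)) {
  structure(list(roi_id = as.integer(roi_id), network = networks,
                 networks = unique(networks),
                 sizes = table(networks)[unique(networks)]),
            class = "network_partition")
}

# atlas data frame -> roi_atlas via a temp file round trip (exercises IO)
write_atlas_df <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
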
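test_that("proportional threshold keeps the strongest positive edges", {
  # 4 nodes, weights {.9,.8,.7,.3,.2,.1}, density 1/3 -> keep {.9,.8}
  z <- matrix(0, 4, 4)
  w <- c(.9, .8, .7, .3, .2, .1)
  z[upper.tri(z)] <- w
  z <- z + t(z)
  C <- apply_masks(z)
  G <- proportional_threshold(C, 1 / 3)
  kept <- sort(G$adjacency[upper.tri(G$adjacency)], decreasing = TRUE)
  expect_equal(G$n_edges, 2L)
  expect_equal(kept[1:2], c(.9, .8))
  expect_true(all(kept[-(1:2)] == 0))

  # density 1: every unmasked positive edge kept
  Gall <- proportional_threshold(C, 1)
  expect_equal(Gall$n_edges, 6L)

  # strongly negative cells are never retained
  z2 <- z
  z2[1, 4] <- z2[4, 1] <- -0.95
  expect_warning(G2 <- proportional_threshold(apply_masks(z2), 1),
                 "keeping all")
  expect_equal(G2$adjacency[1, 4], 0)
  expect_error(proportional_threshold(C, 0), "density")
})

test_that("thresholding: binary mode, masked pairs, sort-oracle equivalence", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 10
    z <- matrix(rnorm(n * n, 0.1, 0.4), n, n); z <- (z + t(z)) / 2
    diag(z) <- 0
    pr <- cbind(1L, 2L)
    C <- apply_masks(z, pairs = pr)
    dens <- sample(c(0.1, 0.25, 0.5), 1)
    G <- suppressWarnings(proportional_threshold(C, dens))
    # sort oracle on the candidate list
    k_valid <- n * (n - 1) / 2 - 1  # one masked pair
    want <- floor(dens * k_valid + 0.5)
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (!(i == 1 && j == 2) && z[i, j] > 0) vals <- c(vals, z[i, j])
    want <- min(want, length(vals))
    expect_equal(G$n_edges, want)
    if (want > 0)
      expect_equal(sort(G$adjacency[upper.tri(G$adjacency)],
                        decreasing = TRUE)[seq_len(want)],
                   sort(vals, decreasing = TRUE)[seq_len(want)])
    expect_equal(G$adjacency[1, 2], 0)  # masked pair never retained
    Gb <- suppressWarnings(proportional_threshold(C, dens, mode = "binary"))
    expect_true(all(Gb$adjacency %in% c(0, 1)))
    expect_equal(sum(Gb$adjacency > 0) / 2, want)
  }
})

test_that("participation coefficient: closed forms", {
  # all edges inside own module -> 0
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  G <- as_thresholded_graph(A, "binary")
  P <- toy_partition()
  expect_equal(unname(participation_coefficient(G, P)), rep(0, 4))

  # degree 4, 2 edges to each of 2 modules -> 0.5
  A2 <- matrix(0, 5, 5)
  A2[1, 2:5] <- A2[2:5, 1] <- 1
  G2 <- as_thresholded_graph(A2, "binary")
  P2 <- toy_partition(c("DMN", "DMN", "DMN", "FP", "FP"))
  expect_equal(unname(participation_coefficient(G2, P2)[1]), 0.5)

  # edges spread evenly over m modules -> 1 - 1/m
  m <- 3
  A3 <- matrix(0, 7, 7)
  A3[1, 2:7] <- A3[2:7, 1] <- 1
  P3 <- toy_partition(c("DMN", "DMN", "DMN", "FP", "FP", "Vis", "Vis"))
  pc <- participation_coefficient(as_thresholded_graph(A3, "binary"), P3)
  expect_equal(unname(pc[1]), 1 - 1 / m)

  # isolated node -> 0
  A4 <- matrix(0, 4, 4)
  A4[1, 2] <- A4[2, 1] <- 1
  pc4 <- participation_coefficient(as_thresholded_graph(A4, "binary"), P)
  expect_equal(unname(pc4[3]), 0)
})

test_that("global efficiency: closed forms", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(as_thresholded_graph(K4, "binary")), 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(as_thresholded_graph(path3, "binary")),
               (1 + 1 + 0.5) / 3)

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(as_thresholded_graph(empty, "binary")), 0)
})

test_that("local efficiency: closed forms", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(unname(local_efficiency(as_thresholded_graph(K3, "binary"))),
               rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  le <- local_efficiency(as_thresholded_graph(star, "binary"))
  expect_equal(unname(le[1]), 0)  # hub neighborhood is edgeless
})

test_that("PC, Eglob, LE match independent oracles on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    mode <- sample(c("weighted", "binary"), 1)
    A <- random_adjacency(n, p = 0.4, weighted = (mode == "weighted"))
    G <- as_thresholded_graph(A, mode)
    modules <- sample(c("DMN", "FP", "Vis"), n, replace = TRUE)
    P <- toy_partition(modules)
    expect_equal(unname(participation_coefficient(G, P)),
                 oracle_pc(A, modules, mode), tolerance = 1e-9)
    expect_equal(global_efficiency(G), oracle_eglob(A, mode),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(G)),
                 oracle_local_efficiency(A, mode), tolerance = 1e-9)
  }
})

test_that("binary metrics equal weighted metrics on unit-weight graphs", {
  set.seed(13)
  for (rep in 1:5) {
    A <- random_adjacency(8, p = 0.5, weighted = FALSE)
    Gw <- as_thresholded_graph(A, "weighted")
    Gb <- as_thresholded_graph(A, "binary")
    expect_equal(global_efficiency(Gw), global_efficiency(Gb))
    expect_equal(local_efficiency(Gw), local_efficiency(Gb))
  }
})

test_that("binary Eglob is monotone in density for nested graphs", {
  set.seed(31)
  z <- matrix(rnorm(30 * 30, 0.2, 0.3), 30, 30); z <- (z + t(z)) / 2
  diag(z) <- 0
  C <- apply_masks(z)
  eg <- vapply(seq(0.05, 0.5, by = 0.05), function(d)
    global_efficiency(proportional_threshold(C, d, mode = "binary")),
    numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("PC is invariant to global weight rescaling", {
  set.seed(17)
  A <- random_adjacency(10, p = 0.5, weighted = TRUE)
  P <- toy_partition(sample(c("DMN", "FP"), 10, replace = TRUE))
  pc1 <- participation_coefficient(as_thresholded_graph(A, "weighted"), P)
  pc2 <- participation_coefficient(as_thresholded_graph(5 * A, "weighted"), P)
  expect_equal(pc1, pc2, tolerance = 1e-12)
})

test_that("evaluate_q: closed forms and oracle equivalence", {
  # single community -> 0
  A <- random_adjacency(6, p = 0.6)
  G <- as_thresholded_graph(A, "weighted")
  expect_equal(evaluate_q(G, rep(1, 6)), 0, tolerance = 1e-12)

  # two disjoint K3s, partition = components -> Q = 0.5
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  two <- rbind(cbind(K3, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), K3))
  G2 <- as_thresholded_graph(two, "binary")
  expect_equal(evaluate_q(G2, rep(1:2, each = 3)), 0.5)

  # random partitions match the igraph modularity oracle
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    A <- random_adjacency(n, p = 0.5)
    if (sum(A) == 0) next
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(evaluate_q(as_thresholded_graph(A, "weighted"), memb),
                 oracle_q(A, memb), tolerance = 1e-9)
  }
})

test_that("louvain finds the exhaustive-best partition on small graphs", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, p = 0.5,
                          weighted = sample(c(TRUE, FALSE), 1))
    if (sum(A) == 0) next
    G <- as_thresholded_graph(A, "weighted")
    res <- modularity_louvain(G, seed = rep, n_restarts = 10)
    best <- oracle_best_q(A)
    expect_equal(res$q, best, tolerance = 1e-9)
  }
  # determinism given (seed, n_restarts)
  A <- random_adjacency(10, p = 0.4)
  G <- as_thresholded_graph(A, "weighted")
  r1 <- modularity_louvain(G, seed = 3, n_restarts = 5)
  r2 <- modularity_louvain(G, seed = 3, n_restarts = 5)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$q, r2$q)
  # labels canonical: community 1 holds node 1
  expect_equal(unname(r1$membership[1]), 1L)
  expect_error(modularity_louvain(as_thresholded_graph(matrix(0, 3, 3),
                                                       "binary")),
               "edgeless")
})

test_that("network_average_nodal averages correctly and is order invariant", {
  P <- toy_partition(c("DMN", "DMN", "FP", "FP"))
  vals <- c(`1` = 1, `2` = 3, `3` = 10, `4` = 20)
  avg <- network_average_nodal(vals, P)
  expect_equal(unname(avg), c(2, 15))
  # constant values -> every network mean equal
  const <- stats::setNames(rep(7, 4), 1:4)
  expect_equal(unname(network_average_nodal(const, P)), c(7, 7))
  # permuted input order
  expect_equal(network_average_nodal(vals[c(3, 1, 4, 2)], P), avg)
  expect_error(network_average_nodal(vals[1:3], P), "missing nodal value")
})

test_that("full metric grid on a 214-ROI subject runs within budget", {
  cfg <- simulation_config(n_per_group = 1L, t_volumes = 150L, seed = 2L)
  coh <- simulate_cohort(cfg)
  P <- partition_from_config(cfg)
  C <- connectivity_from_timeseries(coh$timeseries[[1]])
  elapsed <- system.time(
    gm <- graph_metrics(C, P, seed = 1L)
  )[["elapsed"]]
  expect_lt(elapsed, 5)
  expect_equal(nrow(gm$global), 9L)
  expect_true(all(gm$global$q >= -0.5 & gm$global$q <= 1))
  expect_true(all(gm$nodal$pc >= 0 & gm$nodal$pc <= 1 + 1e-12))
  expect_true(all(gm$nodal$le >= 0))
})
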
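complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

test_that("network strength matches its closed forms", {
  expect_equal(network_strength(matrix(0, 5, 5)), 0)
  W <- matrix(0.5, 3, 3)
  diag(W) <- 0
  expect_equal(network_strength(W), 1.0)
  n <- 7
  W1 <- matrix(1, n, n)
  diag(W1) <- 0
  expect_equal(network_strength(W1), n - 1)
})

test_that("global efficiency matches closed forms and the convention for unreachable pairs", {
  expect_equal(global_efficiency(complete_graph(6)), 1.0)
  expect_equal(global_efficiency(matrix(0L, 5, 5)), 0.0)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  # two disconnected dyads: 4 reachable ordered pairs of 12
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(global_efficiency(A), 4 / 12)
})

test_that("local efficiency matches direct evaluation on canonical graphs", {
  expect_equal(local_efficiency(complete_graph(3)), 1.0)  # triangle
  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  expect_equal(local_efficiency(star), 0.0)
  expect_equal(local_efficiency(matrix(0L, 6, 6)), 0.0)
})

test_that("clustering and path length match enumeration", {
  tri <- clustering_and_pathlength(complete_graph(3))
  expect_equal(tri$C, 1)
  expect_equal(tri$L, 1)
  p3 <- clustering_and_pathlength(path_graph(3))
  expect_equal(p3$C, 0)
  expect_equal(p3$L, 4 / 3)
  kn <- clustering_and_pathlength(complete_graph(8))
  expect_equal(kn$C, 1)
  expect_equal(kn$L, 1)
  expect_error(clustering_and_pathlength(matrix(0L, 3, 3)),
               "no connected pair")
})

test_that("modularity recovers planted components and respects the Q formula", {
  # two disjoint 4-cliques: component partition has Q = 0.5
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  res <- modularity_q(A, seed = 1)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$membership[1:4])), 1)
  expect_equal(length(unique(res$membership[5:8])), 1)
  expect_false(res$membership[1] == res$membership[5])
  expect_equal(oracle_modularity(A, res$membership), 0.5,
               tolerance = 1e-12)

  # complete graph: single community, Q = 0
  resk <- modularity_q(complete_graph(6), seed = 1)
  expect_equal(resk$Q, 0, tolerance = 1e-12)

  expect_error(modularity_q(matrix(0L, 4, 4)), "edgeless")
})

test_that("the detected partition never loses to the trivial one and matches the brute-force Q", {
  set.seed(31)
  for (rep in 1:25) {
    A <- random_adjacency(sample(4:9, 1), stats::runif(1, 0.3, 0.8))
    if (sum(A) == 0) next
    res <- suppressWarnings(modularity_q(A, seed = rep))
    expect_gte(res$Q, 0 - 1e-12)
    expect_equal(res$Q, oracle_modularity(A, res$membership),
                 tolerance = 1e-12)
  }
})

test_that("leading-eigenvector partitions are near-optimal on tiny graphs", {
  # exhaustive maximum over all partitions of <= 6 nodes
  set.seed(32)
  for (rep in 1:8) {
    A <- random_adjacency(6, stats::runif(1, 0.4, 0.8))
    if (sum(A) == 0) next
    res <- suppressWarnings(modularity_q(A, seed = rep))
    qmax <- max(vapply(oracle_all_partitions(6), function(p)
      oracle_modularity(A, p), numeric(1)))
    # spectral detection is a heuristic: demand near-optimality
    expect_gte(res$Q, qmax - 0.15)
    expect_lte(res$Q, qmax + 1e-12)
  }
})

test_that("small-worldness behaves at its fixed points and is deterministic", {
  # complete graphs cannot be rewired: sigma exactly 1
  expect_equal(small_worldness(complete_graph(10), ensemble = 10,
                               seed = 3), 1)
  # ring lattice in the small-world regime
  rl <- ring_lattice(47, 10)
  sig <- vapply(1:10, function(s)
    small_worldness(rl, ensemble = 10, seed = s), numeric(1))
  expect_gte(mean(sig > 1), 0.95)
  # determinism
  A <- ring_lattice(30, 6)
  expect_identical(small_worldness(A, ensemble = 15, seed = 11),
                   small_worldness(A, ensemble = 15, seed = 11))
  expect_false(identical(small_worldness(A, ensemble = 15, seed = 11),
                         small_worldness(A, ensemble = 15, seed = 12)))
})

test_that("degree-preserving rewiring preserves the degree sequence", {
  set.seed(33)
  for (rep in 1:5) {
    A <- random_adjacency(20, 0.3)
    B <- cognectome:::cpp_rewire_adj(A, 10)
    expect_equal(rowSums(B), rowSums(A))
    expect_true(all(diag(B) == 0))
    expect_equal(B, t(B))
  }
})

test_that("all measures are invariant under node relabeling", {
  set.seed(34)
  A <- random_adjacency(15, 0.4)
  p <- sample(15)
  B <- A[p, p]
  expect_equal(global_efficiency(A), global_efficiency(B),
               tolerance = 1e-12)
  expect_equal(local_efficiency(A), local_efficiency(B),
               tolerance = 1e-12)
  ca <- clustering_and_pathlength(A)
  cb <- clustering_and_pathlength(B)
  expect_equal(ca$C, cb$C, tolerance = 1e-12)
  expect_equal(ca$L, cb$L, tolerance = 1e-12)
})

test_that("kernel measures agree with the plain-R oracles on random graphs", {
  set.seed(35)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, stats::runif(1, 0.15, 0.9))
    expect_equal(global_efficiency(A), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_local_efficiency(A),
                 tolerance = 1e-12)
    st <- cognectome:::cpp_adj_stats(A, FALSE)
    expect_equal(st[["clustering"]], oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(st[["path_length"]], oracle_path_length(A),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency is monotone along a nested density stack", {
  pp <- tiny_preprocessed(seed = 36, n_per_group = 15)
  conn <- build_connectome(
    group_scores(pp$dataset, pp$stratification, "LMA_low"))
  mc <- measure_curve(conn, "global_efficiency")
  expect_true(all(diff(mc$values) >= -1e-12))
})

test_that("measure curves carry the right shape and tidy export", {
  pp <- tiny_preprocessed(seed = 37, n_per_group = 12)
  conn <- build_connectome(
    group_scores(pp$dataset, pp$stratification, "EMA_low"), "EMA_low")
  for (m in c("global_efficiency", "local_efficiency", "modularity")) {
    mc <- measure_curve(conn, m)
    expect_equal(length(mc$values), 41)
    expect_true(all(is.finite(mc$values)))
    df <- as.data.frame(mc)
    expect_equal(nrow(df), 41)
    expect_equal(unique(df$measure), m)
  }
  ms <- measure_curve(conn, "strength")
  expect_null(ms$densities)
  expect_length(ms$values, 1)
  expect_equal(ms$values, network_strength(conn))
  # bounds
  mg <- measure_curve(conn, "global_efficiency")
  expect_true(all(mg$values >= 0 & mg$values <= 1))
  ml <- measure_curve(conn, "local_efficiency")
  expect_true(all(ml$values >= 0 & ml$values <= 1))
  mq <- measure_curve(conn, "modularity")
  expect_true(all(mq$values >= -0.5 & mq$values <= 1))
})
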
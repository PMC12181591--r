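test_that("connectome weights are clipped Pearson correlations", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
             c = c(4, 3, 2, 1), d = c(1, 2, 4, 3))
  conn <- build_connectome(X)
  W <- conn$weights
  expect_equal(W["a", "b"], 1.0)            # identical columns
  expect_equal(W["a", "c"], 0.0)            # x vs -x removed
  expect_true(all(diag(W) == 0))
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
})

test_that("a hand-computed correlation survives the pipeline", {
  X <- cbind(u = c(1, 2, 3), v = c(1, 2, 4), w = c(2, 1, 3))
  conn <- build_connectome(X)
  expect_equal(conn$weights["u", "v"], 0.9819805061, tolerance = 1e-9)
})

test_that("constant within-group variables raise a named error", {
  X <- matrix(stats::rnorm(12), 4)
  X[, 2] <- 5
  colnames(X) <- c("x", "y", "z")
  expect_error(build_connectome(X, group = "toy"), "y")
  expect_error(build_connectome(X[1:2, ]), "3 participants")
})

test_that("connectomes are invariant to participant order and location shifts", {
  set.seed(21)
  X <- matrix(stats::rnorm(30 * 8), 30)
  colnames(X) <- paste0("v", 1:8)
  c1 <- build_connectome(X)
  c2 <- build_connectome(X[sample(30), ])
  expect_equal(c1$weights, c2$weights, tolerance = 1e-12)
  X3 <- sweep(X, 2, stats::runif(8, -5, 5), "+")
  c3 <- build_connectome(X3)
  expect_equal(c1$weights, c3$weights, tolerance = 1e-12)
})

test_that("proportional thresholding keeps exactly k strongest edges", {
  set.seed(22)
  X <- matrix(stats::rnorm(60 * 47), 60)
  colnames(X) <- default_roster()$variable
  conn <- build_connectome(X)
  A <- threshold_at_density(conn, 0.20)
  expect_equal(sum(A) / 2, round(0.20 * 47 * 46 / 2))  # 216
  expect_equal(sum(A) / 2, 216)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))

  # saturation: huge density keeps every positive edge
  Asat <- threshold_at_density(conn, 1)
  expect_equal(sum(Asat) / 2, sum(conn$weights[upper.tri(conn$weights)] > 0))

  # top-k on a 3-node toy
  Wt <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  Wt["a", "b"] <- Wt["b", "a"] <- 0.9
  Wt["a", "c"] <- Wt["c", "a"] <- 0.5
  Wt["b", "c"] <- Wt["c", "b"] <- 0.1
  toy <- structure(list(weights = Wt, node_labels = letters[1:3],
                        group = NULL, n_participants = 5),
                   class = "connectome")
  A1 <- threshold_at_density(toy, 1 / 3)
  expect_equal(sum(A1) / 2, 1)
  expect_equal(A1["a", "b"], 1L)

  expect_error(threshold_at_density(conn, 0), "density")
  expect_error(threshold_at_density(conn, 1.2), "density")
})

test_that("tie-breaking is deterministic by label order", {
  W <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(W) <- 0
  toy <- structure(list(weights = W, node_labels = letters[1:4],
                        group = NULL, n_participants = 5),
                   class = "connectome")
  A1 <- threshold_at_density(toy, 2 / 6)
  A2 <- threshold_at_density(toy, 2 / 6)
  expect_identical(A1, A2)
  # ascending (i, j): ties resolved to (a,b) then (a,c)
  expect_equal(A1["a", "b"], 1L)
  expect_equal(A1["a", "c"], 1L)
  expect_equal(sum(A1) / 2, 2)
})

test_that("the density stack is nested with realized densities on target", {
  pp <- tiny_preprocessed(seed = 23, n_per_group = 15)
  conn <- build_connectome(
    group_scores(pp$dataset, pp$stratification, "EMA_high"))
  stack <- build_stack(conn)
  expect_equal(length(stack$adjacency), 41)
  counts <- vapply(stack$adjacency, function(a) sum(a) / 2, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # nestedness edge by edge
  for (i in seq_len(length(stack$adjacency) - 1)) {
    expect_true(all(stack$adjacency[[i]] <= stack$adjacency[[i + 1]]))
  }
  # realized density within one edge of target
  m <- 47 * 46 / 2
  expect_true(all(abs(counts / m - stack$densities) <= 1 / m + 1e-12))
})

test_that("consecutive stack levels differ by exactly the k increment", {
  set.seed(24)
  X <- matrix(stats::rnorm(80 * 47), 80)
  colnames(X) <- default_roster()$variable
  conn <- build_connectome(X)
  d <- c(0.30, 0.31)
  A1 <- threshold_at_density(conn, d[1])
  A2 <- threshold_at_density(conn, d[2])
  m <- 47 * 46 / 2
  expect_equal(sum(A2 - A1) / 2,
               round(d[2] * m) - round(d[1] * m))
  expect_true(all(A2 - A1 >= 0))
})

test_that("density-range selection walks connectivity up and sigma down", {
  fx <- make_fixture("null", seed = 25, n_per_group = 40)
  pp <- preprocess_cohort(fx, threshold = 15)
  conn <- build_connectome(pp$dataset$scores, group = "pooled")
  sel <- select_density_range(conn, densities = density_grid(0.05, 0.95, 0.05),
                              ensemble = 10, seed = 2)
  dg <- sel$diagnostics
  expect_true(all(diff(dg$connected) >= 0))   # monotone connectivity
  expect_true(dg$connected[dg$density == sel$d_min])
  prev <- dg$density < sel$d_min
  if (any(prev)) expect_false(any(dg$connected[prev]))
  expect_gte(dg$sigma[dg$density == sel$d_max], 1)
  after <- which(dg$density > sel$d_max)
  if (length(after)) expect_true(all(dg$sigma[after] < 1, na.rm = TRUE))
})

test_that("range selection fails when the positive skeleton is disconnected", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W[1, 2] <- W[2, 1] <- 0.9   # nodes c, d isolated
  toy <- structure(list(weights = W, node_labels = letters[1:4],
                        group = NULL, n_participants = 10),
                   class = "connectome")
  expect_error(select_density_range(toy), "disconnected")
})

test_that("connectome exports produce readable artifacts", {
  pp <- tiny_preprocessed(seed = 26, n_per_group = 10)
  conn <- build_connectome(
    group_scores(pp$dataset, pp$stratification, "ELD_low"), "ELD_low")
  csv <- tempfile(fileext = ".csv")
  export_connectome(conn, csv)
  back <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(unname(back), unname(conn$weights), tolerance = 1e-6)

  gml <- tempfile(fileext = ".graphml")
  export_connectome(conn, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 47)

  tsv <- tempfile(fileext = ".tsv")
  export_connectome(conn, tsv, density = 0.25)
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), round(0.25 * 47 * 46 / 2))
})
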
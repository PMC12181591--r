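# Plain-R brute-force graph oracles, written independently of the
# package's C++ kernels: adjacency-matrix BFS, direct triangle counting,
# and the modularity formula evaluated term by term.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] == 1)) {
          if (is.infinite(D[s, v]) && v != s) {
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(A[nb, nb]) / 2
    cs[i] <- 2 * links / (k * (k - 1))
  }
  mean(cs)
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  vals <- D[row(D) != col(D)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NaN)
  mean(vals)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    tot <- tot + oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  tot / n
}

oracle_modularity <- function(A, membership) {
  m2 <- sum(A)  # 2m
  if (m2 == 0) stop("edgeless")
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j])
        q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# All set partitions of n elements as restricted-growth strings.
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1))
      rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# Small helper cohorts used across test files.
tiny_preprocessed <- function(seed = 1, n_per_group = 20,
                              scenario = "null") {
  fx <- make_fixture(scenario, seed = seed, n_per_group = n_per_group)
  preprocess_cohort(fx, threshold = 15)
}

make_demo <- function(n, ...) {
  base <- data.frame(
    participant_id = sprintf("id%02d", seq_len(n)),
    age = rep(45L, n), sex = rep("F", n), education_level = rep(3L, n),
    mmse = rep(29L, n), bdrs_personality = rep(0, n),
    bdrs_everyday = rep(0, n), bdrs_habits = rep(0, n),
    faq = rep(0L, n), wais_info = rep(18L, n),
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# Raw-score dataset with the default roster from a plain matrix.
make_dataset <- function(scores, demo = NULL) {
  roster <- default_roster()
  colnames(scores) <- roster$variable
  if (is.null(demo)) demo <- make_demo(nrow(scores))
  cognitive_dataset(demo, scores, roster)
}

group_labels_pub <- function() {
  c("EMA_high", "LMA_high", "ELD_high", "EMA_low", "LMA_low", "ELD_low")
}

# Reach the internal roster validation through the dataset constructor.
validate_roster_pub <- function(r) {
  X <- matrix(stats::rnorm(3 * nrow(r)), 3)
  colnames(X) <- r$variable
  cognitive_dataset(make_demo(3), X, roster = r)
}
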
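check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj))
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have zero diagonal")
  if (!all(adj %in% c(0, 1))) stop("adjacency must be binary")
  storage.mode(adj) <- "integer"
  adj
}

#' Network strength
#'
#' Centrality of the weighted connectome: the mean over nodes of the
#' nodal strength (sum of a node's correlation weights). The only
#' measure computed on the weighted matrix rather than the binarized
#' stack.
#'
#' @param conn A [build_connectome()] result (or a nonnegative symmetric
#'   weight matrix).
#' @return Scalar strength.
#' @export
network_strength <- function(conn) {
  W <- if (inherits(conn, "connectome")) conn$weights else conn
  mean(rowSums(W))
}

#' Global efficiency
#'
#' Integration of a binary network: the mean of inverse shortest-path
#' lengths over all ordered node pairs, unreachable pairs contributing 0.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  cpp_adj_stats(check_adjacency(adj),
                with_local_eff = FALSE)[["global_efficiency"]]
}

#' Local efficiency
#'
#' Segregation of a binary network: for each node, the global efficiency
#' of the subgraph induced by its neighbours (0 for degree < 2),
#' averaged over nodes.
#'
#' @inheritParams global_efficiency
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  cpp_adj_stats(check_adjacency(adj))[["local_efficiency"]]
}

#' Clustering coefficient and characteristic path length
#'
#' Watts-Strogatz ingredients of small-worldness: `C` is the mean local
#' clustering coefficient (`2 * triangles_i / (k_i (k_i - 1))`, 0 when
#' `k_i < 2`); `L` is the mean shortest-path length over connected
#' ordered pairs, with the number of unreachable pairs reported.
#'
#' @inheritParams global_efficiency
#' @return List with `C`, `L`, `unreachable_pairs`.
#' @export
clustering_and_pathlength <- function(adj) {
  st <- cpp_adj_stats(check_adjacency(adj), with_local_eff = FALSE)
  if (!is.finite(st[["path_length"]]))
    stop("path length undefined: graph has no connected pair")
  list(C = st[["clustering"]], L = st[["path_length"]],
       unreachable_pairs = st[["unreachable_pairs"]])
}

#' Modularity via Newman community detection
#'
#' Finds a community partition with Newman's leading-eigenvector
#' (spectral) algorithm (default) or Louvain, and returns its modularity
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' @inheritParams global_efficiency
#' @param seed Integer seed controlling tie-breaking in the detection.
#' @param method `"leading_eigen"` (default) or `"louvain"`.
#' @return List with `Q` and integer `membership`.
#' @export
modularity_q <- function(adj, seed = 1L,
                         method = c("leading_eigen", "louvain")) {
  method <- match.arg(method)
  adj <- check_adjacency(adj)
  if (sum(adj) == 0)
    stop("modularity undefined on an edgeless graph")
  g <- igraph_from_adj(adj)
  set.seed(seed)
  comm <- if (method == "leading_eigen")
    leading_eigen_guarded(g) else igraph::cluster_louvain(g)
  memb <- igraph::membership(comm)
  list(Q = igraph::modularity(g, memb), membership = as.integer(memb))
}

# ARPACK can fail to converge on degenerate spectra; retry with a larger
# iteration budget, then fall back to Louvain so a partition is always
# returned.
leading_eigen_guarded <- function(g) {
  tryCatch(
    igraph::cluster_leading_eigen(g),
    error = function(e) tryCatch(
      igraph::cluster_leading_eigen(
        g, options = list(maxiter = 500000L, tol = 1e-8)),
      error = function(e2) {
        warning("leading-eigenvector detection did not converge; ",
                "falling back to Louvain")
        igraph::cluster_louvain(g)
      }))
}

igraph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      diag = FALSE)
}

igraph_from_edges <- function(i0, j0, k, n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (k > 0)
    g <- igraph::add_edges(g, rbind(i0[seq_len(k)] + 1L,
                                    j0[seq_len(k)] + 1L))
  g
}

#' Small-worldness
#'
#' Watts-Strogatz small-world index
#' `sigma = (C / C_rand) / (L / L_rand)` where `C_rand`, `L_rand` are
#' means over an ensemble of degree-preserving edge-swap randomizations
#' of the graph (`swap_factor * |E|` attempted swaps each). `sigma > 1`
#' indicates small-world topology. Rigid graphs that the rewiring cannot
#' alter (e.g. complete graphs) return exactly 1.
#'
#' @inheritParams global_efficiency
#' @param ensemble Number of randomized reference graphs (default 50).
#' @param seed Integer seed for the rewiring.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return Scalar sigma (NaN if the randomized ensemble is degenerate).
#' @export
small_worldness <- function(adj, ensemble = 50, seed = 1L,
                            swap_factor = 10) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  set.seed(seed)
  cpp_sigma_curve(as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L),
                  nrow(idx), n, ensemble = ensemble,
                  swap_factor = swap_factor)[1]
}

# sigma over a density grid for a connectome (shared by
# select_density_range and measure_curve).
sigma_curve <- function(conn, densities, ensemble = 50, seed = 1L,
                        swap_factor = 10) {
  re <- rank_edges(conn$weights)
  kvec <- pmin(density_k(densities, re$n), re$n_pos)
  set.seed(seed)
  cpp_sigma_curve(re$i, re$j, as.integer(kvec), re$n,
                  ensemble = ensemble, swap_factor = swap_factor)
}

measure_names <- function() {
  c("strength", "global_efficiency", "local_efficiency",
    "modularity", "small_worldness")
}

#' Evaluate a global measure across the density sweep
#'
#' Computes one of the five global network measures for a connectome.
#' `"strength"` is evaluated on the weighted matrix and returns a single
#' scalar; the other four are evaluated on the binarized graphs at every
#' grid density.
#'
#' @param conn A [build_connectome()] result.
#' @param measure One of `"strength"`, `"global_efficiency"`,
#'   `"local_efficiency"`, `"modularity"`, `"small_worldness"`.
#' @param densities Density grid (ignored for strength).
#' @param ensemble Randomized-reference ensemble size for
#'   small-worldness.
#' @param seed Seed for modularity tie-breaking / rewiring.
#' @return An object of class `measure_curve`: list with
#'   `measure`, `densities`, `values`, `metadata`.
#' @export
measure_curve <- function(conn, measure, densities = density_grid(),
                          ensemble = 50, seed = 1L) {
  stopifnot(inherits(conn, "connectome"))
  measure <- match.arg(measure, measure_names())
  re <- rank_edges(conn$weights)
  values <- measure_values(re, measure, densities, ensemble, seed)
  structure(
    list(measure = measure,
         densities = if (measure == "strength") NULL else densities,
         values = values,
         metadata = list(group = conn$group, ensemble = ensemble,
                         seed = seed)),
    class = "measure_curve"
  )
}

# Fast path shared with the permutation engine: measure values from a
# ranked edge list. For strength, `re` must carry the weights.
measure_values <- function(re, measure, densities, ensemble = 10,
                           seed = 1L) {
  if (measure == "strength")
    return(2 * sum(re$w) / re$n)
  kvec <- as.integer(pmin(density_k(densities, re$n), re$n_pos))
  switch(
    measure,
    global_efficiency = cpp_curve_stats(re$i, re$j, kvec, re$n)[,
      "global_efficiency"],
    local_efficiency = cpp_curve_stats(re$i, re$j, kvec, re$n,
      with_local_eff = TRUE)[, "local_efficiency"],
    small_worldness = {
      set.seed(seed)
      as.numeric(cpp_sigma_curve(re$i, re$j, kvec, re$n,
                                 ensemble = ensemble))
    },
    modularity = {
      set.seed(seed)
      vapply(kvec, function(k) {
        g <- igraph_from_edges(re$i, re$j, k, re$n)
        if (k == 0) return(NA_real_)
        memb <- igraph::membership(leading_eigen_guarded(g))
        igraph::modularity(g, memb)
      }, numeric(1))
    }
  )
}

#' @export
print.measure_curve <- function(x, ...) {
  cat("<measure_curve> ", x$measure,
      if (!is.null(x$metadata$group)) paste0(" [", x$metadata$group, "]"),
      "\n", sep = "")
  if (is.null(x$densities)) {
    cat("  strength =", format(x$values, digits = 5), "\n")
  } else {
    cat("  densities ", min(x$densities), "-", max(x$densities),
        ", values ", format(min(x$values, na.rm = TRUE), digits = 4),
        " to ", format(max(x$values, na.rm = TRUE), digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.measure_curve <- function(x, ...) {
  if (is.null(x$densities))
    stop("strength is a scalar; nothing to plot")
  graphics::plot(x$densities, x$values, type = "b", pch = 16,
                 xlab = "network density", ylab = x$measure, ...)
  invisible(x)
}

#' @export
as.data.frame.measure_curve <- function(x, ...) {
  ph <- sprintf("ens%s_seed%s", x$metadata$ensemble %||% NA,
                x$metadata$seed %||% NA)
  if (is.null(x$densities))
    return(data.frame(group = x$metadata$group %||% NA,
                      measure = x$measure, density = NA_real_,
                      value = x$values, params_hash = ph))
  data.frame(group = x$metadata$group %||% NA, measure = x$measure,
             density = x$densities, value = x$values, params_hash = ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
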
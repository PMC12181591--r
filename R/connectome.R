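#' Build a group-level weighted cognitive connectome
#'
#' Nodes are the cognitive variables; the edge weight between two
#' variables is the Pearson correlation of their z-scores across the
#' group's participants, with negative correlations and self-connections
#' removed (set to zero): `w_ij = max(0, r_ij)` for `i != j`.
#'
#' @param group_data Numeric matrix, participants x variables, of
#'   inverted z-scores for one group (>= 3 participants).
#' @param group Optional group label (e.g. `"LMA_low"`).
#' @return An object of class `connectome`: a list with `weights`
#'   (symmetric nonnegative matrix, zero diagonal), `node_labels`,
#'   `group`, `n_participants`.
#' @examples
#' fx <- make_fixture("null", seed = 1, n_per_group = 30)
#' pp <- preprocess_cohort(fx, threshold = 15)
#' conn <- build_connectome(
#'   group_scores(pp$dataset, pp$stratification, "EMA_high"),
#'   group = "EMA_high")
#' @export
build_connectome <- function(group_data, group = NULL) {
  stopifnot(is.matrix(group_data))
  if (nrow(group_data) < 3)
    stop("need at least 3 participants to correlate")
  sds <- apply(group_data, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s) within group ",
         if (is.null(group)) "" else group, ": ",
         paste(colnames(group_data)[sds == 0], collapse = ", "))
  W <- stats::cor(group_data)
  W[W < 0] <- 0
  diag(W) <- 0
  structure(
    list(weights = W, node_labels = colnames(group_data),
         group = group, n_participants = nrow(group_data)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<connectome> ", nrow(x$weights), " nodes",
      if (!is.null(x$group)) paste0(", group ", x$group) else "",
      ", n = ", x$n_participants, "\n", sep = "")
  cat("positive edges:", pos, "of",
      sum(upper.tri(x$weights)), "pairs; mean positive weight",
      round(mean(x$weights[upper.tri(x$weights) & x$weights > 0]), 3),
      "\n")
  invisible(x)
}

#' @export
plot.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  graphics::image(seq_len(n), seq_len(n),
                  t(x$weights[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = if (!is.null(x$group))
                    paste("connectome:", x$group) else "connectome", ...)
  invisible(x)
}

#' Default density grid
#'
#' Proportional thresholding densities from 20% to 60% in 1% steps (41
#' values), the sweep over which binary graph measures are evaluated.
#' @param d_min,d_max,step Grid limits and step, as proportions.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(d_min = 0.20, d_max = 0.60, step = 0.01) {
  stopifnot(d_min < d_max, step > 0)
  round(seq(d_min, d_max, by = step), 10)
}

# Edge count at a target density over all n(n-1)/2 pairs;
# round-half-away-from-zero.
density_k <- function(density, n) {
  m <- n * (n - 1) / 2
  floor(density * m + 0.5)
}

# Rank the positive upper-triangular edges of a weight matrix:
# descending weight, ties by ascending (i, j) label order. Returns
# 0-based endpoint vectors for the C++ kernels.
rank_edges <- function(W) {
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  o <- order(-w, ut[, 1], ut[, 2])
  list(i = as.integer(ut[o, 1] - 1L), j = as.integer(ut[o, 2] - 1L),
       w = w[o], n = n, n_pos = length(w))
}

#' Binarize a connectome at a target density
#'
#' Keeps the `k = round(density * n(n-1)/2)` strongest positive edges
#' (ties broken deterministically: descending weight, then ascending
#' label order) and sets them to 1. When fewer than `k` positive edges
#' exist all positive edges are kept and the realized density is
#' recorded in attribute `realized_density`.
#'
#' @param conn A [build_connectome()] result.
#' @param density Target density in (0, 1].
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
threshold_at_density <- function(conn, density) {
  stopifnot(inherits(conn, "connectome"))
  if (density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  re <- rank_edges(conn$weights)
  n <- re$n
  k <- min(density_k(density, n), re$n_pos)
  A <- matrix(0L, n, n, dimnames = list(conn$node_labels,
                                        conn$node_labels))
  if (k > 0) {
    idx <- cbind(re$i[seq_len(k)] + 1L, re$j[seq_len(k)] + 1L)
    A[idx] <- 1L
    A[idx[, 2:1, drop = FALSE]] <- 1L
  }
  attr(A, "realized_density") <- k / (n * (n - 1) / 2)
  A
}

#' Build the binary graph stack over a density grid
#'
#' One thresholded adjacency per grid density. The deterministic edge
#' ranking makes the stack nested: every edge present at a density is
#' present at all larger densities.
#'
#' @param conn A [build_connectome()] result.
#' @param densities Density grid; defaults to [density_grid()].
#' @return An object of class `graph_stack`: list with `densities`,
#'   `adjacency` (list of binary matrices), `conn`.
#' @export
build_stack <- function(conn, densities = density_grid()) {
  stopifnot(inherits(conn, "connectome"))
  adjacency <- lapply(densities, function(d)
    threshold_at_density(conn, d))
  structure(list(densities = densities, adjacency = adjacency,
                 conn = conn),
            class = "graph_stack")
}

#' @export
print.graph_stack <- function(x, ...) {
  ec <- vapply(x$adjacency, function(a) sum(a) / 2, numeric(1))
  cat("<graph_stack> ", length(x$densities), " densities in [",
      min(x$densities), ", ", max(x$densities), "], edges ",
      min(ec), "-", max(ec), "\n", sep = "")
  invisible(x)
}

#' Select the valid density range for a cohort
#'
#' Sweeps a candidate grid on the whole-cohort connectome and returns the
#' range that excludes disconnected topologies at the low end (d_min:
#' smallest density whose graph is a single connected component) and
#' random topologies at the high end (d_max: largest density whose
#' small-worldness sigma is >= 1).
#'
#' @param conn Whole-cohort [build_connectome()] (all groups pooled).
#' @param densities Candidate grid; defaults to 5%-95% in 1% steps.
#' @param ensemble,seed Small-world ensemble size and seed passed to
#'   [small_worldness()].
#' @return List with `d_min`, `d_max` and a `diagnostics` data frame
#'   (density, connected, sigma).
#' @export
select_density_range <- function(conn,
                                 densities = density_grid(0.05, 0.95),
                                 ensemble = 20, seed = 1L) {
  stopifnot(inherits(conn, "connectome"))
  connected <- vapply(densities, function(d) {
    A <- threshold_at_density(conn, d)
    cpp_adj_stats(A, with_local_eff = FALSE)[["unreachable_pairs"]] == 0
  }, logical(1))
  if (!any(connected))
    stop("no candidate density yields a connected graph; ",
         "the positive-weight skeleton is itself disconnected")
  d_min <- densities[which(connected)[1]]
  sigma <- sigma_curve(conn, densities, ensemble = ensemble, seed = seed)
  ok <- !is.na(sigma) & sigma >= 1
  d_max <- if (any(ok)) densities[max(which(ok))] else NA_real_
  list(d_min = d_min, d_max = d_max,
       diagnostics = data.frame(density = densities,
                                connected = connected, sigma = sigma))
}

#' Export a connectome
#'
#' Writes the weighted matrix as CSV, and optionally GraphML (weighted)
#' or per-density edge-list TSVs for external graph tooling.
#'
#' @param conn A [build_connectome()] result.
#' @param path Output path; extension selects the format (`.csv`,
#'   `.graphml`, `.tsv`).
#' @param density For `.tsv`, the density at which to binarize.
#' @return `path`, invisibly.
#' @export
export_connectome <- function(conn, path, density = NULL) {
  stopifnot(inherits(conn, "connectome"))
  ext <- tolower(sub("^.*\\.", "", path))
  if (ext == "csv") {
    utils::write.csv(conn$weights, path, row.names = TRUE)
  } else if (ext == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(
      conn$weights, mode = "undirected", weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "tsv") {
    if (is.null(density))
      stop("edge-list export needs a density")
    A <- threshold_at_density(conn, density)
    idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
    utils::write.table(
      data.frame(from = conn$node_labels[idx[, 1]],
                 to = conn$node_labels[idx[, 2]]),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else stop("unsupported export format: .", ext)
  invisible(path)
}
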
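# Ranked positive-edge representation straight from a group z-matrix.
ranked_from_scores <- function(X) {
  W <- stats::cor(X)
  W[W < 0] <- 0
  diag(W) <- 0
  rank_edges(W)
}

#' Permutation comparison of a global network measure between two groups
#'
#' The model-like fitting entry point of the package. The observed
#' statistic at each density is the group difference (A minus B) of the
#' measure computed on each group's connectome. The null distribution is
#' built by pooling the participants of both groups, re-splitting them
#' into groups of the original sizes uniformly at random `n_perm` times,
#' rebuilding both connectomes and recomputing the measure at every
#' density. Two-tailed p-values use the add-one convention
#' `p = (1 + #\{|diff_perm| >= |diff_obs|\}) / (1 + n_perm)`, so p is
#' never 0. A comparison is called stable-significant when p < `alpha`
#' at `min_densities` or more grid densities (strength, which has no
#' density axis, is significant iff its single p < `alpha`).
#'
#' @param data_A,data_B Participants x variables matrices of inverted
#'   z-scores (>= 4 participants each, same variables).
#' @param measure One of the five global measures; see [measure_curve()].
#' @param densities Density grid (ignored for strength).
#' @param n_perm Number of permutations; defaults to 1000, or 100 for
#'   small-worldness.
#' @param seed Integer seed; identical seeds give identical results.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param min_densities Stability criterion: minimum number of
#'   significant densities (default 10).
#' @param ensemble Rewiring-ensemble size for small-worldness inside the
#'   permutation loop (default 10, recorded in the metadata).
#' @param labels Character pair naming the groups.
#' @return An object of class `connectome_comparison`.
#' @examples
#' fx <- make_fixture("null", seed = 3, n_per_group = 20)
#' pp <- preprocess_cohort(fx, threshold = 15)
#' a <- group_scores(pp$dataset, pp$stratification, "EMA_high")
#' b <- group_scores(pp$dataset, pp$stratification, "LMA_high")
#' cmp <- compare_connectomes(a, b, "global_efficiency",
#'                            n_perm = 50, seed = 1)
#' print(cmp)
#' @export
compare_connectomes <- function(data_A, data_B, measure,
                                densities = density_grid(),
                                n_perm = NULL, seed = 1L,
                                alpha = 0.05, min_densities = 10L,
                                ensemble = 10L,
                                labels = c("A", "B")) {
  measure <- match.arg(measure, measure_names())
  stopifnot(is.matrix(data_A), is.matrix(data_B),
            ncol(data_A) == ncol(data_B))
  if (nrow(data_A) < 4 || nrow(data_B) < 4)
    stop("both groups need at least 4 participants")
  if (is.null(n_perm))
    n_perm <- if (measure == "small_worldness") 100L else 1000L

  # Pool in a canonical order (smaller group first; content tiebreak) so
  # that swapping the group labels reproduces the identical null
  # distribution and hence identical p-values.
  swap <- if (nrow(data_A) != nrow(data_B)) {
    nrow(data_A) > nrow(data_B)
  } else {
    va <- as.vector(data_A)
    vb <- as.vector(data_B)
    i <- which(va != vb)[1]
    !is.na(i) && va[i] > vb[i]
  }
  X1 <- if (swap) data_B else data_A
  X2 <- if (swap) data_A else data_B
  nA <- nrow(X1)
  pooled <- rbind(X1, X2)
  n_tot <- nrow(pooled)

  # Permutation index draws first, then per-evaluation derived seeds, so
  # that seeded measures (modularity, sigma) cannot disturb the
  # resampling stream.
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n_tot))

  eval_measure <- function(X, sub_seed) {
    measure_values(ranked_from_scores(X), measure, densities,
                   ensemble = ensemble, seed = sub_seed)
  }
  obs_1 <- eval_measure(X1, seed + 1L)
  obs_2 <- eval_measure(X2, seed + 2L)
  obs_A <- if (swap) obs_2 else obs_1
  obs_B <- if (swap) obs_1 else obs_2
  obs_diff <- obs_A - obs_B

  nd <- length(obs_diff)
  perm_diff <- matrix(NA_real_, n_perm, nd)
  for (i in seq_len(n_perm)) {
    idx <- perm_idx[, i]
    pa <- eval_measure(pooled[idx[seq_len(nA)], , drop = FALSE],
                       seed + 2L * i + 1L)
    pb <- eval_measure(pooled[idx[-seq_len(nA)], , drop = FALSE],
                       seed + 2L * i + 2L)
    perm_diff[i, ] <- pa - pb
  }

  if (swap) perm_diff <- -perm_diff  # report on the A - B orientation
  p_values <- vapply(seq_len(nd), function(d) {
    (1 + sum(abs(perm_diff[, d]) >= abs(obs_diff[d]), na.rm = TRUE)) /
      (1 + n_perm)
  }, numeric(1))
  band <- apply(perm_diff, 2, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)

  if (measure == "strength") {
    significant_densities <- as.integer(p_values < alpha)
    stable <- p_values[1] < alpha
  } else {
    sf <- stability_filter(p_values, alpha = alpha,
                           min_densities = min_densities)
    significant_densities <- sf$count
    stable <- sf$stable
  }

  structure(
    list(group_pair = labels, measure = measure,
         densities = if (measure == "strength") NULL else densities,
         observed = list(A = obs_A, B = obs_B),
         observed_diff = obs_diff, p_values = p_values,
         null_band = band, n_perm = n_perm, seed = seed,
         alpha = alpha, min_densities = min_densities,
         ensemble = if (measure == "small_worldness") ensemble else NA,
         significant_densities = significant_densities,
         stable_significant = stable),
    class = "connectome_comparison"
  )
}

#' Density-stability criterion
#'
#' Counts the grid densities at which the permutation p-value falls below
#' `alpha`; the comparison is considered stable when that count reaches
#' `min_densities` (default 10 of the 41-density grid), focusing
#' inference on differences that persist across thresholds.
#'
#' @param p_values Numeric vector of per-density p-values.
#' @param alpha Significance level (default 0.05, two-tailed).
#' @param min_densities Minimum count (default 10).
#' @return List with `count` and logical `stable`.
#' @export
stability_filter <- function(p_values, alpha = 0.05,
                             min_densities = 10L) {
  count <- sum(p_values < alpha, na.rm = TRUE)
  list(count = count, stable = count >= min_densities)
}

#' @export
print.connectome_comparison <- function(x, ...) {
  cat("<connectome_comparison> ", x$group_pair[1], " vs ",
      x$group_pair[2], ": ", x$measure, "\n", sep = "")
  cat("  permutations:", x$n_perm, " seed:", x$seed, "\n")
  if (is.null(x$densities)) {
    cat(sprintf("  observed diff %.4f, p = %.4f (%s)\n",
                x$observed_diff, x$p_values,
                if (x$stable_significant) "significant"
                else "not significant"))
  } else {
    cat(sprintf("  significant at %d/%d densities (alpha %.2f) -> %s\n",
                x$significant_densities, length(x$densities), x$alpha,
                if (x$stable_significant) "STABLE difference"
                else "not stable"))
  }
  invisible(x)
}

#' @export
summary.connectome_comparison <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Comparison ", object$group_pair[1], " vs ", object$group_pair[2],
      " (", object$measure, ")\n", sep = "")
  print(utils::head(df, 5))
  if (!is.null(object$densities)) cat("  ...", nrow(df), "densities\n")
  invisible(df)
}

#' @export
as.data.frame.connectome_comparison <- function(x, ...) {
  data.frame(pair = paste(x$group_pair, collapse = "-"),
             measure = x$measure,
             density = if (is.null(x$densities)) NA_real_ else x$densities,
             obs_diff = x$observed_diff, p = x$p_values)
}

#' @export
plot.connectome_comparison <- function(x, ...) {
  if (is.null(x$densities))
    stop("strength comparison is a scalar; nothing to plot")
  d <- x$densities
  ylim <- range(c(x$observed_diff, x$null_band), na.rm = TRUE)
  graphics::plot(d, x$observed_diff, type = "n", ylim = ylim,
                 xlab = "network density",
                 ylab = paste("difference in", x$measure),
                 main = paste(x$group_pair, collapse = " vs "), ...)
  graphics::polygon(c(d, rev(d)),
                    c(x$null_band[1, ], rev(x$null_band[2, ])),
                    col = grDevices::adjustcolor("grey", 0.5),
                    border = NA)
  graphics::points(d, x$observed_diff, pch = 16,
                   col = ifelse(x$p_values < x$alpha, "red", "black"))
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' The nine default group comparisons
#'
#' Age contrasts within each reserve level (EMA-LMA, LMA-ELD, EMA-ELD in
#' high and in low reserve) plus reserve contrasts within each age bin.
#' @return Data frame with columns `a`, `b`.
#' @export
default_design <- function() {
  rbind(
    data.frame(a = c("EMA_high", "LMA_high", "EMA_high"),
               b = c("LMA_high", "ELD_high", "ELD_high")),
    data.frame(a = c("EMA_low", "LMA_low", "EMA_low"),
               b = c("LMA_low", "ELD_low", "ELD_low")),
    data.frame(a = c("EMA_high", "LMA_high", "ELD_high"),
               b = c("EMA_low", "LMA_low", "ELD_low"))
  )
}

#' Run the full comparison design
#'
#' Executes every (group pair) x (measure) permutation comparison on a
#' stratified cohort — by default the nine canonical pairs crossed with
#' the five global measures (45 comparisons). Per-comparison seeds are
#' derived from the master seed by a fixed counter scheme
#' (`seed + 10000 * comparison_index`), so adding comparisons never
#' shifts existing results.
#'
#' @param dataset A preprocessed [cognitive_dataset()] (inverted
#'   z-scores).
#' @param stratification A [stratify()] result.
#' @param design Data frame of group pairs (columns `a`, `b`); defaults
#'   to [default_design()].
#' @param measures Measures to compare; defaults to all five.
#' @param n_perm Named vector of permutation counts per measure, or a
#'   single count; defaults to 1000 (100 for small-worldness).
#' @param fdr Logical; if `TRUE`, Benjamini-Hochberg adjust all
#'   p-values jointly across the design before counting significant
#'   densities (off by default: the canonical analysis applies no
#'   correction beyond the stability rule).
#' @inheritParams compare_connectomes
#' @return An object of class `design_comparison`: list of
#'   `connectome_comparison` objects plus a `summary` data frame.
#' @export
run_design <- function(dataset, stratification,
                       design = default_design(),
                       measures = measure_names(),
                       densities = density_grid(),
                       n_perm = NULL, seed = 1L, alpha = 0.05,
                       min_densities = 10L, ensemble = 10L,
                       fdr = FALSE) {
  cells <- table(stratification$assignments$group)
  need <- unique(c(design$a, design$b))
  empty <- setdiff(need, names(cells)[cells > 0])
  if (length(empty))
    stop("design refers to empty cell(s): ",
         paste(empty, collapse = ", "))
  perm_count <- function(m) {
    if (is.null(n_perm))
      return(if (m == "small_worldness") 100L else 1000L)
    if (length(n_perm) == 1L && is.null(names(n_perm)))
      return(as.integer(n_perm))
    if (m %in% names(n_perm)) return(as.integer(n_perm[[m]]))
    stop("n_perm must be a single count or named per measure")
  }

  results <- list()
  counter <- 0L
  for (r in seq_len(nrow(design))) {
    ga <- design$a[r]; gb <- design$b[r]
    Xa <- group_scores(dataset, stratification, ga)
    Xb <- group_scores(dataset, stratification, gb)
    for (m in measures) {
      counter <- counter + 1L
      results[[paste(ga, gb, m, sep = ".")]] <- compare_connectomes(
        Xa, Xb, m, densities = densities,
        n_perm = perm_count(m),
        seed = seed + 10000L * counter,
        alpha = alpha, min_densities = min_densities,
        ensemble = ensemble, labels = c(ga, gb))
    }
  }
  if (fdr) {
    all_p <- unlist(lapply(results, `[[`, "p_values"))
    adj <- stats::p.adjust(all_p, method = "BH")
    at <- 0L
    for (nm in names(results)) {
      np <- length(results[[nm]]$p_values)
      results[[nm]]$p_values <- adj[at + seq_len(np)]
      at <- at + np
      x <- results[[nm]]
      if (x$measure == "strength") {
        results[[nm]]$significant_densities <-
          as.integer(x$p_values < alpha)
        results[[nm]]$stable_significant <- x$p_values[1] < alpha
      } else {
        sf <- stability_filter(x$p_values, alpha = alpha,
                               min_densities = min_densities)
        results[[nm]]$significant_densities <- sf$count
        results[[nm]]$stable_significant <- sf$stable
      }
    }
  }
  summary_df <- do.call(rbind, lapply(results, function(x) {
    data.frame(pair = paste(x$group_pair, collapse = "-"),
               measure = x$measure,
               significant_densities = x$significant_densities,
               stable_significant = x$stable_significant,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  structure(list(comparisons = results, summary = summary_df,
                 seed = seed, alpha = alpha,
                 min_densities = min_densities),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("<design_comparison> ", length(x$comparisons),
      " comparisons, master seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
as.data.frame.design_comparison <- function(x, ...) {
  do.call(rbind, c(lapply(unname(x$comparisons), as.data.frame),
                   make.row.names = FALSE))
}
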
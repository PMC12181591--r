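#' Run configuration for the end-to-end pipeline
#'
#' Bundles and validates everything [run_pipeline()] needs before any
#' computation starts.
#'
#' @param input A cohort source: a CSV path (dialect of
#'   [write_cohort()]), a [sim_config()], or a [cognitive_dataset()].
#' @param densities Density grid.
#' @param n_perm Permutation counts (single value or named per measure;
#'   `NULL` for the 1000/100 defaults).
#' @param measures Measures to compare.
#' @param alpha,min_densities Significance level and stability count.
#' @param threshold Reserve threshold (`NULL` = cohort median).
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @return Validated object of class `run_config`.
#' @export
run_config <- function(input, densities = density_grid(),
                       n_perm = NULL, measures = measure_names(),
                       alpha = 0.05, min_densities = 10L,
                       threshold = NULL, seed = 1L,
                       out_dir = tempfile("cognectome_run_")) {
  ok <- inherits(input, "sim_config") ||
    inherits(input, "cognitive_dataset") ||
    (is.character(input) && length(input) == 1L)
  if (!ok)
    stop("input must be a CSV path, a sim_config or a cognitive_dataset")
  if (is.character(input) && !file.exists(input))
    stop("input CSV not found: ", input)
  stopifnot(all(densities > 0), all(densities <= 1),
            alpha > 0, alpha < 1, min_densities >= 1)
  measures <- vapply(measures, match.arg, "", choices = measure_names())
  structure(list(input = input, densities = densities, n_perm = n_perm,
                 measures = unname(measures), alpha = alpha,
                 min_densities = as.integer(min_densities),
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate/load -> eligibility + z-scoring + inversion + stratification
#' -> per-group connectomes -> measure curves -> permutation comparisons
#' -> MANOVA and descriptives, writing every artifact into the run
#' directory: cohort snapshot, stratification table, connectome CSVs,
#' tidy measure-curve CSV, tidy comparison CSV plus a JSON verdict
#' summary, stats JSON, and a manifest with seeds and versions. Stages
#' never mutate their inputs; a failure aborts with the stage name,
#' preserving earlier outputs.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; the loaded artifacts are
#'   attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("input", {
    if (inherits(config$input, "sim_config"))
      generate_cohort(config$input)
    else if (inherits(config$input, "cognitive_dataset"))
      config$input
    else read_cohort(config$input)
  })
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  pp <- stage("preprocess", preprocess_cohort(cohort,
                                              threshold = config$threshold))
  utils::write.csv(pp$stratification$assignments,
                   file.path(config$out_dir, "stratification.csv"),
                   row.names = FALSE)
  if (nrow(pp$excluded))
    utils::write.csv(pp$excluded,
                     file.path(config$out_dir, "excluded.csv"),
                     row.names = FALSE)

  groups <- intersect(group_labels(),
                      unique(pp$stratification$assignments$group))
  conns <- stage("connectome", {
    out <- lapply(groups, function(g)
      build_connectome(group_scores(pp$dataset, pp$stratification, g),
                       group = g))
    names(out) <- groups
    out
  })
  for (g in groups)
    export_connectome(conns[[g]],
                      file.path(config$out_dir,
                                paste0("connectome_", g, ".csv")))

  curves <- stage("measures", {
    rows <- lapply(groups, function(g)
      do.call(rbind, lapply(config$measures, function(m)
        as.data.frame(measure_curve(conns[[g]], m,
                                    densities = config$densities,
                                    seed = config$seed)))))
    do.call(rbind, rows)
  })
  utils::write.csv(curves, file.path(config$out_dir,
                                     "measure_curves.csv"),
                   row.names = FALSE)

  cmp <- stage("compare", run_design(
    pp$dataset, pp$stratification, measures = config$measures,
    densities = config$densities, n_perm = config$n_perm,
    seed = config$seed, alpha = config$alpha,
    min_densities = config$min_densities))
  utils::write.csv(as.data.frame(cmp),
                   file.path(config$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cmp$summary,
                       file.path(config$out_dir,
                                 "comparison_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  statres <- stage("stats", {
    comp <- module_composites(pp$dataset)
    a <- pp$stratification$assignments
    mv <- connectome_manova(comp, a$age_group, a$reserve_group)
    fu <- followup_anovas(comp, a$age_group, a$reserve_group)
    de <- descriptives(pp$dataset, pp$stratification)
    list(manova = list(wilks_lambda = mv$wilks_lambda,
                       f = mv$f_stat, df = mv$df, p = mv$p_value),
         followup = fu,
         spearman = as.list(de$spearman),
         sex_chisq = unname(de$sex_chisq$statistic))
  })
  jsonlite::write_json(statres, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cognectome")),
    r_version = R.version.string,
    seed = config$seed, densities = config$densities,
    measures = config$measures, alpha = config$alpha,
    min_densities = config$min_densities,
    threshold = pp$stratification$split_threshold,
    groups = as.list(table(pp$stratification$assignments$group)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- list(cohort = cohort, preprocess = pp, connectomes = conns,
              curves = curves, comparisons = cmp, stats = statres)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}
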
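#' @useDynLib cognectome, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical six-cell design: 3 age bins x 2 reserve levels.
group_labels <- function() {
  c("EMA_high", "LMA_high", "ELD_high", "EMA_low", "LMA_low", "ELD_low")
}

age_bins <- function() {
  list(EMA = c(37L, 50L), LMA = c(51L, 64L), ELD = c(65L, 78L))
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines a six-group (3 age bins x 2 cognitive-reserve levels) cohort
#' whose 47 cognitive variables follow, within each group, a multivariate
#' normal with block-structured correlations: `r_intra` on same-module
#' pairs, `r_inter` on cross-module pairs, 1 on the diagonal, plus
#' per-module mean shifts. This is exactly the statistical structure the
#' downstream Pearson-correlation connectome analysis assumes, so the
#' generator exercises every pipeline stage without real data.
#'
#' @param group_sizes Named integer vector over the six groups
#'   (`EMA_high`, `LMA_high`, `ELD_high`, `EMA_low`, `LMA_low`,
#'   `ELD_low`). Defaults to the reference cohort sizes
#'   59/67/40/51/39/78 (total 334).
#' @param roster Variable roster ([default_roster()]); defines
#'   `n_variables` and the variable -> module map.
#' @param r_intra,r_inter Named numeric vectors per group in `[0, 1)`:
#'   generating correlation for same-module and cross-module variable
#'   pairs, defined on the analysis orientation (higher = better for
#'   every variable). Raw scores of time-like variables are the negated
#'   latent score, so their raw-scale cross correlations with ability
#'   scores come out negative, as in real batteries. Defaults keep the three high-reserve groups identical
#'   (0.5 / 0.2) and vary the low-reserve groups (0.45/0.15, 0.60/0.45,
#'   0.30/0.10 for EMA/LMA/ELD), mirroring a stable high-reserve
#'   connectome and a reorganising low-reserve one.
#' @param module_means Numeric matrix, groups x modules, of mean shifts in
#'   z units on the raw-score orientation (procedural-memory and
#'   processing-speed scores are time-like: larger = slower). Defaults to
#'   the reference cohort's module composite means.
#' @param noise_sd Positive scalar standard deviation of every variable.
#' @param wais_ranges List with integer `high` and `low` bands for the
#'   WAIS-III Information score; must respect the >15 / <=15 split.
#' @param sex_p_female Named vector per group: probability of female sex.
#' @param mmse_mean,mmse_sd Named vectors per group for the MMSE screen
#'   (clipped to 24..30 so generated cohorts are eligibility-clean).
#' @param sigma_override Optional named list mapping a group label to a
#'   full 47x47 correlation matrix, overriding the block structure for
#'   that group.
#' @param allow_r_inter_above_intra Logical; by default `r_inter <=
#'   r_intra` is enforced per group (set `TRUE` for extreme
#'   dedifferentiation scenarios).
#' @param clip_psd Logical; if `TRUE`, a slightly indefinite implied
#'   correlation matrix has negative eigenvalues clipped to zero instead
#'   of raising an error.
#' @param seed Integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(EMA_high = 59L, LMA_high = 67L,
                                       ELD_high = 40L, EMA_low = 51L,
                                       LMA_low = 39L, ELD_low = 78L),
                       roster = default_roster(),
                       r_intra = c(EMA_high = 0.5, LMA_high = 0.5,
                                   ELD_high = 0.5, EMA_low = 0.45,
                                   LMA_low = 0.60, ELD_low = 0.30),
                       r_inter = c(EMA_high = 0.2, LMA_high = 0.2,
                                   ELD_high = 0.2, EMA_low = 0.15,
                                   LMA_low = 0.45, ELD_low = 0.10),
                       module_means = default_module_means(),
                       noise_sd = 1,
                       wais_ranges = list(high = c(16L, 26L),
                                          low = c(4L, 15L)),
                       sex_p_female = c(EMA_high = 0.373, LMA_high = 0.478,
                                        ELD_high = 0.425, EMA_low = 0.706,
                                        LMA_low = 0.795, ELD_low = 0.641),
                       mmse_mean = c(EMA_high = 29.1, LMA_high = 28.9,
                                     ELD_high = 28.6, EMA_low = 28.9,
                                     LMA_low = 28.1, ELD_low = 27.6),
                       mmse_sd = c(EMA_high = 1.0, LMA_high = 1.1,
                                   ELD_high = 1.5, EMA_low = 1.5,
                                   LMA_low = 1.6, ELD_low = 1.5),
                       sigma_override = NULL,
                       allow_r_inter_above_intra = FALSE,
                       clip_psd = FALSE,
                       seed = 1L) {
  groups <- group_labels()
  validate_roster(roster)
  if (!setequal(names(group_sizes), groups))
    stop("group_sizes must cover exactly the 3x2 design: ",
         paste(groups, collapse = ", "))
  group_sizes <- group_sizes[groups]
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  for (v in list(r_intra = r_intra, r_inter = r_inter)) {
    if (!all(groups %in% names(v))) stop("r_intra/r_inter need all groups")
    if (any(v < 0 | v >= 1)) stop("correlations must lie in [0, 1)")
  }
  r_intra <- r_intra[groups]; r_inter <- r_inter[groups]
  if (!allow_r_inter_above_intra &&
      any(r_inter > r_intra + 1e-12))
    stop("r_inter exceeds r_intra for group(s) ",
         paste(groups[r_inter > r_intra + 1e-12], collapse = ", "),
         " (set allow_r_inter_above_intra = TRUE to override)")
  mods <- levels(roster$module)
  if (!is.matrix(module_means) ||
      !identical(rownames(module_means), groups) ||
      !identical(colnames(module_means), mods))
    stop("module_means must be a groups x modules matrix with the ",
         "canonical dimnames")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (wais_ranges$high[1] <= 15L || wais_ranges$low[2] > 15L)
    stop("wais_ranges must respect the >15 (high) / <=15 (low) split")

  cfg <- structure(
    list(group_sizes = group_sizes, roster = roster,
         r_intra = r_intra, r_inter = r_inter,
         module_means = module_means, noise_sd = noise_sd,
         age_bins = age_bins(), wais_ranges = wais_ranges,
         sex_p_female = sex_p_female[groups],
         mmse_mean = mmse_mean[groups], mmse_sd = mmse_sd[groups],
         sigma_override = sigma_override,
         clip_psd = clip_psd, seed = as.integer(seed)),
    class = "sim_config"
  )
  # Every group's implied correlation matrix must be (numerically) PSD.
  for (g in groups) {
    ev <- min(eigen(group_sigma(cfg, g), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-10 && !clip_psd)
      stop("implied correlation matrix for group ", g,
           " is not positive semidefinite (min eigenvalue ",
           signif(ev, 3), ")")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> six-group synthetic cohort, ",
      sum(x$group_sizes), " participants, ",
      nrow(x$roster), " variables, seed ", x$seed, "\n", sep = "")
  print(data.frame(n = x$group_sizes, r_intra = x$r_intra,
                   r_inter = x$r_inter))
  invisible(x)
}

#' Default per-group module mean shifts
#'
#' Mean shifts (z units, raw orientation) of the five module composites in
#' the six groups of the reference cohort. Procedural-memory and
#' processing-speed rows are on the uninverted scale, where larger scores
#' mean slower performance; hence elderly groups show the largest
#' processing-speed means.
#'
#' @return A 6 x 5 numeric matrix (groups x modules).
#' @export
default_module_means <- function() {
  m <- rbind(
    EMA_high = c(0.5, 0.6, 0.6, -0.2, -0.5),
    LMA_high = c(0.4, 0.3, 0.5, 0.0, -0.4),
    ELD_high = c(-0.1, 0.0, 0.0, -0.3, 0.2),
    EMA_low  = c(0.1, 0.2, 0.1, 0.2, -0.5),
    LMA_low  = c(-0.1, -0.2, -0.3, 0.2, 0.1),
    ELD_low  = c(-0.7, -0.8, -0.8, 0.0, 0.9)
  )
  colnames(m) <- module_levels()
  m
}

# Implied covariance matrix for one group. The block-constant structure
# (r_intra within modules, r_inter across) is defined on the analysis
# orientation, where every variable points "higher = better"; raw scores
# of time-like variables (invert flag) are that latent score negated, so
# their raw-scale correlations with non-inverted variables carry a
# flipped sign: Sigma_raw = D S D with D = diag(+/-1). A full-matrix
# override is taken as the raw-scale correlation matrix directly.
group_sigma <- function(cfg, group) {
  p <- nrow(cfg$roster)
  if (!is.null(cfg$sigma_override) &&
      group %in% names(cfg$sigma_override)) {
    S <- cfg$sigma_override[[group]]
    stopifnot(is.matrix(S), nrow(S) == p, ncol(S) == p)
    return(S * cfg$noise_sd^2)
  }
  same <- outer(cfg$roster$module, cfg$roster$module, "==")
  S <- matrix(cfg$r_inter[[group]], p, p)
  S[same] <- cfg$r_intra[[group]]
  diag(S) <- 1
  d <- ifelse(cfg$roster$invert, -1, 1)
  S <- S * outer(d, d)
  S * cfg$noise_sd^2
}

#' Generate a synthetic cohort
#'
#' Draws, for each of the six groups, `group_sizes[g]` participants whose
#' 47 cognitive scores follow the group's block-structured multivariate
#' normal, with ages uniform in the group's age bin and WAIS-III
#' Information scores uniform in the reserve band. Demographic screeners
#' (MMSE, BDRS, FAQ) are drawn from distributions under which virtually
#' every participant passes the eligibility screen, emulating an
#' already-screened cohort.
#'
#' @param config A [sim_config()].
#' @return A [cognitive_dataset()] in raw units with the generating
#'   config attached as attribute `sim_config` and the true group label
#'   as demographic column `true_group`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$scores)  # 334
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- group_labels()
  p <- nrow(config$roster)
  mods <- as.character(config$roster$module)
  out_demo <- vector("list", length(groups))
  out_scores <- vector("list", length(groups))
  idx0 <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[g]]
    age_grp <- sub("_.*$", "", g)
    res_grp <- sub("^.*_", "", g)
    Sigma <- group_sigma(config, g)
    if (config$clip_psd) {
      e <- eigen(Sigma, symmetric = TRUE)
      e$values[e$values < 0] <- 0
      Sigma <- e$vectors %*% (e$values * t(e$vectors))
    }
    mu <- config$module_means[g, mods]
    X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    if (n == 1L) X <- matrix(X, nrow = 1L)
    colnames(X) <- config$roster$variable

    bin <- config$age_bins[[age_grp]]
    wband <- config$wais_ranges[[res_grp]]
    bdrs_vals <- c(0, 0.5, 1)
    demo <- data.frame(
      participant_id = sprintf("P%04d", idx0 + seq_len(n)),
      age = sample(bin[1]:bin[2], n, replace = TRUE),
      sex = ifelse(stats::runif(n) < config$sex_p_female[[g]],
                   "F", "M"),
      education_level = sample(1:5, n, replace = TRUE,
                               prob = if (res_grp == "high")
                                 c(0.00, 0.02, 0.18, 0.20, 0.60)
                               else c(0.02, 0.20, 0.45, 0.23, 0.10)),
      mmse = pmin(30L, pmax(24L, round(stats::rnorm(
        n, config$mmse_mean[[g]], config$mmse_sd[[g]])))),
      bdrs_personality = sample(bdrs_vals, n, replace = TRUE,
                                prob = c(0.85, 0.10, 0.05)),
      bdrs_everyday = sample(bdrs_vals, n, replace = TRUE,
                             prob = c(0.90, 0.08, 0.02)),
      bdrs_habits = sample(bdrs_vals, n, replace = TRUE,
                           prob = c(0.90, 0.08, 0.02)),
      faq = pmin(5L, stats::rpois(n, 0.3)),
      wais_info = sample(wband[1]:wband[2], n, replace = TRUE),
      true_group = g,
      stringsAsFactors = FALSE
    )
    out_demo[[gi]] <- demo
    out_scores[[gi]] <- X
    idx0 <- idx0 + n
  }
  ds <- cognitive_dataset(do.call(rbind, out_demo),
                          do.call(rbind, out_scores),
                          roster = config$roster, units = "raw")
  attr(ds, "sim_config") <- config
  ds
}

#' Named fixture cohorts for validation scenarios
#'
#' Three documented scenarios used throughout the test suite and the
#' methods vignette:
#' \describe{
#'   \item{`"null"`}{all six groups share one set of generating
#'     parameters (r_intra 0.5, r_inter 0.2, no mean shifts): any
#'     detected group difference is a false positive.}
#'   \item{`"dedifferentiation"`}{as `"null"`, but the late-middle-age
#'     low-reserve group has its cross-module correlation raised to 0.9 x
#'     its intra-module value (0.45), blurring the modular structure —
#'     the planted effect lowers modularity and small-worldness.}
#'   \item{`"stable_reserve"`}{the three high-reserve groups share one
#'     parameter pair (0.5/0.2) while the low-reserve groups differ
#'     across age (0.45/0.15, 0.60/0.45, 0.30/0.10): age contrasts are
#'     null within high reserve and planted within low reserve.}
#' }
#'
#' @param name Scenario name, one of `"null"`, `"dedifferentiation"`,
#'   `"stable_reserve"`.
#' @param seed Integer seed.
#' @param n_per_group Participants per group (default 40).
#' @return A [cognitive_dataset()]; the dedifferentiation scenario marks
#'   the altered group in attribute `flagged_group`.
#' @export
make_fixture <- function(name, seed = 1L, n_per_group = 40L) {
  groups <- group_labels()
  sizes <- stats::setNames(rep(as.integer(n_per_group), 6L), groups)
  base_intra <- stats::setNames(rep(0.5, 6L), groups)
  base_inter <- stats::setNames(rep(0.2, 6L), groups)
  zero_means <- matrix(0, 6, 5,
                       dimnames = list(groups, module_levels()))
  cfg <- switch(
    name,
    "null" = sim_config(group_sizes = sizes, r_intra = base_intra,
                        r_inter = base_inter, module_means = zero_means,
                        seed = seed),
    "dedifferentiation" = {
      ri <- base_inter
      ri[["LMA_low"]] <- 0.9 * base_intra[["LMA_low"]]
      sim_config(group_sizes = sizes, r_intra = base_intra,
                 r_inter = ri, module_means = zero_means, seed = seed)
    },
    "stable_reserve" = sim_config(
      group_sizes = sizes,
      r_intra = c(EMA_high = 0.5, LMA_high = 0.5, ELD_high = 0.5,
                  EMA_low = 0.45, LMA_low = 0.60, ELD_low = 0.30),
      r_inter = c(EMA_high = 0.2, LMA_high = 0.2, ELD_high = 0.2,
                  EMA_low = 0.15, LMA_low = 0.45, ELD_low = 0.10),
      module_means = zero_means, seed = seed),
    stop("unknown scenario name: ", name)
  )
  ds <- generate_cohort(cfg)
  if (name == "dedifferentiation") attr(ds, "flagged_group") <- "LMA_low"
  ds
}
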
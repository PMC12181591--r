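#' Eligibility screen
#'
#' Applies the dementia-screening inclusion rules: MMSE >= 24, FAQ < 6,
#' and BDRS total (sum of the three subscales) < 4 — with the exception
#' that a participant with BDRS total >= 4 stays eligible when (a) the
#' "changes in personality, interests and drive" subscale contributes
#' >= 70% of the total and (b) the other two subscales (everyday
#' activities, habits) each score <= 1.5. Clinical criteria that cannot be
#' recomputed from scores (MCI adjudication, handedness, MRI reading,
#' comorbidity) are honoured as optional pre-computed boolean columns
#' (`mci_free`, `right_handed`, `mri_clear`, `no_comorbidity`): when
#' present they are AND-ed into eligibility.
#'
#' @param dataset A [cognitive_dataset()] in raw units.
#' @return A list with `included` (a [cognitive_dataset()]) and
#'   `excluded` (data frame of `participant_id`, `reason` — the first
#'   failing criterion, in the order MMSE, FAQ, BDRS, then any boolean
#'   flag column).
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 7))
#' res <- eligibility_filter(cohort)
#' nrow(res$included$scores)
#' @export
eligibility_filter <- function(dataset) {
  stopifnot(inherits(dataset, "cognitive_dataset"))
  d <- dataset$demographics
  need <- c("mmse", "faq", "bdrs_personality", "bdrs_everyday",
            "bdrs_habits")
  bad <- need[vapply(need, function(f) anyNA(d[[f]]), logical(1))]
  if (length(bad))
    stop("missing demographic fields ", paste(bad, collapse = ", "),
         " for ids: ",
         paste(utils::head(
           d$participant_id[Reduce(`|`, lapply(bad, function(f)
             is.na(d[[f]])))], 5), collapse = ", "))

  bdrs_total <- d$bdrs_personality + d$bdrs_everyday + d$bdrs_habits
  pers_frac <- ifelse(bdrs_total > 0, d$bdrs_personality / bdrs_total, 0)
  bdrs_ok <- bdrs_total < 4 |
    (pers_frac >= 0.70 & d$bdrs_everyday <= 1.5 & d$bdrs_habits <= 1.5)

  reason <- rep(NA_character_, nrow(d))
  reason[!bdrs_ok] <- "BDRS"
  reason[d$faq >= 6] <- "FAQ"
  reason[d$mmse < 24] <- "MMSE"

  flag_cols <- intersect(
    c("mci_free", "right_handed", "mri_clear", "no_comorbidity"),
    names(d))
  for (fc in rev(flag_cols)) {
    fail <- !is.na(d[[fc]]) & !d[[fc]]
    reason[is.na(reason) & fail] <- fc
  }

  keep <- is.na(reason)
  list(
    included = subset_participants(dataset, keep),
    excluded = data.frame(participant_id = d$participant_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Cohort z-scoring
#'
#' Standardizes every cognitive variable against the whole included
#' cohort (not per group): z = (x - mean) / sd. The sd convention
#' defaults to the sample estimator (n - 1 denominator); the population
#' convention (n denominator) is available via `sd_type`.
#'
#' @param dataset A [cognitive_dataset()] in raw units.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return The dataset with z-unit scores (`units == "z"`).
#' @export
zscore_cohort <- function(dataset, sd_type = c("sample", "population")) {
  stopifnot(inherits(dataset, "cognitive_dataset"))
  sd_type <- match.arg(sd_type)
  if (dataset$units == "z")
    message("scores already in z units; re-standardizing")
  X <- dataset$scores
  n <- nrow(X)
  mu <- colMeans(X)
  ss <- colSums(sweep(X, 2, mu)^2)
  sdv <- sqrt(ss / if (sd_type == "sample") (n - 1) else n)
  if (any(sdv == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  out <- dataset
  out$scores <- Z
  out$units <- "z"
  out$inverted <- FALSE
  out
}

#' Invert scores of time-like variables
#'
#' Multiplies the z-scores of variables flagged in the roster (the
#' procedural-memory and processing-speed modules, where larger raw
#' scores mean slower performance) by -1, so that after inversion higher
#' z-scores denote better performance for every variable. Applying the
#' operation twice restores the original dataset.
#'
#' @param dataset A [cognitive_dataset()] in z units.
#' @return The dataset with flagged columns negated and the `inverted`
#'   flag toggled.
#' @export
invert_scores <- function(dataset) {
  stopifnot(inherits(dataset, "cognitive_dataset"))
  if (dataset$units != "z")
    stop("invert_scores expects z-unit scores; run zscore_cohort first")
  out <- dataset
  flip <- dataset$roster$invert
  out$scores[, flip] <- -out$scores[, flip]
  out$inverted <- !dataset$inverted
  out
}

#' Module composite scores
#'
#' Per-participant performance in each cognitive module: the mean of the
#' (inverted) z-scores of the module's variables.
#'
#' @param dataset A [cognitive_dataset()] in z units with inversion
#'   applied.
#' @return Numeric matrix, participants x modules, columns in module
#'   level order.
#' @export
module_composites <- function(dataset) {
  stopifnot(inherits(dataset, "cognitive_dataset"))
  if (dataset$units != "z" || !dataset$inverted)
    stop("module_composites expects inverted z-scores")
  validate_roster(dataset$roster)
  mods <- levels(dataset$roster$module)
  out <- vapply(mods, function(m) {
    cols <- dataset$roster$module == m
    rowMeans(dataset$scores[, cols, drop = FALSE])
  }, numeric(nrow(dataset$scores)))
  rownames(out) <- dataset$demographics$participant_id
  out
}

#' Age x cognitive-reserve stratification
#'
#' Assigns every participant to one of six cells: age bin (EMA 37-50,
#' LMA 51-64, ELD 65-78 years, closed integer intervals; non-integer ages
#' are floored) crossed with reserve level from the WAIS-III Information
#' score (high: wais > threshold, low: wais <= threshold). The threshold
#' defaults to the cohort median, reported in the result; pass
#' `threshold = 15` to reproduce the canonical split.
#'
#' @param dataset A [cognitive_dataset()].
#' @param threshold Optional numeric reserve cut; default is the cohort
#'   median of `wais_info`.
#' @return An object of class `stratification`: a list with
#'   `assignments` (data frame `participant_id`, `age_group`,
#'   `reserve_group`, `group`) and `split_threshold`.
#' @export
stratify <- function(dataset, threshold = NULL) {
  stopifnot(inherits(dataset, "cognitive_dataset"))
  d <- dataset$demographics
  age <- floor(d$age)
  out_of_range <- age < 37 | age > 78
  if (any(out_of_range))
    stop("ages outside 37-78 for ids: ",
         paste(utils::head(d$participant_id[out_of_range], 5),
               collapse = ", "))
  if (is.null(threshold)) threshold <- stats::median(d$wais_info)
  age_group <- cut(age, breaks = c(36, 50, 64, 78),
                   labels = c("EMA", "LMA", "ELD"))
  reserve_group <- ifelse(d$wais_info > threshold, "high", "low")
  assignments <- data.frame(
    participant_id = d$participant_id,
    age_group = as.character(age_group),
    reserve_group = reserve_group,
    group = paste(age_group, reserve_group, sep = "_"),
    stringsAsFactors = FALSE
  )
  structure(list(assignments = assignments,
                 split_threshold = threshold),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification> WAIS-III Information split at >",
      x$split_threshold, "\n")
  print(table(x$assignments$age_group, x$assignments$reserve_group))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper: eligibility screen, cohort z-scoring, score
#' inversion, stratification.
#'
#' @inheritParams zscore_cohort
#' @inheritParams stratify
#' @return List with `dataset` (inverted z-scores), `stratification`,
#'   `excluded`.
#' @export
#' @details Missing cognitive scores are handled complete-case: rows with
#'   any missing score are dropped with a message, and preprocessing
#'   stops with an error if any of the six stratified cells would lose
#'   more than 10% of its participants that way.
preprocess_cohort <- function(dataset, threshold = NULL,
                              sd_type = "sample") {
  elig <- eligibility_filter(dataset)
  inc <- elig$included
  complete <- stats::complete.cases(inc$scores)
  if (!all(complete)) {
    strat_all <- stratify(inc, threshold = threshold)
    loss <- tapply(!complete, strat_all$assignments$group, mean)
    if (any(loss > 0.10, na.rm = TRUE))
      stop("complete-case filtering would drop >10% of group(s): ",
           paste(names(loss)[which(loss > 0.10)], collapse = ", "))
    message("dropping ", sum(!complete),
            " participant(s) with missing scores (complete-case)")
    inc <- subset_participants(inc, complete)
  }
  z <- invert_scores(zscore_cohort(inc, sd_type = sd_type))
  strat <- stratify(z, threshold = threshold)
  list(dataset = z, stratification = strat, excluded = elig$excluded)
}

#' Extract the score matrix of one stratified group
#'
#' @param dataset A [cognitive_dataset()].
#' @param stratification A [stratify()] result.
#' @param group Group label, e.g. `"EMA_high"`.
#' @return Numeric matrix, group participants x variables.
#' @export
group_scores <- function(dataset, stratification, group) {
  ids <- stratification$assignments$participant_id[
    stratification$assignments$group == group]
  dataset$scores[dataset$demographics$participant_id %in% ids, ,
                 drop = FALSE]
}
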
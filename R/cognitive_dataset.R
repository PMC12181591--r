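#' Construct a cognitive dataset
#'
#' The raw input container for the pipeline: one row per participant with
#' demographic/screening fields plus a participants x variables score
#' matrix tied to a variable roster.
#'
#' @param demographics Data frame with one row per participant. Required
#'   columns: `participant_id`, `age`, `sex`, `education_level`, `mmse`,
#'   `bdrs_personality`, `bdrs_everyday`, `bdrs_habits`, `faq`,
#'   `wais_info`. Additional boolean eligibility columns (e.g.
#'   `mci_free`, `right_handed`, `mri_clear`, `no_comorbidity`) are
#'   carried through and honoured by [eligibility_filter()].
#' @param scores Numeric matrix, participants x variables; column names
#'   must match `roster$variable` exactly (same order).
#' @param roster Variable roster as returned by [default_roster()].
#' @param units `"raw"` or `"z"`; whether scores are raw or cohort
#'   z-scores.
#' @param inverted Logical; whether the inversion of procedural-memory and
#'   processing-speed variables has been applied (only meaningful for
#'   z-units).
#' @return An object of class `cognitive_dataset`.
#' @seealso [generate_cohort()], [zscore_cohort()], [invert_scores()]
#' @export
cognitive_dataset <- function(demographics, scores,
                              roster = default_roster(),
                              units = c("raw", "z"),
                              inverted = FALSE) {
  units <- match.arg(units)
  validate_roster(roster)
  stopifnot(is.data.frame(demographics), is.matrix(scores))
  need <- c("participant_id", "age", "sex", "education_level", "mmse",
            "bdrs_personality", "bdrs_everyday", "bdrs_habits",
            "faq", "wais_info")
  miss <- setdiff(need, names(demographics))
  if (length(miss))
    stop("demographics missing required fields: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(demographics$participant_id))
    stop("duplicate participant ids")
  if (nrow(demographics) != nrow(scores))
    stop("demographics and scores disagree on participant count")
  if (!identical(colnames(scores), roster$variable))
    stop("score columns must match the roster variables in order")
  structure(
    list(demographics = demographics, scores = scores, roster = roster,
         units = units, inverted = inverted),
    class = "cognitive_dataset"
  )
}

#' @export
print.cognitive_dataset <- function(x, ...) {
  cat("<cognitive_dataset> ", nrow(x$scores), " participants x ",
      ncol(x$scores), " variables (", x$units, " units",
      if (x$inverted) ", inverted" else "", ")\n", sep = "")
  cat("modules:",
      paste(sprintf("%s=%d", names(table(x$roster$module)),
                    table(x$roster$module)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cognitive_dataset <- function(object, ...) {
  d <- object$demographics
  cat("Participants:", nrow(d), "\n")
  cat("Age range:", paste(range(d$age), collapse = "-"), "\n")
  cat("WAIS-III Information range:",
      paste(range(d$wais_info), collapse = "-"), "\n")
  cat("Score units:", object$units,
      if (object$inverted) "(inverted)" else "", "\n")
  invisible(object)
}

#' @export
as.data.frame.cognitive_dataset <- function(x, ...) {
  cbind(x$demographics, as.data.frame(x$scores))
}

# Subset a dataset by a logical/integer participant index, keeping the
# class and metadata.
subset_participants <- function(dataset, idx) {
  cognitive_dataset(
    demographics = dataset$demographics[idx, , drop = FALSE],
    scores = dataset$scores[idx, , drop = FALSE],
    roster = dataset$roster,
    units = dataset$units,
    inverted = dataset$inverted
  )
}

#' Write a cohort to CSV (plus config sidecar)
#'
#' Writes one row per participant: demographic columns first, then the 47
#' variable columns in roster order. If the dataset carries a generating
#' `sim_config` attribute it is written as JSON alongside.
#'
#' @param dataset A [cognitive_dataset()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  cfg <- attr(dataset, "sim_config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg),
                         sub("\\.csv$", "_config.json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @param roster Variable roster; defaults to [default_roster()].
#' @param units,inverted Score units flags, as in [cognitive_dataset()].
#' @return A [cognitive_dataset()].
#' @export
read_cohort <- function(path, roster = default_roster(),
                        units = "raw", inverted = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(roster$variable, names(df))
  if (length(miss))
    stop("cohort file missing roster variables: ",
         paste(utils::head(miss, 5), collapse = ", "))
  scores <- as.matrix(df[, roster$variable, drop = FALSE])
  demo <- df[, setdiff(names(df), roster$variable), drop = FALSE]
  cognitive_dataset(demo, scores, roster, units = units,
                    inverted = inverted)
}
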
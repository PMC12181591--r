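#' Default cognitive-variable roster
#'
#' The 47 cognitive variables used to build cognitive connectomes, each
#' allocated to one of five cognitive modules: verbal memory (VM), visual
#' memory and visuospatial functions (VMV), executive and premotor functions
#' (EPF), procedural memory (PM), and processing speed (PS). The allocation
#' follows a Newman-algorithm modular decomposition of the battery
#' established for this cohort. Variables in the procedural-memory and
#' processing-speed modules are time/error-like scores where larger raw
#' values mean worse performance; their `invert` flag is `TRUE` so that
#' after z-scoring all variables point the same way (higher = better).
#'
#' @return A data frame with columns `variable` (character), `module`
#'   (factor with levels VM, VMV, EPF, PM, PS) and `invert` (logical),
#'   one row per variable, 47 rows in total.
#' @examples
#' r <- default_roster()
#' table(r$module)
#' @export
default_roster <- function() {
  vm <- c(
    "lm_a_immediate", "lm_b1_immediate", "lm_b2_immediate",
    "lm_a_delayed", "lm_b_delayed", "lm_a_recognition", "lm_b_recognition",
    "tavec_trial1", "tavec_learning", "tavec_interference",
    "tavec_immediate_total", "tavec_cued_immediate",
    "tavec_delayed_total", "tavec_cued_delayed"
  )
  vmv <- c(
    "frt", "jlot_first_half", "jlot_second_half", "spatial_span_backward",
    "vr_i_total", "vr_ii_total", "vr_copy", "vr_recognition",
    "block_design", "bnt",
    "srt830_trial1", "srt830_learning", "srt830_interference",
    "srt830_immediate", "srt830_delayed"
  )
  epf <- c(
    "stroop_words", "stroop_colours", "stroop_inhibition",
    "phonetic_fluency", "semantic_fluency", "action_fluency",
    "digit_span_forward", "digit_span_backward", "spatial_span_forward",
    "ham_right", "ham_left", "ham_motor_coordination"
  )
  pm <- c("ht_trial1", "ht_learning", "ht_long_delay")
  ps <- c("pcv_decision_time", "pcv_motor_time", "ctt_part_a")

  roster <- data.frame(
    variable = c(vm, vmv, epf, pm, ps),
    module = factor(
      rep(c("VM", "VMV", "EPF", "PM", "PS"),
          times = c(length(vm), length(vmv), length(epf),
                    length(pm), length(ps))),
      levels = c("VM", "VMV", "EPF", "PM", "PS")
    ),
    stringsAsFactors = FALSE
  )
  roster$invert <- roster$module %in% c("PM", "PS")
  roster
}

#' Module labels of the default roster
#' @return Character vector of the five module labels, in roster order.
#' @export
module_levels <- function() c("VM", "VMV", "EPF", "PM", "PS")

#' Read / write a variable roster sidecar
#'
#' A roster sidecar is a CSV with columns `variable`, `module`, `invert`
#' describing an alternative variable set and module map; the packaged
#' default is [default_roster()].
#'
#' @param path CSV path.
#' @return `read_roster()`: a validated roster data frame.
#' @export
read_roster <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  r$module <- factor(r$module, levels = unique(r$module))
  r$invert <- as.logical(r$invert)
  validate_roster(r)
  r
}

#' @rdname read_roster
#' @param roster Roster data frame to write.
#' @export
write_roster <- function(roster, path) {
  validate_roster(roster)
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}

# Validate a roster data frame; used by dataset constructors.
validate_roster <- function(roster) {
  stopifnot(is.data.frame(roster))
  need <- c("variable", "module", "invert")
  if (!all(need %in% names(roster)))
    stop("roster must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(roster$variable))
    stop("duplicate variable names in roster")
  sizes <- table(roster$module)
  if (any(sizes == 0))
    stop("roster has a module with zero variables: ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  invisible(roster)
}
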
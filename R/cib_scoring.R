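# Coding Interactive Behavior (CIB): validation of the 43 item codes
# (1-5 Likert) and aggregation into the eight composite subscores by
# arithmetic mean. Items shared between composites count in each. No
# reverse scoring is applied (the published composite table states no
# reversal rules); missingness above 50% of a composite's items leaves
# that composite undefined.

#' The 43 CIB item names
#'
#' Canonicalised item identifiers. Forty-two items enter at least one
#' composite; `parent_depressed_mood` is a published parent code outside
#' the composite table, carried so a record holds the scale's full 43
#' slots while contributing to no composite.
#'
#' @return character vector of length 43.
#' @export
cib_items <- function() {
  c("acknowledging", "imitating", "elaborating", "parent_gaze",
    "parent_positive_affect", "vocal_appropriateness",
    "appropriate_range_of_affect", "resourcefulness", "praising",
    "affectionate_touch", "supportive_presence", "infant_led_interaction",
    "forcing_physical_manipulation", "overriding_intrusiveness",
    "parent_negative_affect_anger", "parent_anxiety", "criticizing",
    "parent_led_interaction", "consistency_of_style",
    "appropriate_structure_limit_setting", "compliance_to_parent",
    "reliance_on_parent_for_help", "on_task_persistence",
    "child_negative_emotionality_fussy", "withdrawal", "labile_affect",
    "avoidance_of_parent", "joint_attention", "child_positive_affect",
    "affection_to_parent", "alertness", "fatigue",
    "vocalizations_verbal_output", "initiation",
    "competent_use_of_environment", "creative_symbolic_play", "hostility",
    "constriction", "tension", "dyadic_reciprocity",
    "adaptation_regulation", "fluency", "parent_depressed_mood")
}

#' The eight CIB composite subscores and their contributing items
#'
#' @return named list mapping each composite to its item names.
#' @export
cib_composite_map <- function() {
  list(
    parental_sensitivity = c(
      "acknowledging", "imitating", "elaborating", "parent_gaze",
      "parent_positive_affect", "vocal_appropriateness",
      "appropriate_range_of_affect", "resourcefulness", "praising",
      "affectionate_touch", "supportive_presence", "infant_led_interaction"),
    parent_intrusiveness = c(
      "forcing_physical_manipulation", "overriding_intrusiveness",
      "parent_negative_affect_anger", "parent_anxiety", "criticizing",
      "parent_led_interaction"),
    parent_limit_setting = c(
      "consistency_of_style", "resourcefulness",
      "appropriate_structure_limit_setting"),
    child_compliance = c(
      "compliance_to_parent", "reliance_on_parent_for_help",
      "on_task_persistence"),
    child_withdrawal = c(
      "child_negative_emotionality_fussy", "withdrawal", "labile_affect",
      "avoidance_of_parent"),
    child_engagement = c(
      "joint_attention", "child_positive_affect", "affection_to_parent",
      "alertness", "fatigue", "vocalizations_verbal_output", "initiation",
      "competent_use_of_environment", "creative_symbolic_play",
      "infant_led_interaction"),
    dyadic_joint_negative_state = c(
      "parent_negative_affect_anger", "hostility",
      "child_negative_emotionality_fussy", "withdrawal", "labile_affect",
      "fatigue", "constriction", "tension"),
    dyadic_reciprocity = c(
      "parent_gaze", "parent_positive_affect", "praising",
      "affectionate_touch", "joint_attention", "child_positive_affect",
      "vocalizations_verbal_output", "initiation", "dyadic_reciprocity",
      "adaptation_regulation", "fluency"))
}

#' Validate raw CIB item codes
#'
#' @param codes named numeric vector (or 1-row data.frame / named list) of
#'   item codes on the 1-5 Likert scale; `NA` marks a missing rating.
#'   Names must be exactly the 43 items of [cib_items()].
#' @return named numeric vector of class `cib_record`.
#' @export
validate_record <- function(codes) {
  if (is.data.frame(codes)) codes <- unlist(codes[1, , drop = TRUE])
  if (is.list(codes)) codes <- unlist(codes)
  nm <- names(codes)
  if (is.null(nm) || !setequal(nm, cib_items()) || length(codes) != 43L) {
    unknown <- setdiff(nm, cib_items())
    missing <- setdiff(cib_items(), nm)
    abort_dyadscope("SchemaMismatch", paste0(
      "expected exactly the 43 CIB items",
      if (length(unknown)) paste0("; unknown: ", paste(unknown, collapse = ", ")),
      if (length(missing)) paste0("; absent: ", paste(missing, collapse = ", "))))
  }
  codes <- as.numeric(codes)[match(cib_items(), nm)]
  names(codes) <- cib_items()
  bad <- which(!is.na(codes) & (codes < 1 | codes > 5 | codes != round(codes)))
  if (length(bad))
    abort_dyadscope("OutOfRange",
      sprintf("item '%s' has code %s outside the 1-5 Likert scale",
              names(codes)[bad[1]], format(codes[bad[1]])))
  structure(codes, class = "cib_record")
}

#' Compute the eight CIB composite subscores
#'
#' Each composite is the arithmetic mean of its contributing items; items
#' listed in several composites count in each. A composite with more than
#' half of its items missing is returned undefined (`NA`) with a warning.
#'
#' @param record a [validate_record()] result.
#' @return named numeric vector of the eight composites, each in \[1, 5\]
#'   or `NA`.
#' @export
composite_scores <- function(record) {
  if (!inherits(record, "cib_record")) record <- validate_record(record)
  map <- cib_composite_map()
  out <- vapply(names(map), function(comp) {
    v <- unclass(record)[map[[comp]]]
    if (mean(is.na(v)) > 0.5) {
      warning(sprintf("composite '%s' has >50%% missing items; undefined", comp))
      return(NA_real_)
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Plot CIB composite profiles for one or more dyads
#'
#' Grouped bar chart over the eight composites, one series per dyad;
#' undefined composites are omitted and annotated.
#'
#' @param composites named list (one element per dyad) of
#'   [composite_scores()] vectors, or a single such vector.
#' @param path output file (PNG).
#' @return `path`, invisibly.
#' @export
composite_profile_plot <- function(composites, path) {
  if (!is.list(composites)) composites <- list(dyad = composites)
  m <- do.call(rbind, composites)
  grDevices::png(path, width = 1000, height = 520)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(11, 4, 2, 1))
  bp <- graphics::barplot(m, beside = TRUE, ylim = c(0, 5.5), las = 2,
                          legend.text = rownames(m),
                          col = grDevices::hcl.colors(nrow(m), "Dark 3"),
                          ylab = "composite score (1-5)")
  if (any(is.na(m)))
    graphics::text(bp[is.na(m)], 0.2, "n/a", srt = 90, adj = 0, cex = 0.8)
  invisible(path)
}
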
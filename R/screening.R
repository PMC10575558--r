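#' Z-score confidence within each subject
#'
#' Standardizes `confidence_raw` to mean 0, SD 1 within each subject across
#' all of that subject's trials (all conditions pooled). This removes
#' between-subject differences in slider use and puts human ratings and
#' model-native confidences on the same scale.
#'
#' @param trials A trial tibble with `subject_id` and `confidence_raw`.
#' @return The tibble with a `conf_z` column added (replaced if present).
#' @export
zscore_within_subject <- function(trials) {
  if (!all(c("subject_id", "confidence_raw") %in% names(trials))) {
    abort("`trials` needs subject_id and confidence_raw columns.")
  }
  trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(conf_z = {
      s <- sd(.data$confidence_raw)
      if (!is.finite(s) || s == 0) {
        abort(sprintf("Subject %s has constant confidence; cannot z-score.",
                      .data$subject_id[1]))
      }
      (.data$confidence_raw - mean(.data$confidence_raw)) / s
    }) |>
    dplyr::ungroup()
}

#' Screen subjects on type-1 performance
#'
#' Applies the study's two attention checks: overall accuracy (proportion of
#' `"highest"` choices across all conditions) must reach
#' `min_overall_accuracy` (default 0.40; chance is 1/3), and accuracy in the
#' easiest condition must strictly exceed accuracy in each other condition.
#' The easiest condition is the one with the largest highest-vs-second
#' coherence gap in `design` unless given explicitly.
#'
#' @param trials Trial tibble with `subject_id`, `condition_id`,
#'   `choice_category`.
#' @param design An `experiment_design` (used to locate the easiest
#'   condition); defaults to [default_design()].
#' @param min_overall_accuracy Exclusion threshold on overall accuracy.
#' @param easiest_condition_id Override for the easiest condition.
#' @param require_easiest_best Apply the easiest-condition check.
#' @return A tibble per subject: per-condition and overall accuracy,
#'   `retained`, and `reason` for exclusions.
#' @export
screen_subjects <- function(trials, design = default_design(),
                            min_overall_accuracy = 0.40,
                            easiest_condition_id = NULL,
                            require_easiest_best = TRUE) {
  assert_scalar_number(min_overall_accuracy, "min_overall_accuracy",
                       lower = 0, upper = 1)
  easiest <- easiest_condition_id %||% easiest_condition(design)
  acc <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition_id) |>
    dplyr::summarise(accuracy = mean(.data$choice_category == "highest"),
                     n = dplyr::n(), .groups = "drop")
  out <- acc |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      accuracy_overall = sum(.data$accuracy * .data$n) / sum(.data$n),
      accuracy_easiest = .data$accuracy[.data$condition_id == easiest][1],
      accuracy_other_max =
        max(.data$accuracy[.data$condition_id != easiest], -Inf),
      .groups = "drop"
    )
  below <- out$accuracy_overall < min_overall_accuracy
  not_best <- require_easiest_best &
    !(out$accuracy_easiest > out$accuracy_other_max)
  out$retained <- !(below | not_best)
  out$reason <- dplyr::case_when(
    below & not_best ~ "below_threshold; easiest_not_best",
    below ~ "below_threshold",
    not_best ~ "easiest_not_best",
    TRUE ~ NA_character_
  )
  out
}

#' Per-condition behavioral summary
#'
#' Computes the three standard per-condition metrics — mean accuracy
#' (proportion `"highest"`), mean z-scored confidence, and mean reaction
#' time — as per-subject means averaged across subjects. Confidence is
#' z-scored within subject across all conditions first if `conf_z` is
#' absent.
#'
#' @param trials Trial tibble (`subject_id`, `condition_id`,
#'   `choice_category`, `confidence_raw`, optional `rt_ms`).
#' @param by_subject Return the per-subject table instead of the grand means.
#' @return A tibble per condition (or per subject x condition).
#' @export
behavior_summary <- function(trials, by_subject = FALSE) {
  if (!"conf_z" %in% names(trials)) trials <- zscore_within_subject(trials)
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_
  per_subj <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition_id) |>
    dplyr::summarise(
      accuracy = mean(.data$choice_category == "highest"),
      conf_z = mean(.data$conf_z),
      rt_ms = mean(.data$rt_ms),
      n = dplyr::n(), .groups = "drop"
    )
  if (by_subject) {
    return(per_subj)
  }
  per_subj |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy),
      conf_z = mean(.data$conf_z),
      rt_ms = mean(.data$rt_ms),
      n_subjects = dplyr::n(), .groups = "drop"
    )
}
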
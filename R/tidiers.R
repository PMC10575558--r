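#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-subject model comparison
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return One row per model: `subject_id`, `model`, `sigma_hat`, `ce1`,
#'   `ce2`, `best` (logical).
#' @export
tidy.confarb_fit <- function(x, ...) {
  dplyr::mutate(
    x$result[, c("model", "sigma_hat", "ce1", "ce2")],
    subject_id = x$subject_id,
    best = !is.na(x$best_model) & .data$model == x$best_model,
    .before = 1L
  )
}

#' @rdname tidy.confarb_fit
#' @return `glance()`: a one-row tibble with the subject's fitted sigma,
#'   best model and flag.
#' @export
glance.confarb_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, mode = x$mode,
    sigma_hat = x$result$sigma_hat[1],
    best_model = x$best_model,
    min_ce2 = suppressWarnings(min(x$result$ce2[is.finite(x$result$ce2)],
                                   Inf)),
    flag = x$flag
  )
}

#' Tidy a model-recovery study
#'
#' @param x A [run_recovery()] result.
#' @param ... Unused.
#' @return `tidy()`: the confusion matrix in long form (`true_model`,
#'   `best_model`, `n`, `proportion`).
#' @export
tidy.recovery_result <- function(x, ...) {
  tab <- as.data.frame(x$confusion, stringsAsFactors = FALSE)
  names(tab) <- c("true_model", "best_model", "n")
  tab <- tibble::as_tibble(tab)
  tab |>
    dplyr::group_by(.data$true_model) |>
    dplyr::mutate(proportion = .data$n / max(1L, sum(.data$n))) |>
    dplyr::ungroup()
}

#' @rdname tidy.recovery_result
#' @return `glance()`: a one-row tibble with overall accuracy, counts and
#'   exclusions.
#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall_accuracy,
    n_classified = sum(x$confusion),
    n_correct = sum(diag(x$confusion)),
    n_excluded = x$n_excluded
  )
}

#' @rdname tidy.recovery_result
#' @export
glance.selection_robustness <- function(x, ...) {
  tibble::tibble(
    scale = x$scales,
    rank_correlation = as.numeric(x$rank_correlation),
    same_topk = x$same_topk
  )
}
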
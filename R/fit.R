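# empirical choice-category distribution per condition
subject_choice_dist <- function(trials, categories = choice_categories(),
                                condition_ids = NULL) {
  condition_ids <- condition_ids %||% sort(unique(trials$condition_id))
  purrr::map_dfr(condition_ids, function(ci) {
    cc <- trials$choice_category[trials$condition_id == ci]
    counts <- table(factor(cc, levels = categories))
    tibble::tibble(
      condition_id = ci, n = length(cc),
      category = categories, p = as.numeric(counts) / max(1L, length(cc))
    )
  })
}

# CE1 against a cached q table (conditions x categories), weighted by the
# subject's per-condition trial counts
ce1_against <- function(pdist, qtab) {
  conds <- unique(pdist$condition_id)
  w <- vapply(conds, function(ci) pdist$n[pdist$condition_id == ci][1],
              numeric(1))
  w <- w / sum(w)
  ces <- vapply(seq_along(conds), function(i) {
    p <- pdist$p[pdist$condition_id == conds[i]]
    type1_cross_entropy(p, qtab[i, ])
  }, numeric(1))
  sum(w * ces)
}

#' Fit the internal-noise parameter by type-1 cross entropy
#'
#' Grid-searches the cached `sigma` candidates for the value whose simulated
#' choice-category distribution minimizes the trial-count-weighted type-1
#' cross entropy against the subject's choices. In `"shared"` mode one
#' `sigma` is fitted from the common `argmax d` choice rule (all models make
#' the same type-1 decisions under equal priors, equal variances and zero
#' covariance); in `"per_model"` mode each model is fitted against its own
#' choice rule (only the hierarchical observer's can differ). Ties go to the
#' smaller `sigma`.
#'
#' @param trials One subject's trial tibble (`condition_id`,
#'   `choice_category`).
#' @param cache A [build_sigma_cache()] result for the same design.
#' @param mode `"shared"` or `"per_model"`.
#' @return A tibble per model with `sigma_hat` and `ce1` (the minimized
#'   value), with the full CE1 curves attached as attribute `"curves"`.
#' @export
fit_sigma <- function(trials, cache, mode = c("shared", "per_model")) {
  stopifnot(inherits(cache, "sigma_cache"))
  mode <- match.arg(mode)
  pdist <- subject_choice_dist(trials, cache$categories,
                               cache$design$condition_id)
  n_sig <- length(cache$sigma_grid)

  curve_for <- function(qlist) {
    vapply(seq_len(n_sig), function(i) ce1_against(pdist, qlist[[i]]),
           numeric(1))
  }
  argmin_sigma <- function(curve) {
    if (all(!is.finite(curve))) {
      return(NA_integer_)
    }
    which.min(curve) # ties: which.min takes the first, i.e. smaller sigma
  }

  if (mode == "shared") {
    shared_curve <- curve_for(cache$q_shared)
    idx <- argmin_sigma(shared_curve)
    res <- purrr::map_dfr(cache$models, function(m) {
      ce1 <- if (is.na(idx)) {
        Inf
      } else {
        ce1_against(pdist, cache$q_model[[idx]][[m]])
      }
      tibble::tibble(
        model = m,
        sigma_hat = if (is.na(idx)) NA_real_ else cache$sigma_grid[idx],
        sigma_index = idx, ce1 = ce1
      )
    })
    curves <- list(shared = shared_curve)
  } else {
    curves <- lapply(setNames(cache$models, cache$models), function(m) {
      curve_for(lapply(cache$q_model, `[[`, m))
    })
    res <- purrr::map_dfr(cache$models, function(m) {
      idx <- argmin_sigma(curves[[m]])
      tibble::tibble(
        model = m,
        sigma_hat = if (is.na(idx)) NA_real_ else cache$sigma_grid[idx],
        sigma_index = idx,
        ce1 = if (is.na(idx)) Inf else curves[[m]][idx]
      )
    })
  }
  structure(res, curves = curves, mode = mode,
            class = c("sigma_fit", class(res)))
}

#' Compare the four models on one subject's confidence behavior
#'
#' Runs the full per-subject arbitration: fit `sigma` by type-1 cross
#' entropy ([fit_sigma()]), re-use each model's cached simulation at its
#' fitted `sigma`, z-score the model confidences within the design's three
#' conditions and the subject's confidences within subject, and score each
#' model by type-2 cross entropy over the choice-conditioned confidence
#' cells ([type2_cross_entropy()]). The best model is the finite-CE2
#' argmin; subjects where every model's CE2 is non-finite are flagged, and
#' a tie within `tie_tol` is reported as a tie with no winner.
#'
#' @param trials One subject's trial tibble (`subject_id`, `condition_id`,
#'   `choice_category`, `confidence_raw`).
#' @param cache A [build_sigma_cache()] result.
#' @param mode Noise-fit mode, `"shared"` (one sigma for all models) or
#'   `"per_model"`.
#' @param min_cell_count,grid_points,pad_bandwidths KDE settings, see
#'   [type2_cross_entropy()].
#' @param tie_tol Absolute CE2 difference treated as a tie.
#' @return A `confarb_fit` object; see [tidy.confarb_fit()] and
#'   [glance.confarb_fit()].
#' @export
compare_models <- function(trials, cache, mode = c("shared", "per_model"),
                           min_cell_count = 2, grid_points = 512,
                           pad_bandwidths = 3, tie_tol = 1e-9) {
  mode <- match.arg(mode)
  fit <- fit_sigma(trials, cache, mode = mode)
  subj <- zscore_within_subject(trials)
  subj <- subj[, c("condition_id", "choice_category", "conf_z")]

  ce2 <- vapply(seq_len(nrow(fit)), function(i) {
    idx <- fit$sigma_index[i]
    if (is.na(idx)) {
      return(Inf)
    }
    mtr <- cache_model_trials(cache, idx, fit$model[i])
    as.numeric(type2_cross_entropy(
      subj, mtr, min_cell_count = min_cell_count,
      grid_points = grid_points, pad_bandwidths = pad_bandwidths
    ))
  }, numeric(1))

  res <- fit
  res$ce2 <- ce2
  finite <- is.finite(ce2)
  if (!any(finite)) {
    best <- NA_character_
    flag <- "all_ce2_nonfinite"
  } else {
    o <- order(ce2)
    if (sum(finite) > 1L && abs(ce2[o[1]] - ce2[o[2]]) <= tie_tol) {
      best <- NA_character_
      flag <- "ce2_tie"
    } else {
      best <- res$model[o[1]]
      flag <- NA_character_
    }
  }
  structure(
    list(
      subject_id = if ("subject_id" %in% names(trials)) {
        as.character(trials$subject_id[1])
      } else {
        NA_character_
      },
      mode = mode, result = tibble::as_tibble(res),
      best_model = best, flag = flag
    ),
    class = "confarb_fit"
  )
}

#' @export
print.confarb_fit <- function(x, ...) {
  cat(sprintf("<confarb_fit> subject %s (%s sigma)\n", x$subject_id, x$mode))
  print(x$result[, c("model", "sigma_hat", "ce1", "ce2")])
  cat("  best model:",
      if (is.na(x$best_model)) paste0("none (", x$flag, ")") else x$best_model,
      "\n")
  invisible(x)
}

#' Fit every subject in a dataset
#'
#' @param trials Multi-subject trial tibble.
#' @param cache A [build_sigma_cache()] result.
#' @param ... Passed to [compare_models()].
#' @return A tibble with one row per subject x model plus `best_model` and
#'   `flag`; the individual `confarb_fit` objects are attached as attribute
#'   `"fits"`.
#' @export
fit_cohort <- function(trials, cache, ...) {
  ids <- unique(trials$subject_id)
  fits <- lapply(ids, function(id) {
    compare_models(trials[trials$subject_id == id, ], cache, ...)
  })
  out <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(f$result, subject_id = f$subject_id,
                  best_model = f$best_model, flag = f$flag, .before = 1L)
  })
  attr(out, "fits") <- fits
  out
}
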
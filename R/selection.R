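#' Cohen's d between two samples (pooled-SD form)
#'
#' `d = (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)` with sample
#' variances (n - 1 denominator).
#'
#' @param a,b Numeric vectors.
#' @return A single number; `NA` if the pooled variance is zero.
#' @export
#' @examples
#' cohens_d(c(0, 2), c(1, 3)) # 1 / sqrt(2)
cohens_d <- function(a, b) {
  pool <- sqrt((var(a) + var(b)) / 2)
  if (!is.finite(pool) || pool == 0) {
    return(NA_real_)
  }
  (mean(b) - mean(a)) / pool
}

#' Pairwise effect-size map over the stimulus grid
#'
#' At every simulated grid point, computes the pooled-SD Cohen's d between
#' each pair of models' z-scored confidence distributions. The simulation
#' must have been z-scored first ([zscore_confidence()]); d is computed from
#' the per-point standardized means and sample SDs. Points where a pair's
#' pooled variance is zero are recorded as missing.
#'
#' @param sim A z-scored [simulate_grid()] result with at least two models.
#' @param pairs Optional 2-column character matrix of model pairs; defaults
#'   to all unordered pairs in canonical model order.
#' @return An `effect_size_table`: tibble with one row per point x pair
#'   (`model_a`, `model_b`, `d`, per-model means/SDs).
#' @export
cohens_d_map <- function(sim, pairs = NULL) {
  stopifnot(inherits(sim, "grid_simulation"))
  if (is.null(sim$pooled)) {
    abort("Z-score the simulation first (see `zscore_confidence()`).")
  }
  models <- sim$models
  if (length(models) < 2L) abort("Need at least two simulated models.")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(models, 2L))
  }
  s <- sim$summary
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    sa <- s[s$model == a, ]
    sb <- s[s$model == b, ]
    sb <- sb[match(sa$point, sb$point), ]
    pool <- sqrt((sa$conf_sd_z^2 + sb$conf_sd_z^2) / 2)
    d <- ifelse(is.finite(pool) & pool > 0,
                (sb$conf_mean_z - sa$conf_mean_z) / pool, NA_real_)
    tibble::tibble(
      point = sa$point, c1 = sa$c1, c2 = sa$c2, c3 = sa$c3,
      model_a = a, model_b = b, d = d,
      mean_a = sa$conf_mean_z, sd_a = sa$conf_sd_z,
      mean_b = sb$conf_mean_z, sd_b = sb$conf_sd_z
    )
  })
  if (anyNA(out$d)) {
    warn(sprintf("%d point-pair(s) had zero pooled variance; d set to NA.",
                 sum(is.na(out$d))))
  }
  class(out) <- c("effect_size_table", class(out))
  out
}

#' Rank grid points by summed effect size
#'
#' Sums `|d|` over the model pairs at each point, collapses
#' permutation-equivalent points (the system is symmetric, so
#' `[0, 0, 3.5] = [0, 3.5, 0] = [3.5, 0, 0]`) to one canonical
#' ascending-sorted representative by averaging over class members, flags
#' points whose maximum strength is attained by two or more components
#' (ambiguous type-1 correct answer, e.g. `[4.5, 5, 5]`), and ranks the
#' survivors.
#'
#' @param es An [cohens_d_map()] result.
#' @param exclude_ambiguous Drop tied-maximum classes from the ranking
#'   (they stay in the table with `excluded_reason` filled in).
#' @return A tibble of canonical classes with `summed_d`, `excluded_reason`,
#'   and `rank` (NA for excluded classes), sorted by rank.
#' @export
rank_conditions <- function(es, exclude_ambiguous = TRUE) {
  stopifnot(inherits(es, "effect_size_table"))
  per_point <- es |>
    dplyr::group_by(.data$point, .data$c1, .data$c2, .data$c3) |>
    dplyr::summarise(summed_d = sum(abs(.data$d)), .groups = "drop")

  sorted <- t(apply(as.matrix(per_point[, c("c1", "c2", "c3")]), 1L, sort))
  per_point$k1 <- sorted[, 1]
  per_point$k2 <- sorted[, 2]
  per_point$k3 <- sorted[, 3]

  classes <- per_point |>
    dplyr::group_by(.data$k1, .data$k2, .data$k3) |>
    dplyr::summarise(
      summed_d = mean(.data$summed_d), n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(c1 = "k1", c2 = "k2", c3 = "k3") |>
    dplyr::mutate(
      ambiguous = .data$c2 == .data$c3, # sorted ascending: max tied iff c2==c3
      excluded_reason = dplyr::if_else(
        exclude_ambiguous & .data$ambiguous, "ambiguous_type1", NA_character_
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$summed_d))
  eligible <- is.na(classes$excluded_reason) & is.finite(classes$summed_d)
  classes$rank <- NA_integer_
  classes$rank[eligible] <- rank(-classes$summed_d[eligible],
                                 ties.method = "first")
  dplyr::arrange(classes, !eligible, .data$rank)
}

#' Select the top utility-maximizing conditions
#'
#' @param es An [cohens_d_map()] result (or a [rank_conditions()] tibble).
#' @param k Number of conditions to return.
#' @param exclude_ambiguous Passed to [rank_conditions()].
#' @return A tibble of `k` canonical strength triplets with their summed
#'   effect sizes, best first. The full ranking is attached as attribute
#'   `"ranking"` for audit.
#' @export
select_conditions <- function(es, k = 3, exclude_ambiguous = TRUE) {
  ranking <- if (inherits(es, "effect_size_table")) {
    rank_conditions(es, exclude_ambiguous = exclude_ambiguous)
  } else {
    es
  }
  surv <- ranking[!is.na(ranking$rank), ]
  if (k > nrow(surv)) {
    abort(sprintf("`k` = %d exceeds the %d surviving classes.", k, nrow(surv)))
  }
  out <- surv[order(surv$rank), ][seq_len(k), c("c1", "c2", "c3", "summed_d",
                                                "rank")]
  attr(out, "ranking") <- ranking
  out
}

#' Robustness of condition selection to the noise scale
#'
#' Reruns the full simulate / z-score / effect-size / rank pipeline at
#' several covariance scales and reports whether the same top-`k` conditions
#' are selected, plus the Spearman correlation of the summed-`|d|` rankings
#' against the first scale.
#'
#' @param grid A [signal_grid()].
#' @param noise_scales Positive covariance scales to test (the reference
#'   run is the first element).
#' @param n_trials Trials per grid point per run.
#' @param seed Integer seed (distinct child seed per scale).
#' @param k Number of top conditions compared.
#' @param models Model ids to include.
#' @return A list of class `selection_robustness`: per-scale rankings and
#'   selections, the rank correlations, and `same_topk`.
#' @export
robustness_check <- function(grid = signal_grid(),
                             noise_scales = c(1, 0.5, 1.5),
                             n_trials = 1000, seed = 1, k = 3,
                             models = confarb_models()) {
  if (any(noise_scales <= 0)) abort("`noise_scales` must be positive.")
  seeds <- child_seeds(seed, length(noise_scales))
  runs <- purrr::map2(noise_scales, seeds, function(sc, sd_i) {
    sim <- simulate_grid(grid, sigma = sc, n_trials = n_trials,
                         models = models, seed = sd_i)
    sim <- zscore_confidence(sim, "whole_grid")
    ranking <- rank_conditions(cohens_d_map(sim))
    list(scale = sc, ranking = ranking,
         selected = select_conditions(ranking, k = k))
  })
  ref <- runs[[1]]$ranking
  key <- function(r) paste(r$c1, r$c2, r$c3)
  cors <- vapply(runs, function(r) {
    m <- match(key(ref), key(r$ranking))
    cor(ref$summed_d, r$ranking$summed_d[m], method = "spearman")
  }, numeric(1))
  sel_keys <- lapply(runs, function(r) sort(key(r$selected)))
  same <- vapply(sel_keys, identical, logical(1), y = sel_keys[[1]])
  structure(
    list(
      scales = noise_scales,
      rankings = lapply(runs, `[[`, "ranking"),
      selections = lapply(runs, `[[`, "selected"),
      rank_correlation = setNames(cors, noise_scales),
      same_topk = all(same)
    ),
    class = "selection_robustness"
  )
}

#' @export
print.selection_robustness <- function(x, ...) {
  cat("<selection_robustness>\n  scales:", paste(x$scales, collapse = ", "),
      "\n  identical top-k across scales:", x$same_topk, "\n")
  cat("  Spearman rank correlation vs first scale:\n")
  print(round(x$rank_correlation, 4))
  invisible(x)
}
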
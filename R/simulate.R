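#' Monte-Carlo simulation of observer models across the stimulus grid
#'
#' Simulates `n_trials` trials of each requested model at every strength
#' triplet of the grid (11 x 11 x 11 = 1331 points, 10,000 trials per point
#' under the defaults). Within a run all models see the *same* percept stream
#' at each point (common random numbers), so differences between models are
#' purely decisional; this also makes the type-1 agreement of the
#' marginalizing, 3-point and max-rule observers exact rather than
#' statistical.
#'
#' By default only per-point sufficient statistics are stored (choice counts
#' and confidence sums, overall and per choice), which is all that the
#' z-scoring, effect-size and summary steps need; set `keep_trials = TRUE` on
#' small grids to retain the trial-level tibble.
#'
#' @param grid A [signal_grid()].
#' @param sigma Internal-noise variance scale, > 0.
#' @param n_trials Trials per grid point (default 10,000).
#' @param models Character vector of model ids to simulate.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param keep_trials Keep the trial-level tibble (memory heavy on the full
#'   grid).
#' @param tie_handling Tie handling for the marginalizing observer's grid
#'   triplets (see [posterior_plio()]).
#' @param max_draws Guard: refuse runs needing more than this many total
#'   percept draws.
#' @return A `grid_simulation` object: list with `summary` (per model x point
#'   sufficient statistics), optional `trials`, and the run settings.
#' @export
#' @examples
#' sim <- simulate_grid(signal_grid(values = c(0, 2)), n_trials = 200,
#'                      seed = 1)
simulate_grid <- function(grid = signal_grid(), sigma = 1, n_trials = 10000,
                          models = confarb_models(), seed = 1,
                          keep_trials = FALSE,
                          tie_handling = "share", max_draws = 5e7) {
  stopifnot(inherits(grid, "signal_grid"))
  assert_sigma(sigma)
  models <- check_models(models)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) abort("`n_trials` must be at least 1.")
  trip <- grid_triplets(grid)
  npt <- nrow(trip)
  if (as.double(npt) * n_trials > max_draws) {
    abort(sprintf(
      "Run needs %.3g percept draws, above the `max_draws` guard (%.3g).",
      as.double(npt) * n_trials, max_draws
    ))
  }
  cm <- as.matrix(trip)

  summaries <- vector("list", npt)
  trial_rows <- if (keep_trials) vector("list", npt) else NULL

  withr::with_seed(as.integer(seed), {
    for (i in seq_len(npt)) {
      d <- sample_percepts(cm[i, ], sigma = sigma, n = n_trials)
      res <- lapply(models, function(m) {
        decide(m, d, grid = grid, sigma = sigma, tie_handling = tie_handling)
      })
      summaries[[i]] <- point_summary_rows(res, models, cm[i, ], i, n_trials)
      if (keep_trials) {
        trial_rows[[i]] <- purrr::map2_dfr(res, models, function(r, m) {
          tibble::tibble(
            model = m, point = i, c1 = cm[i, 1], c2 = cm[i, 2], c3 = cm[i, 3],
            trial = seq_len(n_trials), choice = r$choice,
            conf_raw = r$confidence
          )
        })
      }
    }
  })

  structure(
    list(
      summary = dplyr::bind_rows(summaries),
      trials = if (keep_trials) dplyr::bind_rows(trial_rows) else NULL,
      pooled = NULL,
      grid = grid, sigma = sigma, n_trials = n_trials,
      models = models, seed = as.integer(seed), tie_handling = tie_handling
    ),
    class = "grid_simulation"
  )
}

# sufficient statistics for one point: choice counts plus confidence sums,
# overall and conditional on choice
point_summary_rows <- function(res, models, c_triplet, point, n_trials) {
  purrr::map2_dfr(res, models, function(r, m) {
    ch <- r$choice
    cf <- r$confidence
    cnt <- tabulate(ch, nbins = 3L)
    cs <- vapply(1:3, function(k) sum(cf[ch == k]), numeric(1))
    css <- vapply(1:3, function(k) sum(cf[ch == k]^2), numeric(1))
    tibble::tibble(
      model = m, point = point,
      c1 = c_triplet[1], c2 = c_triplet[2], c3 = c_triplet[3],
      n = n_trials, n1 = cnt[1], n2 = cnt[2], n3 = cnt[3],
      conf_sum = sum(cs), conf_ss = sum(css),
      cs1 = cs[1], css1 = css[1], cs2 = cs[2], css2 = css[2],
      cs3 = cs[3], css3 = css[3]
    )
  })
}

#' @export
print.grid_simulation <- function(x, ...) {
  cat(sprintf(
    "<grid_simulation> %d points x %d trials, models: %s, sigma = %g\n",
    nrow(x$summary) / length(x$models), x$n_trials,
    paste(x$models, collapse = ", "), x$sigma
  ))
  if (!is.null(x$pooled)) {
    cat(sprintf("  confidence z-scored over scope: %s\n", x$pooled$scope[1]))
  }
  invisible(x)
}

#' Z-score simulated confidence within each model
#'
#' Pools every confidence judgment of a model over the stated scope (the
#' whole grid, or a listed subset of conditions) and standardizes to mean 0,
#' SD 1. This puts the Bayesian models' posterior-probability confidences and
#' the max rule's strength-unit confidences on a common scale before
#' effect-size comparison. Whole-grid scoping is used for condition
#' selection; scoping to the three chosen conditions is used during fitting
#' and recovery.
#'
#' @param sim A [simulate_grid()] result.
#' @param scope `"whole_grid"` or `"conditions"`.
#' @param conditions For `scope = "conditions"`: a list of strength triplets
#'   (or a 3-column matrix) naming the points to pool over.
#' @return The `grid_simulation` with per-point standardized summaries
#'   (`conf_mean_z`, `conf_sd_z`, per-choice z means) and a `pooled` element;
#'   `trials$conf_z` is filled in when trials were kept.
#' @export
zscore_confidence <- function(sim, scope = c("whole_grid", "conditions"),
                              conditions = NULL) {
  stopifnot(inherits(sim, "grid_simulation"))
  scope <- match.arg(scope)
  s <- sim$summary
  in_scope <- if (scope == "whole_grid") {
    rep(TRUE, nrow(s))
  } else {
    if (is.null(conditions)) {
      abort("`conditions` must be given when scope = \"conditions\".")
    }
    cond <- to_triplet_matrix(conditions)
    keys <- paste(s$c1, s$c2, s$c3)
    keys %in% paste(cond[, 1], cond[, 2], cond[, 3])
  }
  if (!any(in_scope)) abort("No simulated points fall in the requested scope.")

  pooled <- s[in_scope, ] |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n = sum(.data$n), sum = sum(.data$conf_sum), ss = sum(.data$conf_ss),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean = .data$sum / .data$n,
      sd = sqrt(var_from_sums(.data$n, .data$sum, .data$ss)),
      scope = scope
    )
  if (any(!is.finite(pooled$sd)) || any(pooled$sd <= 0)) {
    abort("Pooled confidence SD is zero or undefined; cannot z-score.")
  }

  stats <- pooled[match(s$model, pooled$model), ]
  s$conf_mean_z <- (s$conf_sum / s$n - stats$mean) / stats$sd
  s$conf_sd_z <- sqrt(var_from_sums(s$n, s$conf_sum, s$conf_ss)) / stats$sd
  for (k in 1:3) {
    nk <- s[[paste0("n", k)]]
    mk <- ifelse(nk > 0, s[[paste0("cs", k)]] / nk, NA_real_)
    s[[paste0("conf_mean_z", k)]] <- (mk - stats$mean) / stats$sd
  }
  sim$summary <- s
  sim$pooled <- pooled
  if (!is.null(sim$trials)) {
    tstats <- pooled[match(sim$trials$model, pooled$model), ]
    sim$trials$conf_z <- (sim$trials$conf_raw - tstats$mean) / tstats$sd
  }
  sim
}

to_triplet_matrix <- function(conditions) {
  if (is.data.frame(conditions)) {
    conditions <- as.matrix(conditions[, c("c1", "c2", "c3")])
  }
  if (is.list(conditions) && !is.matrix(conditions)) {
    conditions <- do.call(rbind, conditions)
  }
  if (is.null(dim(conditions))) conditions <- matrix(conditions, nrow = 1L)
  stopifnot(ncol(conditions) == 3L)
  conditions
}

#' Per-point behavioral summaries of a grid simulation
#'
#' Accuracy at a point is the probability that the simulated choice equals
#' the designated correct option; at points whose maximum strength is tied
#' across components the designated correct option is uniform over the tied
#' set, so each tied choice counts with weight 1/#tied (a symmetric triplet
#' scores exactly 1/3 in expectation).
#'
#' @param sim A [simulate_grid()] result (z-scored columns are included when
#'   present).
#' @return A tibble per model x point with `accuracy`, mean raw confidence,
#'   and (if available) mean/SD z-confidence for correct and incorrect
#'   choices.
#' @export
summarize_points <- function(sim) {
  stopifnot(inherits(sim, "grid_simulation"))
  s <- sim$summary
  m <- as.matrix(s[, c("c1", "c2", "c3")])
  mx <- rowmax_num(m)
  is_max <- m == mx
  ntied <- rowSums(is_max)
  cnt <- as.matrix(s[, c("n1", "n2", "n3")])
  acc <- rowSums(cnt * is_max) / (ntied * s$n)

  cs <- as.matrix(s[, c("cs1", "cs2", "cs3")])
  css <- as.matrix(s[, c("css1", "css2", "css3")])
  n_cor <- rowSums(cnt * is_max)
  sum_cor <- rowSums(cs * is_max)
  ss_cor <- rowSums(css * is_max)
  n_inc <- s$n - n_cor
  sum_inc <- s$conf_sum - sum_cor
  ss_inc <- s$conf_ss - ss_cor

  out <- tibble::tibble(
    model = s$model, point = s$point, c1 = s$c1, c2 = s$c2, c3 = s$c3,
    n = s$n, accuracy = acc,
    conf_mean = s$conf_sum / s$n,
    conf_mean_correct = ifelse(n_cor > 0, sum_cor / n_cor, NA_real_),
    conf_sd_correct = sqrt(var_from_sums(n_cor, sum_cor, ss_cor)),
    conf_mean_incorrect = ifelse(n_inc > 0, sum_inc / n_inc, NA_real_),
    conf_sd_incorrect = sqrt(var_from_sums(n_inc, sum_inc, ss_inc))
  )
  if (!is.null(sim$pooled)) {
    p <- sim$pooled[match(out$model, sim$pooled$model), ]
    out$conf_mean_z <- (out$conf_mean - p$mean) / p$sd
    out$conf_mean_z_correct <- (out$conf_mean_correct - p$mean) / p$sd
    out$conf_sd_z_correct <- out$conf_sd_correct / p$sd
    out$conf_mean_z_incorrect <- (out$conf_mean_incorrect - p$mean) / p$sd
    out$conf_sd_z_incorrect <- out$conf_sd_incorrect / p$sd
  }
  out
}
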
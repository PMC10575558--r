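#' Precompute model simulations over a noise-level search grid
#'
#' The noise fit is a grid search: for every candidate `sigma` the models'
#' choice-category distributions and confidence samples at the design's three
#' conditions are needed. Because these do not depend on the subject, they are
#' simulated once per `sigma` candidate (with a fixed per-candidate seed, i.e.
#' common random numbers across candidates' consumers) and reused for every
#' subject fitted against the cache.
#'
#' Within a candidate all models share the percept stream. Choice categories
#' are stored per model (only the hierarchical observer's choices can differ
#' from the others') together with a "shared" category from the common
#' `argmax d` rule used for the pooled type-1 fit.
#'
#' @param design An `experiment_design` with 3 conditions.
#' @param sigma_grid Candidate noise values (variance scale), default 0.25 to
#'   6 in steps of 0.05.
#' @param sim_n Simulated trials per condition per candidate.
#' @param seed Integer seed (one child seed per candidate, so results do not
#'   depend on evaluation order).
#' @param models Model ids to include.
#' @param grid [signal_grid()] support for the Bayesian marginalizations.
#' @return A `sigma_cache` object.
#' @export
build_sigma_cache <- function(design, sigma_grid = seq(0.25, 6, by = 0.05),
                              sim_n = 5000, seed = 1,
                              models = confarb_models(),
                              grid = signal_grid()) {
  stopifnot(inherits(design, "experiment_design"))
  models <- check_models(models)
  if (any(sigma_grid <= 0)) abort("`sigma_grid` must be positive.")
  sigma_grid <- sort(unique(as.double(sigma_grid)))
  sim_n <- as.integer(sim_n)
  if (sim_n < 2L) abort("`sim_n` must be at least 2.")
  seeds <- child_seeds(seed, length(sigma_grid))
  cats <- choice_categories()
  strengths <- as.matrix(design[, c("c_lowest", "c_second", "c_highest")])
  # percept component j holds the rank-j coherence: 1 lowest, 2 second,
  # 3 highest
  comp_cat <- c("lowest", "second", "highest")

  entries <- purrr::map2(sigma_grid, seeds, function(sg, sd_i) {
    withr::with_seed(sd_i, {
      lapply(seq_len(nrow(design)), function(ci) {
        d <- sample_percepts(strengths[ci, ], sigma = sg, n = sim_n)
        cat_shared <- comp_cat[row_argmax(d)]
        cat_m <- matrix(NA_character_, sim_n, length(models),
                        dimnames = list(NULL, models))
        conf_m <- matrix(NA_real_, sim_n, length(models),
                         dimnames = list(NULL, models))
        for (m in models) {
          r <- decide(m, d, grid = grid, sigma = sg)
          cat_m[, m] <- comp_cat[r$choice]
          conf_m[, m] <- r$confidence
        }
        list(cat_shared = cat_shared, cat = cat_m, conf = conf_m)
      })
    })
  })

  # choice-category probabilities q[condition, category] per candidate
  qtab <- function(catvec) {
    counts <- table(factor(catvec, levels = cats))
    as.numeric(counts) / length(catvec)
  }
  q_shared <- lapply(entries, function(e) {
    t(vapply(e, function(cond) qtab(cond$cat_shared), numeric(3)))
  })
  q_model <- lapply(entries, function(e) {
    setNames(lapply(models, function(m) {
      t(vapply(e, function(cond) qtab(cond$cat[, m]), numeric(3)))
    }), models)
  })

  structure(
    list(
      design = design, sigma_grid = sigma_grid, sim_n = sim_n,
      seed = as.integer(seed), models = models, grid = grid,
      entries = entries, q_shared = q_shared, q_model = q_model,
      categories = cats
    ),
    class = "sigma_cache"
  )
}

#' @export
print.sigma_cache <- function(x, ...) {
  cat(sprintf(
    "<sigma_cache> %d sigma candidates in [%g, %g], %d trials/condition, models: %s\n",
    length(x$sigma_grid), min(x$sigma_grid), max(x$sigma_grid), x$sim_n,
    paste(x$models, collapse = ", ")
  ))
  invisible(x)
}

# model-simulated trials at one cached candidate, z-scored within the three
# design conditions (pooled across conditions for that model)
cache_model_trials <- function(cache, sigma_index, model) {
  e <- cache$entries[[sigma_index]]
  out <- purrr::map_dfr(seq_along(e), function(ci) {
    tibble::tibble(
      condition_id = cache$design$condition_id[ci],
      choice_category = e[[ci]]$cat[, model],
      conf_raw = e[[ci]]$conf[, model]
    )
  })
  s <- sd(out$conf_raw)
  if (!is.finite(s) || s == 0) s <- 1e-12
  out$conf_z <- (out$conf_raw - mean(out$conf_raw)) / s
  out
}
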
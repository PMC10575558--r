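#' Draw noisy percepts around a stimulus triplet
#'
#' The observer never sees the true strengths `c`; each trial yields a percept
#' `d` drawn from a trivariate normal centred on `c` with covariance
#' `sigma * I3`. `sigma` scales the covariance entries directly, so it is the
#' per-component variance (standard deviation `sqrt(sigma)`).
#'
#' @param c_triplet Numeric length-3 vector of true stimulus strengths.
#' @param sigma Internal-noise scale (per-component variance), > 0.
#' @param n Number of percepts to draw.
#' @return An `n` x 3 numeric matrix of percepts.
#' @export
#' @examples
#' set.seed(1)
#' d <- sample_percepts(c(0, 0, 3.5), sigma = 1, n = 5)
sample_percepts <- function(c_triplet, sigma = 1, n = 1) {
  if (!is.numeric(c_triplet) || length(c_triplet) != 3L ||
      any(!is.finite(c_triplet))) {
    abort("`c_triplet` must be a finite numeric vector of length 3.")
  }
  assert_sigma(sigma)
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1.")
  matrix(rnorm(3L * n, mean = rep(c_triplet, each = n), sd = sqrt(sigma)),
         nrow = n, ncol = 3L)
}

# Per-dimension log-density table: list of three n x K matrices,
# lf[[j]][i, k] = log N(d[i, j]; values[k], sigma).
dim_logdens <- function(d, values, sigma) {
  sdv <- sqrt(sigma)
  lapply(1:3, function(j) {
    outer(d[, j], values, function(x, m) dnorm(x, mean = m, sd = sdv,
                                               log = TRUE))
  })
}

#' Posterior of the marginalizing Bayesian ideal observer
#'
#' Computes `p(S_i | d)` for the three "stimulus i is strongest" hypotheses by
#' marginalizing the likelihood of the percept over the full 3-D grid of
#' candidate strength triplets, partitioned by which component of the triplet
#' is largest. Grid triplets with tied maxima share their prior mass equally
#' across the tied hypotheses (or are excluded, see `tie_handling`). The prior
#' over hypotheses is uniform (1/3) and the prior over triplets is flat on the
#' grid; densities are handled on the log scale to avoid underflow.
#'
#' @param d A percept (length-3 vector) or an `n` x 3 matrix of percepts.
#' @param grid A [signal_grid()] giving the marginalization support.
#' @param sigma Internal-noise variance scale, > 0.
#' @param tie_handling How grid triplets with tied maxima contribute:
#'   `"share"` (default, weight 1/#tied to each tied hypothesis, conserving
#'   prior mass and symmetry), `"exclude"` (boundary triplets dropped),
#'   `"all"` (full weight to every tied hypothesis, i.e. overlapping
#'   weak-inequality regions), or `"first"` (full weight to the
#'   lowest-indexed tied hypothesis; asymmetric, provided for comparison
#'   only).
#' @return An `n` x 3 matrix of posterior probabilities; rows sum to 1.
#' @export
#' @examples
#' posterior_plio(c(1, 0, 0), signal_grid(values = c(0, 1)), sigma = 1)
posterior_plio <- function(d, grid, sigma = 1,
                           tie_handling = c("share", "exclude", "all", "first")) {
  stopifnot(inherits(grid, "signal_grid"))
  assert_sigma(sigma)
  tie_handling <- match.arg(tie_handling)
  d <- as_percept_matrix(d)
  v <- grid$values
  K <- length(v)
  trip <- grid_triplets(grid)
  W <- argmax_weights(trip, tie_handling)
  # triplet component indices into the value vector (expand.grid order:
  # c1 varies fastest)
  idx <- as.matrix(expand.grid(i1 = seq_len(K), i2 = seq_len(K),
                               i3 = seq_len(K), KEEP.OUT.ATTRS = FALSE))
  n <- nrow(d)
  out <- matrix(NA_real_, n, 3L)
  # chunk rows so the n_chunk x K^3 product matrix stays small
  chunk <- max(1L, floor(4e6 / (K^3)))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    lf <- dim_logdens(d[rows, , drop = FALSE], v, sigma)
    # subtract per-row maxima (factorizes over dimensions); the common
    # constant cancels in the normalization
    f <- lapply(lf, function(m) exp(m - rowmax_num(m)))
    G <- f[[1]][, idx[, 1], drop = FALSE] *
      f[[2]][, idx[, 2], drop = FALSE] *
      f[[3]][, idx[, 3], drop = FALSE]
    num <- G %*% W
    out[rows, ] <- num / rowSums(num)
  }
  out
}

#' Posterior of the hierarchical Bayesian observer
#'
#' The observer first infers each source strength to equal the observed
#' evidence on that axis (`c_i* = d_i`), then evaluates the posterior that
#' stimulus `i` is strongest under sources `[d_1,0,0]`, `[0,d_2,0]`,
#' `[0,0,d_3]`. This reduces to `p_i` proportional to
#' `exp(-sum_{j != i} d_j^2 / (2 sigma))`, so the choice tracks
#' `argmax |d_i|`: near the origin a large *negative* evidence component can
#' win, the one place this model's choices deviate from the other three.
#'
#' @inheritParams posterior_plio
#' @return An `n` x 3 matrix of posterior probabilities; rows sum to 1.
#' @export
#' @examples
#' posterior_plh(c(-2, 1, 0.5), sigma = 1) # chooses 1 despite d1 < 0
posterior_plh <- function(d, sigma = 1) {
  assert_sigma(sigma)
  d <- as_percept_matrix(d)
  ln <- d^2 / (2 * sigma)
  e <- exp(ln - rowmax_num(ln))
  e / rowSums(e)
}

#' Posterior of the 3-point Bayesian ideal observer
#'
#' Hypothesis `i` assumes an axis-aligned source: strength `c` on axis `i`
#' and zero on the others, with one shared scalar `c` marginalized over the
#' 1-D grid. `p(S_i | d)` is proportional to
#' `sum_c N(d; c e_i, sigma I3)` under a flat prior over grid values.
#'
#' @inheritParams posterior_plio
#' @return An `n` x 3 matrix of posterior probabilities; rows sum to 1.
#' @export
#' @examples
#' posterior_aio(c(1, 0, 0), signal_grid(values = c(0, 1)), sigma = 1)
posterior_aio <- function(d, grid, sigma = 1) {
  stopifnot(inherits(grid, "signal_grid"))
  assert_sigma(sigma)
  d <- as_percept_matrix(d)
  v <- grid$values
  lf <- dim_logdens(d, v, sigma)
  # log sum over grid of the on-axis density, per dimension
  lse <- vapply(lf, function(m) {
    mx <- rowmax_num(m)
    mx + log(rowSums(exp(m - mx)))
  }, numeric(nrow(d)))
  lse <- matrix(lse, nrow = nrow(d))
  # off-axis components sit at strength 0
  l0 <- vapply(1:3, function(j) dnorm(d[, j], 0, sqrt(sigma), log = TRUE),
               numeric(nrow(d)))
  l0 <- matrix(l0, nrow = nrow(d))
  tot0 <- rowSums(l0)
  ln <- lse + (tot0 - l0) # S_i + sum_{j != i} log N(d_j; 0, sigma)
  e <- exp(ln - rowmax_num(ln))
  e / rowSums(e)
}

#' Response-congruent evidence (max) rule
#'
#' Chooses the axis with the largest evidence and takes as confidence the raw
#' evidence on the chosen axis alone, ignoring the alternatives. Confidence is
#' in stimulus-strength units and unbounded (it can be negative).
#'
#' @param d A percept (length-3 vector) or an `n` x 3 matrix of percepts.
#' @param random_ties Break exact ties uniformly at random from the current
#'   RNG stream (default); otherwise the lowest index wins.
#' @return A tibble with columns `choice` (1, 2 or 3) and `confidence`.
#' @export
#' @examples
#' rce_decision(c(3, 1, 2)) # choice 1, confidence 3
rce_decision <- function(d, random_ties = TRUE) {
  d <- as_percept_matrix(d)
  ch <- row_argmax(d, random_ties = random_ties)
  tibble::tibble(choice = ch, confidence = d[cbind(seq_len(nrow(d)), ch)])
}

#' Model posterior dispatcher
#'
#' Evaluates the named Bayesian model's posterior for one or more percepts.
#' `"rce"` has no posterior; use [rce_decision()].
#'
#' @param model One of `"plio"`, `"plh"`, `"aio"`.
#' @inheritParams posterior_plio
#' @return An `n` x 3 matrix of posterior probabilities.
#' @export
model_posterior <- function(model, d, grid = signal_grid(), sigma = 1,
                            tie_handling = "share") {
  model <- check_models(model)
  stopifnot(length(model) == 1L)
  switch(model,
    plio = posterior_plio(d, grid, sigma, tie_handling),
    plh = posterior_plh(d, sigma),
    aio = posterior_aio(d, grid, sigma),
    rce = abort("`rce` has no posterior; use `rce_decision()`.")
  )
}

# Apply one model's decision rule to a matrix of percepts.
# Returns tibble(choice, confidence): confidence is the posterior probability
# of the chosen option for the Bayesian models, raw chosen evidence for RCE.
decide <- function(model, d, grid, sigma, tie_handling = "share") {
  d <- as_percept_matrix(d)
  if (model == "rce") {
    return(rce_decision(d))
  }
  p <- model_posterior(model, d, grid = grid, sigma = sigma,
                       tie_handling = tie_handling)
  ch <- row_argmax(p)
  tibble::tibble(choice = ch, confidence = p[cbind(seq_len(nrow(d)), ch)])
}

#' Simulate trials of one model at a stimulus triplet
#'
#' Draws `n_trials` percepts around `c_triplet` and applies the model's
#' decision and confidence rules.
#'
#' @param model Model id (see [confarb_models()]).
#' @param c_triplet True stimulus strengths (length 3).
#' @inheritParams posterior_plio
#' @param n_trials Number of trials.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `trial`, `choice`, `confidence`.
#' @export
#' @examples
#' simulate_trials("rce", c(0, 0, 3.5), n_trials = 5, seed = 1)
simulate_trials <- function(model, c_triplet, grid = signal_grid(),
                            sigma = 1, n_trials = 100, seed = NULL,
                            tie_handling = "share") {
  model <- check_models(model)
  stopifnot(length(model) == 1L)
  run <- function() {
    d <- sample_percepts(c_triplet, sigma = sigma, n = n_trials)
    decide(model, d, grid = grid, sigma = sigma, tie_handling = tie_handling)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  dplyr::mutate(out, trial = dplyr::row_number(), .before = 1L)
}
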
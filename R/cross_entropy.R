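#' Type-1 cross entropy between two choice distributions
#'
#' `CE1 = -sum_x p(x) log q(x)` with the natural log, where `p` is the
#' observed (data) distribution over the three choice categories and `q` the
#' model's. Returns `+Inf` when the model assigns zero probability to a
#' category the data uses; this is informative and is never floored.
#'
#' @param p,q Probability vectors of equal length; `p` must sum to 1.
#' @return A non-negative scalar (possibly `Inf`).
#' @export
#' @examples
#' type1_cross_entropy(c(0.5, 0.5, 0), c(0.5, 0.5, 0)) # log(2)
#' type1_cross_entropy(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)) # -log(0.25)
type1_cross_entropy <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  if (any(p < 0) || any(q < 0)) abort("Probabilities must be non-negative.")
  if (abs(sum(p) - 1) > 1e-8) abort("`p` must sum to 1.")
  used <- p > 0
  if (any(q[used] == 0)) {
    return(Inf)
  }
  -sum(p[used] * log(q[used]))
}

# Scott's-rule bandwidth for a 1-D Gaussian KDE; guarded away from zero so a
# degenerate (constant) sample still defines a density.
kde_bandwidth <- function(x) {
  b <- sd(x) * length(x)^(-1 / 5)
  if (!is.finite(b) || b <= 0) b <- 1e-8
  b
}

# Gaussian KDE evaluated at `at`
kde_eval <- function(x, at, bw) {
  rowMeans(dnorm(outer(at, x, "-") / bw)) / bw
}

#' Cross entropy between two samples via Gaussian KDE
#'
#' Smooths both samples with a Gaussian kernel at a *shared* bandwidth (the
#' data sample's Scott's-rule bandwidth), evaluates both on a shared grid of
#' equally spaced points
#' spanning the pooled range extended by `pad_bandwidths` bandwidths,
#' normalizes the data side `p` to a discrete distribution on the grid, and
#' returns `-sum p log q` with `q` kept as a *density*. Keeping `q` in
#' density units makes the value independent of the grid span, so cross
#' entropies computed against different model samples are directly
#' comparable (a grid-renormalized `q` would add a model-dependent
#' log-bin-width constant that can dominate the comparison). The result
#' approximates the differential cross entropy and can be negative for very
#' concentrated model densities. It is `+Inf` when `q` underflows to zero
#' anywhere `p` has mass — no flooring is applied, because such infinities
#' drive the exclusion rules downstream.
#'
#' The shared bandwidth matters twice over. With per-sample bandwidths a
#' small data sample is smoothed more than a large model sample, so the
#' generating model's density systematically looks too narrow against its
#' own data and a slightly wider competitor wins — the estimator would not
#' be consistent. And any bandwidth that depends on the model sample makes
#' the smoothing differ between candidate models, distorting their
#' comparison. Anchoring the bandwidth to the data sample fixes both: equal
#' smoothing on both sides restores the Gibbs property in the large-sample
#' limit, and every candidate model is scored at the same resolution.
#'
#' @param x Data sample (defines `p`).
#' @param y Model sample (defines `q`).
#' @param grid_points Number of evaluation points (default 512).
#' @param pad_bandwidths Grid padding in units of the larger bandwidth.
#' @return A scalar cross entropy (possibly `Inf`), with the evaluation grid
#'   and bandwidths attached as attributes.
#' @export
#' @examples
#' set.seed(1)
#' kde_cross_entropy(rnorm(100), rnorm(100)) # close to N(0,1) entropy
kde_cross_entropy <- function(x, y, grid_points = 512, pad_bandwidths = 3) {
  if (length(x) < 2L || length(y) < 2L) {
    return(structure(Inf, reason = "sample_too_small"))
  }
  bw <- kde_bandwidth(x)
  pad <- pad_bandwidths * bw
  at <- seq(min(x, y) - pad, max(x, y) + pad, length.out = grid_points)
  pd <- kde_eval(x, at, bw)
  qd <- kde_eval(y, at, bw)
  p <- pd / sum(pd)
  used <- p > 0
  out <- if (any(qd[used] == 0)) Inf else -sum(p[used] * log(qd[used]))
  structure(out, bandwidth = bw, grid_range = range(at))
}

#' Type-2 cross entropy over choice-conditioned confidence distributions
#'
#' For every condition x choice-category cell, compares the subject's and the
#' model's z-scored confidence samples by [kde_cross_entropy()], then
#' averages the per-cell cross entropies weighted by the subject's empirical
#' cell frequencies. Subject cells with fewer than `min_cell_count` trials
#' are skipped (and listed in the output); a cell where the model sample is
#' degenerate or its density underflows contributes `+Inf`, mirroring the
#' infinity-driven observer exclusions downstream.
#'
#' @param subject Tibble with columns `condition_id`, `choice_category`,
#'   `conf_z` (subject trials).
#' @param model Tibble with the same columns (model-simulated trials at the
#'   fitted noise level, z-scored within the design's conditions).
#' @param min_cell_count Minimum subject trials for a cell to enter the sum.
#' @param grid_points,pad_bandwidths Passed to [kde_cross_entropy()].
#' @return A scalar CE2 (possibly `Inf`) with a per-cell tibble attached as
#'   attribute `"cells"`.
#' @export
type2_cross_entropy <- function(subject, model, min_cell_count = 2,
                                grid_points = 512, pad_bandwidths = 3) {
  need <- c("condition_id", "choice_category", "conf_z")
  if (!all(need %in% names(subject)) || !all(need %in% names(model))) {
    abort("`subject` and `model` need condition_id, choice_category, conf_z.")
  }
  cells <- subject |>
    dplyr::count(.data$condition_id, .data$choice_category, name = "n_subject")
  cells$skipped <- cells$n_subject < min_cell_count
  used <- cells[!cells$skipped, ]
  if (nrow(used) == 0L) {
    return(structure(Inf, cells = cells, reason = "no_usable_cells"))
  }
  used$weight <- used$n_subject / sum(used$n_subject)
  used$ce <- purrr::map_dbl(seq_len(nrow(used)), function(i) {
    sx <- subject$conf_z[subject$condition_id == used$condition_id[i] &
                           subject$choice_category == used$choice_category[i]]
    my <- model$conf_z[model$condition_id == used$condition_id[i] &
                         model$choice_category == used$choice_category[i]]
    as.numeric(kde_cross_entropy(sx, my, grid_points = grid_points,
                                 pad_bandwidths = pad_bandwidths))
  })
  out <- sum(used$weight * used$ce)
  cells <- dplyr::left_join(
    cells, used[, c("condition_id", "choice_category", "weight", "ce")],
    by = c("condition_id", "choice_category")
  )
  structure(out, cells = cells)
}
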
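#' Stimulus-strength grid
#'
#' Defines the discrete grid of candidate stimulus strengths used both to
#' enumerate simulated stimulus triplets and as the support of the flat prior
#' over source strengths in the Bayesian observers' marginalizations. The
#' defaults (0 to 5 in steps of 0.5, 11 values, 1331 triplets) are the
#' workflow's standard simulation grid; strengths are in arbitrary stimulus
#' units that map onto motion coherence by a fixed scale factor (see
#' [design_from_strengths()]).
#'
#' @param min_strength,max_strength Range of strengths (inclusive).
#' @param step Grid spacing; must divide the range evenly.
#' @param values Optional explicit strictly increasing value vector; overrides
#'   the range arguments.
#' @return An object of class `signal_grid`: a list with `values` (ordered
#'   strengths) and the defining range.
#' @export
#' @examples
#' g <- signal_grid()
#' length(g$values) # 11
#' nrow(grid_triplets(g)) # 1331
signal_grid <- function(min_strength = 0, max_strength = 5, step = 0.5,
                        values = NULL) {
  if (is.null(values)) {
    assert_scalar_number(min_strength, "min_strength")
    assert_scalar_number(max_strength, "max_strength")
    assert_scalar_number(step, "step", lower = 0, strict_lower = TRUE)
    if (max_strength <= min_strength) {
      abort("`max_strength` must exceed `min_strength`.")
    }
    values <- seq(min_strength, max_strength, by = step)
  } else {
    if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values))) {
      abort("`values` must be a non-empty finite numeric vector.")
    }
    if (is.unsorted(values, strictly = TRUE)) {
      abort("`values` must be strictly increasing.")
    }
    min_strength <- min(values)
    max_strength <- max(values)
    step <- if (length(values) > 1L) values[2L] - values[1L] else NA_real_
  }
  structure(
    list(
      values = as.double(values),
      min_strength = as.double(min_strength),
      max_strength = as.double(max_strength),
      step = as.double(step)
    ),
    class = "signal_grid"
  )
}

#' @export
print.signal_grid <- function(x, ...) {
  cat(sprintf(
    "<signal_grid> %d strengths in [%g, %g] (step %g); %d triplets\n",
    length(x$values), x$min_strength, x$max_strength, x$step,
    length(x$values)^3
  ))
  invisible(x)
}

#' Enumerate all strength triplets of a grid
#'
#' @param grid A [signal_grid()].
#' @return A tibble with columns `c1`, `c2`, `c3`, one row per ordered triplet
#'   (`length(grid$values)^3` rows).
#' @export
grid_triplets <- function(grid) {
  stopifnot(inherits(grid, "signal_grid"))
  v <- grid$values
  tibble::as_tibble(expand.grid(c1 = v, c2 = v, c3 = v,
                                KEEP.OUT.ATTRS = FALSE))
}

# Hypothesis-weight matrix for the region-marginalizing ideal observer:
# one row per grid triplet, one column per "stimulus i is strongest"
# hypothesis. A triplet whose maximum is attained by a single component gives
# weight 1 to that hypothesis; tied maxima either share their prior mass
# equally ("share") or are dropped ("exclude").
argmax_weights <- function(triplets,
                           tie_handling = c("share", "exclude", "all",
                                            "first")) {
  tie_handling <- match.arg(tie_handling)
  m <- as.matrix(triplets[, c("c1", "c2", "c3")])
  mx <- rowmax_num(m)
  is_max <- m == mx
  ntied <- rowSums(is_max)
  w <- is_max * 1
  if (tie_handling == "share") {
    w <- w / ntied
  } else if (tie_handling == "exclude") {
    w[ntied > 1L, ] <- 0
  } else if (tie_handling == "first") {
    # whole mass to the lowest-indexed tied component (asymmetric)
    w <- matrix(0, nrow(m), 3L)
    w[cbind(seq_len(nrow(m)), max.col(is_max, ties.method = "first"))] <- 1
  } # "all": full weight to every tied hypothesis
  w
}
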
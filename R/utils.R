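# internal helpers: validation, seeds, row-wise numerics

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g.", name, upper))
  }
  invisible(x)
}

assert_sigma <- function(sigma) {
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
}

# Coerce percepts to an n x 3 matrix; a length-3 vector is one percept.
as_percept_matrix <- function(d) {
  if (is.data.frame(d)) d <- as.matrix(d)
  if (is.null(dim(d))) {
    if (length(d) != 3L) abort("A single percept must have 3 components.")
    d <- matrix(d, nrow = 1L)
  }
  if (ncol(d) != 3L) abort("Percepts must have 3 columns (one per stimulus).")
  storage.mode(d) <- "double"
  if (any(!is.finite(d))) abort("Percepts must be finite.")
  d
}

# Independent child seeds from a master seed. Drawing them all up front makes
# downstream results independent of execution order. Kept below 2^31.
child_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Row-wise argmax with uniform random tie-breaking from the current RNG
# stream. Ties have probability zero for continuous percepts but occur in
# degenerate test inputs.
row_argmax <- function(x, random_ties = TRUE) {
  mx <- do.call(pmax, as.data.frame(x))
  is_max <- x == mx
  ntied <- rowSums(is_max)
  out <- max.col(is_max, ties.method = "first")
  tied <- which(ntied > 1L)
  if (length(tied) > 0L && random_ties) {
    out[tied] <- vapply(tied, function(i) {
      cand <- which(is_max[i, ])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
  }
  out
}

rowmax_num <- function(x) do.call(pmax, as.data.frame(x))

# mean/sd summaries from accumulated sums (sample variance, n - 1)
var_from_sums <- function(n, s, ss) {
  ifelse(n > 1, pmax(0, (ss - s^2 / n) / (n - 1)), NA_real_)
}
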
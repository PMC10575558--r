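# shared small fixtures for fast tests

tiny_grid <- function() signal_grid(values = c(0, 1))
small_grid <- function() signal_grid(values = c(0, 1, 2))

test_design <- function() default_design()

# a coarse, small sigma cache reused across fitting tests (built once)
quick_cache <- local({
  cache <- NULL
  function(sigma_grid = seq(0.5, 5, by = 0.25), sim_n = 800, seed = 99) {
    if (is.null(cache)) {
      cache <<- build_sigma_cache(test_design(), sigma_grid = sigma_grid,
                                  sim_n = sim_n, seed = seed)
    }
    cache
  }
})

# independent brute-force oracle for the region-marginalizing posterior:
# plain loops over all grid triplets, no shared code with the implementation
oracle_plio <- function(d, values, sigma, tie_handling = "share") {
  num <- c(0, 0, 0)
  for (a in values) for (b in values) for (cc in values) {
    trip <- c(a, b, cc)
    lik <- prod(dnorm(d, mean = trip, sd = sqrt(sigma)))
    tied <- which(trip == max(trip))
    w <- switch(tie_handling,
      share = rep(1 / length(tied), length(tied)),
      all = rep(1, length(tied)),
      exclude = if (length(tied) > 1) rep(0, length(tied)) else 1
    )
    num[tied] <- num[tied] + lik * w
  }
  num / sum(num)
}

# brute-force oracle for the 3-point observer: axis-aligned sources, shared
# scalar strength enumerated over the 1-D grid
oracle_aio <- function(d, values, sigma) {
  num <- vapply(1:3, function(i) {
    tot <- 0
    for (v in values) {
      mu <- c(0, 0, 0)
      mu[i] <- v
      tot <- tot + prod(dnorm(d, mean = mu, sd = sqrt(sigma)))
    }
    tot
  }, numeric(1))
  num / sum(num)
}

random_percepts <- function(n, seed = 1, scale = 3) {
  withr::with_seed(seed, matrix(rnorm(n * 3, sd = scale), n, 3))
}
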
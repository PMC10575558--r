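test_that("sample_percepts matches its generating distribution", {
  # vanishing-noise limit
  d <- sample_percepts(c(1, 2, 3), sigma = 1e-12, n = 1)
  expect_equal(as.numeric(d), c(1, 2, 3), tolerance = 1e-5)

  # law of large numbers on the mean
  n <- 1e5
  d <- withr::with_seed(11, sample_percepts(c(0, 0, 3.5), sigma = 1, n = n))
  se <- 1 / sqrt(n)
  expect_true(all(abs(colMeans(d) - c(0, 0, 3.5)) < 3 * se))

  # empirical covariance is the identity
  d <- withr::with_seed(12, sample_percepts(c(0, 0, 0), sigma = 1, n = n))
  expect_true(max(abs(cov(d) - diag(3))) < 0.05)

  expect_error(sample_percepts(c(0, NA, 1), 1, 1), "finite")
  expect_error(sample_percepts(c(0, 0, 0), sigma = 0, n = 1), "sigma")
})

test_that("marginalizing-observer posterior matches brute-force enumeration", {
  for (grid in list(tiny_grid(), small_grid())) {
    for (tie in c("share", "all", "exclude")) {
      for (seed in 1:3) {
        d <- as.numeric(random_percepts(1, seed = seed))
        got <- posterior_plio(d, grid, sigma = 1, tie_handling = tie)
        want <- oracle_plio(d, grid$values, 1, tie_handling = tie)
        expect_equal(as.numeric(got), want, tolerance = 1e-12)
      }
    }
    # canonical hand case
    got <- posterior_plio(c(1, 0, 0), grid, sigma = 1)
    expect_equal(as.numeric(got), oracle_plio(c(1, 0, 0), grid$values, 1),
                 tolerance = 1e-12)
  }
})

test_that("3-point-observer posterior matches brute-force enumeration", {
  for (grid in list(tiny_grid(), small_grid())) {
    for (seed in 4:6) {
      d <- as.numeric(random_percepts(1, seed = seed))
      got <- posterior_aio(d, grid, sigma = 1)
      expect_equal(as.numeric(got), oracle_aio(d, grid$values, 1),
                   tolerance = 1e-12)
    }
  }
  # hand case: d = [1,0,0], grid {0,1}. Hypothesis 1 sums
  # phi(1;c)phi(0;0)phi(0;0) over c in {0,1}; hypothesis 2 sums
  # phi(1;0)phi(0;c)phi(0;0). Their ratio reduces to exp(1/2).
  p <- posterior_aio(c(1, 0, 0), tiny_grid(), sigma = 1)
  expect_equal(p[1] / p[2], exp(1 / 2), tolerance = 1e-12)
  expect_equal(p[2], p[3], tolerance = 1e-12)
})

test_that("posteriors are normalized, symmetric and permutation-equivariant", {
  grid <- signal_grid()
  d <- random_percepts(50, seed = 7)
  for (fn in list(
    function(x) posterior_plio(x, grid, 1.3),
    function(x) posterior_plh(x, 1.3),
    function(x) posterior_aio(x, grid, 1.3)
  )) {
    p <- fn(d)
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0 & p <= 1))
    # equal evidence -> uniform posterior
    expect_equal(as.numeric(fn(c(2.2, 2.2, 2.2))), rep(1 / 3, 3),
                 tolerance = 1e-9)
    # permuting the percept permutes the posterior identically
    perm <- c(3, 1, 2)
    expect_equal(fn(d[, perm]), p[, perm], tolerance = 1e-12)
  }
})

test_that("hierarchical observer follows the projected-source kernel", {
  # direct evaluation of the unnormalized kernel exp(-sum_{j!=i} d_j^2 / 2)
  p <- posterior_plh(c(-2, 1, 0.5), sigma = 1)
  z <- exp(-0.625) + exp(-2.125) + exp(-2.5)
  expect_equal(as.numeric(p), c(exp(-0.625), exp(-2.125), exp(-2.5)) / z,
               tolerance = 1e-9)
  # chooses stimulus 1 despite negative evidence there
  expect_equal(which.max(p), 1L)

  # all-nonnegative percepts agree with the evidence argmax
  expect_equal(which.max(posterior_plh(c(3, 1, 0.5), 1)), 1L)

  # choice rule is argmax |d_i| in general
  d <- random_percepts(500, seed = 8)
  p <- posterior_plh(d, sigma = 2)
  expect_equal(max.col(p), max.col(abs(d)))
})

test_that("max-rule decisions read out the chosen evidence", {
  out <- rce_decision(c(3, 1, 2))
  expect_equal(out$choice, 1L)
  expect_equal(out$confidence, 3)

  out <- rce_decision(c(-1, -2, -3))
  expect_equal(out$choice, 1L)
  expect_equal(out$confidence, -1)

  # exact tie: uniform over the tied set
  ch <- withr::with_seed(1, vapply(1:400, function(i) {
    rce_decision(c(2, 2, 1))$choice
  }, integer(1)))
  expect_setequal(unique(ch), c(1L, 2L))
  expect_gt(mean(ch == 1L), 0.4)
  expect_lt(mean(ch == 1L), 0.6)
})

test_that("the three non-hierarchical models make identical type-1 choices", {
  grid <- signal_grid()
  d <- random_percepts(10000, seed = 9)
  unique_max <- apply(d, 1, function(r) sum(r == max(r)) == 1)
  d <- d[unique_max, ]
  ch_rce <- max.col(d)
  expect_equal(max.col(posterior_plio(d, grid, 1)), ch_rce)
  expect_equal(max.col(posterior_aio(d, grid, 1)), ch_rce)
  # the hierarchical observer deviates exactly where a negative component
  # has the largest magnitude
  ch_plh <- max.col(posterior_plh(d, 1))
  expect_equal(ch_plh == ch_rce, max.col(abs(d)) == ch_rce)
})

test_that("simulated trials approach certainty as noise vanishes", {
  # noiseless max rule: picks the true maximum and reads out its strength
  tr <- simulate_trials("rce", c(0, 0, 3.5), sigma = 1e-6, n_trials = 20,
                        seed = 1)
  expect_true(all(tr$choice == 3L))
  expect_equal(tr$confidence, rep(3.5, 20), tolerance = 1e-2)

  # Bayesian confidence converges to 1 on a unique-argmax grid point
  tr <- simulate_trials("plio", c(0, 0, 3.5), sigma = 0.05, n_trials = 50,
                        seed = 2)
  expect_true(all(tr$choice == 3L))
  expect_true(all(tr$confidence > 0.99))

  # posterior-readout confidence is always a probability
  for (m in c("plio", "plh", "aio")) {
    tr <- simulate_trials(m, c(1, 2, 3), sigma = 2, n_trials = 200, seed = 3)
    expect_true(all(tr$confidence >= 0 & tr$confidence <= 1))
  }
  expect_error(simulate_trials("nope", c(0, 0, 1)), "Unknown model")
})
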
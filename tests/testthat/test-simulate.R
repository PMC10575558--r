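test_that("grid simulation is reproducible and respects its guard", {
  g <- small_grid()
  s1 <- simulate_grid(g, n_trials = 150, seed = 5, keep_trials = TRUE)
  s2 <- simulate_grid(g, n_trials = 150, seed = 5, keep_trials = TRUE)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$trials, s2$trials)
  expect_equal(nrow(s1$summary), 27 * 4) # 3^3 points x 4 models
  expect_true(all(s1$summary$n1 + s1$summary$n2 + s1$summary$n3 == 150))

  s3 <- simulate_grid(g, n_trials = 150, seed = 6)
  expect_false(identical(s1$summary$conf_sum, s3$summary$conf_sum))

  expect_error(simulate_grid(g, n_trials = 1e9), "max_draws")
})

test_that("models sharing a percept stream agree point by point", {
  # common random numbers make the type-1 equivalence exact per point
  s <- simulate_grid(small_grid(), n_trials = 300, seed = 2)
  sm <- s$summary
  for (m in c("aio", "rce")) {
    expect_identical(
      sm[sm$model == m, c("n1", "n2", "n3")],
      sm[sm$model == "plio", c("n1", "n2", "n3")]
    )
  }
})

test_that("choice probabilities match a numerical-integration oracle", {
  # P(choice = 3) at c = [0,0,3.5]: integral of phi(x - 3.5) Phi(x)^2 dx
  p_oracle <- integrate(function(x) dnorm(x - 3.5) * pnorm(x)^2,
                        -Inf, Inf)$value
  n <- 4000
  tr <- simulate_trials("rce", c(0, 0, 3.5), sigma = 1, n_trials = n,
                        seed = 3)
  p_hat <- mean(tr$choice == 3L)
  se <- sqrt(p_oracle * (1 - p_oracle) / n)
  expect_lt(abs(p_hat - p_oracle), 3 * se)
})

test_that("z-scored confidence standardizes the pooled distribution", {
  s <- simulate_grid(small_grid(), n_trials = 200, seed = 4,
                     keep_trials = TRUE)
  z <- zscore_confidence(s, "whole_grid")
  pooled <- z$trials |>
    dplyr::group_by(model) |>
    dplyr::summarise(m = mean(conf_z), s = sd(conf_z))
  expect_true(all(abs(pooled$m) < 1e-6))
  expect_true(all(abs(pooled$s - 1) < 1e-6))

  # affine invariance: scoping to a subset preserves per-point rank order
  z3 <- zscore_confidence(s, "conditions",
                          conditions = list(c(0, 0, 2), c(0, 1, 2),
                                            c(1, 1, 2)))
  a <- z$summary[z$summary$model == "rce", ]
  b <- z3$summary[z3$summary$model == "rce", ]
  expect_identical(order(a$conf_mean_z), order(b$conf_mean_z))

  # degenerate (constant-confidence) simulation refuses to z-score
  s0 <- simulate_grid(small_grid(), n_trials = 50, seed = 1,
                      models = "plio", sigma = 1)
  s0$summary$conf_sum <- s0$summary$n * 0.7 # constant confidence 0.7
  s0$summary$conf_ss <- s0$summary$n * 0.7^2
  expect_error(zscore_confidence(s0, "whole_grid"), "SD")
})

test_that("per-point summaries match a naive per-trial loop", {
  s <- simulate_grid(small_grid(), n_trials = 200, seed = 8,
                     keep_trials = TRUE)
  s <- zscore_confidence(s, "whole_grid")
  sp <- summarize_points(s)

  # loop oracle on a handful of points, including a tied-maximum point
  for (pt in c(1, 14, 27)) {
    for (m in c("plio", "rce")) {
      tr <- s$trials[s$trials$point == pt & s$trials$model == m, ]
      cvec <- as.numeric(tr[1, c("c1", "c2", "c3")])
      tied <- which(cvec == max(cvec))
      correct <- 0
      for (i in seq_len(nrow(tr))) {
        if (tr$choice[i] %in% tied) correct <- correct + 1 / length(tied)
      }
      row <- sp[sp$point == pt & sp$model == m, ]
      expect_equal(row$accuracy, correct / nrow(tr), tolerance = 1e-12)
    }
  }

  # symmetric point scores 1/3; easy point scores high
  sym <- sp[sp$c1 == sp$c2 & sp$c2 == sp$c3 & sp$model == "rce", ]
  expect_true(all(abs(sym$accuracy - 1 / 3) < 3 * sqrt(2 / 9 / 200)))
  easy <- simulate_grid(signal_grid(values = c(0, 3.5)), sigma = 0.05,
                        n_trials = 100, seed = 1, models = "rce")
  ez <- summarize_points(easy)
  expect_gt(ez$accuracy[ez$c1 == 0 & ez$c2 == 0 & ez$c3 == 3.5], 0.99)
})

test_that("accuracy grows with the strength gap along a 1-D slice", {
  g <- signal_grid(values = c(0, 1, 2, 3))
  s <- simulate_grid(g, n_trials = 400, seed = 10, models = "rce")
  sp <- summarize_points(s)
  slice <- sp[sp$c1 == 0 & sp$c2 == 0, ]
  slice <- slice[order(slice$c3), ]
  expect_true(all(diff(slice$accuracy) >= 0))
})
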
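test_that("pooled-SD Cohen's d matches hand evaluation and its symmetries", {
  expect_equal(cohens_d(c(0, 2), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  x <- rnorm(20)
  y <- rnorm(20, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x), tolerance = 1e-12)
  expect_equal(cohens_d(x, x), 0)
  expect_true(is.na(cohens_d(rep(1, 5), rep(2, 5))))
})

test_that("effect-size map is zero on itself and flags degenerate points", {
  s <- simulate_grid(small_grid(), n_trials = 120, seed = 3)
  s <- zscore_confidence(s, "whole_grid")
  es <- cohens_d_map(s)
  expect_s3_class(es, "effect_size_table")
  expect_equal(nrow(es), 27 * 6)

  # comparing a model against itself gives d = 0 everywhere
  es_self <- cohens_d_map(s, pairs = cbind("rce", "rce"))
  expect_true(all(es_self$d == 0))

  expect_error(cohens_d_map(simulate_grid(small_grid(), n_trials = 50,
                                          seed = 1)),
               "Z-score")
})

test_that("ranking collapses permutation classes and excludes ambiguity", {
  s <- simulate_grid(small_grid(), n_trials = 200, seed = 5)
  s <- zscore_confidence(s, "whole_grid")
  es <- cohens_d_map(s)
  rk <- rank_conditions(es)

  # 3 values -> 10 multisets of size 3
  expect_equal(nrow(rk), 10)
  expect_equal(sum(rk$n_members), 27)
  # sorted-ascending canonical representative; tied-max classes excluded
  expect_true(all(rk$c1 <= rk$c2 & rk$c2 <= rk$c3))
  expect_true(all(is.na(rk$rank[rk$c2 == rk$c3])))
  expect_true(all(!is.na(rk$rank[rk$c2 < rk$c3])))

  # a toy table with a known winner ranks it first
  toy <- tibble::tibble(
    point = 1:3, c1 = c(0, 0, 0), c2 = c(0, 1, 2), c3 = c(2, 2, 3),
    model_a = "plio", model_b = "rce", d = c(0.5, -3, 1),
    mean_a = 0, sd_a = 1, mean_b = 0, sd_b = 1
  )
  class(toy) <- c("effect_size_table", class(toy))
  sel <- select_conditions(toy, k = 2)
  expect_equal(unlist(sel[1, c("c1", "c2", "c3")], use.names = FALSE),
               c(0, 1, 2))
  expect_error(select_conditions(toy, k = 9), "exceeds")
})

test_that("effect sizes are permutation-invariant across equivalent points", {
  s <- simulate_grid(small_grid(), n_trials = 3000, seed = 6,
                     models = c("plio", "rce"))
  s <- zscore_confidence(s, "whole_grid")
  es <- cohens_d_map(s)
  perm_class <- es[paste(es$c1, es$c2, es$c3) %in%
                     c("0 1 2", "2 1 0", "1 0 2"), ]
  expect_equal(diff(range(perm_class$d)), 0, tolerance = 0.2)
})

test_that("selection is stable across covariance scales and seeds", {
  rb <- robustness_check(small_grid(), noise_scales = c(1, 0.5, 1.5),
                         n_trials = 400, seed = 2, k = 2)
  expect_true(rb$same_topk)
  expect_true(all(rb$rank_correlation > 0.9))
  g <- glance(rb)
  expect_equal(nrow(g), 3)

  # trivial single-scale run is identical to itself
  rb1 <- robustness_check(small_grid(), noise_scales = 1, n_trials = 200,
                          seed = 3, k = 2)
  expect_equal(as.numeric(rb1$rank_correlation[1]), 1)

  # two independent seeds rank conditions almost identically
  r1 <- robustness_check(small_grid(), noise_scales = 1, n_trials = 600,
                         seed = 11, k = 2)
  r2 <- robustness_check(small_grid(), noise_scales = 1, n_trials = 600,
                         seed = 12, k = 2)
  key <- function(r) paste(r$c1, r$c2, r$c3)
  m <- match(key(r1$rankings[[1]]), key(r2$rankings[[1]]))
  expect_gt(cor(r1$rankings[[1]]$summed_d, r2$rankings[[1]]$summed_d[m],
                method = "spearman"), 0.95)
})

test_that("strength triplets translate exactly into coherence conditions", {
  des <- default_design()
  expect_equal(des$coh_lowest, c(0, 0.56, 0.64))
  expect_equal(des$coh_second, c(0.0001, 0.72, 0.72))
  expect_equal(des$coh_highest, c(0.56, 0.80, 0.80))

  # epsilon applied in coherence space, exactly once, to the tied pair
  one <- design_from_strengths(list(c(0, 0, 3.5)))
  expect_identical(c(one$coh_lowest, one$coh_second, one$coh_highest),
                   c(0, 0.0001, 0.56))

  expect_error(design_from_strengths(list(c(0, 0, 7))), "exceeds 1")
  expect_error(design_from_strengths(list(c(0, 0, 3.5)),
                                     coherence_scale = 2), "exceeds 1")
})

test_that("choice categorization follows the arrangement", {
  expect_equal(categorize_choice(1, 2, 3, 1), "highest")
  expect_equal(categorize_choice(3, 1, 2, 1), "second")
  # arrangement invariance: permuting positions while tracking the choice
  perms <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    expect_equal(categorize_choice(p[1], p[2], p[3], p[2]), "second")
  }
  expect_error(categorize_choice(1, 1, 3, 1), "permutation")
  expect_error(categorize_choice(c(1), c(2), c(3), 4), "match no")
})
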
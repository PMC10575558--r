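test_that("subjects are screened on overall and easiest-condition accuracy", {
  des <- test_design()
  mk_subject <- function(id, acc) {
    # acc: named accuracies per condition (1 = easiest by design gap)
    purrr::map_dfr(1:3, function(ci) {
      n <- 100
      n_hi <- round(acc[ci] * n)
      tibble::tibble(
        subject_id = id, condition_id = ci,
        choice_category = c(rep("highest", n_hi),
                            rep("second", n - n_hi)),
        confidence_raw = runif(n)
      )
    })
  }
  expect_equal(easiest_condition(des), 1L) # [0,0,3.5] has the widest gap
  trials <- dplyr::bind_rows(
    mk_subject("good", c(0.70, 0.43, 0.42)),
    mk_subject("guesser", c(0.33, 0.30, 0.27)),
    mk_subject("inverted", c(0.45, 0.50, 0.44))
  )
  sc <- screen_subjects(trials, des)
  expect_true(sc$retained[sc$subject_id == "good"])
  expect_false(sc$retained[sc$subject_id == "guesser"])
  expect_match(sc$reason[sc$subject_id == "guesser"], "below_threshold")
  expect_false(sc$retained[sc$subject_id == "inverted"])
  expect_match(sc$reason[sc$subject_id == "inverted"], "easiest_not_best")
})

test_that("behavior summaries equal a naive per-trial loop", {
  obs <- dplyr::bind_rows(
    generate_observer("rce", 1.5, test_design(), 40, seed = 1,
                      subject_id = "s1"),
    generate_observer("aio", 2.5, test_design(), 40, seed = 2,
                      subject_id = "s2")
  )
  summ <- behavior_summary(obs)
  z <- zscore_within_subject(obs)
  for (ci in 1:3) {
    accs <- conf <- c()
    for (id in c("s1", "s2")) {
      rows <- which(z$subject_id == id & z$condition_id == ci)
      acc_i <- conf_i <- 0
      for (r in rows) {
        acc_i <- acc_i + (z$choice_category[r] == "highest") / length(rows)
        conf_i <- conf_i + z$conf_z[r] / length(rows)
      }
      accs <- c(accs, acc_i)
      conf <- c(conf, conf_i)
    }
    expect_equal(summ$accuracy[summ$condition_id == ci], mean(accs),
                 tolerance = 1e-12)
    expect_equal(summ$conf_z[summ$condition_id == ci], mean(conf),
                 tolerance = 1e-12)
  }
  # z-scoring makes each subject's grand confidence mean zero
  grand <- z |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(conf_z))
  expect_true(all(abs(grand$m) < 1e-9))
})

test_that("noise fitting recovers the generating sigma", {
  cache <- quick_cache()
  for (true_sigma in c(1, 2.5)) {
    obs <- generate_observer("rce", true_sigma, test_design(),
                             n_trials_per_condition = 2000,
                             seed = 40 + true_sigma)
    fit <- fit_sigma(obs, cache, mode = "shared")
    expect_lt(abs(fit$sigma_hat[1] - true_sigma),
              0.1 * true_sigma + 0.25 + 1e-9) # grid step + MC slack
    # the argmin property holds on the evaluated curve
    curve <- attr(fit, "curves")$shared
    expect_equal(cache$sigma_grid[which.min(curve)], fit$sigma_hat[1])
    expect_true(all(curve[is.finite(curve)] >=
                      min(curve[is.finite(curve)])))
  }
})

test_that("shared type-1 behavior gives one sigma for the agreeing models", {
  cache <- quick_cache()
  obs <- generate_observer("plio", 2, test_design(),
                           n_trials_per_condition = 500, seed = 77)
  fit <- fit_sigma(obs, cache, mode = "per_model")
  sig <- setNames(fit$sigma_hat, fit$model)
  # percept streams are common within the cache, so the three agreeing
  # models see identical choice distributions
  expect_equal(sig[["plio"]], sig[["aio"]])
  expect_equal(sig[["plio"]], sig[["rce"]])
})

test_that("model comparison identifies the generator and ignores the scale", {
  cache <- quick_cache()
  obs <- generate_observer("plh", 1.2, test_design(),
                           n_trials_per_condition = 1000, seed = 55)
  fit <- compare_models(obs, cache)
  expect_s3_class(fit, "confarb_fit")
  expect_equal(fit$best_model, "plh")
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(td$best[td$model == "plh"])
  expect_equal(glance(fit)$best_model, "plh")

  # mapping native confidence onto a 0-100 slider changes nothing after
  # within-subject z-scoring
  slider <- dplyr::mutate(obs, confidence_raw = 100 * confidence_raw)
  fit2 <- compare_models(slider, cache)
  expect_equal(fit2$result$ce2, fit$result$ce2, tolerance = 1e-9)
  expect_equal(fit2$result$sigma_hat, fit$result$sigma_hat)
})
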
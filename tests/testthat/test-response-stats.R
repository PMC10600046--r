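# Small hand-built trial tables -------------------------------------------

trial_row <- function(observer_id, condition_id, correct, confidence = 3,
                      observer_type = "human", is_catch = FALSE) {
  tibble::tibble(observer_id = observer_id, observer_type = observer_type,
                 condition_id = condition_id, true_class = "disk",
                 predicted_class = if (correct) "disk" else "square",
                 confidence = confidence, response_time = 1, is_catch = is_catch)
}

make_observer_trials <- function(observer_id, accuracy, n = 10,
                                 catch_correct = n_catch, n_catch = 3) {
  main <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    trial_row(observer_id, "c1", i <= round(accuracy * n))))
  catch <- dplyr::bind_rows(lapply(seq_len(n_catch), function(i)
    trial_row(observer_id, "catch", i <= catch_correct, is_catch = TRUE)))
  dplyr::bind_rows(main, catch)
}

test_that("participant filtering drops catch failures and MAD outliers with reasons", {
  # identical observers: nobody excluded at any positive mad_c
  cohort <- dplyr::bind_rows(lapply(sprintf("o%d", 1:6), make_observer_trials,
                                    accuracy = 0.8))
  res <- filter_participants(cohort, mad_c = 0.5)
  expect_identical(nrow(res$exclusions), 0L)
  expect_identical(sort(unique(res$trials$observer_id)), sprintf("o%d", 1:6))

  # 9 observers at 0.9 and 1 at 0.1: exactly the outlier goes, reason "mad"
  # (median 0.9, deviations 0 for the cohort, 0.8 for the outlier)
  cohort <- dplyr::bind_rows(c(lapply(sprintf("g%d", 1:9), make_observer_trials,
                                      accuracy = 0.9),
                               list(make_observer_trials("bad", 0.1))))
  res <- filter_participants(cohort, mad_c = 3)
  expect_identical(res$exclusions$observer_id, "bad")
  expect_identical(res$exclusions$reason, "mad")
  expect_false("bad" %in% res$trials$observer_id)

  # failing all catch trials excludes with reason "catch"
  cohort <- dplyr::bind_rows(make_observer_trials("ok", 0.9),
                             make_observer_trials("sleeper", 0.9, catch_correct = 0))
  res <- filter_participants(cohort, catch_min = 2 / 3)
  expect_identical(res$exclusions$observer_id, "sleeper")
  expect_identical(res$exclusions$reason, "catch")

  # everything excluded is an error, as is an empty table
  lone <- make_observer_trials("x", 0.9, catch_correct = 0)
  expect_error(filter_participants(lone), "excluded")
  expect_error(filter_participants(lone[0, ]), "empty")
})

test_that("condition summaries aggregate accuracy, confidence and n correctly", {
  tr <- dplyr::bind_rows(trial_row("o1", "c1", TRUE, 5),
                         trial_row("o1", "c1", TRUE, 4),
                         trial_row("o1", "c1", FALSE, 1),
                         trial_row("o1", "c2", TRUE, 3),
                         trial_row("o1", "catch", TRUE, 5, is_catch = TRUE))
  cs <- condition_accuracy(tr)
  expect_identical(nrow(cs), 2L)                 # catch trials excluded
  c1 <- cs[cs$condition_id == "c1", ]
  expect_equal(c1$accuracy, 2 / 3)
  expect_equal(c1$mean_confidence, 10 / 3)
  expect_identical(c1$n_trials, 3L)

  # summaries aggregate to the overall accuracy weighted by n, and the
  # aggregation commutes with partitioning the trial table
  obs <- list(human_observer_spec("h1", 0.7), human_observer_spec("h2", 0.4))
  big <- simulate_trials(obs, n_trials_per_condition = 5, seed = 3)
  cs <- condition_accuracy(big)
  overall <- sum(cs$accuracy * cs$n_trials) / sum(cs$n_trials)
  main <- big[!big$is_catch, ]
  expect_equal(overall, mean(main$predicted_class == main$true_class))
  half <- seq_len(nrow(big)) %% 2 == 0
  merged <- dplyr::bind_rows(condition_accuracy(big[half, ]),
                             condition_accuracy(big[!half, ]))
  key <- paste(merged$observer_type, merged$condition_id)
  re_acc <- tapply(merged$accuracy * merged$n_trials, key, sum) /
    tapply(merged$n_trials, key, sum)
  whole <- stats::setNames(cs$accuracy, paste(cs$observer_type, cs$condition_id))
  expect_equal(as.numeric(re_acc[names(whole)]), as.numeric(whole))
})

test_that("transform ranking orders families by mean accuracy with flagged ties", {
  sm <- tibble::tibble(observer_type = "human",
                       condition_id = c("a1", "a2", "b1", "c1"),
                       family = c("alpha", "alpha", "beta", "gamma"),
                       n_trials = 10,
                       accuracy = c(0.8, 1.0, 0.5, 0.2),
                       mean_confidence = 3)
  rk <- transform_ranking(sm)
  expect_identical(rk$family, c("alpha", "beta", "gamma"))
  expect_equal(rk$mean_accuracy, c(0.9, 0.5, 0.2))
  expect_identical(rk$rank, 1:3)
  expect_false(any(rk$tied))
  # singleton and exact tie
  expect_identical(nrow(transform_ranking(sm[1, ])), 1L)
  sm$accuracy <- c(0.5, 0.5, 0.5, 0.2)
  rk <- transform_ranking(sm)
  expect_identical(rk$family[rk$tied], c("alpha", "beta"))
})

test_that("planted family difficulties are recovered by the ranking", {
  all34 <- enumerate_all_conditions()
  fam_means <- c(baseline = 0.99, color_flatten = 0.15, full_random = 0.55,
                 grid = 0.9, local_structure = 0.45, seg_displacement = 0.3,
                 seg_within = 0.7, within_grid = 0.8)
  acc <- unname(fam_means[all34$family])
  obs <- lapply(sprintf("h%d", 1:5), human_observer_spec, accuracy = acc)
  tr <- simulate_trials(obs, n_trials_per_condition = 60, seed = 11)
  rk <- transform_ranking(condition_accuracy(tr))
  expect_identical(rk$family, names(sort(fam_means, decreasing = TRUE)))
})

test_that("paired t reproduces the closed form, the sign convention and t.test", {
  same <- c(0.5, 0.6, 0.7)
  res <- paired_comparison(same, same)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)

  a <- c(2, 4, 6); b <- c(1, 2, 3)          # differences (1, 2, 3)
  res <- paired_comparison(a, b)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_identical(res$df, 2)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # antisymmetric under swapping
  expect_equal(paired_comparison(b, a)$statistic, -res$statistic)
  # df override changes the p value, not the statistic
  res3 <- paired_comparison(a, b, df = 3)
  expect_identical(res3$statistic, res$statistic)
  expect_identical(res3$df, 3)
  expect_equal(res3$p_value, 2 * stats::pt(-abs(res$statistic), 3))
  # degenerate variance is an error, not an infinite t
  expect_error(paired_comparison(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  # data-frame pairing by condition id
  da <- data.frame(condition_id = c("x", "y", "z"), accuracy = a)
  db <- data.frame(condition_id = c("z", "y", "x"), accuracy = b)
  res_df <- paired_comparison(da, db)
  expect_equal(res_df$estimate, mean(c(2 - 3, 4 - 2, 6 - 1)))
  expect_error(paired_comparison(da, data.frame(condition_id = "q", accuracy = 1)),
               "pair")
})

test_that("pearson and OLS reproduce the worked closed forms to 1e-10", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x)$estimate, 1, tolerance = 1e-10)
  expect_equal(pearson_r(x, -x)$estimate, -1, tolerance = 1e-10)
  r <- pearson_r(x, c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8, tolerance = 1e-10)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  fit <- suppressWarnings(ols_fit(2 * x + 1, x))  # exact fit: lm warns
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(ols_fit(x, rep(1, 4)), "singular")

  # R^2 identity with the squared correlation on noisy data
  set.seed(5)
  xx <- rnorm(30); yy <- 0.5 * xx + rnorm(30)
  expect_equal(ols_fit(yy, xx)$r_squared, pearson_r(xx, yy)$estimate^2,
               tolerance = 1e-10)
})

test_that("slope p-values are uniform under a permutation null", {
  set.seed(9)
  xx <- rnorm(20); yy <- rnorm(20)
  pv <- vapply(1:200, function(i) ols_fit(sample(yy), xx)$p_value, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("confidence-accuracy correlation separates human-like from network-like observers", {
  # noiseless affine confidence -> r = 1 by construction
  accs <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  tr <- dplyr::bind_rows(lapply(seq_along(accs), function(i) {
    n <- 10
    dplyr::bind_rows(lapply(seq_len(n), function(j)
      trial_row("h", paste0("c", i), j <= accs[i] * n,
                confidence = 1 + 4 * accs[i])))
  }))
  expect_equal(confidence_accuracy_correlation(tr, "human")$estimate, 1,
               tolerance = 1e-10)

  # simulated cohorts at the full 34-condition grid
  all34 <- enumerate_all_conditions()
  planted <- seq(0.05, 0.95, length.out = nrow(all34))
  humans <- lapply(sprintf("h%d", 1:4), human_observer_spec, accuracy = planted)
  nets <- lapply(sprintf("n%d", 1:4), network_observer_spec, accuracy = planted)
  tr <- simulate_trials(c(humans, nets), n_trials_per_condition = 25, seed = 21)
  rh <- confidence_accuracy_correlation(tr, "human")
  rn <- confidence_accuracy_correlation(tr, "network")
  expect_gt(rh$estimate, 0.9)
  expect_lt(abs(rn$estimate), 0.3)
  expect_error(confidence_accuracy_correlation(tr[1:3, ], "alien"), "at least 3")
})

test_that("trial tables round-trip through CSV with schema validation", {
  obs <- list(human_observer_spec("h1", 0.7))
  tr <- simulate_trials(obs, n_trials_per_condition = 2, seed = 2)
  path <- file.path(tempdir(), "trials.csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_identical(back$predicted_class, tr$predicted_class)
  expect_identical(back$is_catch, tr$is_catch)
  expect_equal(back$confidence, tr$confidence)
  bad <- tr; bad$confidence <- NULL
  write_trials(bad, path)
  expect_error(read_trials(path), "missing columns")
})
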
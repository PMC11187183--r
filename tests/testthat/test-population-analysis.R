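# build a two-condition population array with a mean offset after bin `from`
make_pop <- function(n_units = 12, n_bins = 20, n_trials = 16, sep = 0,
                     from = 1, seed = 1) {
  set.seed(seed)
  labels <- rep(c("water", "quinine"), each = n_trials / 2)
  arr <- array(runif(n_units * n_bins * n_trials, 0, 0.5),
               c(n_units, n_bins, n_trials))
  for (tr in which(labels == "water")) {
    arr[, from:n_bins, tr] <- arr[, from:n_bins, tr] + sep
  }
  population_matrix(normalize_rate(arr), labels, bin = 0.005)
}

test_that("decoder is near perfect on separable and at chance on shuffled data", {
  sep <- make_pop(sep = 0.4, seed = 31)
  r <- fit_decoder(sep, repeats = 10, seed = 1)
  expect_gte(r$accuracy_mean, 0.9)
  # label shuffling destroys decodability
  null <- make_pop(sep = 0, seed = 32)
  rn <- fit_decoder(null, repeats = 12, seed = 2)
  expect_lt(abs(rn$accuracy_mean - 0.5),
            3 * max(rn$accuracy_sd, 0.05) + 0.15)
  expect_lt(abs(mean(rn$shuffled_accuracies) - 0.5), 0.2)
})

test_that("PCA dimension rule keeps one component for rank-1 activity", {
  set.seed(33)
  u <- runif(8)
  arr <- array(0, c(8, 5, 12))
  for (tr in 1:12) arr[, , tr] <- outer(u * runif(1, 0.5, 1.5), rep(1, 5))
  pop <- population_matrix(arr, rep(c("a", "b"), 6))
  r <- fit_decoder(pop, repeats = 5, seed = 3)
  expect_identical(r$pc_dims_used, 1L)
})

test_that("decoder rejects degenerate designs", {
  arr <- array(runif(8 * 5 * 6), c(8, 5, 6))
  expect_error(fit_decoder(population_matrix(arr, rep("a", 6))),
               "two conditions")
  expect_error(population_matrix(arr, rep("a", 5)), "one label per trial")
})

test_that("pseudo populations decode at chance against real labels", {
  trains <- lapply(1:6, function(i) poisson_train(15, 60, seed = 40 + i))
  ps <- pseudo_population(trains, n_trials = 8, n_repeats = 4, seed = 5)
  accs <- fit_decoder(ps, repeats = 10, seed = 6)
  expect_lt(abs(accs$accuracy_mean - 0.5), 0.2)
  expect_true(all(ps$values >= 0 & ps$values <= 1))
})

test_that("time-resolved decoding marks only the separable epoch", {
  pop <- make_pop(n_bins = 24, sep = 0.5, from = 13, seed = 34)
  res <- decode_time_resolved(pop, window_bins = 6, step_bins = 6,
                              repeats = 10, seed = 7)
  expect_equal(res$start_bin, c(1, 7, 13, 19))
  expect_true(all(res$significant[3:4]))
  expect_false(any(res$significant[1:2]))
})

test_that("trajectory distance matches brute force and translation", {
  set.seed(35)
  A <- matrix(rnorm(6 * 15), 6, 15)
  expect_equal(pca_trajectory_distance(A, A), 0, tolerance = 1e-10)
  v <- rnorm(6)
  expect_equal(pca_trajectory_distance(A, A + v), sqrt(sum(v^2)),
               tolerance = 1e-8)
  B <- matrix(rnorm(6 * 15), 6, 15)
  brute <- mean(sqrt(colSums((A - B)^2)))
  expect_equal(pca_trajectory_distance(A, B), brute, tolerance = 1e-8)
})

test_that("edge score is positive for a lagged copy and null for independence", {
  a <- poisson_train(20, 3, seed = 51)
  b <- spike_train(a$times + 0.002, span = c(0, 3.1))
  sc <- tspe_score(a, b)
  expect_true(sc$computable)
  null <- tspe_null_scores(a, b, n_shuffles = 100, seed = 52)
  expect_gt(sc$score, quantile(null, 0.99))
  # independent pair stays inside the null band
  c2 <- poisson_train(20, 3, seed = 53)
  sc2 <- tspe_score(a, c2)
  null2 <- tspe_null_scores(a, c2, n_shuffles = 100, seed = 54)
  expect_lt(sc2$score, quantile(null2, 0.99))
  # empty reference is not computable
  empty <- spike_train(numeric(0), span = c(0, 3))
  expect_false(tspe_score(empty, a)$computable)
})

test_that("edge score decays with spike-time jitter", {
  mean_score <- function(jit_sd) {
    mean(vapply(1:6, function(s) {
      a <- poisson_train(25, 3, seed = 60 + s)
      set.seed(600 + s)
      bt <- sort(a$times + 0.002 + rnorm(length(a$times), 0, jit_sd))
      bt <- bt[bt > 0 & bt < 3.2]
      tspe_score(a, spike_train(bt[!duplicated(bt)], span = c(0, 3.2)))$score
    }, numeric(1)))
  }
  scores <- vapply(c(0.002, 0.005, 0.012), mean_score, numeric(1))
  expect_true(all(diff(scores) < 0))
  # by 20 ms of jitter the coupling signal is deep in the noise floor
  expect_lt(mean_score(0.02), 0.5 * scores[1])
})

test_that("percentile schedule follows the reference table", {
  ps <- rnorm(500)
  pick <- function(n) tspe_network_test(rnorm(max(n, 1)), ps, n = n)
  expect_true(pick(9)$skipped)
  expect_identical(pick(9)$percentile_used, "none")
  expect_identical(pick(10)$percentile_used, 80)
  expect_identical(pick(14)$percentile_used, 80)
  expect_identical(pick(15)$percentile_used, 90)
  expect_identical(pick(19)$percentile_used, 90)
  expect_identical(pick(20)$percentile_used, 95)
  expect_identical(pick(25)$percentile_used, 95)
  expect_identical(pick(31)$percentile_used, 95)
  expect_identical(pick(32)$percentile_used, 99)
  expect_identical(pick(50)$percentile_used, 99)
})

test_that("schedule test calibrates at the scheduled false-positive rate", {
  set.seed(65)
  hits <- replicate(300, {
    pseudo <- rnorm(200)
    real <- rnorm(25)          # drawn from the same null
    tspe_network_test(real, pseudo, n = 25)$significant
  })
  # mean of 25 null scores vs the 95th percentile of the null: rare
  expect_lte(mean(hits), 0.05)
})
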
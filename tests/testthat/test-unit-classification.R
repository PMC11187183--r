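test_that("zscore_separation matches hand arithmetic and is antisymmetric", {
  x <- c(1, 2, 3)
  expect_equal(zscore_separation(x, x), 0)
  # mean 2 / sd 1 vs mean 0 / sd 1 -> z = 2 / sqrt(2)
  a <- as.vector(scale(rnorm(50))) + 2
  b <- as.vector(scale(rnorm(50)))
  expect_equal(zscore_separation(a, b), sqrt(2), tolerance = 1e-10)
  expect_equal(zscore_separation(b, a), -sqrt(2), tolerance = 1e-10)
  expect_warning(z <- zscore_separation(rep(1, 4), rep(1, 4)), "undefined")
  expect_true(is.na(z))
  expect_error(zscore_separation(numeric(0), 1), "non-empty")
})

test_that("euclidean_step_norm has the closed-form values and homogeneity", {
  expect_equal(euclidean_step_norm(rep(3, 5)), rep(3 * sqrt(2), 4))
  expect_equal(euclidean_step_norm(numeric(4)), rep(0, 3))
  v <- runif(10)
  expect_equal(euclidean_step_norm(7 * v), 7 * euclidean_step_norm(v))
  expect_error(euclidean_step_norm(1), "two bins")
})

test_that("frobenius time-bias flags structure and calibrates on nulls", {
  # constant matrix: norm zero, unbiased
  fb <- frobenius_time_bias(matrix(2, 6, 10), seed = 1)
  expect_identical(fb$norm, 0)
  expect_false(fb$biased)
  # strong monotone ramp across bins is detected
  set.seed(2)
  ramp <- matrix(rep(seq(0, 5, length.out = 20), each = 8), 8) +
    matrix(rnorm(160, sd = 0.3), 8)
  fb2 <- frobenius_time_bias(ramp, seed = 2)
  expect_true(fb2$biased)
  # an independent coarse permutation oracle agrees on the flag
  m <- ramp - mean(ramp)
  real <- sqrt(sum((colMeans(m) - mean(colMeans(m)))^2))
  set.seed(3)
  null200 <- replicate(200, {
    p <- matrix(sample(as.vector(m)), nrow(m))
    sqrt(sum((colMeans(p) - mean(colMeans(p)))^2))
  })
  expect_identical(fb2$biased, real > quantile(null200, 0.95, names = FALSE))
  # element-shuffled copies of the biased matrix are null in most seeds
  set.seed(4)
  fp <- mean(replicate(40, {
    shuf <- matrix(sample(as.vector(ramp)), nrow(ramp))
    frobenius_time_bias(shuf, n_shuffles = 300)$biased
  }))
  expect_lte(fp, 0.15)
})

test_that("trial-bias test detects rate shifts and respects grouping rules", {
  set.seed(5)
  # i.i.d. trials: false-positive rate near the nominal 5%
  fp <- mean(replicate(60, {
    trial_bias_test(matrix(rnorm(32 * 18), 32), n_shuffles = 300)$biased
  }))
  expect_lte(fp, 0.15)
  # rate doubling halfway through the trials is detected
  m <- rbind(matrix(rnorm(16 * 18, 5), 16), matrix(rnorm(16 * 18, 10), 16))
  expect_true(trial_bias_test(m, seed = 6)$biased)
  expect_message(sk <- trial_bias_test(matrix(rnorm(10 * 18), 10)), "skipped")
  expect_true(sk$skipped)
})

test_that("pseudo-trial matrices flatten temporal structure of the baseline", {
  # empty baseline -> all-zero pseudo matrix
  empty <- spike_train(numeric(0), span = c(0, 10))
  pm0 <- make_pseudo_trials(empty, lick_times = c(20, 20.3, 20.6, 20.9),
                            n_shuffles = 50, seed = 1)
  expect_true(all(pm0 == 0))
  expect_identical(dim(pm0), c(4L, 36L))
  # homogeneous baseline -> approximately flat at the baseline rate
  base <- poisson_train(20, 10, seed = 7)
  pm <- make_pseudo_trials(base, lick_times = c(20, 20.3, 20.6, 20.9),
                           n_shuffles = 400, seed = 2)
  expect_equal(mean(pm), 20, tolerance = 0.15 * 20)
  expect_lt(stats::sd(pm) / mean(pm), 0.1)  # shuffling homogenises bins
  # determinism
  pm_a <- make_pseudo_trials(base, c(20, 20.4), n_shuffles = 5, seed = 3)
  pm_b <- make_pseudo_trials(base, c(20, 20.4), n_shuffles = 5, seed = 3)
  expect_identical(pm_a, pm_b)
  expect_error(make_pseudo_trials(base, 20), "lick interval")
  expect_error(
    make_pseudo_trials(base, c(20, 32)), "shorter than the lick pattern")
})

test_that("valence classifier recovers engineered PV, NV and flat units", {
  labs <- sapply(101:105, function(seed) {
    sess <- gen_session(labels = c("PV", "NV", "none"), seed = seed)
    wl <- sess$licks$lick_times[sess$licks$liquid == "water"]
    ql <- sess$licks$lick_times[sess$licks$liquid == "quinine"]
    vapply(sess$spikes, function(tr) {
      classify_valence(tr, wl, ql, n_shuffles = 300, seed = 11)$label
    }, character(1))
  })
  expect_gte(sum(labs[1, ] == "PV"), 4)   # >= 80% recovery per class
  expect_gte(sum(labs[2, ] == "NV"), 4)
  expect_gte(sum(labs[3, ] == "UV"), 4)
})

test_that("phase classifier recovers engineered initial and terminal units", {
  sess <- gen_session(labels = c("initial_pre", "initial_post", "terminal",
                                 "none"), seed = 102)
  first_LO <- sess$events$time_s[sess$events$event == "LO" &
                                 sess$events$liquid == "water"]
  qDO <- sess$events$time_s[sess$events$event == "DO" &
                            sess$events$liquid == "quinine"]
  labs <- vapply(sess$spikes, function(tr) {
    classify_phase(tr, first_LO, qDO, n_pseudo = 400, seed = 12)$label
  }, character(1))
  expect_identical(labs[1], "initial_pre")
  expect_identical(labs[2], "initial_post")
  expect_identical(labs[3], "terminal")
  expect_identical(labs[4], "unrelated")
})

test_that("classification is invariant under uniform time translation", {
  sess <- gen_session(labels = c("PV"), seed = 103)
  tr <- sess$spikes[[1]]
  wl <- sess$licks$lick_times[sess$licks$liquid == "water"]
  ql <- sess$licks$lick_times[sess$licks$liquid == "quinine"]
  l0 <- classify_valence(tr, wl, ql, n_shuffles = 200, seed = 21)$label
  shift <- 13.7
  tr2 <- spike_train(tr$times + shift, span = tr$span + shift)
  l1 <- classify_valence(tr2, wl + shift, ql + shift,
                         baseline_window = c(0, 10) + shift,
                         n_shuffles = 200, seed = 21)$label
  expect_identical(l0, l1)
})

test_that("short recordings trigger the full-span pseudo warning", {
  short <- poisson_train(10, 60, seed = 8)
  expect_warning(classify_phase(short, first_water_LO = 20, quinine_DO = 40,
                                n_pseudo = 100, seed = 13),
                 "shorter than 70 s")
})
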
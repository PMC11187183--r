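test_that("plateau inter-lick interval matches the requested rate", {
  prof <- lick_profile(plateau_rate = 6.5, session_length = 30)
  r <- gen_lick_raster(prof, DO = 0, seed = 11)
  lt <- r$lick_times
  plateau <- lt[lt > 5]  # past the initial-phase ramp
  ili <- diff(plateau)
  expect_equal(mean(ili), 1 / 6.5, tolerance = 0.03)
  emp_rate <- 1 / mean(ili)
  expect_lt(abs(emp_rate - 6.5), 0.5)
  expect_true(all(diff(lt) > 0))
})

test_that("no-jitter equal-rate profile gives a perfectly periodic raster", {
  prof <- lick_profile(peak_rate = 6.5, plateau_rate = 6.5, jitter_sd = 0,
                       session_length = 10)
  r <- gen_lick_raster(prof, DO = 0, seed = 1)
  expect_equal(diff(r$lick_times), rep(1 / 6.5, length(r$lick_times) - 1),
               tolerance = 1e-12)
})

test_that("generated rasters satisfy the persistence definition and bias rules", {
  # persistent movement: > 6 Hz sustained for at least 5 s
  for (seed in 1:5) {
    prof <- lick_profile(plateau_rate = 6.7, session_length = 20)
    r <- gen_lick_raster(prof, DO = 0, seed = seed)
    lt <- r$lick_times
    win_counts <- vapply(seq(lt[1], lt[1] + 4, by = 0.5),
                         function(s) sum(lt >= s & lt < s + 1), numeric(1))
    expect_true(all(win_counts >= 6))          # no sub-6 Hz second anywhere
    first5 <- lt[lt <= lt[1] + 5]
    expect_gt(1 / mean(diff(first5)), 6)       # repetition rate above 6 Hz

    expect_gt(initiation_bias(r, DO = 0)$bias, 0)
  }
})

test_that("no licks occur after the termination time", {
  prof <- lick_profile(session_length = 30, termination_time = 12)
  r <- gen_lick_raster(prof, DO = 5, seed = 3)
  expect_true(all(r$lick_times <= 5 + 12))
})

test_that("lick profile rejects non-finite and negative fields", {
  expect_error(lick_profile(first_lick_latency = -1), "finite")
  expect_error(lick_profile(peak_rate = NA), "finite")
  expect_error(lick_profile(termination_time = 40, session_length = 30),
               "termination_time")
})

test_that("untuned spike train has the expected Poisson count", {
  sp <- spike_tuning_spec(baseline_rate = 5, tuned_rate = 5,
                          tuning_kind = "none")
  tr <- gen_tuned_spike_train(sp, anchors = 0, span = c(0, 100), seed = 7)
  expect_lt(abs(length(tr$times) - 500), 4 * sqrt(500))
  expect_identical(attr(tr, "truth"), "none")
})

test_that("tuned windows carry elevated rate relative to elsewhere", {
  anchors <- seq(10, 90, by = 2)
  sp <- spike_tuning_spec(baseline_rate = 5, tuned_rate = 25,
                          tuning_kind = "PV")
  tr <- gen_tuned_spike_train(sp, anchors, span = c(0, 100), seed = 8)
  in_win <- sum(vapply(anchors, function(a) {
    sum(tr$times >= a - 0.1 & tr$times < a + 0.08)
  }, numeric(1)))
  win_t <- length(anchors) * 0.18
  out_rate <- (length(tr$times) - in_win) / (100 - win_t)
  expect_gt(in_win / win_t, 3 * out_rate)
})

test_that("degenerate tuning specs and bad inputs are handled", {
  z <- spike_tuning_spec(baseline_rate = 0, tuned_rate = 0,
                         tuning_kind = "PV")
  tr <- gen_tuned_spike_train(z, anchors = 1, span = c(0, 50), seed = 1)
  expect_length(tr$times, 0)
  expect_error(gen_tuned_spike_train(z, anchors = numeric(0)), "non-empty")
  expect_error(spike_tuning_spec(baseline_rate = -1), ">= 0")
  # tuning_kind none forces tuned = baseline
  s <- spike_tuning_spec(baseline_rate = 4, tuned_rate = 40,
                         tuning_kind = "none")
  expect_equal(s$tuned_rate, 4)
})

test_that("pseudo baseline generator respects contract", {
  expect_length(gen_pseudo_baseline(10, 0, seed = 1)$times, 0)
  tr <- gen_pseudo_baseline(10, 20, seed = 2)
  expect_lt(abs(length(tr$times) - 200), 4 * sqrt(200))
  expect_error(gen_pseudo_baseline(5, 10), "at least 10")
  expect_error(gen_pseudo_baseline(10, -1), ">= 0")
  expect_identical(gen_pseudo_baseline(12, 15, seed = 9)$times,
                   gen_pseudo_baseline(12, 15, seed = 9)$times)
})

test_that("HOG sequences have the requested frame-to-frame correlation", {
  h0 <- gen_hog_sequence(10, 32, drift = 0, seed = 1)
  expect_equal(h0[1, ], h0[10, ])
  h1 <- gen_hog_sequence(400, 64, drift = 1, seed = 2)
  cors <- vapply(seq_len(399), function(i) cor(h1[i, ], h1[i + 1, ]),
                 numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  h3 <- gen_hog_sequence(600, 64, drift = 0.3, seed = 3)
  act <- facial_activity(h3)
  expect_equal(mean(act), 0.3, tolerance = 0.05)
  expect_error(gen_hog_sequence(1, 8, 0.1), "n_frames")
  expect_error(gen_hog_sequence(5, 8, 1.2), "drift")
})

test_that("sessions are deterministic in their seed and internally consistent", {
  s1 <- gen_session(seed = 42)
  s2 <- gen_session(seed = 42)
  expect_identical(s1$licks$lick_times, s2$licks$lick_times)
  expect_identical(lapply(s1$spikes, `[[`, "times"),
                   lapply(s2$spikes, `[[`, "times"))
  # events within span; every LO follows a DO
  expect_true(all(s1$events$time_s >= s1$licks$span[1] &
                  s1$events$time_s <= s1$licks$span[2]))
  lo <- s1$events[s1$events$event == "LO", ]
  do <- s1$events[s1$events$event == "DO", ]
  for (i in seq_len(nrow(lo))) {
    expect_gt(lo$time_s[i], do$time_s[do$liquid == lo$liquid[i]])
  }
  expect_length(s1$truth, length(s1$spikes))
})

test_that("session round-trips through the plain-text writer", {
  s <- gen_session(labels = c("PV", "none"), seed = 5)
  dir <- tempfile("sess")
  write_session(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("spikes.csv", "licks.csv", "events.csv", "truth.json")))))
  back <- read_session(dir)
  expect_equal(back$licks$lick_times, s$licks$lick_times)
  expect_equal(sort(back$spikes[[1]]$times), s$spikes[[1]]$times)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$labels, use.names = FALSE), s$truth)
  unlink(dir, recursive = TRUE)
})
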
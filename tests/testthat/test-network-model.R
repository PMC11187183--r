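# small configurations keep the simulator tests fast; the vignette records
# the problem sizes used for the full reference protocol
small_cfg <- function(n_exc = 300, n_inh = 240, seed = 1) {
  network_config(n_exc = n_exc, n_inh = n_inh, seed = seed)
}

test_that("connectivity has the expected Bernoulli structure", {
  cfg <- network_config(n_exc = 200, n_inh = 160, seed = 2)
  net <- build_network(cfg)
  n <- 360
  n_e_syn <- net$syn_ptr[201] - net$syn_ptr[1]
  n_i_syn <- length(net$syn_post) - n_e_syn
  expect_lt(abs(n_e_syn - 200 * (n - 1) * 0.1),
            4 * sqrt(200 * n * 0.1 * 0.9))
  expect_lt(abs(n_i_syn - 160 * (n - 1) * 0.2),
            4 * sqrt(160 * n * 0.2 * 0.8))
  # no synapses at zero probability
  none <- build_network(network_config(n_exc = 50, n_inh = 40, p_exc = 0,
                                       p_inh = 0, seed = 3))
  expect_length(none$syn_post, 0)
  # determinism
  net2 <- build_network(cfg)
  expect_identical(net$syn_post, net2$syn_post)
  expect_identical(net$syn_w, net2$syn_w)
})

test_that("input protocols discretize to the documented piecewise shape", {
  p0 <- input_protocol(delay = 0.05, amplitude = 100, duration = 1)
  I <- make_input(p0, dt = 0.5)
  expect_identical(unique(I[1:100]), 0)          # before the delay
  expect_identical(unique(I[101:2000]), 100)     # single rectangular pulse
  p2 <- input_protocol(delay = 0, amplitude = 80,
                       gap_starts = c(0.3, 0.6), duration = 1)
  I2 <- make_input(p2, dt = 0.5)
  runs <- rle(I2 > 0)
  expect_identical(runs$values, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(runs$lengths[c(2, 4)], c(400L, 400L))  # two 200 ms gaps
  expect_true(all(make_input(input_protocol(amplitude = 0)) == 0))
  expect_error(input_protocol(gap_starts = c(0.3, 0.4)), "overlap")
  expect_error(input_protocol(gap_starts = 4.9, duration = 5), "within")
})

test_that("an isolated driven neuron spikes regularly; zero drive is silent", {
  cfg <- network_config(n_exc = 1, n_inh = 0, p_exc = 0, p_inh = 0, seed = 4)
  net <- build_network(cfg)
  sim <- simulate_network(net, input_protocol(delay = 0, amplitude = 150,
                                              duration = 2), seed = 4)
  isi <- diff(sim$times)
  expect_gt(length(sim$times), 50)
  expect_lt(stats::sd(isi[-1]) / mean(isi[-1]), 0.01)  # CV ~ 0 when isolated
  quiet <- simulate_network(net, input_protocol(delay = 0, amplitude = 0,
                                                duration = 2), seed = 4)
  expect_lt(length(quiet$times), 5)  # spontaneous baseline is near-silent
})

test_that("network state stays bounded and is seed-deterministic", {
  net <- build_network(small_cfg(seed = 5))
  prot <- input_protocol(delay = 0.05, amplitude = 125, duration = 1.5)
  s1 <- simulate_network(net, prot, seed = 5)
  s2 <- simulate_network(net, prot, seed = 5)
  expect_identical(s1$times, s2$times)
  expect_identical(s1$ids, s2$ids)
  expect_lte(s1$u_max, 1)
  expect_gte(s1$x_min, 0)
  expect_gt(length(s1$times), 100)
})

test_that("halving the integration step changes the population rate by < 5%", {
  prot <- input_protocol(delay = 0.05, amplitude = 125, duration = 1.5)
  cfg1 <- small_cfg(seed = 6)
  r1 <- simulate_network(build_network(cfg1), prot, seed = 6)$mean_rate
  cfg2 <- small_cfg(seed = 6)
  cfg2$dt <- 0.025
  r2 <- simulate_network(build_network(cfg2), prot, seed = 6)$mean_rate
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("lick decision implements the nine-phase product-and-dispersion rule", {
  # no spikes -> no licks
  empty <- list(times = numeric(0), ids = integer(0), n_neurons = 90,
                t_end = 2)
  expect_length(lick_decision(empty, seed = 1)$lick_times, 0)
  # all pools equally active with dispersion below threshold -> lick at
  # every evaluation point
  # every neuron spikes every 10 ms, so each 17 ms phase sub-window holds
  # at least one spike from every pool
  grid_t <- seq(0.005, 2, by = 0.01)
  spk_t <- rep(grid_t, each = 90)
  spk_i <- rep(1:90, times = length(grid_t))
  full <- list(times = spk_t, ids = spk_i, n_neurons = 90, t_end = 2)
  dec <- lick_decision(full, seed = 2)
  expect_identical(dec$lick_times, dec$eval_times)
  expect_true(all(dec$counts > 0))
  expect_true(all(apply(dec$counts, 1, sd) < 30))
  # silencing one pool suppresses every lick (product of counts is zero)
  pools <- dec$pools
  keep <- pools[spk_i] != 1
  gated <- list(times = spk_t[keep], ids = spk_i[keep], n_neurons = 90,
                t_end = 2)
  expect_length(lick_decision(gated, seed = 2)$lick_times, 0)
  # dispersion above threshold suppresses licks even with all pools active
  imb <- lick_decision(full, std_threshold = 1e-6, seed = 2)
  expect_length(imb$lick_times, 0)
  expect_error(lick_decision(full, n_phases = 0), "n_phases")
})

test_that("a trial produces persistent licking with the documented bias", {
  tr <- mp_trial(input_protocol(delay = 0.05, amplitude = 125, duration = 2.5),
                 config = small_cfg(), t_end = 2.5, seed = 7)
  expect_gt(length(tr$licks$lick_times), 8)
  expect_gt(tr$ibias$bias, 0)
  # rasters are reproducible from the seed
  tr2 <- mp_trial(input_protocol(delay = 0.05, amplitude = 125,
                                 duration = 2.5),
                  config = small_cfg(), t_end = 2.5, seed = 7)
  expect_identical(tr$licks$lick_times, tr2$licks$lick_times)
})

test_that("reducing the neuron count lowers the initiation bias", {
  res <- run_silencing_experiment(neuron_counts = c(540, 90), n_trials = 3,
                                  t_end = 3, seed = 8)
  m <- tapply(res$ibias, res$n_neurons, mean)
  expect_lt(m[["90"]], m[["540"]])
  zero <- run_silencing_experiment(neuron_counts = 0, n_trials = 2,
                                   t_end = 3, seed = 9)
  expect_true(all(zero$ibias == 0))
})

test_that("no linear relation links mean rate to lick frequency or bias", {
  # across drive amplitudes that keep the network licking, the mean firing
  # rate keeps rising while lick rate and initiation bias saturate
  amps <- c(110, 140, 170, 200)
  rows <- lapply(amps, function(a) {
    tr <- mp_trial(input_protocol(delay = 0.05, amplitude = a, duration = 3),
                   config = small_cfg(), t_end = 3, seed = 10)
    data.frame(rate = tr$sim$mean_rate,
               lick_hz = length(tr$licks$lick_times) / 3,
               ibias = tr$ibias$bias)
  })
  d <- do.call(rbind, rows)
  expect_gt(max(d$rate) / min(d$rate), 1.2)  # the drive does move the rate
  r2 <- function(y) {
    if (stats::sd(y) == 0) return(0)
    summary(stats::lm(y ~ d$rate))$r.squared
  }
  expect_lt(r2(d$lick_hz), 0.5)
  expect_lt(r2(d$ibias), 0.5)
})

test_that("model configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("network:", "  n_exc: 120", "  n_inh: 100", "  seed: 3",
               "input:", "  amplitude: 90", "  delay: 0.05",
               "synapse:", "  w_i_max: 1.2"), path)
  m <- read_model_config(path)
  expect_equal(m$config$n_exc, 120)
  expect_equal(m$protocol$amplitude, 90)
  expect_equal(m$synapse$w_i_max, 1.2)
  expect_equal(m$neuron$cm, 200)  # defaults fill the gaps
  unlink(path)
})
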
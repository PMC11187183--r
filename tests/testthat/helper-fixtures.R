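# deterministic fixtures shared across test files

# periodic lick times at `rate` Hz starting at `start`
periodic_licks <- function(rate, start, end, phase = 0) {
  seq(start + phase, end, by = 1 / rate)
}

# homogeneous Poisson train over [0, dur]
poisson_train <- function(rate, dur, seed, unit_id = "u") {
  set.seed(seed)
  k <- rpois(1, rate * dur)
  spike_train(sort(runif(k, 0, dur)), span = c(0, dur), unit_id = unit_id)
}

# independent re-implementation of the initiation-bias scan used as an
# oracle: literal sample-by-sample evaluation of the scan rules
oracle_ibias <- function(sma, threshold = 1.2) {
  zeros <- which(sma == 0)
  last_zero <- if (length(zeros)) max(zeros) else 0
  idx <- 0
  for (k in seq_along(sma)) {
    if (k <= last_zero) next
    idx <- idx + 1
    if (sma[k] > threshold) return(list(bias = 1 / idx, idx = idx))
  }
  list(bias = 0, idx = NA)
}

# small synthetic session reused by classification tests
small_session <- function(seed, labels = c("PV", "NV", "none")) {
  gen_session(labels = labels, seed = seed)
}
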
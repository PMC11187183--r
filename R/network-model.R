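#' Neuron parameters for the MP network model
#'
#' Conductance-based Hodgkin-Huxley point-neuron parameters.  The membrane
#' equation combines leak, transient sodium, delayed-rectifier potassium,
#' excitatory and inhibitory synaptic conductances, and the external drive:
#' \deqn{C_m dV/dt = g_l(E_l - V) - g_{Na} m^3 h (V - E_{Na})
#'   - g_K n^4 (V - E_K) + g_e(E_e - V) + g_i(E_i - V) + I_{ex}}
#' Gating kinetics follow the standard Traub-Miles rate functions with
#' threshold offset `vt`; the remaining constants are the canonical values
#' for a 20000 um^2 cortical point neuron and are exposed here because only
#' the synaptic time constants are fixed by the modelling convention — the
#' conductances are calibrated so the driven network's inter-spike-interval
#' statistics match the target profile (see the package vignette and
#' `scripts/calibrate.R`).
#'
#' @param cm Membrane capacitance, pF.
#' @param gl,el Leak conductance (nS) and reversal (mV).
#' @param gna,ena Maximal sodium conductance (nS) and reversal (mV).
#' @param gk,ek Maximal potassium conductance (nS) and reversal (mV).
#' @param ee,ei Excitatory/inhibitory synaptic reversals (mV).
#' @param vt Gating threshold offset (mV).
#' @return Named list of class `neuron_params`.
#' @export
neuron_params <- function(cm = 200, gl = 10, el = -65, gna = 20000,
                          ena = 50, gk = 6000, ek = -90, ee = 0, ei = -80,
                          vt = -63) {
  if (any(c(cm, gl, gna, gk) < 0)) stop("conductances/capacitance must be >= 0")
  if (!(ei < el && el < ena)) stop("require E_i < E_l < E_Na")
  structure(list(cm = cm, gl = gl, el = el, gna = gna, ena = ena, gk = gk,
                 ek = ek, ee = ee, ei = ei, vt = vt),
            class = "neuron_params")
}

#' Synapse parameters with short-term plasticity
#'
#' Exponential conductance synapses (time constants 5 ms excitatory, 10 ms
#' inhibitory) with presynaptic facilitation/depression: between spikes the
#' neurotransmitter usage decays, `du/dt = -omega_f u`, and the availability
#' recovers, `dx/dt = omega_d (1 - x)`; at a presynaptic spike `u` jumps by
#' `U (1 - u)` with resting release probability `U = 0.6`, the transmitted
#' conductance increment is `w * u * x`, and `x` is reduced by `u * x`.
#' Synaptic weights are drawn uniformly from `[0, w_e_max]` (excitatory) and
#' `[0, w_i_max]` (inhibitory).
#'
#' @param tau_e,tau_i Synaptic decay time constants, ms.
#' @param omega_f Facilitation rate, s^-1 (default 3.33).
#' @param omega_d Depression recovery rate, s^-1 (default 2).
#' @param u_rest Resting release probability (default 0.6).
#' @param w_e_max,w_i_max Upper bounds of the uniform weight ranges, nS
#'   (defaults 0.06 and 1.5).
#' @return Named list of class `synapse_params`.
#' @export
synapse_params <- function(tau_e = 5, tau_i = 10, omega_f = 3.33,
                           omega_d = 2, u_rest = 0.6, w_e_max = 0.06,
                           w_i_max = 1.5) {
  if (tau_e <= 0 || tau_i <= 0) stop("time constants must be positive")
  if (u_rest < 0 || u_rest > 1) stop("u_rest must lie in [0, 1]")
  structure(list(tau_e = tau_e, tau_i = tau_i, omega_f = omega_f,
                 omega_d = omega_d, u_rest = u_rest, w_e_max = w_e_max,
                 w_i_max = w_i_max),
            class = "synapse_params")
}

#' Network configuration
#'
#' @param n_exc,n_inh Numbers of excitatory and inhibitory neurons
#'   (defaults 1000 and 800).
#' @param p_exc,p_inh Connection probabilities from excitatory (0.1) and
#'   inhibitory (0.2) neurons.
#' @param v_init Range (mV) for the uniform random initial membrane
#'   potential, default `c(-65, -63)`.
#' @param het Fractional cell-to-cell spread of intrinsic excitability:
#'   the leak conductance and the effective drive of each neuron are scaled
#'   by independent uniform factors in `[1 - het, 1 + het]` (default 0.15).
#'   Heterogeneous drive spreads the single-neuron firing rates, which keeps
#'   the driven network asynchronous, as in cortex.
#' @param dt Integration step, ms (default 0.05).
#' @param seed Integer seed controlling connectivity, weights, initial
#'   conditions and phase-pool assignment.
#' @return Named list of class `network_config`.
#' @export
network_config <- function(n_exc = 1000, n_inh = 800, p_exc = 0.1,
                           p_inh = 0.2, v_init = c(-65, -63), het = 0.15,
                           dt = 0.05, seed = 1) {
  if (n_exc < 0 || n_inh < 0) stop("neuron counts must be >= 0")
  if (p_exc < 0 || p_exc > 1 || p_inh < 0 || p_inh > 1) {
    stop("connection probabilities must lie in [0, 1]")
  }
  if (dt <= 0 || dt > 0.05 + 1e-12) {
    stop("dt must be positive and at most 0.05 ms for stable integration")
  }
  if (het < 0 || het >= 1) stop("het must lie in [0, 1)")
  structure(list(n_exc = n_exc, n_inh = n_inh, p_exc = p_exc, p_inh = p_inh,
                 v_init = v_init, het = het, dt = dt, seed = as.integer(seed)),
            class = "network_config")
}

#' Input current protocol
#'
#' Piecewise-constant external current: zero before `DO + delay`, then
#' `amplitude` pA until the end of the trial, optionally zeroed during
#' 200 ms interruptions.  Default interruption onsets probe the initiation
#' epoch of licking (1.0 s for one gap; 1.0 and 2.2 s for two), when the
#' moving-average lick statistic is still ramping toward its threshold.
#'
#' @param delay Start delay after the delivery onset, s.  Either a fixed
#'   value (50 ms convention) or `"flexible"` to draw uniformly from
#'   1-200 ms at simulation time.
#' @param amplitude Current amplitude, pA, in the 50-200 pA operating range.
#' @param gap_starts Onset times (s, relative to DO) of zero-amplitude
#'   interruptions; must be non-overlapping.
#' @param gap_duration Interruption duration, s (default 0.2).
#' @param duration Stimulation span, s (default 5).
#' @return Named list of class `input_protocol`.
#' @export
input_protocol <- function(delay = 0.05, amplitude = 125,
                           gap_starts = numeric(0), gap_duration = 0.2,
                           duration = 5) {
  if (!identical(delay, "flexible")) {
    if (!is.finite(delay) || delay < 0) stop("delay must be >= 0")
  }
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  gap_starts <- sort(as.numeric(gap_starts))
  if (length(gap_starts) > 1L &&
      any(diff(gap_starts) < gap_duration - 1e-12)) {
    stop("interruptions must not overlap")
  }
  if (length(gap_starts) &&
      (min(gap_starts) < 0 || max(gap_starts) + gap_duration > duration)) {
    stop("interruptions must lie within the stimulation span")
  }
  structure(list(delay = delay, amplitude = amplitude,
                 gap_starts = gap_starts, gap_duration = gap_duration,
                 duration = duration),
            class = "input_protocol")
}

#' Default interruption onsets
#'
#' Gap onsets used by [run_interruption_experiment()]: interruptions are
#' placed inside the initiation epoch (starting 1.0 s after DO, then every
#' 1.2 s), where they can intercept the developing lick-initiation window.
#'
#' @param n Number of interruptions (0, 1, 2; larger values extrapolate the
#'   spacing and emit a warning).
#' @return Numeric vector of gap onset times (s).
#' @export
default_gap_starts <- function(n) {
  if (n == 0) return(numeric(0))
  if (n > 2) warning("more than two interruptions extrapolates the reference protocol")
  1.0 + 1.2 * (seq_len(n) - 1)
}

#' Build the MP network
#'
#' Samples the directed random connectivity (independent Bernoulli edges with
#' probability `p_exc` from excitatory neurons and `p_inh` from inhibitory
#' neurons, no self-connections) and the uniform synaptic weights.  Neurons
#' `1..n_exc` are excitatory.
#'
#' @param config A [network_config()].
#' @param neuron A [neuron_params()].
#' @param synapse A [synapse_params()].
#' @param seed Seed for connectivity and weights (defaults to `config$seed`).
#' @return Object of class `mp_network` holding the configuration and the
#'   compressed adjacency (`syn_ptr`, `syn_post`, `syn_w`).
#' @export
build_network <- function(config = network_config(), neuron = neuron_params(),
                          synapse = synapse_params(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_exc + config$n_inh
  ptr <- integer(n + 1L)
  post <- vector("list", n)
  wts <- vector("list", n)
  for (j in seq_len(n)) {
    exc <- j <= config$n_exc
    p <- if (exc) config$p_exc else config$p_inh
    if (p > 0 && n > 1L) {
      tgt <- which(stats::runif(n) < p)
      tgt <- tgt[tgt != j]
    } else {
      tgt <- integer(0)
    }
    post[[j]] <- tgt - 1L  # 0-based for the C++ core
    wmax <- if (exc) synapse$w_e_max else synapse$w_i_max
    wts[[j]] <- stats::runif(length(tgt), 0, wmax)
    ptr[j + 1L] <- ptr[j] + length(tgt)
  }
  structure(list(config = config, neuron = neuron, synapse = synapse,
                 syn_ptr = ptr, syn_post = unlist(post),
                 syn_w = unlist(wts), seed = seed),
            class = "mp_network")
}

#' @export
print.mp_network <- function(x, ...) {
  cat(sprintf("<mp_network: %d E + %d I neurons, %d synapses>\n",
              x$config$n_exc, x$config$n_inh, length(x$syn_post)))
  invisible(x)
}

#' Discretized input current series
#'
#' @param protocol An [input_protocol()] (with a numeric delay).
#' @param t_end Trial length, s.
#' @param dt Integration step, ms.
#' @return Numeric vector of the current (pA) at each integration step.
#' @export
make_input <- function(protocol, t_end = protocol$duration, dt = 0.05) {
  stopifnot(inherits(protocol, "input_protocol"))
  if (identical(protocol$delay, "flexible")) {
    stop("resolve a flexible delay (draw it) before discretizing the input")
  }
  t <- seq(0, t_end, by = dt / 1000)
  t <- t[-length(t)]
  I <- ifelse(t >= protocol$delay, protocol$amplitude, 0)
  for (g in protocol$gap_starts) {
    I[t >= g & t < g + protocol$gap_duration] <- 0
  }
  I
}

#' Simulate the MP network
#'
#' Integrates the Hodgkin-Huxley network (compiled core) under the given
#' input protocol.  The external current drives every neuron.  Initial
#' membrane potentials are drawn uniformly from the configured range.
#'
#' @param network An [build_network()] result.
#' @param protocol An [input_protocol()]; a `"flexible"` delay is resolved
#'   here by drawing uniformly from 1-200 ms.
#' @param t_end Simulated time, s (default `protocol$duration`).
#' @param seed Seed for initial conditions (and flexible delay); defaults to
#'   the network seed.
#' @return List of class `sim_result` with `times` (s), `ids` (1-based
#'   neuron indices), `mean_rate` (Hz per neuron), `delay`, `u_max`,
#'   `x_min`, `n_neurons`, `t_end`.
#' @export
simulate_network <- function(network, protocol,
                             t_end = protocol$duration, seed = network$seed) {
  stopifnot(inherits(network, "mp_network"),
            inherits(protocol, "input_protocol"))
  set.seed(seed)
  cfg <- network$config
  n <- cfg$n_exc + cfg$n_inh
  v0 <- stats::runif(n, cfg$v_init[1], cfg$v_init[2])
  het <- if (is.null(cfg$het)) 0.15 else cfg$het
  gl_i <- network$neuron$gl * stats::runif(n, 1 - het, 1 + het)
  I_scale <- stats::runif(n, 1 - het, 1 + het)
  delay <- protocol$delay
  if (identical(delay, "flexible")) delay <- stats::runif(1, 0.001, 0.2)
  prot <- protocol
  prot$delay <- delay
  I <- make_input(prot, t_end = t_end, dt = cfg$dt)
  syn <- network$synapse
  pars <- list(cm = network$neuron$cm, gl = network$neuron$gl,
               el = network$neuron$el, gna = network$neuron$gna,
               ena = network$neuron$ena, gk = network$neuron$gk,
               ek = network$neuron$ek, ee = network$neuron$ee,
               ei = network$neuron$ei, vt = network$neuron$vt,
               tau_e = syn$tau_e, tau_i = syn$tau_i,
               omega_f = syn$omega_f / 1000,  # s^-1 -> ms^-1
               omega_d = syn$omega_d / 1000,
               u_rest = syn$u_rest)
  out <- hh_simulate_cpp(cfg$n_exc, cfg$n_inh, network$syn_ptr,
                         network$syn_post, network$syn_w, v0, gl_i,
                         I_scale, I, cfg$dt, pars)
  structure(list(times = out$times, ids = out$ids,
                 mean_rate = out$mean_rate, delay = delay,
                 u_max = out$u_max, x_min = out$x_min,
                 n_neurons = n, t_end = t_end),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %d spikes from %d neurons over %.2f s (%.2f Hz/neuron)>\n",
              length(x$times), x$n_neurons, x$t_end, x$mean_rate))
  invisible(x)
}

#' Nine-phase lick decision rule
#'
#' Converts network spikes to lick events.  Neurons are partitioned at random
#' into `n_phases` equal pools (one lick cycle is assumed to be traversed by
#' a rotational population dynamic, one pool per phase).  At each evaluation
#' time `t` (every `cycle` seconds) the lick cycle ending `lag` seconds
#' before `t` is divided into `n_phases` sub-windows, and the spikes of pool
#' `i` falling in sub-window `i` are counted.  A lick is emitted at `t` when
#' every pooled count is positive and the standard deviation of the counts is
#' below `std_threshold`.
#'
#' @param sim A `sim_result` (or a list with `times`, `ids`, `n_neurons`,
#'   `t_end`).
#' @param n_phases Number of phase pools (default 9).
#' @param lag Decision lag, s (default 0.280).
#' @param std_threshold Dispersion threshold in spikes per pooled sub-window
#'   (default 30).
#' @param cycle Lick-cycle duration, s (default `1/6.5`, capping the lick
#'   rate near 6.5 Hz).
#' @param seed Seed for the random pool assignment.
#' @return List with `lick_times`, `eval_times`, `counts` (evaluations x
#'   phases), `pools`.
#' @export
lick_decision <- function(sim, n_phases = 9, lag = 0.28, std_threshold = 30,
                          cycle = 1 / 6.5, seed = 1) {
  if (n_phases < 1) stop("n_phases must be >= 1")
  times <- sim$times
  ids <- sim$ids
  n_neurons <- sim$n_neurons
  t_end <- sim$t_end
  set.seed(seed)
  pools <- sample(rep_len(seq_len(n_phases), n_neurons))
  k_min <- ceiling((lag + cycle) / cycle - 1e-9)
  k_max <- floor(t_end / cycle + 1e-9)
  if (k_max < k_min) {
    return(list(lick_times = numeric(0), eval_times = numeric(0),
                counts = matrix(0, 0, n_phases), pools = pools))
  }
  eval_times <- seq(k_min, k_max) * cycle
  K <- length(eval_times)
  counts <- matrix(0L, K, n_phases)
  if (length(times)) {
    k <- floor((times + lag) / cycle - 1e-12) + 1L
    rel <- times + lag - (k - 1L) * cycle          # position within the cycle
    sub <- pmin(pmax(floor(rel / (cycle / n_phases)) + 1L, 1L), n_phases)
    keep <- k >= k_min & k <= k_max & pools[ids] == sub
    if (any(keep)) {
      kk <- k[keep] - k_min + 1L
      ss <- sub[keep]
      tab <- tabulate((ss - 1L) * K + kk, nbins = K * n_phases)
      counts <- matrix(tab, K, n_phases)
    }
  }
  active <- matrixStats_all_positive(counts)
  sds <- apply(counts, 1L, stats::sd)
  if (n_phases == 1L) sds <- rep(0, K)
  P <- active & (sds < std_threshold)
  list(lick_times = eval_times[P], eval_times = eval_times,
       counts = counts, pools = pools)
}

# row-wise "all counts positive" without matrixStats
matrixStats_all_positive <- function(m) {
  if (!nrow(m)) return(logical(0))
  rowSums(m > 0) == ncol(m)
}

#' Run one simulated licking trial
#'
#' Builds a network, simulates it under the protocol, converts the spikes to
#' licks and computes the initiation bias of the resulting raster relative to
#' the delivery onset at `t = 0`.
#'
#' @param protocol An [input_protocol()].
#' @param config A [network_config()]; its seed is overridden by `seed`.
#' @param neuron,synapse Model parameters.
#' @param t_end Simulated time, s.
#' @param seed Integer trial seed (controls connectivity, weights, initial
#'   conditions, flexible delay and pool assignment).
#' @param decision List of [lick_decision()] arguments.
#' @return List with `ibias` (a `bias_result`), `licks`, `sim`, `seed`.
#' @export
mp_trial <- function(protocol, config = network_config(),
                     neuron = neuron_params(), synapse = synapse_params(),
                     t_end = protocol$duration, seed = 1,
                     decision = list()) {
  config$seed <- as.integer(seed)
  net <- build_network(config, neuron, synapse)
  sim <- simulate_network(net, protocol, t_end = t_end, seed = seed)
  dec <- do.call(lick_decision, c(list(sim = sim, seed = seed), decision))
  raster <- lick_raster(dec$lick_times, DO_times = 0,
                        span = c(0, t_end))
  ib <- initiation_bias(raster, DO = 0, horizon = min(6, t_end))
  list(ibias = ib, licks = dec, sim = sim, seed = seed)
}

.trial_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(2^30, k)
}

#' Neuron-number reduction (simulated silencing) experiment
#'
#' Scales the network down (preserving the 1000:800 excitatory:inhibitory
#' ratio), runs `n_trials` seeded trials per size with a flexible input delay
#' (1-200 ms), and reports the initiation bias of each trial's lick raster.
#' Reduced populations inhibit the initiation of persistent licking.
#'
#' @param neuron_counts Total neuron counts to simulate (default
#'   `c(1800, 450, 180)`).
#' @param n_trials Trials per count (default 10).
#' @param amplitude Input amplitude, pA.
#' @param t_end Simulated time per trial, s (default 5).
#' @param seed Master seed.
#' @param ... Passed to [mp_trial()] (e.g. `neuron`, `synapse`).
#' @return Data frame with `n_neurons`, `trial`, `ibias`.
#' @export
run_silencing_experiment <- function(neuron_counts = c(1800, 450, 180),
                                     n_trials = 10, amplitude = 125,
                                     t_end = 5, seed = 1, ...) {
  seeds <- .trial_seeds(seed, length(neuron_counts) * n_trials)
  res <- list()
  idx <- 0L
  for (count in neuron_counts) {
    n_exc <- round(count * 1000 / 1800)
    n_inh <- count - n_exc
    for (j in seq_len(n_trials)) {
      idx <- idx + 1L
      if (count == 0) {
        res[[idx]] <- data.frame(n_neurons = count, trial = j, ibias = 0)
        next
      }
      cfg <- network_config(n_exc = n_exc, n_inh = n_inh)
      prot <- input_protocol(delay = "flexible", amplitude = amplitude,
                             duration = t_end)
      tr <- mp_trial(prot, config = cfg, t_end = t_end, seed = seeds[idx], ...)
      res[[idx]] <- data.frame(n_neurons = count, trial = j,
                               ibias = tr$ibias$bias)
    }
  }
  do.call(rbind, res)
}

#' Input interruption experiment
#'
#' Runs the fixed-delay (50 ms) interruption protocol: per condition
#' (0, 1 or 2 zero-amplitude 200 ms interruptions at the default onsets,
#' see [default_gap_starts()]), `n_trials` seeded trials are simulated, the
#' decision-rule lick rasters scored with [initiation_bias()], and the
#' per-condition mean and standard error of the initiation bias are reported
#' as percentages.
#'
#' @param n_interruptions Integer vector of interruption counts
#'   (default `c(0, 1, 2)`).
#' @param n_trials Trials per condition (default 10).
#' @param delay Fixed input delay, s (default 0.05).
#' @param amplitude Input amplitude, pA (default 125).
#' @param t_end Simulated time per trial, s (default 5).
#' @param seed Master seed.
#' @param gap_starts Optional list of gap-onset vectors, one per condition;
#'   defaults to [default_gap_starts()].
#' @param ... Passed to [mp_trial()].
#' @return Object of class `interruption_result`: `trials` data frame
#'   (`n_interruptions`, `trial`, `ibias`) and `summary` data frame
#'   (`n_interruptions`, `mean_pct`, `sem_pct`).
#' @export
run_interruption_experiment <- function(n_interruptions = c(0, 1, 2),
                                        n_trials = 10, delay = 0.05,
                                        amplitude = 125, t_end = 5,
                                        seed = 1, gap_starts = NULL, ...) {
  seeds <- .trial_seeds(seed, length(n_interruptions) * n_trials)
  rows <- list()
  idx <- 0L
  for (ci in seq_along(n_interruptions)) {
    nint <- n_interruptions[ci]
    gs <- if (is.null(gap_starts)) default_gap_starts(nint)
          else gap_starts[[ci]]
    prot <- input_protocol(delay = delay, amplitude = amplitude,
                           gap_starts = gs, duration = t_end)
    for (j in seq_len(n_trials)) {
      idx <- idx + 1L
      tr <- mp_trial(prot, t_end = t_end, seed = seeds[idx], ...)
      rows[[idx]] <- data.frame(n_interruptions = nint, trial = j,
                                ibias = tr$ibias$bias)
    }
  }
  trials <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(trials, trials$n_interruptions),
    function(d) data.frame(
      n_interruptions = d$n_interruptions[1],
      mean_pct = 100 * mean(d$ibias),
      sem_pct = 100 * stats::sd(d$ibias) / sqrt(nrow(d)))))
  sm <- sm[order(sm$n_interruptions), ]
  rownames(sm) <- NULL
  structure(list(trials = trials, summary = sm), class = "interruption_result")
}

#' @export
print.interruption_result <- function(x, ...) {
  cat("<interruption_result>\n")
  print(x$summary)
  invisible(x)
}

#' Inter-spike-interval summary of a simulation
#'
#' Pools the per-neuron inter-spike intervals of a simulation and reports
#' their mean, coefficient of variation, and the mean single-neuron rate;
#' used to calibrate the free model constants against a target ISI profile.
#'
#' @param sim A `sim_result`.
#' @return List with `mean_isi` (s), `cv_isi`, `rate_hz`, `n_isi`.
#' @export
isi_summary <- function(sim) {
  isis <- unlist(lapply(split(sim$times, sim$ids), function(tt) {
    if (length(tt) > 1L) diff(sort(tt)) else numeric(0)
  }), use.names = FALSE)
  list(mean_isi = mean(isis), cv_isi = stats::sd(isis) / mean(isis),
       rate_hz = sim$mean_rate, n_isi = length(isis))
}

#' Read a model configuration file
#'
#' Reads a YAML key-value file describing the network, neuron, synapse,
#' input and decision parameters, filling unspecified values with the
#' package defaults.
#'
#' @param path Path to a YAML file with optional sections `network`,
#'   `neuron`, `synapse`, `input`, `decision`.
#' @return List with `config`, `neuron`, `synapse`, `protocol`, `decision`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(fun, section) do.call(fun, if (is.null(y[[section]])) list() else y[[section]])
  list(config = pick(network_config, "network"),
       neuron = pick(neuron_params, "neuron"),
       synapse = pick(synapse_params, "synapse"),
       protocol = pick(input_protocol, "input"),
       decision = if (is.null(y$decision)) list() else y$decision)
}

#' Write a configuration snapshot
#'
#' @param trial Result of [mp_trial()] or a list of parameter objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_snapshot <- function(trial, path) {
  snap <- list(seed = trial$seed,
               n_neurons = trial$sim$n_neurons,
               t_end = trial$sim$t_end,
               delay = trial$sim$delay)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
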
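#' Lick-raster generation profile
#'
#' Parameterizes the synthetic persistent-lick generator: an inhomogeneous
#' renewal process whose rate starts at `peak_rate` at the first lick, relaxes
#' linearly to `plateau_rate` over `ramp_duration` seconds (the initial-phase
#' frequency peak), then stays at `plateau_rate` until `termination_time`
#' (sharp termination).  Inter-lick intervals receive Gaussian jitter with
#' standard deviation `jitter_sd`.
#'
#' @param first_lick_latency Latency from delivery onset to the first lick,
#'   seconds (default 1.3).
#' @param peak_rate Initial-phase peak lick rate, Hz (default 7.5).
#' @param plateau_rate Sustained lick rate, Hz (default 6.5; persistent
#'   licking plateaus at 6-7 Hz).
#' @param session_length Session length after delivery onset, seconds.
#' @param termination_time Time after delivery onset at which licking stops
#'   (default `session_length`); must not exceed `session_length`.
#' @param jitter_sd SD of inter-lick-interval jitter, seconds (default 0.01;
#'   a free choice, the interval variability is not otherwise constrained).
#' @param ramp_duration Duration of the initial-phase rate ramp, seconds
#'   (default 3).
#' @return Object of class `lick_profile`.
#' @export
lick_profile <- function(first_lick_latency = 1.3, peak_rate = 7.5,
                         plateau_rate = 6.5, session_length = 30,
                         termination_time = session_length,
                         jitter_sd = 0.01, ramp_duration = 3) {
  vals <- c(first_lick_latency, peak_rate, plateau_rate, session_length,
            termination_time, jitter_sd, ramp_duration)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("lick profile fields must be finite and non-negative")
  }
  if (termination_time > session_length + 1e-9) {
    stop("termination_time must not exceed session_length")
  }
  if (plateau_rate <= 0) stop("plateau_rate must be positive")
  structure(list(first_lick_latency = first_lick_latency,
                 peak_rate = peak_rate, plateau_rate = plateau_rate,
                 session_length = session_length,
                 termination_time = termination_time,
                 jitter_sd = jitter_sd, ramp_duration = ramp_duration),
            class = "lick_profile")
}

#' Generate a synthetic persistent-lick raster
#'
#' Draws lick times from the renewal process described in [lick_profile()],
#' anchored at a delivery onset.  No licks occur after the termination time.
#'
#' @param profile A [lick_profile()].
#' @param DO Delivery-onset time, seconds (default 0).
#' @param liquid Liquid label for the generated licks.
#' @param seed Optional integer seed for reproducibility.
#' @return A [lick_raster()] whose span covers the session.
#' @export
gen_lick_raster <- function(profile, DO = 0, liquid = "water", seed = NULL) {
  stopifnot(inherits(profile, "lick_profile"))
  if (!is.null(seed)) set.seed(seed)
  p <- profile
  t0 <- DO + p$first_lick_latency +
    if (p$jitter_sd > 0) stats::rnorm(1, 0, p$jitter_sd) else 0
  t_stop <- DO + p$termination_time
  rate_at <- function(dt_from_first) {
    if (p$ramp_duration <= 0) return(p$plateau_rate)
    w <- min(1, max(0, dt_from_first / p$ramp_duration))
    p$peak_rate + w * (p$plateau_rate - p$peak_rate)
  }
  times <- numeric(0)
  t <- t0
  while (t <= t_stop) {
    times <- c(times, t)
    ili <- 1 / rate_at(t - t0) +
      if (p$jitter_sd > 0) stats::rnorm(1, 0, p$jitter_sd) else 0
    ili <- max(ili, 0.02)  # physiological minimum; keeps intervals positive
    t <- t + ili
  }
  lick_raster(times, liquid = liquid, DO_times = DO, DO_liquid = liquid,
              span = c(min(DO, 0), DO + p$session_length))
}

#' Spike-train tuning specification
#'
#' Encodes the ground-truth rate structure of a generated unit: a baseline
#' Poisson rate everywhere and an elevated (or suppressed) rate inside windows
#' anchored at behavioral events.  `tuning_kind` names the window convention:
#' `"PV"`/`"NV"`/`"lick"` use the peri-lick window (default LO-0.1 to
#' LO+0.08 s around water, quinine, or all licks), `"MV"` uses
#' liquid-specific sub-windows so the two liquids have different rate peaks,
#' `"initial_pre"`/`"initial_post"` use 2 s windows before/after the first
#' water lick onset, `"terminal"` a 2 s window after quinine delivery onset,
#' and `"none"` is untuned (the tuned rate is forced equal to baseline).
#'
#' @param baseline_rate Baseline rate, Hz (>= 0; default 20, typical of
#'   task-engaged deep-layer prefrontal units).
#' @param tuned_rate Rate inside tuned windows, Hz (>= 0).
#' @param tuning_kind One of `"PV"`, `"NV"`, `"lick"`, `"MV"`,
#'   `"initial_pre"`, `"initial_post"`, `"terminal"`, `"none"`.
#' @param tuned_window Interval relative to the anchor event, seconds;
#'   defaults depend on `tuning_kind`.
#' @return Object of class `spike_tuning_spec`.
#' @export
spike_tuning_spec <- function(baseline_rate = 20, tuned_rate = 60,
                              tuning_kind = c("PV", "NV", "lick", "MV",
                                              "initial_pre", "initial_post",
                                              "terminal", "none"),
                              tuned_window = NULL) {
  tuning_kind <- match.arg(tuning_kind)
  if (!is.finite(baseline_rate) || baseline_rate < 0) {
    stop("baseline_rate must be >= 0")
  }
  if (!is.finite(tuned_rate) || tuned_rate < 0) stop("tuned_rate must be >= 0")
  if (tuning_kind == "none") tuned_rate <- baseline_rate
  if (is.null(tuned_window)) {
    tuned_window <- switch(tuning_kind,
      PV = , NV = , lick = , MV = c(-0.1, 0.08),
      initial_pre = c(-2, 0),
      initial_post = c(0, 2),
      terminal = c(0, 2),
      none = c(0, 0))
  }
  structure(list(baseline_rate = baseline_rate, tuned_rate = tuned_rate,
                 tuning_kind = tuning_kind,
                 tuned_window = as.numeric(tuned_window)),
            class = "spike_tuning_spec")
}

# piecewise-constant-rate Poisson sampler; window_sets is a list of
# list(windows = 2-col matrix, rate = Hz), earlier sets take precedence
.sample_piecewise <- function(span, window_sets, base_rate) {
  edges <- span
  for (ws in window_sets) {
    if (!is.null(ws$windows) && nrow(ws$windows)) {
      edges <- c(edges, pmax(pmin(as.vector(ws$windows), span[2]), span[1]))
    }
  }
  brk <- sort(unique(edges))
  rate_of <- function(a, b) {
    mid <- (a + b) / 2
    for (ws in window_sets) {
      w <- ws$windows
      if (!is.null(w) && nrow(w) && any(mid >= w[, 1] & mid < w[, 2])) {
        return(ws$rate)
      }
    }
    base_rate
  }
  times <- numeric(0)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    r <- rate_of(a, b)
    if (r <= 0 || b <= a) next
    k <- stats::rpois(1, r * (b - a))
    if (k > 0) times <- c(times, stats::runif(k, a, b))
  }
  sort(times)
}

.sample_inhomog <- function(span, windows, base_rate, tuned_rate) {
  .sample_piecewise(span, list(list(windows = windows, rate = tuned_rate)),
                    base_rate)
}

.merge_windows <- function(w) {
  if (is.null(w) || nrow(w) == 0L) return(w)
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    if (w[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], w[i, 2])
    } else {
      out <- rbind(out, w[i, ])
    }
  }
  out
}

#' Generate a tuned spike train
#'
#' Samples an inhomogeneous Poisson process whose rate equals the baseline
#' rate outside the tuned windows and the tuned rate inside them.  Windows are
#' `anchors + tuned_window` (merged when overlapping).  The ground-truth label
#' is attached as the `"truth"` attribute.
#'
#' @param spec A [spike_tuning_spec()].
#' @param anchors Non-empty numeric vector of anchor event times (s).
#' @param span Recording span `[t0, t1]` (s).
#' @param seed Optional integer seed.
#' @param unit_id Unit identifier.
#' @return A [spike_train()] with attribute `"truth"` = `spec$tuning_kind`.
#' @export
gen_tuned_spike_train <- function(spec, anchors, span = c(0, 100),
                                  seed = NULL, unit_id = NA_character_) {
  stopifnot(inherits(spec, "spike_tuning_spec"))
  if (length(anchors) == 0L) stop("anchors must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  w <- cbind(anchors + spec$tuned_window[1], anchors + spec$tuned_window[2])
  w <- .merge_windows(w)
  times <- .sample_inhomog(span, w, spec$baseline_rate, spec$tuned_rate)
  # enforce strict ordering (ties have measure zero but guard anyway)
  times <- times[!duplicated(times)]
  tr <- spike_train(times, span = span, unit_id = unit_id)
  attr(tr, "truth") <- spec$tuning_kind
  tr
}

#' Generate a homogeneous Poisson baseline train
#'
#' Pseudo-trial construction uses a baseline of at least 10 s; this samples a
#' homogeneous Poisson spike train over `[0, duration]`.
#'
#' @param duration Baseline duration in seconds (>= 10).
#' @param rate Rate in Hz (>= 0).
#' @param seed Optional integer seed (fixed seed gives identical output).
#' @return A [spike_train()].
#' @export
gen_pseudo_baseline <- function(duration, rate, seed = NULL) {
  if (!is.finite(duration) || duration < 10) {
    stop("baseline duration must be at least 10 s")
  }
  if (!is.finite(rate) || rate < 0) stop("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  k <- stats::rpois(1, rate * duration)
  times <- sort(stats::runif(k, 0, duration))
  times <- times[!duplicated(times)]
  spike_train(times, span = c(0, duration))
}

#' Generate a synthetic HOG feature sequence
#'
#' Consecutive frames follow a stationary AR(1) process in feature space with
#' lag-one correlation `1 - drift`, so the facial-activity metric
#' (`1 - correlation`) of the sequence averages `drift`.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_features Feature dimension.
#' @param drift Frame-to-frame decorrelation in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Matrix `n_frames` x `n_features`.
#' @export
gen_hog_sequence <- function(n_frames, n_features = 64, drift = 0.1,
                             seed = NULL) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (!is.finite(drift) || drift < 0 || drift > 1) {
    stop("drift must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- 1 - drift
  out <- matrix(0, n_frames, n_features)
  out[1, ] <- stats::rnorm(n_features)
  innov_sd <- sqrt(max(0, 1 - a^2))
  for (t in 2:n_frames) {
    out[t, ] <- a * out[t - 1, ] + innov_sd * stats::rnorm(n_features)
  }
  out
}

#' Generate a full synthetic session
#'
#' Builds a session with a silent 10 s baseline, a water delivery with
#' persistent licking, a quinine delivery that terminates licking after a
#' short quinine lick bout, spike trains with ground-truth tuning labels,
#' wheel-encoder pulses, and a HOG frame sequence.  All analyses in the
#' package can run on the returned object.
#'
#' @param labels Character vector of ground-truth tuning kinds, one unit per
#'   entry (see [spike_tuning_spec()]).
#' @param baseline_rate,rate_ratio Baseline rate (Hz) and tuned/baseline rate
#'   ratio applied to every tuned unit.
#' @param water_DO,quinine_DO Delivery-onset times (s).
#' @param session_length Total span (s); at least 80 s so phase pseudo-windows
#'   can be drawn from more than 70 s of data.
#' @param lick_jitter_sd Inter-lick jitter SD passed to the lick generator.
#' @param seed Integer seed; the whole session is a deterministic function of
#'   it.
#' @return Object of class `synthetic_session`: list with `licks`
#'   (a [lick_raster()]), `spikes` (list of [spike_train()] with `"truth"`
#'   attributes), `events` (data frame: event, time_s, liquid), `truth`
#'   (label per unit), `wheel_pulses`, `hog_frames`, `seed`.
#' @export
gen_session <- function(labels = c("PV", "NV", "lick", "initial_pre",
                                   "initial_post", "terminal", "none"),
                        baseline_rate = 20, rate_ratio = 3,
                        water_DO = 10, quinine_DO = 25,
                        session_length = 100, lick_jitter_sd = 0.01,
                        seed = 1) {
  set.seed(seed)
  span <- c(0, session_length)
  prof <- lick_profile(session_length = session_length - water_DO,
                       termination_time = quinine_DO - water_DO + 1.6,
                       jitter_sd = lick_jitter_sd)
  water <- gen_lick_raster(prof, DO = water_DO)
  wl <- water$lick_times[water$lick_times < quinine_DO]
  # short quinine bout: the taste is sampled with a few licks, then licking stops
  q_first <- quinine_DO + 0.25
  ql <- q_first + cumsum(c(0, abs(1 / 6.5 + stats::rnorm(5, 0, lick_jitter_sd))))
  licks <- lick_raster(c(wl, ql),
                       liquid = c(rep("water", length(wl)),
                                  rep("quinine", length(ql))),
                       DO_times = c(water_DO, quinine_DO),
                       DO_liquid = c("water", "quinine"),
                       span = span)
  first_LO <- wl[1]
  tuned <- baseline_rate * rate_ratio
  anchors_for <- function(kind) {
    switch(kind,
      PV = wl, NV = ql, lick = c(wl, ql), MV = c(wl, ql),
      initial_pre = first_LO, initial_post = first_LO,
      terminal = quinine_DO, none = 0)
  }
  suppressed <- baseline_rate / rate_ratio
  spikes <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    kind <- labels[i]
    sp <- spike_tuning_spec(baseline_rate, tuned, tuning_kind = kind)
    sets <- switch(kind,
      # phase units are elevated in their own window and suppressed in the
      # complementary test window, matching the classifier's joint rule
      # suppression extends 0.5 s beyond the classifier's test window so the
      # long-window smoother does not bleed baseline rate into its endpoints
      initial_pre = list(
        list(windows = cbind(first_LO - 2, first_LO), rate = tuned),
        list(windows = cbind(quinine_DO - 0.5, quinine_DO + 2.5),
             rate = suppressed)),
      initial_post = list(
        list(windows = cbind(first_LO, first_LO + 2), rate = tuned),
        list(windows = cbind(quinine_DO - 0.5, quinine_DO + 2.5),
             rate = suppressed)),
      terminal = list(
        list(windows = cbind(quinine_DO, quinine_DO + 2), rate = tuned),
        list(windows = cbind(first_LO - 2.5, first_LO + 2.5),
             rate = suppressed)),
      # liquid-specific sub-windows so the two liquids peak at different times
      MV = list(
        list(windows = .merge_windows(rbind(cbind(wl - 0.1, wl),
                                            cbind(ql - 0.02, ql + 0.08))),
             rate = tuned)),
      NULL)
    if (is.null(sets)) {
      spikes[[i]] <- gen_tuned_spike_train(sp, anchors_for(kind), span = span,
                                           unit_id = sprintf("u%02d", i))
    } else {
      times <- .sample_piecewise(span, sets, baseline_rate)
      tr <- spike_train(times[!duplicated(times)], span = span,
                        unit_id = sprintf("u%02d", i))
      attr(tr, "truth") <- kind
      spikes[[i]] <- tr
    }
  }
  events <- data.frame(
    event = c("DO", "LO", "DO", "LO"),
    time_s = c(water_DO, first_LO, quinine_DO, ql[1]),
    liquid = c("water", "water", "quinine", "quinine"),
    stringsAsFactors = FALSE)
  wheel <- seq(0.05, session_length, by = 0.05) +
    stats::rnorm(length(seq(0.05, session_length, by = 0.05)), 0, 0.002)
  wheel <- sort(wheel[wheel > 0 & wheel < session_length])
  hog <- gen_hog_sequence(200, 64, drift = 0.1)
  structure(list(licks = licks, spikes = spikes, events = events,
                 truth = labels, wheel_pulses = wheel, hog_frames = hog,
                 seed = seed),
            class = "synthetic_session")
}

#' Write a synthetic session to plain-text files
#'
#' Writes `spikes.csv` (unit_id, spike_time_s), `licks.csv` (lick_time_s,
#' liquid), `events.csv` (event, time_s, liquid) and `truth.json` (labels and
#' seed) into `dir`.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- do.call(rbind, lapply(session$spikes, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(unit_id = tr$unit_id, spike_time_s = tr$times)
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0),
                                    spike_time_s = numeric(0))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(lick_time_s = session$licks$lick_times,
                              liquid = session$licks$liquid),
                   file.path(dir, "licks.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  truth <- list(labels = as.list(stats::setNames(session$truth,
                  vapply(session$spikes, function(tr) tr$unit_id, ""))),
                seed = session$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `spikes.csv`, `licks.csv`, `events.csv`.
#' @return A list with `spikes` (list of [spike_train()]), `licks`
#'   (a [lick_raster()]), `events` (data frame).
#' @export
read_session <- function(dir) {
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  li <- utils::read.csv(file.path(dir, "licks.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  t_max <- max(c(sp$spike_time_s, li$lick_time_s, ev$time_s, 0))
  do_rows <- ev[ev$event == "DO", , drop = FALSE]
  spikes <- lapply(split(sp$spike_time_s, sp$unit_id), function(tt) {
    spike_train(sort(tt), span = c(0, t_max))
  })
  licks <- lick_raster(li$lick_time_s, liquid = li$liquid,
                       DO_times = do_rows$time_s, DO_liquid = do_rows$liquid,
                       span = c(0, t_max))
  list(spikes = spikes, licks = licks, events = ev)
}
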
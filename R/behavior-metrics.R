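#' Construct a lick raster
#'
#' Ordered lick-contact times with liquid labels and the delivery-onset (DO)
#' anchors of the session.
#'
#' @param lick_times Numeric vector of lick times (s), increasing.
#' @param liquid Character vector (recycled) of liquid labels per lick, each
#'   one of `"water"`, `"sucrose"`, `"quinine"`.
#' @param DO_times Numeric vector of delivery-onset times (s).
#' @param DO_liquid Liquid label per delivery onset.
#' @param span Recording span `[t0, t1]`; defaults to covering all events.
#' @return Object of class `lick_raster`.
#' @export
lick_raster <- function(lick_times, liquid = "water", DO_times = numeric(0),
                        DO_liquid = rep("water", length(DO_times)),
                        span = NULL) {
  lick_times <- as.numeric(lick_times)
  if (is.unsorted(lick_times)) lick_times <- sort(lick_times)
  liquid <- rep_len(as.character(liquid), length(lick_times))
  ok <- liquid %in% c("water", "sucrose", "quinine")
  if (length(liquid) && !all(ok)) {
    stop("liquid labels must be water, sucrose or quinine")
  }
  if (is.null(span)) {
    all_t <- c(lick_times, DO_times, 0)
    span <- range(all_t)
  }
  structure(list(lick_times = lick_times, liquid = liquid,
                 DO_times = as.numeric(DO_times),
                 DO_liquid = as.character(DO_liquid),
                 span = as.numeric(span)),
            class = "lick_raster")
}

#' @export
print.lick_raster <- function(x, ...) {
  cat(sprintf("<lick_raster: %d licks, %d deliveries, span [%.2f, %.2f] s>\n",
              length(x$lick_times), length(x$DO_times), x$span[1], x$span[2]))
  invisible(x)
}

.lick_counts <- function(lick_times, anchor, window, k_from, k_to) {
  # count licks in half-open bins [anchor+(k-1)w, anchor+kw) for k in k_from:k_to
  nb <- k_to - k_from + 1L
  if (length(lick_times) == 0L) return(numeric(nb))
  rel <- (lick_times - anchor) / window
  bin <- floor(rel + 1e-9) + 1L - (k_from - 1L)
  bin <- bin[bin >= 1L & bin <= nb]
  as.numeric(tabulate(bin, nbins = nb))
}

#' Simple moving average (SMA) of lick counts
#'
#' The SMA at sample `k` (sampled every `window` seconds after `anchor`) is
#' the mean lick count over the `n` most recent `window`-second bins ending at
#' `anchor + k * window`.  With `memory = "from_anchor"` the average only uses
#' bins after the anchor, so the first `n - 1` samples are partial
#' (`warmup = "partial"` averages over the bins available;
#' `warmup = "strict"` marks them `NA`).  With `memory = "pre_anchor"` the
#' moving window extends before the anchor, which is the appropriate reading
#' for termination analyses where licking is ongoing at the anchor.
#'
#' A lick rate of 6 Hz corresponds to SMA = 1.2 (licks per 200 ms bin).
#'
#' @param licks A [lick_raster()] or numeric vector of lick times.
#' @param anchor Anchor time in seconds (e.g. a delivery onset).
#' @param window Bin width in seconds (default 0.2).
#' @param n Number of bins in the moving average (default 5).
#' @param horizon Scan length after the anchor in seconds (default 6);
#'   clamped to the raster span.
#' @param memory `"from_anchor"` (initiation) or `"pre_anchor"` (termination).
#' @param warmup `"partial"` or `"strict"` (only used for `"from_anchor"`).
#' @return Numeric vector of SMA values at samples `anchor + window * (1:K)`,
#'   with attributes `counts` and `sample_times`.
#' @export
sma_series <- function(licks, anchor, window = 0.2, n = 5, horizon = 6,
                       memory = c("from_anchor", "pre_anchor"),
                       warmup = c("partial", "strict")) {
  memory <- match.arg(memory)
  warmup <- match.arg(warmup)
  lt <- if (inherits(licks, "lick_raster")) licks$lick_times else as.numeric(licks)
  span_end <- if (inherits(licks, "lick_raster")) licks$span[2] else Inf
  eff <- min(horizon, span_end - anchor)
  K <- floor(eff / window + 1e-9)
  if (K < 1L) stop("anchor leaves no room for any SMA sample")
  if (memory == "from_anchor") {
    counts <- .lick_counts(lt, anchor, window, 1L, K)
    sma <- vapply(seq_len(K), function(k) {
      lo <- max(1L, k - n + 1L)
      if (warmup == "strict" && k < n) return(NA_real_)
      mean(counts[lo:k])
    }, numeric(1))
  } else {
    counts <- .lick_counts(lt, anchor, window, -(n - 2L), K)
    off <- n - 1L  # counts[k + off] is the bin ending at anchor + k*window
    sma <- vapply(seq_len(K), function(k) mean(counts[(k):(k + off)]), numeric(1))
    counts <- counts[(off + 1L):(off + K)]
  }
  attr(sma, "counts") <- counts
  attr(sma, "sample_times") <- anchor + window * seq_len(K)
  sma
}

.bias_result <- function(bias, idx, sma) {
  structure(list(bias = bias, idx = idx, sma_series = sma),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result: bias = %.4g, idx = %s>\n", x$bias,
              if (is.na(x$idx)) "none" else x$idx))
  invisible(x)
}

#' Initiation bias of persistent licking
#'
#' Scans the SMA of lick counts after a delivery onset.  Samples up to and
#' including the last zero-valued SMA sample are ignored, so `idx` counts from
#' the sample after the last zero.  The initiation bias is `1/idx` at the
#' first sample with SMA > `threshold` (default 1.2, i.e. 6 Hz); it is 0 if
#' the SMA stays at zero throughout the horizon or the threshold is never
#' crossed after the last zero.
#'
#' @inheritParams sma_series
#' @param DO Delivery-onset anchor time (s).  If `licks` is a `lick_raster`
#'   with recorded `DO_times`, `DO` must be one of them.
#' @param threshold SMA threshold (default 1.2).
#' @param exclude_pre_DO If `TRUE`, signal an error when the 3 s before `DO`
#'   contain licking above 0.5 Hz (trial-exclusion rule used with
#'   optogenetic silencing).
#' @return A `bias_result` with fields `bias` (in `[0, 1]`), `idx`
#'   (positive integer or `NA`), `sma_series`.
#' @export
initiation_bias <- function(licks, DO, threshold = 1.2, window = 0.2, n = 5,
                            horizon = 6, warmup = c("partial", "strict"),
                            exclude_pre_DO = FALSE) {
  warmup <- match.arg(warmup)
  if (inherits(licks, "lick_raster") && length(licks$DO_times) &&
      !any(abs(licks$DO_times - DO) < 1e-9)) {
    stop("DO is not a delivery onset of this raster")
  }
  lt <- if (inherits(licks, "lick_raster")) licks$lick_times else as.numeric(licks)
  if (exclude_pre_DO) {
    pre <- sum(lt >= DO - 3 & lt < DO)
    if (pre / 3 > 0.5) {
      stop("trial excluded: pre-DO licking above 0.5 Hz")
    }
  }
  s <- sma_series(licks, DO, window = window, n = n, horizon = horizon,
                  memory = "from_anchor", warmup = warmup)
  ok <- !is.na(s)
  zero_idx <- which(ok & s == 0)
  last_zero <- if (length(zero_idx)) max(zero_idx) else 0L
  cand <- which(ok & s > threshold)
  cand <- cand[cand > last_zero]
  if (!length(cand)) return(.bias_result(0, NA_integer_, s))
  first <- min(cand)
  # idx counts evaluated samples after the last zero
  idx <- sum(ok[(last_zero + 1L):first])
  .bias_result(1 / idx, as.integer(idx), s)
}

#' Termination bias of persistent licking
#'
#' Scans the SMA of lick counts starting at the first sample after the stop
#' anchor (quinine delivery onset, or the end of water/sucrose delivery).  The
#' moving-average memory extends before the anchor, so ongoing licking drains
#' out of the window over `n` samples.  The termination bias is `1/idx` at the
#' first sample with SMA < `threshold` (default 1, i.e. 5 Hz) and 0 if the
#' SMA never drops below the threshold within the horizon.
#'
#' @inheritParams sma_series
#' @param stop_anchor Anchor time in seconds.
#' @param threshold SMA threshold (default 1).
#' @return A `bias_result`.
#' @export
termination_bias <- function(licks, stop_anchor, threshold = 1, window = 0.2,
                             n = 5, horizon = 6) {
  s <- sma_series(licks, stop_anchor, window = window, n = n,
                  horizon = horizon, memory = "pre_anchor")
  cand <- which(s < threshold)
  if (!length(cand)) return(.bias_result(0, NA_integer_, s))
  idx <- min(cand)
  .bias_result(1 / idx, as.integer(idx), s)
}

#' Locomotor speed from rotary-encoder pulses
#'
#' The wheel emits `cpr` pulses per revolution; the speed between two
#' consecutive pulses is `circumf / (cpr * dt)` where `dt` is the pulse
#' interval.
#'
#' @param pulse_times Numeric vector of pulse times (s), increasing.
#' @param circumf_cm Wheel circumference in cm.
#' @param cpr Cycles (pulses) per revolution, default 360.
#' @return Data frame with `time_s` (time of the later pulse of each pair) and
#'   `speed_cm_s`.  Fewer than two pulses yield an empty series; duplicate
#'   pulse times are dropped with a message.
#' @export
locomotor_speed <- function(pulse_times, circumf_cm, cpr = 360) {
  pt <- sort(as.numeric(pulse_times))
  if (anyDuplicated(pt)) {
    message(sprintf("locomotor_speed: dropping %d duplicate pulse(s)",
                    sum(duplicated(pt))))
    pt <- unique(pt)
  }
  if (length(pt) < 2L) {
    return(data.frame(time_s = numeric(0), speed_cm_s = numeric(0)))
  }
  dt <- diff(pt)
  data.frame(time_s = pt[-1], speed_cm_s = circumf_cm / (cpr * dt))
}

#' Facial activity from HOG feature vectors
#'
#' Facial motion energy at each time step is `1 - r` where `r` is the Pearson
#' correlation between temporally adjacent histogram-of-oriented-gradients
#' (HOG) feature vectors, giving values in `[0, 2]`.  Frames are expected as
#' precomputed HOG vectors (the reference parameterization is 8 orientations,
#' 32 pixels per cell, 1 cell per block).
#'
#' @param hog_frames Numeric matrix, rows = frames, columns = HOG features
#'   (at least 2 frames and 2 features).
#' @return Numeric vector of length `nrow(hog_frames) - 1`; steps where either
#'   frame has zero variance are `NA`.
#' @export
facial_activity <- function(hog_frames) {
  hog_frames <- as.matrix(hog_frames)
  if (nrow(hog_frames) < 2L) stop("need at least two frames")
  if (ncol(hog_frames) < 2L) stop("need at least two HOG features")
  n <- nrow(hog_frames)
  sds <- apply(hog_frames, 1L, stats::sd)
  out <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    if (sds[i] > 0 && sds[i + 1L] > 0) {
      out[i] <- 1 - stats::cor(hog_frames[i, ], hog_frames[i + 1L, ])
    }
  }
  out
}
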
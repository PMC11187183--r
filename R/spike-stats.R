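#' Construct a spike train
#'
#' A spike train is an ordered vector of event times (seconds) for one unit
#' together with the recording span it was observed in.
#'
#' @param times Numeric vector of spike times in seconds, strictly increasing.
#' @param span Length-2 numeric, recording span `[t0, t1]` in seconds.
#'   Defaults to the range of `times` (or `c(0, 0)` for an empty train).
#' @param unit_id Optional unit identifier.
#' @return An object of class `spike_train` with fields `times`, `span`,
#'   `unit_id`.
#' @export
spike_train <- function(times, span = NULL, unit_id = NA_character_) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    times <- sort(times)
    if (anyDuplicated(times)) {
      stop("spike times must be strictly increasing (duplicates found)")
    }
  }
  if (is.null(span)) {
    span <- if (length(times)) range(times) else c(0, 0)
  }
  span <- as.numeric(span)
  if (length(span) != 2L || span[2] < span[1]) {
    stop("span must be an increasing [t0, t1] pair")
  }
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2])) {
    stop("all spike times must lie within span")
  }
  structure(list(times = times, span = span, unit_id = unit_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes in [%.3f, %.3f] s>\n",
              x$unit_id, length(x$times), x$span[1], x$span[2]))
  invisible(x)
}

#' Crop a spike train to a sub-interval
#'
#' @param train A [spike_train()].
#' @param window Length-2 numeric interval in seconds.
#' @param rebase If `TRUE`, shift times so the window start maps to 0.
#' @return A `spike_train` restricted to `window`.
#' @export
crop_spike_train <- function(train, window, rebase = FALSE) {
  stopifnot(inherits(train, "spike_train"), length(window) == 2L)
  keep <- train$times >= window[1] & train$times <= window[2]
  times <- train$times[keep]
  span <- c(max(window[1], train$span[1]), min(window[2], train$span[2]))
  if (rebase) {
    times <- times - window[1]
    span <- span - window[1]
  }
  spike_train(times, span = span, unit_id = train$unit_id)
}

#' Bayesian adaptive kernel smoother (BAKS) firing-rate estimate
#'
#' Estimates an instantaneous firing rate from a spike train with a Gaussian
#' kernel whose bandwidth adapts over time.  The adaptive bandwidth at grid
#' time `t` is
#' \deqn{h(t) = \frac{\Gamma(\alpha)}{\Gamma(\alpha + 1/2)}
#'   \frac{\sum_i ((t - t_i)^2/2 + 1/\beta)^{-\alpha}}
#'        {\sum_i ((t - t_i)^2/2 + 1/\beta)^{-(\alpha + 1/2)}}}
#' and the rate is the sum of Gaussian kernels of width `h(t)` centred on the
#' spikes.  Defaults follow the convention `alpha = 4` and
#' `beta = n^(4/5)` where `n` is the number of spikes.  `bandwidth` acts as a
#' lower floor on the adaptive bandwidth and encodes the analysis scale:
#' 0.005 s for short peri-lick windows (180 ms), 0.2 s for long windows (5 s).
#'
#' @param train A [spike_train()].
#' @param grid Numeric vector of evaluation times within the train span.
#'   Defaults to a uniform grid over the span at spacing `dt`.
#' @param alpha Shape parameter (> 0), default 4.
#' @param beta Scale parameter (> 0); defaults to `n^(4/5)`.
#' @param bandwidth Bandwidth floor in seconds (default 0.005).
#' @param dt Grid spacing used when `grid` is `NULL` (default 0.001 s).
#' @return An object of class `rate_trace`: list with `times`, `rate` (Hz),
#'   `bandwidth` (the per-point bandwidth used), `alpha`, `beta`.
#'   An empty train yields an all-zero trace.
#' @export
baks_rate <- function(train, grid = NULL, alpha = 4, beta = NULL,
                      bandwidth = 0.005, dt = 0.001) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  if (is.null(grid)) {
    grid <- seq(train$span[1], train$span[2], by = dt)
  }
  tol <- 1e-9
  if (any(grid < train$span[1] - tol) || any(grid > train$span[2] + tol)) {
    stop("grid must lie within the train span")
  }
  n <- length(train$times)
  if (n == 0L) {
    return(structure(list(times = grid, rate = numeric(length(grid)),
                          bandwidth = rep(bandwidth, length(grid)),
                          alpha = alpha, beta = beta),
                     class = "rate_trace"))
  }
  if (is.null(beta)) beta <- n^(4 / 5)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  pref <- gamma(alpha) / gamma(alpha + 0.5)
  st <- train$times
  rate <- numeric(length(grid))
  h_all <- numeric(length(grid))
  # chunk over the grid to bound the size of the outer() matrices
  chunk <- max(1L, floor(2e6 / n))
  idx <- seq_along(grid)
  for (block in split(idx, ceiling(idx / chunk))) {
    d2 <- outer(grid[block], st, "-")^2 / 2 + 1 / beta
    num <- rowSums(d2^(-alpha))
    den <- rowSums(d2^(-(alpha + 0.5)))
    h <- pmax(pref * num / den, bandwidth)
    r <- rowSums(stats::dnorm(outer(grid[block], st, "-"), mean = 0, sd = h))
    rate[block] <- r
    h_all[block] <- h
  }
  structure(list(times = grid, rate = rate, bandwidth = h_all,
                 alpha = alpha, beta = beta),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace: %d points, mean %.2f Hz, bandwidth [%.4g, %.4g] s>\n",
              length(x$times), mean(x$rate), min(x$bandwidth), max(x$bandwidth)))
  invisible(x)
}

#' Normalize a rate trace or matrix to its maximum
#'
#' Divides by the maximum value so the result lies in `[0, 1]` with maximum
#' exactly 1 for non-degenerate input.  All-zero input is passed through
#' unchanged.
#'
#' @param x Numeric vector, matrix, array, or `rate_trace`.
#' @return Same shape as `x`.
#' @export
normalize_rate <- function(x) {
  if (inherits(x, "rate_trace")) {
    x$rate <- normalize_rate(x$rate)
    return(x)
  }
  m <- max(x, na.rm = TRUE)
  if (is.finite(m) && m > 0) x / m else x
}

#' Baseline z-score of a trial matrix
#'
#' Subtracts the baseline mean and divides by the baseline standard deviation
#' row-wise (one row per unit or trial), so the baseline bins have mean 0 and
#' unit variance.  Rows with zero baseline variance cannot be scaled; they are
#' set to `NA`, flagged in the `"excluded"` attribute, and reported with a
#' message.
#'
#' @param mat Numeric matrix, rows = units (or trials), columns = time bins.
#' @param baseline Integer vector of baseline column indices.
#' @return Matrix of the same shape, with attribute `"excluded"` listing rows
#'   with degenerate baselines.
#' @export
baseline_zscore <- function(mat, baseline) {
  stopifnot(is.matrix(mat), length(baseline) >= 2L)
  mu <- rowMeans(mat[, baseline, drop = FALSE])
  sd0 <- apply(mat[, baseline, drop = FALSE], 1L, stats::sd)
  bad <- !is.finite(sd0) | sd0 == 0
  out <- (mat - mu) / ifelse(bad, NA_real_, sd0)
  if (any(bad)) {
    message(sprintf("baseline_zscore: %d unit(s) with zero baseline variance excluded", sum(bad)))
    out[bad, ] <- NA_real_
  }
  attr(out, "excluded") <- which(bad)
  out
}

# trapezoidal integral of a rate trace; used for mass-conservation checks
#' Integrate a rate trace over time
#'
#' Trapezoidal integral of the rate over the grid; for a well-behaved kernel
#' estimate this approximates the number of spikes.
#'
#' @param trace A `rate_trace`.
#' @return Scalar integral (expected spike count).
#' @export
integrate_rate <- function(trace) {
  stopifnot(inherits(trace, "rate_trace"))
  x <- trace$times
  y <- trace$rate
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
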
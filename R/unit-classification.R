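#' Peri-event firing-rate trial matrix
#'
#' Estimates the firing rate (BAKS, [baks_rate()]) of one unit in a window
#' around each anchor event, returning a trials x bins matrix.  The default
#' window is the peri-lick window LO-100 ms to LO+80 ms with 5 ms bins and a
#' 5 ms bandwidth floor (the short-window convention); phase analyses use 2 s
#' windows with a 200 ms bandwidth.
#'
#' @param train A [spike_train()].
#' @param anchors Event times (s); one trial per anchor.
#' @param window Interval relative to each anchor, default `c(-0.1, 0.08)`.
#' @param bin Bin width in seconds (default 0.005).
#' @param bandwidth Bandwidth floor passed to [baks_rate()].
#' @param local If `TRUE` (default), each trial's rate is estimated from the
#'   spikes inside its own (padded) window, with the BAKS scale `beta` set
#'   from that window's spike count — the per-window estimation convention.
#'   If `FALSE`, the whole train is smoothed once.
#' @return Matrix (length(anchors) x n_bins) of rates in Hz, with attributes
#'   `bin`, `window`, `anchors`.
#' @export
trial_rate_matrix <- function(train, anchors, window = c(-0.1, 0.08),
                              bin = 0.005, bandwidth = 0.005, local = TRUE) {
  stopifnot(inherits(train, "spike_train"), length(anchors) >= 1L)
  centers <- seq(window[1] + bin / 2, window[2] - bin / 2 + 1e-12, by = bin)
  if (local) {
    m <- .local_rate_windows(train$times, anchors, centers, window, bandwidth)
  } else {
    grid <- as.vector(outer(centers, anchors, "+"))
    grid <- pmin(pmax(grid, train$span[1]), train$span[2])
    tr <- baks_rate(train, grid = grid, bandwidth = bandwidth)
    m <- matrix(tr$rate, nrow = length(anchors), ncol = length(centers),
                byrow = TRUE)
  }
  attr(m, "bin") <- bin
  attr(m, "window") <- window
  attr(m, "anchors") <- anchors
  m
}

# adaptive-kernel rate at scattered time points, with the kernel sum
# truncated to spikes within `reach` seconds (negligible truncation error
# for sub-second bandwidths); beta from the full-train spike count
.baks_points <- function(times, pts, bandwidth, reach = 3) {
  out <- numeric(length(pts))
  n <- length(times)
  if (n == 0L) return(out)
  inv_beta <- n^(-4 / 5)
  pref <- gamma(4) / gamma(4.5)
  ord <- order(pts)
  sp <- pts[ord]
  res <- numeric(length(sp))
  for (b in split(seq_along(sp), ceiling(seq_along(sp) / 200))) {
    lo <- findInterval(sp[b[1]] - reach, times) + 1L
    hi <- findInterval(sp[b[length(b)]] + reach, times)
    if (hi < lo) next
    st <- times[lo:hi]
    d <- outer(sp[b], st, "-")
    d2 <- d^2 / 2 + inv_beta
    d2a <- d2^-4
    h <- pmax(pref * rowSums(d2a) / rowSums(d2a * d2^-0.5), bandwidth)
    res[b] <- rowSums(stats::dnorm(d, 0, h))
  }
  out[ord] <- res
  out
}

# lean BAKS evaluation for many peri-event windows: per window, the rate at
# `centers` is estimated from the spikes inside the (padded) window with
# beta from that window's spike count; returns an anchors x centers matrix
.local_rate_windows <- function(times, anchors, centers, window, bandwidth) {
  pad <- max(0.05, 2 * bandwidth)
  pref <- gamma(4) / gamma(4.5)
  n_c <- length(centers)
  lo <- findInterval(anchors + window[1] - pad, times) + 1L
  hi <- findInterval(anchors + window[2] + pad, times)
  m <- matrix(0, length(anchors), n_c)
  for (j in seq_along(anchors)) {
    if (hi[j] < lo[j]) next
    st <- times[lo[j]:hi[j]] - anchors[j]
    inv_beta <- length(st)^(-4 / 5)
    d2 <- outer(centers, st, "-")^2 / 2 + inv_beta
    d2a <- d2^-4
    h <- pmax(pref * rowSums(d2a) / rowSums(d2a * d2^-0.5), bandwidth)
    m[j, ] <- rowSums(stats::dnorm(outer(centers, st, "-"), 0, h))
  }
  m
}

#' Pseudo-trial matrix from a baseline spike train
#'
#' Builds the null-condition trial matrix used by the valence classifier:
#' pseudo lick onsets with the same inter-lick intervals as the real licks are
#' placed at a random position within the (>= 10 s) baseline, the per-bin
#' firing-rate values of the pseudo trials are concatenated horizontally and
#' shuffled, and the procedure is repeated `n_shuffles` times; the returned
#' matrix is the element-wise mean over shuffles.
#'
#' @param baseline A [spike_train()] covering the baseline period (span of at
#'   least 10 s).
#' @param lick_times Real lick-onset times (s); their inter-lick intervals are
#'   preserved (at least one interval, i.e. two licks).
#' @param window,bin,bandwidth As in [trial_rate_matrix()].
#' @param n_shuffles Number of placement/shuffle repeats (default 1000).
#' @param seed Optional integer seed.
#' @return Matrix with one row per real lick and the same bin structure as
#'   the real trial matrix.
#' @export
make_pseudo_trials <- function(baseline, lick_times, window = c(-0.1, 0.08),
                               bin = 0.005, bandwidth = 0.005,
                               n_shuffles = 1000, seed = NULL) {
  stopifnot(inherits(baseline, "spike_train"))
  if (length(lick_times) < 2L) stop("need at least one lick interval")
  if (!is.null(seed)) set.seed(seed)
  span <- baseline$span
  if (diff(span) < 10 - 1e-9) stop("baseline span must be at least 10 s")
  pat <- sort(lick_times) - min(lick_times)
  lo <- span[1] - window[1]
  hi <- span[2] - (max(pat) + window[2])
  if (hi <= lo) stop("baseline shorter than the lick pattern")
  n_tr <- length(pat)
  centers <- seq(window[1] + bin / 2, window[2] - bin / 2 + 1e-12, by = bin)
  n_bin <- length(centers)
  starts <- stats::runif(n_shuffles, lo, hi)
  anchors <- as.vector(outer(pat, starts, "+"))   # trial-major per shuffle
  vals <- .local_rate_windows(baseline$times, anchors, centers, window,
                              bandwidth)
  len <- n_tr * n_bin
  acc <- numeric(len)
  for (s in seq_len(n_shuffles)) {
    rows <- ((s - 1L) * n_tr + 1L):(s * n_tr)
    flat <- as.vector(t(vals[rows, , drop = FALSE]))
    acc <- acc + flat[sample.int(len)]
  }
  m <- matrix(acc / n_shuffles, nrow = n_tr, ncol = n_bin, byrow = TRUE)
  attr(m, "bin") <- bin
  attr(m, "window") <- window
  m
}

#' Separation z-score between two distributions
#'
#' \deqn{z_{12} = (\mu_1 - \mu_2) / \sqrt{\sigma_1^2 + \sigma_2^2}}
#' Two distributions are considered significantly different when `|z|`
#' exceeds 1.29; the peak-time criterion uses 1.64.
#'
#' @param x,y Numeric samples of the two distributions.
#' @return The signed z-score; `NA` (with a warning) when the combined
#'   variance is zero.
#' @export
zscore_separation <- function(x, y) {
  if (!length(x) || !length(y)) stop("both distributions must be non-empty")
  v <- stats::var(x) + stats::var(y)
  if (!is.finite(v) || v == 0) {
    warning("zscore_separation: zero combined variance, z undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(v)
}

#' Euclidean norm of temporally adjacent rate estimates
#'
#' For a rate vector sampled on a uniform grid, returns
#' `sqrt(r_t^2 + r_{t+1}^2)` for every adjacent pair; these per-bin values
#' form the distributions compared by [zscore_separation()] in the valence
#' classifier.
#'
#' @param trace Numeric vector of rate estimates (>= 2 bins), or a matrix
#'   (applied row-wise and concatenated).
#' @return Numeric vector of adjacent-pair norms.
#' @export
euclidean_step_norm <- function(trace) {
  if (is.matrix(trace)) {
    return(as.vector(t(apply(trace, 1L, euclidean_step_norm))))
  }
  if (length(trace) < 2L) stop("need at least two bins")
  sqrt(trace[-length(trace)]^2 + trace[-1]^2)
}

.frob_norm_cols <- function(m) {
  ti <- colMeans(m)
  sqrt(sum((ti - mean(ti))^2))
}

#' Time-bias test via shuffled Frobenius norms
#'
#' Mean-centers the trial matrix, computes the Frobenius-style norm of the
#' column (time-bin) means, and compares it with the norms of `n_shuffles`
#' matrices obtained by permuting the concatenated entries.  The unit is
#' time-biased when the real norm exceeds 95% of the shuffled norms.
#'
#' @param mat Trials x time-bins matrix (10 ms bins by convention).
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Optional integer seed.
#' @return List with `norm`, `percentile_rank` (fraction of shuffled norms
#'   below the real norm), `biased` (logical).
#' @export
frobenius_time_bias <- function(mat, n_shuffles = 1000, seed = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  m <- mat - mean(mat)
  real <- .frob_norm_cols(m)
  if (real == 0) {
    return(list(norm = 0, percentile_rank = 0, biased = FALSE))
  }
  v <- as.vector(m)
  nr <- nrow(m)
  sh <- vapply(seq_len(n_shuffles), function(i) {
    .frob_norm_cols(matrix(v[sample.int(length(v))], nrow = nr))
  }, numeric(1))
  rank <- mean(real > sh)
  list(norm = real, percentile_rank = rank, biased = rank > 0.95)
}

#' Trial-bias test on binned water-lick trials
#'
#' Trials are grouped into consecutive bins of `bin_trials` (default 8), the
#' per-group mean matrices are reduced to row (group) means, and the
#' Frobenius-style norm of the group means is compared against
#' `n_shuffles` trial-permuted norms.  Fewer than two full groups make the
#' test undecidable; it is skipped with a message.
#'
#' @param mat Trials x time-bins matrix over water licks.
#' @param bin_trials Trials per group (default 8).
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Optional integer seed.
#' @return List with `norm`, `biased`, `skipped`.
#' @export
trial_bias_test <- function(mat, bin_trials = 8, n_shuffles = 1000,
                            seed = NULL) {
  stopifnot(is.matrix(mat))
  n_tr <- nrow(mat)
  n_grp <- n_tr %/% bin_trials
  if (n_grp < 2L) {
    message("trial_bias_test: fewer than two trial groups, test skipped")
    return(list(norm = NA_real_, biased = NA, skipped = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  use <- n_grp * bin_trials
  grp <- rep(seq_len(n_grp), each = bin_trials)
  norm_of <- function(rows) {
    gm <- rowsum(rowMeans(mat[rows, , drop = FALSE]), grp) / bin_trials
    sqrt(sum((gm - mean(gm))^2))
  }
  real <- norm_of(seq_len(use))
  if (real == 0) return(list(norm = 0, biased = FALSE, skipped = FALSE))
  sh <- vapply(seq_len(n_shuffles), function(i) norm_of(sample.int(n_tr, use)),
               numeric(1))
  list(norm = real, biased = mean(real > sh) > 0.95, skipped = FALSE)
}

.class_label <- function(label, statistics, n_shuffles) {
  structure(list(label = label, statistics = statistics,
                 n_shuffles = n_shuffles),
            class = "class_label")
}

#' @export
print.class_label <- function(x, ...) {
  cat(sprintf("<class_label: %s>\n", x$label))
  invisible(x)
}

#' Classify a unit's valence representation
#'
#' Applies the shuffle-based valence classification: firing rates in the
#' peri-lick window (LO-100 ms to LO+80 ms) of the first four water and the
#' first four quinine lick trials are compared with a pseudo-trial matrix
#' built from the 10 s baseline ([make_pseudo_trials()]).  Distributions of
#' adjacent-bin Euclidean norms are compared with [zscore_separation()] at
#' threshold 1.29; rate-peak times are compared per trial with a two-sample
#' t-test (p < 0.05); the time bias uses [frobenius_time_bias()] on 10 ms
#' bins.  Labels (in precedence order):
#' \itemize{
#'   \item `lick`: water > pseudo and quinine > pseudo, no peak-time
#'     difference between liquids, with time bias;
#'   \item `PV`: water > pseudo, water > quinine, quinine not > pseudo;
#'   \item `NV`: quinine > pseudo, quinine > water, water not > pseudo;
#'   \item `MV`: water > pseudo and quinine > pseudo, with peak-time
#'     difference and time bias;
#'   \item `UV`: otherwise.
#' }
#' "Not greater" is read as not-significantly-greater (z <= 1.29).
#'
#' @param train A [spike_train()].
#' @param water_LOs,quinine_LOs Lick-onset times per liquid; the first four
#'   of each are used.
#' @param baseline_window 10 s baseline interval, default `c(0, 10)`.
#' @param window Peri-lick window, default `c(-0.1, 0.08)`.
#' @param n_shuffles Shuffle count for pseudo trials and norm tests.
#' @param n_trials Number of real trials per liquid (default 4).
#' @param seed Optional integer seed.
#' @return A `class_label` with the decision statistics attached.
#' @export
classify_valence <- function(train, water_LOs, quinine_LOs,
                             baseline_window = c(0, 10),
                             window = c(-0.1, 0.08), n_shuffles = 1000,
                             n_trials = 4, seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (length(water_LOs) < n_trials || length(quinine_LOs) < n_trials) {
    stop(sprintf("need at least %d lick trials per liquid", n_trials))
  }
  if (!is.null(seed)) set.seed(seed)
  wa <- sort(water_LOs)[seq_len(n_trials)]
  qa <- sort(quinine_LOs)[seq_len(n_trials)]
  W <- trial_rate_matrix(train, wa, window = window)
  Q <- trial_rate_matrix(train, qa, window = window)
  base <- crop_spike_train(train, baseline_window)
  P <- make_pseudo_trials(base, wa, window = window, n_shuffles = n_shuffles)
  en_w <- euclidean_step_norm(W)
  en_q <- euclidean_step_norm(Q)
  en_p <- euclidean_step_norm(P)
  z_wp <- zscore_separation(en_w, en_p)
  z_qp <- zscore_separation(en_q, en_p)
  z_wq <- zscore_separation(en_w, en_q)
  gt <- function(z) is.finite(z) && z > 1.29
  # peak-time comparison: per-trial argmax times, two-sample t-test
  centers <- seq(window[1], window[2], length.out = ncol(W))
  pk_w <- centers[apply(W, 1L, which.max)]
  pk_q <- centers[apply(Q, 1L, which.max)]
  peak_p <- tryCatch(stats::t.test(pk_w, pk_q)$p.value, error = function(e) 1)
  peak_diff <- is.finite(peak_p) && peak_p < 0.05
  # time bias on 10 ms bins over the combined water+quinine trials
  W10 <- trial_rate_matrix(train, wa, window = window, bin = 0.01)
  Q10 <- trial_rate_matrix(train, qa, window = window, bin = 0.01)
  tb <- frobenius_time_bias(rbind(W10, Q10), n_shuffles = n_shuffles)
  label <-
    if (gt(z_qp) && gt(z_wp) && !peak_diff && tb$biased) "lick"
    else if (gt(z_wp) && gt(z_wq) && !gt(z_qp)) "PV"
    else if (gt(z_qp) && is.finite(z_wq) && -z_wq > 1.29 && !gt(z_wp)) "NV"
    else if (gt(z_wp) && gt(z_qp) && peak_diff && tb$biased) "MV"
    else "UV"
  .class_label(label,
               statistics = list(z_water_pseudo = z_wp, z_quinine_pseudo = z_qp,
                                 z_water_quinine = z_wq, peak_p = peak_p,
                                 time_bias = tb),
               n_shuffles = n_shuffles)
}

#' Classify a unit's movement-phase representation
#'
#' Compares BAKS firing-rate estimates (200 ms bandwidth) at five time points
#' (0, 0.5, 1, 1.5, 2 s spacing) inside 2 s windows around the first water
#' lick onset and the quinine delivery onset against pseudo windows drawn at
#' random positions from the full (> 70 s) spike train:
#' \itemize{
#'   \item `initial_pre`: rate above the 65th pseudo percentile at all five
#'     points of (first water LO - 2 s, first water LO) and below the 35th at
#'     all five points of (quinine DO, quinine DO + 2 s);
#'   \item `initial_post`: the same with the window (first LO, first LO + 2 s);
#'   \item `terminal`: above 65% in (quinine DO, quinine DO + 2 s) and below
#'     35% across (first water LO - 2 s, first water LO + 2 s) (five points at
#'     1 s spacing);
#'   \item `unrelated`: otherwise.
#' }
#' The percentile rule is applied jointly at every time point (the strictest
#' reading).
#'
#' @param train A [spike_train()] (span longer than 70 s; shorter spans are
#'   used in full, with a warning).
#' @param first_water_LO First water lick-onset time (s).
#' @param quinine_DO Quinine delivery-onset time (s).
#' @param n_pseudo Number of random pseudo windows (default 1000).
#' @param bandwidth BAKS bandwidth floor, default 0.2 s (long-window scale).
#' @param seed Optional integer seed.
#' @return A `class_label`.
#' @export
classify_phase <- function(train, first_water_LO, quinine_DO, n_pseudo = 1000,
                           bandwidth = 0.2, seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.null(seed)) set.seed(seed)
  span <- train$span
  if (diff(span) < 70) {
    warning("classify_phase: recording shorter than 70 s, pseudo windows drawn from the full span")
  }
  off5 <- seq(0, 2, by = 0.5)
  off5w <- seq(0, 4, by = 1)
  pts <- list(A = first_water_LO - 2 + off5,   # (LO-2, LO)
              B = first_water_LO + off5,       # (LO, LO+2)
              C = quinine_DO + off5,           # (qDO, qDO+2)
              D = first_water_LO - 2 + off5w)  # (LO-2, LO+2)
  starts2 <- stats::runif(n_pseudo, span[1], span[2] - 2)
  starts4 <- stats::runif(n_pseudo, span[1], max(span[1] + 1e-6, span[2] - 4))
  grid <- c(unlist(pts, use.names = FALSE),
            as.vector(outer(off5, starts2, "+")),
            as.vector(outer(off5w, starts4, "+")))
  grid <- pmin(pmax(grid, span[1]), span[2])
  rate <- .baks_points(train$times, grid, bandwidth)
  n_real <- 20L
  real <- matrix(rate[seq_len(n_real)], nrow = 5L)  # columns A,B,C,D
  ps2 <- matrix(rate[n_real + seq_len(5L * n_pseudo)], nrow = 5L)
  ps4 <- matrix(rate[n_real + 5L * n_pseudo + seq_len(5L * n_pseudo)],
                nrow = 5L)
  hi65 <- apply(ps2, 1L, stats::quantile, probs = 0.65, names = FALSE)
  lo35 <- apply(ps2, 1L, stats::quantile, probs = 0.35, names = FALSE)
  hi65w <- apply(ps4, 1L, stats::quantile, probs = 0.65, names = FALSE)
  lo35w <- apply(ps4, 1L, stats::quantile, probs = 0.35, names = FALSE)
  high <- function(v, q) all(v > q)
  low <- function(v, q) all(v < q)
  label <-
    if (high(real[, 1], hi65) && low(real[, 3], lo35)) "initial_pre"
    else if (high(real[, 2], hi65) && low(real[, 3], lo35)) "initial_post"
    else if (high(real[, 3], hi65) && low(real[, 4], lo35w)) "terminal"
    else "unrelated"
  .class_label(label,
               statistics = list(real = real, hi65 = hi65, lo35 = lo35,
                                 hi65_wide = hi65w, lo35_wide = lo35w),
               n_shuffles = n_pseudo)
}
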
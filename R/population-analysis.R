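#' Construct a population matrix
#'
#' Container for normalized population activity: a 3-D array
#' (units x time-bins x trials) with one condition label per trial.  Values
#' are expected in `[0, 1]` after [normalize_rate()].
#'
#' @param values Numeric array, units x bins x trials.
#' @param labels Condition label per trial (length = 3rd dimension), e.g.
#'   water/quinine or initial/terminal.
#' @param bin Bin width in seconds (metadata).
#' @return Object of class `population_matrix`.
#' @export
population_matrix <- function(values, labels, bin = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(labels) != dim(values)[3]) {
    stop("one label per trial is required")
  }
  structure(list(values = values, labels = factor(labels), bin = bin),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<population_matrix: %d units x %d bins x %d trials (%s)>\n",
              d[1], d[2], d[3],
              paste(levels(x$labels), collapse = "/")))
  invisible(x)
}

.pop_features <- function(pop) {
  d <- dim(pop$values)
  t(matrix(pop$values, nrow = d[1] * d[2], ncol = d[3]))  # trials x features
}

.pc_dims_over <- function(sdev, threshold = 0.85) {
  v <- sdev^2
  frac <- cumsum(v) / sum(v)
  max(1L, which(frac > threshold)[1])
}

.linear_decoder_once <- function(X, y, split, seed_draw = NULL,
                                 var_threshold = 0.85) {
  lev <- levels(y)
  tr_idx <- unlist(lapply(lev, function(l) {
    i <- which(y == l)
    sample(i, max(1L, floor(length(i) * split)))
  }))
  te_idx <- setdiff(seq_along(y), tr_idx)
  if (!length(te_idx)) return(NA_real_)
  pc <- stats::prcomp(X[tr_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- .pc_dims_over(pc$sdev, var_threshold)
  Ztr <- pc$x[, seq_len(k), drop = FALSE]
  Zte <- scale(X[te_idx, , drop = FALSE], center = pc$center, scale = FALSE) %*%
    pc$rotation[, seq_len(k), drop = FALSE]
  fit <- tryCatch(
    e1071::svm(Ztr, y[tr_idx], kernel = "linear", scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  pred <- stats::predict(fit, Zte)
  c(acc = mean(pred == y[te_idx]), k = k)
}

#' Fit a population decoder with pseudo-data control
#'
#' Reduces the trial-by-feature matrix with PCA, keeping the smallest number
#' of components explaining more than 85% of the variance, trains a linear
#' decoder (a binary linear SVM, the two-class reduction of an
#' error-correcting-output-codes classifier) on half of the trials and tests
#' on the other half, repeating `repeats` times.  The control distribution is
#' the same pipeline run on label-shuffled data (or, when `pseudo` is given,
#' on pseudo trials built from random lick-onset placement, labelled at
#' random).
#'
#' @param pop A [population_matrix()] with exactly two condition levels.
#' @param pseudo Optional [population_matrix()] of pseudo trials (see
#'   [pseudo_population()]); defaults to label shuffling of `pop`.
#' @param split Training fraction (default 0.5).
#' @param repeats Number of split repeats (default 10).
#' @param var_threshold PCA variance threshold (default 0.85).
#' @param seed Optional integer seed.
#' @return Object of class `decoder_result`: `accuracy_mean`, `accuracy_sd`,
#'   `accuracies`, `shuffled_accuracies`, `pc_dims_used`, `n_repeats`.
#' @export
fit_decoder <- function(pop, pseudo = NULL, split = 0.5, repeats = 10,
                        var_threshold = 0.85, seed = NULL) {
  stopifnot(inherits(pop, "population_matrix"))
  if (nlevels(pop$labels) < 2L) stop("need at least two conditions")
  if (min(table(pop$labels)) < 2L) stop("need at least two trials per condition")
  if (!is.null(seed)) set.seed(seed)
  X <- .pop_features(pop)
  y <- pop$labels
  res <- t(vapply(seq_len(repeats), function(i) {
    .linear_decoder_once(X, y, split, var_threshold = var_threshold)
  }, numeric(2)))
  if (is.null(pseudo)) {
    Xs <- X
  } else {
    stopifnot(inherits(pseudo, "population_matrix"))
    Xs <- .pop_features(pseudo)
  }
  sh <- vapply(seq_len(repeats), function(i) {
    ys <- factor(sample(as.character(y), nrow(Xs), replace = nrow(Xs) > length(y)),
                 levels = levels(y))
    r <- .linear_decoder_once(Xs, ys, split, var_threshold = var_threshold)
    r[1]
  }, numeric(1))
  acc <- res[, 1]
  structure(list(accuracy_mean = mean(acc, na.rm = TRUE),
                 accuracy_sd = stats::sd(acc),
                 accuracies = acc,
                 shuffled_accuracies = sh,
                 pc_dims_used = as.integer(stats::median(res[, 2])),
                 n_repeats = repeats),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result: accuracy %.3f +/- %.3f (%d PCs, %d repeats); shuffled %.3f>\n",
              x$accuracy_mean, x$accuracy_sd, x$pc_dims_used, x$n_repeats,
              mean(x$shuffled_accuracies, na.rm = TRUE)))
  invisible(x)
}

#' Pseudo population from random lick-onset placement
#'
#' Builds decoder pseudo data: for each repeat, pseudo lick onsets are drawn
#' uniformly over the entire span of each spike train, peri-event rates are
#' extracted as for real trials, and each repeat is normalized by its maximum
#' rate.
#'
#' @param trains List of [spike_train()] (one per unit).
#' @param n_trials Pseudo trials per repeat.
#' @param window Peri-event window (s), default `c(-0.1, 0.08)`.
#' @param bin,bandwidth Passed to [trial_rate_matrix()].
#' @param n_repeats Number of repeats (default 50).
#' @param labels Labels assigned cyclically to pseudo trials (for control
#'   decoding), default `c("a", "b")`.
#' @param seed Optional integer seed.
#' @return A [population_matrix()] with `n_trials * n_repeats` trials.
#' @export
pseudo_population <- function(trains, n_trials, window = c(-0.1, 0.08),
                              bin = 0.005, bandwidth = 0.005, n_repeats = 50,
                              labels = c("a", "b"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_units <- length(trains)
  centers <- seq(window[1] + bin / 2, window[2] - bin / 2 + 1e-12, by = bin)
  n_bin <- length(centers)
  out <- array(0, c(n_units, n_bin, n_trials * n_repeats))
  for (r in seq_len(n_repeats)) {
    block <- (r - 1L) * n_trials + seq_len(n_trials)
    for (u in seq_len(n_units)) {
      span <- trains[[u]]$span
      anchors <- stats::runif(n_trials, span[1] - window[1],
                              span[2] - window[2])
      m <- trial_rate_matrix(trains[[u]], anchors, window = window,
                             bin = bin, bandwidth = bandwidth)
      out[u, , block] <- t(m)
    }
    out[, , block] <- normalize_rate(out[, , block])
  }
  population_matrix(out, rep_len(labels, n_trials * n_repeats), bin = bin)
}

#' Time-resolved decoding with a Kolmogorov-Smirnov significance mask
#'
#' Slides a window over the time bins, fits the decoder ([fit_decoder()]) in
#' each window, and marks the windows whose real accuracy distribution (over
#' repeats) is higher than and significantly different from the shuffled one
#' by a two-sample Kolmogorov-Smirnov test at p < 0.05.
#'
#' @param pop A [population_matrix()].
#' @param window_bins Window length in bins.
#' @param step_bins Step between windows in bins (equal to `window_bins`
#'   gives contiguous non-overlapping windows).
#' @param repeats Decoder repeats per window (default 10).
#' @param seed Optional integer seed.
#' @return List with `start_bin`, `accuracy` (mean per window),
#'   `shuffled_accuracy`, `p_value`, `significant` (logical mask).
#' @export
decode_time_resolved <- function(pop, window_bins, step_bins = window_bins,
                                 repeats = 10, seed = NULL) {
  stopifnot(inherits(pop, "population_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n_bin <- dim(pop$values)[2]
  starts <- seq(1L, n_bin - window_bins + 1L, by = step_bins)
  acc <- shacc <- pval <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window_bins - 1L)
    sub <- population_matrix(pop$values[, idx, , drop = FALSE], pop$labels,
                             bin = pop$bin)
    dr <- fit_decoder(sub, repeats = repeats)
    acc[i] <- dr$accuracy_mean
    shacc[i] <- mean(dr$shuffled_accuracies, na.rm = TRUE)
    pval[i] <- tryCatch(
      suppressWarnings(stats::ks.test(dr$accuracies,
                                      dr$shuffled_accuracies)$p.value),
      error = function(e) 1)
  }
  list(start_bin = starts, accuracy = acc, shuffled_accuracy = shacc,
       p_value = pval,
       significant = pval < 0.05 & acc > shacc)
}

#' Mean Euclidean distance between PCA trajectories
#'
#' Embeds two condition trajectories (units x bins matrices over a common
#' unit set) in a shared PC basis fitted to their concatenation, and returns
#' the mean over time of the Euclidean distance between them computed over
#' all PC dimensions.  Because all components are retained, the distance
#' equals the brute-force distance in the original space.
#'
#' @param traj_a,traj_b Numeric matrices, units x bins, same dimensions.
#' @return Scalar mean distance.
#' @export
pca_trajectory_distance <- function(traj_a, traj_b) {
  if (!all(dim(traj_a) == dim(traj_b))) stop("trajectory bins/units mismatch")
  A <- t(traj_a)  # bins x units
  B <- t(traj_b)
  pc <- stats::prcomp(rbind(A, B), center = TRUE, scale. = FALSE)
  n <- nrow(A)
  ZA <- pc$x[seq_len(n), , drop = FALSE]
  ZB <- pc$x[n + seq_len(n), , drop = FALSE]
  mean(sqrt(rowSums((ZA - ZB)^2)))
}

# cross-correlogram of two binned spike trains at integer-lag resolution
.spike_ccg <- function(ta, tb, bin, max_lag_bins) {
  ia <- floor(ta / bin)
  ib <- floor(tb / bin)
  d <- as.vector(outer(ib, ia, "-"))
  d <- d[abs(d) <= max_lag_bins]
  tabulate(d + max_lag_bins + 1L, nbins = 2L * max_lag_bins + 1L)
}

#' Spiking-probability edge score between two spike trains
#'
#' A cross-correlogram-based score for a putative excitatory connection
#' a -> b.  The first `crop` seconds of both trains are binned at 1 ms, the
#' cross-correlogram over +/- `max_lag` is normalized by the number of
#' reference spikes (spiking probability of `b` conditioned on an `a` spike),
#' and multi-scale edge filters (peak minus surrounding flanks, widths 2-5 ms)
#' are summed; the score is the maximum of the summed filter response over
#' causal delays.  Positive scores indicate putative excitation a -> b.
#'
#' @param train_a,train_b [spike_train()] objects (reference and target).
#' @param crop Crop duration in seconds (default 3).
#' @param max_lag Correlogram half-window in seconds (default 0.05).
#' @param bin Correlogram bin in seconds (default 0.001).
#' @return Object of class `edge_estimate`: `score` (NA when not
#'   computable), `n_pairs`, `computable`, `percentile_used` (filled by
#'   [tspe_network_test()]), `significant`.
#' @export
tspe_score <- function(train_a, train_b, crop = 3, max_lag = 0.05,
                       bin = 0.001) {
  stopifnot(inherits(train_a, "spike_train"), inherits(train_b, "spike_train"))
  t0 <- max(train_a$span[1], train_b$span[1])
  ta <- train_a$times[train_a$times >= t0 & train_a$times < t0 + crop] - t0
  tb <- train_b$times[train_b$times >= t0 & train_b$times < t0 + crop] - t0
  out <- structure(list(score = NA_real_, n_pairs = 0L, computable = FALSE,
                        percentile_used = "none", significant = NA),
                   class = "edge_estimate")
  if (!length(ta) || !length(tb)) return(out)
  L <- as.integer(round(max_lag / bin))
  cc <- .spike_ccg(ta, tb, bin, L + 6L)  # pad for the filter flanks
  if (sum(cc) == 0L) return(out)
  ncc <- cc / length(ta)
  lag_of <- function(i) i - (L + 6L) - 1L  # index -> lag in bins
  score_at <- function(lag, w) {
    i <- lag + L + 7L
    peak <- mean(ncc[i:(i + w - 1L)])
    flank <- mean(c(ncc[(i - w):(i - 1L)], ncc[(i + w):(i + 2L * w - 1L)]))
    peak - flank
  }
  lags <- 1:(L - 10L)  # causal delays, keep room for the widest filter
  total <- rep(0, length(lags))
  for (w in 2:5) {
    total <- total + vapply(lags, score_at, numeric(1), w = w)
  }
  out$score <- max(total)
  out$n_pairs <- length(ta) * length(tb)
  out$computable <- TRUE
  out
}

#' @export
print.edge_estimate <- function(x, ...) {
  cat(sprintf("<edge_estimate: score = %s, computable = %s>\n",
              format(x$score, digits = 4), x$computable))
  invisible(x)
}

#' Null edge scores by inter-spike-interval shuffling
#'
#' Generates the pseudo score distribution for [tspe_network_test()]: the
#' target train's inter-spike intervals are permuted `n_shuffles` times and
#' the edge score is recomputed for each surrogate.
#'
#' @param train_a,train_b As in [tspe_score()].
#' @param n_shuffles Number of surrogates (default 200).
#' @param seed Optional integer seed.
#' @param ... Passed to [tspe_score()].
#' @return Numeric vector of null scores (NAs dropped).
#' @export
tspe_null_scores <- function(train_a, train_b, n_shuffles = 200, seed = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  tb <- train_b$times
  if (length(tb) < 3L) return(numeric(0))
  isi <- diff(tb)
  out <- vapply(seq_len(n_shuffles), function(i) {
    tt <- tb[1] + c(0, cumsum(sample(isi)))
    sb <- spike_train(sort(tt), span = train_b$span)
    tspe_score(train_a, sb, ...)$score
  }, numeric(1))
  out[is.finite(out)]
}

#' Percentile schedule test for network-level edge scores
#'
#' Compares the mean real edge score of a group of unit pairs with a
#' percentile of the pseudo (shuffled) score distribution.  The percentile
#' depends only on the number of real units `n`:
#' fewer than 10, the comparison is skipped; 10-14 uses the 80th percentile;
#' 15-19 the 90th; 20-31 the 95th; 32 or more the 99th.
#'
#' @param real_scores Numeric vector of real edge scores (one per unit pair).
#' @param pseudo_scores Numeric vector of shuffled scores.
#' @param n Number of real units behind the scores (default
#'   `length(real_scores)`).
#' @return List with `significant` (logical, `NA` when skipped),
#'   `percentile_used` (one of `"none"`, 80, 90, 95, 99), `threshold`,
#'   `skipped`.
#' @export
tspe_network_test <- function(real_scores, pseudo_scores,
                              n = length(real_scores)) {
  perc <- if (n < 10) NA_real_
          else if (n < 15) 80
          else if (n < 20) 90
          else if (n < 32) 95
          else 99
  if (is.na(perc)) {
    return(list(significant = NA, percentile_used = "none",
                threshold = NA_real_, skipped = TRUE))
  }
  thr <- stats::quantile(pseudo_scores, perc / 100, names = FALSE,
                         na.rm = TRUE)
  list(significant = mean(real_scores, na.rm = TRUE) > thr,
       percentile_used = perc, threshold = thr, skipped = FALSE)
}
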
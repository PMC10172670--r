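# ERP preprocessing: resampling, zero-phase band-pass, epoching/baseline,
# artifact rejection, bad-channel interpolation, average reference, averaging.

# apply f(channels x samples matrix) -> matrix to every trial / the ERP
.map_signal <- function(x, f) {
  if (inherits(x, "eeg_erp")) {
    x$data <- f(x$data)
    rownames(x$data) <- x$layout$channel_names
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    d <- x$data
    out <- NULL
    for (tr in seq_len(dim(d)[1])) {
      y <- f(matrix(d[tr, , ], dim(d)[2], dim(d)[3]))
      if (is.null(out)) out <- array(0, c(dim(d)[1], nrow(y), ncol(y)))
      out[tr, , ] <- y
    }
    x$data <- out
    return(x)
  }
  stop("expected an 'eeg_epochs' or 'eeg_erp'")
}

# FFT-domain resampling of one series (the scipy/MNE approach): truncate or
# zero-pad the spectrum, which is exact for band-limited content and applies
# ideal anti-aliasing when downsampling. Content at the retained Nyquist bin
# itself is not disambiguated; irrelevant for band-passed EEG far below it.
.fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  h <- floor(min(n, m) / 2)
  Y[seq_len(h + 1)] <- X[seq_len(h + 1)]
  if (h > 0) Y[(m - h + 1):m] <- X[(n - h + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample epochs or an ERP
#'
#' Frequency-domain resampling: the spectrum is truncated (downsampling, which
#' is ideal anti-aliasing) or zero-padded (upsampling), preserving all content
#' below the lower of the two Nyquist frequencies. The sample count is
#' rescaled by `target_rate / rate` and the time axis regenerated from the
#' epoch start.
#'
#' @param x An [eeg_epochs()] or [eeg_erp()].
#' @param target_rate New sampling rate (Hz), > 0.
#' @return Object of the same class at the new rate.
#' @export
resample <- function(x, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("'target_rate' must be a positive scalar")
  if (target_rate == x$rate) return(x)
  n_old <- length(x$times)
  m <- as.integer(round(n_old * target_rate / x$rate))
  out <- .map_signal(x, function(V) t(apply(V, 1, .fft_resample, m = m)))
  out$rate <- target_rate
  out$times <- x$times[1] + (seq_len(m) - 1L) * 1000 / target_rate
  out
}

#' Zero-phase band-pass filter
#'
#' Cascade of forward-backward (zero-phase) Butterworth filters: a 2nd-order
#' high-pass at `low` (skipped when `low = 0`) and a 4th-order low-pass at
#' `high`. Effective attenuation is the squared magnitude response, giving
#' < 5% passband loss at mid-band and >= 90% attenuation at twice the
#' high edge for the default 0.1-30 Hz band.
#'
#' @param x An [eeg_epochs()] or [eeg_erp()].
#' @param low,high Band edges in Hz; `0 <= low < high < rate / 2`.
#' @return Filtered object of the same class.
#' @export
bandpass <- function(x, low = 0.1, high = 30) {
  fn <- x$rate / 2
  if (!(low >= 0 && low < high && high < fn))
    stop("need 0 <= low < high < rate/2")
  lp <- signal::butter(4, high / fn, type = "low")
  hp <- if (low > 0) signal::butter(2, low / fn, type = "high") else NULL
  .map_signal(x, function(V) {
    t(apply(V, 1, function(ch) {
      y <- signal::filtfilt(lp, ch)
      if (!is.null(hp)) y <- signal::filtfilt(hp, y)
      y
    }))
  })
}

#' Crop trials to an epoch window and apply baseline correction
#'
#' The retained samples lie on the half-open grid `[window[1], window[2])`
#' relative to stimulus onset; the per-channel mean over `baseline_window`
#' (same convention) is subtracted from every trial.
#'
#' @param x An [eeg_epochs()] (already cut around events) or [eeg_erp()].
#' @param window Epoch limits in ms.
#' @param baseline_window Baseline limits in ms; must lie inside `window`.
#'   `NULL` skips baseline correction.
#' @return Cropped, baseline-corrected object of the same class.
#' @export
epoch_and_baseline <- function(x, window = c(-200, 1000),
                               baseline_window = c(-200, 0)) {
  step <- 1000 / x$rate
  keep <- x$times >= window[1] - step / 2 & x$times < window[2] - step / 2
  if (!any(keep)) stop("'window' lies outside the recorded epoch")
  if (!is.null(baseline_window)) {
    if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
      stop("'baseline_window' must lie inside 'window'")
  }
  tsel <- x$times[keep]
  bsel <- if (is.null(baseline_window)) logical(length(tsel)) else
    tsel >= baseline_window[1] - step / 2 & tsel < baseline_window[2] - step / 2
  out <- .map_signal(x, function(V) {
    V <- V[, keep, drop = FALSE]
    if (any(bsel)) V <- V - rowMeans(V[, bsel, drop = FALSE])
    V
  })
  out$times <- tsel
  out
}

#' Reject trials with large artifacts
#'
#' Removes trials whose maximum per-channel peak-to-peak amplitude exceeds
#' `peak_to_peak_limit` (microvolts).
#'
#' @param epochs An [eeg_epochs()].
#' @param peak_to_peak_limit Positive amplitude limit.
#' @return A list with `epochs` (retained trials) and `rejected_count`.
#' @export
reject_artifacts <- function(epochs, peak_to_peak_limit = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (peak_to_peak_limit <= 0) stop("'peak_to_peak_limit' must be positive")
  d <- epochs$data
  ptp <- apply(d, 1, function(tr) {
    m <- matrix(tr, dim(d)[2], dim(d)[3])
    max(apply(m, 1, function(ch) diff(range(ch))))
  })
  keep <- ptp <= peak_to_peak_limit
  if (!any(keep)) stop("all trials exceed the peak-to-peak limit")
  epochs$data <- d[keep, , , drop = FALSE]
  list(epochs = epochs, rejected_count = sum(!keep))
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its `k`
#' nearest good channels (Euclidean distance between unit-sphere positions).
#'
#' @param x An [eeg_epochs()] or [eeg_erp()].
#' @param bad Character vector of channel names to rebuild.
#' @param k Number of good neighbors to average.
#' @return Object of the same class with bad channels replaced.
#' @export
interpolate_bad_channels <- function(x, bad, k = 6L) {
  if (length(bad) == 0L) return(x)
  layout <- x$layout
  bi <- .chan_index(layout, bad)
  good <- setdiff(seq_len(layout$n_channels), bi)
  if (length(good) < 3L) stop("need at least 3 good channels")
  k <- min(k, length(good))
  W <- lapply(bi, function(b) {
    d <- sqrt(colSums((t(layout$positions[good, , drop = FALSE]) -
                         layout$positions[b, ])^2))
    nb <- good[order(d)][seq_len(k)]
    w <- 1 / pmax(sort(d)[seq_len(k)], 1e-12)
    list(nb = nb, w = w / sum(w))
  })
  .map_signal(x, function(V) {
    for (j in seq_along(bi))
      V[bi[j], ] <- crossprod(V[W[[j]]$nb, , drop = FALSE], W[[j]]$w)
    V
  })
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, the reference convention
#' required by the topography normalization used in microstate analysis. The
#' operation is idempotent.
#'
#' @param x An [eeg_epochs()] or [eeg_erp()].
#' @return Object of the same class with zero channel-mean at every sample.
#' @export
average_reference <- function(x) {
  .map_signal(x, function(V) sweep(V, 2, colMeans(V)))
}

#' Average trials into an ERP
#'
#' @param epochs An [eeg_epochs()] with at least one trial.
#' @return An [eeg_erp()]; `n_trials_averaged` records the trial count.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- epochs$data
  if (dim(d)[1] < 1L) stop("no trials to average")
  m <- apply(d, c(2, 3), mean)
  eeg_erp(m, rate = epochs$rate, times = epochs$times, layout = epochs$layout,
          subject_id = epochs$subject_id, condition = epochs$condition,
          n_trials_averaged = dim(d)[1])
}

#' Extract (difference) waveforms at midline electrodes
#'
#' Returns the named channels' series from an ERP; when a second ERP is given,
#' the difference `erp - erp2` (e.g. negative minus neutral cue) is extracted
#' instead.
#'
#' @param erp An [eeg_erp()].
#' @param erp2 Optional second [eeg_erp()] on the same grid to subtract.
#' @param electrodes Channel names to extract.
#' @param plot If `TRUE`, draw the series against time.
#' @return A data frame with `time_ms` and one column per electrode.
#' @export
midline_waveforms <- function(erp, erp2 = NULL,
                              electrodes = c("Fz", "FCz", "Cz", "CPz", "Pz"),
                              plot = FALSE) {
  stopifnot(inherits(erp, "eeg_erp"))
  i <- .chan_index(erp$layout, electrodes)
  V <- erp$data
  if (!is.null(erp2)) {
    stopifnot(inherits(erp2, "eeg_erp"), ncol(erp2$data) == ncol(V))
    V <- V - erp2$data
  }
  out <- data.frame(time_ms = erp$times, t(V[i, , drop = FALSE]))
  names(out) <- c("time_ms", electrodes)
  if (plot) {
    graphics::matplot(out$time_ms, as.matrix(out[, -1]), type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "amplitude (µV)")
    graphics::legend("topright", electrodes, col = seq_along(electrodes),
                     lty = 1, bty = "n")
    graphics::abline(v = 0, col = "grey")
  }
  out
}
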
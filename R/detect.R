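## Beta-burst detection and epoch alignment: Butterworth beta bandpass,
## Hilbert amplitude envelope, median + 1.75 SD thresholding, fixed-width
## re-epoching around envelope peaks, and an adaptive Woody filter.

#' Burst detection configuration
#'
#' @param band_hz beta band edges in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective order is doubled and the phase response is zero).
#' @param threshold_sd burst threshold in envelope standard deviations above
#'   the median envelope.
#' @param epoch_halfwidth_ms half width of the re-epoching window (ms).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(band_hz = c(13, 30), filter_order = 4,
                             threshold_sd = 1.75, epoch_halfwidth_ms = 100) {
  if (band_hz[1] >= band_hz[2]) stop("band low edge must be below high edge")
  if (threshold_sd <= 0) stop("threshold_sd must be positive")
  structure(list(band_hz = band_hz, filter_order = filter_order,
                 threshold_sd = threshold_sd,
                 epoch_halfwidth_ms = epoch_halfwidth_ms),
            class = "detection_config")
}

## analytic signal via the frequency-domain construction (one-sided spectrum)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Beta-band amplitude envelope
#'
#' Band-passes the series with a zero-phase Butterworth filter (forward and
#' backward via `signal::filtfilt`, so envelope peaks are not lag-shifted)
#' and returns the instantaneous amplitude of the analytic signal.
#'
#' @param ts numeric time series.
#' @param fs_hz sampling rate; must exceed twice the band's upper edge.
#' @param cfg a [detection_config()].
#' @return Non-negative envelope samples, same length as `ts`.
#' @export
beta_envelope <- function(ts, fs_hz, cfg = detection_config()) {
  if (fs_hz < 2 * cfg$band_hz[2])
    stop("sampling rate below twice the band's upper edge")
  bf <- signal::butter(cfg$filter_order, cfg$band_hz / (fs_hz / 2),
                       type = "pass")
  xf <- signal::filtfilt(bf, ts)
  Mod(analytic_signal(xf))
}

#' Detect high-amplitude bursts in an envelope
#'
#' Thresholds the envelope at `median + threshold_sd * SD` (both statistics
#' over the full record, so detection is invariant to positive rescaling);
#' every contiguous supra-threshold run becomes one event with its peak at
#' the envelope maximum.
#'
#' @param envelope non-negative envelope samples.
#' @param fs_hz sampling rate (Hz).
#' @param cfg a [detection_config()].
#' @return A data.frame of class `burst_events` with columns `onset_ms`,
#'   `peak_ms`, `offset_ms`, `duration_ms`, `peak_amplitude` and the sample
#'   indices `onset`, `peak`, `offset`.
#' @export
detect_bursts <- function(envelope, fs_hz, cfg = detection_config()) {
  if (any(envelope < 0)) stop("envelope must be non-negative")
  thr <- stats::median(envelope) + cfg$threshold_sd * stats::sd(envelope)
  above <- envelope > thr
  ev <- data.frame(onset = integer(0), peak = integer(0),
                   offset = integer(0), peak_amplitude = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values)
    ev <- do.call(rbind, lapply(ok, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      pk <- i0 + which.max(envelope[i0:i1]) - 1
      data.frame(onset = i0, peak = pk, offset = i1,
                 peak_amplitude = envelope[pk])
    }))
  }
  step <- 1000 / fs_hz
  ev$onset_ms <- (ev$onset - 1) * step
  ev$peak_ms <- (ev$peak - 1) * step
  ev$offset_ms <- (ev$offset - 1) * step
  ev$duration_ms <- ev$offset_ms - ev$onset_ms + step
  class(ev) <- c("burst_events", "data.frame")
  attr(ev, "threshold") <- thr
  ev
}

#' Re-epoch a record around burst peaks
#'
#' Cuts fixed-length windows of +/- `halfwidth_ms` around each event peak
#' (51 samples at 250 Hz and the default 100 ms). Events whose window would
#' cross a record edge are dropped; the count is recorded in the `dropped`
#' attribute.
#'
#' @param raw numeric vector, or channels x samples matrix.
#' @param events a `burst_events` table.
#' @param fs_hz sampling rate (Hz).
#' @param halfwidth_ms epoch half width (ms).
#' @return Events x samples matrix (vector input) or events x channels x
#'   samples array (matrix input), with attributes `dropped` (count) and
#'   `kept` (row indices of retained events).
#' @export
epoch_around_peaks <- function(raw, events, fs_hz = 250,
                               halfwidth_ms = 100) {
  k <- round(halfwidth_ms * fs_hz / 1000)
  nsamp <- if (is.matrix(raw)) ncol(raw) else length(raw)
  keep <- which(events$peak - k >= 1 & events$peak + k <= nsamp)
  idx <- lapply(events$peak[keep], function(p) (p - k):(p + k))
  out <- if (is.matrix(raw)) {
    arr <- array(0, c(length(keep), nrow(raw), 2 * k + 1))
    for (i in seq_along(idx)) arr[i, , ] <- raw[, idx[[i]]]
    arr
  } else {
    do.call(rbind, lapply(idx, function(ii) raw[ii]))
  }
  if (length(keep) == 0)
    out <- if (is.matrix(raw)) array(0, c(0, nrow(raw), 2 * k + 1))
           else matrix(0, 0, 2 * k + 1)
  attr(out, "dropped") <- nrow(events) - length(keep)
  attr(out, "kept") <- keep
  out
}

#' Woody filter configuration
#'
#' @param tolerance convergence tolerance: relative change in template RMS
#'   between iterations.
#' @param max_iterations iteration cap.
#' @param max_lag_ms bound on the per-epoch lag search (ms).
#' @return An object of class `woody_config`.
#' @export
woody_config <- function(tolerance = 0.1, max_iterations = 100,
                         max_lag_ms = 40) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 max_lag_ms = max_lag_ms), class = "woody_config")
}

## unbiased cross-correlation of x against template at integer lags
## r(l) = sum_i x[i + l] t[i] / (n - |l|)
xcorr_unbiased <- function(x, tmpl, max_lag) {
  n <- length(x)
  lags <- -max_lag:max_lag
  vapply(lags, function(l) {
    if (l >= 0) {
      i <- 1:(n - l)
      sum(x[i + l] * tmpl[i]) / (n - l)
    } else {
      i <- 1:(n + l)
      sum(x[i] * tmpl[i - l]) / (n + l)
    }
  }, numeric(1))
}

shift_epoch <- function(x, lag) {
  n <- length(x)
  out <- numeric(n)
  if (lag > 0) out[1:(n - lag)] <- x[(lag + 1):n]
  else if (lag < 0) out[(-lag + 1):n] <- x[1:(n + lag)]
  else out <- x
  out
}

#' Adaptive Woody-filter epoch alignment
#'
#' Iteratively aligns epochs to their evolving average template: on each
#' pass, every epoch is shifted by the lag maximizing its unbiased
#' cross-correlation with the current template, the template is recomputed,
#' and iteration stops when the relative change in template RMS falls below
#' the tolerance or the iteration cap is reached.
#'
#' When the continuous `record` and the original `peaks` are supplied,
#' shifting re-windows the epoch from the record (no data loss); otherwise
#' epochs are shifted with zero padding.
#'
#' @param epochs epochs x samples matrix.
#' @param cfg a [woody_config()].
#' @param fs_hz sampling rate (Hz).
#' @param record optional continuous record the epochs were cut from.
#' @param peaks optional sample indices of the original epoch centres in
#'   `record`.
#' @return A list with the aligned `epochs`, total integer `lags` (samples),
#'   the final `template`, `n_iterations` and a `converged` flag.
#' @export
woody_align <- function(epochs, cfg = woody_config(), fs_hz = 250,
                        record = NULL, peaks = NULL) {
  stopifnot(is.matrix(epochs), nrow(epochs) >= 1)
  ne <- nrow(epochs); ns <- ncol(epochs)
  max_lag <- min(round(cfg$max_lag_ms * fs_hz / 1000), ns - 1)
  lags <- integer(ne)
  if (ne == 1) {
    return(list(epochs = epochs, lags = lags,
                template = epochs[1, ], n_iterations = 1L,
                converged = TRUE))
  }
  rewindow <- !is.null(record) && !is.null(peaks)
  half <- (ns - 1) / 2
  cur <- epochs
  tmpl <- colMeans(cur)
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iterations) {
    it <- it + 1L
    for (e in seq_len(ne)) {
      r <- xcorr_unbiased(cur[e, ], tmpl, max_lag)
      l <- (-max_lag:max_lag)[which.max(r)]
      if (l != 0) {
        lags[e] <- lags[e] + l
        if (rewindow) {
          c0 <- peaks[e] + lags[e]
          if (c0 - half >= 1 && c0 + half <= length(record)) {
            cur[e, ] <- record[(c0 - half):(c0 + half)]
          } else {
            cur[e, ] <- shift_epoch(cur[e, ], l)
          }
        } else {
          cur[e, ] <- shift_epoch(cur[e, ], l)
        }
      }
    }
    ## Woody latencies are identifiable only up to a common offset; anchor
    ## the lag distribution at zero mean so the template cannot drift
    off <- as.integer(round(mean(lags)))
    if (off != 0) {
      lags <- lags - off
      for (e in seq_len(ne)) {
        if (rewindow) {
          c0 <- peaks[e] + lags[e]
          if (c0 - half >= 1 && c0 + half <= length(record)) {
            cur[e, ] <- record[(c0 - half):(c0 + half)]
            next
          }
        }
        cur[e, ] <- shift_epoch(cur[e, ], -off)
      }
    }
    new_tmpl <- colMeans(cur)
    denom <- sqrt(mean(tmpl^2))
    delta <- if (denom > 0) sqrt(mean((new_tmpl - tmpl)^2)) / denom
             else sqrt(mean(new_tmpl^2))
    tmpl <- new_tmpl
    if (delta < cfg$tolerance) { converged <- TRUE; break }
  }
  list(epochs = cur, lags = lags, template = tmpl,
       n_iterations = it, converged = converged)
}

#' Virtual-channel time series from sensor data
#'
#' Projects sensor data onto a unit-gain spatial filter built from a patch
#' gain vector (`w = g / (g'g)`, so a source of moment m nAm reads m on the
#' virtual channel). This supplies the source-level series that burst
#' detection operates on when the generating patch is known or has been
#' localized.
#'
#' @param x channels x samples matrix, epochs x channels x samples array,
#'   or `sensor_dataset`.
#' @param gain per-channel gain vector of the target patch.
#' @return Samples vector (matrix input) or epochs x samples matrix.
#' @export
virtual_channel <- function(x, gain) {
  w <- gain / sum(gain^2)
  if (inherits(x, "sensor_dataset")) x <- x$data
  if (is.matrix(x)) return(as.numeric(w %*% x))
  t(apply(x, 1, function(m) as.numeric(w %*% m)))
}
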
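## Assembly of synthetic sensor epochs: projection of layer dipole traces
## through patch gains, calibrated white/pink noise injection, and virtual
## subject generation.

new_sensor_dataset <- function(data, fs_hz, times_ms, sensors,
                               truth = NULL, snr_db = NA_real_) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times_ms))
  structure(list(data = data, fs_hz = fs_hz, times_ms = times_ms,
                 sensors = sensors, truth = truth, snr_db = snr_db),
            class = "sensor_dataset")
}

#' Project layer dipole traces to the sensors
#'
#' Builds noiseless sensor epochs: for every trial, the data are
#' `gain_deep x deep_trace + gain_superficial x superficial_trace`. The
#' gains are link-oriented patch gains (fT per nAm); current direction is
#' carried by the signed traces.
#'
#' @param deep,superficial `dipole_timeseries` on a common time grid with
#'   equal trial counts.
#' @param gains list with numeric vectors `deep` and `superficial` (one
#'   value per channel), e.g. from [patch_gain()] with
#'   `orientation = "link"`.
#' @param sensors the `sensor_array` the gains refer to.
#' @param fs_hz sampling rate (Hz).
#' @return A `sensor_dataset` (epochs x channels x samples, fT).
#' @export
project_to_sensors <- function(deep, superficial, gains, sensors,
                               fs_hz = 250) {
  if (!isTRUE(all.equal(deep$times_ms, superficial$times_ms)))
    stop("deep and superficial traces are on different time grids")
  if (deep$n_trials != superficial$n_trials)
    stop("deep and superficial traces have different trial counts")
  nt <- deep$n_trials
  nc <- length(gains$deep)
  ns <- length(deep$times_ms)
  data <- array(0, c(nt, nc, ns))
  for (e in seq_len(nt)) {
    data[e, , ] <- outer(gains$deep, deep$moment_nAm[e, ]) +
      outer(gains$superficial, superficial$moment_nAm[e, ])
  }
  new_sensor_dataset(data, fs_hz, deep$times_ms, sensors,
                     truth = list(deep = deep, superficial = superficial,
                                  gains = gains),
                     snr_db = Inf)
}

as_epoch_array <- function(x) {
  if (inherits(x, "sensor_dataset")) x$data
  else if (length(dim(x)) == 3) x
  else stop("expected a sensor_dataset or epochs x channels x samples array")
}

#' Amplitude signal-to-noise ratio in dB
#'
#' Per channel, 20 log10 of the ratio of signal RMS to noise RMS (over all
#' epochs and samples), then averaged over channels: the "amplitude SNR
#' averaged over all sensors". Channels with zero signal RMS are excluded
#' from the average; zero noise yields the `+Inf` sentinel.
#'
#' @param signal a `sensor_dataset` or epochs x channels x samples array.
#' @param noise an array of the same shape.
#' @param per_epoch if `TRUE`, return one SNR value per epoch instead of a
#'   single pooled value.
#' @return Scalar dB value, or a vector if `per_epoch = TRUE`.
#' @export
snr_db <- function(signal, noise, per_epoch = FALSE) {
  s <- as_epoch_array(signal)
  n <- as_epoch_array(noise)
  if (!all(dim(s) == dim(n))) stop("signal and noise shapes differ")
  one <- function(sm, nm) {
    rs <- sqrt(rowMeans(sm^2))   # channel RMS
    rn <- sqrt(rowMeans(nm^2))
    keep <- rs > 0
    if (!any(keep)) return(NaN)
    if (any(rn[keep] == 0)) return(Inf)
    mean(20 * log10(rs[keep] / rn[keep]))
  }
  if (per_epoch) {
    vapply(seq_len(dim(s)[1]),
           function(e) one(s[e, , , drop = TRUE], n[e, , , drop = TRUE]),
           numeric(1))
  } else {
    dm <- dim(s)
    one(matrix(aperm(s, c(2, 1, 3)), dm[2]),
        matrix(aperm(n, c(2, 1, 3)), dm[2]))
  }
}

#' Noise specification
#'
#' @param color `"white"` or `"pink"` (1/f amplitude spectrum per channel).
#' @param target_snr_db per-burst amplitude SNR target in dB.
#' @param seed optional RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(color = c("white", "pink"), target_snr_db = -20,
                       seed = NULL) {
  color <- match.arg(color)
  if (!is.finite(target_snr_db)) stop("target SNR must be finite")
  structure(list(color = color, target_snr_db = target_snr_db, seed = seed),
            class = "noise_spec")
}

#' Generate a colored noise series
#'
#' White noise, or pink noise shaped in the frequency domain to a 1/f power
#' spectrum (log-log power slope -1).
#'
#' @param n number of samples.
#' @param color `"white"` or `"pink"`.
#' @return Numeric vector with (asymptotically) unit variance.
#' @export
colored_noise <- function(n, color = c("white", "pink")) {
  color <- match.arg(color)
  x <- stats::rnorm(n)
  if (color == "white") return(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)          # two-sided frequency index
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Add calibrated sensor noise to a clean dataset
#'
#' Draws independent noise for every epoch and channel and scales it per
#' epoch so that the realized per-burst amplitude SNR equals the target
#' exactly (the scaling solves the SNR equation in closed form). The clean
#' signal and the injected noise are retained so that
#' `data - noise == clean` holds bit-for-bit.
#'
#' @param clean a noiseless `sensor_dataset`.
#' @param spec a [noise_spec()].
#' @return A `sensor_dataset` with noisy `data`, the `noise` array, and the
#'   realized `snr_db`.
#' @export
add_noise <- function(clean, spec = noise_spec()) {
  stopifnot(inherits(clean, "sensor_dataset"), inherits(spec, "noise_spec"))
  dm <- dim(clean$data)
  noise <- with_seed(spec$seed, {
    n <- array(stats::rnorm(prod(dm)), dm)
    if (spec$color == "pink") {
      for (e in seq_len(dm[1])) for (ch in seq_len(dm[2])) {
        n[e, ch, ] <- colored_noise_from(n[e, ch, ])
      }
    }
    n
  })
  raw_snr <- snr_db(clean$data, noise, per_epoch = TRUE)
  scale <- 10^((raw_snr - spec$target_snr_db) / 20)
  for (e in seq_len(dm[1])) noise[e, , ] <- noise[e, , ] * scale[e]
  out <- clean
  out$clean <- clean$data
  out$noise <- noise
  out$data <- clean$data + noise
  out$snr_db <- mean(snr_db(clean$data, noise, per_epoch = TRUE))
  out$noise_color <- spec$color
  out
}

## pink-shape an existing white series (keeps add_noise's single RNG draw)
colored_noise_from <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Average the epochs of a dataset
#'
#' @param ds a `sensor_dataset`.
#' @return A channels x samples matrix of the burst-averaged data.
#' @export
average_epochs <- function(ds) {
  apply(as_epoch_array(ds), c(2, 3), mean)
}

#' Simulate a cohort of virtual subjects
#'
#' For each subject, draws `n_bursts` burst epochs from the model, projects
#' them through the scene's patch gains, adds noise at the per-burst SNR
#' target, and stores the burst-averaged data alongside the epochs. Each
#' subject uses an independent seed derived from the master seed, so a
#' fixed master seed reproduces the cohort bit-for-bit.
#'
#' @param model a `burst_model_spec`.
#' @param scene a `burst_scene` from [make_scene()].
#' @param n_subjects number of virtual subjects.
#' @param n_bursts bursts per subject.
#' @param noise a [noise_spec()], or `NULL` for noiseless data.
#' @param seed master seed.
#' @return A list of `sensor_dataset`s, each with an `avg` matrix element.
#' @export
make_virtual_subjects <- function(model, scene, n_subjects = 10,
                                  n_bursts = 50, noise = noise_spec(),
                                  seed = NULL) {
  stopifnot(n_subjects >= 1, n_bursts >= 1)
  lapply(seq_len(n_subjects), function(s) {
    simulate_subject(model, scene, n_bursts, noise,
                     seed = if (is.null(seed)) NULL
                            else derive_seed(seed, "subject", s))
  })
}

#' Simulate one virtual subject
#'
#' @inheritParams make_virtual_subjects
#' @param seed subject seed.
#' @return A `sensor_dataset` with per-burst epochs, injected noise, and the
#'   burst average in `$avg`.
#' @export
simulate_subject <- function(model, scene, n_bursts = 50,
                             noise = noise_spec(), seed = NULL) {
  tr <- cumulative_dipole(model, n_trials = n_bursts,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, "dipole"),
                          times_ms = scene$times_ms)
  clean <- project_to_sensors(tr$deep, tr$superficial, scene$sim_gains,
                              scene$sensors, fs_hz = scene$fs_hz)
  ds <- if (!is.null(noise)) {
    ns <- noise
    ns$seed <- if (is.null(seed)) NULL else derive_seed(seed, "noise")
    add_noise(clean, ns)
  } else clean
  ds$truth$model <- model
  ds$avg <- average_epochs(ds)
  ds
}
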
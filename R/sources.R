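## Layer-specific current-dipole time courses: a phenomenological surrogate
## of the proximal/distal two-drive burst mechanism, the simplified Gaussian
## model, and the alternative-model battery.
##
## Sign convention: positive dipole moment points along the link vector,
## i.e. out of the cortex toward the pial surface. A proximal (deep) drive
## pushes current up and out of the cortex (+1); a distal (superficial)
## drive pushes current down into the cortex (-1).

#' Specification of one exogenous synaptic drive
#'
#' Describes the surrogate cumulative-dipole response to one layer-specific
#' synaptic drive: a smooth unimodal response window of fixed duration whose
#' centre time is jittered across trials. Defaults follow the two-drive
#' burst mechanism: a broad (~100 ms) weak proximal drive with 20 ms timing
#' jitter pushing current out of the cortex, and a faster (~50 ms) stronger
#' distal drive with 7 ms jitter pushing current into the cortex.
#'
#' @param kind `"proximal"` or `"distal"`.
#' @param timing_mean_ms mean of the trial-to-trial centre-time jitter (ms,
#'   0 = epoch centre).
#' @param timing_sd_ms standard deviation of the centre-time jitter (ms).
#' @param response_duration_ms duration of the response window (ms); the
#'   Gaussian response uses sigma = duration / 4.
#' @param peak_moment_nAm unsigned peak dipole moment (nAm).
#' @param polarity +1 (out of cortex, toward pial) or -1 (into cortex).
#' @param shape `"gaussian"` (default) or `"halfcosine"` response window.
#' @return An object of class `drive_spec`.
#' @export
drive_spec <- function(kind = c("proximal", "distal"),
                       timing_mean_ms = 0,
                       timing_sd_ms = NULL,
                       response_duration_ms = NULL,
                       peak_moment_nAm = NULL,
                       polarity = NULL,
                       shape = c("gaussian", "halfcosine")) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  defaults <- switch(kind,
    proximal = list(sd = 20, dur = 100, peak = 6, pol = 1),
    distal   = list(sd = 7,  dur = 50,  peak = 8, pol = -1))
  timing_sd_ms <- if (is.null(timing_sd_ms)) defaults$sd else timing_sd_ms
  response_duration_ms <- if (is.null(response_duration_ms)) defaults$dur
    else response_duration_ms
  peak_moment_nAm <- if (is.null(peak_moment_nAm)) defaults$peak
    else peak_moment_nAm
  polarity <- if (is.null(polarity)) defaults$pol else polarity
  if (response_duration_ms <= 0) stop("response duration must be positive")
  if (timing_sd_ms < 0) stop("timing jitter sd must be non-negative")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(kind = kind, timing_mean_ms = timing_mean_ms,
                 timing_sd_ms = timing_sd_ms,
                 response_duration_ms = response_duration_ms,
                 peak_moment_nAm = peak_moment_nAm,
                 polarity = polarity, shape = shape),
            class = "drive_spec")
}

new_dipole_timeseries <- function(times_ms, moment, layer) {
  moment <- rbind(moment)
  dimnames(moment) <- NULL
  stopifnot(ncol(moment) == length(times_ms))
  structure(list(times_ms = times_ms, moment_nAm = moment,
                 layer = layer, n_trials = nrow(moment)),
            class = "dipole_timeseries")
}

response_window <- function(times_ms, center_ms, duration_ms, shape) {
  if (shape == "gaussian") {
    s <- duration_ms / 4
    exp(-(times_ms - center_ms)^2 / (2 * s^2))
  } else {
    x <- (times_ms - center_ms) / duration_ms
    ifelse(abs(x) < 0.5, cos(pi * x), 0)
  }
}

#' Surrogate cumulative-dipole response to a layer-specific drive
#'
#' Generates per-trial dipole moment traces for one drive: a smooth unimodal
#' response of the specified duration, centred at a time drawn per trial
#' from Normal(timing_mean, timing_sd), scaled to the peak moment and signed
#' by the drive polarity. This is a phenomenological stand-in for the
#' network-level cumulative dipole: it reproduces the response duration,
#' polarity, relative strength and trial-timing statistics of the two-drive
#' mechanism without simulating the neurons.
#'
#' @param spec a [drive_spec()].
#' @param n_trials number of trials (>= 1).
#' @param seed optional RNG seed.
#' @param times_ms epoch time grid (ms).
#' @param layer layer label attached to the result.
#' @return A `dipole_timeseries` with an `n_trials` x `length(times_ms)`
#'   moment matrix in nAm.
#' @export
surrogate_drive_dipole <- function(spec, n_trials, seed = NULL,
                                   times_ms = default_times(),
                                   layer = NULL) {
  stopifnot(inherits(spec, "drive_spec"), n_trials >= 1)
  centers <- with_seed(seed,
    stats::rnorm(n_trials, spec$timing_mean_ms, spec$timing_sd_ms))
  m <- t(vapply(centers, function(cc) {
    spec$polarity * spec$peak_moment_nAm *
      response_window(times_ms, cc, spec$response_duration_ms, spec$shape)
  }, numeric(length(times_ms))))
  if (is.null(layer))
    layer <- if (spec$kind == "proximal") "deep" else "superficial"
  new_dipole_timeseries(times_ms, m, layer)
}

#' Simplified Gaussian dipole time course
#'
#' The deterministic single-Gaussian source model: a bump of the given width
#' centred at t = 0 on the epoch grid. By default `width_ms` is interpreted
#' as the Gaussian sigma; set `width_is = "fwhm"` for the alternative
#' reading.
#'
#' @param width_ms Gaussian width (ms).
#' @param peak_moment_nAm unsigned peak moment (nAm).
#' @param polarity +1 (out of cortex) or -1 (into cortex).
#' @param layer layer label.
#' @param times_ms epoch time grid (ms).
#' @param width_is `"sigma"` (default) or `"fwhm"`.
#' @return A single-trial `dipole_timeseries`.
#' @export
simplified_gaussian_dipole <- function(width_ms, peak_moment_nAm, polarity,
                                       layer = NULL,
                                       times_ms = default_times(),
                                       width_is = c("sigma", "fwhm")) {
  width_is <- match.arg(width_is)
  if (width_ms <= 0) stop("width must be positive")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  s <- if (width_is == "sigma") width_ms else fwhm_to_sigma(width_ms)
  tr <- polarity * peak_moment_nAm * exp(-times_ms^2 / (2 * s^2))
  new_dipole_timeseries(times_ms, tr, layer %||% "unspecified")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-layer burst model specification
#'
#' Bundles the deep (white-matter) and superficial (pial) source
#' descriptions into one model. Two source families are supported:
#' `"surrogate"` (jittered drive responses, trial-mean amplitudes scaled to
#' 8 nAm pial / 6 nAm white matter) and `"simplified"` (deterministic
#' Gaussians: pial width 10 ms / 6 nAm into the cortex; white matter width
#' 25 ms / 4.5 nAm out of the cortex).
#'
#' @param source `"surrogate"` or `"simplified"`.
#' @param variant model variant, see [build_model()].
#' @return An object of class `burst_model_spec`.
#' @export
burst_model <- function(source = c("surrogate", "simplified"),
                        variant = "canonical") {
  source <- match.arg(source)
  if (source == "surrogate") {
    base <- structure(list(
      source_kind = "surrogate",
      deep = drive_spec("proximal"),
      superficial = drive_spec("distal"),
      normalize = "mean",
      variant = "canonical"
    ), class = "burst_model_spec")
  } else {
    base <- structure(list(
      source_kind = "simplified",
      deep = list(width_ms = 25, peak_moment_nAm = 4.5, polarity = 1),
      superficial = list(width_ms = 10, peak_moment_nAm = 6, polarity = -1),
      normalize = "none",
      variant = "canonical"
    ), class = "burst_model_spec")
  }
  if (variant == "canonical") base else build_model(variant, base)
}

#' Derive an alternative-model variant from a base model
#'
#' Variants probe what the laminar comparison reports when the generating
#' model is altered:
#' * `reversed_waveforms` - swap the waveform parameters (duration/width,
#'   jitter, amplitude) between layers; each layer keeps its own current
#'   direction, so the superficial source becomes broad and weak, the deep
#'   source brief and strong, and the net sensor waveform is inverted.
#' * `reversed_polarities` - flip both current directions (dipoles point
#'   away from, rather than toward, each other).
#' * `deep_only` / `superficial_only` - silence one layer.
#' * `same_direction` - both currents directed into the cortex.
#'
#' @param variant variant name (see above; `"canonical"` returns the base).
#' @param base a `burst_model_spec`.
#' @return A `burst_model_spec` for the variant.
#' @export
build_model <- function(variant, base = burst_model("surrogate")) {
  stopifnot(inherits(base, "burst_model_spec"))
  out <- base
  ## swap the full source descriptions (waveform, jitter and its RNG
  ## stream) between layers, but keep each layer's own current direction
  swap_waveform <- function(m) {
    pd <- m$deep$polarity; ps <- m$superficial$polarity
    tmp <- m$deep; m$deep <- m$superficial; m$superficial <- tmp
    m$deep$polarity <- pd
    m$superficial$polarity <- ps
    m
  }
  out <- switch(variant,
    canonical = out,
    reversed_waveforms = swap_waveform(out),
    reversed_polarities = {
      out$deep$polarity <- -out$deep$polarity
      out$superficial$polarity <- -out$superficial$polarity
      out
    },
    deep_only = { out$superficial$peak_moment_nAm <- 0; out },
    superficial_only = { out$deep$peak_moment_nAm <- 0; out },
    same_direction = {
      out$deep$polarity <- out$superficial$polarity
      out
    },
    stop("unknown model variant: ", variant)
  )
  out$variant <- variant
  out
}

layer_trace <- function(model, layer, n_trials, seed, times_ms) {
  spec <- model[[layer]]
  lab <- if (layer == "deep") "deep" else "superficial"
  if (model$source_kind == "surrogate") {
    ts <- surrogate_drive_dipole(spec, n_trials, seed, times_ms, layer = lab)
    if (identical(model$normalize, "mean") && spec$peak_moment_nAm > 0) {
      mpk <- max(abs(colMeans(ts$moment_nAm)))
      if (mpk > 0)
        ts$moment_nAm <- ts$moment_nAm * (spec$peak_moment_nAm / mpk)
    }
    ts
  } else {
    one <- simplified_gaussian_dipole(
      max(spec$width_ms, .Machine$double.eps), spec$peak_moment_nAm,
      spec$polarity, layer = lab, times_ms = times_ms)
    new_dipole_timeseries(times_ms,
      matrix(one$moment_nAm, n_trials, length(times_ms), byrow = TRUE), lab)
  }
}

#' Per-layer and net cumulative dipole traces for a burst model
#'
#' Samples (or evaluates) the deep and superficial dipole time courses of a
#' model and their sum. For the canonical two-drive surrogate the net
#' trial-mean trace has the stereotyped wavelet shape: a dominant negative
#' peak near t = 0 flanked by positive tails.
#'
#' @param model a `burst_model_spec`.
#' @param n_trials number of trials/bursts.
#' @param seed optional RNG seed (layer streams are derived from it).
#' @param times_ms epoch time grid (ms).
#' @return A list with `dipole_timeseries` elements `deep`, `superficial`
#'   and `net`, plus the model spec.
#' @export
cumulative_dipole <- function(model, n_trials = 50, seed = NULL,
                              times_ms = default_times()) {
  stopifnot(inherits(model, "burst_model_spec"))
  ## seed streams follow the drive (not the layer), so variants that move a
  ## waveform between layers keep its trial-timing realization
  stage <- function(layer) {
    sp <- model[[layer]]
    if (!is.null(sp$kind)) sp$kind else layer
  }
  sd_seed <- if (is.null(seed)) NULL else derive_seed(seed, stage("deep"))
  ss_seed <- if (is.null(seed)) NULL
             else derive_seed(seed, stage("superficial"))
  deep <- layer_trace(model, "deep", n_trials, sd_seed, times_ms)
  sup <- layer_trace(model, "superficial", n_trials, ss_seed, times_ms)
  net <- new_dipole_timeseries(times_ms,
                               deep$moment_nAm + sup$moment_nAm, "net")
  list(deep = deep, superficial = sup, net = net, model = model)
}
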
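## Sliding-window laminar free-energy comparison: Hann-tapered 40 ms
## windows advanced in 4 ms steps over the averaged burst, with
## dF(t) = F_pial(t) - F_white(t), plus summary metrics over the burst
## tails and peak and fixed-effects pooling across subjects.

new_laminar_comparison <- function(window_centers_ms, dF,
                                   F_pial = NULL, F_white = NULL,
                                   threshold = 3, n_vertices = 1L,
                                   tail_window_ms = c(10, 40),
                                   peak_window_ms = c(-10, 10)) {
  m <- comparison_metrics(window_centers_ms, dF, tail_window_ms,
                          peak_window_ms)
  structure(c(list(window_centers_ms = window_centers_ms, dF = dF,
                   F_pial = F_pial, F_white = F_white,
                   significance_threshold = threshold,
                   n_vertices = n_vertices,
                   tail_window_ms = tail_window_ms,
                   peak_window_ms = peak_window_ms), m),
            class = "laminar_comparison")
}

#' Tail and peak summary metrics of a free-energy difference time series
#'
#' The burst tails are the windows centred in \[-40, -10\] and \[10, 40\] ms
#' and the burst peak is \[-10, 10\] ms. Reported are the minimum and
#' maximum of dF over each region; the canonical bilaminar pattern has
#' `tail_min < -3` (deep dominance in the tails) and `peak_max > +3`
#' (superficial dominance at the peak).
#'
#' @param centers_ms window-centre times (ms).
#' @param dF free-energy difference values.
#' @param tail_window_ms positive tail window; mirrored to negative times.
#' @param peak_window_ms peak window.
#' @return A list with `tail_min`, `tail_max`, `peak_min`, `peak_max`.
#' @export
comparison_metrics <- function(centers_ms, dF, tail_window_ms = c(10, 40),
                               peak_window_ms = c(-10, 10)) {
  tails <- (centers_ms >= tail_window_ms[1] &
              centers_ms <= tail_window_ms[2]) |
    (centers_ms >= -tail_window_ms[2] & centers_ms <= -tail_window_ms[1])
  peak <- centers_ms >= peak_window_ms[1] & centers_ms <= peak_window_ms[2]
  list(tail_min = if (any(tails)) min(dF[tails]) else NA_real_,
       tail_max = if (any(tails)) max(dF[tails]) else NA_real_,
       peak_min = if (any(peak)) min(dF[peak]) else NA_real_,
       peak_max = if (any(peak)) max(dF[peak]) else NA_real_)
}

## project data into a model's source-component eigenbasis and accumulate
## per-window tapered power
window_power <- function(Y, model, centers_idx, half, taper) {
  s <- sqrt(mean(Y^2))
  if (!is.finite(s) || s == 0) s <- 1
  Ys <- Y / s
  Z2 <- crossprod(model$U, Ys)^2
  cs <- colSums(Ys^2)
  T2 <- taper^2
  W <- vapply(centers_idx, function(cc) {
    as.numeric(Z2[, (cc - half):(cc + half), drop = FALSE] %*% T2)
  }, numeric(model$rank))
  tot <- vapply(centers_idx, function(cc) {
    sum(cs[(cc - half):(cc + half)] * T2)
  }, numeric(1))
  W <- matrix(W, nrow = model$rank)
  list(W = W, w0 = pmax(tot - colSums(W), 0), scale = s)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Sliding-window laminar free-energy comparison
#'
#' Advances a Hann-tapered window (default 40 ms, 4 ms steps) along the
#' averaged burst time course. In every window position the ReML free
#' energy is evaluated under the pial and the white-matter generative
#' model — both sharing the data, the noise component and the hyperpriors,
#' and differing only in gain and source prior — and the difference
#' `dF = F_pial - F_white` is recorded at the window centre. Windows that
#' would cross the epoch edge are dropped.
#'
#' @param avg channels x samples averaged burst data (or a
#'   `sensor_dataset`, whose `avg` element is used).
#' @param pial_model,white_model [generative_model()]s of the two surfaces.
#' @param times_ms sample times of `avg` (ms).
#' @param fs_hz sampling rate (Hz).
#' @param window_ms analysis window length (ms).
#' @param step_ms window step (ms).
#' @param taper `"hann"` or `"none"`.
#' @param max_iter,tol ReML iteration controls.
#' @return A `laminar_comparison` with the dF time series, per-model free
#'   energies and tail/peak summary metrics.
#' @export
sliding_laminar_compare <- function(avg, pial_model, white_model,
                                    times_ms = default_times(),
                                    fs_hz = 250, window_ms = 40,
                                    step_ms = 4,
                                    taper = c("hann", "none"),
                                    max_iter = 64, tol = 1e-3) {
  taper <- match.arg(taper)
  if (inherits(avg, "sensor_dataset")) avg <- avg$avg
  stopifnot(nrow(avg) == pial_model$n_channels,
            pial_model$n_channels == white_model$n_channels)
  ns <- ncol(avg)
  win_len <- round(window_ms * fs_hz / 1000) + 1
  half <- (win_len - 1) %/% 2
  step <- max(1, round(step_ms * fs_hz / 1000))
  centers <- seq(1 + half, ns - half, by = step)
  if (length(centers) == 0) stop("window longer than the epoch")
  tp <- if (taper == "hann") hann_window(win_len) else rep(1, win_len)

  Fs <- lapply(list(pial_model, white_model), function(mod) {
    wp <- window_power(avg, mod, centers, half, tp)
    m <- mod$n_channels - mod$rank
    fit <- reml2_fit(wp$W, wp$w0, mod$a, m, win_len, mod$n_channels,
                     max_iter = max_iter, tol = tol)
    fit$F - win_len * mod$n_channels * log(wp$scale)
  })
  new_laminar_comparison(times_ms[centers], Fs[[1]] - Fs[[2]],
                         F_pial = Fs[[1]], F_white = Fs[[2]])
}

#' Whole-window laminar model comparison
#'
#' Single free-energy comparison over the entire burst epoch (no taper),
#' as used for the net laminar-bias check before the sliding analysis.
#'
#' @inheritParams sliding_laminar_compare
#' @return A list with `dF`, `F_pial`, `F_white`.
#' @export
whole_window_compare <- function(avg, pial_model, white_model,
                                 max_iter = 64, tol = 1e-3) {
  if (inherits(avg, "sensor_dataset")) avg <- avg$avg
  ns <- ncol(avg)
  Fs <- vapply(list(pial_model, white_model), function(mod) {
    s <- sqrt(mean(avg^2)); if (!is.finite(s) || s == 0) s <- 1
    Ys <- avg / s
    Z <- crossprod(mod$U, Ys)
    w <- rowSums(Z^2)
    w0 <- max(sum(Ys^2) - sum(w), 0)
    fit <- reml2_fit(matrix(w), w0, mod$a, mod$n_channels - mod$rank,
                     ns, mod$n_channels, max_iter = max_iter, tol = tol)
    fit$F[1] - ns * mod$n_channels * log(s)
  }, numeric(1))
  list(dF = Fs[1] - Fs[2], F_pial = Fs[1], F_white = Fs[2])
}

#' Fixed-effects pooling of laminar comparisons across subjects
#'
#' Sums the free-energy difference time series pointwise over subjects
#' (log evidences add across independent datasets).
#'
#' @param per_subject list of `laminar_comparison` objects on identical
#'   window grids.
#' @return A `laminar_comparison` with the summed dF.
#' @export
fixed_effects_sum <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  ctr <- per_subject[[1]]$window_centers_ms
  for (s in per_subject) {
    if (!isTRUE(all.equal(s$window_centers_ms, ctr)))
      stop("window grids differ between subjects")
  }
  dF <- Reduce(`+`, lapply(per_subject, `[[`, "dF"))
  Fp <- Reduce(`+`, lapply(per_subject, `[[`, "F_pial"))
  Fw <- Reduce(`+`, lapply(per_subject, `[[`, "F_white"))
  new_laminar_comparison(ctr, dF, F_pial = Fp, F_white = Fw,
                         n_vertices = per_subject[[1]]$n_vertices)
}

#' Average laminar comparisons over vertices
#'
#' Vertex-level dF time series are averaged (unweighted), mirroring the
#' within-cluster averaging of the sliding-window comparison.
#'
#' @param per_vertex list of `laminar_comparison` objects.
#' @return A `laminar_comparison`.
#' @export
average_comparisons <- function(per_vertex) {
  stopifnot(length(per_vertex) >= 1)
  ctr <- per_vertex[[1]]$window_centers_ms
  n <- length(per_vertex)
  dF <- Reduce(`+`, lapply(per_vertex, `[[`, "dF")) / n
  Fp <- Reduce(`+`, lapply(per_vertex, `[[`, "F_pial")) / n
  Fw <- Reduce(`+`, lapply(per_vertex, `[[`, "F_white")) / n
  new_laminar_comparison(ctr, dF, F_pial = Fp, F_white = Fw,
                         n_vertices = n)
}

#' @export
print.laminar_comparison <- function(x, ...) {
  cat("Laminar free-energy comparison (dF = F_pial - F_white)\n")
  cat(sprintf("  windows: %d centres from %g to %g ms\n",
              length(x$window_centers_ms), min(x$window_centers_ms),
              max(x$window_centers_ms)))
  cat(sprintf("  tail_min = %.2f, peak_max = %.2f (threshold +/- %g)\n",
              x$tail_min, x$peak_max, x$significance_threshold))
  invisible(x)
}

#' @export
plot.laminar_comparison <- function(x, ...) {
  graphics::plot(x$window_centers_ms, x$dF, type = "l",
                 xlab = "window centre (ms)",
                 ylab = expression(Delta * F == F[pial] - F[white]), ...)
  graphics::abline(h = c(-x$significance_threshold,
                         x$significance_threshold), lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
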
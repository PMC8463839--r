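fs <- 250

test_that("beta envelope tracks in-band amplitude and rejects out-of-band tones", {
  t <- seq(0, 20, by = 1 / fs)[-1]
  env20 <- beta_envelope(3 * sin(2 * pi * 20 * t), fs)
  core <- seq(2 * fs, length(t) - 2 * fs)   # away from filter edges
  expect_true(all(abs(env20[core] - 3) < 0.06))
  env50 <- beta_envelope(3 * sin(2 * pi * 50 * t), fs)
  expect_lt(max(env50[core]), 0.1)
  expect_error(beta_envelope(rnorm(100), 50), "sampling rate")

  ## adding noise cannot lower the mean envelope (Monte-Carlo)
  set.seed(1)
  tone <- sin(2 * pi * 20 * t)
  m_noise <- mean(replicate(5, {
    mean(beta_envelope(tone + rnorm(length(t)), fs)[core])
  }))
  expect_gte(m_noise, mean(env20[core]) / 3)
})

test_that("burst detection finds planted events and only those", {
  t <- seq(0, 100, by = 1 / fs)[-1]
  set.seed(2)
  x <- 0.5 * rnorm(length(t))
  peaks_true <- seq(5, 95, by = 5)
  for (pt in peaks_true) {
    x <- x + 4 * exp(-(t - pt)^2 / (2 * 0.04^2)) * sin(2 * pi * 20 * (t - pt))
  }
  env <- beta_envelope(x, fs)
  ev <- detect_bursts(env, fs)
  ## recall >= 0.95 with at most 1 false positive per 100 s at SNR >= 0 dB
  hits <- sapply(peaks_true, function(p) any(abs(ev$peak_ms / 1000 - p) < 0.1))
  expect_gte(mean(hits), 0.95)
  expect_lte(nrow(ev) - sum(hits), 1)
  ## events are temporally ordered with onset <= peak <= offset
  expect_true(all(diff(ev$peak) > 0))
  expect_true(all(ev$onset <= ev$peak & ev$peak <= ev$offset))
  expect_true(all(ev$duration_ms > 0))

  ## scale invariance of the threshold rule
  ev2 <- detect_bursts(env * 7.3, fs)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$peak, ev$peak)

  ## constant envelope yields no events
  expect_equal(nrow(detect_bursts(rep(1, 1000), fs)), 0)
})

test_that("re-epoching cuts 51-sample windows and drops edge events", {
  x <- rnorm(5000)
  ev <- data.frame(peak = c(10, 300, 1200, 4990))
  ep <- epoch_around_peaks(x, ev, fs, halfwidth_ms = 100)
  expect_equal(ncol(ep), 51)
  expect_equal(nrow(ep), 2)                 # two interior peaks
  expect_equal(attr(ep, "dropped"), 2)
  expect_equal(ep[1, ], x[(300 - 25):(300 + 25)])

  ## matrix input gives epochs x channels x samples
  xm <- matrix(rnorm(3 * 5000), 3)
  epm <- epoch_around_peaks(xm, ev, fs)
  expect_equal(dim(epm), c(2, 3, 51))
})

test_that("woody alignment recovers planted lags and never degrades coherence", {
  tmpl <- exp(-seq(-100, 100, 4)^2 / (2 * 6^2))
  ## zero-mean integer delays: recovery is exact (latency is identifiable
  ## only up to a common offset, which the zero-mean anchor removes)
  delays <- c(0, 2, -3, 5, -1, -3)
  circ <- function(x, k) {
    n <- length(x)
    k <- ((k %% n) + n) %% n
    if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
  }
  eps <- t(sapply(delays, circ, x = tmpl))
  wa <- woody_align(eps, woody_config(tolerance = 1e-8))
  expect_identical(wa$lags, as.integer(delays))
  ## after alignment all epochs coincide with the template
  expect_lt(max(abs(sweep(wa$epochs, 2, wa$template))), 1e-9)

  ## identical epochs: zero lags after one iteration
  same <- matrix(rep(tmpl, 4), 4, byrow = TRUE)
  wi <- woody_align(same)
  expect_identical(wi$lags, integer(4))
  expect_equal(wi$n_iterations, 1L)

  ## single epoch: no-op
  w1 <- woody_align(matrix(tmpl, 1))
  expect_identical(w1$lags, 0L)

  ## alignment raises mean pairwise epoch correlation
  set.seed(5)
  noisy <- t(sapply(c(3, -2, 4, 0, -4, 1, 2, -1), function(l) {
    laminarbeta:::shift_epoch(tmpl, -l) + 0.05 * rnorm(length(tmpl))
  }))
  mean_cor <- function(m) mean(cor(t(m))[lower.tri(diag(nrow(m)))])
  aligned <- woody_align(noisy, woody_config(tolerance = 1e-4))
  expect_gt(mean_cor(aligned$epochs), mean_cor(noisy))
})

test_that("the virtual channel reads the source moment with unit gain", {
  scene <- small_scene()
  tr <- cumulative_dipole(burst_model("simplified", "deep_only"), 2)
  ds <- project_to_sensors(tr$deep, tr$superficial, scene$sim_gains,
                           scene$sensors)
  vc <- virtual_channel(ds, scene$sim_gains$deep)
  expect_equal(dim(vc), c(2, 51))
  expect_equal(vc[1, ], tr$deep$moment_nAm[1, ], tolerance = 1e-9)
})
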
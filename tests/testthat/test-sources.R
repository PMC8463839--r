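test_that("surrogate drive traces honour amplitude, determinism and jitter statistics", {
  spec0 <- drive_spec("distal", peak_moment_nAm = 0)
  z <- surrogate_drive_dipole(spec0, 5, seed = 1)
  expect_true(all(z$moment_nAm == 0))

  ## no jitter: every trial identical, mean equals a single trial
  spec <- drive_spec("distal", timing_sd_ms = 0)
  ts <- surrogate_drive_dipole(spec, 50, seed = 2)
  expect_equal(ts$moment_nAm[1, ], colMeans(ts$moment_nAm))
  expect_true(all(apply(ts$moment_nAm, 2, function(x) diff(range(x)) == 0)))

  ## distal jitter: SD of per-trial peak latencies ~ 7 ms at n = 500
  specj <- drive_spec("distal")
  tsj <- surrogate_drive_dipole(specj, 500, seed = 3)
  lat <- apply(abs(tsj$moment_nAm), 1, function(x) tsj$times_ms[which.max(x)])
  expect_equal(sd(lat), 7, tolerance = 1.5 / 7)

  ## linearity in peak moment
  s1 <- surrogate_drive_dipole(drive_spec("proximal"), 10, seed = 4)
  s3 <- surrogate_drive_dipole(
    drive_spec("proximal", peak_moment_nAm = 18), 10, seed = 4)
  expect_equal(s3$moment_nAm, 3 * s1$moment_nAm, tolerance = 1e-12)
})

test_that("simplified Gaussian pair evaluates to the printed amplitudes", {
  pial <- simplified_gaussian_dipole(10, 6, -1, layer = "superficial")
  white <- simplified_gaussian_dipole(25, 4.5, +1, layer = "deep")
  i0 <- which(pial$times_ms == 0)
  expect_equal(pial$moment_nAm[1, i0], -6)
  expect_equal(white$moment_nAm[1, i0], 4.5)
  expect_equal(pial$moment_nAm[1, i0] + white$moment_nAm[1, i0], -1.5)
  ## net of the canonical simplified model: negative peak, positive tails
  net <- cumulative_dipole(burst_model("simplified"), 1)$net
  i50 <- which(abs(net$times_ms) == 48)
  expect_lt(net$moment_nAm[1, i0], 0)
  expect_true(all(net$moment_nAm[1, i50] > 0))
})

test_that("model variants transform sources as named", {
  base <- burst_model("surrogate")
  ## involution: reversing polarities twice restores the canonical model
  twice <- build_model("reversed_polarities",
                       build_model("reversed_polarities", base))
  expect_equal(twice$deep$polarity, base$deep$polarity)
  expect_equal(twice$superficial$polarity, base$superficial$polarity)

  d_only <- cumulative_dipole(build_model("deep_only", base), 5, seed = 1)
  expect_true(all(d_only$superficial$moment_nAm == 0))
  expect_false(all(d_only$deep$moment_nAm == 0))

  ## reversed waveforms: the variant's deep trace carries the canonical
  ## superficial waveform; polarity stays with the layer, so the traces
  ## match up to the sign flip
  can <- cumulative_dipole(base, 20, seed = 7)
  rw <- cumulative_dipole(build_model("reversed_waveforms", base), 20,
                          seed = 7)
  expect_equal(rw$deep$moment_nAm, -can$superficial$moment_nAm,
               tolerance = 1e-12)
  expect_equal(rw$superficial$moment_nAm, -can$deep$moment_nAm,
               tolerance = 1e-12)

  ## reversed polarities: seed-matched net trace is the negated canonical
  rp <- cumulative_dipole(build_model("reversed_polarities", base), 20,
                          seed = 7)
  expect_equal(rp$net$moment_nAm, -can$net$moment_nAm, tolerance = 1e-12)

  sm <- build_model("same_direction", base)
  expect_equal(sm$deep$polarity, sm$superficial$polarity)
  expect_error(build_model("nonsense", base), "unknown")
})

test_that("canonical surrogate mean trace has the wavelet sign pattern and scaled amplitudes", {
  cd <- cumulative_dipole(burst_model("surrogate"), 50, seed = 11)
  ## trial-mean layer amplitudes are scaled to 8 (pial) and 6 (white) nAm
  expect_equal(max(abs(colMeans(cd$superficial$moment_nAm))), 8,
               tolerance = 1e-9)
  expect_equal(max(abs(colMeans(cd$deep$moment_nAm))), 6, tolerance = 1e-9)
  net <- colMeans(cd$net$moment_nAm)
  t <- cd$net$times_ms
  peak <- t >= -10 & t <= 10
  tails <- (t >= 24 & t <= 60) | (t <= -24 & t >= -60)
  expect_lt(min(net[peak]), 0)
  expect_gt(mean(net[tails]), 0)
  ## jitter widens the mean response: mean-trace FWHM >= single-trial FWHM
  fwhm <- function(x) {
    ax <- abs(x)
    sum(ax >= max(ax) / 2)
  }
  expect_gte(fwhm(colMeans(cd$superficial$moment_nAm)),
             fwhm(cd$superficial$moment_nAm[1, ]))
})
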
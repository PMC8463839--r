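test_that("sensor projection is exact, rank-revealing and grid-checked", {
  scene <- small_scene()
  ## zero traces -> zero data
  z <- new_ts <- cumulative_dipole(burst_model("simplified"), 3)
  z$deep$moment_nAm[] <- 0
  z$superficial$moment_nAm[] <- 0
  ds0 <- project_to_sensors(z$deep, z$superficial, scene$sim_gains,
                            scene$sensors)
  expect_true(all(ds0$data == 0))

  ## deep-only data are rank one across channels
  d <- cumulative_dipole(burst_model("simplified", "deep_only"), 1)
  ds <- project_to_sensors(d$deep, d$superficial, scene$sim_gains,
                           scene$sensors)
  sv <- svd(ds$data[1, , ])$d
  expect_lt(sv[2] / sv[1], 1e-9)

  ## canonical model: max-gain channel carries the wavelet (+,-,+) shape,
  ## with its global minimum (the central trough) at t = 0
  tr <- cumulative_dipole(burst_model("simplified"), 1)
  dsc <- project_to_sensors(tr$deep, tr$superficial, scene$sim_gains,
                            scene$sensors)
  ch <- which.max(abs(scene$sim_gains$superficial))
  w <- dsc$data[1, ch, ] * sign(scene$sim_gains$superficial[ch])
  expect_equal(which.min(w), which(dsc$times_ms == 0))
  expect_true(all(w[abs(dsc$times_ms) >= 40] > 0))

  ## mismatched grids are rejected
  short <- cumulative_dipole(burst_model("simplified"), 1,
                             times_ms = seq(-80, 80, 4))
  expect_error(project_to_sensors(short$deep, tr$superficial,
                                  scene$sim_gains, scene$sensors),
               "grid")
})

test_that("amplitude SNR follows its defining identities", {
  set.seed(1)
  s <- array(rnorm(4 * 10 * 51), c(4, 10, 51))
  expect_equal(snr_db(s, s), 0)
  expect_equal(snr_db(s, s * 10), -20)
  n <- array(rnorm(4 * 10 * 51), c(4, 10, 51))
  base <- snr_db(s, n)
  expect_equal(snr_db(s, n * sqrt(10)), base - 10, tolerance = 1e-9)
  expect_equal(snr_db(s, n * 0), Inf)
})

test_that("noise injection hits the target SNR and preserves the clean signal", {
  scene <- small_scene()
  tr <- cumulative_dipole(burst_model("surrogate"), 8, seed = 3)
  clean <- project_to_sensors(tr$deep, tr$superficial, scene$sim_gains,
                              scene$sensors)
  for (target in c(-40, -20, 0, 60)) {
    nd <- add_noise(clean, noise_spec("white", target, seed = 5))
    expect_equal(nd$snr_db, target, tolerance = 0.1)
    expect_true(max(abs(nd$data - nd$noise - nd$clean)) < 1e-10)
  }
  pk <- add_noise(clean, noise_spec("pink", -20, seed = 5))
  expect_equal(pk$snr_db, -20, tolerance = 0.1)
})

test_that("pink noise has a 1/f power spectrum", {
  pn <- with_seed(3, colored_noise(2^14, "pink"))
  sp <- spec.pgram(ts(pn, frequency = 250), plot = FALSE, taper = 0)
  sel <- sp$freq > 2 & sp$freq < 100
  slope <- coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
})

test_that("virtual subjects are reproducible and obey the averaging law", {
  scene <- small_scene()
  model <- burst_model("simplified")
  a <- make_virtual_subjects(model, scene, 2, 5, noise_spec("white", -20),
                             seed = 9)
  b <- make_virtual_subjects(model, scene, 2, 5, noise_spec("white", -20),
                             seed = 9)
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$avg, b[[2]]$avg)
  ## subjects differ from each other
  expect_false(identical(a[[1]]$data, a[[2]]$data))

  ## averaging n_bursts bursts raises amplitude SNR by ~ 10*log10(n)
  n_bursts <- 50
  ds <- simulate_subject(model, scene, n_bursts, noise_spec("white", -20),
                         seed = 4)
  clean_avg <- apply(ds$clean, c(2, 3), mean)
  noise_avg <- apply(ds$noise, c(2, 3), mean)
  gain <- snr_db(array(clean_avg, c(1, dim(clean_avg))),
                 array(noise_avg, c(1, dim(noise_avg)))) - (-20)
  expect_equal(gain, 10 * log10(n_bursts), tolerance = 2)

  ## one burst, no noise: the average is the single projected burst
  one <- simulate_subject(model, scene, 1, NULL, seed = 2)
  expect_equal(one$avg, one$data[1, , ])
})
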
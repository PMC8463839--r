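## Reduced-size experiment runs: the full-scale study conditions are
## exercised in the acceptance suite; here the mechanics are checked on a
## small helmet and patch.

## large enough that genuine laminar effects clear the +/-3 evidence
## threshold, small enough to keep the suite fast
scene <- small_scene(n_channels = 160, n_vertices = 20)

test_that("the canonical validation run recovers the bilaminar pattern", {
  val <- run_validation(scene, n_subjects = 3, n_bursts = 30,
                        snr_db = -20, seed = 21)
  expect_length(val$per_subject, 3)
  expect_true(val$detected)
  expect_gt(val$peak_max, 3)
  expect_lt(val$tail_min, -3)
  ## reproducibility under the master seed
  val2 <- run_validation(scene, n_subjects = 3, n_bursts = 30,
                         snr_db = -20, seed = 21)
  expect_identical(val$fixed_effects$dF, val2$fixed_effects$dF)
})

test_that("noiseless validation gives the same verdict with larger |dF|", {
  noisy <- run_validation(scene, n_subjects = 1, n_bursts = 10,
                          snr_db = -20, seed = 22, use_localizer = FALSE)
  clean <- run_validation(scene, n_subjects = 1, n_bursts = 10,
                          snr_db = NA, seed = 22, use_localizer = FALSE)
  expect_true(clean$detected)
  expect_gt(clean$peak_max, noisy$peak_max)
  expect_lt(clean$tail_min, noisy$tail_min)
})

test_that("SNR sweep output is well-formed with detectability rising in SNR", {
  sw <- run_snr_sweep(scene, levels_db = c(-50, -30, -20), reps = 3,
                      n_bursts = 30, seed = 23)
  expect_equal(nrow(sw$table), 9)
  expect_equal(sw$summary$level, c(-50, -30, -20))
  expect_false(sw$summary$detected[1])
  expect_true(sw$summary$detected[3])
  expect_true(sw$threshold_db %in% c(-30, -20))
  ## detected fraction monotone over this coarse grid
  expect_true(all(diff(sw$summary$detected_fraction) >= 0))
})

test_that("coreg sweep perturbs only the inversion and stays detected at zero error", {
  sw <- run_coreg_sweep(scene, levels = c(0, 1), reps = 3, n_bursts = 30,
                        seed = 24)
  expect_true(sw$summary$detected[sw$summary$level == 0])
  expect_true(all(c("level", "rep", "tail_min", "peak_max", "detected")
                  %in% names(sw$table)))
})

test_that("the model battery classifies canonical, inverted and single-layer signatures", {
  bat <- run_model_battery(scene, variants = c("canonical",
                                               "reversed_waveforms",
                                               "deep_only",
                                               "superficial_only"),
                           snr_db = -10, n_bursts = 50, seed = 25)
  sig <- setNames(bat$results$signature, bat$results$variant)
  expect_equal(sig[["canonical"]], "canonical")
  expect_equal(sig[["reversed_waveforms"]], "inverted")
  ## single-layer variants: single-signed dF wherever significant
  d <- bat$comparisons$deep_only
  expect_true(all(d$dF[abs(d$dF) > 3] < 0))
  s <- bat$comparisons$superficial_only
  expect_true(all(s$dF[abs(s$dF) > 3] > 0))
})

test_that("reversed polarities negate the sensor data but not the laminar verdict", {
  ## the laminar free energies depend on the data only through its
  ## covariance, so globally negated data yield an identical comparison
  can <- cumulative_dipole(burst_model("surrogate"), 10, seed = 26)
  rev <- cumulative_dipole(burst_model("surrogate", "reversed_polarities"),
                           10, seed = 26)
  dc <- project_to_sensors(can$deep, can$superficial, scene$sim_gains,
                           scene$sensors)
  dr <- project_to_sensors(rev$deep, rev$superficial, scene$sim_gains,
                           scene$sensors)
  expect_equal(dr$data, -dc$data, tolerance = 1e-12)
  mods <- laminar_models_at(scene, 1)
  c1 <- sliding_laminar_compare(average_epochs(dc), mods$pial, mods$white)
  c2 <- sliding_laminar_compare(average_epochs(dr), mods$pial, mods$white)
  expect_equal(c2$dF, c1$dF, tolerance = 1e-6)
})

test_that("spatial and temporal controls flatten the dF time course", {
  ctl <- run_controls(scene, n_bursts = 30, snr_db = -20, seed = 27)
  expect_gte(ctl$spatial_flat_fraction, 0.95)
  expect_lt(ctl$temporal$peak_max, 3)
  ## the reference (unshuffled, true vertex) keeps the canonical verdict
  expect_gt(ctl$reference$peak_max, 3)
  expect_lt(ctl$reference$tail_min, -3)
})
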
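test_that("coherence components are PSD with the prior vertex dominant", {
  pair <- make_column_patch(c(30, -20, 55), n_vertices = 12)
  Q <- patch_coherence_component(pair, 1, fwhm_mm = 5)
  expect_true(all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_equal(Q[1, 1], max(diag(Q)))
  ## fwhm -> 0 limit: single-entry indicator at the prior vertex
  Q0 <- patch_coherence_component(pair, 3, fwhm_mm = 1e-4)
  E <- matrix(0, 12, 12); E[3, 3] <- 1
  expect_equal(Q0, E, tolerance = 1e-10)
})

test_that("ReML free energy matches the dense Gaussian oracle and rises monotonically", {
  scene <- small_scene(n_channels = 20, n_vertices = 8)
  mod <- generative_model(scene$gain_pial, scene$pair, "superficial")
  h <- c(2.5, 0.7)
  C <- model_covariance(mod, h)
  set.seed(2)
  Y <- matrix(rnorm(20 * 11), 20, 11)
  ## fixed hyperparameters: F is exactly the log marginal likelihood
  res <- reml_free_energy(Y, mod, fix_h = h)
  expect_equal(res$F, dense_gaussian_logev(Y, C), tolerance = 1e-8)

  ## estimated hyperparameters: monotone objective, recovery within 20%
  hs <- replicate(50, {
    Yt <- t(chol(C)) %*% matrix(rnorm(20 * 60), 20, 60)
    r <- reml_free_energy(Yt, mod)
    expect_true(all(diff(r$F_trace) > -1e-6))
    r$h
  })
  expect_equal(unname(apply(hs, 1, median)), h, tolerance = 0.2)

  ## identical models agree to numerical precision
  r1 <- reml_free_energy(Y, mod)
  r2 <- reml_free_energy(Y, mod)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})

test_that("a free-energy difference of 3 is an evidence ratio of about 20", {
  expect_equal(exp(3), 20.09, tolerance = 1e-3)
  ## and dF between fixed-h models equals the dense log evidence ratio
  scene <- small_scene(n_channels = 15, n_vertices = 6)
  mp <- generative_model(scene$gain_pial, scene$pair, "superficial")
  mw <- generative_model(scene$gain_white, scene$pair, "deep")
  set.seed(3)
  Y <- matrix(rnorm(15 * 11), 15, 11)
  h <- c(1, 0.5)
  dF <- reml_free_energy(Y, mp, fix_h = h)$F -
    reml_free_energy(Y, mw, fix_h = h)$F
  oracle <- dense_gaussian_logev(Y, model_covariance(mp, h)) -
    dense_gaussian_logev(Y, model_covariance(mw, h))
  expect_equal(dF, oracle, tolerance = 1e-8)
  expect_equal(exp(dF), exp(oracle), tolerance = 1e-6)
})

test_that("EBB priors localize active sources and scale quadratically", {
  scene <- small_scene(n_channels = 40, n_vertices = 12)
  ## single active vertex at high SNR: argmax at the true vertex
  v <- 5
  tr <- 6 * exp(-seq(-100, 100, 4)^2 / (2 * 10^2))
  clean <- outer(scene$gain_pial[, v], tr)
  set.seed(4)
  Y <- clean + 0.01 * sd(clean) * matrix(rnorm(length(clean)), nrow(clean))
  pv <- ebb_prior(Y, scene$gain_pial)
  expect_equal(which.max(pv), v)
  ## homogeneity: scaling the data scales the prior variances by c^2
  expect_equal(ebb_prior(3 * Y, scene$gain_pial), 9 * pv,
               tolerance = 1e-9)
  ## pure noise: prior roughly flat over the patch
  flat <- sapply(1:5, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(40 * 51), 40)
    p <- ebb_prior(Z, scene$gain_pial)
    max(p) / min(p)
  })
  expect_lt(median(flat), 3)
})

test_that("the localizer recovers the simulated vertex and honours mask and threshold", {
  scene <- small_scene(n_channels = 40, n_vertices = 12)
  ds <- simulate_subject(burst_model("simplified"), scene, 20,
                         noise_spec("white", 0), seed = 6)
  loc <- localize(ds$avg, scene$gain_pial, scene$pair)
  expect_equal(loc$peak_vertex, scene$pair$center_index)
  expect_true(scene$pair$center_index %in% loc$cluster)
  ## threshold 1 restricts the cluster to the argmax
  loc1 <- localize(ds$avg, scene$gain_pial, scene$pair, threshold = 1)
  expect_equal(loc1$cluster, loc1$peak_vertex)
  ## empty mask errors
  expect_error(localize(ds$avg, scene$gain_pial, scene$pair, mask_mm = -1),
               "mask")
})

test_that("sliding comparison is antisymmetric with exact zero for identical models", {
  scene <- small_scene(n_channels = 25, n_vertices = 8)
  mods <- laminar_models_at(scene, 1)
  set.seed(7)
  Y <- matrix(rnorm(25 * 51), 25, 51)
  same <- sliding_laminar_compare(Y, mods$pial, mods$pial)
  expect_true(all(same$dF == 0))
  ab <- sliding_laminar_compare(Y, mods$pial, mods$white)
  ba <- sliding_laminar_compare(Y, mods$white, mods$pial)
  expect_identical(ab$dF, -ba$dF)
  ## window bookkeeping: 41 centres, -80..80 ms at 40 ms / 4 ms
  expect_equal(length(ab$window_centers_ms), 41)
  expect_equal(range(ab$window_centers_ms), c(-80, 80))
})

test_that("whole-window comparison separates single-layer simulations", {
  scene <- small_scene()
  mods <- laminar_models_at(scene, 1)
  deep_ds <- simulate_subject(burst_model("simplified", "deep_only"),
                              scene, 30, noise_spec("white", -10), seed = 8)
  sup_ds <- simulate_subject(burst_model("simplified", "superficial_only"),
                             scene, 30, noise_spec("white", -10), seed = 8)
  expect_lt(whole_window_compare(deep_ds$avg, mods$pial, mods$white)$dF, -3)
  expect_gt(whole_window_compare(sup_ds$avg, mods$pial, mods$white)$dF, 3)
  expect_equal(whole_window_compare(deep_ds$avg, mods$pial, mods$pial)$dF, 0)
})

test_that("fixed-effects pooling is the pointwise sum", {
  scene <- small_scene(n_channels = 20, n_vertices = 6)
  mods <- laminar_models_at(scene, 1)
  set.seed(9)
  Y <- matrix(rnorm(20 * 51), 20, 51)
  one <- sliding_laminar_compare(Y, mods$pial, mods$white)
  expect_equal(fixed_effects_sum(list(one))$dF, one$dF)
  flip <- one; flip$dF <- -one$dF
  flip$F_pial <- one$F_white; flip$F_white <- one$F_pial
  expect_true(all(abs(fixed_effects_sum(list(one, flip))$dF) < 1e-12))
  expect_equal(fixed_effects_sum(list(one, one, one))$dF, 3 * one$dF)
  short <- one; short$window_centers_ms <- one$window_centers_ms + 4
  expect_error(fixed_effects_sum(list(one, short)), "grids")
})
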
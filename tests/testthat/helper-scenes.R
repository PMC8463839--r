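## Shared small geometries so tests stay fast: a reduced helmet and patch
## are enough for every numerical property; full-size scenes are exercised
## in the acceptance tests.

small_scene <- function(n_channels = 40, n_vertices = 12, ...) {
  make_scene(n_channels = n_channels, n_vertices = n_vertices, ...)
}

## dense multivariate-normal log marginal likelihood, the independent
## oracle for the ReML free energy with fixed hyperparameters
dense_gaussian_logev <- function(Y, C) {
  Ci <- solve(C)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  n <- nrow(Y)
  sum(apply(Y, 2, function(y) {
    -0.5 * (as.numeric(t(y) %*% Ci %*% y) + ld + n * log(2 * pi))
  }))
}

model_covariance <- function(model, h) {
  A <- model$U %*% (model$a * t(model$U))
  h[1] * diag(model$n_channels) + h[2] * A
}
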
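## Empirical-Bayes source inversion: ReML covariance-component estimation
## with a variational free-energy objective, an empirical Bayesian
## beamformer (EBB) localizer, and the sliding-window pial-vs-white free
## energy comparison.
##
## Every laminar generative model has two covariance components in sensor
## space: sensor noise (identity on channels) and one source patch prior
## (gain-projected spatial coherence component around the prior vertex),
##     C = h0 * I + h1 * L Q L'.
## Because L Q L' has rank at most n_vertices << n_channels, the model is
## diagonalized once (eigenvectors U, eigenvalues a) and every ReML
## iteration costs O(rank) per analysis window.

#' Spatial coherence source covariance component
#'
#' Positive semidefinite source covariance with Gaussian falloff of both
#' variance and correlation around the prior vertex:
#' `Q_ij = sqrt(w_i w_j) K_ij` with `w` the Gaussian variance profile
#' centred on the prior vertex and `K` the Gaussian correlation kernel,
#' both with the same FWHM. As FWHM -> 0 the component tends to a
#' single-entry indicator at the prior vertex.
#'
#' @param pair a `cortical_patch_pair`.
#' @param prior_vertex index of the prior vertex.
#' @param fwhm_mm kernel FWHM (mm, default 5).
#' @return An n_vertices x n_vertices PSD matrix with unit diagonal at the
#'   prior vertex.
#' @export
patch_coherence_component <- function(pair, prior_vertex = pair$center_index,
                                      fwhm_mm = 5) {
  pos <- pair$pial_positions
  n <- nrow(pos)
  stopifnot(prior_vertex >= 1, prior_vertex <= n)
  s <- fwhm_to_sigma(fwhm_mm)
  d2 <- as.matrix(stats::dist(pos))^2
  K <- exp(-d2 / (2 * s^2))
  w <- exp(-d2[prior_vertex, ] / (2 * s^2))
  sw <- sqrt(w)
  Q <- outer(sw, sw) * K
  dimnames(Q) <- NULL
  Q
}

#' Laminar generative model
#'
#' Bundles one surface's per-vertex gain matrix with the two covariance
#' components (identity sensor noise and the gain-projected coherence prior
#' at the prior vertex) and precomputes the low-rank diagonalization of the
#' source component used by [reml_free_energy()].
#'
#' @param gain n_channels x n_vertices lead-field matrix of the surface
#'   (from [gain_matrix()]).
#' @param pair the `cortical_patch_pair` the gain refers to.
#' @param layer `"superficial"` or `"deep"` (metadata).
#' @param prior_vertex prior vertex index.
#' @param fwhm_mm coherence prior FWHM (mm).
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(gain, pair, layer = "superficial",
                             prior_vertex = pair$center_index,
                             fwhm_mm = 5) {
  Q <- patch_coherence_component(pair, prior_vertex, fwhm_mm)
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  R <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
  B <- gain %*% R
  sv <- svd(B, nv = 0)
  keep2 <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep2, drop = FALSE]
  a <- sv$d[keep2]^2
  n_c <- nrow(gain)
  ## normalize the source component to trace n_channels (a pure
  ## reparameterization of its hyperparameter, applied to every model)
  a <- a * (n_c / sum(a))
  structure(list(gain = gain, Q = Q, U = U, a = a,
                 n_channels = n_c, rank = length(a),
                 layer = layer, prior_vertex = prior_vertex,
                 fwhm_mm = fwhm_mm, pair = pair),
            class = "generative_model")
}

## Vectorized two-component ReML (Fisher scoring on log-hyperparameters
## with backtracking so the objective never decreases).
##
## W: rank x n_windows projected data power; w0: complement power; a:
## source-component eigenvalues; m: complement dimension; N: samples per
## window; n_c: channels. Hyperpriors: lambda ~ N(pm, pv) i.i.d.
reml2_fit <- function(W, w0, a, m, N, n_c, pm = 0, pv = 256,
                      max_iter = 64, tol = 1e-3, trace = FALSE) {
  W <- cbind(W)
  nw <- ncol(W)
  r <- length(a)
  log2pi <- log(2 * pi)

  obj <- function(l0, l1) {
    h0 <- exp(l0); h1 <- exp(l1)
    d <- a %o% h1 + matrix(h0, r, nw, byrow = TRUE)
    L <- -0.5 * (N * (m * log(h0) + colSums(log(d))) +
                   w0 / h0 + colSums(W / d) + N * n_c * log2pi)
    L - ((l0 - pm)^2 + (l1 - pm)^2) / (2 * pv)
  }

  ## initialization: split the average per-channel power between components
  p_hat <- pmax((w0 + colSums(W)) / (N * n_c), .Machine$double.eps)
  l0 <- log(p_hat / 2)
  l1 <- log(p_hat / 2)
  Fcur <- obj(l0, l1)
  Ftr <- if (trace) list(Fcur) else NULL
  conv <- rep(FALSE, nw)
  it <- 0L
  while (it < max_iter && !all(conv)) {
    it <- it + 1L
    h0 <- exp(l0); h1 <- exp(l1)
    d <- a %o% h1 + matrix(h0, r, nw, byrow = TRUE)
    iv1 <- 1 / d; iv2 <- iv1 * iv1
    g0 <- -0.5 * (N * (m / h0 + colSums(iv1)) -
                    (w0 / h0^2 + colSums(W * iv2))) * h0 - (l0 - pm) / pv
    g1 <- -0.5 * (N * colSums(a * iv1) -
                    colSums(W * (a * iv2))) * h1 - (l1 - pm) / pv
    I00 <- 0.5 * N * (m / h0^2 + colSums(iv2)) * h0^2 + 1 / pv
    I11 <- 0.5 * N * colSums((a * iv1)^2) * h1^2 + 1 / pv
    I01 <- 0.5 * N * colSums(a * iv2) * h0 * h1
    det <- pmax(I00 * I11 - I01^2, .Machine$double.eps)
    d0 <- (I11 * g0 - I01 * g1) / det
    d1 <- (I00 * g1 - I01 * g0) / det
    d0 <- pmin(pmax(d0, -4), 4)
    d1 <- pmin(pmax(d1, -4), 4)
    d0[conv] <- 0; d1[conv] <- 0

    step <- rep(1, nw)
    Fnew <- Fcur
    l0n <- l0; l1n <- l1
    for (bt in 1:16) {
      l0c <- l0 + step * d0
      l1c <- l1 + step * d1
      Fc <- obj(l0c, l1c)
      worse <- !conv & (Fc < Fcur - 1e-10)
      better <- !conv & !worse
      l0n[better] <- l0c[better]
      l1n[better] <- l1c[better]
      Fnew[better] <- Fc[better]
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      if (bt == 16) conv[worse] <- TRUE   # no improving step found
    }
    dF <- abs(Fnew - Fcur)
    conv <- conv | (dF < tol)
    l0 <- pmin(pmax(l0n, -32), 32)
    l1 <- pmin(pmax(l1n, -32), 32)
    Fcur <- Fnew
    if (trace) Ftr[[length(Ftr) + 1]] <- Fcur
  }
  ## hyperparameter-uncertainty (Occam) term from the final curvature
  h0 <- exp(l0); h1 <- exp(l1)
  d <- a %o% h1 + matrix(h0, r, nw, byrow = TRUE)
  iv1 <- 1 / d; iv2 <- iv1 * iv1
  I00 <- 0.5 * N * (m / h0^2 + colSums(iv2)) * h0^2 + 1 / pv
  I11 <- 0.5 * N * colSums((a * iv1)^2) * h1^2 + 1 / pv
  I01 <- 0.5 * N * colSums(a * iv2) * h0 * h1
  detH <- pmax(I00 * I11 - I01^2, .Machine$double.eps)
  Focc <- 0.5 * (-2 * log(pv) - log(detH))
  list(F = Fcur + Focc, F_reml = Fcur, lambda = rbind(l0, l1),
       h = rbind(exp(l0), exp(l1)), n_iterations = it,
       converged = conv,
       F_trace = if (trace) do.call(rbind, Ftr) else NULL)
}

#' ReML free energy of a laminar generative model
#'
#' Maximizes the variational free energy of the linear Gaussian model
#' `Y = L J + e` over the two covariance-component hyperparameters
#' (`C = h0 I + h1 L Q L'`, log-parameterized with broad Gaussian
#' hyperpriors) by Fisher scoring with backtracking, so the objective is
#' non-decreasing across iterations. The returned free energy combines the
#' restricted log likelihood, the hyperprior density, and the
#' hyperparameter-uncertainty (Occam) term; the hyperprior constants are
#' identical for any two models with the same component count and cancel in
#' free-energy differences.
#'
#' With `fix_h` the hyperparameters are clamped and the returned `F` is the
#' plain Gaussian log marginal likelihood of `Y` under `C(fix_h)` (no
#' hyperprior or uncertainty terms), which is directly comparable to a
#' dense multivariate-normal evaluation.
#'
#' @param Y channels x samples data matrix.
#' @param model a [generative_model()].
#' @param max_iter maximum ReML iterations.
#' @param tol convergence tolerance on the objective change.
#' @param fix_h optional length-2 vector `c(h_noise, h_source)` of fixed
#'   hyperparameters in data units.
#' @param hyperprior list with elements `mean` and `var` of the Gaussian
#'   hyperprior on the log-hyperparameters.
#' @return An object of class `inversion_result` with `F`, `h`, `lambda`,
#'   `n_iterations`, `converged`, the per-iteration `F_trace`, and the
#'   posterior mean `source_estimate` at the prior vertex.
#' @export
reml_free_energy <- function(Y, model, max_iter = 64, tol = 1e-3,
                             fix_h = NULL,
                             hyperprior = list(mean = 0, var = 256)) {
  stopifnot(inherits(model, "generative_model"),
            nrow(Y) == model$n_channels, ncol(Y) >= 1)
  N <- ncol(Y)
  n_c <- model$n_channels
  s <- sqrt(mean(Y^2))
  if (!is.finite(s) || s == 0) s <- 1
  Ys <- Y / s
  Z <- crossprod(model$U, Ys)
  w <- rowSums(Z^2)
  tot <- sum(Ys^2)
  w0 <- max(tot - sum(w), 0)
  m <- n_c - model$rank
  offset <- -N * n_c * log(s)

  if (!is.null(fix_h)) {
    h0 <- fix_h[1] / s^2
    h1 <- fix_h[2] / s^2
    d <- h0 + h1 * model$a
    L <- -0.5 * (N * (m * log(h0) + sum(log(d))) + w0 / h0 +
                   sum(w / d) + N * n_c * log(2 * pi))
    res <- list(F = L + offset, h = fix_h, lambda = log(fix_h),
                n_iterations = 0L, converged = TRUE, F_trace = L + offset)
  } else {
    fit <- reml2_fit(matrix(w), w0, model$a, m, N, n_c,
                     pm = hyperprior$mean, pv = hyperprior$var,
                     max_iter = max_iter, tol = tol, trace = TRUE)
    res <- list(F = fit$F[1] + offset,
                h = fit$h[, 1] * s^2,
                lambda = fit$lambda[, 1] + log(s^2),
                n_iterations = fit$n_iterations,
                converged = fit$converged[1],
                F_trace = fit$F_trace[, 1] + offset)
  }
  ## posterior mean source trace at the prior vertex:
  ## J = h1 Q L' C^{-1} Y
  h0 <- res$h[1]; h1 <- res$h[2]
  dinv <- 1 / (h0 + h1 * model$a)
  UtY <- crossprod(model$U, Y)
  CinvY <- model$U %*% (dinv * UtY) + (Y - model$U %*% UtY) / h0
  qv <- model$Q[model$prior_vertex, ]
  res$source_estimate <- as.numeric(h1 * (qv %*% crossprod(model$gain,
                                                           CinvY)))
  class(res) <- "inversion_result"
  res
}

#' Empirical Bayesian beamformer source variance prior
#'
#' Per-source prior variance proportional to the unit-gain minimum-variance
#' beamformer power estimate, `1 / (l' Cy^-1 l)` for each lead-field column
#' `l`, with a small ridge on the sample covariance when it is
#' rank-deficient.
#'
#' @param Y channels x samples data matrix.
#' @param gain n_channels x n_sources lead-field matrix.
#' @param ridge relative ridge factor applied to the sample covariance.
#' @return Numeric vector of per-source prior variances.
#' @export
ebb_prior <- function(Y, gain, ridge = 1e-8) {
  N <- ncol(Y)
  Cy <- tcrossprod(Y) / N
  md <- mean(diag(Cy))
  if (md <= 0) stop("data have zero power")
  rc <- tryCatch(rcond(Cy), error = function(e) 0)
  lam <- if (rc < 1e-10) 1e-4 else ridge
  Cy <- Cy + lam * md * diag(nrow(Cy))
  Z <- solve(Cy, gain)
  1 / colSums(gain * Z)
}

#' Localize burst activity on the pial surface
#'
#' Runs the EBB localizer on a window centred on the peak of the averaged
#' burst time course (default 200 ms, i.e. the full epoch at 250 Hz),
#' masks vertices within `mask_mm` of the ROI centre, and returns the
#' cluster of vertices whose beamformer power reaches `threshold` of the
#' masked maximum. Ties at the maximum resolve to the lowest vertex index.
#'
#' @param avg channels x samples averaged data matrix (or `sensor_dataset`
#'   with an `avg` element).
#' @param gain pial-surface lead-field matrix.
#' @param pair the `cortical_patch_pair`.
#' @param roi_center index of the ROI-centre vertex for the mask.
#' @param window_ms localizer window length (ms).
#' @param threshold cluster threshold as a fraction of the masked maximum.
#' @param mask_mm ROI mask radius (mm).
#' @param fs_hz sampling rate (Hz).
#' @return A list with `peak_vertex`, `cluster` (vertex indices), and the
#'   per-vertex `power` (NA outside the mask).
#' @export
localize <- function(avg, gain, pair, roi_center = pair$center_index,
                     window_ms = 200, threshold = 0.8, mask_mm = 50,
                     fs_hz = 250) {
  if (inherits(avg, "sensor_dataset")) avg <- avg$avg
  ns <- ncol(avg)
  halfw <- round(window_ms * fs_hz / 1000 / 2)
  pk <- which.max(colSums(avg^2))
  i0 <- max(1, pk - halfw); i1 <- min(ns, pk + halfw)
  pow <- ebb_prior(avg[, i0:i1, drop = FALSE], gain)
  d <- sqrt(rowSums(sweep(pair$pial_positions, 2,
                          pair$pial_positions[roi_center, ])^2))
  inmask <- d <= mask_mm
  if (!any(inmask)) stop("no vertices within the ROI mask")
  pow_m <- ifelse(inmask, pow, NA_real_)
  mx <- max(pow_m, na.rm = TRUE)
  cluster <- which(!is.na(pow_m) & pow_m >= threshold * mx)
  peak <- which(!is.na(pow_m) & pow_m == mx)[1]
  list(peak_vertex = peak, cluster = cluster, power = pow_m)
}
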
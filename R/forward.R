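## Forward model: closed-form magnetic field of a current dipole in a
## homogeneous conducting sphere (Sarvas solution), and weighted patch lead
## fields with Gaussian spatial smoothing.

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Evaluates the closed-form external field of a current dipole inside a
#' homogeneous conducting sphere and projects it onto each channel's sensing
#' axis. The radial component of the source moment is magnetically silent:
#' a moment parallel to the source's radial direction yields exactly zero on
#' all channels, as does a source at the sphere centre.
#'
#' @param source_pos 3-vector source position (mm, head frame).
#' @param moment_nAm 3-vector dipole moment (nAm).
#' @param sensors a `sensor_array`.
#' @param head a `sphere_head`; the source must lie strictly inside and all
#'   sensors strictly outside.
#' @return Numeric vector of per-channel field values in fT.
#' @export
sphere_dipole_field <- function(source_pos, moment_nAm, sensors, head) {
  r0 <- (as.numeric(source_pos) - head$center) * 1e-3   # m
  if (vnorm(r0) >= head$radius_mm * 1e-3)
    stop("dipole source must lie strictly inside the head sphere")
  rs <- sweep(sensors$positions, 2, head$center) * 1e-3
  rr <- sqrt(rowSums(rs^2))
  if (any(rr <= head$radius_mm * 1e-3))
    stop("all sensors must lie strictly outside the head sphere")
  q <- as.numeric(moment_nAm) * 1e-9                    # Am
  qxr0 <- cross3(q, r0)
  if (sum(qxr0^2) == 0) return(numeric(sensors$n_channels))

  avec <- rs - matrix(r0, nrow(rs), 3, byrow = TRUE)
  a <- sqrt(rowSums(avec^2))
  r0dr <- as.numeric(rs %*% r0)
  adr <- rowSums(avec * rs)
  Fs <- a * (rr * a + rr^2 - r0dr)
  c1 <- a^2 / rr + adr / a + 2 * a + 2 * rr
  c2 <- a + 2 * rr + adr / a
  gradF <- c1 * rs - outer(c2, r0)
  qxr0dr <- as.numeric(rs %*% qxr0)
  B <- 1e-7 * (outer(Fs, qxr0) - qxr0dr * gradF) / Fs^2  # Tesla
  rowSums(B * sensors$orientations) * 1e15               # fT
}

#' Gaussian spatial weighting of a patch
#'
#' Max-normalized Gaussian weights around the patch centre vertex, computed
#' on Euclidean pial distances (the patch extent is far below the curvature
#' radius). These weights implement the spatial smoothing of simulated
#' dipole time courses over the patch.
#'
#' @param pair a `cortical_patch_pair`.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 5).
#' @param center_index vertex the kernel is centred on.
#' @return An object of class `patch_weighting` with unit-peak weights.
#' @export
patch_weighting <- function(pair, fwhm_mm = 5,
                            center_index = pair$center_index) {
  stopifnot(fwhm_mm > 0)
  d <- sqrt(rowSums(sweep(pair$pial_positions, 2,
                          pair$pial_positions[center_index, ])^2))
  s <- fwhm_to_sigma(fwhm_mm)
  w <- exp(-d^2 / (2 * s^2))
  structure(list(fwhm_mm = fwhm_mm, weights = w / max(w),
                 center_index = center_index),
            class = "patch_weighting")
}

#' Sensor gain of a smoothly weighted dipole patch
#'
#' Weighted sum over the patch vertices of unit-moment (1 nAm) dipole
#' fields oriented along the link vectors. With `orientation = "layer"` the
#' layer's canonical current direction is applied: the deep (white-matter)
#' patch points out of the cortex (+link) and the superficial (pial) patch
#' into the cortex (-link), the opposite-polarity configuration of the
#' two-layer burst model. With `orientation = "link"` both layers use the
#' raw +link direction and any signs are carried by the source traces.
#'
#' @param pair a `cortical_patch_pair`.
#' @param layer `"superficial"` (pial vertices) or `"deep"` (white-matter
#'   vertices).
#' @param sensors a `sensor_array`.
#' @param head a `sphere_head`.
#' @param weighting a `patch_weighting` (default FWHM 5 mm).
#' @param orientation `"layer"` or `"link"`, see above.
#' @return Numeric vector: fT per channel per nAm of source moment.
#' @export
patch_gain <- function(pair, layer = c("superficial", "deep"),
                       sensors, head = pair$head,
                       weighting = patch_weighting(pair),
                       orientation = c("layer", "link")) {
  layer <- match.arg(layer)
  orientation <- match.arg(orientation)
  pos <- if (layer == "deep") pair$white_positions else pair$pial_positions
  n <- nrow(pos)
  if (n < 1) stop("empty patch")
  sgn <- if (orientation == "link") 1 else if (layer == "deep") 1 else -1
  g <- numeric(sensors$n_channels)
  for (i in seq_len(n)) {
    g <- g + weighting$weights[i] *
      sphere_dipole_field(pos[i, ], sgn * pair$link_vectors[i, ],
                          sensors, head)
  }
  g
}

#' Per-vertex lead-field matrix of one laminar surface
#'
#' Columns are the sensor fields of unit (1 nAm) dipoles at each vertex of
#' the requested surface, oriented along the +link vector. This is the gain
#' matrix entering the laminar generative models; source covariance priors
#' act on its columns.
#'
#' @param pair a `cortical_patch_pair`.
#' @param layer `"superficial"` (pial) or `"deep"` (white matter).
#' @param sensors a `sensor_array`.
#' @param head a `sphere_head`.
#' @return An n_channels x n_vertices matrix (fT per nAm).
#' @export
gain_matrix <- function(pair, layer = c("superficial", "deep"),
                        sensors, head = pair$head) {
  layer <- match.arg(layer)
  pos <- if (layer == "deep") pair$white_positions else pair$pial_positions
  n <- nrow(pos)
  L <- matrix(0, sensors$n_channels, n)
  for (i in seq_len(n)) {
    L[, i] <- sphere_dipole_field(pos[i, ], pair$link_vectors[i, ],
                                  sensors, head)
  }
  L
}
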
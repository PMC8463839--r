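## Toy cortical geometry: paired pial/white spherical-cap patches with
## link-vector column orientations, a helmet sensor array, a spherical head
## model, and rigid co-registration perturbations.

#' Spherical head model
#'
#' A homogeneous conducting sphere standing in for the realistic single-shell
#' head model: on spherical geometry the two coincide, and the closed-form
#' dipole field requires no surface mesh.
#'
#' @param radius_mm sphere radius in mm.
#' @param center 3-vector sphere centre (head frame, mm).
#' @return An object of class `sphere_head`.
#' @export
make_sphere_head <- function(radius_mm = 90, center = c(0, 0, 0)) {
  stopifnot(radius_mm > 0, length(center) == 3)
  structure(list(radius_mm = radius_mm, center = as.numeric(center)),
            class = "sphere_head")
}

#' Paired pial/white cortical patch
#'
#' Builds a curved patch of `n_vertices` paired vertices on a sphere-aligned
#' pial surface, with each white-matter vertex displaced inward by
#' `thickness_mm` along the local radial direction. Link vectors point from
#' the white to the pial vertex and approximate the orientation of the
#' cortical column (apical dendrites) at each location; they are the dipole
#' orientation used throughout.
#'
#' Vertex 1 is the patch centre and is the designated prior vertex
#' (`center_index`). Remaining vertices are laid out in a sunflower pattern
#' over a spherical cap of geodesic radius `extent_mm`.
#'
#' Column orientation: purely radial current dipoles are magnetically
#' silent in a spherical conductor, so a patch of radial columns would be
#' invisible to MEG. Cortical sources that dominate MEG sit on sulcal
#' walls, where the column direction is strongly tilted away from the
#' head-radial direction; `column_tilt_deg` sets that tilt (default 60
#' degrees, a sulcal-bank-like column; 0 reproduces a radial gyral-crown
#' column). All columns share one tilt azimuth, approximating the locally
#' parallel columns of a single sulcal bank.
#'
#' @param center 3-vector, pial-surface position of the patch centre (mm).
#' @param extent_mm geodesic radius of the patch on the pial sphere (mm).
#' @param thickness_mm cortical thickness, i.e. pial-white separation (mm).
#' @param n_vertices number of vertex pairs (>= 1).
#' @param head `sphere_head` the patch must lie strictly inside.
#' @param column_tilt_deg tilt of the column direction away from the local
#'   outward radial direction (degrees, in \[0, 90)).
#' @param tilt_azimuth_deg azimuth of the tilt direction in the patch's
#'   tangent plane (degrees); rotating it emulates sulcal banks facing
#'   different directions.
#' @return An object of class `cortical_patch_pair` with matrices
#'   `pial_positions`, `white_positions`, `link_vectors` (n x 3),
#'   `vertex_areas` and `center_index`.
#' @export
make_column_patch <- function(center, extent_mm = 10, thickness_mm = 2.5,
                              n_vertices = 30, head = make_sphere_head(),
                              column_tilt_deg = 60, tilt_azimuth_deg = 0) {
  stopifnot(extent_mm > 0, thickness_mm > 0, n_vertices >= 1,
            column_tilt_deg >= 0, column_tilt_deg < 90)
  u <- as.numeric(center) - head$center
  rp <- vnorm(u)
  if (rp <= 0) stop("patch centre must not coincide with the head centre")
  if (rp >= head$radius_mm)
    stop("patch centre lies outside the head sphere")
  u <- u / rp
  basis <- orthobasis(u)
  alpha_max <- extent_mm / rp
  golden <- pi * (3 - sqrt(5))

  pial <- matrix(NA_real_, n_vertices, 3)
  pial[1, ] <- head$center + rp * u
  if (n_vertices > 1) {
    n2 <- n_vertices - 1
    for (j in seq_len(n2)) {
      a <- alpha_max * sqrt(j / n2)
      phi <- j * golden
      dirv <- cos(a) * u +
        sin(a) * (cos(phi) * basis$e1 + sin(phi) * basis$e2)
      pial[j + 1, ] <- head$center + rp * dirv
    }
  }
  radial <- sweep(pial, 2, head$center)
  radial <- radial / sqrt(rowSums(radial^2))
  ## column direction: radial tilted by column_tilt_deg toward a common
  ## tangential azimuth (e1), per vertex
  tilt <- column_tilt_deg * pi / 180
  az <- tilt_azimuth_deg * pi / 180
  tdir <- cos(az) * basis$e1 + sin(az) * basis$e2
  tang <- matrix(tdir, n_vertices, 3, byrow = TRUE) -
    radial * as.numeric(radial %*% tdir)
  tang <- tang / sqrt(rowSums(tang^2))
  coldir <- cos(tilt) * radial + sin(tilt) * tang
  white <- pial - thickness_mm * coldir
  if (any(sqrt(rowSums(sweep(pial, 2, head$center)^2)) >= head$radius_mm) ||
      any(sqrt(rowSums(sweep(white, 2, head$center)^2)) >= head$radius_mm))
    stop("patch vertices fall outside the head sphere")

  cap_area <- 2 * pi * rp^2 * (1 - cos(alpha_max))
  structure(list(
    pial_positions = pial,
    white_positions = white,
    link_vectors = coldir,
    vertex_areas = rep(cap_area / n_vertices, n_vertices),
    center_index = 1L,
    thickness_mm = thickness_mm,
    extent_mm = extent_mm,
    head = head
  ), class = "cortical_patch_pair")
}

#' Helmet sensor array
#'
#' Places `n_channels` axial channels approximately uniformly over the upper
#' part of a helmet sphere (a CTF-like axial-gradiometer layout), with
#' sensing axes pointing radially outward.
#'
#' @param n_channels number of channels (default 274, the usable channel
#'   count of a 275-channel CTF system).
#' @param helmet_radius_mm radius of the helmet sphere (mm); must exceed the
#'   head radius.
#' @param coverage_deg maximum polar angle from +z covered by the helmet.
#' @return An object of class `sensor_array` with `positions`,
#'   `orientations` (n x 3), `n_channels` and `labels`.
#' @export
make_sensor_array <- function(n_channels = 274, helmet_radius_mm = 115,
                              coverage_deg = 120) {
  if (n_channels < 1) stop("n_channels must be at least 1")
  stopifnot(helmet_radius_mm > 0, coverage_deg > 0, coverage_deg <= 180)
  zmin <- cos(coverage_deg * pi / 180)
  golden <- pi * (3 - sqrt(5))
  if (n_channels == 1) {
    z <- 1
    phi <- 0
  } else {
    i <- seq_len(n_channels)
    z <- 1 - (i - 0.5) / n_channels * (1 - zmin)
    phi <- i * golden
  }
  st <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), z)
  structure(list(
    positions = helmet_radius_mm * dirs,
    orientations = dirs,
    n_channels = as.integer(n_channels),
    helmet_radius_mm = helmet_radius_mm,
    labels = sprintf("MEG%03d", seq_len(n_channels))
  ), class = "sensor_array")
}

#' Sample a random co-registration perturbation
#'
#' Draws a rigid-body perturbation whose translation direction and rotation
#' axis are uniform on the sphere, with the translation norm fixed at
#' `magnitude` mm and the rotation angle fixed at `magnitude` degrees (the
#' two error axes are driven jointly by one scalar). Rotation acts about the
#' head centre (origin).
#'
#' @param magnitude non-negative scalar, mm of translation and degrees of
#'   rotation.
#' @param seed optional RNG seed.
#' @return An object of class `coreg_perturbation`.
#' @export
sample_coreg_perturbation <- function(magnitude, seed = NULL) {
  if (magnitude < 0) stop("perturbation magnitude must be non-negative")
  draw <- function() unit_vector(stats::rnorm(3))
  if (magnitude == 0) {
    tdir <- c(0, 0, 0)
    axis <- c(0, 0, 1)
  } else {
    dirs <- with_seed(seed, list(draw(), draw()))
    tdir <- dirs[[1]]
    axis <- dirs[[2]]
  }
  structure(list(
    translation = magnitude * tdir,
    rotation_angle = magnitude,
    rotation_axis = axis,
    magnitude = magnitude,
    seed = seed
  ), class = "coreg_perturbation")
}

#' Apply a rigid co-registration perturbation to geometry
#'
#' Returns a rigid-body transformed copy of a cortical patch pair or sensor
#' array; the input is untouched. Positions are rotated about the head-frame
#' origin and then translated; direction fields (link vectors, sensing axes)
#' are rotated only.
#'
#' @param geometry a `cortical_patch_pair` or `sensor_array`.
#' @param p a `coreg_perturbation`.
#' @param inverse if `TRUE`, apply the inverse transform.
#' @return An object of the same class as `geometry`.
#' @export
apply_perturbation <- function(geometry, p, inverse = FALSE) {
  UseMethod("apply_perturbation")
}

transform_points <- function(x, R, t, inverse) {
  if (inverse) sweep(x, 2, t) %*% R       # x %*% t(t(R)) = x R for R^-1 = R^T
  else x %*% t(R) + matrix(t, nrow(x), 3, byrow = TRUE)
}

#' @export
apply_perturbation.cortical_patch_pair <- function(geometry, p,
                                                   inverse = FALSE) {
  R <- rotation_matrix(p$rotation_axis, p$rotation_angle)
  rot_dir <- if (inverse) function(v) v %*% R else function(v) v %*% t(R)
  out <- geometry
  out$pial_positions <- transform_points(geometry$pial_positions, R,
                                         p$translation, inverse)
  out$white_positions <- transform_points(geometry$white_positions, R,
                                          p$translation, inverse)
  out$link_vectors <- rot_dir(geometry$link_vectors)
  out
}

#' @export
apply_perturbation.sensor_array <- function(geometry, p, inverse = FALSE) {
  R <- rotation_matrix(p$rotation_axis, p$rotation_angle)
  out <- geometry
  out$positions <- transform_points(geometry$positions, R, p$translation,
                                    inverse)
  out$orientations <- if (inverse) geometry$orientations %*% R
  else geometry$orientations %*% t(R)
  out
}
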
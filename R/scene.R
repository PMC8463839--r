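## Simulation scene: head sphere, helmet array, cortical column patch pair,
## smoothing weights, simulation patch gains and per-vertex inversion gains,
## bundled so experiments can share one geometry.

#' Assemble a simulation scene
#'
#' Builds the full synthetic measurement geometry: a spherical head model,
#' a CTF-like helmet array, a paired pial/white cortical patch at a
#' motor-cortex-like location, the Gaussian patch smoothing weights, the
#' link-oriented patch gains used to project simulated sources, and the
#' per-vertex lead fields of both surfaces used by the inversion.
#'
#' @param n_channels helmet channel count.
#' @param helmet_radius_mm helmet sphere radius (mm).
#' @param head_radius_mm conducting sphere radius (mm).
#' @param patch_direction unit direction of the patch centre from the head
#'   centre (default an upper lateral, precentral-like location).
#' @param pial_radius_mm radial distance of the pial surface (mm).
#' @param extent_mm patch geodesic radius (mm).
#' @param thickness_mm cortical thickness (mm).
#' @param n_vertices vertices per surface.
#' @param fwhm_mm spatial smoothing / coherence prior FWHM (mm).
#' @param fs_hz sampling rate (Hz).
#' @param epoch_halfwidth_ms epoch half width (ms).
#' @return An object of class `burst_scene`.
#' @export
make_scene <- function(n_channels = 274, helmet_radius_mm = 115,
                       head_radius_mm = 90,
                       patch_direction = c(0.45, -0.35, 0.82),
                       pial_radius_mm = 70, extent_mm = 10,
                       thickness_mm = 2.5, n_vertices = 30,
                       fwhm_mm = 5, fs_hz = 250,
                       epoch_halfwidth_ms = 100) {
  head <- make_sphere_head(head_radius_mm)
  sensors <- make_sensor_array(n_channels, helmet_radius_mm)
  center <- unit_vector(patch_direction) * pial_radius_mm
  pair <- make_column_patch(center, extent_mm, thickness_mm, n_vertices,
                            head)
  weighting <- patch_weighting(pair, fwhm_mm)
  sim_gains <- list(
    deep = patch_gain(pair, "deep", sensors, head, weighting,
                      orientation = "link"),
    superficial = patch_gain(pair, "superficial", sensors, head, weighting,
                             orientation = "link"))
  structure(list(
    head = head, sensors = sensors, pair = pair, weighting = weighting,
    sim_gains = sim_gains,
    gain_pial = gain_matrix(pair, "superficial", sensors, head),
    gain_white = gain_matrix(pair, "deep", sensors, head),
    fwhm_mm = fwhm_mm, fs_hz = fs_hz,
    times_ms = default_times(fs_hz, epoch_halfwidth_ms)
  ), class = "burst_scene")
}

#' Select cluster vertices by link-vector angle
#'
#' Vertices whose link vector deviates from the cluster-peak vertex's link
#' vector by at most `angle_tol` radians; these are the vertices entering
#' the within-cluster dF average.
#'
#' @param pair a `cortical_patch_pair`.
#' @param peak_vertex cluster peak vertex index.
#' @param angle_tol angular tolerance in radians (default 0.1).
#' @return Integer vector of vertex indices (always includes the peak).
#' @export
cluster_vertices <- function(pair, peak_vertex, angle_tol = 0.1) {
  lv <- pair$link_vectors
  ref <- lv[peak_vertex, ]
  ang <- acos(pmin(1, pmax(-1, as.numeric(lv %*% ref))))
  which(ang <= angle_tol)
}

#' Build the pial/white generative-model pair for one prior vertex
#'
#' @param scene a `burst_scene` (supplies the default gains and patch).
#' @param vertex prior vertex index.
#' @param pair optionally, a perturbed patch pair to use for the inversion
#'   geometry (co-registration error studies).
#' @param gain_pial,gain_white optionally, lead fields matching `pair`.
#' @param fwhm_mm coherence prior FWHM.
#' @return List with elements `pial` and `white`.
#' @export
laminar_models_at <- function(scene, vertex, pair = scene$pair,
                              gain_pial = scene$gain_pial,
                              gain_white = scene$gain_white,
                              fwhm_mm = scene$fwhm_mm) {
  list(pial = generative_model(gain_pial, pair, "superficial", vertex,
                               fwhm_mm),
       white = generative_model(gain_white, pair, "deep", vertex, fwhm_mm))
}

#' Cluster-level sliding laminar comparison
#'
#' Runs the sliding-window pial-vs-white comparison with the prior placed
#' at every vertex whose link-vector angle is within `angle_tol` radians of
#' the cluster peak's, and averages the dF time series over those vertices.
#'
#' @param avg channels x samples averaged burst data.
#' @param scene a `burst_scene`.
#' @param peak_vertex cluster peak vertex (e.g. from [localize()]).
#' @param angle_tol link-vector angular tolerance (radians).
#' @param pair,gain_pial,gain_white optional inversion geometry overrides
#'   (see [laminar_models_at()]).
#' @param ... passed to [sliding_laminar_compare()].
#' @return A `laminar_comparison` averaged over the cluster vertices.
#' @export
laminar_compare_cluster <- function(avg, scene, peak_vertex,
                                    angle_tol = 0.1, pair = scene$pair,
                                    gain_pial = scene$gain_pial,
                                    gain_white = scene$gain_white, ...) {
  verts <- cluster_vertices(pair, peak_vertex, angle_tol)
  cmps <- lapply(verts, function(v) {
    mods <- laminar_models_at(scene, v, pair, gain_pial, gain_white)
    sliding_laminar_compare(avg, mods$pial, mods$white,
                            times_ms = scene$times_ms,
                            fs_hz = scene$fs_hz, ...)
  })
  average_comparisons(cmps)
}
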
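## Run configuration (YAML) and result serialization: every default equals
## the analysis parameters used throughout the package, so an empty config
## file reproduces the standard pipeline.

#' Default run configuration
#'
#' Nested list of every tunable pipeline parameter with its standard value:
#' beta band 13-30 Hz, 4th-order Butterworth, burst threshold 1.75 SD above
#' the median envelope, +/-100 ms epochs, 40 ms Hann windows advanced in
#' 4 ms steps, 5 mm coherence prior FWHM, dF significance threshold 3,
#' -20 dB per-burst SNR, 10 subjects x 50 bursts, SNR sweep -50..-20 dB in
#' 5 dB steps and co-registration sweep 0..3 mm/deg in 0.5 steps with 50
#' repetitions.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    geometry = list(
      n_channels = 274, helmet_radius_mm = 115, head_radius_mm = 90,
      pial_radius_mm = 70, extent_mm = 10, thickness_mm = 2.5,
      n_vertices = 30, fwhm_mm = 5),
    model = list(source = "surrogate", variant = "canonical"),
    noise = list(color = "white", target_snr_db = -20),
    detection = list(
      band_hz = c(13, 30), filter_order = 4, threshold_sd = 1.75,
      epoch_halfwidth_ms = 100),
    woody = list(tolerance = 0.1, max_iterations = 100, max_lag_ms = 40),
    inversion = list(
      window_ms = 40, step_ms = 4, taper = "hann", fwhm_mm = 5,
      dF_threshold = 3, angle_tol_rad = 0.1),
    experiments = list(
      n_subjects = 10, n_bursts = 50, reps = 50,
      snr_levels_db = seq(-50, -20, by = 5),
      coreg_levels = seq(0, 3, by = 0.5))
  ), class = "run_config")
}

validate_config <- function(cfg) {
  d <- cfg$detection
  if (!is.null(d$band_hz) && d$band_hz[1] >= d$band_hz[2])
    stop("config error: detection.band_hz low edge must be below high edge")
  if (!is.null(d$threshold_sd) && d$threshold_sd <= 0)
    stop("config error: detection.threshold_sd must be positive")
  g <- cfg$geometry
  if (!is.null(g$pial_radius_mm) && !is.null(g$head_radius_mm) &&
      g$pial_radius_mm >= g$head_radius_mm)
    stop("config error: geometry.pial_radius_mm must be inside the head")
  if (!is.null(cfg$inversion$window_ms) && cfg$inversion$window_ms <= 0)
    stop("config error: inversion.window_ms must be positive")
  invisible(cfg)
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("config error: unknown key '", key, "'")
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config error: '", key, "' must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], key)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected with an
#' error naming the offending key; basic consistency checks are applied.
#' An empty file yields [default_config()].
#'
#' @param path path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) cfg <- merge_config(unclass(cfg), user)
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Scene and model from a configuration
#' @param cfg a `run_config`.
#' @return A list with `scene`, `model` and `noise`.
#' @export
config_objects <- function(cfg) {
  g <- cfg$geometry
  list(scene = make_scene(n_channels = g$n_channels,
                          helmet_radius_mm = g$helmet_radius_mm,
                          head_radius_mm = g$head_radius_mm,
                          pial_radius_mm = g$pial_radius_mm,
                          extent_mm = g$extent_mm,
                          thickness_mm = g$thickness_mm,
                          n_vertices = g$n_vertices, fwhm_mm = g$fwhm_mm),
       model = burst_model(cfg$model$source, cfg$model$variant),
       noise = noise_spec(cfg$noise$color, cfg$noise$target_snr_db))
}

comparison_to_df <- function(cmp) {
  data.frame(window_center_ms = cmp$window_centers_ms, dF = cmp$dF,
             F_pial = if (is.null(cmp$F_pial)) NA else cmp$F_pial,
             F_white = if (is.null(cmp$F_white)) NA else cmp$F_white)
}

#' Write experiment results and a run manifest
#'
#' Serializes results to TSV (one row per window centre for dF time
#' series; one row per repetition for sweep tables) and a JSON summary,
#' then writes a manifest listing every file, the configuration hash and
#' the seed. The manifest is written atomically (temp file + rename) as
#' the final step. Rerunning with the same seed reproduces the files
#' byte-for-byte.
#'
#' @param results named list; `laminar_comparison` objects, data.frames
#'   and scalar summaries are handled.
#' @param out_dir output directory (created if needed).
#' @param cfg optional `run_config` stored alongside.
#' @param seed seed recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, cfg = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  summary <- list()
  t0 <- proc.time()[["elapsed"]]
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "laminar_comparison")) {
      f <- file.path(out_dir, paste0(nm, "_dF.tsv"))
      utils::write.table(comparison_to_df(x), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
      summary[[nm]] <- list(tail_min = x$tail_min, peak_max = x$peak_max)
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    } else if (is.atomic(x) && length(x) == 1) {
      summary[[nm]] <- x
    }
  }
  sf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sf)
  if (!is.null(cfg)) {
    cf <- file.path(out_dir, "config.yaml")
    save_config(cfg, cf)
    files <- c(files, cf)
  }
  manifest <- list(
    package = "laminarbeta",
    version = as.character(utils::packageVersion("laminarbeta")),
    seed = seed,
    config_hash = if (is.null(cfg)) NA_character_
                  else digest_config(cfg),
    elapsed_s = proc.time()[["elapsed"]] - t0,
    files = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  tmp <- paste0(mf, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, mf)
  invisible(manifest)
}

## order-stable FNV-style hash of the serialized configuration
digest_config <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
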
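#' @keywords internal
"_PACKAGE"

## Coordinate frame used throughout the package: right-handed, head-centred,
## millimetres, +z toward the vertex of the head. Dipole moments are in nAm,
## sensor fields in femtotesla (fT).

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards. A `NULL` seed leaves the RNG
#' untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed plus a stage label (and optional
#' index) to a new seed, so that every stochastic stage of a pipeline draws
#' from an independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index optional integer (e.g. subject or repetition number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage = "", index = 0L) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 31 + as.double(index) * 2654435761) %% 2147483647
  as.integer(h)
}

## -- small vector helpers -------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## any unit vector orthogonal to u
orthobasis <- function(u) {
  u <- unit_vector(u)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit_vector(cross3(ref, u))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum.
#' @return The corresponding Gaussian sigma.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; rotations act about the head-frame origin.
#'
#' @param axis 3-vector rotation axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit_vector(axis)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Default epoch time grid
#'
#' The standard burst epoch: +/-100 ms around the burst peak sampled at
#' 250 Hz, i.e. 51 samples.
#'
#' @param fs_hz sampling rate (Hz).
#' @param halfwidth_ms epoch half width (ms).
#' @return Numeric vector of sample times in ms, symmetric about 0.
#' @export
default_times <- function(fs_hz = 250, halfwidth_ms = 100) {
  step <- 1000 / fs_hz
  seq(-halfwidth_ms, halfwidth_ms, by = step)
}
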
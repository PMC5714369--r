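# small shared helpers (internal)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular midpoint of two angles
#'
#' Midpoint along the shortest arc between two angles in degrees; used to
#' assign a representative gantry angle to the subfield between two control
#' points. The 359/1 degree midpoint is 0.
#'
#' @param a,b angles in degrees.
#' @return midpoint angle in `[0, 360)` degrees.
#' @export
circular_midpoint <- function(a, b) {
  d <- ((b - a + 180) %% 360) - 180
  d <- ifelse(d <= -180 + 1e-12, d + 360, d) # antipodal: +180 by convention
  (a + d / 2) %% 360
}

# meterset-weighted circular mean, degrees
circular_weighted_mean <- function(angles, w) {
  a <- deg2rad(angles)
  rad2deg(atan2(sum(w * sin(a)), sum(w * cos(a)))) %% 360
}

# rotation about the cylinder (z) axis that ADDS delta to the diode angle
# convention (angle measured from anterior +y toward +x)
rotate_z <- function(pts, delta_deg) {
  d <- deg2rad(delta_deg)
  cbind(pts[, 1] * cos(d) + pts[, 2] * sin(d),
        -pts[, 1] * sin(d) + pts[, 2] * cos(d),
        pts[, 3])
}

# rotation about the vertical (anterior-posterior, y) axis; positive angle
# turns +x toward +z (couch yaw with the phantom supine)
rotate_y <- function(pts, delta_deg) {
  d <- deg2rad(delta_deg)
  cbind(pts[, 1] * cos(d) + pts[, 3] * sin(d),
        pts[, 2],
        -pts[, 1] * sin(d) + pts[, 3] * cos(d))
}

# deterministic FNV-1a hash of a character scalar, hex string; used to stamp
# QA reports with a config fingerprint without external digest packages
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a plain double
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)
    # 32-bit modular multiply by 16777619 done in two 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
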
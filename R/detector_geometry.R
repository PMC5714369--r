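# Cylindrical diode-array geometry: spiral layout, annular phantom, rays.
#
# Coordinate frame (fixed, IEC-style, phantom supine):
#   x = right-left (+x patient left), y = anterior-posterior (+y anterior,
#   i.e. up), z = superior-inferior along the cylinder axis. Gantry 0 deg
#   places the source anterior at (0, SAD, 0); the diode spiral angle is
#   measured from anterior (+y) toward +x.

#' Build the spiral diode-array layout
#'
#' Places diodes along a helix on the detector cylinder: `per_rev` diodes per
#' revolution (the circumference divided by the nominal inter-detector
#' distance), advancing one `pitch` per revolution. The default configuration
#' (1 cm pitch, 1 cm spacing, 21 cm diameter, 21 cm axial length) yields the
#' 1,386-diode cylindrical array.
#'
#' The nominal spacing must divide the circumference to within 1e-3 cm per
#' inter-diode gap; the actual stored `spacing` is the exact helical
#' arc-length step between consecutive diodes.
#'
#' @param pitch cm of axial advance per revolution.
#' @param spacing nominal arc-length between consecutive diodes, cm.
#' @param diameter detector-cylinder diameter, cm.
#' @param axial_length axial detection length, cm (must be an integer number
#'   of pitches).
#' @param angular_origin angle (radians) of the first diode, measured from
#'   anterior; the documented default 0 puts column 1 of the unwrapped map at
#'   the anterior midline.
#' @return an object of class `diode_array_layout` with a `diodes` data frame
#'   (`diode_index`, `x`, `y`, `z`, `angle`) and scalar geometry fields.
#' @export
#' @examples
#' lay <- build_layout()
#' lay$n_diodes # 1386
build_layout <- function(pitch = 1, spacing = 1, diameter = 21,
                         axial_length = 21, angular_origin = 0) {
  if (any(c(pitch, spacing, diameter, axial_length) <= 0))
    stop_config("all layout dimensions must be positive")
  circumference <- pi * diameter
  per_rev <- round(circumference / spacing)
  if (per_rev < 1)
    stop_config("spacing %.4g cm exceeds the circumference %.4g cm",
                spacing, circumference)
  residual <- abs(circumference / per_rev - spacing)
  if (residual > 1e-3)
    stop_config(paste0(
      "spacing %.6g cm is not commensurate with the detector circumference ",
      "%.6g cm: per-gap residual %.4g cm exceeds 1e-3 cm"),
      spacing, circumference, residual)
  n_rev <- round(axial_length / pitch)
  if (n_rev < 1 || abs(axial_length / pitch - n_rev) > 1e-6)
    stop_config("axial_length %.4g cm is not an integer number of pitches (%.4g cm)",
                axial_length, pitch)
  n <- as.integer(per_rev * n_rev)
  k <- seq_len(n) - 1L
  radius <- diameter / 2
  angle <- (angular_origin + 2 * pi * k / per_rev) %% (2 * pi)
  z <- -axial_length / 2 + pitch * k / per_rev
  diodes <- data.frame(
    diode_index = k + 1L,
    x = radius * sin(angle),
    y = radius * cos(angle),
    z = z,
    angle = angle
  )
  structure(list(
    diodes = diodes,
    radius = radius,
    diameter = diameter,
    pitch = pitch,
    # exact helix arc-length step between consecutive diodes
    spacing = sqrt((circumference / per_rev)^2 + (pitch / per_rev)^2),
    nominal_spacing = spacing,
    per_rev = as.integer(per_rev),
    n_rev = as.integer(n_rev),
    n_diodes = n,
    axial_length = axial_length,
    angular_origin = angular_origin
  ), class = "diode_array_layout")
}

#' @export
print.diode_array_layout <- function(x, ...) {
  cat(sprintf(
    "<diode_array_layout> %d diodes (%d/revolution x %d revolutions)\n",
    x$n_diodes, x$per_rev, x$n_rev))
  cat(sprintf("  cylinder: diameter %.4g cm, pitch %.4g cm, spacing %.6g cm\n",
              x$diameter, x$pitch, x$spacing))
  invisible(x)
}

layout_points <- function(layout) {
  as.matrix(layout$diodes[, c("x", "y", "z")])
}

#' Annular phantom model
#'
#' The acrylic annulus that carries the diode cylinder, with an optional
#' central plug filling the hollow core. Densities are in g/cc relative to
#' water; the region outside the outer cylinder contributes
#' `exterior_density` (default 0) to radiological paths.
#'
#' @param outer_diameter,inner_diameter cm.
#' @param shell_density acrylic shell density, g/cc.
#' @param plug_present logical; is the homogeneous central plug inserted?
#' @param plug_density g/cc of the plug material (acrylic).
#' @param cavity_density g/cc of the hollow core when the plug is out (air).
#' @param exterior_density g/cc outside the phantom.
#' @return object of class `phantom_model`.
#' @export
phantom_model <- function(outer_diameter = 26.59, inner_diameter = 15.0,
                          shell_density = 1.17, plug_present = TRUE,
                          plug_density = 1.17, cavity_density = 0.0012,
                          exterior_density = 0) {
  if (inner_diameter <= 0 || outer_diameter <= inner_diameter)
    stop_config("need 0 < inner_diameter < outer_diameter")
  if (any(c(shell_density, plug_density, cavity_density, exterior_density) < 0))
    stop_config("densities must be nonnegative")
  structure(list(
    outer_diameter = outer_diameter, inner_diameter = inner_diameter,
    outer_radius = outer_diameter / 2, inner_radius = inner_diameter / 2,
    shell_density = shell_density, plug_present = isTRUE(plug_present),
    plug_density = plug_density, cavity_density = cavity_density,
    exterior_density = exterior_density
  ), class = "phantom_model")
}

core_density <- function(phantom) {
  if (phantom$plug_present) phantom$plug_density else phantom$cavity_density
}

#' Geometric ray
#'
#' @param source_point cm triple in the fixed frame.
#' @param direction direction vector; normalized to unit length.
#' @param source_axis_distance cm, optional.
#' @return object of class `ray`.
#' @export
ray <- function(source_point, direction, source_axis_distance = NULL) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop_config("ray direction must be nonzero")
  structure(list(source_point = as.numeric(source_point),
                 direction = as.numeric(direction) / n,
                 source_axis_distance = source_axis_distance),
            class = "ray")
}

#' Entrance and exit diode masks for a beam direction
#'
#' Splits the array into the source-facing (entrance) and far-side (exit)
#' halves for a given gantry angle. A diode lies in the entrance half when
#' its position has a nonnegative component along the isocenter-to-source
#' direction; diodes exactly on the dividing plane are assigned to entrance
#' (documented tie-break).
#'
#' @param layout a `diode_array_layout`.
#' @param gantry_angle degrees in `[0, 360)`.
#' @return list with logical vectors `entrance` and `exit` of length
#'   `n_diodes` (a partition of the array).
#' @export
entrance_exit_masks <- function(layout, gantry_angle) {
  if (gantry_angle < 0 || gantry_angle >= 360)
    stop_config("gantry_angle must lie in [0, 360)")
  g <- deg2rad(gantry_angle)
  s <- c(sin(g), cos(g)) # isocenter -> source direction
  d <- layout$diodes$x * s[1] + layout$diodes$y * s[2]
  tie_tol <- 1e-9 * layout$radius
  entrance <- d >= -tie_tol
  list(entrance = entrance, exit = !entrance)
}

#' Unwrap the spiral onto a rows-by-columns cylinder map
#'
#' Maps each diode to an (axial bin, angular bin) cell: row = revolution
#' number (inferior to superior), column = angular position with column 1 at
#' the angular origin (anterior by default). The mapping is a bijection onto
#' the `n_rev x per_rev` grid.
#'
#' @param layout a `diode_array_layout`.
#' @return data frame `diode_index`, `row`, `col` with attributes `dims`,
#'   `row_z` (mean axial coordinate per row, cm), `col_angle` (radians) and
#'   `col_arc` (arc length at detector radius, cm).
#' @export
unwrap_index <- function(layout) {
  k <- layout$diodes$diode_index - 1L
  row <- k %/% layout$per_rev + 1L
  col <- k %% layout$per_rev + 1L
  out <- data.frame(diode_index = layout$diodes$diode_index, row = row, col = col)
  col_angle <- (layout$angular_origin +
                  2 * pi * (seq_len(layout$per_rev) - 1) / layout$per_rev) %% (2 * pi)
  attr(out, "dims") <- c(layout$n_rev, layout$per_rev)
  attr(out, "row_z") <- vapply(seq_len(layout$n_rev), function(r)
    mean(layout$diodes$z[row == r]), numeric(1))
  attr(out, "col_angle") <- col_angle
  attr(out, "col_arc") <- layout$radius * 2 * pi * (seq_len(layout$per_rev) - 1) /
    layout$per_rev
  out
}

# ---- radiological (water-equivalent) path ---------------------------------

# Vectorized water-equivalent depth from a single source point to each row of
# `pts`, through the annular phantom. Intersections with the two coaxial
# cylinders are solved analytically per ray; segment lengths are weighted by
# region density relative to water.
radiological_depth <- function(phantom, src, pts) {
  pts <- matrix(pts, ncol = 3)
  u <- sweep(pts, 2, src)                    # segment vectors
  L <- sqrt(rowSums(u^2))
  a <- u[, 1]^2 + u[, 2]^2
  b <- 2 * (src[1] * u[, 1] + src[2] * u[, 2])
  c0 <- src[1]^2 + src[2]^2

  # parametric [t1, t2] (clamped to [0,1]) where the segment is inside radius R
  inside_len <- function(R) {
    cc <- c0 - R^2
    disc <- b^2 - 4 * a * cc
    axial <- a < 1e-14                       # ray parallel to the axis
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    len <- ifelse(axial,
                  ifelse(cc < 0, 1, 0),      # fully inside or fully outside
                  ifelse(disc <= 0, 0,
                         pmax(0, pmin(t2, 1) - pmax(t1, 0))))
    len
  }

  f_outer <- inside_len(phantom$outer_radius)
  f_inner <- inside_len(phantom$inner_radius)
  dens_core <- core_density(phantom)
  L * ((f_outer - f_inner) * phantom$shell_density +
         f_inner * dens_core +
         (1 - f_outer) * phantom$exterior_density)
}

#' Water-equivalent (radiological) path length through the phantom
#'
#' Effective path length between two points: the geometric length of each
#' traversed region (outside, acrylic shell, central core) scaled by its
#' density relative to water, from analytic line-circle intersections.
#'
#' @param phantom a `phantom_model`.
#' @param from_point,to_point cm triples.
#' @param ray optional `ray`; when supplied, both points must lie on it
#'   (contract check).
#' @return water-equivalent depth in cm.
#' @export
radiological_path <- function(phantom, from_point, to_point, ray = NULL) {
  from_point <- as.numeric(from_point); to_point <- as.numeric(to_point)
  if (!is.null(ray)) {
    for (p in list(from_point, to_point)) {
      v <- p - ray$source_point
      off <- v - sum(v * ray$direction) * ray$direction
      if (sqrt(sum(off^2)) > 1e-6)
        stop_config("contract violation: point (%.3f, %.3f, %.3f) is not on the ray",
                    p[1], p[2], p[3])
    }
  }
  as.numeric(radiological_depth(phantom, from_point, matrix(to_point, 1)))
}

# ---- plain-text layout / phantom config I/O --------------------------------

#' Export / import a diode layout as a plain-text table
#'
#' The file carries a commented header (pitch, nominal spacing, diameter,
#' axial length, angular origin) followed by an `index x y z angle` table.
#' `read_layout` rebuilds the layout from the header and verifies the table.
#'
#' @param layout a `diode_array_layout`.
#' @param path file path.
#' @return `read_layout` returns a `diode_array_layout`.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# arcqa diode array layout",
    sprintf("# pitch_cm: %.10g", layout$pitch),
    sprintf("# nominal_spacing_cm: %.10g", layout$nominal_spacing),
    sprintf("# diameter_cm: %.10g", layout$diameter),
    sprintf("# axial_length_cm: %.10g", layout$axial_length),
    sprintf("# angular_origin_rad: %.10g", layout$angular_origin),
    "diode_index x y z angle"), con)
  utils::write.table(format(layout$diodes, digits = 10, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# [a-z_]+:", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop_config("layout file missing header field '%s'", key)
    as.numeric(sub(".*: *", "", m[1]))
  }
  layout <- build_layout(pitch = get("pitch_cm"),
                         spacing = get("nominal_spacing_cm"),
                         diameter = get("diameter_cm"),
                         axial_length = get("axial_length_cm"),
                         angular_origin = get("angular_origin_rad"))
  tab <- utils::read.table(path, comment.char = "#", header = TRUE)
  if (nrow(tab) != layout$n_diodes ||
      max(abs(as.matrix(tab[, c("x", "y", "z")]) - layout_points(layout))) > 1e-6)
    stop_config("layout table does not match its header parameters")
  layout
}

#' Write / read a phantom configuration block
#'
#' Simple `key: value` text block (YAML-style scalars) for the phantom
#' dimensions and densities.
#'
#' @param phantom a `phantom_model`.
#' @param path file path.
#' @export
write_phantom_config <- function(phantom, path) {
  flds <- c("outer_diameter", "inner_diameter", "shell_density",
            "plug_present", "plug_density", "cavity_density",
            "exterior_density")
  writeLines(c("# arcqa phantom model",
               vapply(flds, function(f)
                 sprintf("%s: %s", f, format(phantom[[f]], digits = 10)),
                 character(1))), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  lines <- grep("^[a-z_]+:", readLines(path), value = TRUE)
  kv <- strsplit(lines, ": *")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  phantom_model(outer_diameter = num("outer_diameter"),
                inner_diameter = num("inner_diameter"),
                shell_density = num("shell_density"),
                plug_present = identical(toupper(vals[["plug_present"]]), "TRUE"),
                plug_density = num("plug_density"),
                cavity_density = num("cavity_density"),
                exterior_density = num("exterior_density"))
}
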
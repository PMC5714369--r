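# Radiotherapy object I/O: DICOM-RT Plan, DICOM-RT Dose, CT-number ramp.
# Internal units are cm and Gy; DICOM stores positions in mm.

#' Arc-plan control point
#'
#' One sampled delivery state of a VMAT beam: machine angles, jaw and MLC
#' aperture (cm at the isocenter plane), and the cumulative fraction of the
#' beam meterset delivered so far.
#'
#' @param gantry_angle,collimator_angle,couch_angle degrees.
#' @param jaws `c(x1, x2, y1, y2)` cm, with `x1 <= x2`, `y1 <= y2`.
#' @param mlc 60x2 matrix of leaf tip positions, columns `A` (left bank) and
#'   `B` (right bank); per pair `A <= B`.
#' @param cumulative_weight fraction of the beam meterset in `[0, 1]`.
#' @return object of class `control_point`.
#' @export
control_point <- function(gantry_angle, collimator_angle = 0, couch_angle = 0,
                          jaws = c(-5, 5, -5, 5),
                          mlc = default_mlc_positions(),
                          cumulative_weight = 0) {
  mlc <- as.matrix(mlc)
  if (!all(dim(mlc) == c(60, 2))) stop_config("mlc must be a 60x2 matrix")
  colnames(mlc) <- c("A", "B")
  if (any(mlc[, "A"] > mlc[, "B"] + 1e-9))
    stop_config("MLC bank A positions must not exceed bank B")
  if (jaws[1] > jaws[2] || jaws[3] > jaws[4])
    stop_config("jaws must satisfy x1 <= x2 and y1 <= y2")
  structure(list(gantry_angle = gantry_angle %% 360,
                 collimator_angle = collimator_angle %% 360,
                 couch_angle = couch_angle %% 360,
                 jaws = as.numeric(jaws), mlc = mlc,
                 cumulative_weight = cumulative_weight),
            class = "control_point")
}

default_mlc_positions <- function(open = 5) {
  cbind(A = rep(-open, 60), B = rep(open, 60))
}

#' Arc plan container
#'
#' @param beams list of beams; each beam is a list with `control_points`
#'   (list of [control_point()]), `mu` (total beam meterset, MU) and `energy`
#'   (label such as `"6X"`).
#' @return object of class `arc_plan`.
#' @export
arc_plan <- function(beams) {
  plan <- structure(list(beams = beams), class = "arc_plan")
  validate_plan(plan)
  plan
}

#' Validate an arc plan
#'
#' Checks the control-point invariants: at least two control points per
#' beam, cumulative weights nondecreasing from 0 to 1, and MLC banks not
#' crossing. Errors name the offending beam and control point.
#'
#' @param plan an `arc_plan`.
#' @return the plan, invisibly.
#' @export
validate_plan <- function(plan) {
  for (bi in seq_along(plan$beams)) {
    beam <- plan$beams[[bi]]
    cps <- beam$control_points
    if (length(cps) < 2)
      stop_config("beam %d: needs at least 2 control points", bi)
    if (is.null(beam$mu) || beam$mu < 0)
      stop_config("beam %d: missing or negative meterset", bi)
    w <- vapply(cps, `[[`, numeric(1), "cumulative_weight")
    if (abs(w[1]) > 1e-6)
      stop_config("beam %d control point 1: first cumulative weight must be 0", bi)
    if (abs(w[length(w)] - 1) > 1e-6)
      stop_config("beam %d control point %d: last cumulative weight must be 1",
                  bi, length(w))
    bad <- which(diff(w) < -1e-9)
    if (length(bad))
      stop_config("beam %d control point %d: cumulative weights not nondecreasing",
                  bi, bad[1] + 1)
    for (ci in seq_along(cps)) {
      m <- cps[[ci]]$mlc
      if (any(m[, "A"] > m[, "B"] + 1e-9))
        stop_config("beam %d control point %d: MLC banks cross", bi, ci)
    }
  }
  invisible(plan)
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf("<arc_plan> %d beam(s)\n", length(x$beams)))
  for (b in x$beams)
    cat(sprintf("  %s, %.4g MU, %d control points\n",
                b$energy %||% "?", b$mu, length(b$control_points)))
  invisible(x)
}

#' 3D dose grid
#'
#' Absolute dose on a rectilinear, axis-aligned grid. `values[i, j, k]` is
#' the dose at `origin + (i-1, j-1, k-1) * spacing` (voxel centers), axes in
#' the fixed frame order x (right-left), y (anterior-posterior),
#' z (superior-inferior).
#'
#' @param values 3D array, Gy, nonnegative.
#' @param origin cm triple: center of voxel `[1, 1, 1]`.
#' @param spacing cm triple, all positive.
#' @param axes orientation labels; only the identity orientation
#'   `c("x", "y", "z")` is supported.
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing, axes = c("x", "y", "z")) {
  if (length(dim(values)) != 3) stop_config("values must be a 3D array")
  if (any(values < 0)) stop_config("dose values must be nonnegative")
  if (any(spacing <= 0)) stop_config("grid spacing must be positive")
  if (!identical(axes, c("x", "y", "z")))
    stop_config("only the axis-aligned x/y/z orientation is supported")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), axes = axes),
            class = "dose_grid")
}

grid_axis <- function(grid, i) {
  grid$origin[i] + (seq_len(dim(grid$values)[i]) - 1) * grid$spacing[i]
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) cm, max %.4g Gy\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              max(x$values)))
  invisible(x)
}

# trilinear interpolation of a dose grid at points (n x 3 cm); points outside
# the grid raise an error listing the offending row indices
interp_grid <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(grid$values)
  fi <- lapply(1:3, function(a) (pts[, a] - grid$origin[a]) / grid$spacing[a])
  out_of_range <- Reduce(`|`, lapply(1:3, function(a)
    fi[[a]] < -1e-9 | fi[[a]] > d[a] - 1 + 1e-9))
  if (any(out_of_range))
    stop_config("points outside dose grid: indices %s",
                paste(utils::head(which(out_of_range), 20), collapse = ", "))
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(fi[[a]]), 0), d[a] - 2))
  fr <- lapply(1:3, function(a) pmin(pmax(fi[[a]] - i0[[a]], 0), 1))
  v <- grid$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[[1]] + 1 + dx, i0[[2]] + 1 + dy, i0[[3]] + 1 + dz)]
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  (idx(0, 0, 0) * (1 - fx) + idx(1, 0, 0) * fx) * (1 - fy) * (1 - fz) +
    (idx(0, 1, 0) * (1 - fx) + idx(1, 1, 0) * fx) * fy * (1 - fz) +
    (idx(0, 0, 1) * (1 - fx) + idx(1, 0, 1) * fx) * (1 - fy) * fz +
    (idx(0, 1, 1) * (1 - fx) + idx(1, 1, 1) * fx) * fy * fz
}

# ---- DICOM-RT Plan ---------------------------------------------------------

#' Write / read a DICOM-RT Plan
#'
#' Serializes an [arc_plan()] to a DICOM-RT Plan file (explicit VR little
#' endian) with per-control-point gantry/collimator/couch angles, jaw and
#' 120-leaf MLC positions and cumulative meterset weights, and reads it back.
#' Round trips preserve angles, positions and weights to better than 1e-4
#' and the beam meterset exactly at the stored decimal precision.
#'
#' @param plan an `arc_plan`.
#' @param path file path.
#' @param boundaries 61 leaf-edge positions (cm) stored with each beam;
#'   defaults to the Millennium-style 120-leaf layout of [mlc_model()].
#' @return `read_plan` returns an `arc_plan`.
#' @export
write_plan <- function(plan, path, boundaries = NULL) {
  validate_plan(plan)
  if (is.null(boundaries)) boundaries <- mlc_model()$boundaries
  uid <- dcm_uid(paste0("plan:", length(plan$beams), ":",
                        paste(vapply(plan$beams, function(b)
                          sprintf("%.6f", b$mu), character(1)), collapse = ",")))
  beam_items <- lapply(seq_along(plan$beams), function(bi) {
    beam <- plan$beams[[bi]]
    cp_items <- lapply(seq_along(beam$control_points), function(ci) {
      cp <- beam$control_points[[ci]]
      bld_items <- list(
        c(dcm_element(0x300A, 0x00B8, "CS", enc_txt("ASYMX")),
          dcm_element(0x300A, 0x011C, "DS", enc_ds(cp$jaws[1:2] * 10))),
        c(dcm_element(0x300A, 0x00B8, "CS", enc_txt("ASYMY")),
          dcm_element(0x300A, 0x011C, "DS", enc_ds(cp$jaws[3:4] * 10))),
        c(dcm_element(0x300A, 0x00B8, "CS", enc_txt("MLCX")),
          dcm_element(0x300A, 0x011C, "DS",
                      enc_ds(c(cp$mlc[, "A"], cp$mlc[, "B"]) * 10)))
      )
      c(dcm_element(0x300A, 0x0112, "IS", enc_is(ci - 1)),
        dcm_sequence(0x300A, 0x011A, bld_items),
        dcm_element(0x300A, 0x011E, "DS", enc_ds(cp$gantry_angle)),
        dcm_element(0x300A, 0x0120, "DS", enc_ds(cp$collimator_angle)),
        dcm_element(0x300A, 0x0122, "DS", enc_ds(cp$couch_angle)),
        dcm_element(0x300A, 0x0134, "DS", enc_ds(cp$cumulative_weight)))
    })
    c(dcm_element(0x300A, 0x00C0, "IS", enc_is(bi)),
      dcm_element(0x300A, 0x00C2, "LO", enc_txt(beam$energy %||% "6X")),
      dcm_sequence(0x300A, 0x00B6, list(
        c(dcm_element(0x300A, 0x00B8, "CS", enc_txt("MLCX")),
          dcm_element(0x300A, 0x00BC, "IS", enc_is(60)),
          dcm_element(0x300A, 0x00BE, "DS", enc_ds(boundaries * 10))))),
      dcm_element(0x300A, 0x010E, "DS", enc_ds(1)),
      dcm_element(0x300A, 0x0110, "IS", enc_is(length(beam$control_points))),
      dcm_sequence(0x300A, 0x0111, cp_items))
  })
  fg_items <- list(c(
    dcm_element(0x300A, 0x0078, "IS", enc_is(1)),
    dcm_sequence(0x300C, 0x0004, lapply(seq_along(plan$beams), function(bi)
      c(dcm_element(0x300A, 0x0086, "DS", enc_ds(plan$beams[[bi]]$mu)),
        dcm_element(0x300C, 0x0006, "IS", enc_is(bi)))))))
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", enc_ui(UID_RTPLAN)),
    dcm_element(0x0008, 0x0018, "UI", enc_ui(uid)),
    dcm_element(0x0008, 0x0060, "CS", enc_txt("RTPLAN")),
    dcm_element(0x300A, 0x0002, "SH", enc_txt("arcqa")),
    dcm_sequence(0x300A, 0x0070, fg_items),
    dcm_sequence(0x300A, 0x00B0, beam_items)
  )
  dcm_write_file(path, UID_RTPLAN, uid, dataset)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  ds <- dcm_read_file(path)
  modality <- ds[["00080060"]]
  if (!identical(modality, "RTPLAN"))
    stop_config("not a DICOM-RT Plan (modality %s)", modality %||% "missing")
  beam_items <- dcm_get(ds, "300A00B0", "BeamSequence")
  # beam metersets from the fraction-group sequence
  mu_by_beam <- list()
  fg <- ds[["300A0070"]]
  if (!is.null(fg)) {
    for (it in fg) for (rb in it[["300C0004"]] %||% list()) {
      num <- rb[["300C0006"]]
      if (!is.null(num)) mu_by_beam[[as.character(num)]] <- rb[["300A0086"]]
    }
  }
  beams <- lapply(seq_along(beam_items), function(bi) {
    b <- beam_items[[bi]]
    beam_num <- b[["300A00C0"]] %||% bi
    cps_raw <- dcm_get(b, "300A0111", sprintf("beam %d ControlPointSequence", bi))
    final_w <- b[["300A010E"]] %||% 1
    prev <- list(jaws = NULL, mlc = NULL, gantry = 0, colli = 0, couch = 0)
    cps <- vector("list", length(cps_raw))
    for (ci in seq_along(cps_raw)) {
      cp <- cps_raw[[ci]]
      for (bld in cp[["300A011A"]] %||% list()) {
        type <- bld[["300A00B8"]]
        pos <- bld[["300A011C"]] / 10
        if (identical(type, "ASYMX")) prev$jaws[1:2] <- pos
        else if (identical(type, "ASYMY")) prev$jaws[3:4] <- pos
        else if (identical(type, "MLCX")) {
          if (length(pos) != 120)
            stop_config("beam %d control point %d: MLCX must carry 120 positions",
                        bi, ci)
          prev$mlc <- cbind(A = pos[1:60], B = pos[61:120])
        }
      }
      if (ci == 1 && is.null(prev$mlc))
        stop_config("beam %d: missing MLC sequence in control point 1", bi)
      prev$gantry <- cp[["300A011E"]] %||% prev$gantry
      prev$colli <- cp[["300A0120"]] %||% prev$colli
      prev$couch <- cp[["300A0122"]] %||% prev$couch
      w_raw <- cp[["300A0134"]]
      if (is.null(w_raw))
        stop_config("beam %d control point %d: missing cumulative meterset weight",
                    bi, ci)
      cps[[ci]] <- control_point(prev$gantry, prev$colli, prev$couch,
                                 jaws = prev$jaws, mlc = prev$mlc,
                                 cumulative_weight = w_raw / final_w)
    }
    mu <- mu_by_beam[[as.character(beam_num)]]
    if (is.null(mu)) stop_config("beam %d: missing beam meterset", bi)
    list(control_points = cps, mu = mu, energy = b[["300A00C2"]] %||% "6X")
  })
  arc_plan(beams)
}

# ---- DICOM-RT Dose ---------------------------------------------------------

#' Write / read a DICOM-RT Dose grid
#'
#' Stores the grid with DICOM-RT Dose semantics: 32-bit unsigned voxels times
#' a `DoseGridScaling` factor, frames along z with a grid frame offset
#' vector, pixel rows along y and columns along x. Round trips are exact to
#' within one quantization step of the chosen scaling.
#'
#' @param grid a [dose_grid()].
#' @param path file path.
#' @return `read_dose` returns a `dose_grid`.
#' @export
write_dose <- function(grid, path) {
  d <- dim(grid$values)
  maxv <- max(grid$values)
  scaling <- if (maxv > 0) maxv / (2^31 - 1) else 1
  ints <- as.integer(round(grid$values / scaling))
  uid <- dcm_uid(sprintf("dose:%d:%d:%d:%.8g", d[1], d[2], d[3], maxv))
  offsets <- (seq_len(d[3]) - 1) * grid$spacing[3] * 10
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", enc_ui(UID_RTDOSE)),
    dcm_element(0x0008, 0x0018, "UI", enc_ui(uid)),
    dcm_element(0x0008, 0x0060, "CS", enc_txt("RTDOSE")),
    dcm_element(0x0020, 0x0032, "DS", enc_ds(grid$origin * 10)),
    dcm_element(0x0020, 0x0037, "DS", enc_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", enc_us(1)),
    dcm_element(0x0028, 0x0008, "IS", enc_is(d[3])),
    dcm_element(0x0028, 0x0010, "US", enc_us(d[2])),       # rows = y
    dcm_element(0x0028, 0x0011, "US", enc_us(d[1])),       # columns = x
    dcm_element(0x0028, 0x0030, "DS", enc_ds(c(grid$spacing[2], grid$spacing[1]) * 10)),
    dcm_element(0x0028, 0x0100, "US", enc_us(32)),
    dcm_element(0x0028, 0x0101, "US", enc_us(32)),
    dcm_element(0x0028, 0x0102, "US", enc_us(31)),
    dcm_element(0x0028, 0x0103, "US", enc_us(0)),
    dcm_element(0x3004, 0x0002, "CS", enc_txt("GY")),
    dcm_element(0x3004, 0x0004, "CS", enc_txt("PHYSICAL")),
    dcm_element(0x3004, 0x000A, "CS", enc_txt("PLAN")),
    dcm_element(0x3004, 0x000C, "DS", enc_ds(offsets)),
    dcm_element(0x3004, 0x000E, "DS", enc_txt(sprintf("%.16g", scaling))),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(ints, raw(), size = 4, endian = "little"))
  )
  dcm_write_file(path, UID_RTDOSE, uid, dataset)
}

#' @rdname write_dose
#' @export
read_dose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(ds[["00080060"]], "RTDOSE"))
    stop_config("not a DICOM-RT Dose (modality %s)", ds[["00080060"]] %||% "missing")
  orient <- ds[["00200037"]] %||% c(1, 0, 0, 0, 1, 0)
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-9)
    stop_config("oblique dose-grid orientations are not supported")
  nx <- dcm_get(ds, "00280011", "Columns")
  ny <- dcm_get(ds, "00280010", "Rows")
  nz <- dcm_get(ds, "00280008", "NumberOfFrames")
  offsets <- dcm_get(ds, "3004000C", "GridFrameOffsetVector") / 10
  if (nz > 1) {
    dz <- diff(offsets)
    if (max(abs(dz - dz[1])) > 1e-6)
      stop_config("nonuniform grid-frame offsets are not supported")
    dz <- dz[1]
  } else dz <- 1
  scaling <- dcm_get(ds, "3004000E", "DoseGridScaling")
  if (is.character(scaling)) scaling <- as.numeric(scaling)
  ipp <- dcm_get(ds, "00200032", "ImagePositionPatient") / 10
  px <- dcm_get(ds, "00280030", "PixelSpacing") / 10 # (row, col) = (y, x)
  pix <- ds[["7FE00010"]]
  if (is.null(pix)) stop_config("parse error: missing PixelData")
  ints <- readBin(pix, "integer", n = nx * ny * nz, size = 4, endian = "little")
  vals <- array(ints * scaling, dim = c(nx, ny, nz))
  dose_grid(vals, origin = ipp, spacing = c(px[2], px[1], dz))
}

# ---- CT number to density ramp ---------------------------------------------

#' Piecewise-linear CT-number to density ramp
#'
#' @param knots data frame with columns `ct` (strictly increasing CT numbers)
#'   and `density` (g/cc, nonnegative).
#' @return object of class `density_ramp`.
#' @export
density_ramp <- function(knots) {
  knots <- as.data.frame(knots)
  if (nrow(knots) < 2) stop_config("ramp needs at least 2 knots")
  if (any(diff(knots$ct) <= 0)) stop_config("CT numbers must be strictly increasing")
  if (any(knots$density < 0)) stop_config("densities must be nonnegative")
  structure(list(knots = knots), class = "density_ramp")
}

#' Default stand-in CT ramp
#'
#' A synthetic air / water / acrylic-like ramp. The scanner-specific
#' megavoltage-CT ramp of the physical device is not published, so this
#' default is a documented stand-in; supply a measured ramp via
#' [density_ramp()] for real data.
#'
#' @return a `density_ramp`.
#' @export
default_density_ramp <- function() {
  density_ramp(data.frame(ct = c(-1000, 0, 170),
                          density = c(0.0012, 1.0, 1.17)))
}

#' Convert CT numbers to densities
#'
#' Linear interpolation between ramp knots, clamped to the end densities
#' outside the knot range.
#'
#' @param ramp a [density_ramp()].
#' @param ct_number numeric vector of CT numbers.
#' @return densities in g/cc.
#' @export
hu_to_density <- function(ramp, ct_number) {
  stats::approx(ramp$knots$ct, ramp$knots$density, xout = ct_number,
                method = "linear", rule = 2)$y
}
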
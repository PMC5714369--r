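# Simplified primary-ray dose engine: TMR with effective path lengths and
# inverse-square corrections. A desk-scale stand-in for Monte Carlo / TPS /
# measurement: no scatter kernels, no source model, flat in-field profile.

#' Photon beam model
#'
#' Calibration and depth-dose behavior of the virtual linac: 1 cGy/MU at
#' `dmax` for a 10x10 cm2 field at 100 cm SSD (TG-51 style), an analytic
#' tissue-maximum ratio (linear buildup to `dmax`, then exponential falloff
#' with an effective attenuation coefficient), and the source-axis distance.
#' A tabulated TMR may be supplied instead of the analytic default.
#'
#' @param energy label; `"6X"` (dmax 1.5 cm, 0.035/cm) and `"10X"`
#'   (dmax 2.5 cm, 0.0275/cm) carry built-in defaults.
#' @param dmax depth of maximum dose, cm.
#' @param atten_coef effective attenuation coefficient beyond dmax, 1/cm.
#' @param calibration dose per MU at dmax for the reference field, cGy/MU.
#' @param sad source-axis distance, cm.
#' @param tmr optional `function(depth_cm, field_size_cm)`; must equal 1 at
#'   `(dmax, 10)`.
#' @param tmr_table optional data frame `depth`, `tmr` interpolated linearly
#'   (clamped outside the knots); must equal 1 at dmax within 1e-6.
#' @return object of class `beam_model`.
#' @export
beam_model <- function(energy = "6X", dmax = NULL, atten_coef = NULL,
                       calibration = 1, sad = 100, tmr = NULL,
                       tmr_table = NULL) {
  defaults <- list(`6X` = c(dmax = 1.5, atten = 0.035),
                   `10X` = c(dmax = 2.5, atten = 0.0275))
  def <- defaults[[energy]] %||% defaults[["6X"]]
  dmax <- dmax %||% unname(def["dmax"])
  atten_coef <- atten_coef %||% unname(def["atten"])
  if (!is.null(tmr_table)) {
    f <- stats::approxfun(tmr_table$depth, tmr_table$tmr, rule = 2)
    if (abs(f(dmax) - 1) > 1e-6)
      stop_config("tabulated TMR must equal 1 at dmax = %.3g cm", dmax)
    tmr <- function(depth, field_size = 10) f(depth)
  }
  if (is.null(tmr)) {
    tmr <- function(depth, field_size = 10) {
      ifelse(depth <= 0, 0,
             ifelse(depth < dmax, depth / dmax,
                    exp(-atten_coef * (depth - dmax))))
    }
  } else {
    if (abs(tmr(dmax, 10) - 1) > 1e-6)
      stop_config("TMR(dmax, 10) must equal 1")
  }
  structure(list(energy = energy, dmax = dmax, atten_coef = atten_coef,
                 calibration = calibration, sad = sad, tmr = tmr),
            class = "beam_model")
}

# beam-frame unit vectors in the phantom frame for gantry/couch angles (deg):
# sv points isocenter -> source, beam travel = -sv, e1 crossplane (leaf
# travel), e2 leaf-stacking (cylinder axis for coplanar beams). A setup
# misalignment of the phantom set maps the beam into the phantom frame by
# the inverse transform (rotating the frame and moving the source).
beam_frame <- function(gantry, couch = 0, setup = NULL, sad = 100) {
  g <- deg2rad(gantry)
  f <- rbind(sv = c(sin(g), cos(g), 0),
             e1 = c(cos(g), -sin(g), 0),
             e2 = c(0, 0, 1))
  if (couch != 0) f <- rotate_y(f, -couch)
  src <- sad * f[1, ]
  if (!is.null(setup)) {
    inv <- invert_transform(setup)
    src <- as.numeric(transform_points(inv, src))
    f <- transform_directions(inv, f)
  }
  list(sv = f[1, ], e1 = f[2, ], e2 = f[3, ], src = src)
}

#' Dose at arbitrary points from a set of beam projections
#'
#' The core ray engine. For each projection (a [render_fluence()] /
#' [accumulate_fluence()] map with its gantry, collimator and couch angles)
#' and each point, the dose contribution is
#' `meterset x calibration x fluence(ray) x TMR(d_eff) x (SAD / r)^2`,
#' where `d_eff` is the water-equivalent depth from the source through the
#' phantom and `r` the source-to-point distance. Deterministic.
#'
#' @param points n x 3 matrix, cm (phantom frame).
#' @param projections list of `fluence_map` objects.
#' @param beam a [beam_model()].
#' @param phantom a [phantom_model()].
#' @param setup optional [rigid_transform()] applied to the phantom+detector
#'   set; the beams are inverse-transformed into the phantom frame.
#' @return dose vector, cGy per the calibration units.
#' @export
dose_at_points <- function(points, projections, beam, phantom, setup = NULL) {
  points <- matrix(points, ncol = 3)
  total <- numeric(nrow(points))
  for (proj in projections) {
    if (proj$meterset <= 0) next
    fr <- beam_frame(proj$gantry, proj$couch_angle %||% 0, setup, beam$sad)
    src <- fr$src
    w <- sweep(points, 2, src)
    zeta <- w %*% fr$sv * (-1) # depth along beam axis from the source
    zeta <- as.numeric(zeta)
    ok <- zeta > 1e-6
    xi <- as.numeric(w %*% fr$e1) * beam$sad / zeta
    eta <- as.numeric(w %*% fr$e2) * beam$sad / zeta
    kap <- deg2rad(proj$collimator_angle %||% 0)
    if (kap != 0) {
      xi2 <- xi * cos(kap) + eta * sin(kap)
      eta <- -xi * sin(kap) + eta * cos(kap)
      xi <- xi2
    }
    f <- fluence_at(proj, xi, eta)
    active <- ok & f > 0
    if (!any(active)) next
    deff <- radiological_depth(phantom, src, points[active, , drop = FALSE])
    r2 <- rowSums(w[active, , drop = FALSE]^2)
    total[active] <- total[active] +
      proj$meterset * beam$calibration * f[active] *
      beam$tmr(deff, proj$field_size %||% 10) * beam$sad^2 / r2
  }
  total
}

#' Compute a 3D dose grid
#'
#' Runs [dose_at_points()] over the voxel centers of a rectilinear grid.
#'
#' @param projections list of `fluence_map` objects.
#' @param beam a [beam_model()].
#' @param phantom a [phantom_model()].
#' @param grid list with `origin` (cm triple, first voxel center), `spacing`
#'   (cm triple) and `dims` (integer triple).
#' @param setup optional [rigid_transform()] of the phantom set.
#' @return a [dose_grid()]; values are in the calibration unit (cGy for the
#'   default 1 cGy/MU calibration).
#' @export
compute_dose_grid <- function(projections, beam, phantom, grid, setup = NULL) {
  axes <- lapply(1:3, function(i)
    grid$origin[i] + (seq_len(grid$dims[i]) - 1) * grid$spacing[i])
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  d <- dose_at_points(pts, projections, beam, phantom, setup = setup)
  dose_grid(array(d, dim = grid$dims), origin = grid$origin,
            spacing = grid$spacing)
}

#' Open static field as a single projection
#'
#' Convenience wrapper building the fluence map of an open square field with
#' all leaves retracted behind the jaws.
#'
#' @param field side length, cm (or `c(x, y)` lengths).
#' @param mu meterset, MU.
#' @param gantry,collimator,couch angles in degrees.
#' @param mlc an [mlc_model()].
#' @param spacing fluence grid spacing, cm.
#' @return a `fluence_map`.
#' @export
open_field_projection <- function(field = 10, mu = 100, gantry = 0,
                                  collimator = 0, couch = 0,
                                  mlc = mlc_model(), spacing = 0.25) {
  field <- rep(field, length.out = 2)
  sf <- structure(list(
    mlc = cbind(A = rep(-field[1] / 2, 60), B = rep(field[1] / 2, 60)),
    jaws = c(-field[1] / 2, field[1] / 2, -field[2] / 2, field[2] / 2),
    meterset = mu, gantry_span = c(gantry, gantry),
    representative_gantry = gantry, collimator_angle = collimator,
    couch_angle = couch), class = "subfield")
  m <- mlc
  m$rounded_leaf_end_offset <- 0 # leaves parked at the jaw edge: clean field
  render_fluence(sf, m, spacing)
}

# ---- TMR / inverse-square diode prediction --------------------------------

#' Predict diode doses from a central reference dose
#'
#' The absolute-dose calibration chain of the cylindrical array: given a
#' known dose at the phantom center (isocenter, SAD setup), the dose at each
#' diode is `D_center x TMR(d_diode) / TMR(d_center) x (SAD / r_diode)^2`,
#' with effective depths from [radiological_path()] (acrylic scaled to
#' water). Diodes outside the beam are flagged, not computed.
#'
#' @param center_dose cGy at the isocenter.
#' @param beam a [beam_model()].
#' @param phantom a [phantom_model()].
#' @param layout a [build_layout()] layout.
#' @param gantry_angle degrees.
#' @param field_size square field side, cm.
#' @return data frame `diode_index`, `dose_cgy` (NA outside the beam),
#'   `in_beam`, `entrance`.
#' @export
diode_dose_from_center <- function(center_dose, beam, phantom, layout,
                                   gantry_angle, field_size = 10) {
  fr <- beam_frame(gantry_angle, 0, sad = beam$sad)
  src <- fr$src
  pts <- layout_points(layout)
  w <- sweep(pts, 2, src)
  zeta <- -as.numeric(w %*% fr$sv)
  xi <- as.numeric(w %*% fr$e1) * beam$sad / zeta
  eta <- as.numeric(w %*% fr$e2) * beam$sad / zeta
  in_beam <- zeta > 0 & abs(xi) <= field_size / 2 + 1e-9 &
    abs(eta) <= field_size / 2 + 1e-9
  d_center <- radiological_path(phantom, src, c(0, 0, 0))
  deff <- radiological_depth(phantom, src, pts)
  r2 <- rowSums(w^2)
  dose <- center_dose * beam$tmr(deff, field_size) /
    beam$tmr(d_center, field_size) * beam$sad^2 / r2
  dose[!in_beam] <- NA_real_
  masks <- entrance_exit_masks(layout, gantry_angle %% 360)
  data.frame(diode_index = layout$diodes$diode_index, dose_cgy = dose,
             in_beam = in_beam, entrance = masks$entrance)
}

# ---- detector response and perturbations ----------------------------------

#' Diode angular-response model
#'
#' Relative response as a function of the angle between the beam travel
#' direction and the diode's outward normal: a symmetric raised-cosine lobe
#' `1 - amplitude * sin^2(alpha)`, equal to 1 at normal incidence through
#' either face and maximally depressed (by `amplitude`) at grazing
#' incidence. The vendor correction is modeled as division by the same
#' factor, so an enabled correction with a matching model recovers the
#' unperturbed reading exactly.
#'
#' @param amplitude maximum fractional response deviation (default 0.08).
#' @param enabled apply the response perturbation?
#' @param correction apply the (perfect-model) correction?
#' @return object of class `angular_response`.
#' @export
angular_response <- function(amplitude = 0.08, enabled = TRUE,
                             correction = FALSE) {
  if (amplitude < 0 || amplitude >= 1) stop_config("amplitude must lie in [0, 1)")
  structure(list(amplitude = amplitude, enabled = isTRUE(enabled),
                 correction = isTRUE(correction)),
            class = "angular_response")
}

angular_factor <- function(angular, layout, beam_direction) {
  n <- cbind(layout$diodes$x, layout$diodes$y, 0) / layout$radius
  b <- beam_direction / sqrt(sum(beam_direction^2))
  cosa <- pmin(pmax(n %*% b, -1), 1)
  1 - angular$amplitude * (1 - as.numeric(cosa)^2)
}

#' Virtual diode readings
#'
#' Samples a dose distribution at the diode positions (trilinear from a
#' [dose_grid()], or a direct-ray dose function) and applies the detector
#' model: angular response (if enabled), its correction (if enabled) and
#' multiplicative Gaussian noise. Stochastic paths require an explicit seed
#' and leave the caller's RNG state untouched.
#'
#' @param dose a `dose_grid`, or `function(points)` returning dose, or a
#'   numeric vector of per-diode doses.
#' @param layout a [build_layout()] layout.
#' @param angular an [angular_response()]; needs `beam_direction` when
#'   enabled.
#' @param beam_direction unit beam travel direction in the phantom frame.
#' @param noise_sd fractional Gaussian noise standard deviation.
#' @param seed integer; required when `noise_sd > 0`.
#' @return numeric vector of readings, one per diode.
#' @export
virtual_diode_readings <- function(dose, layout,
                                   angular = angular_response(enabled = FALSE),
                                   beam_direction = NULL,
                                   noise_sd = 0, seed = NULL) {
  pts <- layout_points(layout)
  base <- if (inherits(dose, "dose_grid")) interp_grid(dose, pts)
  else if (is.function(dose)) dose(pts)
  else if (is.numeric(dose) && length(dose) == layout$n_diodes) dose
  else stop_config("dose must be a dose_grid, a function, or a per-diode vector")
  reading <- base
  if (angular$enabled || angular$correction) {
    if (is.null(beam_direction))
      stop_config("beam_direction is required when the angular model is active")
    fac <- angular_factor(angular, layout, beam_direction)
    if (angular$enabled) reading <- reading * fac
    if (angular$correction) reading <- reading / fac
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop_config("stochastic readings require an explicit seed")
    noise <- with_seed(seed, stats::rnorm(length(reading), 0, noise_sd))
    reading <- reading * (1 + noise)
  }
  reading
}

# ---- rigid setup transforms ------------------------------------------------

#' Rigid setup misalignment
#'
#' Translation given in patient axes (AP = anterior-posterior = +y,
#' RL = right-left = +x, SI = superior-inferior = +z) plus a rotation about
#' the cylinder axis (default) or the vertical axis (couch yaw).
#'
#' @param translation cm triple `c(AP, RL, SI)`.
#' @param rotation degrees in `(-180, 180]`.
#' @param axis `"cylinder"` (z) or `"vertical"` (y).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = 0,
                            axis = c("cylinder", "vertical")) {
  axis <- match.arg(axis)
  if (rotation <= -180 || rotation > 180)
    stop_config("rotation must lie in (-180, 180]")
  structure(list(translation = as.numeric(translation), rotation = rotation,
                 axis = axis,
                 # internal xyz order: x = RL, y = AP, z = SI
                 t_xyz = c(translation[2], translation[1], translation[3])),
            class = "rigid_transform")
}

transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  if (transform$rotation != 0) {
    pts <- if (transform$axis == "cylinder") rotate_z(pts, transform$rotation)
    else rotate_y(pts, transform$rotation)
  }
  sweep(pts, 2, transform$t_xyz, `+`)
}

transform_directions <- function(transform, dirs) {
  if (transform$rotation == 0) return(matrix(dirs, ncol = 3))
  if (transform$axis == "cylinder") rotate_z(matrix(dirs, ncol = 3), transform$rotation)
  else rotate_y(matrix(dirs, ncol = 3), transform$rotation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform` (rotation applied after the negated
#'   translation, so `apply_misalignment(inv, apply_misalignment(t, x))`
#'   recovers `x` to 1e-12).
#' @export
invert_transform <- function(transform) {
  # inverse of x -> R x + t is x -> R^-1 (x - t); fold R^-1 t into t_xyz
  inv <- rigid_transform(rotation = -transform$rotation, axis = transform$axis)
  ti <- -transform_directions(inv, transform$t_xyz)
  inv$t_xyz <- as.numeric(ti)
  inv$translation <- c(inv$t_xyz[2], inv$t_xyz[1], inv$t_xyz[3])
  inv
}

#' Apply a rigid misalignment to detector geometry
#'
#' Rigidly moves diode positions (a layout), a point matrix, or a phantom
#' (recorded as a `setup` attribute used by the dose engine, since the
#' analytic phantom stays axis-aligned internally).
#'
#' @param transform a [rigid_transform()].
#' @param x a `diode_array_layout`, an n x 3 point matrix, or a
#'   `phantom_model`.
#' @return the transformed object.
#' @export
apply_misalignment <- function(transform, x) {
  if (inherits(x, "diode_array_layout")) {
    p <- transform_points(transform, layout_points(x))
    x$diodes$x <- p[, 1]; x$diodes$y <- p[, 2]; x$diodes$z <- p[, 3]
    if (transform$axis == "cylinder")
      x$diodes$angle <- (x$diodes$angle + deg2rad(transform$rotation)) %% (2 * pi)
    attr(x, "setup") <- transform
    return(x)
  }
  if (inherits(x, "phantom_model")) {
    attr(x, "setup") <- transform
    return(x)
  }
  transform_points(transform, x)
}

# ---- fixture generation ----------------------------------------------------

# aperture builders: x-tips per control point for the modulation patterns
fixture_apertures <- function(pattern, n_cp, field, rng_jitter = 0) {
  half <- field / 2
  k <- seq_len(n_cp) - 1
  frac <- k / (n_cp - 1)
  a <- rep(-half, n_cp)
  b <- rep(half, n_cp)
  if (pattern == "wedge") {
    # sliding-window sweep (dynamic-wedge style): both leaf edges travel, so
    # no aperture edge is static across the arc. Integrated fluence rises
    # 0 -> 1 over [-half, -1.5], is flat within |x| < 1.5 cm (low-gradient
    # center for the chamber probe) and falls 1 -> 0 over [1.5, half].
    sweep_len <- half - 1.5
    a <- -half + sweep_len * frac
    b <- pmin(half, 1.5 + sweep_len * frac)
  } else if (pattern == "multiseg") {
    # three static segments with unequal weights: stepped fluence
    seg <- cut(frac, c(-0.01, 0.5, 0.8, 1.01), labels = FALSE)
    a <- c(-half, -1.5, 1.5)[seg]
    b <- c(-1.5, 1.5, half)[seg]
  } else if (pattern == "arcsweep") {
    # 6 cm window whose center oscillates with gantry (5 cycles per arc):
    # a smoothly gantry-correlated modulation giving a strongly nonuniform
    # peripheral dose with a flat center (the window always covers the
    # chamber), the desk-scale analog of a modulated clinical arc
    cc <- 2 * sin(2 * pi * 5 * frac)
    a <- pmax(-half, cc - 3)
    b <- pmin(half, cc + 3)
  }
  if (rng_jitter > 0) {
    a <- a + stats::runif(n_cp, -rng_jitter, rng_jitter)
    b <- pmax(a + 0.05, b + stats::runif(n_cp, -rng_jitter, rng_jitter))
  }
  list(a = a, b = b)
}

#' Build a synthetic arc plan
#'
#' A full arc with `n_cp` equally spaced control points and one of four
#' modulation patterns: `"open"` (static square field), `"wedge"`
#' (sliding-window sweep whose integrated fluence is flat in the central
#' +/-1.5 cm and wedge-shaped on both flanks), `"multiseg"` (three static
#' segments carrying 50/30/20% of the meterset) or `"arcsweep"` (a 6 cm
#' window oscillating with gantry angle, giving smooth, strongly nonuniform
#' peripheral dose and a flat low-gradient center; used by the misalignment
#' study).
#'
#' @param pattern `"open"`, `"wedge"`, `"multiseg"` or `"arcsweep"`.
#' @param n_cp number of control points (default 177).
#' @param field square field side, cm.
#' @param mu beam meterset, MU.
#' @param energy beam energy label.
#' @param gantry_start first control point's gantry angle; the arc spans a
#'   full revolution.
#' @param jitter cm of uniform random leaf-tip jitter (0 disables; any
#'   nonzero value requires the caller to seed via [make_fixtures()]).
#' @return an [arc_plan()] with one beam.
#' @export
fixture_plan <- function(pattern = c("open", "wedge", "multiseg", "arcsweep"),
                         n_cp = 177, field = 10, mu = 100, energy = "6X",
                         gantry_start = 180, jitter = 0) {
  pattern <- match.arg(pattern)
  tips <- fixture_apertures(pattern, n_cp, field, jitter)
  half <- field / 2
  mlc0 <- mlc_model()
  centers <- (mlc0$boundaries[-1] + mlc0$boundaries[-61]) / 2
  open_pair <- abs(centers) < half
  k <- seq_len(n_cp) - 1
  gantry <- (gantry_start + 360 * k / (n_cp - 1)) %% 360
  weights <- k / (n_cp - 1)
  cps <- lapply(seq_len(n_cp), function(i) {
    mlc <- cbind(A = rep(-half, 60), B = rep(-half, 60)) # parked closed
    mlc[open_pair, "A"] <- tips$a[i]
    mlc[open_pair, "B"] <- pmax(tips$b[i], tips$a[i])
    control_point(gantry_angle = gantry[i], jaws = c(-half, half, -half, half),
                  mlc = mlc, cumulative_weight = weights[i])
  })
  arc_plan(list(list(control_points = cps, mu = mu, energy = energy)))
}

#' Generate a synthetic fixture set (plan, dose, readings)
#'
#' Produces the three files a plan-QA run consumes: a DICOM-RT Plan
#' ([fixture_plan()]), a DICOM-RT Dose computed from it with the ray engine,
#' and a plain-text diode readings table (virtual readings of that dose with
#' optional noise) carrying the central chamber dose in its header. All
#' randomness is governed by `seed`; identical spec + seed give identical
#' files.
#'
#' @param spec list: `pattern`, `n_cp`, `field`, `mu`, `energy`,
#'   `grid_spacing` (cm), `angular_bin` (deg), `noise_sd`, `jitter`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param layout,phantom,beam geometry/beam overrides.
#' @return list with file paths (`plan`, `dose`, `readings`) and the
#'   in-memory objects.
#' @export
make_fixtures <- function(spec = list(), seed = 1, dir = tempdir(),
                          layout = build_layout(),
                          phantom = phantom_model(plug_present = FALSE),
                          beam = NULL) {
  spec <- utils::modifyList(list(pattern = "wedge", n_cp = 177, field = 10,
                                 mu = 200, energy = "6X", grid_spacing = 0.5,
                                 angular_bin = 2.1, noise_sd = 0.01,
                                 jitter = 0), spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plan <- with_seed(seed, fixture_plan(spec$pattern, spec$n_cp, spec$field,
                                       spec$mu, spec$energy, jitter = spec$jitter))
  if (is.null(beam)) beam <- beam_model(spec$energy)
  projections <- accumulate_fluence(decompose_subfields(plan$beams[[1]]),
                                    angular_bin = spec$angular_bin)
  half_xy <- phantom$outer_radius + spec$grid_spacing
  half_z <- layout$axial_length / 2 + spec$grid_spacing
  dims <- c(rep(2 * ceiling(half_xy / spec$grid_spacing) + 1, 2),
            2 * ceiling(half_z / spec$grid_spacing) + 1)
  grid <- list(origin = -(dims - 1) / 2 * spec$grid_spacing,
               spacing = rep(spec$grid_spacing, 3), dims = dims)
  dose <- compute_dose_grid(projections, beam, phantom, grid)
  dose_fun <- function(p) dose_at_points(p, projections, beam, phantom)
  readings <- virtual_diode_readings(dose_fun, layout,
                                     noise_sd = spec$noise_sd,
                                     seed = if (spec$noise_sd > 0) seed + 1)
  probe <- chamber_probe()
  chamber <- mean(dose_fun(probe_sample_points(probe)))
  paths <- list(plan = file.path(dir, "fixture_plan.dcm"),
                dose = file.path(dir, "fixture_dose.dcm"),
                readings = file.path(dir, "fixture_readings.txt"))
  write_plan(plan, paths$plan)
  write_dose(dose, paths$dose)
  write_readings(readings, layout, paths$readings, chamber_cgy = chamber,
                 seed = seed)
  c(paths, list(plan_obj = plan, dose_obj = dose, readings_obj = readings,
                chamber_cgy = chamber, projections = projections,
                beam = beam, phantom = phantom, layout = layout))
}

#' Write / read a diode readings table
#'
#' Plain-text table (`diode_index`, `reading_cgy`) with a commented header
#' carrying the central chamber dose and the generating seed.
#'
#' @param readings numeric vector, one value per diode.
#' @param layout the layout the readings index into.
#' @param path file path.
#' @param chamber_cgy optional central chamber dose, cGy.
#' @param seed optional seed recorded in the header.
#' @export
write_readings <- function(readings, layout, path, chamber_cgy = NA,
                           seed = NA) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# arcqa diode readings",
               sprintf("# n_diodes: %d", layout$n_diodes),
               sprintf("# chamber_cgy: %.10g", chamber_cgy),
               sprintf("# seed: %s", format(seed)),
               "diode_index reading_cgy"), con)
  utils::write.table(
    data.frame(diode_index = layout$diodes$diode_index,
               reading_cgy = sprintf("%.10g", readings)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_readings
#' @export
read_readings <- function(path) {
  lines <- readLines(path)
  ch <- grep("^# chamber_cgy:", lines, value = TRUE)
  chamber <- if (length(ch)) as.numeric(sub(".*: *", "", ch[1])) else NA_real_
  tab <- utils::read.table(path, comment.char = "#", header = TRUE)
  structure(list(readings = tab$reading_cgy,
                 diode_index = tab$diode_index,
                 chamber_cgy = chamber), class = "diode_readings")
}
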
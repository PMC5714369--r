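# End-to-end QA studies on synthetic fixtures: open-field validation,
# couch-rotation angular study, misalignment sensitivity (cylindrical array
# vs planar array vs central chamber), and composite plan QA.

#' Planar detector-array layout
#'
#' Idealized regular 2D lattice of point detectors on a plane through the
#' isocenter (a planar-array comparator; a model, not a device emulation).
#' The coronal default spans the x (right-left) and z (superior-inferior)
#' axes at y = 0.
#'
#' @param pitch detector pitch, cm (default 0.762).
#' @param n detectors per side (default 32).
#' @param plane `"coronal"` only (x-z plane through the isocenter).
#' @return object of class `planar_array_layout` with `points` (n^2 x 3) and
#'   axis coordinate vectors `u` (x) and `v` (z).
#' @export
planar_array_layout <- function(pitch = 0.762, n = 32, plane = "coronal") {
  if (!identical(plane, "coronal")) stop_config("only the coronal plane is supported")
  off <- (seq_len(n) - (n + 1) / 2) * pitch
  g <- expand.grid(u = off, v = off)
  structure(list(points = cbind(g$u, 0, g$v), u = off, v = off,
                 pitch = pitch, n = n, plane = plane),
            class = "planar_array_layout")
}

planar_map <- function(playout, values) {
  dose_plane(matrix(values, playout$n, playout$n), playout$u, playout$v)
}

#' Cylindrical ion-chamber probe
#'
#' Sensitive volume of the central chamber (nominal 0.125 cc), a cylinder
#' with its axis along the phantom axis, centered at the isocenter by
#' default. Dimensions must reproduce the nominal volume within 5%.
#'
#' @param radius,length cm.
#' @param center cm triple.
#' @param nominal_volume cc.
#' @return object of class `chamber_probe`.
#' @export
chamber_probe <- function(radius = 0.275, length = 0.526,
                          center = c(0, 0, 0), nominal_volume = 0.125) {
  vol <- pi * radius^2 * length
  if (abs(vol - nominal_volume) / nominal_volume > 0.05)
    stop_config("probe dimensions give %.4g cc, inconsistent with nominal %.3g cc",
                vol, nominal_volume)
  structure(list(radius = radius, length = length, center = as.numeric(center),
                 volume = vol), class = "chamber_probe")
}

# regular subdivision sample points inside the probe cylinder (step <= 0.5 mm)
probe_sample_points <- function(probe, step = 0.05) {
  r <- probe$radius; hl <- probe$length / 2
  sym <- function(half) {
    n <- max(1, floor(2 * half / step))
    (seq_len(n) - (n + 1) / 2) * step # symmetric about the probe center
  }
  ax <- sym(r)
  az <- sym(hl)
  g <- expand.grid(dx = ax, dy = ax, dz = az)
  g <- g[g$dx^2 + g$dy^2 <= r^2, ]
  sweep(as.matrix(g), 2, probe$center, `+`)
}

#' Mean dose over the chamber sensitive volume
#'
#' Volume-averaged dose of the probe cylinder, computed by subdivision
#' sampling at a 0.5 mm step (partial voxels enter through their
#' sample-point fraction) with trilinear interpolation of the grid.
#'
#' @param grid a [dose_grid()].
#' @param probe a [chamber_probe()].
#' @return mean dose in the grid's units.
#' @export
central_dose <- function(grid, probe) {
  pts <- probe_sample_points(probe)
  for (a in 1:3) {
    ax <- grid_axis(grid, a)
    if (min(pts[, a]) < ax[1] - 1e-9 || max(pts[, a]) > ax[length(ax)] + 1e-9)
      stop_config("probe extends outside the dose grid on axis %d", a)
  }
  mean(interp_grid(grid, pts))
}

# ---- QA report container ---------------------------------------------------

#' QA report
#'
#' @param study study label.
#' @param tables named list of data frames.
#' @param config the configuration list used (hashed into the metadata).
#' @param seed seed used for any stochastic element (NA if none).
#' @return object of class `qa_report` with `meta` (seed, config hash).
#' @export
qa_report <- function(study, tables, config = list(), seed = NA) {
  structure(list(study = study, tables = tables,
                 meta = list(seed = seed,
                             config_hash = fnv1a_hex(paste(
                               deparse(config, control = "all"), collapse = "")),
                             config = config)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s (seed %s, config %s)\n", x$study,
              format(x$meta$seed), x$meta$config_hash))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(utils::head(x$tables[[nm]], 12), digits = 4)
  }
  invisible(x)
}

#' Write a QA report to CSV + JSON
#'
#' @param report a [qa_report()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_qa_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, sprintf("%s_%s.csv", report$study, nm)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(study = report$study, meta = report$meta[c("seed", "config_hash")],
         tables = report$tables),
    file.path(dir, sprintf("%s.json", report$study)),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# serialize a report deterministically (reproducibility checks)
report_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(study = report$study, meta = report$meta[c("seed", "config_hash")],
         tables = report$tables), auto_unbox = TRUE, digits = 10))
}

# ---- study 1: open-field validation ----------------------------------------

#' Open-field depth-dose validation study
#'
#' Delivers a static open field (gantry 0, SAD setup) onto the phantom with
#' and without the central plug and reports: the central-axis depth dose
#' through the annulus, the entrance/exit doses at the central diodes
#' sampled by the ray engine versus the TMR/inverse-square calibration
#' prediction anchored at the isocenter dose, and their percent differences.
#' The exit dose must rise when the plug is removed (air gap shortens the
#' effective path).
#'
#' @param config list: `energy` ("6X"), `mu` (100), `field` (10 cm),
#'   `depth_step` (0.25 cm).
#' @param layout,phantom_plug,phantom_noplug geometry overrides.
#' @return a [qa_report()] with tables `depth_dose`, `diode_check`,
#'   `summary`.
#' @export
run_open_field_study <- function(config = list(), layout = build_layout(),
                                 phantom_plug = phantom_model(plug_present = TRUE),
                                 phantom_noplug = phantom_model(plug_present = FALSE)) {
  config <- utils::modifyList(list(energy = "6X", mu = 100, field = 10,
                                   depth_step = 0.25), config)
  beam <- beam_model(config$energy)
  proj <- list(open_field_projection(config$field, config$mu, gantry = 0))
  phantoms <- list(plug = phantom_plug, noplug = phantom_noplug)

  outer_r <- phantom_plug$outer_radius
  ys <- seq(outer_r, -outer_r, by = -config$depth_step)
  axis_pts <- cbind(0, ys, 0)

  depth_tabs <- list(); diode_tabs <- list()
  for (nm in names(phantoms)) {
    ph <- phantoms[[nm]]
    d_axis <- dose_at_points(axis_pts, proj, beam, ph)
    depth_tabs[[nm]] <- data.frame(plug = nm, depth_cm = outer_r - ys,
                                   dose_cgy = d_axis)
    iso <- dose_at_points(matrix(c(0, 0, 0), 1), proj, beam, ph)
    engine <- dose_at_points(layout_points(layout), proj, beam, ph)
    tmr_pred <- diode_dose_from_center(iso, beam, ph, layout, 0, config$field)
    # central diodes: nearest to the beam axis plane on each side
    sel <- function(entr) {
      ok <- tmr_pred$in_beam & (if (entr) tmr_pred$entrance else !tmr_pred$entrance)
      cand <- which(ok)
      cand[which.max(abs(layout$diodes$y[cand]))]
    }
    for (side in c("entrance", "exit")) {
      i <- sel(side == "entrance")
      diode_tabs[[paste(nm, side)]] <- data.frame(
        plug = nm, side = side, diode_index = i,
        engine_cgy = engine[i], tmr_calc_cgy = tmr_pred$dose_cgy[i],
        pct_diff = 100 * (engine[i] - tmr_pred$dose_cgy[i]) / tmr_pred$dose_cgy[i])
    }
  }
  diode_check <- do.call(rbind, diode_tabs)
  exit_plug <- diode_check$engine_cgy[diode_check$plug == "plug" &
                                        diode_check$side == "exit"]
  exit_noplug <- diode_check$engine_cgy[diode_check$plug == "noplug" &
                                          diode_check$side == "exit"]
  summary <- data.frame(
    exit_dose_plug_cgy = exit_plug, exit_dose_noplug_cgy = exit_noplug,
    exit_increase_without_plug = exit_noplug > exit_plug)
  qa_report("open_field",
            list(depth_dose = do.call(rbind, depth_tabs),
                 diode_check = diode_check, summary = summary),
            config = config)
}

# ---- study 2: couch-rotation angular dependency ----------------------------

#' Couch-rotation (noncoplanar) angular-dependency study
#'
#' A lateral open field (gantry 90) is delivered with a series of couch
#' rotations. The reference is the engine dose at the diodes; the evaluated
#' distribution is the virtual readings with the angular-response model
#' applied per the configuration. Gamma passing rates are tabulated per
#' couch angle and criteria pair. With the correction enabled and no noise
#' every cell is 100% (perfect-model correction).
#'
#' @param config list: `couch_angles` (0,10,20,30,40), `dose_pct` (1:3),
#'   `dta_mm` (1:3), `amplitude` (0.08), `response` (TRUE), `correction`
#'   (TRUE), `noise_sd` (0), `seed`, `field`, `mu`, `energy`.
#' @param layout,phantom geometry overrides.
#' @return a [qa_report()] with table `passing_rates`.
#' @export
run_couch_rotation_study <- function(config = list(), layout = build_layout(),
                                     phantom = phantom_model(plug_present = FALSE)) {
  config <- utils::modifyList(list(couch_angles = c(0, 10, 20, 30, 40),
                                   dose_pct = 1:3, dta_mm = 1:3,
                                   amplitude = 0.08, response = TRUE,
                                   correction = TRUE, noise_sd = 0, seed = 1,
                                   field = 10, mu = 100, energy = "6X"),
                              config)
  beam <- beam_model(config$energy)
  ang <- angular_response(config$amplitude, enabled = config$response,
                          correction = config$correction)
  rows <- list()
  for (couch in config$couch_angles) {
    proj <- list(open_field_projection(config$field, config$mu, gantry = 90,
                                       couch = couch))
    fr <- beam_frame(90, couch, sad = beam$sad)
    ref_dose <- dose_at_points(layout_points(layout), proj, beam, phantom)
    readings <- virtual_diode_readings(
      ref_dose, layout, angular = ang, beam_direction = -fr$sv,
      noise_sd = config$noise_sd,
      seed = if (config$noise_sd > 0) config$seed + couch)
    sweep_tab <- criteria_sweep(cylindrical_dose_map(layout, ref_dose),
                                cylindrical_dose_map(layout, readings),
                                config$dose_pct, config$dta_mm,
                                shortcut = TRUE)
    sweep_tab$couch_deg <- couch
    rows[[as.character(couch)]] <- sweep_tab
  }
  qa_report("couch_rotation", list(passing_rates = do.call(rbind, rows)),
            config = config, seed = config$seed)
}

# ---- study 3: misalignment sensitivity -------------------------------------

default_misalignment_transforms <- function(translations_mm = c(1, 2, 3, 5, 10),
                                            rotations_deg = 1:3,
                                            rotation_axis = "cylinder") {
  out <- list()
  for (mm in translations_mm) {
    out[[sprintf("AP_%gmm", mm)]] <- rigid_transform(c(mm / 10, 0, 0))
    out[[sprintf("RL_%gmm", mm)]] <- rigid_transform(c(0, mm / 10, 0))
  }
  for (dg in rotations_deg)
    out[[sprintf("ROT_%gdeg", dg)]] <- rigid_transform(rotation = dg,
                                                       axis = rotation_axis)
  out
}

#' Misalignment-sensitivity study
#'
#' A modulated (wedge) full-arc fixture plan is delivered to the nominal
#' geometry (baseline) and to rigidly misaligned geometries. For each
#' transform the study reports gamma passing rates of the cylindrical diode
#' array and of the planar comparator array (each normalized to its own
#' reference maximum), plus the central chamber dose ratio to baseline. The
#' zero transform reproduces the baseline exactly.
#'
#' @param config list: `transforms` (named list of [rigid_transform()];
#'   default the 1/2/3/5/10 mm AP and RL translations and 1-3 degree
#'   rotations), `dose_pct`, `dta_mm`, `pattern`, `n_cp`, `mu`, `energy`,
#'   `angular_bin`, `rotation_axis`, `seed`.
#' @param layout,phantom,planar geometry overrides.
#' @return a [qa_report()] with tables `passing_rates` and `chamber`.
#' @export
run_misalignment_study <- function(config = list(), layout = build_layout(),
                                   phantom = phantom_model(plug_present = TRUE),
                                   planar = planar_array_layout()) {
  config <- utils::modifyList(list(transforms = NULL, dose_pct = 1:3,
                                   dta_mm = 1:3, pattern = "arcsweep",
                                   n_cp = 177, mu = 200, energy = "6X",
                                   angular_bin = 2.1,
                                   rotation_axis = "cylinder", seed = 1),
                              config)
  transforms <- config$transforms %||%
    default_misalignment_transforms(rotation_axis = config$rotation_axis)
  beam <- beam_model(config$energy)
  plan <- fixture_plan(config$pattern, config$n_cp, mu = config$mu,
                       energy = config$energy)
  proj <- accumulate_fluence(decompose_subfields(plan$beams[[1]]),
                             angular_bin = config$angular_bin)
  probe <- chamber_probe()
  ppts <- probe_sample_points(probe)

  base_cyl <- dose_at_points(layout_points(layout), proj, beam, phantom)
  base_pln <- dose_at_points(planar$points, proj, beam, phantom)
  base_chm <- mean(dose_at_points(ppts, proj, beam, phantom))
  ref_cyl <- cylindrical_dose_map(layout, base_cyl)
  ref_pln <- planar_map(planar, base_pln)

  rate_rows <- list(); chm_rows <- list()
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    ev_cyl <- dose_at_points(layout_points(layout), proj, beam, phantom,
                             setup = tr)
    ev_pln <- dose_at_points(planar$points, proj, beam, phantom, setup = tr)
    ev_chm <- mean(dose_at_points(ppts, proj, beam, phantom, setup = tr))
    sc <- criteria_sweep(ref_cyl, cylindrical_dose_map(layout, ev_cyl),
                         config$dose_pct, config$dta_mm, shortcut = TRUE)
    sp <- criteria_sweep(ref_pln, planar_map(planar, ev_pln),
                         config$dose_pct, config$dta_mm, shortcut = TRUE)
    sc$array <- "cylindrical"; sp$array <- "planar"
    both <- rbind(sc, sp)
    both$transform <- nm
    rate_rows[[nm]] <- both
    chm_rows[[nm]] <- data.frame(transform = nm,
                                 chamber_ratio = ev_chm / base_chm)
  }
  qa_report("misalignment",
            list(passing_rates = do.call(rbind, rate_rows),
                 chamber = do.call(rbind, chm_rows),
                 baseline = data.frame(chamber_cgy = base_chm,
                                       cyl_max_cgy = max(base_cyl),
                                       planar_max_cgy = max(base_pln))),
            config = config[names(config) != "transforms"],
            seed = config$seed)
}

# ---- study 4: composite plan QA --------------------------------------------

#' Composite VMAT plan QA
#'
#' Reads a DICOM-RT Plan, a reference DICOM-RT Dose and a diode readings
#' table, then reports (a) the gamma passing rate of the composite
#' peripheral dose (the per-diode total over all beams, i.e. the summed
#' entrance and exit doses) for each criteria pair, with the reference map
#' interpolated from the dose grid at the diode positions, and (b) the
#' percent difference of the central dose, chamber measurement versus the
#' [central_dose()] volume average of the reference grid
#' (100 x (measured - calculated) / calculated).
#'
#' @param plan_path,dose_path,readings_path input files.
#' @param dose_pct,dta_mm criteria vectors.
#' @param threshold_pct low-dose threshold (also the report display cutoff).
#' @param layout,phantom,probe geometry overrides.
#' @return a [qa_report()] with tables `passing_rates`, `central` and
#'   `plan_summary`.
#' @export
run_plan_qa <- function(plan_path, dose_path, readings_path,
                        dose_pct = 3, dta_mm = 3, threshold_pct = 10,
                        layout = build_layout(),
                        phantom = phantom_model(plug_present = FALSE),
                        probe = chamber_probe()) {
  plan <- read_plan(plan_path)
  grid <- read_dose(dose_path)
  rd <- read_readings(readings_path)
  missing <- setdiff(layout$diodes$diode_index, rd$diode_index)
  if (length(missing))
    stop_config("readings missing diodes: %s",
                paste(utils::head(missing, 20), collapse = ", "))
  readings <- rd$readings[match(layout$diodes$diode_index, rd$diode_index)]
  ref_vals <- interp_grid(grid, layout_points(layout))
  sweep_tab <- criteria_sweep(cylindrical_dose_map(layout, ref_vals),
                              cylindrical_dose_map(layout, readings),
                              dose_pct, dta_mm, threshold_pct = threshold_pct,
                              shortcut = TRUE)
  calc <- central_dose(grid, probe)
  central <- data.frame(
    chamber_cgy = rd$chamber_cgy, calculated_cgy = calc,
    pct_diff = 100 * (rd$chamber_cgy - calc) / calc)
  plan_summary <- data.frame(
    n_beams = length(plan$beams),
    n_control_points = sum(vapply(plan$beams, function(b)
      length(b$control_points), numeric(1))),
    total_mu = sum(vapply(plan$beams, `[[`, numeric(1), "mu")))
  qa_report("plan_qa", list(passing_rates = sweep_tab, central = central,
                            plan_summary = plan_summary),
            config = list(dose_pct = dose_pct, dta_mm = dta_mm,
                          threshold_pct = threshold_pct))
}
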
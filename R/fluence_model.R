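# Control-point -> subfield decomposition and MLC fluence rendering.
# Fluence maps live on the isocenter plane: x along leaf travel, y along the
# leaf-stacking direction (patient superior-inferior for a coplanar beam at
# collimator 0).

#' MLC transmission model
#'
#' Geometry and dosimetric parameters of the 120-leaf MLC used when
#' rasterizing apertures: leaf-edge boundaries across the field, intraleaf
#' transmission, a rounded-leaf-end dosimetric gap added per leaf tip, and a
#' tongue-and-groove strip rendered at transmission where adjacent leaves
#' with different tip positions meet.
#'
#' Defaults: 40 central pairs of 0.5 cm and 20 outer pairs of 1.0 cm
#' (Millennium-style, configurable), 1.5% transmission, 0.1 cm rounded-end
#' offset and 0.05 cm tongue-and-groove width. The transmission parameters
#' are exposed stand-ins, not vendor measurements.
#'
#' @param leaf_widths 60 leaf-pair widths, cm (isocenter scale).
#' @param transmission fraction in `[0, 1)`.
#' @param rounded_leaf_end_offset cm added to each leaf tip opening.
#' @param tongue_and_groove_width cm.
#' @return object of class `mlc_model` with `boundaries` (61 leaf edges).
#' @export
mlc_model <- function(leaf_widths = c(rep(1, 10), rep(0.5, 40), rep(1, 10)),
                      transmission = 0.015,
                      rounded_leaf_end_offset = 0.1,
                      tongue_and_groove_width = 0.05) {
  if (length(leaf_widths) != 60) stop_config("need 60 leaf-pair widths")
  if (transmission < 0 || transmission >= 1)
    stop_config("transmission must lie in [0, 1)")
  if (rounded_leaf_end_offset < 0 || tongue_and_groove_width < 0)
    stop_config("offsets must be nonnegative")
  half <- sum(leaf_widths) / 2
  structure(list(leaf_widths = leaf_widths,
                 boundaries = c(0, cumsum(leaf_widths)) - half,
                 transmission = transmission,
                 rounded_leaf_end_offset = rounded_leaf_end_offset,
                 tongue_and_groove_width = tongue_and_groove_width),
            class = "mlc_model")
}

#' Decompose an arc beam into MU-weighted subfields
#'
#' Each adjacent pair of control points defines one subfield: its meterset is
#' the cumulative-weight increment times the beam meterset, its aperture is
#' the midpoint of the two bounding apertures (leaves and jaws), and its
#' representative gantry angle is the circular midpoint of the two gantry
#' angles (shortest arc). An N-control-point beam yields exactly N-1
#' subfields whose metersets sum to the beam meterset.
#'
#' @param beam one beam of an [arc_plan()].
#' @return list of `subfield` objects.
#' @export
decompose_subfields <- function(beam) {
  cps <- beam$control_points
  n <- length(cps)
  if (n < 2) stop_config("beam needs at least 2 control points")
  lapply(seq_len(n - 1), function(i) {
    a <- cps[[i]]; b <- cps[[i + 1]]
    structure(list(
      mlc = (a$mlc + b$mlc) / 2,
      jaws = (a$jaws + b$jaws) / 2,
      meterset = (b$cumulative_weight - a$cumulative_weight) * beam$mu,
      gantry_span = c(a$gantry_angle, b$gantry_angle),
      representative_gantry = circular_midpoint(a$gantry_angle, b$gantry_angle),
      collimator_angle = circular_midpoint(a$collimator_angle, b$collimator_angle),
      couch_angle = circular_midpoint(a$couch_angle, b$couch_angle)
    ), class = "subfield")
  })
}

fluence_grid_axes <- function(jaws, spacing, margin = 2) {
  ext <- function(lo, hi) {
    lo <- floor((lo - margin * spacing) / spacing) * spacing
    hi <- ceiling((hi + margin * spacing) / spacing) * spacing
    seq(lo + spacing / 2, hi - spacing / 2, by = spacing)
  }
  list(x = ext(jaws[1], jaws[2]), y = ext(jaws[3], jaws[4]))
}

#' Render a subfield aperture to a relative fluence map
#'
#' Rasterizes the MLC aperture on an isocenter-plane grid (pixel-center
#' sampling): the open region is 1, the region under leaves but inside the
#' jaws is `transmission`, and outside the jaws is 0. Each leaf tip is
#' opened by the rounded-leaf-end offset before rasterization; where two
#' adjacent leaf pairs have different tip positions, a tongue-and-groove
#' strip of the configured width on the open side of the leaf boundary is
#' rendered at transmission.
#'
#' @param subfield a subfield from [decompose_subfields()].
#' @param mlc an [mlc_model()].
#' @param spacing grid spacing, cm (> 0).
#' @param axes optional list with pixel-center coordinates `x`, `y`; defaults
#'   to a grid covering the jaw opening plus a margin.
#' @return object of class `fluence_map`: `values[i, j]` at `x[i]`, `y[j]`,
#'   with `meterset`, beam angles and an equivalent `field_size` (cm).
#' @export
render_fluence <- function(subfield, mlc = mlc_model(), spacing = 0.25,
                           axes = NULL) {
  if (spacing <= 0) stop_config("grid spacing must be positive")
  jaws <- subfield$jaws
  if (is.null(axes)) axes <- fluence_grid_axes(jaws, spacing)
  xs <- axes$x; ys <- axes$y
  nx <- length(xs); ny <- length(ys)
  tr <- mlc$transmission
  off <- mlc$rounded_leaf_end_offset
  w <- mlc$tongue_and_groove_width

  pair_of_y <- findInterval(ys, mlc$boundaries, rightmost.closed = TRUE)
  pair_of_y[pair_of_y < 1 | pair_of_y > 60] <- NA

  # open_x[i, p]: is x_i inside the (rounded-end widened) gap of pair p?
  lo <- subfield$mlc[, "A"] - off
  hi <- subfield$mlc[, "B"] + off
  open_x <- outer(xs, lo, `>=`) & outer(xs, hi, `<=`)

  vals <- matrix(0, nx, ny)
  inside_x <- xs >= jaws[1] & xs <= jaws[2]
  for (j in seq_len(ny)) {
    if (ys[j] < jaws[3] || ys[j] > jaws[4]) next
    p <- pair_of_y[j]
    col <- rep(tr, nx)
    if (!is.na(p)) col[open_x[, p]] <- 1
    # tongue-and-groove: strip on the open side of a staggered leaf boundary
    if (w > 0 && !is.na(p)) {
      for (q in c(p - 1L, p + 1L)) {
        if (q < 1 || q > 60) next
        edge <- mlc$boundaries[max(p, q)] # boundary between p and q
        if (abs(ys[j] - edge) >= w) next
        differs <- abs(subfield$mlc[p, "A"] - subfield$mlc[q, "A"]) > 1e-9 ||
          abs(subfield$mlc[p, "B"] - subfield$mlc[q, "B"]) > 1e-9
        if (!differs) next
        shadow <- open_x[, p] & !open_x[, q]
        col[shadow] <- tr
      }
    }
    col[!inside_x] <- 0
    vals[, j] <- col
  }
  structure(list(values = vals, x = xs, y = ys, spacing = spacing,
                 meterset = subfield$meterset, jaws = jaws,
                 gantry = subfield$representative_gantry,
                 collimator_angle = subfield$collimator_angle %||% 0,
                 couch_angle = subfield$couch_angle %||% 0,
                 field_size = sqrt((jaws[2] - jaws[1]) * (jaws[4] - jaws[3]))),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d px @ %.3g cm, meterset %.4g MU, gantry %.1f deg\n",
              length(x$x), length(x$y), x$spacing, x$meterset, x$gantry))
  invisible(x)
}

# bilinear fluence lookup at isocenter-plane coordinates; 0 outside the map
fluence_at <- function(map, xq, yq) {
  xs <- map$x; ys <- map$y
  fx <- (xq - xs[1]) / map$spacing
  fy <- (yq - ys[1]) / map$spacing
  nx <- length(xs); ny <- length(ys)
  inside <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  out <- numeric(length(xq))
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]
  i0 <- pmin(pmax(floor(fx), 0), nx - 2); j0 <- pmin(pmax(floor(fy), 0), ny - 2)
  ax <- fx - i0; ay <- fy - j0
  v <- map$values
  out[inside] <-
    v[cbind(i0 + 1, j0 + 1)] * (1 - ax) * (1 - ay) +
    v[cbind(i0 + 2, j0 + 1)] * ax * (1 - ay) +
    v[cbind(i0 + 1, j0 + 2)] * (1 - ax) * ay +
    v[cbind(i0 + 2, j0 + 2)] * ax * ay
  out
}

#' Accumulate subfield fluences into angular bins
#'
#' Groups a beam's subfields by representative gantry angle into bins of
#' `angular_bin` degrees and sums their meterset-weighted fluences on a
#' common grid. The composite map of a bin keeps relative fluence in
#' `[0, 1]` (meterset-weighted mean) and carries the summed meterset, so the
#' total meterset is conserved across bins.
#'
#' @param subfields list from [decompose_subfields()].
#' @param mlc an [mlc_model()].
#' @param angular_bin bin width in degrees; `360` collapses the beam into a
#'   single composite map.
#' @param spacing grid spacing, cm.
#' @return list of `fluence_map`, one per populated bin, ordered by angle.
#' @export
accumulate_fluence <- function(subfields, mlc = mlc_model(), angular_bin = 360,
                               spacing = 0.25) {
  if (!length(subfields)) return(list())
  all_jaws <- vapply(subfields, `[[`, numeric(4), "jaws")
  common <- c(min(all_jaws[1, ]), max(all_jaws[2, ]),
              min(all_jaws[3, ]), max(all_jaws[4, ]))
  axes <- fluence_grid_axes(common, spacing)
  gantry <- vapply(subfields, `[[`, numeric(1), "representative_gantry")
  bin <- floor((gantry %% 360) / angular_bin)
  out <- list()
  for (b in sort(unique(bin))) {
    members <- subfields[bin == b]
    ms <- vapply(members, `[[`, numeric(1), "meterset")
    total <- sum(ms)
    acc <- 0
    for (k in seq_along(members)) {
      fm <- render_fluence(members[[k]], mlc, spacing, axes = axes)
      acc <- acc + ms[k] * fm$values
    }
    proto <- render_fluence(members[[1]], mlc, spacing, axes = axes)
    proto$values <- if (total > 0) acc / total else acc * 0
    proto$meterset <- total
    proto$gantry <- circular_weighted_mean(
      vapply(members, `[[`, numeric(1), "representative_gantry"),
      if (total > 0) ms else rep(1, length(ms)))
    proto$collimator_angle <- circular_weighted_mean(
      vapply(members, function(s) s$collimator_angle %||% 0, numeric(1)),
      if (total > 0) ms else rep(1, length(ms)))
    proto$couch_angle <- circular_weighted_mean(
      vapply(members, function(s) s$couch_angle %||% 0, numeric(1)),
      if (total > 0) ms else rep(1, length(ms)))
    proto$jaws <- common
    proto$field_size <- sqrt((common[2] - common[1]) * (common[4] - common[3]))
    out[[length(out) + 1L]] <- proto
  }
  out
}

#' Export a fluence map as a plain 2D array with a header
#'
#' @param map a `fluence_map`.
#' @param path file path.
#' @export
write_fluence <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# arcqa fluence map",
               sprintf("# spacing_cm: %.10g", map$spacing),
               sprintf("# origin_cm: %.10g %.10g", map$x[1], map$y[1]),
               sprintf("# meterset_mu: %.10g", map$meterset),
               sprintf("# gantry_deg: %.10g", map$gantry)), con)
  utils::write.table(format(map$values, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
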
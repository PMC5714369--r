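# Gamma-index comparison of dose distributions on planar grids and on the
# unwrapped detector cylinder (periodic angular coordinate).
#
# gamma(r) = min over r' of sqrt(|r - r'|^2 / DTA^2 + (D_ev(r') - D_ref(r))^2
# / dD^2), minimized over the evaluated distribution upsampled to a step of
# at most DTA/10. The fast path searches a window of radius 3 x DTA around
# each reference point and expands it whenever a farther minimizer could
# still win (min gamma > radius/DTA), so it matches the exhaustive search
# exactly; both paths sample the same evaluated-grid-anchored lattice.

#' Gamma evaluation criteria
#'
#' @param dose_pct dose-difference tolerance, percent of the normalization
#'   dose.
#' @param dta_mm distance-to-agreement, mm.
#' @param threshold_pct low-dose threshold: reference points below this
#'   percentage of the maximum reference dose are excluded (default 10, and
#'   configurable as the analysis/display cutoff).
#' @param normalization `"global"` (percent of the reference maximum; the QA
#'   convention, default) or `"local"` (percent of each point's own dose).
#' @return object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 3, dta_mm = 3, threshold_pct = 10,
                           normalization = c("global", "local")) {
  if (dose_pct <= 0 || dta_mm <= 0) stop_config("criteria must be positive")
  if (threshold_pct < 0 || threshold_pct >= 100)
    stop_config("threshold must lie in [0, 100)")
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 threshold_pct = threshold_pct,
                 normalization = match.arg(normalization)),
            class = "gamma_criteria")
}

#' Planar dose distribution
#'
#' @param values matrix, `values[i, j]` at `x[i]`, `y[j]` (cm, uniform
#'   spacing per axis).
#' @param x,y coordinate vectors, cm.
#' @return object of class `dose_plane`.
#' @export
dose_plane <- function(values, x = NULL, y = NULL) {
  values <- as.matrix(values)
  x <- x %||% (seq_len(nrow(values)) - 1)
  y <- y %||% (seq_len(ncol(values)) - 1)
  stopifnot(length(x) == nrow(values), length(y) == ncol(values))
  structure(list(values = values, x = as.numeric(x), y = as.numeric(y)),
            class = "dose_plane")
}

#' Unwrapped cylindrical dose map
#'
#' Per-diode values arranged on the `n_rev x per_rev` unwrap grid of the
#' spiral layout: rows are axial bins (cm), columns angular bins expressed
#' as arc length at the detector radius (cm, periodic with the
#' circumference). The sub-pitch helical offset of diodes within a row is
#' folded into the row coordinate (vendor-style unwrap).
#'
#' @param layout a [build_layout()] layout.
#' @param values numeric vector, one dose per diode (layout order).
#' @return object of class `cylindrical_dose_map` (also a `dose_plane` with
#'   `x` = axial cm, `y` = arc cm and a `period` attribute).
#' @export
cylindrical_dose_map <- function(layout, values) {
  if (length(values) != layout$n_diodes)
    stop_config("need one value per diode (%d)", layout$n_diodes)
  u <- unwrap_index(layout)
  m <- matrix(NA_real_, layout$n_rev, layout$per_rev)
  m[cbind(u$row, u$col)] <- values
  structure(list(values = m, x = attr(u, "row_z"), y = attr(u, "col_arc"),
                 period = 2 * pi * layout$radius, radius = layout$radius,
                 layout_n = layout$n_diodes),
            class = c("cylindrical_dose_map", "dose_plane"))
}

# ---- evaluated-distribution sampling ---------------------------------------

# Upsampling lattice anchored on the evaluated grid with step <= dta/10 that
# divides the native spacing (so fast and exhaustive search share it).
gamma_lattice <- function(coord, dta_cm, period = NULL) {
  sp <- coord[2] - coord[1]
  sub <- ceiling(sp / (dta_cm / 10))
  h <- sp / sub
  n_native <- length(coord)
  if (is.null(period)) {
    list(start = coord[1], h = h, n = (n_native - 1) * sub + 1, sub = sub)
  } else {
    list(start = coord[1], h = h, n = n_native * sub, sub = sub,
         period = period)
  }
}

# bilinear sample of a dose_plane at lattice index positions (may be
# fractional native indices); periodic wrap in y when period is set
sample_plane <- function(plane, fx, fy, period_cols = NULL) {
  dm <- dim(fx)
  fx <- as.vector(fx); fy <- as.vector(fy)
  nx <- nrow(plane$values); ny <- ncol(plane$values)
  if (is.null(period_cols)) {
    fy0 <- pmin(pmax(fy, 0), ny - 1)
    j0 <- pmin(floor(fy0), ny - 2); ay <- fy0 - j0
    jlo <- j0 + 1; jhi <- j0 + 2
  } else {
    fy0 <- fy %% ny
    j0 <- floor(fy0); ay <- fy0 - j0
    jlo <- j0 + 1; jhi <- (j0 + 1) %% ny + 1
  }
  fx0 <- pmin(pmax(fx, 0), nx - 1)
  i0 <- pmin(floor(fx0), nx - 2); ax <- fx0 - i0
  v <- plane$values
  out <- v[cbind(i0 + 1, jlo)] * (1 - ax) * (1 - ay) +
    v[cbind(i0 + 2, jlo)] * ax * (1 - ay) +
    v[cbind(i0 + 1, jhi)] * (1 - ax) * ay +
    v[cbind(i0 + 2, jhi)] * ax * ay
  if (!is.null(dm)) dim(out) <- dm
  out
}

# ---- gamma engines ---------------------------------------------------------

gamma_result <- function(gamma, included, criteria) {
  pass <- gamma <= 1 + 1e-12
  structure(list(gamma = gamma, pass = pass, included = included,
                 n_evaluated = sum(included),
                 passing_rate = 100 * sum(pass[included]) / sum(included),
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f%% passing (%d evaluated, %g%%/%g mm, threshold %g%%)\n",
              x$passing_rate, x$n_evaluated, x$criteria$dose_pct,
              x$criteria$dta_mm, x$criteria$threshold_pct))
  invisible(x)
}

gamma_core <- function(reference, evaluated, criteria, periodic = FALSE,
                       shortcut = FALSE, exhaustive = FALSE) {
  rv <- reference$values
  if (!all(dim(rv) == dim(evaluated$values)) ||
      max(abs(reference$x - evaluated$x)) > 1e-9 ||
      max(abs(reference$y - evaluated$y)) > 1e-9)
    stop_config("reference and evaluated distributions are on different grids")
  dta_cm <- criteria$dta_mm / 10
  norm <- max(rv)
  included <- rv >= criteria$threshold_pct / 100 * norm
  if (norm <= 0 || !any(included))
    stop_config("no evaluable points above the dose threshold")
  dd_global <- criteria$dose_pct / 100 * norm

  period <- if (periodic) evaluated$period else NULL
  lx <- gamma_lattice(evaluated$x, dta_cm)
  ly <- gamma_lattice(evaluated$y, dta_cm, period = period)
  spx <- evaluated$x[2] - evaluated$x[1]
  spy <- evaluated$y[2] - evaluated$y[1]
  if (periodic && abs(ly$n * ly$h - period) > 1e-6)
    stop_config("angular lattice does not tile the period")

  gam <- matrix(NA_real_, nrow(rv), ncol(rv))
  idx <- which(included, arr.ind = TRUE)
  max_r <- sqrt((lx$n * lx$h)^2 + (ly$n * ly$h)^2) # no cap can exceed this

  if (exhaustive) {
    ex_i <- seq_len(lx$n) - 1
    ex_j <- seq_len(ly$n) - 1
    ex_x <- lx$start + ex_i * lx$h
    ex_y <- ly$start + ex_j * ly$h
    FX <- matrix(rep(ex_i / lx$sub, times = ly$n), lx$n, ly$n)
    FY <- matrix(rep(ex_j / ly$sub, each = lx$n), lx$n, ly$n)
    ED <- sample_plane(evaluated, FX, FY, period_cols = if (periodic) TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      d0 <- rv[i, j]
      dd <- if (criteria$normalization == "local") criteria$dose_pct / 100 * d0 else dd_global
      dx <- ex_x - reference$x[i]
      dy <- ex_y - reference$y[j]
      if (periodic) dy <- dy - period * round(dy / period)
      D2 <- outer(dx^2, dy^2, `+`)
      gam[i, j] <- sqrt(min(D2 / dta_cm^2 + (ED - d0)^2 / dd^2))
    }
    return(gamma_result(gam, included, criteria))
  }

  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    d0 <- rv[i, j]
    dd <- if (criteria$normalization == "local") criteria$dose_pct / 100 * d0 else dd_global
    x0 <- reference$x[i]; y0 <- reference$y[j]
    if (shortcut) {
      e0 <- sample_plane(evaluated, (x0 - lx$start) / spx, (y0 - ly$start) / spy,
                         period_cols = if (periodic) TRUE)
      g0 <- abs(e0 - d0) / dd
      if (g0 <= 1) { gam[i, j] <- g0; next }
    }
    r <- 3 * dta_cm
    repeat {
      # lattice indices within the window (clamped / wrapped)
      i_lo <- ceiling((x0 - r - lx$start) / lx$h)
      i_hi <- floor((x0 + r - lx$start) / lx$h)
      i_rng <- max(i_lo, 0):min(i_hi, lx$n - 1)
      j_lo <- ceiling((y0 - r - ly$start) / ly$h)
      j_hi <- floor((y0 + r - ly$start) / ly$h)
      if (periodic && (j_hi - j_lo + 1) >= ly$n) { j_lo <- 0; j_hi <- ly$n - 1 }
      j_rng <- if (periodic) j_lo:j_hi else max(j_lo, 0):min(j_hi, ly$n - 1)
      cx <- lx$start + i_rng * lx$h
      cy <- ly$start + j_rng * ly$h
      FX <- matrix(rep(i_rng / lx$sub, times = length(j_rng)),
                   length(i_rng), length(j_rng))
      FYj <- if (periodic) (j_rng %% ly$n) else j_rng
      FY <- matrix(rep(FYj / ly$sub, each = length(i_rng)),
                   length(i_rng), length(j_rng))
      ED <- sample_plane(evaluated, FX, FY, period_cols = if (periodic) TRUE)
      dx <- cx - x0
      dy <- cy - y0
      if (periodic) dy <- dy - period * round(dy / period)
      D2 <- outer(dx^2, dy^2, `+`)
      g <- sqrt(min(D2 / dta_cm^2 + (ED - d0)^2 / dd^2))
      if (g <= r / dta_cm || r >= max_r) { gam[i, j] <- g; break }
      r <- 2 * r # a farther minimizer could still win: expand the search
    }
  }
  gamma_result(gam, included, criteria)
}

#' Gamma map between two planar dose distributions
#'
#' @param reference,evaluated [dose_plane()] objects on the same grid (or
#'   plain matrices, taken on a unit-spacing grid).
#' @param criteria a [gamma_criteria()].
#' @param shortcut when TRUE, points whose same-location dose difference is
#'   already within tolerance take that (upper-bound) gamma without a
#'   spatial search; pass/fail and passing rates are unaffected. Default
#'   FALSE (exact minimized gamma everywhere).
#' @return a `gamma_result`: per-point `gamma`, `pass` mask, `n_evaluated`
#'   and `passing_rate` (percent).
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      shortcut = FALSE) {
  if (!inherits(reference, "dose_plane")) reference <- dose_plane(reference)
  if (!inherits(evaluated, "dose_plane")) evaluated <- dose_plane(evaluated)
  gamma_core(reference, evaluated, criteria, periodic = FALSE,
             shortcut = shortcut)
}

#' Exhaustive-search gamma (oracle)
#'
#' Brute-force minimization over every point of the upsampled evaluated
#' distribution with no search-radius cap. Slow; kept as the independent
#' check of [gamma_map()] and [unwrapped_gamma()].
#'
#' @inheritParams gamma_map
#' @param periodic treat `y` as the periodic (angular) coordinate of a
#'   `cylindrical_dose_map`.
#' @return a `gamma_result`.
#' @export
gamma_exhaustive <- function(reference, evaluated, criteria = gamma_criteria(),
                             periodic = FALSE) {
  if (!inherits(reference, "dose_plane")) reference <- dose_plane(reference)
  if (!inherits(evaluated, "dose_plane")) evaluated <- dose_plane(evaluated)
  gamma_core(reference, evaluated, criteria, periodic = periodic,
             exhaustive = TRUE)
}

#' Gamma on the unwrapped detector cylinder
#'
#' As [gamma_map()], with the angular coordinate periodic: distances across
#' the 0/360 degree seam are measured along the cylinder surface (arc
#' length), never through the seam discontinuity.
#'
#' @param reference,evaluated [cylindrical_dose_map()] objects on the same
#'   layout grid.
#' @param criteria a [gamma_criteria()].
#' @param shortcut see [gamma_map()].
#' @return a `gamma_result`.
#' @export
unwrapped_gamma <- function(reference, evaluated, criteria = gamma_criteria(),
                            shortcut = FALSE) {
  if (!inherits(reference, "cylindrical_dose_map") ||
      !inherits(evaluated, "cylindrical_dose_map"))
    stop_config("unwrapped_gamma needs cylindrical_dose_map inputs")
  gamma_core(reference, evaluated, criteria, periodic = TRUE,
             shortcut = shortcut)
}

#' Passing-rate table over a grid of criteria
#'
#' One gamma evaluation per (dose, DTA) pair. Rates are nondecreasing along
#' both loosening axes by construction.
#'
#' @param reference,evaluated distributions as in [gamma_map()] /
#'   [unwrapped_gamma()] (cylindrical maps are detected automatically).
#' @param dose_pct,dta_mm criteria vectors (nonempty).
#' @param threshold_pct low-dose threshold.
#' @param shortcut see [gamma_map()].
#' @return data frame `dose_pct`, `dta_mm`, `passing_rate`, `n_evaluated`.
#' @export
criteria_sweep <- function(reference, evaluated, dose_pct = 1:3, dta_mm = 1:3,
                           threshold_pct = 10, shortcut = FALSE) {
  if (!length(dose_pct) || !length(dta_mm))
    stop_config("criteria lists must be nonempty")
  cyl <- inherits(reference, "cylindrical_dose_map")
  grid <- expand.grid(dose_pct = dose_pct, dta_mm = dta_mm)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    cr <- gamma_criteria(grid$dose_pct[k], grid$dta_mm[k], threshold_pct)
    if (cyl) unwrapped_gamma(reference, evaluated, cr, shortcut = shortcut)
    else gamma_map(reference, evaluated, cr, shortcut = shortcut)
  })
  grid$passing_rate <- vapply(res, `[[`, numeric(1), "passing_rate")
  grid$n_evaluated <- vapply(res, `[[`, numeric(1), "n_evaluated")
  grid
}

#' Export a criteria sweep as CSV
#'
#' Wide table: DTA criteria as rows, dose criteria as columns, passing rates
#' as percentages with one decimal.
#'
#' @param sweep data frame from [criteria_sweep()].
#' @param path file path.
#' @export
write_sweep_csv <- function(sweep, path) {
  wide <- stats::reshape(sweep[, c("dta_mm", "dose_pct", "passing_rate")],
                         idvar = "dta_mm", timevar = "dose_pct",
                         direction = "wide")
  names(wide) <- sub("passing_rate.", "dose_", names(wide), fixed = TRUE)
  wide[-1] <- lapply(wide[-1], function(v) sprintf("%.1f", v))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
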
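test_that("default spiral layout reproduces the 1,386-diode array", {
  lay <- build_layout(pitch = 1, spacing = 1, diameter = 21, axial_length = 21)
  expect_identical(lay$n_diodes, 1386L)
  expect_identical(lay$per_rev, 66L)
  expect_identical(lay$n_rev, 21L)
  expect_equal(lay$radius, 10.5)
  # all diodes share the cylinder radius; helix step matches stored spacing
  r <- sqrt(lay$diodes$x^2 + lay$diodes$y^2)
  expect_lt(max(abs(r - lay$radius)), 1e-12)
  dtheta <- diff(lay$diodes$angle) %% (2 * pi)
  step <- sqrt((lay$radius * dtheta)^2 + diff(lay$diodes$z)^2)
  expect_lt(max(abs(step - lay$spacing)), 1e-6)
  # axial extent equals pitch x revolutions
  expect_equal(lay$axial_length, lay$pitch * lay$n_rev)
})

test_that("layout agrees with a brute-force spiral walk", {
  lay <- build_layout()
  walk <- oracle_spiral_walk(1, 1, 21, 21)
  expect_identical(walk$n, 1386L)
  expect_identical(walk$per_rev_counts, rep(66L, 21))
  expect_lt(max(abs(walk$z - lay$diodes$z)), 1e-9)
  dd <- abs(walk$angle - lay$diodes$angle)
  expect_lt(max(pmin(dd, 2 * pi - dd)), 1e-9)
})

test_that("single-ring and error cases behave per contract", {
  ring <- build_layout(pitch = 2, spacing = 1, diameter = 21, axial_length = 2)
  expect_identical(ring$n_rev, 1L)
  expect_identical(ring$n_diodes, ring$per_rev)
  expect_error(build_layout(spacing = 1.37), "residual")
  expect_error(build_layout(pitch = -1), "positive")
  expect_error(build_layout(axial_length = 21.5), "integer number of pitches")
})

test_that("diode count is invariant under rotation of the angular origin", {
  for (org in c(0, 0.4, pi / 3, 3)) {
    lay <- build_layout(angular_origin = org)
    expect_identical(lay$n_diodes, 1386L)
  }
})

test_that("entrance/exit masks partition the array at every angle", {
  lay <- build_layout()
  for (g in seq(0, 359, by = 1)) {
    m <- entrance_exit_masks(lay, g)
    expect_identical(sum(m$entrance) + sum(m$exit), lay$n_diodes)
    expect_false(any(m$entrance & m$exit))
  }
  # gantry 0: anterior half (positive y) is entrance
  m0 <- entrance_exit_masks(lay, 0)
  expect_true(all(m0$entrance[lay$diodes$y > 1e-9]))
  expect_true(all(m0$exit[lay$diodes$y < -1e-9]))
  expect_error(entrance_exit_masks(lay, 360), "\\[0, 360\\)")
})

test_that("gantry 90 vs 270 masks swap except documented entrance ties", {
  lay <- build_layout()
  m90 <- entrance_exit_masks(lay, 90)
  m270 <- entrance_exit_masks(lay, 270)
  # brute-force dot products against the source directions
  d90 <- lay$diodes$x * sin(pi / 2) + lay$diodes$y * cos(pi / 2)
  d270 <- lay$diodes$x * sin(3 * pi / 2) + lay$diodes$y * cos(3 * pi / 2)
  tie <- abs(d90) < 1e-9 * lay$radius | abs(d270) < 1e-9 * lay$radius
  expect_identical(m90$entrance[!tie], m270$exit[!tie])
  expect_identical(m90$exit[!tie], m270$entrance[!tie])
  # the tie-break rule assigns plane-diodes to entrance at both angles
  expect_true(all(m90$entrance[abs(d90) < 1e-9 * lay$radius]))
  expect_true(all(m270$entrance[abs(d270) < 1e-9 * lay$radius]))
})

test_that("unwrap_index is a bijection onto the n_rev x per_rev grid", {
  lay <- build_layout()
  u <- unwrap_index(lay)
  expect_identical(attr(u, "dims"), c(21L, 66L))
  cells <- paste(u$row, u$col)
  expect_identical(anyDuplicated(cells), 0L)        # no shared cells
  expect_identical(nrow(u), 21L * 66L)              # fully populated
  # round trip diode -> cell -> diode
  back <- matrix(NA_integer_, 21, 66)
  back[cbind(u$row, u$col)] <- u$diode_index
  expect_identical(back[cbind(u$row, u$col)], u$diode_index)
  ring <- build_layout(pitch = 1, spacing = 1, diameter = 21, axial_length = 1)
  ur <- unwrap_index(ring)
  expect_identical(attr(ur, "dims"), c(1L, 66L))
})

test_that("radiological_path matches identity, scaling and quadrature", {
  water <- phantom_model(shell_density = 1, plug_density = 1,
                         cavity_density = 1, exterior_density = 1)
  p0 <- c(-9, 2, 1); p1 <- c(6, -4, -2)
  expect_equal(radiological_path(water, p0, p1),
               sqrt(sum((p1 - p0)^2)), tolerance = 1e-12)

  acrylic <- phantom_model(plug_present = TRUE)  # all-acrylic with plug
  d <- radiological_path(acrylic, c(0, 13.295, 0), c(0, -13.295, 0))
  expect_equal(d, 26.59 * 1.17, tolerance = 1e-9)

  set.seed(42)
  ph <- phantom_model(plug_present = FALSE)
  for (k in 1:8) {
    p0 <- c(runif(1, -13, 13), 13.295, runif(1, -5, 5))
    p1 <- c(runif(1, -13, 13), -13.295, runif(1, -5, 5))
    expect_equal(radiological_path(ph, p0, p1),
                 oracle_radiological_path(ph, p0, p1), tolerance = 1e-3)
  }
})

test_that("radiological_path is additive, symmetric, and plug-sensitive", {
  ph <- phantom_model(plug_present = TRUE)
  p0 <- c(-12, 3, 1); pm <- c(0, 0.5, 0); p1 <- c(11, -4, -1)
  # pm chosen on the p0-p1 segment? additivity only needs collinearity
  t <- 0.45; pm <- p0 + t * (p1 - p0)
  expect_equal(radiological_path(ph, p0, p1),
               radiological_path(ph, p0, pm) + radiological_path(ph, pm, p1),
               tolerance = 1e-9)
  expect_equal(radiological_path(ph, p0, p1), radiological_path(ph, p1, p0),
               tolerance = 1e-12)
  nop <- phantom_model(plug_present = FALSE)
  # any ray crossing the cavity: plug removal strictly shortens the path
  for (y in c(0, 3, -6)) {
    a <- c(-13, y, 0); b <- c(13, y, 0)
    expect_lt(radiological_path(nop, a, b), radiological_path(ph, a, b))
  }
  # contract: points must lie on the supplied ray
  rr <- ray(c(0, 100, 0), c(0, -1, 0))
  expect_error(radiological_path(ph, c(1, 5, 0), c(0, -5, 0), ray = rr),
               "contract violation")
})

test_that("layout and phantom survive plain-text export/import", {
  lay <- build_layout()
  f <- tempfile(fileext = ".txt")
  write_layout(lay, f)
  lay2 <- read_layout(f)
  expect_equal(layout_points(lay2), layout_points(lay), tolerance = 1e-9)
  expect_identical(lay2$n_diodes, lay$n_diodes)

  ph <- phantom_model(plug_present = FALSE, cavity_density = 0.0012)
  g <- tempfile(fileext = ".yml")
  write_phantom_config(ph, g)
  ph2 <- read_phantom_config(g)
  expect_equal(ph2[c("outer_diameter", "inner_diameter", "shell_density",
                     "plug_present", "plug_density", "cavity_density")],
               ph[c("outer_diameter", "inner_diameter", "shell_density",
                    "plug_present", "plug_density", "cavity_density")])
})
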
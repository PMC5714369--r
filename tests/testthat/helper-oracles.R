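# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's analytic code paths.

# brute-force quadrature of the water-equivalent path: midpoint rule with
# a fixed step along the segment, density looked up per sample
oracle_radiological_path <- function(phantom, p0, p1, step = 1e-4) {
  u <- p1 - p0
  L <- sqrt(sum(u^2))
  n <- max(1, ceiling(L / step))
  t_mid <- (seq_len(n) - 0.5) / n
  xy2 <- (p0[1] + t_mid * u[1])^2 + (p0[2] + t_mid * u[2])^2
  r <- sqrt(xy2)
  core <- if (phantom$plug_present) phantom$plug_density else phantom$cavity_density
  dens <- ifelse(r > phantom$outer_radius, phantom$exterior_density,
                 ifelse(r > phantom$inner_radius, phantom$shell_density, core))
  sum(dens) * L / n
}

# brute-force spiral walk: emit a diode every `spacing` of helical arc
# length and report positions and per-revolution counts
oracle_spiral_walk <- function(pitch, spacing, diameter, axial_length) {
  circumference <- pi * diameter
  per_rev <- round(circumference / spacing)
  actual <- sqrt((circumference / per_rev)^2 + (pitch / per_rev)^2)
  rev_len <- per_rev * actual          # helix arc length of one revolution
  n_rev <- round(axial_length / pitch)
  total <- rev_len * n_rev
  s <- seq(0, total - actual / 2, by = actual)
  frac <- s / rev_len                  # revolutions completed
  list(n = length(s),
       per_rev_counts = as.integer(table(floor(frac + 1e-12))),
       angle = (2 * pi * frac) %% (2 * pi),
       z = -axial_length / 2 + pitch * frac)
}

# seeded random-but-valid arc plan for round-trip tests
random_plan <- function(seed, n_cp = 8, n_beams = 1) {
  set.seed(seed)
  beams <- lapply(seq_len(n_beams), function(b) {
    w <- sort(c(0, runif(n_cp - 2), 1))
    cps <- lapply(seq_len(n_cp), function(i) {
      a <- runif(60, -6, 2)
      control_point(gantry_angle = runif(1, 0, 359.9),
                    collimator_angle = runif(1, 0, 359.9),
                    couch_angle = runif(1, 0, 90),
                    jaws = c(-runif(1, 3, 8), runif(1, 3, 8),
                             -runif(1, 3, 8), runif(1, 3, 8)),
                    mlc = cbind(A = a, B = a + runif(60, 0, 6)),
                    cumulative_weight = w[i])
    })
    list(control_points = cps, mu = runif(1, 50, 400),
         energy = sample(c("6X", "10X"), 1))
  })
  arc_plan(beams)
}

plan_field <- function(plan, field, fun = `[[`) {
  lapply(plan$beams, function(b) sapply(b$control_points, fun, field))
}

# flat (attenuation-free) beam: TMR identically 1
flat_beam <- function(sad = 100) {
  beam_model("6X", tmr = function(depth, field_size = 10) rep(1, length(depth)),
             sad = sad)
}

# random smooth dose plane pair for gamma tests: reference plus a perturbed
# evaluated distribution
random_plane_pair <- function(seed, n = 15, spacing = 0.5, noise = 0.015) {
  set.seed(seed)
  base <- matrix(runif(n * n, 40, 100), n, n)
  # smooth the raw noise so the fields have dose-like structure
  k <- function(m) {
    p <- rbind(m[1, ], m, m[n, ]); p <- cbind(p[, 1], p, p[, n])
    (p[1:n, 1:n] + p[1:n, 2:(n + 1)] + p[1:n, 3:(n + 2)] +
       p[2:(n + 1), 1:n] + 4 * p[2:(n + 1), 2:(n + 1)] + p[2:(n + 1), 3:(n + 2)] +
       p[3:(n + 2), 1:n] + p[3:(n + 2), 2:(n + 1)] + p[3:(n + 2), 3:(n + 2)]) / 12
  }
  ref <- k(k(base))
  ev <- ref * (1 + noise * matrix(rnorm(n * n), n, n))
  ax <- (seq_len(n) - 1) * spacing
  list(ref = dose_plane(ref, ax, ax), ev = dose_plane(ev, ax, ax))
}
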
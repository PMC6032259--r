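zaxis <- pore_axis(c(0, 0, 0), c(0, 0, 1), -6, 6)

test_that("a symmetric atom ring forces the sphere onto the axis", {
  th <- 2 * pi * (0:7) / 8
  ring <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = 1:8, icode = "", resid = "WAL", elety = "PSE",
    element = "C", x = 5 * cos(th), y = 5 * sin(th), z = 0, vdw = 1.7))
  res <- max_sphere_in_slice(ring, zaxis, 0, profiler_params(seed = 3))
  expect_equal(res$radius, 3.3, tolerance = 1e-6)
  expect_equal(res$center, c(0, 0, 0), tolerance = 1e-4)
  expect_false(res$open)
})

test_that("an empty slice is reported open at the cap", {
  far <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = 1, icode = "", resid = "WAL", elety = "PSE",
    element = "C", x = 0, y = 0, z = 100, vdw = 1.7))
  res <- max_sphere_in_slice(far, zaxis, 0, profiler_params(r_max = 10))
  expect_true(res$open)
  expect_equal(res$radius, 10)
  expect_equal(res$center, c(0, 0, 0))
})

test_that("irregular enclosing slices match the exhaustive grid oracle", {
  for (seed in 1:3) {
    s <- irregular_ring_structure(seed)
    got <- max_sphere_in_slice(s, zaxis, 0,
                               profiler_params(seed = 10 + seed))$radius
    oracle <- grid_search_sphere(s, zaxis, 0)
    expect_lt(abs(got - oracle), 0.05)
  }
})

test_that("radii are true clearance lower bounds at the returned center", {
  w <- make_channel_wall(channel_spec(function(z) 4 + 0.1 * z, c(-8, 8)))
  p <- compute_profile(w, pore_axis(c(0, 0, 0), c(0, 0, 1), -5, 5),
                       profiler_params(seed = 2))
  xyz <- aqpstruct:::atom_xyz(w)
  for (i in seq_len(nrow(p$samples))) {
    sm <- p$samples[i, ]
    d <- sqrt((xyz[, 1] - sm$cx)^2 + (xyz[, 2] - sm$cy)^2 +
              (xyz[, 3] - sm$cz)^2) - w$atoms$vdw
    expect_lt(abs(min(min(d), 10) - sm$radius), 1e-6)
  }
})

test_that("analytic cylinder and cone walls are recovered", {
  cyl <- make_channel_wall(channel_spec(function(z) 4.0, c(-8, 8),
                                        atom_density = 1, atom_vdw = 1.5))
  p <- compute_profile(cyl, pore_axis(c(0, 0, 0), c(0, 0, 1), -6, 6),
                       profiler_params(seed = 7))
  r <- p$samples$radius[!p$samples$open]
  expect_true(all(abs(r - 2.5) < 0.15))
  expect_lt(stats::var(r), 0.05)

  cone <- make_channel_wall(channel_spec(function(z) 4.0 + 0.1 * z,
                                         c(-10, 10)))
  pc <- compute_profile(cone, pore_axis(c(0, 0, 0), c(0, 0, 1), -8, 8),
                        profiler_params(seed = 7))
  expect_true(all(abs(pc$samples$radius - (2.5 + 0.1 * pc$samples$z)) < 0.15))
})

test_that("profiles are seed-reproducible and rigid-motion invariant", {
  w <- make_channel_wall(channel_spec(function(z) 4 - 0.05 * z^2 / 8,
                                      c(-8, 8)))
  ax <- pore_axis(c(0, 0, 0), c(0, 0, 1), -5, 5)
  pp <- profiler_params(seed = 9)
  p1 <- compute_profile(w, ax, pp)
  p2 <- compute_profile(w, ax, pp)
  expect_identical(p1$samples, p2$samples)
  # rotate structure and axis together
  R <- aqpstruct:::rotation_about(c(1, 1, 0), 0.7)
  w2 <- w
  xyz <- aqpstruct:::atom_xyz(w) %*% t(R)
  w2$atoms$x <- xyz[, 1]; w2$atoms$y <- xyz[, 2]; w2$atoms$z <- xyz[, 3]
  ax2 <- pore_axis(c(0, 0, 0), as.numeric(R %*% c(0, 0, 1)), -5, 5)
  p3 <- compute_profile(w2, ax2, pp)
  expect_equal(p3$samples$radius, p1$samples$radius, tolerance = 0.01)
})

test_that("inflating every vdW radius shrinks the profile by exactly that", {
  cyl <- make_channel_wall(channel_spec(function(z) 4.0, c(-6, 6)))
  ax <- pore_axis(c(0, 0, 0), c(0, 0, 1), -4, 4)
  pp <- profiler_params(seed = 21)
  p1 <- compute_profile(cyl, ax, pp)
  cyl2 <- cyl
  cyl2$atoms$vdw <- cyl2$atoms$vdw + 0.25
  p2 <- compute_profile(cyl2, ax, pp)
  expect_equal(p1$samples$radius - p2$samples$radius,
               rep(0.25, nrow(p1$samples)), tolerance = 1e-9)
})

test_that("axis estimation matches construction and flags degeneracy", {
  b <- make_bundle_channel(6, 9, 30)
  ax <- estimate_axis(b)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(2 * pi / 180))
  # tetramer monomer axis is parallel to the assembly axis within 5 degrees
  h <- make_ideal_helix(20, "A", placement = list(t = c(7, 0, 0)))
  tet <- build_c4_assembly(h)
  ca <- tet$atoms[tet$atoms$chain == "A" & tet$atoms$elety == "CA", ]
  mono <- aqpstruct:::new_structure(tet$atoms[tet$atoms$chain == "A", ])
  axm <- estimate_axis(mono)
  expect_gt(abs(sum(axm$direction * c(0, 0, 1))), cos(5 * pi / 180))
  # near-spherical cloud: degenerate inertia is an error
  blob <- aqpstruct:::with_local_seed(5, {
    n <- 60
    aqpstruct:::new_structure(data.frame(
      chain = "A", resno = 1:n, icode = "", resid = "ALA", elety = "CA",
      element = "C", x = stats::rnorm(n), y = stats::rnorm(n),
      z = stats::rnorm(n)))
  })
  expect_error(estimate_axis(blob), "degenerate")
})

test_that("profile comparison localizes narrowing and errors on disjoint z", {
  base <- function(z) 5 - 1.5 * exp(-z^2 / 8)
  wt <- make_channel_wall(channel_spec(base, c(-16, 16)))
  mutfun <- function(z) base(z) - 1.0 * exp(-(z + 10)^2 / 4)
  mut <- make_channel_wall(channel_spec(mutfun, c(-16, 16)))
  ax <- pore_axis(c(0, 0, 0), c(0, 0, 1), -14, 14)
  pp <- profiler_params(seed = 3)
  pw <- compute_profile(wt, ax, pp)
  pm <- compute_profile(mut, ax, pp)
  expect_equal(pw$z0, 0, tolerance = pp$step + 1e-9)
  # identical profiles: no delta
  d0 <- compare_profiles(pw, pw)
  expect_true(all(abs(d0$samples$delta) < 1e-12))
  expect_equal(nrow(d0$regions), 0)
  dd <- compare_profiles(pw, pm, threshold = 0.3, min_run = 3)
  expect_gte(nrow(dd$regions), 1)
  main <- dd$regions[which.max(dd$regions$max_reduction), ]
  expect_equal(main$side, "cytoplasmic")
  expect_true(main$z_start <= -10 && main$z_end >= -10)
  # disjoint ranges are an error
  ax_hi <- pore_axis(c(0, 0, 0), c(0, 0, 1), 20, 24)
  expect_error(compare_profiles(pw, structure(list(
    samples = data.frame(z = c(21, 22), radius = 1, open = FALSE)),
    class = "pore_profile")), "disjoint")
})

test_that("a structure with no enclosed channel raises an error", {
  far <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = 1, icode = "", resid = "WAL", elety = "PSE",
    element = "C", x = 50, y = 50, z = 0, vdw = 1.5))
  expect_error(compute_profile(far, pore_axis(c(0, 0, 0), c(0, 0, 1), -2, 2),
                               profiler_params()),
               "no channel")
})
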
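test_that("formal charges are assigned to the canonical group atoms", {
  h <- make_ideal_helix(10, "A")
  expect_equal(nrow(assign_charges(h)), 0)
  hr <- make_ideal_helix(10, "AAAARAAAAA")
  ch <- assign_charges(hr)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$q, 1)
  expect_equal(ch$resid, "ARG")
  # mutant differs from wild type by exactly one negative site
  wt <- make_ideal_helix(12, "A")
  mut <- mutate_residue(wt, mutation_spec("A", 6, "A", "E"))
  cm <- assign_charges(mut)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$q, -1)
  expect_equal(cm$resno, 6)
  # missing charged-group atoms skip the residue with a warning
  broken <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = 1, icode = "", resid = "ASP", elety = "OD1",
    element = "O", x = 0, y = 0, z = 0))
  expect_warning(out <- assign_charges(broken), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the solver reproduces Coulomb in a uniform dielectric", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  g <- solve_pb(NULL, ch, pb_params(eps_solute = 80, padding = 12))
  r <- c(5, 6, 7, 8, 9, 10)
  phi <- grid_potential(g, cbind(r, 0, 0))
  exact <- 560.74 / (80 * r)
  expect_true(all(abs(phi / exact - 1) < 0.05))
})

test_that("zero charge gives a zero grid and non-convergence errors", {
  h <- make_ideal_helix(6, "A")
  g0 <- solve_pb(h, assign_charges(h))
  expect_true(all(g0$phi == 0))
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  expect_error(solve_pb(NULL, ch, pb_params(max_iter = 2, padding = 10)),
               "did not converge")
})

test_that("the linearized solver is linear and superposable", {
  pp <- pb_params()
  bx <- rbind(c(-12, 12), c(-10, 10), c(-10, 10))
  c1 <- data.frame(x = -3, y = 0, z = 0, q = 1)
  c2 <- data.frame(x = 3, y = 0, z = 0, q = -1)
  g1 <- solve_pb(NULL, c1, pp, box = bx)
  g2 <- solve_pb(NULL, c2, pp, box = bx)
  g12 <- solve_pb(NULL, rbind(c1, c2), pp, box = bx)
  pts <- aqpstruct:::with_local_seed(3, {
    cbind(stats::runif(25, -8, 8), stats::runif(25, -6, 6),
          stats::runif(25, -6, 6))
  })
  expect_equal(grid_potential(g12, pts),
               grid_potential(g1, pts) + grid_potential(g2, pts),
               tolerance = 1e-3)
  gs <- solve_pb(NULL, transform(c1, q = 2), pp, box = bx)
  expect_equal(grid_potential(gs, pts), 2 * grid_potential(g1, pts),
               tolerance = 1e-3)
  # mirror-symmetric +/- pair: antisymmetric potential
  mir <- cbind(-pts[, 1], pts[, 2], pts[, 3])
  expect_equal(grid_potential(g12, pts), -grid_potential(g12, mir),
               tolerance = 1e-3)
})

test_that("grid refinement shrinks the Coulomb discretization error", {
  ch <- data.frame(x = 0.3, y = 0.2, z = -0.1, q = 1)
  bx <- rbind(c(-9, 9), c(-9, 9), c(-9, 9))
  pts <- cbind(c(4, 5, 6), 0.5, -0.5)
  err <- function(spacing) {
    g <- solve_pb(NULL, ch,
                  pb_params(eps_solute = 80, grid_spacing_coarse = 2,
                            grid_spacing_fine = spacing, padding = 6),
                  box = bx)
    exact <- 560.74 / (80 * sqrt(rowSums(sweep(pts, 2,
      c(0.3, 0.2, -0.1))^2)))
    max(abs(grid_potential(g, pts) - exact))
  }
  expect_lt(err(0.75), err(1.5))
})

test_that("surface-potential deltas localize an introduced charge", {
  wt <- make_ideal_helix(12, "A")
  mut <- mutate_residue(wt, mutation_spec("A", 6, "A", "E"))
  box <- rbind(range(mut$atoms$x) + c(-8, 8),
               range(mut$atoms$y) + c(-8, 8),
               range(mut$atoms$z) + c(-8, 8))
  pp <- pb_params()
  gw <- solve_pb(wt, assign_charges(wt), pp, box = box)
  gm <- solve_pb(mut, assign_charges(mut), pp, box = box)
  ca <- unlist(wt$atoms[wt$atoms$resno == 6 & wt$atoms$elety == "CA",
                        c("x", "y", "z")])
  dd <- surface_potential_delta(gw, gm, ca, radius = 8)
  expect_lt(dd$mean, 0)
  # identical grids give exactly zero
  d0 <- surface_potential_delta(gw, gw, ca, radius = 8)
  expect_equal(d0$mean, 0)
  expect_equal(d0$min, 0)
  # mismatched lattices are rejected
  gw2 <- solve_pb(wt, assign_charges(wt), pp,
                  box = box + matrix(c(-1, 1), 3, 2, byrow = TRUE))
  expect_error(surface_potential_delta(gw2, gm, ca), "different lattices")
})
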
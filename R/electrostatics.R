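# Finite-difference linearized Poisson-Boltzmann solver for surface
# electrostatics. Potentials are in kT/e, lengths in angstrom, charges
# formal (+1 Arg/Lys, -1 Asp/Glu carboxylate midpoints). The dielectric
# boundary is the union of van der Waals spheres; the linear system is
# solved by red-black successive over-relaxation with two-pass coarse-to-
# fine grid focusing.

# Coulomb constant e^2/(4 pi eps0 kT) in angstrom, i.e. phi = 560.7/(eps r)
# kT/e for a unit charge, at T = 298.15 K; rescaled with temperature.
.coulomb_kT_A <- function(temperature) 560.74 * 298.15 / temperature

#' Poisson-Boltzmann parameters
#'
#' Defaults follow common continuum-electrostatics practice for membrane
#' proteins: solute dielectric 1.0, solvent dielectric 80.0, coarse grid
#' spacing 1.5 A focused to a fine spacing of 1.0 A.
#'
#' @param eps_solute,eps_solvent interior and solvent dielectric constants.
#' @param grid_spacing_coarse,grid_spacing_fine grid spacings in angstrom
#'   (fine must not exceed coarse).
#' @param ionic_strength mol/L; the Debye term acts in the solvent only.
#' @param temperature kelvin.
#' @param padding solvent margin around the structure for the fine grid, in
#'   angstrom; the coarse grid uses twice this margin.
#' @param tol SOR convergence tolerance on the maximum update, kT/e.
#' @param max_iter SOR iteration cap.
#' @return a `pb_params` list.
#' @export
pb_params <- function(eps_solute = 1.0, eps_solvent = 80.0,
                      grid_spacing_coarse = 1.5, grid_spacing_fine = 1.0,
                      ionic_strength = 0, temperature = 298.15,
                      padding = 8, tol = 1e-4, max_iter = 5000L) {
  stopifnot(grid_spacing_coarse > 0, grid_spacing_fine > 0,
            grid_spacing_fine <= grid_spacing_coarse,
            eps_solute >= 1, eps_solvent >= 1, padding > 0)
  structure(list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                 grid_spacing_coarse = grid_spacing_coarse,
                 grid_spacing_fine = grid_spacing_fine,
                 ionic_strength = ionic_strength, temperature = temperature,
                 padding = padding, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "pb_params")
}

#' Assign formal charges to a structure
#'
#' +1 at Arg CZ and Lys NZ; -1 at the midpoint of the Asp and Glu
#' carboxylate oxygens; His neutral. Residues missing their charged-group
#' atoms are skipped with a warning.
#'
#' @param structure an `aqp_structure`.
#' @return data frame (chain, resno, resid, x, y, z, q).
#' @export
assign_charges <- function(structure) {
  a <- structure$atoms
  rt <- residue_table(structure)
  out <- list()
  spec <- list(ARG = list(at = "CZ", q = +1), LYS = list(at = "NZ", q = +1),
               ASP = list(at = c("OD1", "OD2"), q = -1),
               GLU = list(at = c("OE1", "OE2"), q = -1))
  for (i in seq_len(nrow(rt))) {
    sp <- spec[[rt$resid[i]]]
    if (is.null(sp)) next
    idx <- a$chain == rt$chain[i] & a$resno == rt$resno[i] &
      a$icode == rt$icode[i] & a$elety %in% sp$at
    if (sum(idx) < length(sp$at)) {
      warning("charged-group atom(s) missing in ", rt$resid[i], " ",
              rt$resno[i], "; residue skipped")
      next
    }
    out[[length(out) + 1]] <- data.frame(
      chain = rt$chain[i], resno = rt$resno[i], resid = rt$resid[i],
      x = mean(a$x[idx]), y = mean(a$y[idx]), z = mean(a$z[idx]),
      q = sp$q, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), x = numeric(), y = numeric(),
                      z = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build one grid level: dielectric map from vdW spheres, Debye factor in
# the solvent, charge spread by trilinear weights, boundary potential from
# the screened-Coulomb superposition, then red-black SOR.
solve_pb_level <- function(xyz, vdw, charges, spacing, lims, params,
                           boundary = NULL) {
  C <- .coulomb_kT_A(params$temperature)
  dims <- pmax(8L, as.integer(ceiling((lims[, 2] - lims[, 1]) / spacing)) + 1L)
  origin <- lims[, 1]
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  gx <- origin[1] + (seq_len(nx) - 1) * spacing
  gy <- origin[2] + (seq_len(ny) - 1) * spacing
  gz <- origin[3] + (seq_len(nz) - 1) * spacing

  eps <- array(params$eps_solvent, dim = dims)
  if (!is.null(xyz) && nrow(xyz) > 0) {
    for (i in seq_len(nrow(xyz))) {
      r <- vdw[i]
      ix <- which(abs(gx - xyz[i, 1]) <= r)
      iy <- which(abs(gy - xyz[i, 2]) <= r)
      iz <- which(abs(gz - xyz[i, 3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (gx[ix] - xyz[i, 1])^2
      dy2 <- (gy[iy] - xyz[i, 2])^2
      dz2 <- (gz[iz] - xyz[i, 3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      sub <- eps[ix, iy, iz]
      sub[inside] <- params$eps_solute
      eps[ix, iy, iz] <- sub
    }
  }
  # Debye screening in the solvent only: kappa^2 = 8 pi l_B n_ion
  lB <- C / params$eps_solvent
  n_ion <- params$ionic_strength * 6.022e-4  # ions / A^3 at 1 mol/L
  kappa2 <- 8 * pi * lB * n_ion
  solv <- eps == params$eps_solvent

  # charge density: trilinear (cloud-in-cell) spreading, units e per node
  rho <- array(0, dim = dims)
  for (i in seq_len(nrow(charges))) {
    fx <- (charges$x[i] - origin[1]) / spacing
    fy <- (charges$y[i] - origin[2]) / spacing
    fz <- (charges$z[i] - origin[3]) / spacing
    i0 <- floor(c(fx, fy, fz))
    w <- c(fx, fy, fz) - i0
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      ii <- i0 + c(ox, oy, oz) + 1
      if (any(ii < 1) || any(ii > dims)) next
      wt <- prod(ifelse(c(ox, oy, oz) == 1, w, 1 - w))
      rho[ii[1], ii[2], ii[3]] <- rho[ii[1], ii[2], ii[3]] + charges$q[i] * wt
    }
  }

  phi <- array(0, dim = dims)
  if (is.null(boundary)) {
    # screened-Coulomb Dirichlet boundary
    kap <- sqrt(kappa2)
    face_phi <- function(px, py, pz) {
      v <- 0
      for (i in seq_len(nrow(charges))) {
        r <- sqrt((px - charges$x[i])^2 + (py - charges$y[i])^2 +
                  (pz - charges$z[i])^2)
        r <- pmax(r, spacing / 2)
        v <- v + charges$q[i] * C * exp(-kap * r) / (params$eps_solvent * r)
      }
      v
    }
    phi[1, , ] <- outer(gy, gz, function(py, pz) face_phi(gx[1], py, pz))
    phi[nx, , ] <- outer(gy, gz, function(py, pz) face_phi(gx[nx], py, pz))
    phi[, 1, ] <- outer(gx, gz, function(px, pz) face_phi(px, gy[1], pz))
    phi[, ny, ] <- outer(gx, gz, function(px, pz) face_phi(px, gy[ny], pz))
    phi[, , 1] <- outer(gx, gy, function(px, py) face_phi(px, py, gz[1]))
    phi[, , nz] <- outer(gx, gy, function(px, py) face_phi(px, py, gz[nz]))
  } else {
    # focusing: boundary interpolated from the coarse solution
    bset <- function(ii, jj, kk) {
      pts <- as.matrix(expand.grid(gx[ii], gy[jj], gz[kk]))
      vals <- interp_grid(boundary, pts)
      phi[ii, jj, kk] <<- array(vals, dim = c(length(ii), length(jj),
                                              length(kk)))
    }
    bset(1L, seq_len(ny), seq_len(nz))
    bset(nx, seq_len(ny), seq_len(nz))
    bset(seq_len(nx), 1L, seq_len(nz))
    bset(seq_len(nx), ny, seq_len(nz))
    bset(seq_len(nx), seq_len(ny), 1L)
    bset(seq_len(nx), seq_len(ny), nz)
  }

  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nz - 1)
  # link dielectrics (arithmetic mean across each face)
  exp_ <- function(sh) eps[ii + sh[1], jj + sh[2], kk + sh[3]]
  e0 <- eps[ii, jj, kk]
  eW <- (e0 + exp_(c(-1, 0, 0))) / 2; eE <- (e0 + exp_(c(1, 0, 0))) / 2
  eS <- (e0 + exp_(c(0, -1, 0))) / 2; eN <- (e0 + exp_(c(0, 1, 0))) / 2
  eD <- (e0 + exp_(c(0, 0, -1))) / 2; eU <- (e0 + exp_(c(0, 0, 1))) / 2
  diagc <- eW + eE + eS + eN + eD + eU +
    ifelse(solv[ii, jj, kk], params$eps_solvent * kappa2 * spacing^2, 0)
  src <- 4 * pi * C * rho[ii, jj, kk] / spacing
  # red-black mask on the interior
  rb <- (outer(outer(ii, jj, `+`), kk, `+`)) %% 2
  omega <- 2 / (1 + pi / mean(dims))
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    delta_max <- 0
    for (colr in 0:1) {
      nb <- eW * phi[ii - 1, jj, kk] + eE * phi[ii + 1, jj, kk] +
        eS * phi[ii, jj - 1, kk] + eN * phi[ii, jj + 1, kk] +
        eD * phi[ii, jj, kk - 1] + eU * phi[ii, jj, kk + 1]
      new <- (nb + src) / diagc
      cur <- phi[ii, jj, kk]
      upd <- cur + omega * (new - cur)
      mask <- rb == colr
      delta <- abs(upd - cur) * mask
      delta_max <- max(delta_max, max(delta))
      cur[mask] <- upd[mask]
      phi[ii, jj, kk] <- cur
    }
    if (delta_max < params$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("PB solver did not converge: residual %.2e after %d iters",
                 delta_max, params$max_iter))
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 phi = phi, eps = eps, kappa2 = kappa2,
                 eps_solvent = params$eps_solvent),
            class = "pb_grid")
}

# Trilinear interpolation of a pb_grid at arbitrary points (n x 3 matrix).
interp_grid <- function(grid, pts) {
  f <- sweep(pts, 2, grid$origin) / grid$spacing
  f <- pmin(pmax(f, 0), matrix(rep(grid$dims - 1, each = nrow(pts)),
                               ncol = 3) - 1e-9)
  i0 <- floor(f)
  w <- f - i0
  val <- numeric(nrow(pts))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    wt <- (if (ox == 1) w[, 1] else 1 - w[, 1]) *
      (if (oy == 1) w[, 2] else 1 - w[, 2]) *
      (if (oz == 1) w[, 3] else 1 - w[, 3])
    idx <- cbind(i0[, 1] + ox + 1, i0[, 2] + oy + 1, i0[, 3] + oz + 1)
    val <- val + wt * grid$phi[idx]
  }
  val
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Two-pass focusing: a coarse solve with screened-Coulomb boundary
#' conditions over an extended box, then a fine solve whose boundary is
#' interpolated from the coarse solution. With `structure = NULL` the
#' dielectric is uniform at the solvent value (the analytic Coulomb
#' regime).
#'
#' @param structure an `aqp_structure`, or `NULL` for uniform dielectric.
#' @param charges data frame (x, y, z, q), e.g. from [assign_charges()].
#' @param params a [pb_params()].
#' @param focus set `FALSE` to skip focusing and solve a single fine grid.
#' @param box optional 3 x 2 matrix of x/y/z limits for the fine grid;
#'   supply the same box to wild type and mutant so their grids share a
#'   lattice.
#' @return a `pb_grid` with the potential in kT/e.
#' @export
solve_pb <- function(structure, charges, params = pb_params(),
                     focus = TRUE, box = NULL) {
  if (nrow(charges) == 0 || all(charges$q == 0)) {
    # trivially zero potential on the fine lattice
    lims <- box %||% charge_lims(structure, charges, params$padding)
    dims <- pmax(8L, as.integer(ceiling((lims[, 2] - lims[, 1]) /
                                          params$grid_spacing_fine)) + 1L)
    return(structure(list(origin = lims[, 1],
                          spacing = params$grid_spacing_fine,
                          dims = dims, phi = array(0, dim = dims),
                          eps = array(params$eps_solvent, dim = dims),
                          kappa2 = 0, eps_solvent = params$eps_solvent),
                     class = "pb_grid"))
  }
  xyz <- NULL; vdw <- NULL
  if (!is.null(structure)) {
    xyz <- atom_xyz(structure); vdw <- structure$atoms$vdw
  }
  lims_fine <- box %||% charge_lims(structure, charges, params$padding)
  if (focus) {
    lims_coarse <- lims_fine + matrix(c(-1, 1) * params$padding,
                                      nrow = 3, ncol = 2, byrow = TRUE)
    coarse <- solve_pb_level(xyz, vdw, charges, params$grid_spacing_coarse,
                             lims_coarse, params, boundary = NULL)
    solve_pb_level(xyz, vdw, charges, params$grid_spacing_fine, lims_fine,
                   params, boundary = coarse)
  } else {
    solve_pb_level(xyz, vdw, charges, params$grid_spacing_fine, lims_fine,
                   params, boundary = NULL)
  }
}

charge_lims <- function(structure, charges, pad) {
  pts <- as.matrix(charges[, c("x", "y", "z")])
  if (!is.null(structure)) pts <- rbind(pts, atom_xyz(structure))
  rbind(range(pts[, 1]) + c(-pad, pad),
        range(pts[, 2]) + c(-pad, pad),
        range(pts[, 3]) + c(-pad, pad))
}

#' @export
print.pb_grid <- function(x, ...) {
  cat("pb_grid: ", paste(x$dims, collapse = " x "), " nodes, spacing ",
      x$spacing, " A\n", sep = "")
  cat("  potential range [", round(min(x$phi), 3), ", ",
      round(max(x$phi), 3), "] kT/e\n", sep = "")
  invisible(x)
}

#' Potential of a grid at arbitrary points
#'
#' @param grid a `pb_grid`.
#' @param pts n x 3 matrix of coordinates (angstrom).
#' @return numeric vector, kT/e.
#' @export
grid_potential <- function(grid, pts) {
  interp_grid(grid, as.matrix(pts))
}

#' Mean surface-potential change near a mutation site
#'
#' Averages the potential difference (mutant minus wild type) over
#' solvent-side nodes within `radius` of the site centre. Grids must share
#' the lattice.
#'
#' @param wt_grid,mut_grid `pb_grid`s on the same lattice.
#' @param center length-3 site coordinates (e.g. the mutated residue's CA).
#' @param radius sphere radius in angstrom.
#' @return list with `mean`, `min`, `max` potential difference (kT/e) and
#'   `n_nodes`.
#' @export
surface_potential_delta <- function(wt_grid, mut_grid, center, radius = 8) {
  if (!all(wt_grid$dims == mut_grid$dims) ||
      max(abs(wt_grid$origin - mut_grid$origin)) > 1e-9 ||
      wt_grid$spacing != mut_grid$spacing) {
    stop("potential grids are on different lattices")
  }
  dims <- wt_grid$dims
  gx <- wt_grid$origin[1] + (seq_len(dims[1]) - 1) * wt_grid$spacing
  gy <- wt_grid$origin[2] + (seq_len(dims[2]) - 1) * wt_grid$spacing
  gz <- wt_grid$origin[3] + (seq_len(dims[3]) - 1) * wt_grid$spacing
  dx2 <- (gx - center[1])^2
  dy2 <- (gy - center[2])^2
  dz2 <- (gz - center[3])^2
  near <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  solv <- wt_grid$eps == wt_grid$eps_solvent &
    mut_grid$eps == mut_grid$eps_solvent
  sel <- near & solv
  if (!any(sel)) stop("no solvent nodes within the given radius")
  dphi <- mut_grid$phi[sel] - wt_grid$phi[sel]
  list(mean = mean(dphi), min = min(dphi), max = max(dphi),
       n_nodes = sum(sel))
}

#' Write a potential grid in OpenDX scalar-field format
#'
#' @param grid a `pb_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dims
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: z fastest-varying
  v <- numeric(prod(d))
  n <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v[n + seq_len(d[3])] <- grid$phi[i, j, ]
    n <- n + d[3]
  }
  writeLines(paste(formatC(v, format = "e", digits = 5),
                   collapse = "\n"), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
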
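# Pore-radius profiling by maximal-sphere search along a channel axis, in
# the style of HOLE: at each slice plane the largest sphere not overlapping
# any van der Waals sphere is found by seeded stochastic search plus a
# deterministic compass polish, the sphere centre being constrained to the
# slice plane.

#' Channel axis description
#'
#' @param origin a point on the axis (angstrom).
#' @param direction axis direction; by convention + points extracellular.
#' @param z_min,z_max profiled range along the axis, relative to `origin`.
#' @return a `pore_axis` object.
#' @export
pore_axis <- function(origin, direction, z_min, z_max) {
  stopifnot(z_min < z_max)
  structure(list(origin = as.numeric(origin), direction = unit(direction),
                 z_min = z_min, z_max = z_max),
            class = "pore_axis")
}

#' Estimate the channel axis of a membrane-channel structure
#'
#' The axis is the first principal inertial axis of the transmembrane CA
#' atoms (annotated helix ranges when an annotation is attached, all CA atoms
#' otherwise) through their centroid; the profiled range covers the
#' transmembrane region plus 5 angstrom on both sides.
#'
#' @param structure an `aqp_structure` with at least 50 atoms.
#' @param flip set `TRUE` if the estimated + direction points cytoplasmic.
#' @return a `pore_axis`.
#' @export
estimate_axis <- function(structure, flip = FALSE) {
  a <- structure$atoms
  if (nrow(a) < 50) stop("structure too small to estimate an axis")
  ca <- a[a$elety == "CA", , drop = FALSE]
  if (!is.null(structure$annotation)) {
    keep <- rep(FALSE, nrow(ca))
    for (iv in structure$annotation$helix_ranges) {
      keep <- keep | (ca$resno >= iv[1] & ca$resno <= iv[2])
    }
    if (sum(keep) >= 10) ca <- ca[keep, , drop = FALSE]
  }
  if (nrow(ca) < 4) ca <- a
  pa <- principal_axes(as.matrix(ca[, c("x", "y", "z")]))
  if (pa$values[1] < 1.5 * pa$values[2]) {
    stop("degenerate inertia tensor (near-spherical atom cloud); ",
         "supply the channel axis explicitly")
  }
  dir <- pa$vectors[, 1]
  if (flip) dir <- -dir
  proj <- as.matrix(ca[, c("x", "y", "z")]) %*% dir -
    sum(pa$center * dir)
  pore_axis(pa$center, dir, min(proj) - 5, max(proj) + 5)
}

#' Profiler parameters
#'
#' @param step slice spacing in angstrom.
#' @param r_max radius cap; a slice reaching it is declared open, mirroring
#'   HOLE's end-of-pore behaviour.
#' @param seed integer seed for the stochastic sphere search.
#' @param anneal_steps proposals per slice; the proposal step starts at
#'   0.5 A and decays by 0.9 every 50 proposals.
#' @return a `profiler_params` list.
#' @export
profiler_params <- function(step = 0.5, r_max = 10, seed = 42L,
                            anneal_steps = 400L) {
  stopifnot(step > 0, r_max > 0, anneal_steps >= 0)
  structure(list(step = step, r_max = r_max, seed = as.integer(seed),
                 anneal_steps = as.integer(anneal_steps)),
            class = "profiler_params")
}

# Clearance at an in-plane point (a, b): min over atoms of
# |centre - atom| - vdw, capped at r_max.
.slice_clearance <- function(ab, sp, atoms_xyz, atoms_vdw, r_max) {
  ctr <- sp$p0 + ab[1] * sp$u + ab[2] * sp$v
  if (nrow(atoms_xyz) == 0) return(r_max)
  d <- sqrt((atoms_xyz[, 1] - ctr[1])^2 +
            (atoms_xyz[, 2] - ctr[2])^2 +
            (atoms_xyz[, 3] - ctr[3])^2) - atoms_vdw
  min(min(d), r_max)
}

#' Largest sphere in one slice plane
#'
#' Maximises the clearance `min_i(|c - x_i| - vdw_i)` over centres `c`
#' constrained to the plane at axial coordinate `z`, by seeded stochastic
#' hill-climbing (step 0.5 A decaying by 0.9 per 50 proposals) followed by a
#' deterministic compass polish. The radius is capped at `r_max`; hitting the
#' cap sets the open flag.
#'
#' @param structure an `aqp_structure`, or a list with elements `xyz`
#'   (matrix) and `vdw`.
#' @param axis a `pore_axis`.
#' @param z axial coordinate of the slice, relative to the axis origin.
#' @param params a [profiler_params()].
#' @param start_center in-plane starting offset `c(a, b)`.
#' @return list with `center` (3D point), `radius`, `open`.
#' @export
max_sphere_in_slice <- function(structure, axis, z,
                                params = profiler_params(),
                                start_center = c(0, 0)) {
  if (inherits(structure, "aqp_structure")) {
    xyz <- atom_xyz(structure); vdw <- structure$atoms$vdw
  } else {
    xyz <- as.matrix(structure$xyz); vdw <- structure$vdw
  }
  bs <- plane_basis(axis$direction)
  p0 <- axis$origin + z * bs$w
  sp <- list(p0 = p0, u = bs$u, v = bs$v)
  # atoms that can possibly constrain a sphere of radius <= r_max
  zx <- as.numeric(xyz %*% bs$w) - sum(p0 * bs$w)
  reach <- params$r_max + max(vdw, 0) + 1e-9
  sel <- abs(zx) <= reach
  axyz <- xyz[sel, , drop = FALSE]; avdw <- vdw[sel]
  f <- function(ab) .slice_clearance(ab, sp, axyz, avdw, params$r_max)
  cur <- as.numeric(start_center)
  best <- f(cur)
  if (nrow(axyz) > 0 && params$anneal_steps > 0) {
    with_local_seed(params$seed + round(1000 * z), {
      stepsize <- 0.5
      for (i in seq_len(params$anneal_steps)) {
        ang <- stats::runif(1, 0, 2 * pi)
        trial <- cur + stepsize * c(cos(ang), sin(ang))
        ft <- f(trial)
        if (ft > best) {
          cur <- trial; best <- ft
        }
        if (i %% 50 == 0) stepsize <- stepsize * 0.9
      }
    })
  }
  # deterministic coarse-grid second start guards against a stochastic
  # search stranded in a shallow local basin
  if (nrow(axyz) > 0) {
    g <- seq(-2, 2, by = 0.5)
    gr <- expand.grid(a = g + cur[1], b = g + cur[2])
    fg <- vapply(seq_len(nrow(gr)), function(i) f(c(gr$a[i], gr$b[i])),
                 numeric(1))
    k <- which.max(fg)
    starts <- list(cur, c(gr$a[k], gr$b[k]))
  } else {
    starts <- list(cur)
  }
  # compass polish each start to a deterministic local maximum
  polish <- function(c0) {
    b0 <- f(c0)
    h <- 0.25
    while (h > 5e-5) {
      moved <- FALSE
      for (d in list(c(h, 0), c(-h, 0), c(0, h), c(0, -h))) {
        ft <- f(c0 + d)
        if (ft > b0 + 1e-12) {
          c0 <- c0 + d; b0 <- ft; moved <- TRUE
        }
      }
      if (!moved) h <- h / 2
    }
    list(c = c0, f = b0)
  }
  for (s0 in starts) {
    r <- polish(s0)
    if (r$f > best) {
      cur <- r$c; best <- r$f
    }
  }
  open <- best >= params$r_max - 1e-9
  list(center = sp$p0 + cur[1] * sp$u + cur[2] * sp$v,
       radius = min(best, params$r_max), open = open,
       ab = cur)
}

#' Pore-radius profile along the channel axis
#'
#' Slices every `step` angstrom from `z_min` to `z_max`; each slice search is
#' seeded from the previous slice centre (the first from the axis origin).
#' The pore-centre reference `z0` is the axial coordinate of the radius
#' minimum within the annotated NPA region when the structure carries one,
#' otherwise the global minimum over non-open slices.
#'
#' @param structure an `aqp_structure`.
#' @param axis a `pore_axis`; computed by [estimate_axis()] when `NULL`.
#' @param params a [profiler_params()].
#' @return a `pore_profile` with a `samples` data frame (z, x, y, z-coords of
#'   centre, radius, open), `z0`, `step` and the axis.
#' @export
compute_profile <- function(structure, axis = NULL,
                            params = profiler_params()) {
  if (is.null(axis)) axis <- estimate_axis(structure)
  zs <- seq(axis$z_min, axis$z_max, by = params$step)
  ab <- c(0, 0)
  rows <- vector("list", length(zs))
  dat <- list(xyz = atom_xyz(structure), vdw = structure$atoms$vdw)
  for (i in seq_along(zs)) {
    res <- max_sphere_in_slice(dat, axis, zs[i], params, start_center = ab)
    if (!res$open) ab <- res$ab
    rows[[i]] <- data.frame(z = zs[i], cx = res$center[1], cy = res$center[2],
                            cz = res$center[3], radius = res$radius,
                            open = res$open)
  }
  samples <- do.call(rbind, rows)
  if (all(samples$open)) stop("no channel found: all slices are open")
  closed <- samples[!samples$open, , drop = FALSE]
  z0 <- closed$z[which.min(closed$radius)]
  ann <- structure$annotation
  if (!is.null(ann) && length(ann$npa_residues)) {
    sel <- structure$atoms$resno %in% ann$npa_residues
    if (any(sel)) {
      znpa <- atom_xyz(structure, sel) %*% axis$direction -
        sum(axis$origin * axis$direction)
      inb <- closed$z >= min(znpa) - 2 & closed$z <= max(znpa) + 2
      if (any(inb)) z0 <- closed$z[inb][which.min(closed$radius[inb])]
    }
  }
  structure(list(samples = samples, z0 = z0, step = params$step,
                 axis = axis, params = params),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore_profile: ", nrow(x$samples), " slices, step ", x$step,
      " A, z in [", min(x$samples$z), ", ", max(x$samples$z),
      "], z0 = ", x$z0, "\n", sep = "")
  cl <- x$samples[!x$samples$open, ]
  cat("  min radius ", round(min(cl$radius), 2), " A at z = ",
      cl$z[which.min(cl$radius)], "\n", sep = "")
  invisible(x)
}

#' Compare wild-type and mutant pore profiles
#'
#' Computes the per-slice radius difference (wild type minus mutant) and
#' reports narrowing regions: runs of at least `min_run` consecutive slices
#' with a reduction of at least `threshold` angstrom. Regions are labelled
#' cytoplasmic (below the wild-type `z0`) or extracellular (above it).
#' Profiles on different z-grids are resampled by linear interpolation onto
#' the wild-type grid.
#'
#' @param wt,mut `pore_profile` objects on the same axis.
#' @param threshold minimum radius reduction (angstrom).
#' @param min_run minimum number of consecutive slices.
#' @return a `profile_delta` with `samples` (z, wt, mut, delta) and
#'   `regions` (z_start, z_end, max_reduction, side).
#' @export
compare_profiles <- function(wt, mut, threshold = 0.3, min_run = 3) {
  zs <- wt$samples$z
  if (max(mut$samples$z) < min(zs) || min(mut$samples$z) > max(zs)) {
    stop("profiles cover disjoint z-ranges")
  }
  mr <- stats::approx(mut$samples$z, mut$samples$radius, xout = zs,
                      rule = 1)$y
  keep <- !is.na(mr) & !wt$samples$open
  df <- data.frame(z = zs[keep], wt = wt$samples$radius[keep],
                   mut = mr[keep])
  df$delta <- df$wt - df$mut
  hit <- df$delta >= threshold
  regions <- list()
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_run) {
      seg <- df[starts[i]:ends[i], ]
      mid <- mean(range(seg$z))
      regions[[length(regions) + 1]] <-
        data.frame(z_start = min(seg$z), z_end = max(seg$z),
                   max_reduction = max(seg$delta),
                   side = if (mid < wt$z0) "cytoplasmic" else "extracellular")
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(z_start = numeric(), z_end = numeric(),
               max_reduction = numeric(), side = character())
  structure(list(samples = df, regions = regions, z0 = wt$z0,
                 threshold = threshold, min_run = min_run),
            class = "profile_delta")
}

#' @export
print.profile_delta <- function(x, ...) {
  cat("profile_delta: ", nrow(x$samples), " compared slices, ",
      nrow(x$regions), " narrowing region(s)\n", sep = "")
  if (nrow(x$regions)) print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Write a pore profile as TSV
#'
#' @param profile a `pore_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile$samples[, c("z", "radius", "open")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a pore profile, optionally against a mutant
#'
#' @param x a `pore_profile`.
#' @param mut optional second profile drawn for comparison.
#' @param ... passed to [plot()].
#' @export
plot.pore_profile <- function(x, mut = NULL, ...) {
  s <- x$samples[!x$samples$open, ]
  plot(s$z - x$z0, s$radius, type = "l", col = "blue",
       xlab = "distance from pore centre (A)", ylab = "pore radius (A)", ...)
  if (!is.null(mut)) {
    sm <- mut$samples[!mut$samples$open, ]
    graphics::lines(sm$z - x$z0, sm$radius, col = "violetred")
  }
  invisible(x)
}
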
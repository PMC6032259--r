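# Small 3D geometry kernel shared by the mutator, profiler and generators.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` radians about the (unnormalised) `axis`.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, theta) {
  k <- unit(axis)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Dihedral angle a-b-c-d in degrees, signed by the standard convention.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural extension reference frame (NeRF) placement: returns the position of
# atom D given reference atoms A, B, C, the C-D bond length, the B-C-D angle
# and the A-B-C-D dihedral (both in degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

# Orthonormal basis (u, v) completing a unit direction w to a right-handed frame.
plane_basis <- function(w) {
  w <- unit(w)
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(vcross(ref, w))
  v <- vcross(w, u)
  list(u = u, v = v, w = w)
}

# Principal axes of a point cloud (rows = points). Returns eigenvectors
# (columns, decreasing variance) and eigenvalues.
principal_axes <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  e <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  list(center = ctr, vectors = e$vectors, values = e$values)
}

# Evaluate RNG-dependent code under a local, seeded stream without disturbing
# the caller's .Random.seed.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
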
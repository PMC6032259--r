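# Synthetic structures, channels and alignments with known ground truth.
# These are geometric test objects: alpha-helical bundles with a prescribed
# wall profile, C4-assemblable units, and toy alignments with controlled
# per-column conservation. They emulate the geometry the pipeline analyses,
# not physically realistic membrane proteins.

# Ideal backbone geometry (angstrom / degrees)
.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.8)

#' Ideal alpha helix
#'
#' Builds an all-atom ideal alpha helix (phi = -57, psi = -47, omega = 180;
#' 1.5 A rise and ~100 degrees per residue) aligned to the z axis with
#' residue 1 at the bottom, then applies an optional rigid placement. Side
#' chains use the packaged template geometry with default chi angles.
#'
#' @param n_res number of residues (>= 4).
#' @param sequence one-letter sequence; a single letter is recycled.
#'   Default poly-alanine.
#' @param placement optional list with rotation matrix `R` and translation
#'   `t` applied after construction.
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @param spin rotation (degrees) about the helix axis applied before
#'   placement, used to control which face points where.
#' @return an `aqp_structure`.
#' @export
make_ideal_helix <- function(n_res, sequence = "A", placement = NULL,
                             chain = "A", resno_start = 1L, spin = 0) {
  if (n_res < 4) stop("need at least 4 residues for a helix")
  seq1 <- toupper(strsplit(paste(rep(sequence,
                                     ceiling(n_res / nchar(sequence))),
                                 collapse = ""), "")[[1]][seq_len(n_res)])
  bad <- !seq1 %in% names(.aa1to3)
  if (any(bad)) stop("unknown residue letter(s): ",
                     paste(unique(seq1[bad]), collapse = ", "))
  g <- .bb_geom
  phi <- -57; psi <- -47; omega <- 180
  # seed the first three backbone atoms
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]], g$ca_c, g$ang_n_ca_c, 120)
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_n, g$ang_ca_c_n, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], g$n_ca,
                              g$ang_c_n_ca, omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], g$ca_c,
                             g$ang_n_ca_c, phi)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    aa3 <- unname(.aa1to3[seq1[i]])
    Oref <- if (i < n_res) N[[i + 1]] else
      place_atom(N[[i]], CA[[i]], C[[i]], g$c_n, g$ang_ca_c_n, psi)
    O <- place_atom(Oref, CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o, 180)
    bb <- data.frame(elety = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = c(N[[i]][1], CA[[i]][1], C[[i]][1], O[1]),
                     y = c(N[[i]][2], CA[[i]][2], C[[i]][2], O[2]),
                     z = c(N[[i]][3], CA[[i]][3], C[[i]][3], O[3]),
                     stringsAsFactors = FALSE)
    sc <- build_side_chain(list(N = N[[i]], CA = CA[[i]], C = C[[i]]), aa3)
    res <- rbind(bb, sc)
    res$chain <- chain
    res$resno <- resno_start + i - 1L
    res$icode <- ""
    res$resid <- aa3
    rows[[i]] <- res
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  # align the helix axis (principal CA axis) to +z, residue 1 at the bottom
  ca_xyz <- xyz[atoms$elety == "CA", , drop = FALSE]
  pa <- principal_axes(ca_xyz)
  ax <- pa$vectors[, 1]
  if (sum((ca_xyz[nrow(ca_xyz), ] - ca_xyz[1, ]) * ax) < 0) ax <- -ax
  rot_axis <- vcross(ax, c(0, 0, 1))
  if (vnorm(rot_axis) > 1e-9) {
    th <- acos(max(-1, min(1, ax[3])))
    R <- rotation_about(rot_axis, th)
  } else {
    R <- diag(3)
  }
  xyz <- sweep(xyz, 2, pa$center) %*% t(R)
  if (spin != 0) xyz <- xyz %*% t(rotation_about(c(0, 0, 1), spin * pi / 180))
  if (!is.null(placement)) {
    if (!is.null(placement$R)) xyz <- xyz %*% t(placement$R)
    if (!is.null(placement$t)) xyz <- sweep(xyz, 2, placement$t, `+`)
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  new_structure(atoms[, c("chain", "resno", "icode", "resid", "elety",
                          "element", "x", "y", "z")],
                source = "synthetic")
}

#' Channel-wall specification
#'
#' @param wall_radius_fn function of z returning the wall radius (angstrom).
#' @param z_range length-2 axial interval.
#' @param atom_density pseudo-atoms per square angstrom of wall surface.
#' @param atom_vdw van der Waals radius assigned to the pseudo-atoms.
#' @param seed reserved for reproducibility; the tiling is deterministic.
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(wall_radius_fn, z_range, atom_density = 1.0,
                         atom_vdw = 1.5, seed = 1L) {
  stopifnot(is.function(wall_radius_fn), atom_density > 0, atom_vdw > 0)
  structure(list(wall_radius_fn = wall_radius_fn,
                 z_range = as.numeric(z_range),
                 atom_density = atom_density, atom_vdw = atom_vdw,
                 seed = as.integer(seed)),
            class = "channel_spec")
}

#' Analytic channel wall
#'
#' Tiles pseudo-atoms on the surface of radius `wall_radius_fn(z)` around the
#' z axis. The expected pore radius at height z is
#' `wall_radius_fn(z) - atom_vdw`, the analytic oracle for the profiler.
#'
#' @param spec a [channel_spec()].
#' @return an `aqp_structure` with a `ground_truth` attribute carrying the
#'   expected-profile function.
#' @export
make_channel_wall <- function(spec) {
  s <- 1 / sqrt(spec$atom_density)
  if (s - 2 * spec$atom_vdw > spec$atom_vdw) {
    stop("atom density too low to close the wall (mean gap ",
         round(s - 2 * spec$atom_vdw, 2), " A exceeds the vdW radius)")
  }
  zs <- seq(spec$z_range[1], spec$z_range[2], by = s)
  rows <- list()
  for (i in seq_along(zs)) {
    R <- spec$wall_radius_fn(zs[i])
    if (R <= spec$atom_vdw) stop("wall radius must exceed the atom radius")
    n <- max(3L, round(2 * pi * R / s))
    th <- 2 * pi * (seq_len(n) - 1) / n + (i %% 2) * pi / n
    rows[[i]] <- data.frame(chain = "W", resno = i, icode = "",
                            resid = "WAL", elety = paste0("C", seq_len(n)),
                            element = "C",
                            x = R * cos(th), y = R * sin(th), z = zs[i],
                            vdw = spec$atom_vdw, stringsAsFactors = FALSE)
  }
  out <- new_structure(do.call(rbind, rows), source = "synthetic")
  attr(out, "ground_truth") <- list(
    expected_profile = function(z) spec$wall_radius_fn(z) - spec$atom_vdw,
    spec = spec)
  out
}

#' Helical bundle around a central channel
#'
#' Places `n_helices` ideal helices vertically on a circle of radius
#' `ring_radius`, axes parallel to z, enclosing a channel along z - the
#' geometry of a transmembrane helix bundle. Each helix is spun so that its
#' side chains face a consistent direction; a planted bulky residue can be
#' made to face the channel axis.
#'
#' @param n_helices at least 3.
#' @param ring_radius circle radius in angstrom.
#' @param length axial helix length in angstrom (1.5 A per residue).
#' @param sequence per-helix one-letter sequences (recycled).
#' @param plant optional list `(helix, position, aa)`: residue `position` of
#'   helix `helix` is set to `aa` and spun to face the bundle axis.
#' @param chain chain identifier (single chain; use [build_c4_assembly()]
#'   for tetramer fixtures).
#' @return an `aqp_structure`; helix h occupies residues (h-1)*100 + 1..n.
#' @export
make_bundle_channel <- function(n_helices, ring_radius, length,
                                sequence = "A", plant = NULL, chain = "A") {
  if (n_helices < 3) stop("need at least 3 helices")
  n_res <- max(4L, round(length / 1.5))
  if (ring_radius < 4.5) stop("ring radius too small: helices overlap")
  seqs <- rep(sequence, length.out = n_helices)
  if (!is.null(plant)) {
    sq <- strsplit(paste(rep(seqs[plant$helix], n_res), collapse = ""),
                   "")[[1]][seq_len(n_res)]
    sq[plant$position] <- plant$aa
    seqs[plant$helix] <- paste(sq, collapse = "")
  }
  parts <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    th <- 2 * pi * (h - 1) / n_helices
    pos <- c(ring_radius * cos(th), ring_radius * sin(th), 0)
    spin <- 0
    if (!is.null(plant) && h == plant$helix) {
      # spin the helix so the planted residue's CB points at the bundle axis
      trial <- make_ideal_helix(n_res, seqs[h], chain = chain)
      cb <- trial$atoms[trial$atoms$resno == plant$position &
                        trial$atoms$elety == "CB", , drop = FALSE]
      ca <- trial$atoms[trial$atoms$resno == plant$position &
                        trial$atoms$elety == "CA", , drop = FALSE]
      if (nrow(cb)) {
        cur <- atan2(cb$y[1] - 0, cb$x[1] - 0)
        want <- atan2(-pos[2], -pos[1])
        spin <- (want - cur) * 180 / pi
      }
    }
    hx <- make_ideal_helix(n_res, seqs[h], chain = chain,
                           resno_start = (h - 1L) * 100L + 1L, spin = spin,
                           placement = list(t = pos))
    parts[[h]] <- hx$atoms
  }
  new_structure(do.call(rbind, parts), source = "synthetic")
}

#' Toy multiple alignment with controlled conservation
#'
#' @param n_seqs number of sequences.
#' @param length alignment length (columns).
#' @param conserved_columns column indices fully conserved across sequences.
#' @param seed RNG seed; the alignment is reproducible.
#' @param conserved_residue optional vector of residues (recycled) used at
#'   the conserved columns; sampled when `NULL`.
#' @return an `aa_alignment`: list of `names` and `seqs` (character strings).
#' @export
make_toy_alignment <- function(n_seqs, length, conserved_columns = integer(),
                               seed = 1L, conserved_residue = NULL) {
  stopifnot(all(conserved_columns >= 1), all(conserved_columns <= length))
  letters20 <- names(.aa1to3)
  n_cons <- base::length(conserved_columns)
  with_local_seed(seed, {
    m <- matrix(sample(letters20, n_seqs * length, replace = TRUE),
                nrow = n_seqs)
    if (n_cons > 0) {
      cons <- if (is.null(conserved_residue)) {
        sample(letters20, n_cons, replace = TRUE)
      } else rep(conserved_residue, length.out = n_cons)
      for (i in seq_along(conserved_columns)) {
        m[, conserved_columns[i]] <- cons[i]
      }
    }
    aa_alignment(paste0("seq", seq_len(n_seqs)),
                 apply(m, 1, paste, collapse = ""))
  })
}
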
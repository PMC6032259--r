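# Shared fixture builders. All fixtures are generated in code; seeds are
# fixed so every test is reproducible.

# Random point-cloud structure used by brute-force oracle tests.
random_atom_structure <- function(n, seed = 1, box = 15, chains = c("A", "B"),
                                  resid = "ALA", elety = "CB") {
  withr_seed <- function(code) aqpstruct:::with_local_seed(seed, code)
  withr_seed({
    new_structure_ <- aqpstruct:::new_structure
    new_structure_(data.frame(
      chain = rep(chains, length.out = n), resno = rep(seq_len(n %/% 2 + 1),
                                                       each = 2)[seq_len(n)],
      icode = "", resid = resid, elety = elety, element = "C",
      x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
      z = stats::runif(n, 0, box)))
  })
}

# C4 tetramer of a 26-residue helix (poly-Gly with Leu 10 at the
# inter-monomer interface), annotated with a helix, a C-tail and a
# phosphosite; ground truth for planted variant categories.
make_tetramer_fixture <- function(ring = 6.5) {
  h <- make_ideal_helix(26, paste(c(rep("G", 9), "L", rep("G", 16)),
                                  collapse = ""))
  h$atoms$x <- h$atoms$x + ring
  tet <- build_c4_assembly(h)
  ann <- as_topology(list(helix_ranges = list(H1 = c(2, 19)), loops = list(),
                          c_tail_start = 20, phosphosites = 24))
  annotate_topology(tet, ann)
}

# Planted variant catalog matching make_tetramer_fixture().
planted_catalog <- function() {
  txt <- c("protein\tchange\tdisease\tlocation\tdefect",
           "SYN1\tL10G\tsyn\tH1\ttetramer assembly",
           "SYN1\tG5P\tsyn\tH1\tmonomer folding",
           "SYN1\tG15P\tsyn\tH1\tmonomer folding",
           "SYN1\tG22A\tsyn\tC-ter\tsignal loss",
           "SYN1\tG24A\tsyn\tC-ter\tsignal loss")
  parse_humsavar(text = txt)
}

# Six-helix bundle whose residue 10 of helix 1 faces the channel axis;
# mutating it to Trp narrows the pore without straining the monomer.
make_pore_bundle <- function() {
  b <- make_bundle_channel(6, 9, 30,
                           plant = list(helix = 1, position = 10, aa = "A"))
  ann <- as_topology(list(helix_ranges = list(H1 = c(1, 20)), loops = list(),
                          c_tail_start = 525, phosphosites = integer()))
  annotate_topology(b, ann)
}

# Two-residue charged fixture: an Arg guanidinium and a Glu carboxylate at a
# controlled minimum N-O distance.
salt_bridge_fixture <- function(distance = 3.2) {
  aqpstruct:::new_structure(data.frame(
    chain = "A", resno = c(1, 1, 1, 2, 2), icode = "",
    resid = c("ARG", "ARG", "ARG", "GLU", "GLU"),
    elety = c("NE", "NH1", "NH2", "OE1", "OE2"),
    element = c("N", "N", "N", "O", "O"),
    x = c(-1.0, 0, -0.5, distance, distance + 1.1),
    y = c(0.9, 0, -1.1, 0, 0.4), z = 0))
}

# Brute-force clash-score oracle: all pairs, no prefiltering, same
# exclusion map as the implementation is NOT used - exclusions are taken
# from an explicit empty map so the oracle checks raw pair arithmetic.
brute_force_pair_score <- function(sc, env) {
  s <- 0
  for (i in seq_len(nrow(sc))) {
    for (j in seq_len(nrow(env))) {
      d <- sqrt(sum((c(sc$x[i], sc$y[i], sc$z[i]) -
                     c(env$x[j], env$y[j], env$z[j]))^2))
      s <- s + max(0, sc$vdw[i] + env$vdw[j] - d)^2
    }
  }
  s
}

# Brute-force residue contact oracle (double loop over residue pairs).
brute_force_contacts <- function(structure, cutoff) {
  a <- structure$atoms
  rt <- aqpstruct:::residue_table(structure)
  out <- list()
  for (i in seq_len(nrow(rt))) {
    for (j in seq_len(nrow(rt))) {
      if (i == j) next
      ii <- aqpstruct:::residue_index(structure, rt$chain[i], rt$resno[i],
                                      rt$icode[i])
      jj <- aqpstruct:::residue_index(structure, rt$chain[j], rt$resno[j],
                                      rt$icode[j])
      dmin <- Inf
      for (p in which(ii)) {
        for (q in which(jj)) {
          d <- sqrt((a$x[p] - a$x[q])^2 + (a$y[p] - a$y[q])^2 +
                    (a$z[p] - a$z[q])^2)
          dmin <- min(dmin, d)
        }
      }
      if (dmin <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          chain_a = rt$chain[i], resno_a = rt$resno[i],
          chain_b = rt$chain[j], resno_b = rt$resno[j], min_dist = dmin)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Exhaustive in-plane grid search oracle for the maximal-sphere problem
# (vectorised over the 0.01 A grid).
grid_search_sphere <- function(structure, axis, z, r_max = 10, span = 4,
                               h = 0.01) {
  bs <- aqpstruct:::plane_basis(axis$direction)
  p0 <- axis$origin + z * bs$w
  xyz <- aqpstruct:::atom_xyz(structure)
  vdw <- structure$atoms$vdw
  g <- seq(-span, span, by = h)
  ab <- expand.grid(a = g, b = g)
  ctr_x <- p0[1] + ab$a * bs$u[1] + ab$b * bs$v[1]
  ctr_y <- p0[2] + ab$a * bs$u[2] + ab$b * bs$v[2]
  ctr_z <- p0[3] + ab$a * bs$u[3] + ab$b * bs$v[3]
  clearance <- rep(Inf, nrow(ab))
  for (i in seq_len(nrow(xyz))) {
    d <- sqrt((ctr_x - xyz[i, 1])^2 + (ctr_y - xyz[i, 2])^2 +
              (ctr_z - xyz[i, 3])^2) - vdw[i]
    clearance <- pmin(clearance, d)
  }
  min(max(clearance), r_max)
}

# Irregular but enclosing atom ring in the z = 0 slice: angles and radii are
# jittered, yet the gaps stay too narrow for the sphere to escape, so the
# constrained maximum is interior and the exhaustive grid oracle applies.
irregular_ring_structure <- function(seed, n = 10) {
  aqpstruct:::with_local_seed(seed, {
    th <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(n, -0.1, 0.1)
    rr <- stats::runif(n, 3.8, 4.8)
    aqpstruct:::new_structure(data.frame(
      chain = "A", resno = seq_len(n), icode = "", resid = "WAL",
      elety = "PSE", element = "C", x = rr * cos(th), y = rr * sin(th),
      z = stats::runif(n, -0.5, 0.5), vdw = 1.7))
  })
}
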
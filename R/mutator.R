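# Template-based in-silico point mutagenesis: strip the side chain, rebuild
# the mutant type from ideal internal coordinates, search a staggered chi
# grid against a purely repulsive clash objective and polish by coordinate
# descent. Backbone atoms never move.

.template_env <- new.env(parent = emptyenv())

sidechain_templates <- function() {
  if (is.null(.template_env$tab)) {
    path <- system.file("extdata", "sidechain_templates.tsv",
                        package = "aqpstruct")
    .template_env$tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
  }
  .template_env$tab
}

aa_template <- function(aa3) {
  tab <- sidechain_templates()
  tab[tab$aa == aa3, , drop = FALSE]
}

#' Number of rotatable chi angles of an amino acid
#'
#' @param aa one-letter or three-letter residue code.
#' @return integer count (0 for Gly/Ala/Pro in this template set).
#' @export
n_chi <- function(aa) {
  aa3 <- if (nchar(aa) == 1) .aa1to3[toupper(aa)] else toupper(aa)
  tpl <- aa_template(aa3)
  sum(grepl("^CHI", tpl$torsion_kind))
}

#' Mutation specification
#'
#' @param chain chain identifier.
#' @param position residue number (author numbering).
#' @param wt_aa,mut_aa one-letter codes; `wt_aa` must match the residue found
#'   at the site.
#' @param icode insertion code, usually `""`.
#' @return a `mutation_spec` list.
#' @export
mutation_spec <- function(chain, position, wt_aa, mut_aa, icode = "") {
  structure(list(chain = chain, position = as.integer(position),
                 wt_aa = toupper(wt_aa), mut_aa = toupper(mut_aa),
                 icode = icode),
            class = "mutation_spec")
}

#' Parse a substitution token such as "G64R" or "p.Gly64Arg"
#'
#' @param token substitution string in either one-letter or `p.` three-letter
#'   dialect.
#' @return list with `wt_aa`, `position`, `mut_aa`.
#' @export
parse_mutation <- function(token) {
  token <- trimws(token)
  m <- regmatches(token,
                  regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                          token))[[1]]
  if (length(m) == 4) {
    wt <- .aa3to1[toupper(m[2])]
    mut <- .aa3to1[toupper(m[4])]
    if (is.na(wt) || is.na(mut)) stop("unknown amino-acid code in '",
                                      token, "'")
    return(list(wt_aa = unname(wt), position = as.integer(m[3]),
                mut_aa = unname(mut)))
  }
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) == 4) {
    wt <- toupper(m[2]); mut <- toupper(m[4])
    if (!wt %in% names(.aa1to3) || !mut %in% names(.aa1to3)) {
      stop("unknown amino-acid code in '", token, "'")
    }
    return(list(wt_aa = wt, position = as.integer(m[3]), mut_aa = mut))
  }
  stop("malformed substitution token '", token, "'")
}

#' Side-chain placement parameters
#'
#' @param rotamer_grid base chi-angle candidates in degrees.
#' @param perturbations additional offsets tried around each base angle.
#' @param refine_steps coordinate-descent polishing steps.
#' @param clash_weight multiplier on the repulsive objective (unitless).
#' @param radius environment radius around the site CA, in angstrom.
#' @param seed recorded for provenance; the placement itself is
#'   deterministic.
#' @return a `placement_params` list.
#' @export
placement_params <- function(rotamer_grid = c(-60, 60, 180),
                             perturbations = c(-30, 30),
                             refine_steps = 200, clash_weight = 1,
                             radius = 8, seed = 1L) {
  stopifnot(refine_steps >= 0)
  structure(list(rotamer_grid = rotamer_grid, perturbations = perturbations,
                 refine_steps = as.integer(refine_steps),
                 clash_weight = clash_weight, radius = radius,
                 seed = as.integer(seed)),
            class = "placement_params")
}

# Build side-chain atoms for residue type aa3 on a backbone frame.
# bb: list with named positions N, CA, C. chis: numeric vector of chi angles
# (degrees); missing entries use the template defaults.
build_side_chain <- function(bb, aa3, chis = NULL) {
  tpl <- aa_template(aa3)
  if (nrow(tpl) == 0) {
    return(data.frame(elety = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  }
  pos <- list(N = bb$N, CA = bb$CA, C = bb$C)
  out <- vector("list", nrow(tpl))
  for (i in seq_len(nrow(tpl))) {
    row <- tpl[i, ]
    tor <- row$torsion
    if (grepl("^CHI", row$torsion_kind)) {
      k <- as.integer(sub("CHI", "", row$torsion_kind))
      if (!is.null(chis) && length(chis) >= k && is.finite(chis[k])) {
        tor <- chis[k]
      }
    }
    p <- place_atom(pos[[row$torsion_ref]], pos[[row$angle_ref]],
                    pos[[row$parent]], row$bond, row$angle, tor)
    pos[[row$atom]] <- p
    out[[i]] <- data.frame(elety = row$atom, element = row$element,
                           x = p[1], y = p[2], z = p[3],
                           stringsAsFactors = FALSE)
  }
  sc <- do.call(rbind, out)
  if (aa3 == "PRO") {
    gap <- abs(vnorm(pos$CD - pos$N) - 1.47)
    if (gap > 0.1) {
      warning(sprintf("proline ring closure off by %.2f A (tolerance 0.1)",
                      gap))
    }
  }
  sc
}

# Measure the current chi angles of a residue (NA where atoms are missing).
measure_chis <- function(structure, chain, resno, icode = "") {
  idx <- residue_index(structure, chain, resno, icode)
  res <- structure$atoms[idx, , drop = FALSE]
  aa3 <- res$resid[1]
  tpl <- aa_template(aa3)
  chi_rows <- tpl[grepl("^CHI", tpl$torsion_kind), , drop = FALSE]
  if (nrow(chi_rows) == 0) return(numeric())
  getp <- function(nm) {
    r <- res[res$elety == nm, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  vapply(seq_len(nrow(chi_rows)), function(i) {
    row <- chi_rows[i, ]
    ps <- lapply(c(row$torsion_ref, row$angle_ref, row$parent, row$atom), getp)
    if (any(vapply(ps, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

# Repulsive clash objective between a proposed side chain and the
# environment: sum over non-bonded heavy-atom pairs of
# max(0, vdw_i + vdw_j - d_ij)^2.
score_side_chain <- function(sc, env, excl_pairs, clash_weight = 1) {
  if (nrow(sc) == 0 || nrow(env) == 0) return(0)
  dx <- outer(sc$x, env$x, `-`)
  dy <- outer(sc$y, env$y, `-`)
  dz <- outer(sc$z, env$z, `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  ov <- outer(sc$vdw, env$vdw, `+`) - d
  for (i in seq_len(nrow(sc))) {
    ex <- excl_pairs[[sc$elety[i]]]
    if (!is.null(ex)) {
      j <- which(env$.key %in% ex)
      if (length(j)) ov[i, j] <- 0
    }
  }
  clash_weight * sum(pmax(ov, 0)^2)
}

#' Repulsive clash score of one residue's side chain
#'
#' Sum over heavy-atom pairs (site side chain x environment within `radius`,
#' excluding pairs coupled through up to four covalent bonds) of
#' `max(0, vdw_i + vdw_j - d_ij)^2`, in square angstrom.
#'
#' @param structure an `aqp_structure`.
#' @param chain,resno,icode residue key of the site.
#' @param radius environment radius in angstrom around the site's side-chain
#'   atoms.
#' @return non-negative numeric score.
#' @export
side_chain_clash_score <- function(structure, chain, resno, icode = "",
                                   radius = 8) {
  idx <- residue_index(structure, chain, resno, icode)
  if (!any(idx)) stop("no residue ", resno, " in chain ", chain)
  res <- structure$atoms[idx, , drop = FALSE]
  aa3 <- res$resid[1]
  sc <- res[!res$backbone, , drop = FALSE]
  if (nrow(sc) == 0) return(0)
  env <- environment_atoms(structure, chain, resno, icode, radius, sc)
  score_side_chain(sc, env, steric_exclusions(structure, chain, resno, icode))
}

# Environment for the clash objective: all atoms outside the site side chain,
# restricted to those within `radius` of any side-chain atom. Atoms carry a
# `.label` used by the bonded-pair exclusion (own backbone by atom name,
# preceding-residue backbone as "prev.*").
environment_atoms <- function(structure, chain, resno, icode, radius, sc) {
  a <- structure$atoms
  own_sc <- residue_index(structure, chain, resno, icode) & !a$backbone
  env <- a[!own_sc, , drop = FALSE]
  env$.key <- paste(env$chain, env$resno, env$elety, sep = "|")
  local <- env$chain == chain & abs(env$resno - resno) <= 2
  if (nrow(sc)) {
    keep <- rep(FALSE, nrow(env))
    for (i in seq_len(nrow(sc))) {
      keep <- keep | (abs(env$x - sc$x[i]) < radius &
                      abs(env$y - sc$y[i]) < radius &
                      abs(env$z - sc$z[i]) < radius)
    }
    env <- env[keep | local, , drop = FALSE]
  }
  env
}

#' Replace one residue's side chain by the mutant type
#'
#' Backbone atoms are untouched; the side chain is rebuilt with ideal bond
#' lengths and angles for the target type. Chi angles minimise the repulsive
#' clash score over a staggered rotamer grid (-60/60/180 per chi, with +-30
#' perturbations around the best candidate) and are then polished by
#' coordinate descent. The procedure is deterministic for a fixed input.
#'
#' @param structure an `aqp_structure`.
#' @param spec a [mutation_spec()].
#' @param params a [placement_params()].
#' @return the mutated `aqp_structure`.
#' @export
mutate_residue <- function(structure, spec,
                           params = placement_params()) {
  a <- structure$atoms
  idx <- residue_index(structure, spec$chain, spec$position, spec$icode)
  if (!any(idx)) {
    stop("no residue ", spec$position, " in chain ", spec$chain)
  }
  res <- a[idx, , drop = FALSE]
  found <- unname(.aa3to1[res$resid[1]])
  if (!is.na(spec$wt_aa) && !is.na(found) && found != spec$wt_aa) {
    stop("wild-type mismatch at ", spec$chain, ":", spec$position,
         ": found ", found, ", expected ", spec$wt_aa)
  }
  mut3 <- unname(.aa1to3[spec$mut_aa])
  if (is.na(mut3)) stop("unknown target amino acid '", spec$mut_aa, "'")
  getp <- function(nm) {
    r <- res[res$elety == nm, , drop = FALSE]
    if (nrow(r) == 0) stop("backbone atom ", nm, " missing at site; ",
                           "cannot rebuild side chain")
    c(r$x[1], r$y[1], r$z[1])
  }
  bb <- list(N = getp("N"), CA = getp("CA"), C = getp("C"))

  k <- n_chi(mut3)
  build <- function(chis) build_side_chain(bb, mut3, chis)
  sc0 <- build(NULL)
  excl <- steric_exclusions(structure, spec$chain, spec$position, spec$icode,
                            site_aa3 = mut3)
  env <- environment_atoms(structure, spec$chain, spec$position, spec$icode,
                           params$radius,
                           if (nrow(sc0)) sc0 else
                             data.frame(x = bb$CA[1], y = bb$CA[2],
                                        z = bb$CA[3]))
  score <- function(sc) {
    if (nrow(sc) == 0) return(0)
    sc$vdw <- vdw_radius(sc$element)
    score_side_chain(sc, env, excl, params$clash_weight)
  }

  best_chis <- numeric(0)
  if (k > 0) {
    cand <- as.matrix(expand.grid(rep(list(params$rotamer_grid), k)))
    if (found == spec$mut_aa) {
      cur <- measure_chis(structure, spec$chain, spec$position, spec$icode)
      if (length(cur) == k && all(is.finite(cur))) {
        cand <- rbind(matrix(cur, nrow = 1), cand)
      }
    }
    sc_scores <- apply(cand, 1, function(ch) score(build(ch)))
    best <- which.min(sc_scores)
    best_chis <- cand[best, ]
    best_score <- sc_scores[best]
    # +-30 degree perturbations around the best base rotamer, one chi at a time
    for (j in seq_len(k)) {
      for (d in params$perturbations) {
        trial <- best_chis
        trial[j] <- trial[j] + d
        s <- score(build(trial))
        if (s < best_score - 1e-12) {
          best_chis <- trial; best_score <- s
        }
      }
    }
    # coordinate descent with a shrinking step
    step <- 20
    for (it in seq_len(params$refine_steps)) {
      j <- (it - 1) %% k + 1
      improved <- FALSE
      for (d in c(step, -step)) {
        trial <- best_chis
        trial[j] <- trial[j] + d
        s <- score(build(trial))
        if (s < best_score - 1e-12) {
          best_chis <- trial; best_score <- s; improved <- TRUE
          break
        }
      }
      if (j == k && !improved) step <- step * 0.7
      if (step < 0.05) break
    }
  }
  sc <- build(best_chis)
  if (nrow(sc)) sc$vdw <- vdw_radius(sc$element)

  # splice: keep backbone rows of the site, drop old side chain, append new
  keep_bb <- idx & a$backbone
  pre <- a[seq_len(max(which(idx))) , , drop = FALSE]
  pre <- pre[!(residue_index_rows(pre, spec) & !pre$backbone), , drop = FALSE]
  post_rows <- setdiff(seq_len(nrow(a)), seq_len(max(which(idx))))
  post <- a[post_rows, , drop = FALSE]
  if (nrow(sc)) {
    sc_rows <- data.frame(chain = spec$chain, resno = spec$position,
                          icode = spec$icode, resid = mut3,
                          elety = sc$elety, element = sc$element,
                          x = sc$x, y = sc$y, z = sc$z, vdw = sc$vdw,
                          backbone = FALSE, stringsAsFactors = FALSE)
    pre <- rbind(pre, sc_rows)
  }
  newatoms <- rbind(pre, post)
  newatoms$resid[newatoms$chain == spec$chain &
                 newatoms$resno == spec$position &
                 newatoms$icode == spec$icode] <- mut3
  out <- new_structure(newatoms, source = structure$source,
                       assembly = structure$assembly,
                       annotation = structure$annotation)
  out
}

residue_index_rows <- function(atoms, spec) {
  atoms$chain == spec$chain & atoms$resno == spec$position &
    atoms$icode == spec$icode
}
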
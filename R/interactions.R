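# Residue-residue interaction analysis: contact maps with hydrophobic and
# salt-bridge sub-typing, steric-clash detection around a site, wild-type vs
# mutant contact differencing, and helix-destabilising proline flagging.
#
# Cutoffs (declared assumptions, exposed as arguments): generic contact
# 8 A between any heavy atoms, hydrophobic 4.5 A between apolar carbons or
# sulfurs, salt bridge 4.0 A between oppositely charged side-chain N/O.

.polar_side_carbons <- list(ARG = "CZ", ASP = "CG", GLU = "CD",
                            ASN = "CG", GLN = "CD")

.charged_atoms <- list(
  ARG = list(atoms = c("NH1", "NH2", "NE"), sign = +1),
  LYS = list(atoms = "NZ", sign = +1),
  HIS = list(atoms = c("ND1", "NE2"), sign = +1),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1))

# Atom-level typing used by the contact sub-classifier.
atom_classes <- function(atoms) {
  apolar <- (atoms$element == "S") |
    (atoms$element == "C" & !(atoms$elety %in% c("C", "CA")) &
       !mapply(function(r, e) {
         !is.null(.polar_side_carbons[[r]]) && e %in% .polar_side_carbons[[r]]
       }, atoms$resid, atoms$elety))
  charge <- numeric(nrow(atoms))
  for (r in names(.charged_atoms)) {
    hit <- atoms$resid == r & atoms$elety %in% .charged_atoms[[r]]$atoms
    charge[hit] <- .charged_atoms[[r]]$sign
  }
  list(apolar = as.logical(apolar), charge = charge)
}

# Resolve a selection into a logical atom index. NULL = all atoms;
# a list may give `chain` and/or `resno` (vector of residue numbers).
select_atoms <- function(structure, sel) {
  a <- structure$atoms
  if (is.null(sel)) return(rep(TRUE, nrow(a)))
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  keep
}

#' Residue contact map with interaction sub-typing
#'
#' A residue pair is a contact when any heavy-atom pair is within `cutoff`.
#' Contacts are sub-typed hydrophobic when an apolar carbon/sulfur pair is
#' within 4.5 A, and salt bridge when charged-group N/O atoms of oppositely
#' charged side chains are within 4.0 A. `scope` is `inter_monomer` exactly
#' when the chains differ.
#'
#' @param structure an `aqp_structure`.
#' @param sel_a,sel_b selections: `NULL` for all atoms or a list with
#'   `chain` and/or `resno`.
#' @param cutoff generic heavy-atom contact cutoff in angstrom.
#' @param hydrophobic_cutoff,salt_bridge_cutoff sub-type cutoffs.
#' @return data frame of contacts; one row per residue pair with `min_dist`,
#'   logical `hydrophobic` and `salt_bridge` columns and a priority `kind`.
#' @export
contact_map <- function(structure, sel_a = NULL, sel_b = NULL, cutoff = 8,
                        hydrophobic_cutoff = 4.5, salt_bridge_cutoff = 4.0) {
  a <- structure$atoms
  ia <- which(select_atoms(structure, sel_a))
  ib <- which(select_atoms(structure, sel_b))
  if (length(ia) == 0 || length(ib) == 0) stop("empty atom selection")
  cls <- atom_classes(a)
  keyA <- paste(a$chain[ia], a$resno[ia], a$icode[ia], sep = "|")
  keyB <- paste(a$chain[ib], a$resno[ib], a$icode[ib], sep = "|")
  out <- list()
  # block over residues of the smaller selection to bound memory
  for (ka in unique(keyA)) {
    sa <- ia[keyA == ka]
    sb <- ib[keyB != ka]
    if (length(sb) == 0) next
    dx <- outer(a$x[sa], a$x[sb], `-`)
    dy <- outer(a$y[sa], a$y[sb], `-`)
    dz <- outer(a$z[sa], a$z[sb], `-`)
    d <- sqrt(dx^2 + dy^2 + dz^2)
    near <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(near) == 0) next
    kb <- keyB[keyB != ka][near[, 2]]
    for (pk in unique(kb)) {
      rows <- near[kb == pk, , drop = FALSE]
      dd <- d[rows]
      i1 <- sa[rows[, 1]]
      i2 <- sb[rows[, 2]]
      hyd <- any(dd <= hydrophobic_cutoff & cls$apolar[i1] & cls$apolar[i2])
      sbr <- any(dd <= salt_bridge_cutoff &
                   cls$charge[i1] * cls$charge[i2] < 0)
      p1 <- strsplit(ka, "|", fixed = TRUE)[[1]]
      p2 <- strsplit(pk, "|", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <- data.frame(
        chain_a = p1[1], resno_a = as.integer(p1[2]),
        resid_a = a$resid[i1[1]],
        chain_b = p2[1], resno_b = as.integer(p2[2]),
        resid_b = a$resid[i2[1]],
        min_dist = min(dd), hydrophobic = hyd, salt_bridge = sbr,
        scope = if (p1[1] == p2[1]) "intra_monomer" else "inter_monomer",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      min_dist = numeric(), hydrophobic = logical(),
                      salt_bridge = logical(), scope = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$kind <- ifelse(res$salt_bridge, "salt_bridge",
                     ifelse(res$hydrophobic, "hydrophobic", "contact"))
  rownames(res) <- NULL
  res
}

#' Steric clashes around a site residue
#'
#' Heavy-atom pairs between the site residue and its environment with
#' `vdw_i + vdw_j - d >= clash_threshold`, excluding covalently bonded
#' 1-2/1-3 pairs across the peptide bond, aggregated per residue pair with
#' the maximum overlap.
#'
#' @param structure an `aqp_structure`.
#' @param chain,resno,icode site residue key.
#' @param radius environment radius in angstrom.
#' @param clash_threshold minimum overlap (angstrom) counted as a clash.
#' @return data frame of clashes (partner residue, `overlap`, `min_dist`,
#'   `scope`, `kind = "clash"`).
#' @export
detect_clashes <- function(structure, chain, resno, icode = "", radius = 6,
                           clash_threshold = 0.1) {
  a <- structure$atoms
  idx <- residue_index(structure, chain, resno, icode)
  if (!any(idx)) stop("no residue ", resno, " in chain ", chain)
  site <- a[idx, , drop = FALSE]
  env <- a[!idx, , drop = FALSE]
  # environment prefilter
  keep <- rep(FALSE, nrow(env))
  for (i in seq_len(nrow(site))) {
    keep <- keep | (abs(env$x - site$x[i]) < radius &
                    abs(env$y - site$y[i]) < radius &
                    abs(env$z - site$z[i]) < radius)
  }
  env <- env[keep, , drop = FALSE]
  if (nrow(env) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), min_dist = numeric(),
                      overlap = numeric(), scope = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  dx <- outer(site$x, env$x, `-`)
  dy <- outer(site$y, env$y, `-`)
  dz <- outer(site$z, env$z, `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  ov <- outer(site$vdw, env$vdw, `+`) - d
  # through-bond couplings with the flanking residues are not steric
  excl <- steric_exclusions(structure, chain, resno, icode)
  env_key <- paste(env$chain, env$resno, env$elety, sep = "|")
  for (i in seq_len(nrow(site))) {
    ex <- excl[[site$elety[i]]]
    if (!is.null(ex)) {
      j <- which(env_key %in% ex)
      if (length(j)) ov[i, j] <- -Inf
    }
  }
  hits <- which(ov >= clash_threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), min_dist = numeric(),
                      overlap = numeric(), scope = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  pk <- paste(env$chain[hits[, 2]], env$resno[hits[, 2]],
              env$icode[hits[, 2]], sep = "|")
  out <- lapply(unique(pk), function(k) {
    rows <- hits[pk == k, , drop = FALSE]
    j <- rows[1, 2]
    data.frame(chain_a = chain, resno_a = resno,
               chain_b = env$chain[j], resno_b = env$resno[j],
               resid_b = env$resid[j],
               min_dist = min(d[rows]), overlap = max(ov[rows]),
               scope = if (env$chain[j] == chain) "intra_monomer"
                       else "inter_monomer",
               kind = "clash", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wild-type vs mutant contact difference at the mutated site
#'
#' Both structures must be identical away from the site. Interactions
#' involving the site residue are compared on the packing-relevant sub-types
#' (hydrophobic, salt bridge) plus steric clashes; the loose generic contact
#' is deliberately not differenced.
#'
#' @param wt,mut `aqp_structure`s differing only at the site.
#' @param chain,resno,icode mutated residue key.
#' @param cutoff contact cutoff passed to [contact_map()].
#' @param clash_threshold passed to [detect_clashes()].
#' @return a `contact_diff`: list with `lost` and `gained` data frames
#'   (partner residue + kind) and the site key.
#' @export
diff_contacts <- function(wt, mut, chain, resno, icode = "", cutoff = 8,
                          clash_threshold = 0.1) {
  iw <- residue_index(wt, chain, resno, icode)
  im <- residue_index(mut, chain, resno, icode)
  aw <- wt$atoms[!iw, c("chain", "resno", "icode", "elety", "x", "y", "z")]
  am <- mut$atoms[!im, c("chain", "resno", "icode", "elety", "x", "y", "z")]
  if (nrow(aw) != nrow(am) ||
      any(aw$chain != am$chain) || any(aw$resno != am$resno) ||
      any(aw$elety != am$elety) ||
      max(abs(aw$x - am$x), abs(aw$y - am$y), abs(aw$z - am$z)) > 1e-6) {
    stop("structures differ away from the mutated site")
  }
  site_sel <- list(chain = chain, resno = resno)
  edge_set <- function(s) {
    cm <- contact_map(s, site_sel, NULL, cutoff = cutoff)
    keys <- character(0); rows <- list()
    if (nrow(cm)) {
      for (i in seq_len(nrow(cm))) {
        for (kind in c("hydrophobic", "salt_bridge")) {
          if (isTRUE(cm[[kind]][i])) {
            keys <- c(keys, paste(cm$chain_b[i], cm$resno_b[i], kind,
                                  sep = "|"))
            rows[[length(rows) + 1]] <-
              data.frame(chain = cm$chain_b[i], resno = cm$resno_b[i],
                         resid = cm$resid_b[i], kind = kind,
                         scope = cm$scope[i], stringsAsFactors = FALSE)
          }
        }
      }
    }
    cl <- detect_clashes(s, chain, resno, icode,
                         clash_threshold = clash_threshold)
    if (nrow(cl)) {
      for (i in seq_len(nrow(cl))) {
        keys <- c(keys, paste(cl$chain_b[i], cl$resno_b[i], "clash",
                              sep = "|"))
        rows[[length(rows) + 1]] <-
          data.frame(chain = cl$chain_b[i], resno = cl$resno_b[i],
                     resid = cl$resid_b[i], kind = "clash",
                     scope = cl$scope[i], stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chain = character(), resno = integer(), resid = character(),
                 kind = character(), scope = character(),
                 stringsAsFactors = FALSE)
    df$key <- keys
    df[!duplicated(df$key), , drop = FALSE]
  }
  ew <- edge_set(wt)
  em <- edge_set(mut)
  lost <- ew[!(ew$key %in% em$key), , drop = FALSE]
  gained <- em[!(em$key %in% ew$key), , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  structure(list(lost = lost, gained = gained,
                 site = list(chain = chain, resno = resno, icode = icode)),
            class = "contact_diff")
}

#' @export
print.contact_diff <- function(x, ...) {
  cat("contact_diff at ", x$site$chain, ":", x$site$resno, " - ",
      nrow(x$lost), " lost, ", nrow(x$gained), " gained\n", sep = "")
  if (nrow(x$lost)) {
    cat("  lost:   ", paste(x$lost$resid, x$lost$resno, " (", x$lost$kind,
                            ")", sep = "", collapse = ", "), "\n")
  }
  if (nrow(x$gained)) {
    cat("  gained: ", paste(x$gained$resid, x$gained$resno, " (",
                            x$gained$kind, ")", sep = "", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Salt bridges in a structure or region
#'
#' Arg/Lys/His side-chain nitrogens against Asp/Glu carboxylate oxygens
#' within the salt-bridge cutoff, aggregated per residue pair.
#'
#' @param structure an `aqp_structure`.
#' @param region optional `c(start, end)` residue-number range.
#' @param cutoff salt-bridge distance cutoff in angstrom.
#' @return data frame of salt-bridge contacts.
#' @export
salt_bridges <- function(structure, region = NULL, cutoff = 4.0) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(region)) keep <- a$resno >= region[1] & a$resno <= region[2]
  cls <- atom_classes(a)
  pos <- which(keep & cls$charge > 0)
  neg <- which(keep & cls$charge < 0)
  if (length(pos) == 0 || length(neg) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      min_dist = numeric(), scope = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  dx <- outer(a$x[pos], a$x[neg], `-`)
  dy <- outer(a$y[pos], a$y[neg], `-`)
  dz <- outer(a$z[pos], a$z[neg], `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      min_dist = numeric(), scope = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  pk <- paste(a$chain[pos[hits[, 1]]], a$resno[pos[hits[, 1]]],
              a$chain[neg[hits[, 2]]], a$resno[neg[hits[, 2]]], sep = "|")
  out <- lapply(unique(pk), function(k) {
    rows <- hits[pk == k, , drop = FALSE]
    i <- pos[rows[1, 1]]; j <- neg[rows[1, 2]]
    data.frame(chain_a = a$chain[i], resno_a = a$resno[i],
               resid_a = a$resid[i], chain_b = a$chain[j],
               resno_b = a$resno[j], resid_b = a$resid[j],
               min_dist = min(d[rows]),
               scope = if (a$chain[i] == a$chain[j]) "intra_monomer"
                       else "inter_monomer",
               kind = "salt_bridge", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Does a mutation introduce a proline inside a helix?
#'
#' True exactly when the mutant residue is proline and the position lies
#' inside an annotated helix, excluding the helix's two N-terminal positions
#' (where proline is tolerated).
#'
#' @param annotation a `topology_annotation` (or annotated structure).
#' @param spec a [mutation_spec()].
#' @return logical flag.
#' @export
proline_in_helix <- function(annotation, spec) {
  ann <- if (inherits(annotation, "aqp_structure")) annotation$annotation
         else annotation
  if (is.null(ann)) stop("no topology annotation supplied")
  if (spec$mut_aa != "P") return(FALSE)
  for (iv in ann$helix_ranges) {
    if (spec$position >= iv[1] + 2 && spec$position <= iv[2]) return(TRUE)
  }
  FALSE
}
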
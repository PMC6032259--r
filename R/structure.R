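# Coordinate container, PDB input/output, van der Waals radii, C4 assembly
# and membrane-topology annotation.

# Bondi van der Waals radii (angstrom); heavy atoms only in practice, the
# pipeline discards hydrogens on input.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)
.vdw_fallback <- 1.70

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Assign van der Waals radii by element
#'
#' Uses the packaged Bondi radii; unknown elements fall back to 1.7 A with a
#' warning so the assignment is total.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_table[el]
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(el[miss]), collapse = ", "),
            "; using fallback vdW radius ", .vdw_fallback, " A")
    r[miss] <- .vdw_fallback
  }
  unname(r)
}

# Construct an aqp_structure from an atom table. Required columns:
# chain, resno, icode, resid (3-letter), elety (atom name), element, x, y, z.
new_structure <- function(atoms, source = "synthetic",
                          assembly = c("monomer", "tetramer"),
                          annotation = NULL) {
  assembly <- match.arg(assembly)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  atoms$backbone <- atoms$elety %in% .backbone_names
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(atoms$vdw > 0))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source, assembly = assembly,
                 annotation = annotation),
            class = "aqp_structure")
}

#' @export
print.aqp_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("aqp_structure [", x$source, "] ", x$assembly, "\n", sep = "")
  cat("  ", nrow(x$atoms), " heavy atoms, ",
      nrow(unique(x$atoms[, c("chain", "resno", "icode")])), " residues, ",
      length(ch), " chain(s): ", paste(ch, collapse = " "), "\n", sep = "")
  if (!is.null(x$annotation)) cat("  topology annotation attached\n")
  invisible(x)
}

# Unique residue table (chain, resno, icode, resid, aa) in file order.
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  idx <- !duplicated(key)
  out <- a[idx, c("chain", "resno", "icode", "resid")]
  out$aa <- unname(.aa3to1[out$resid])
  rownames(out) <- NULL
  out
}

# Logical index of atoms belonging to one residue.
residue_index <- function(structure, chain, resno, icode = "") {
  a <- structure$atoms
  a$chain == chain & a$resno == resno & a$icode == icode
}

atom_xyz <- function(structure, idx = TRUE) {
  as.matrix(structure$atoms[idx, c("x", "y", "z")])
}

#' Read a PDB file into an `aqp_structure`
#'
#' Loads ATOM records through [bio3d::read.pdb()], discards hydrogens and
#' water, keeps the highest-occupancy alternate conformer and attaches Bondi
#' van der Waals radii. A standard residue without a CA atom is kept with a
#' warning.
#'
#' @param path path to a PDB-format file.
#' @return an object of class `aqp_structure`.
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("unparseable PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  el <- at$elesy
  bad <- is.na(el) | el == ""
  if (any(bad)) el[bad] <- substr(gsub("[0-9' ]", "", at$elety[bad]), 1, 1)
  el <- toupper(el)
  keep <- !(el %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]; el <- el[keep]
  # alternate locations: keep the highest-occupancy conformer per atom slot
  at$insert[is.na(at$insert)] <- ""
  slot <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(slot)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(slot, -occ)
    at <- at[ord, , drop = FALSE]; el <- el[ord]
    keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                              sep = "|"))
    at <- at[keep, , drop = FALSE]; el <- el[keep]
    ord <- order(match(at$chain, unique(at$chain)), at$resno, at$eleno)
    at <- at[ord, , drop = FALSE]; el <- el[ord]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, icode = at$insert,
                      resid = at$resid, elety = at$elety, element = el,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  s <- new_structure(atoms, source = tools::file_path_sans_ext(basename(path)),
                     assembly = if (length(unique(atoms$chain)) >= 4)
                       "tetramer" else "monomer")
  rt <- residue_table(s)
  std <- rt[!is.na(rt$aa), , drop = FALSE]
  if (nrow(std)) {
    has_ca <- vapply(seq_len(nrow(std)), function(i) {
      any(s$atoms$elety == "CA" & residue_index(s, std$chain[i], std$resno[i],
                                                std$icode[i]))
    }, logical(1))
    if (any(!has_ca)) {
      warning("residue(s) without CA kept: ",
              paste(std$resid[!has_ca], std$resno[!has_ca], collapse = ", "))
    }
  }
  s
}

#' Write an `aqp_structure` to a PDB file
#'
#' Coordinates survive a write/read round trip to 0.001 A together with all
#' chain/residue keys.
#'
#' @param structure an `aqp_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (anyDuplicated(paste(a$chain, a$resno, a$icode, a$elety, sep = "|"))) {
    stop("chain/residue/atom key collision; refusing to write ambiguous PDB")
  }
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, chain = a$chain,
                   resid = a$resid, eleno = seq_len(nrow(a)), elety = a$elety,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Build a C4 homotetramer from a single-chain monomer
#'
#' Places four copies of the monomer related by successive 90 degree
#' rotations about `axis` (through `origin`), as in the aquaporin biological
#' assembly. Intra-monomer distances are preserved exactly.
#'
#' @param monomer a single-chain `aqp_structure`.
#' @param axis rotation axis (length-3, need not be unit).
#' @param origin a point on the axis. Default the coordinate origin.
#' @param chains chain identifiers for the four copies.
#' @return an `aqp_structure` with `assembly = "tetramer"`.
#' @export
build_c4_assembly <- function(monomer, axis = c(0, 0, 1),
                              origin = c(0, 0, 0),
                              chains = c("A", "B", "C", "D")) {
  if (length(unique(monomer$atoms$chain)) != 1) {
    stop("C4 assembly requires a single-chain monomer")
  }
  stopifnot(length(chains) == 4, !anyDuplicated(chains))
  xyz <- atom_xyz(monomer)
  parts <- lapply(0:3, function(k) {
    R <- rotation_about(axis, k * pi / 2)
    at <- monomer$atoms
    rot <- sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
    at$x <- rot[, 1]; at$y <- rot[, 2]; at$z <- rot[, 3]
    at$chain <- chains[k + 1]
    at
  })
  new_structure(do.call(rbind, parts), source = monomer$source,
                assembly = "tetramer", annotation = monomer$annotation)
}

#' Read a topology annotation from YAML
#'
#' The annotation lists helix ranges (H1..H6 and the half-helices HB/HE),
#' loops, the first C-tail residue, phosphosites, and the NPA and ar/R site
#' residues.
#'
#' @param path YAML file.
#' @return a `topology_annotation` list.
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  as_topology(y)
}

#' @rdname read_topology
#' @param x a list with elements `helix_ranges`, `loops`, `c_tail_start`,
#'   `phosphosites`, `npa_residues`, `arR_residues`.
#' @export
as_topology <- function(x) {
  rng <- function(v) c(as.integer(v[[1]]), as.integer(v[[2]]))
  helix <- lapply(x$helix_ranges, rng)
  loops <- lapply(x$loops, rng)
  ann <- list(helix_ranges = helix, loops = loops,
              c_tail_start = as.integer(x$c_tail_start %||% NA),
              phosphosites = as.integer(x$phosphosites %||% integer()),
              npa_residues = as.integer(x$npa_residues %||% integer()),
              arR_residues = as.integer(x$arR_residues %||% integer()))
  iv <- c(helix, loops)
  if (length(iv) > 1) {
    m <- do.call(rbind, iv)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("topology intervals overlap within the monomer")
    }
  }
  if (!is.na(ann$c_tail_start) && length(helix)) {
    if (ann$c_tail_start <= max(vapply(helix, `[`, 1L, 2))) {
      stop("c_tail_start must lie beyond the last helix")
    }
  }
  class(ann) <- "topology_annotation"
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach a topology annotation to a structure
#'
#' Every residue receives a structural-element label: its helix or loop, or
#' `"C-ter"` past `c_tail_start`, or `"other"`.
#'
#' @param structure an `aqp_structure`.
#' @param annotation a `topology_annotation` (or list coercible by
#'   [as_topology()]).
#' @return the structure with the annotation attached.
#' @export
annotate_topology <- function(structure, annotation) {
  if (!inherits(annotation, "topology_annotation")) {
    annotation <- as_topology(annotation)
  }
  resno <- structure$atoms$resno
  for (nm in names(annotation$helix_ranges)) {
    iv <- annotation$helix_ranges[[nm]]
    if (iv[1] < min(resno) || iv[2] > max(resno)) {
      stop("annotation interval ", nm, " [", iv[1], ",", iv[2],
           "] lies outside the structure's residue range")
    }
  }
  structure$annotation <- annotation
  structure
}

#' Structural-element label of a residue
#'
#' @param structure an annotated `aqp_structure` (or the annotation itself).
#' @param resno residue number(s).
#' @return character vector of labels (`"H1"`, `"loop C"`, `"C-ter"`, ...).
#' @export
residue_location <- function(structure, resno) {
  ann <- if (inherits(structure, "topology_annotation")) structure
         else structure$annotation
  if (is.null(ann)) stop("structure carries no topology annotation")
  vapply(resno, function(p) {
    for (nm in names(ann$helix_ranges)) {
      iv <- ann$helix_ranges[[nm]]
      if (p >= iv[1] && p <= iv[2]) return(nm)
    }
    for (nm in names(ann$loops)) {
      iv <- ann$loops[[nm]]
      if (p >= iv[1] && p <= iv[2]) return(nm)
    }
    if (!is.na(ann$c_tail_start) && p >= ann$c_tail_start) return("C-ter")
    "other"
  }, character(1))
}
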
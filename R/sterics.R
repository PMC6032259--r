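# Shared steric bookkeeping: which atom pairs near a site are coupled
# through covalent structure and therefore not scored as clashes.
#
# Local covalent geometry places through-bond neighbours up to four bonds
# apart (e.g. CB against the preceding carbonyl in an alpha helix) below
# the sum of their Bondi radii; a repulsive-only objective must ignore
# them, as force fields do by scaling local interactions. The exclusion is
# computed on the residue's bonded graph (backbone, side-chain template
# bonds, the proline ring bond and the flanking peptide bonds).

# Exclusion map around one residue: a named list, per site atom name, of
# environment keys "chain|resno|elety" within `bond_sep` covalent bonds.
# `site_aa3` overrides the site residue type (used while evaluating mutant
# candidates before the structure is rebuilt).
steric_exclusions <- function(structure, chain, resno, icode = "",
                              site_aa3 = NULL, bond_sep = 4) {
  a <- structure$atoms
  window <- a$chain == chain & a$resno >= resno - 2 & a$resno <= resno + 2
  win <- a[window, c("resno", "resid", "elety")]
  restypes <- list()
  for (r in unique(win$resno)) {
    restypes[[as.character(r)]] <- win$resid[win$resno == r][1]
  }
  if (!is.null(site_aa3)) restypes[[as.character(resno)]] <- site_aa3
  node <- function(r, at) paste(r, at, sep = "|")
  edges <- list()
  add <- function(r1, a1, r2, a2) {
    edges[[length(edges) + 1]] <<- c(node(r1, a1), node(r2, a2))
  }
  rs <- sort(as.integer(names(restypes)))
  for (r in rs) {
    aa3 <- restypes[[as.character(r)]]
    add(r, "N", r, "CA"); add(r, "CA", r, "C")
    add(r, "C", r, "O"); add(r, "C", r, "OXT")
    tpl <- aa_template(aa3)
    for (i in seq_len(nrow(tpl))) add(r, tpl$atom[i], r, tpl$parent[i])
    if (identical(aa3, "PRO")) add(r, "CD", r, "N")
    if ((r + 1) %in% rs) add(r, "C", r + 1, "N")
  }
  nodes <- unique(unlist(edges))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  site_aa <- restypes[[as.character(resno)]]
  site_atoms <- unique(c(.backbone_names, aa_template(site_aa)$atom))
  out <- list()
  for (at in site_atoms) {
    start <- node(resno, at)
    if (is.null(adj[[start]])) next
    seen <- start
    frontier <- start
    for (depth in seq_len(bond_sep)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
    }
    reach <- setdiff(seen, start)
    parts <- strsplit(reach, "|", fixed = TRUE)
    keys <- vapply(parts, function(p) paste(chain, p[1], p[2], sep = "|"),
                   character(1))
    out[[at]] <- keys
  }
  out
}
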
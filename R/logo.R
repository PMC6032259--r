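# Pore-lining residue identification, geometric ordering along the channel
# axis, mapping onto alignment columns and pore-logo frequency matrices.

#' Amino-acid alignment container
#'
#' @param names sequence identifiers.
#' @param seqs aligned sequences (equal-length strings, `-` for gaps).
#' @return an `aa_alignment`.
#' @export
aa_alignment <- function(names, seqs) {
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must have equal length")
  }
  structure(list(names = as.character(names), seqs = unname(seqs)),
            class = "aa_alignment")
}

#' Read a multiple alignment (FASTA or Clustal)
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`; guessed from the extension when
#'   missing.
#' @return an `aa_alignment`.
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("aln", "clustal", "clw")) "clustal" else "fasta"
  }
  aln <- seqinr::read.alignment(path, format = format)
  aa_alignment(aln$nam, unlist(aln$seq))
}

#' Write an alignment as FASTA
#'
#' @param alignment an `aa_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  seqinr::write.fasta(as.list(alignment$seqs), alignment$names, path,
                      nbchar = 60)
  invisible(path)
}

#' Pore-lining residues, ordered along the channel axis
#'
#' A residue lines the pore when at least one heavy atom lies within
#' `margin` of the surface of any profile sphere, i.e.
#' `| |atom - centre| - (radius + vdw) | <= margin`. Residues are ordered by
#' the axial coordinate of their closest-approach atom, cytoplasmic side
#' first; ties break towards the lower residue number.
#'
#' @param structure the `aqp_structure` the profile was computed on.
#' @param profile a `pore_profile`.
#' @param margin tolerance in angstrom; the default 1.4 is a water-probe
#'   contact criterion.
#' @return data frame (chain, resno, icode, resid, aa, z) in pore order.
#' @export
pore_lining_residues <- function(structure, profile, margin = 1.4) {
  if (is.null(profile$samples) || nrow(profile$samples) == 0) {
    stop("empty pore profile")
  }
  sm <- profile$samples[!profile$samples$open, , drop = FALSE]
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- as.matrix(sm[, c("cx", "cy", "cz")])
  # closeness of each atom to any sphere surface
  best <- rep(Inf, nrow(a))
  for (i in seq_len(nrow(sm))) {
    d <- sqrt((xyz[, 1] - ctr[i, 1])^2 + (xyz[, 2] - ctr[i, 2])^2 +
              (xyz[, 3] - ctr[i, 3])^2)
    gap <- abs(d - (sm$radius[i] + a$vdw))
    best <- pmin(best, gap)
  }
  lining <- best <= margin
  if (!any(lining)) {
    return(data.frame(chain = character(), resno = integer(),
                      icode = character(), resid = character(),
                      aa = character(), z = numeric()))
  }
  ax <- profile$axis
  zproj <- as.numeric(xyz %*% ax$direction) - sum(ax$origin * ax$direction)
  df <- data.frame(chain = a$chain, resno = a$resno, icode = a$icode,
                   resid = a$resid, z = zproj, gap = best)[lining, ]
  # per residue: axial coordinate of the closest-approach atom
  key <- paste(df$chain, df$resno, df$icode, sep = "|")
  ord <- order(key, df$gap)
  df <- df[ord, ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$icode, sep = "|")), ]
  df <- df[order(df$z, df$resno), ]
  df$aa <- unname(.aa3to1[df$resid])
  rownames(df) <- NULL
  df[, c("chain", "resno", "icode", "resid", "aa", "z")]
}

#' Map geometrically ordered residues onto alignment columns
#'
#' @param ordered_resno residue numbers in pore order (cytoplasmic first),
#'   e.g. the `resno` column of [pore_lining_residues()].
#' @param alignment an `aa_alignment` containing the reference sequence.
#' @param reference name of the reference sequence in the alignment.
#' @param ref_start residue number of the first (non-gap) position of the
#'   reference sequence; author numbering.
#' @return a `pore_mapping` data frame (position, resno, column, aa).
#' @export
map_alignment_columns <- function(ordered_resno, alignment, reference,
                                  ref_start = 1L) {
  i <- match(reference, alignment$names)
  if (is.na(i)) stop("reference sequence '", reference,
                     "' not found in the alignment")
  chars <- strsplit(alignment$seqs[i], "")[[1]]
  notgap <- which(chars != "-")
  resnos <- ref_start + seq_along(notgap) - 1L
  cols <- integer(length(ordered_resno))
  aas <- character(length(ordered_resno))
  for (k in seq_along(ordered_resno)) {
    j <- match(ordered_resno[k], resnos)
    if (is.na(j)) stop("reference residue ", ordered_resno[k],
                       " not found in the alignment")
    cols[k] <- notgap[j]
    aas[k] <- chars[notgap[j]]
  }
  out <- data.frame(position = seq_along(ordered_resno),
                    resno = as.integer(ordered_resno),
                    column = cols, aa = aas)
  class(out) <- c("pore_mapping", "data.frame")
  out
}

#' Read a packaged pore-position mapping
#'
#' A mapping is a TSV with columns `position` (1..N from the cytoplasmic
#' side), `resno` (reference-protein residue number) and optionally `aa` and
#' `column`.
#'
#' @param path TSV file.
#' @return a `pore_mapping` data frame.
#' @export
read_pore_mapping <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("position", "resno") %in% names(out)))
  if (any(out$position != seq_len(nrow(out)))) {
    stop("mapping positions must be contiguous from 1")
  }
  class(out) <- c("pore_mapping", "data.frame")
  out
}

#' Pore-logo position of a residue
#'
#' @param mapping a `pore_mapping`.
#' @param resno residue number in the reference protein.
#' @return 1-based pore position from the cytoplasmic side, or `NA` when the
#'   residue is not pore-lining.
#' @export
position_of <- function(mapping, resno) {
  idx <- match(resno, mapping$resno)
  out <- mapping$position[idx]
  if (anyNA(out)) {
    warning("residue(s) ", paste(resno[is.na(out)], collapse = ", "),
            " not in the pore mapping")
  }
  out
}

#' Pore-logo frequency matrix
#'
#' Per mapped column: amino-acid relative frequencies over the chosen
#' sequences (gaps excluded from the denominator) and information content
#' `log2(20) - H` in bits. A fully gapped column is flagged undefined (all-NA
#' frequency row).
#'
#' @param alignment an `aa_alignment`.
#' @param mapping a `pore_mapping` with a `column` component, or positions
#'   are taken as columns directly when absent.
#' @param subset sequence names to include; default all.
#' @return a `logo_matrix`: list with `freq` (positions x 20), `info` (bits)
#'   and the mapping.
#' @export
logo_frequencies <- function(alignment, mapping, subset = NULL) {
  if (is.null(subset)) subset <- alignment$names
  if (length(subset) == 0) stop("empty sequence subset")
  idx <- match(subset, alignment$names)
  if (anyNA(idx)) stop("unknown sequence name(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  chars <- do.call(rbind, strsplit(alignment$seqs[idx], ""))
  cols <- if (!is.null(mapping$column)) mapping$column else mapping$position
  aas <- names(.aa1to3)
  freq <- matrix(NA_real_, nrow = length(cols), ncol = 20,
                 dimnames = list(mapping$position, aas))
  info <- rep(NA_real_, length(cols))
  for (k in seq_along(cols)) {
    col <- chars[, cols[k]]
    col <- col[col != "-"]
    if (length(col) == 0) next  # entirely gapped: row stays undefined
    tab <- table(factor(col, levels = aas))
    p <- as.numeric(tab) / length(col)
    freq[k, ] <- p
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    info[k] <- log2(20) - h
  }
  structure(list(freq = freq, info = info, mapping = mapping,
                 n_seqs = length(subset)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("logo_matrix: ", nrow(x$freq), " pore positions over ", x$n_seqs,
      " sequences\n", sep = "")
  cat("  mean information ", round(mean(x$info, na.rm = TRUE), 2),
      " bits (max ", round(log2(20), 2), ")\n", sep = "")
  invisible(x)
}

#' Write a logo frequency matrix as TSV
#'
#' Positions x 20 amino-acid frequencies plus the information column,
#' consumable by standard logo renderers.
#'
#' @param logo a `logo_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
  df <- data.frame(position = rownames(logo$freq), logo$freq,
                   information = logo$info, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
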
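# Variant-catalog bookkeeping: parsing HUMSAVAR-style tab-text into SAP
# records, summaries, and the selection of mutants that can be modelled on
# available structural coverage. The package ships the curated table of the
# 34 disease-associated aquaporin SAPs and the table of experimental human
# AQP structures as plain-text fixtures.

#' Parse a HUMSAVAR-style variant table
#'
#' Each non-comment line carries a gene/protein identifier, a substitution
#' token in either the `p.Leu22Val` or `L22V` dialect, and a disease label,
#' tab-separated; optional extra columns give the structural location, the
#' hypothesized defect category, a prior-characterization flag and the
#' HUMSAVAR variant-type flag. Malformed substitution tokens or unknown
#' amino-acid codes reject the line with a record-level error (collected,
#' with line numbers, in the `errors` attribute); synonymous lines
#' (wild-type equal to mutant) are rejected.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a `sap_catalog` data frame with columns protein, wt_aa, position,
#'   mut_aa, disease, location, defect, prior_structural_ref,
#'   variant_category; rejected lines in `attr(, "errors")`.
#' @export
parse_humsavar <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- list()
  errs <- list()
  header <- NULL
  for (n in idx) {
    fields <- strsplit(lines[n], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (is.null(header) && identical(tolower(fields[1]), "protein")) {
      header <- tolower(fields)
      next
    }
    if (length(fields) < 3) {
      errs[[length(errs) + 1]] <- data.frame(
        line = n, message = "expected at least 3 tab-separated fields")
      next
    }
    getcol <- function(nm, k) {
      if (!is.null(header)) {
        j <- match(nm, header)
        if (!is.na(j) && j <= length(fields)) return(fields[j])
      }
      if (!is.na(k) && k <= length(fields)) return(fields[k])
      NA_character_
    }
    protein <- getcol("protein", 1)
    token <- getcol("change", 2)
    disease <- getcol("disease", 3)
    mut <- tryCatch(parse_mutation(token), error = function(e) e)
    if (inherits(mut, "error")) {
      errs[[length(errs) + 1]] <- data.frame(
        line = n, message = conditionMessage(mut))
      next
    }
    if (mut$wt_aa == mut$mut_aa) {
      errs[[length(errs) + 1]] <- data.frame(
        line = n, message = paste0("synonymous substitution '", token, "'"))
      next
    }
    recs[[length(recs) + 1]] <- data.frame(
      protein = protein, wt_aa = mut$wt_aa, position = mut$position,
      mut_aa = mut$mut_aa, disease = disease,
      location = getcol("location", 4),
      defect = getcol("defect", 5),
      prior_structural_ref = getcol("prior_structural_ref", 6),
      variant_category = getcol("variant_category", 7),
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(protein = character(), wt_aa = character(),
               position = integer(), mut_aa = character(),
               disease = character(), location = character(),
               defect = character(), prior_structural_ref = character(),
               variant_category = character(), stringsAsFactors = FALSE)
  out$prior_structural_ref[is.na(out$prior_structural_ref)] <- "none"
  class(out) <- c("sap_catalog", "data.frame")
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), message = character())
  out
}

#' Format SAP records back to HUMSAVAR-style lines
#'
#' The inverse of [parse_humsavar()]: `parse(format(x))` preserves all
#' fields.
#'
#' @param records a `sap_catalog`.
#' @param dialect `"p3"` for `p.Leu22Val` tokens, `"short"` for `L22V`.
#' @return character vector of tab-separated lines (with header).
#' @export
format_humsavar <- function(records, dialect = c("p3", "short")) {
  dialect <- match.arg(dialect)
  token <- if (dialect == "p3") {
    aa3cap <- function(a1) {
      a3 <- .aa1to3[a1]
      paste0(substr(a3, 1, 1), tolower(substr(a3, 2, 3)))
    }
    paste0("p.", aa3cap(records$wt_aa), records$position,
           aa3cap(records$mut_aa))
  } else {
    paste0(records$wt_aa, records$position, records$mut_aa)
  }
  c(paste(c("protein", "change", "disease", "location", "defect",
            "prior_structural_ref", "variant_category"), collapse = "\t"),
    paste(records$protein, token, records$disease, records$location,
          records$defect, records$prior_structural_ref,
          records$variant_category, sep = "\t"))
}

#' Summarize a SAP catalog
#'
#' Counts per protein, per disease and per defect category; counts always
#' sum to the number of records. Records are ordered by protein then
#' position.
#'
#' @param records a non-empty `sap_catalog`.
#' @return a `sap_summary` list of named count vectors plus `n`.
#' @export
summarize_catalog <- function(records) {
  if (nrow(records) == 0) stop("empty variant catalog")
  records <- records[order(records$protein, records$position), ]
  cnt <- function(x) {
    t <- table(x, useNA = "no")
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(n = nrow(records),
                 by_protein = cnt(records$protein),
                 by_disease = cnt(records$disease),
                 by_defect = cnt(records$defect)),
            class = "sap_summary")
}

#' @export
print.sap_summary <- function(x, ...) {
  cat("SAP catalog: ", x$n, " records\n", sep = "")
  cat("  by protein: ", paste(names(x$by_protein), x$by_protein,
                              sep = ":", collapse = ", "), "\n", sep = "")
  cat("  by disease: ", paste(names(x$by_disease), x$by_disease,
                              sep = ":", collapse = ", "), "\n", sep = "")
  cat("  by defect:  ", paste(names(x$by_defect), x$by_defect,
                              sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Records without prior structural characterization
#'
#' Keeps records whose `prior_structural_ref` flag is `none` or
#' `functional-only` - the variants for which only functional data, not a
#' structural rationale, had been reported.
#'
#' @param records a `sap_catalog`.
#' @return the filtered `sap_catalog`.
#' @export
filter_uncharacterized <- function(records) {
  out <- records[records$prior_structural_ref %in%
                   c("none", "functional-only"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sap_catalog", "data.frame")
  out
}

#' Select variants that can be modelled on available coverage
#'
#' @param records a `sap_catalog`.
#' @param coverage named list: per protein, the `c(start, end)` residue
#'   interval with structural coordinates. Proteins missing from the map
#'   are skipped with a warning.
#' @return the subset of `records` whose position lies inside coverage.
#' @export
select_modelable <- function(records, coverage) {
  if (nrow(records) == 0) return(records)
  keep <- logical(nrow(records))
  missing_prot <- character()
  for (i in seq_len(nrow(records))) {
    cov <- coverage[[records$protein[i]]]
    if (is.null(cov)) {
      missing_prot <- c(missing_prot, records$protein[i])
      next
    }
    keep[i] <- records$position[i] >= cov[1] & records$position[i] <= cov[2]
  }
  if (length(missing_prot)) {
    warning("no structural coverage for: ",
            paste(unique(missing_prot), collapse = ", "), "; skipped")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sap_catalog", "data.frame")
  out
}

#' Packaged catalog of disease-associated aquaporin SAPs
#'
#' The 34 single amino-acid polymorphisms reported for human aquaporins as
#' disease-associated (28 in AQP2/NDI, 5 in AQP5/PPKB, 1 in AQP8/colorectal
#' tumor), with structural location, hypothesized defect category and
#' prior-characterization flag.
#'
#' @return a `sap_catalog`.
#' @export
aqp_sap_catalog <- function() {
  parse_humsavar(system.file("extdata", "table2.tsv", package = "aqpstruct"))
}

#' Packaged table of experimental human AQP structures
#'
#' @return data frame of structure entries (protein, residue range, PDB id,
#'   mutation, assembly, method, resolution, year).
#' @export
aqp_structure_table <- function() {
  out <- utils::read.table(system.file("extdata", "table1.tsv",
                                       package = "aqpstruct"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(out$resolution > 0), all(out$res_start < out$res_end))
  out
}

#' Structural coverage map derived from a structure table
#'
#' Per protein, the widest residue interval covered by any listed structure;
#' entries in `extra` (e.g. homology models) are merged in.
#'
#' @param structures a structure table, default the packaged one.
#' @param extra named list of additional `c(start, end)` intervals.
#' @return named list of intervals.
#' @export
coverage_map <- function(structures = aqp_structure_table(), extra = NULL) {
  cov <- list()
  for (p in unique(structures$protein)) {
    sub <- structures[structures$protein == p, ]
    # widest single-structure interval (models are built on one template)
    w <- which.max(sub$res_end - sub$res_start)
    cov[[p]] <- c(sub$res_start[w], sub$res_end[w])
  }
  for (p in names(extra)) cov[[p]] <- extra[[p]]
  cov
}
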
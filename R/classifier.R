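# Rule-based classification of a variant's structural defect from the
# evidence gathered by the upstream analyses. Categories follow the
# four-way scheme for aquaporin disease variants: pore features, tetramer
# assembly, monomer folding, and C-tail phosphorylation-signal loss.

#' Classifier thresholds
#'
#' @param clash_score minimum summed squared-overlap (square angstrom)
#'   counted as a folding/assembly-relevant steric strain; 0.25 corresponds
#'   to roughly one 0.5 A overlap.
#' @param pore_narrowing minimum sustained pore-radius reduction (angstrom).
#' @param min_run slices over which the narrowing must persist.
#' @param phosphosite_window residue distance to a phosphosite counted as
#'   "near" (covers an affected site two residues upstream of a
#'   phosphoserine).
#' @param contacts_lost minimum number of lost packing interactions.
#' @return a `defect_thresholds` list.
#' @export
defect_thresholds <- function(clash_score = 0.25, pore_narrowing = 0.3,
                              min_run = 3, phosphosite_window = 4,
                              contacts_lost = 2) {
  stopifnot(clash_score > 0, pore_narrowing > 0, min_run >= 1,
            phosphosite_window >= 0, contacts_lost >= 1)
  structure(list(clash_score = clash_score, pore_narrowing = pore_narrowing,
                 min_run = min_run, phosphosite_window = phosphosite_window,
                 contacts_lost = contacts_lost),
            class = "defect_thresholds")
}

#' Gather classification evidence for one mutation
#'
#' Runs the contact/clash differential at the site and combines it with the
#' topology annotation, C-tail salt-bridge bookkeeping and, when profiles
#' are supplied, the pore-narrowing comparison.
#'
#' @param wt annotated wild-type `aqp_structure`.
#' @param mut mutant structure from [mutate_residue()].
#' @param spec a [mutation_spec()].
#' @param profiles optional list with `wt` and `mut` `pore_profile`s.
#' @param lining optional precomputed [pore_lining_residues()] table for the
#'   wild type; derived from `profiles$wt` when absent.
#' @param thresholds a [defect_thresholds()].
#' @return an `evidence` list.
#' @export
gather_evidence <- function(wt, mut, spec, profiles = NULL, lining = NULL,
                            thresholds = defect_thresholds()) {
  ann <- wt$annotation
  if (is.null(ann)) stop("missing upstream stage: topology annotation")
  loc <- residue_location(ann, spec$position)
  is_c_tail <- loc == "C-ter"
  near_phos <- length(ann$phosphosites) > 0 &&
    any(abs(spec$position - ann$phosphosites) <= thresholds$phosphosite_window)
  lost_sb_ctail <- FALSE
  if (is_c_tail) {
    sbw <- salt_bridges(wt)
    sbm <- salt_bridges(mut)
    involves <- function(sb) {
      nrow(sb) > 0 & ((sb$chain_a == spec$chain & sb$resno_a == spec$position) |
                      (sb$chain_b == spec$chain & sb$resno_b == spec$position))
    }
    lost_sb_ctail <- any(involves(sbw)) && !any(involves(sbm))
  }
  pro_helix <- proline_in_helix(ann, spec)
  cl <- detect_clashes(mut, spec$chain, spec$position, spec$icode)
  intra_clash <- sum(cl$overlap[cl$scope == "intra_monomer"]^2)
  inter_clash <- sum(cl$overlap[cl$scope == "inter_monomer"]^2)
  dd <- diff_contacts(wt, mut, spec$chain, spec$position, spec$icode)
  lost_pack <- dd$lost[dd$lost$kind != "clash", , drop = FALSE]
  intra_lost <- sum(lost_pack$scope == "intra_monomer")
  inter_lost <- sum(lost_pack$scope == "inter_monomer")
  is_lining <- FALSE
  max_narrow <- 0
  narrow_side <- "none"
  if (!is.null(profiles)) {
    if (is.null(profiles$wt) || is.null(profiles$mut)) {
      stop("missing upstream stage: pore profile (need both wt and mut)")
    }
    if (is.null(lining)) lining <- pore_lining_residues(wt, profiles$wt)
    is_lining <- spec$position %in% lining$resno
    pd <- compare_profiles(profiles$wt, profiles$mut,
                           threshold = thresholds$pore_narrowing,
                           min_run = thresholds$min_run)
    if (nrow(pd$regions)) {
      w <- which.max(pd$regions$max_reduction)
      max_narrow <- pd$regions$max_reduction[w]
      narrow_side <- pd$regions$side[w]
    }
  } else if (!is.null(lining)) {
    is_lining <- spec$position %in% lining$resno
  }
  structure(list(location_label = loc, is_c_tail = is_c_tail,
                 near_phosphosite = near_phos,
                 lost_salt_bridge_c_tail = lost_sb_ctail,
                 pro_in_helix = pro_helix,
                 intra_clash_score = intra_clash,
                 intra_contacts_lost = intra_lost,
                 inter_contacts_lost = inter_lost,
                 inter_clash_score = inter_clash,
                 is_pore_lining = is_lining,
                 max_narrowing = max_narrow,
                 narrowing_side = narrow_side),
            class = "evidence")
}

#' Classify evidence into a structural-defect category
#'
#' Pure function of the evidence and thresholds. Rules fire in fixed
#' precedence: (1) signal loss for C-tail sites near a phosphosite or
#' losing a C-tail salt bridge; (2) monomer folding for helix-breaking
#' prolines, intra-monomer steric strain or lost intra-monomer packing;
#' (3) tetramer assembly for lost inter-monomer packing or inter-monomer
#' strain; (4) pore features for pore-lining sites with sustained
#' narrowing; otherwise unclassified. Folding outranks pore features so a
#' pore-lining residue whose substitution strains the monomer interior is
#' called a folding defect, not mere narrowing.
#'
#' @param evidence an `evidence` list from [gather_evidence()].
#' @param thresholds a [defect_thresholds()].
#' @return a `defect_report` with `category`, ordered `rationale` and the
#'   evidence.
#' @export
classify <- function(evidence, thresholds = defect_thresholds()) {
  fired <- character()
  category <- "unclassified"
  if (evidence$is_c_tail &&
      (evidence$near_phosphosite || evidence$lost_salt_bridge_c_tail)) {
    category <- "signal loss"
    if (evidence$near_phosphosite) {
      fired <- c(fired, "C-tail site near a phosphosite")
    }
    if (evidence$lost_salt_bridge_c_tail) {
      fired <- c(fired, "C-tail salt bridge lost")
    }
  } else if (evidence$pro_in_helix ||
             evidence$intra_clash_score >= thresholds$clash_score ||
             evidence$intra_contacts_lost >= thresholds$contacts_lost) {
    category <- "monomer folding"
    if (evidence$pro_in_helix) {
      fired <- c(fired, "proline introduced inside a helix")
    }
    if (evidence$intra_clash_score >= thresholds$clash_score) {
      fired <- c(fired, sprintf("intra-monomer clash score %.2f >= %.2f",
                                evidence$intra_clash_score,
                                thresholds$clash_score))
    }
    if (evidence$intra_contacts_lost >= thresholds$contacts_lost) {
      fired <- c(fired, sprintf("%d intra-monomer packing contacts lost",
                                evidence$intra_contacts_lost))
    }
  } else if (evidence$inter_contacts_lost >= thresholds$contacts_lost ||
             evidence$inter_clash_score >= thresholds$clash_score) {
    category <- "tetramer assembly"
    if (evidence$inter_contacts_lost >= thresholds$contacts_lost) {
      fired <- c(fired, sprintf("%d inter-monomer packing contacts lost",
                                evidence$inter_contacts_lost))
    }
    if (evidence$inter_clash_score >= thresholds$clash_score) {
      fired <- c(fired, sprintf("inter-monomer clash score %.2f >= %.2f",
                                evidence$inter_clash_score,
                                thresholds$clash_score))
    }
  } else if (evidence$is_pore_lining &&
             evidence$max_narrowing >= thresholds$pore_narrowing) {
    category <- "pore features"
    fired <- c(fired, sprintf(
      "pore-lining site with %.2f A sustained narrowing (%s side)",
      evidence$max_narrowing, evidence$narrowing_side))
  }
  structure(list(category = category, rationale = fired,
                 evidence = evidence, thresholds = thresholds),
            class = "defect_report")
}

#' @export
print.defect_report <- function(x, ...) {
  cat("defect_report: ", x$category, "\n", sep = "")
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Batch classification of a variant catalog
#'
#' Models each variant on its protein's structure, gathers evidence and
#' classifies it; per-record failures are collected and the run continues.
#' When the catalog carries curated defect labels, agreement statistics are
#' attached.
#'
#' @param records a `sap_catalog` (positions must be covered by the supplied
#'   structures).
#' @param structures named list: per protein, an annotated `aqp_structure`
#'   (wild type).
#' @param thresholds a [defect_thresholds()].
#' @param placement a [placement_params()].
#' @param profiler a [profiler_params()], used for pore-lining sites.
#' @param with_profiles set `FALSE` to skip pore profiling entirely.
#' @return a `defect_table` data frame (one row per record: mutation,
#'   category, agreement with any curated label); failures in
#'   `attr(, "failures")`, agreement counts in `attr(, "agreement")`.
#' @export
batch_report <- function(records, structures,
                         thresholds = defect_thresholds(),
                         placement = placement_params(),
                         profiler = profiler_params(),
                         with_profiles = TRUE) {
  rows <- list()
  failures <- list()
  prof_cache <- list()
  lining_cache <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      wt <- structures[[rec$protein]]
      if (is.null(wt)) stop("no structure supplied for ", rec$protein)
      chain <- wt$atoms$chain[1]
      spec <- mutation_spec(chain, rec$position, rec$wt_aa, rec$mut_aa)
      mut <- mutate_residue(wt, spec, placement)
      profiles <- NULL
      lining <- NULL
      if (with_profiles) {
        if (is.null(prof_cache[[rec$protein]])) {
          prof_cache[[rec$protein]] <- compute_profile(wt, params = profiler)
          lining_cache[[rec$protein]] <-
            pore_lining_residues(wt, prof_cache[[rec$protein]])
        }
        lining <- lining_cache[[rec$protein]]
        if (rec$position %in% lining$resno) {
          pw <- prof_cache[[rec$protein]]
          pm <- compute_profile(mut, axis = pw$axis, params = profiler)
          profiles <- list(wt = pw, mut = pm)
        }
      }
      ev <- gather_evidence(wt, mut, spec, profiles = profiles,
                            lining = lining, thresholds = thresholds)
      rep <- classify(ev, thresholds)
      data.frame(protein = rec$protein,
                 mutation = paste0(rec$wt_aa, rec$position, rec$mut_aa),
                 disease = rec$disease, location = ev$location_label,
                 category = rep$category,
                 expected = rec$defect %||% NA_character_,
                 match = if (is.na(rec$defect)) NA else
                   rep$category == rec$defect,
                 rationale = paste(rep$rationale, collapse = "; "),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        protein = rec$protein,
        mutation = paste0(rec$wt_aa, rec$position, rec$mut_aa),
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), mutation = character(),
               disease = character(), location = character(),
               category = character(), expected = character(),
               match = logical(), rationale = character(),
               stringsAsFactors = FALSE)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
    else data.frame(protein = character(), mutation = character(),
                    message = character())
  lab <- !is.na(out$match)
  attr(out, "agreement") <- list(n_labelled = sum(lab),
                                 n_match = sum(out$match[lab]))
  class(out) <- c("defect_table", "data.frame")
  out
}
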
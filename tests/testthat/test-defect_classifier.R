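base_evidence <- function(...) {
  ev <- list(location_label = "H1", is_c_tail = FALSE,
             near_phosphosite = FALSE, lost_salt_bridge_c_tail = FALSE,
             pro_in_helix = FALSE, intra_clash_score = 0,
             intra_contacts_lost = 0, inter_contacts_lost = 0,
             inter_clash_score = 0, is_pore_lining = FALSE,
             max_narrowing = 0, narrowing_side = "none")
  mods <- list(...)
  ev[names(mods)] <- mods
  class(ev) <- "evidence"
  ev
}

test_that("classification is a pure function with fixed rule precedence", {
  ev <- base_evidence(is_pore_lining = TRUE, max_narrowing = 0.8,
                      narrowing_side = "cytoplasmic")
  r1 <- classify(ev)
  r2 <- classify(ev)
  expect_equal(r1$category, "pore features")
  expect_identical(r1$category, r2$category)
  expect_identical(r1$rationale, r2$rationale)
  # empty evidence stays unclassified
  expect_equal(classify(base_evidence())$category, "unclassified")
})

test_that("intra-monomer strain overrides a pore-narrowing verdict", {
  # a pore-lining site that also strains the monomer interior is a folding
  # defect, never the reverse
  pore_ev <- base_evidence(is_pore_lining = TRUE, max_narrowing = 1.0,
                           narrowing_side = "extracellular")
  expect_equal(classify(pore_ev)$category, "pore features")
  strained <- base_evidence(is_pore_lining = TRUE, max_narrowing = 1.0,
                            narrowing_side = "extracellular",
                            intra_clash_score = 0.6)
  expect_equal(classify(strained)$category, "monomer folding")
  # and removing narrowing from a folding case never yields pore features
  strained$max_narrowing <- 0
  expect_equal(classify(strained)$category, "monomer folding")
})

test_that("rule order is monotone in the pore threshold", {
  th_lo <- defect_thresholds(pore_narrowing = 0.05)
  for (ev in list(base_evidence(pro_in_helix = TRUE, is_pore_lining = TRUE,
                                max_narrowing = 0.2),
                  base_evidence(is_c_tail = TRUE, near_phosphosite = TRUE,
                                is_pore_lining = TRUE, max_narrowing = 0.2))) {
    expect_equal(classify(ev)$category,
                 classify(ev, th_lo)$category)
  }
})

test_that("signal-loss evidence fires for C-tail phosphosite neighbours", {
  ev <- base_evidence(location_label = "C-ter", is_c_tail = TRUE,
                      near_phosphosite = TRUE)
  expect_equal(classify(ev)$category, "signal loss")
  ev2 <- base_evidence(location_label = "C-ter", is_c_tail = TRUE,
                       lost_salt_bridge_c_tail = TRUE)
  expect_equal(classify(ev2)$category, "signal loss")
  # off the C-tail the same flags do not fire
  ev3 <- base_evidence(near_phosphosite = TRUE)
  expect_equal(classify(ev3)$category, "unclassified")
})

test_that("gathered evidence matches the planted tetramer scenario", {
  tet <- make_tetramer_fixture()
  spec <- mutation_spec("A", 10, "L", "G")
  mut <- mutate_residue(tet, spec)
  ev <- gather_evidence(tet, mut, spec)
  expect_gte(ev$inter_contacts_lost, 2)
  expect_equal(ev$intra_contacts_lost, 0)
  expect_lt(ev$intra_clash_score, 0.25)
  expect_equal(classify(ev)$category, "tetramer assembly")
  # wt-vs-wt evidence is all zero
  spec0 <- mutation_spec("A", 12, "G", "G")
  wt2 <- mutate_residue(tet, spec0)
  ev0 <- gather_evidence(tet, wt2, spec0)
  expect_equal(ev0$intra_clash_score, 0)
  expect_equal(ev0$inter_contacts_lost + ev0$intra_contacts_lost, 0)
  expect_false(ev0$pro_in_helix)
})

test_that("a pore-facing bulky substitution classifies as pore features", {
  b <- make_pore_bundle()
  spec <- mutation_spec("A", 10, "A", "W")
  mut <- mutate_residue(b, spec)
  ax <- estimate_axis(b)
  pp <- profiler_params(seed = 5)
  pw <- compute_profile(b, ax, pp)
  pm <- compute_profile(mut, ax, pp)
  ev <- gather_evidence(b, mut, spec, profiles = list(wt = pw, mut = pm))
  expect_true(ev$is_pore_lining)
  expect_gte(ev$max_narrowing, 0.3)
  expect_lt(ev$intra_clash_score, 0.25)
  expect_equal(classify(ev)$category, "pore features")
})

test_that("a buried bulky substitution classifies as monomer folding", {
  b <- make_bundle_channel(6, 7.5, 30)
  ann <- as_topology(list(helix_ranges = list(H1 = c(1, 20)), loops = list(),
                          c_tail_start = 525, phosphosites = integer()))
  b <- annotate_topology(b, ann)
  spec <- mutation_spec("A", 11, "A", "W")
  mut <- mutate_residue(b, spec)
  ev <- gather_evidence(b, mut, spec)
  expect_gte(ev$intra_clash_score, 0.25)
  expect_equal(classify(ev)$category, "monomer folding")
})

test_that("missing upstream stages are named", {
  tet <- make_tetramer_fixture()
  spec <- mutation_spec("A", 10, "L", "G")
  mut <- mutate_residue(tet, spec)
  bare <- tet
  bare$annotation <- NULL
  expect_error(gather_evidence(bare, mut, spec), "topology annotation")
  expect_error(gather_evidence(tet, mut, spec, profiles = list(wt = NULL)),
               "pore profile")
})

test_that("batch classification recovers planted categories", {
  tet <- make_tetramer_fixture()
  recs <- planted_catalog()
  rep <- batch_report(recs, list(SYN1 = tet), with_profiles = FALSE)
  expect_equal(nrow(rep), 5)
  ag <- attr(rep, "agreement")
  expect_equal(ag$n_labelled, 5)
  expect_gte(ag$n_match, 4)
  expect_equal(nrow(attr(rep, "failures")), 0)
  # empty input gives an empty table
  rep0 <- batch_report(recs[0, ], list(SYN1 = tet))
  expect_equal(nrow(rep0), 0)
  # per-record failures are collected, the run continues
  bad <- recs
  bad$protein[1] <- "MISSING"
  rep1 <- batch_report(bad, list(SYN1 = tet), with_profiles = FALSE)
  expect_equal(nrow(rep1), 4)
  expect_equal(nrow(attr(rep1, "failures")), 1)
})
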
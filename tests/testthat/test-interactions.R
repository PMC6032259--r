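test_that("contact maps equal the brute-force oracle and are symmetric", {
  s <- random_atom_structure(60, seed = 8, box = 18)
  cm <- contact_map(s, NULL, NULL, cutoff = 6)
  oracle <- brute_force_contacts(s, 6)
  key <- function(df) sort(paste(df$chain_a, df$resno_a, df$chain_b,
                                 df$resno_b))
  expect_equal(key(cm), key(oracle))
  # min distances agree
  ocr <- oracle[order(oracle$chain_a, oracle$resno_a, oracle$chain_b,
                      oracle$resno_b), ]
  cmr <- cm[order(cm$chain_a, cm$resno_a, cm$chain_b, cm$resno_b), ]
  expect_equal(cmr$min_dist, ocr$min_dist, tolerance = 1e-9)
  # symmetry: (a,b) present iff (b,a) present
  ab <- paste(cmr$chain_a, cmr$resno_a, cmr$chain_b, cmr$resno_b)
  ba <- paste(cmr$chain_b, cmr$resno_b, cmr$chain_a, cmr$resno_a)
  expect_setequal(ab, ba)
  # out-of-range pair is no contact
  far <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = 1:2, icode = "", resid = "ALA", elety = "CB",
    element = "C", x = c(0, 9), y = 0, z = 0))
  expect_equal(nrow(contact_map(far, NULL, NULL, cutoff = 8)), 0)
  expect_equal(nrow(contact_map(far, NULL, NULL, cutoff = 9.5)), 2)
})

test_that("clash detection follows the overlap definition and threshold", {
  mk <- function(d) aqpstruct:::new_structure(data.frame(
    chain = "A", resno = c(1, 5), icode = "", resid = c("ALA", "ALA"),
    elety = "CB", element = "C", x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(detect_clashes(mk(3.5), "A", 1)), 0)
  cl <- detect_clashes(mk(2.9), "A", 1)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 0.5, tolerance = 1e-9)
  # monotone in the threshold: lower threshold finds a superset
  b <- make_bundle_channel(6, 7.5, 30)
  m <- mutate_residue(b, mutation_spec("A", 11, "A", "W"))
  hi <- detect_clashes(m, "A", 11, clash_threshold = 0.3)
  lo <- detect_clashes(m, "A", 11, clash_threshold = 0.05)
  expect_true(all(paste(hi$chain_b, hi$resno_b) %in%
                  paste(lo$chain_b, lo$resno_b)))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("contact differencing is empty for identical structures", {
  b <- make_bundle_channel(4, 8, 20, sequence = "AVL")
  d <- diff_contacts(b, b, "A", 10)
  expect_equal(nrow(d$lost), 0)
  expect_equal(nrow(d$gained), 0)
  # structures differing away from the site are rejected
  b2 <- b
  b2$atoms$x[1] <- b2$atoms$x[1] + 1
  expect_error(diff_contacts(b, b2, "A", 10), "differ away")
})

test_that("interface side-chain shortening loses inter-monomer packing", {
  tet <- make_tetramer_fixture()
  cm <- contact_map(tet, list(chain = "A", resno = 10), NULL, cutoff = 8)
  hyd <- cm[cm$hydrophobic & cm$scope == "inter_monomer", ]
  expect_gte(nrow(hyd), 2)
  mut <- mutate_residue(tet, mutation_spec("A", 10, "L", "G"))
  dd <- diff_contacts(tet, mut, "A", 10)
  lost_pack <- dd$lost[dd$lost$kind != "clash", ]
  expect_gte(sum(lost_pack$scope == "inter_monomer"), 2)
  expect_equal(sum(lost_pack$scope == "intra_monomer"), 0)
})

test_that("salt bridges are recognized by geometry and charge", {
  near <- salt_bridge_fixture(3.2)
  sb <- salt_bridges(near)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$resid_a, "ARG")
  expect_equal(sb$resid_b, "GLU")
  # an 8 A separated pair is no bridge
  expect_equal(nrow(salt_bridges(salt_bridge_fixture(8))), 0)
  # region filter excludes the pair
  expect_equal(nrow(salt_bridges(near, region = c(5, 9))), 0)
  # like charges never bridge
  pos2 <- aqpstruct:::new_structure(data.frame(
    chain = "A", resno = c(1, 2), icode = "", resid = c("ARG", "LYS"),
    elety = c("NH1", "NZ"), element = "N", x = c(0, 3), y = 0, z = 0))
  expect_equal(nrow(salt_bridges(pos2)), 0)
})

test_that("helix-proline flagging respects annotation and N-terminal slack", {
  ann <- read_topology(system.file("extdata", "aqp2_topology.yaml",
                                   package = "aqpstruct"))
  expect_true(proline_in_helix(ann, mutation_spec("A", 28, "L", "P")))
  expect_true(proline_in_helix(ann, mutation_spec("A", 216, "S", "P")))
  # removing a proline is not flagged
  expect_false(proline_in_helix(ann, mutation_spec("A", 262, "P", "L")))
  # the two N-terminal helix positions tolerate proline
  expect_false(proline_in_helix(ann, mutation_spec("A", 12, "A", "P")))
  expect_false(proline_in_helix(ann, mutation_spec("A", 13, "A", "P")))
  expect_true(proline_in_helix(ann, mutation_spec("A", 14, "A", "P")))
  # loop and C-tail prolines are not helix-breaking
  expect_false(proline_in_helix(ann, mutation_spec("A", 125, "T", "P")))
})
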
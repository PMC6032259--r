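test_that("pore-lining residues are found and ordered axially", {
  # cylinder wall plus one helix pressed against it from outside the wall:
  # only the wall rings line the pore
  w <- make_channel_wall(channel_spec(function(z) 4.0, c(-8, 8)))
  ax <- pore_axis(c(0, 0, 0), c(0, 0, 1), -6, 6)
  p <- compute_profile(w, ax, profiler_params(seed = 13))
  lin <- pore_lining_residues(w, p, margin = 1.4)
  expect_gt(nrow(lin), 0)
  # ordered by axial coordinate, cytoplasmic first
  expect_true(all(diff(lin$z) >= 0))
  # wall rings within the profiled range are all tangent to the spheres
  rings_in <- unique(w$atoms$resno[abs(w$atoms$z) <= 6])
  expect_true(all(rings_in %in% lin$resno))
  # empty profile errors
  expect_error(pore_lining_residues(w, list(samples = NULL)), "empty")
})

test_that("geometric ordering is invariant under rigid motion", {
  b <- make_pore_bundle()
  ax <- estimate_axis(b)
  pp <- profiler_params(seed = 17)
  p <- compute_profile(b, ax, pp)
  lin <- pore_lining_residues(b, p)
  R <- aqpstruct:::rotation_about(c(1, 0, 1), 1.1)
  b2 <- b
  xyz <- aqpstruct:::atom_xyz(b) %*% t(R)
  b2$atoms$x <- xyz[, 1] + 3; b2$atoms$y <- xyz[, 2] - 2
  b2$atoms$z <- xyz[, 3] + 1
  ax2 <- pore_axis(as.numeric(R %*% ax$origin) + c(3, -2, 1),
                   as.numeric(R %*% ax$direction), ax$z_min, ax$z_max)
  p2 <- compute_profile(b2, ax2, pp)
  lin2 <- pore_lining_residues(b2, p2)
  # epsilon-robust set invariance: each lining set at the working margin is
  # contained in the other's set at a marginally wider margin, so only
  # exact-boundary residues may differ
  lin_w <- pore_lining_residues(b, p, margin = 1.45)
  lin2_w <- pore_lining_residues(b2, p2, margin = 1.45)
  expect_true(all(lin$resno %in% lin2_w$resno))
  expect_true(all(lin2$resno %in% lin_w$resno))
  # the axial ordering is preserved up to ties between equal-z residues
  common <- intersect(lin$resno, lin2$resno)
  expect_gt(stats::cor(match(common, lin$resno), match(common, lin2$resno),
                       method = "spearman"), 0.99)
})

test_that("alignment columns map through gaps", {
  aln <- aa_alignment(c("ref", "other"),
                      c("ACDEFGHIKL", "ACDEFGHIKL"))
  m <- map_alignment_columns(c(2, 5, 9), aln, "ref")
  expect_equal(m$column, c(2, 5, 9))
  expect_equal(m$position, 1:3)
  # a gap before the region shifts columns by one
  aln2 <- aa_alignment(c("ref", "other"),
                       c("AC-DEFGHIKL", "ACXDEFGHIKL"))
  m2 <- map_alignment_columns(c(3, 5), aln2, "ref")
  expect_equal(m2$column, c(4, 6))
  expect_error(map_alignment_columns(c(99), aln2, "ref"), "99")
  expect_error(map_alignment_columns(c(1), aln2, "nope"), "not found")
})

test_that("logo frequencies and information behave at the closed forms", {
  aln <- make_toy_alignment(10, 30, conserved_columns = 7, seed = 2,
                            conserved_residue = "W")
  mp <- data.frame(position = 1, resno = 7, column = 7)
  lg <- logo_frequencies(aln, mp)
  expect_equal(sum(lg$freq[1, ]), 1, tolerance = 1e-9)
  expect_equal(lg$freq[1, "W"], 1)
  expect_equal(lg$info[1], log2(20))
  # two-sequence 50/50 column
  aln2 <- aa_alignment(c("a", "b"), c("AW", "AY"))
  lg2 <- logo_frequencies(aln2, data.frame(position = 1:2, resno = 1:2,
                                           column = 1:2))
  expect_equal(lg2$info[1], log2(20))
  expect_equal(lg2$info[2], log2(20) - 1)
  # gaps drop out of the denominator; an all-gap column is undefined
  aln3 <- aa_alignment(c("a", "b", "c"), c("A-", "A-", "W-"))
  lg3 <- logo_frequencies(aln3, data.frame(position = 1:2, resno = 1:2,
                                           column = 1:2))
  expect_equal(lg3$freq[1, "A"], 2 / 3)
  expect_true(all(is.na(lg3$freq[2, ])))
  # frequencies are invariant under sequence order permutation
  aln4 <- aa_alignment(rev(aln$names), rev(aln$seqs))
  lg4 <- logo_frequencies(aln4, mp)
  expect_equal(lg4$freq, lg$freq)
})

test_that("the packaged pore mappings carry the documented anchors", {
  pm <- read_pore_mapping(system.file("extdata",
                                      "pore_mapping_aqp2_synthetic.tsv",
                                      package = "aqpstruct"))
  expect_equal(nrow(pm), 51)
  expect_equal(position_of(pm, 64), 10)
  expect_equal(position_of(pm, 180), 41)
  expect_equal(position_of(pm, 181), 36)
  expect_equal(position_of(pm, 71), 21)
  expect_equal(position_of(pm, 168), 26)
  pm5 <- read_pore_mapping(system.file("extdata",
                                       "pore_mapping_aqp5_synthetic.tsv",
                                       package = "aqpstruct"))
  expect_equal(position_of(pm5, 188), 30)
  expect_equal(position_of(pm5, 177), 40)
  # position_of inverts the ordered list
  expect_equal(position_of(pm, pm$resno), pm$position)
  expect_warning(out <- position_of(pm, 9999), "not in the pore mapping")
  expect_true(is.na(out))
})

test_that("the synthetic family alignment keeps its planted conservation", {
  aln <- read_alignment(system.file("extdata",
                                    "aqp_alignment_synthetic.fasta",
                                    package = "aqpstruct"))
  expect_equal(length(aln$names), 13)
  pm <- read_pore_mapping(system.file("extdata",
                                      "pore_mapping_aqp2_synthetic.tsv",
                                      package = "aqpstruct"))
  mp <- map_alignment_columns(pm$resno, aln, "AQP2")
  expect_equal(nrow(mp), 51)
  canonical <- c("AQP0", "AQP1", "AQP2", "AQP4", "AQP5", "AQP6", "AQP8",
                 "AQP3", "AQP7", "AQP9", "AQP10")
  lg <- logo_frequencies(aln, mp, subset = canonical)
  expect_equal(lg$freq[position_of(pm, 64), "G"], 1)
  expect_equal(lg$freq[position_of(pm, 180), "G"], 1)
  expect_equal(lg$freq[position_of(pm, 187), "R"], 1)
})
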
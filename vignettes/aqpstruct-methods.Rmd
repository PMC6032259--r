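---
title: "Methods: structural defect assessment of aquaporin variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural defect assessment of aquaporin variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Aquaporins are C4-symmetric homotetramers; each monomer encloses a narrow
water channel lined by six transmembrane helices and two half-helices whose
NPA motifs form the mid-channel constriction, with the ar/R selectivity
filter on the extracellular side. A disease-associated missense variant
(SAP) can compromise the protein in qualitatively different ways, and the
clinical phenotype tracks the mechanism: variants that merely narrow the
pore or weaken the tetramer interface retain partial function, while
variants that destabilise the monomer fold are degraded or retained in the
ER, and C-tail variants can leave the channel intact but destroy the
phosphorylation-dependent trafficking signal. `aqpstruct` turns that
reasoning into a reproducible pipeline: model the mutant side chain,
measure what changed (pore geometry, packing, strain, charge), and apply an
explicit rule set to name the defect.

This vignette records the model assumptions, the tunable parameters and
why their defaults are what they are, the numerical choices, and what the
synthetic validation does and does not establish.

## Side-chain modelling

`mutate_residue()` strips the side chain at the site and rebuilds the
target residue from a packaged internal-coordinate template table (one
canonical heavy-atom geometry per amino acid: bond lengths, bond angles,
and fixed dihedrals for rings and planar groups; the CB is placed with the
L-configuration torsion of +122.5 degrees against the backbone). Rotatable
chi angles are selected in three deterministic stages:

1. a staggered base grid of -60/60/180 degrees per chi (all combinations);
2. +-30 degree perturbations of the best base rotamer, one chi at a time;
3. coordinate descent with a shrinking step (20 degrees decaying by 0.7
   per sweep, 200 steps by default), accepting only strict improvements.

The objective is purely repulsive: `sum over pairs max(0, r_i + r_j -
d_ij)^2` (square angstrom) between the proposed side chain and all heavy
atoms of the environment. There is no force-field energy, no backbone
relaxation and no multi-site support; the claim the mutator supports is
geometric (which neighbours a substitution crowds or abandons), not
thermodynamic. When the target type equals the current type, the current
chi angles are injected as the first candidate, so a mutate-to-self is an
identity unless a strictly better placement exists.

**Through-bond exclusions.** Ideal covalent geometry places atom pairs up
to four bonds apart (for instance CB against the preceding carbonyl in an
alpha helix) below the sum of their Bondi radii. All steric scoring
therefore ignores pairs coupled through four or fewer covalent bonds,
computed on the residue's bonded graph (backbone, side-chain template
bonds, the proline ring closure, the flanking peptide bonds). This mirrors
how force fields scale local interactions and is what makes "zero clashes
in an unstrained helix" a meaningful statement.

Proline targets are rebuilt from the ring template and checked for ring
closure: a CD-N gap above 0.1 angstrom warns.

## Pore profiling

`compute_profile()` reimplements the maximal-sphere idea: at each slice
plane along the channel axis (step 0.5 angstrom by default) the largest
sphere not penetrating any van der Waals sphere is sought, its centre
constrained to the slice plane. The search is a seeded stochastic
hill-climb (proposal step 0.5 angstrom decaying by 0.9 every 50 of the 400
proposals), then a deterministic coarse-grid second start (+-2 angstrom at
0.5 spacing, guarding against a shallow local basin), and finally a
compass polish down to a 5e-5 angstrom step. Each slice is seeded from the
previous slice's centre, so the search tracks a curving lumen. Radii are
capped at `r_max` (10 angstrom); a slice reaching the cap is declared
open, which is how the channel mouths terminate the pore.

Design choices worth making explicit:

- **Centre constrained to the plane.** The full 3-D sphere wander of the
  original algorithm is not implemented; for near-axial channels the
  in-plane search loses little and is simpler to reason about. The
  synthetic-wall oracles quantify the residual error (at most 0.15
  angstrom on cylinder and cone walls at unit atom density).
- **Pore centre z0.** Profiles are reported as distance from the pore
  centre. When an NPA annotation is present, z0 is the radius minimum
  within the NPA region (+-2 angstrom); otherwise the global minimum over
  closed slices. The NPA constriction is the physical mid-channel
  reference; the global minimum is the best annotation-free proxy.
- **Monomer by default.** Profiles are computed on whatever structure is
  supplied; the pipeline profiles the monomer (the channel is entirely
  intra-monomeric), and a tetramer can be supplied deliberately.
- **Axis.** `estimate_axis()` uses the first principal inertial axis of
  the transmembrane CA atoms; a near-spherical cloud (leading eigenvalue
  less than 1.5 times the second) is refused rather than guessed. The +
  direction cannot be inferred from geometry alone; a `flip` flag is the
  user's statement of which side is extracellular.

`compare_profiles()` reports narrowing regions: runs of at least
`min_run = 3` consecutive slices in which the wild-type minus mutant
radius is at least `threshold = 0.3` angstrom, labelled cytoplasmic or
extracellular by their position relative to z0. The 0.3 angstrom / 3
slices default is the same sustained-narrowing criterion the classifier
uses, chosen as roughly twice the profiler's oracle error bound so that
discretisation noise cannot fire the rule.

## Pore-lining residues and logos

A residue lines the pore when any heavy atom comes within `margin` of a
profile sphere surface, i.e. `| |x - c| - (radius + vdw) | <= margin`;
the default margin of 1.4 angstrom is a water-probe contact criterion.
Residues are ordered by the axial coordinate of their closest-approach
atom, cytoplasmic first, with ties broken toward the lower residue number
for determinism. `map_alignment_columns()` pairs the ordered residues with
alignment columns through the ungapped reference sequence;
`logo_frequencies()` computes per-column amino-acid frequencies (gaps
excluded from the denominator; an all-gap column is flagged undefined) and
information content `log2(20) - H` bits.

The canonical 51-position pore mapping for AQP2 is shipped as a data
fixture. Only its anchor rows are documented facts (positions 10, 21, 23,
26, 30, 36 and 41); the remaining rows are synthetic placeholders, and the
file is named `*_synthetic.tsv` to say so. The same applies to the
packaged 13-sequence family alignment, which is a generated stand-in with
conservation planted at the anchor columns: it exercises the machinery,
and conclusions about real AQP conservation require supplying the real
alignment.

## Contacts, clashes and salt bridges

Residue pairs are contacts when any heavy-atom pair is within 8 angstrom
(the conventional contact-map default of the interface-analysis
literature); the packing-relevant sub-types are hydrophobic (apolar
carbon/sulfur pairs within 4.5 angstrom; backbone C and CA and
side-chain carbons bonded to O/N are excluded from "apolar") and salt
bridge (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 against Asp OD1/OD2, Glu
OE1/OE2 within 4.0 angstrom). Wild-type vs mutant differencing
deliberately compares only these sub-types plus clashes: the loose 8
angstrom contact barely changes when a side chain shortens, and the
figures this analysis supports depict packing interactions.
`detect_clashes()` reports pairs with vdW overlap of at least 0.1
angstrom (aggregated per residue pair with the maximum overlap), with the
same four-bond exclusion as the mutator.

## Electrostatics

The linearized Poisson-Boltzmann equation is solved by finite differences
with red-black successive over-relaxation on a node-centred grid, link
dielectrics averaged across faces, charges spread by trilinear weights,
and a screened-Coulomb Dirichlet boundary. Two-pass focusing solves a
coarse grid (1.5 angstrom spacing over an extended box) whose solution
provides the fine-grid boundary (1.0 angstrom). Defaults: solute
dielectric 1.0, solvent 80.0, zero ionic strength, 298.15 K, convergence
at a 1e-4 kT/e maximum update. The dielectric boundary is the union of
van der Waals spheres (no reentrant surface) and charges are formal: +1
on Arg CZ and Lys NZ, -1 at the Asp/Glu carboxylate-oxygen midpoints,
histidine neutral. These simplifications change magnitudes, not the
sign-and-locality statements the pipeline makes (a mutation introducing a
negative charge makes the nearby surface potential more negative); the
solver is validated against the analytic Coulomb potential (within 5% at
5-10 angstrom), superposition, linearity and mirror antisymmetry. A
uniform-dielectric mode (`structure = NULL`) exists exactly for those
oracle checks. A "reference environment" dielectric has no role in a
single-state linear solve and is intentionally not a parameter.

## Classification

`classify()` is a pure function of an evidence record and thresholds.
Rules fire in fixed precedence:

1. **signal loss** - C-tail site and (within +-4 residues of a
   phosphosite, or a C-tail salt bridge involving the site is lost);
2. **monomer folding** - helix-interior proline (excluding the two
   N-terminal helix positions, where proline is tolerated), or
   intra-monomer clash score >= 0.25 square angstrom, or >= 2
   intra-monomer packing contacts lost;
3. **tetramer assembly** - >= 2 inter-monomer packing contacts lost, or
   inter-monomer clash score >= 0.25;
4. **pore features** - pore-lining site with sustained narrowing >= 0.3
   angstrom over >= 3 slices;
5. otherwise **unclassified**.

The precedence encodes the biology: a C-tail site has no transmembrane
context, so signal loss is tested first; and a pore-lining residue whose
substitution strains the monomer interior is a folding defect, not mere
narrowing - lowering the pore threshold can therefore never flip a folding
or signal-loss verdict. The numeric thresholds are gap-filling defaults
(0.25 square angstrom is about one 0.5 angstrom overlap; the +-4
phosphosite window covers a site two residues upstream of a
phosphoserine as well as one directly adjacent) and are exposed in
`defect_thresholds()`. "Impaired metal binding" is a curated label that
requires a metal-site annotation; it is never auto-assigned, and records
carrying it are reported as the evidence dictates.

## The synthetic generators, and what passing means

`make_channel_wall()` tiles carbon-typed pseudo-atoms on a surface of
prescribed radius R(z); the expected profile R(z) - vdw is the analytic
oracle. `make_ideal_helix()` builds phi = -57 / psi = -47 helices from
ideal backbone geometry; `make_bundle_channel()` rings them around an
axis, optionally spinning one helix so a planted residue faces the pore.
`make_toy_alignment()` plants exactly conserved columns. Generators are
deterministic under a fixed seed and emit their ground truth.

These fixtures emulate the *geometry* the pipeline measures - wall
profiles, C4 symmetry, planted clashes and contact patches, controlled
conservation - and none of the physics they do not: no membrane, no
solvent, no side-chain flexibility beyond the rotamer search, no
crystallographic noise, B-factors or missing atoms beyond what the PDB
reader tolerates. A green suite therefore establishes that each stage
computes its defined quantity correctly and that the rule set recovers
planted defect classes end-to-end; it does not by itself establish
category assignments for real proteins, which additionally depend on real
coordinates and a real alignment supplied by the user.

Problem sizes used by the tests and the acceptance script (chosen so a
full run stays interactive): channel walls of a few hundred pseudo-atoms
at unit density, 6-helix bundles of about 600 heavy atoms, C4 tetramers
of a 26-residue helix, PB grids of about 25^3 fine nodes, and an
exhaustive 0.01 angstrom slice-oracle over an 8 x 8 angstrom window.

## Degenerate inputs and tie-breaking

- Residues without CA are kept with a warning; unknown elements fall back
  to a 1.7 angstrom radius with a warning (the assignment is total).
- Alternate locations: the highest-occupancy conformer is kept.
- Hydrogens are discarded everywhere; all criteria are heavy-atom.
- An all-open profile ("no channel found"), a degenerate inertia tensor,
  a reference residue absent from the alignment, overlapping topology
  intervals, and disjoint profile z-ranges are errors, not guesses.
- Equal axial coordinates order by residue number; equal clash scores
  keep the first candidate in the deterministic grid order.

## Known limitations

- The mutator is geometric; it will not find placements stabilised by
  hydrogen bonding or electrostatics, and asserts nothing about mutant
  coordinates beyond clash/contact conclusions.
- The profiler's in-plane constraint slightly overestimates radii in
  strongly tilted channel segments.
- Formal charges and a vdW dielectric boundary make PB magnitudes
  approximate; only sign/locality comparisons are supported.
- The packaged pore mapping and family alignment are synthetic stand-ins
  beyond their documented anchor facts.
- Real-structure category assignments should be read together with the
  curated labels in the packaged catalogue; the classifier's thresholds
  reproduce the planted synthetic cases and are exposed for calibration
  against real data.
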
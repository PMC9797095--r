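---
title: "Methods: sequence-sensitive elastic networks for RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-sensitive elastic networks for RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaenm)
```

# The model

Coarse-grained normal mode analysis represents a macromolecule as beads
joined by harmonic springs and reads its intrinsic motions off the
eigendecomposition of the potential's Hessian at the input structure.  The
central assumption is that the input conformation is an equilibrium
structure and that functionally relevant motions are dominated by the
low-frequency end of the harmonic spectrum.  All potentials here are
pseudo-physical: eigenvalues and frequencies carry model units, not
physical ones, and only their relative structure (orderings, ratios,
subspaces) is meaningful.

## Coarse-graining

Each nucleotide contributes up to three beads, positioned on its P, C1'
and C2 atoms.  Member atoms partition across the beads: the phosphate
group with its 5' ester oxygen (P, OP1, OP2, OP3, O5') belongs to the
phosphate bead, the ribose with O2' and O3' to the sugar bead, and all
remaining atoms to the base bead.  A bead exists only if its center atom
does, so a 5'-dephosphorylated terminal residue yields two beads; a
residue missing C1' or C2 is an error, since the model cannot place its
sugar or base.  Bead order is (chain, residue, then P, S, B), and the
eigenvector components `3k-2..3k` always belong to bead `k` — every
downstream metric relies on this frozen layout.

The bonded topology joins P–S and S–B within a residue and S–P between
consecutive residues of one chain.  A chain break severs the inter-residue
bond without error; two residues count as consecutive when they share a
chain identifier, their numbering is adjacent, and — whenever both atoms
are present — the O3'–P distance is below 2.5 Å.  The distance guard
prevents spurious springs across unmodelled gaps.  Angles are all simple
three-bead paths along bonds and dihedrals all simple four-bead paths,
deduplicated under reversal; a two-nucleotide strand, for instance, has 5
bonds, 5 angles and 3 dihedrals.

`coarse_grain(scheme = "p")` provides a deliberately impoverished
one-bead-per-nucleotide alternative (all atoms mapped to the P bead) used
to demonstrate that backbone-only networks cannot feel base identity.

## The potentials

Three potentials share this bead layout.  The sequence-sensitive model
combines bond-stretch, angle-bend and dihedral terms over the bonded
topology with a long-range 12-10 term over all bead pairs farther than
three steps apart on the bond graph (including pairs in different
connected components, hence different chains).  The graph-distance rule is
our generalization of the linear-chain "more than three residues apart"
convention to a branched three-bead topology; bonded, angular and dihedral
pairs are exactly the pairs it excludes.  Term weights default to
α₁ = 10³, α₂ = 10⁴ (per radian²), α₃ = 10⁴ and α₄ = 10⁻²; they encode
relative term importance, not measurable stiffnesses, and the same set is
used for every structure.

The long-range spring of a bead pair is `β_ij + α₄`, where `β_ij` sums
type-weighted atomic contact surfaces over the two beads' member atoms.
Favorable class pairs (donor with acceptor, aromatic with aromatic or with
a donor's π interaction, hydrophobic with hydrophobic, the neutral class
with everything) weigh 3, unfavorable ones (donor–donor,
acceptor–acceptor, polar–hydrophobic) weigh 1.  The eight-class atom
typing of the four ribonucleotides and the 8×8 favorability matrix ship as
editable CSVs under `inst/extdata/`; the assignments follow the standard
donor/acceptor/aromatic semantics of each atom (e.g. guanine N1 and N2 are
donors, O6 an acceptor, ring carbons aromatic, sugar carbons hydrophobic,
O2' the lone hydrophilic donor-plus-acceptor).  This chemistry is what
makes a G·C pair stiffer than an A·U pair and a purine–purine stack
stiffer than a pyrimidine–pyrimidine one at matched geometry — orderings
the test suite asserts.

The two baselines depend on bead geometry alone: the cutoff network joins
all pairs within `rc` (default 10 Å, the value that works best for
three-bead RNA networks; the classical protein default is 18 Å) with
uniform springs γ = 1, and the power-dependent network joins every pair
with spring constant `γ / r₀ˣ`, default x = 7.

## Contact surfaces

`S_kl` is computed as the area of the face shared by the two atoms'
additively-weighted (power/Laguerre) Voronoi cells, each constrained to
the atom's extended sphere — van der Waals radius (C 1.70, N 1.55, O 1.52,
P 1.80 Å) plus a 1.4 Å water radius.  The extension lets two atoms
separated by a solvent-sized gap remain in (solvent-mediated) contact,
while any third atom whose extended sphere reaches the shared face
occludes it.  Hydrogens are ignored; deposited RNA structures rarely carry
them and the typing covers heavy atoms.

The face of a pair lives on the radical plane of the two extended spheres:
a disc, clipped by one half-plane per proximal third atom (the radical
plane of that atom against the nearer pair member, which is linear on the
face plane).  The implementation clips a bounding square by all
half-planes (Sutherland–Hodgman) and integrates the convex
polygon-with-arcs area exactly via circular-segment decomposition, in
C++, with a uniform cell list at the occluder-reach cutoff (3× the largest
extended radius) so the cost is O(n·k).  Tests verify the closed-form disc
area of an isolated pair, occlusion monotonicity, rigid-motion invariance
of the total area, and agreement within 2% with an independent in-plane
grid oracle that classifies points by raw power distances.

## The Hessian and its modes

Every term of every potential is a function of one internal coordinate
(pair distance, angle, dihedral) whose first derivative vanishes at the
reference geometry — harmonic terms sit at their minimum and the 12-10
term at its well.  The Hessian therefore assembles exactly as
`Σ g''(q₀) ∇q ∇qᵀ` with Wilson-row gradients; no second-derivative tensors
of the internal coordinates survive.  Scalar curvatures are `2α₁`, `2α₂`,
`5.5 α₃` (from the 1:3 cosine pair) and `120 (β_ij + α₄)/r₀²`.  Each 3×3
row block sums to zero by construction (translation invariance) and
rotational invariance follows from the vanishing gradients, so
non-degenerate structures have exactly six numerically-zero modes.  The
whole assembly is validated against central finite differences of the
energy (step 10⁻⁵ Å, agreement to ~10⁻⁶ relative on a 3-nt toy).

Diagonalization uses the dense symmetric eigensolver; eigenvalues are
sorted ascending and modes below `10⁻⁸ × max λ` are classified trivial,
then verified by requiring squared projection ≥ 0.99 onto the analytic
rigid-body basis (three unit translations plus three orthonormalized
rotations about the centroid).  More than six near-zero modes — a
disconnected cutoff network, for instance — triggers a warning, not an
error.  The dense solver is comfortable to roughly 2000 beads
(≈ 670 nucleotides); larger systems are out of the intended scale of this
package.

# Fluctuation descriptors

`msf()` is the inverse-eigenvalue-weighted sum of squared per-bead mode
components over nontrivial modes — equivalently the trace of the bead's
3×3 block of the Hessian pseudoinverse, which the tests assert.
`entropic_signature()` replaces the 1/λ weight with the vibrational
entropy `S_vib(βν) = βν/(e^{βν}−1) − ln(1−e^{−βν})` of each mode, a
monotone-decreasing function of frequency.  The thermodynamic scaling
factor β is a unitless multiplier (the models being pseudo-physical, a
physical temperature has no meaning here): large β concentrates the
signature on the slowest modes, small β flattens it toward the MSF-like
regime.  Sums over all nontrivial modes are the default; anything
classified trivial — including degenerate extras — is excluded, since a
zero-frequency mode has no defined vibrational entropy.  Per-model default
β centers are e^0.25 (contact-modulated), e^1 (cutoff) and e^9.5
(power-dependent); `beta_grid()` produces the standard 41-point sweep in
natural-log increments of 0.25 around any center.  B-factor agreement is a
plain Pearson correlation at every bead (three per nucleotide) against the
center atom's experimental B-factor — per-bead, not per-nucleotide
averaged.

# Conformational-space comparison

Conformation pairs are superposed by reflection-guarded least squares
(Kabsch); the displacement vector is target-minus-start after
superposition, and pairs below 2 Å bead-center RMSD are rejected as
resampling the same conformation.  Overlap is the absolute cosine between
a mode and the displacement; cumulative overlap the root-sum-square over
the first n nontrivial modes.  Mode counts quoted as percentages use
`ceiling(fraction × (3N − 6))`, so at least one mode is always used.

For ensembles, `nrt_pca()` superposes all conformations onto the first,
computes PCA by SVD, and removes rotational-translational content by
Gram-Schmidt against the reference model's six rigid-body vectors (rigid
basis first).  With more than two conformations, raw PCs generically mix
internal and rigid variance — superposition minimizes per-conformation
RMSD, not ensemble-level rigid content — so each PC's explained variance
is corrected by the rigid fraction it lost and renormalized, and PCs are
re-ordered by corrected variance.  PCs are retained to 99% cumulative
corrected variance.  Two degenerate inputs are distinguished: identical
conformations are an error (nothing to analyze), while conformations
differing only by rigid transforms return an explicit degenerate flag with
zero components rather than dividing by zero.  RMSIP and NCO then compare
a mode subspace with the retained PCs, NCO weighting each PC by its
corrected variance.  Ensemble fixtures from `make_ensemble()` plant known
internal motions with optional random rigid noise; the first conformation
stays in the reference frame so that recovered components remain
comparable to the planted vectors.

# Sequence clustering

Benchmark metrics are averaged within sequence clusters before the global
mean, so heavily re-deposited molecules do not dominate.  Similarity is
the Needleman–Wunsch global alignment score (match +1, mismatch −1, linear
gap −1) divided by the shorter sequence's length; the clustering distance
is one minus that similarity.  (The normalized score itself is sometimes
labelled a distance; the threshold semantics — 0.1 keeping sequences ≥ 90%
similar together — only cohere for 1 − similarity, which is what we
implement, exposing both quantities.)  Complete linkage is agglomerated
directly with deterministic lowest-index tie-breaking and a stopping rule
(merge while the smallest complete-linkage distance is within the
threshold), equivalent to cutting the dendrogram at the threshold; the
maximum intra-cluster distance is re-verified on every result.

# The variant-effect regression

Per-variant entropic signatures (one column per bead, optionally plus a
standardized folding-energy column) are standardized with training-set
means and standard deviations that are frozen into the fit object —
prediction applies them unchanged, so test rows cannot influence the
scaling.  Zero-variance training columns are excluded and carry
coefficient exactly zero; this is the mechanism by which a ±1 sequence
encoding collapses to a constant predictor on a position-disjoint split,
where every test-varying column is training-constant.  The lasso objective
is `(1/2n)‖y − Xw − b‖² + λ‖w‖₁` with the intercept unpenalized (solver
conventions differ, so the scaling is fixed and documented; the λ grid
2⁻¹⁵..1 in log₂ steps is meaningful under it).  Predictive R² is the
standard out-of-sample form `1 − SS_res/SS_tot` with the *test-set* mean in
the denominator, hence negative for models worse than that mean.

Two benchmark splits are provided.  The position-disjoint ("hard") split
reserves variants touching only the middle base pair of their mutation box
for testing and variants touching only the bottom/top pairs for training,
excluding stragglers; disjointness of mutated positions is asserted on
every split.  The low-redundancy ("inverted") split trains on all variants
with one or two mutations and tests on the rest.  A noise-combination
simulation calibrates significance of a combined model: the dynamics
feature is replaced by draws from a normal with the training mean and half
the training standard deviation, combined with the energy column in the
same two-feature regression, and the empirical exceedance fraction is the
p-value (reported as "< 1/n" when no replicate reaches the observed R²).

# Synthetic structures and datasets

The generators exist so every stage is testable offline and deterministic.

`build_aform()` places rigid all-atom nucleotide templates by helical
symmetry (twist 32.7°, rise 2.81 Å); the complementary strand is the
base-pair dyad image, which makes Watson–Crick geometry exact by
construction.  The template itself was derived once: base atoms in
standard base-pair reference frames, a C3'-endo ribose and phosphate
attached by internal-coordinate chain extension, and the handful of free
torsions plus the helical placement optimized for backbone closure
(O3'–P = 1.62 Å between successive residues, glycosidic and phosphate
geometry within normal ranges, no non-bonded contact under 2.6 Å).  The
frozen coordinates live in `inst/extdata/aform_template.csv`; they are an
implementation choice validated purely through geometric invariants.
`build_hairpin()` folds a stem into one chain and places loop residues by
screw interpolation between the stem-end frames with an outward bulge —
complete residues, but no claim of thermodynamic loop realism; the loop
junction O3'–P distances exceed the bonding guard, so bonded terms sever
there while long-range terms still couple the loop to the stem.

`mutate_base()` replaces base atoms with an idealized base aligned on the
glycosidic frame (glycosidic nitrogen, direction to C1', base plane),
leaving backbone and sugar bit-for-bit untouched.  Because each base's
bead atom (C2) sits elsewhere relative to that frame, a mutation normally
moves the base bead slightly — exactly the geometric side channel that
lets geometry-only networks appear weakly sequence-sensitive.  The
`pin_bead` option additionally translates the new base so C2 lands exactly
on the old bead center, isolating chemical from geometric sequence
sensitivity in controlled experiments.

`make_maturation_dataset()` enumerates exhaustive box mutants of a
reference hairpin (each box three consecutive stem base pairs, six
positions; a 13-box scan with a dinucleotide bulge reproduces the
53 251-variant census), optionally subsamples, builds every variant's
structure, computes entropic signatures over a β grid, and sets the
readout to a planted linear combination of the β*-signature plus Gaussian
noise.  The synthetic folding-energy column is pure noise and the
MFE-match flags are all true; both are consumed as given, never computed —
2D folding thermodynamics is out of scope.  What the generator emulates is
the *regression problem* (many variants, few causal beads, correlated
features, noisy readout); what it does not emulate is real maturation
biochemistry, real folding ensembles, or measurement artifacts of pooled
assays — so passing recovery tests demonstrates that the pipeline is
correct and identifiable under its own assumptions, not that any
particular biological claim holds.

## Validation problem sizes

The end-to-end recovery experiment uses a 22-nt idealized hairpin (9-bp
stem, 4-nt loop, 66 beads), three mutation boxes, five planted
coefficients placed on beads of box residues, noise at 0.1× the signal's
standard deviation, and 2000 subsampled variants — a size at which the
whole experiment (structure building, contact surfaces, Hessians,
eigendecompositions, signatures at 41 β values, lasso grid) completes in a
few minutes on one CPU while leaving the planted support identifiable.
Planting on beads of never-mutated residues would make the support
unidentifiable for any solver, since those signature columns barely
respond to the mutations.  The recovery fit uses λ = 2⁻¹⁰, small enough to
keep weak causal features alive and large enough to zero most of the
correlated background; success means recovered support ⊇ planted support,
exact sign agreement, predictive R² within 0.05 of the noise ceiling
`1 − σ²_noise/σ²_y`, and a β-grid argmax within one grid step of the
planted β*.

# Numerical choices

* Trivial-mode threshold `10⁻⁸ × max λ`, plus the 0.99 rigid-body
  projection check; configurable through `enm_control()`.
* Finite-difference validation step 10⁻⁵ Å; agreement asserted relative to
  the Hessian's largest entry.
* Contact faces smaller than 10⁻⁹ Å² are dropped; coincident atom centers
  are a hard error.
* Superposition guards against reflections via the determinant and errors
  on fewer than three or collinear points.
* Gram-Schmidt discards PCs whose residual after rigid-body projection has
  norm below 10⁻⁸ (they were pure rigid motion).
* Alignment-free ties: complete-linkage merges break ties by lowest
  cluster index, making results permutation-invariant on generic
  (distinct-distance) inputs.
* All generators and simulations take explicit integer seeds; repeated
  calls are bitwise identical.

# Known limitations

* The eight-class atom typing and favorability matrix are reconstructed
  from the published classification's semantics, not transcribed from a
  primary table; both are shipped as data files precisely so users can
  substitute their own.
* No electrostatic term: for RNA, charge–charge effects are folded only
  implicitly into contact chemistry.
* Crystallographic B-factor artifacts (rigid-body/TLS motion, crystal
  packing, cryogenic biphasic behavior) are not modeled; per-structure
  B-factor correlations inherit that noise.
* Hairpin loop geometry is idealized for completeness, not realism, and
  its bonded topology is severed at the loop junctions.
* Dense eigensolver only; practical to ~2000 beads.
* Modified nucleotides are rejected rather than replaced; pre-process
  structures to standard residues before reading.
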
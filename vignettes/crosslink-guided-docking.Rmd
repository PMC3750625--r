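---
title: "Crosslink-guided rigid-body docking of homodimers: models and methods"
author: "xldock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink-guided rigid-body docking of homodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chemical crosslinking followed by mass spectrometry (XL-MS) reports
pairs of residues that were close in space when a bifunctional reagent
bridged them. For a homodimer whose monomer structure is known but
whose quaternary arrangement is not, those pairs carry two kinds of
information: *looplinks* (both ends on one chain) validate the monomer
fold, and *intermolecular* links constrain the relative placement of
the two chains. `xldock` implements the complete path from a protein
sequence and peak lists to a restraint-consistent rigid-body dimer
model:

1. in-silico digestion and enumeration of theoretical crosslinked
   products (dead-end, looplink, inter-peptide) with exact mass
   arithmetic;
2. mass matching against crosslinked and control peak lists
   (crosslinked-minus-control differential design);
3. classification of identified site pairs against the monomer
   structure by C&beta;–C&beta; distance;
4. exhaustive rigid-body pose generation by FFT shape-complementarity
   correlation with an electrostatic screen;
5. filtering of poses by crosslink distance restraints, soft-core
   rigid-body refinement, minimum-energy model selection; and
6. interface characterization (buried area, interface residues,
   parallel/antiparallel orientation, two-fold residual).

The motivating application is the N-terminal domain (NTD) of a
retroviral integrase: a zinc-binding domain of roughly a hundred
residues that dimerizes in solution, studied with the amine-reactive
crosslinker BS³ (11.4 Å spacer; bridge +138.068 Da, hydrolyzed
dead-end +156.0786 Da) and a productive C&beta;–C&beta; limit of
21.3 Å.

## Peptide chemistry

Digestion follows standard specificity rules: trypsin cleaves
C-terminal to K/R except before proline; chymotrypsin C-terminal to
F/Y/W/L/M except before proline. All fragments with up to a chosen
number of missed cleavages are enumerated. Masses are sums of residue
masses plus one water; both monoisotopic and average values are
carried.

A crosslinked (acylated) lysine cannot be cleaved by trypsin, so a
linked lysine must sit at a missed-cleavage position. Enumeration
therefore excludes a reactive lysine at a tryptic peptide's C-terminal
cleavage position from the candidate link sites. Inter-peptide
enumeration pairs every peptide with every other *and with a second
copy of itself*: in a homodimer the same residue on both chains can be
bridged (a self-link such as K24–K24), and such products are direct
evidence of two chains. At the MS1 level two site assignments within
the same peptide pair are indistinguishable (identical mass); the
pipeline therefore groups matched interlinks by product mass and turns
each mass into one *ambiguous* restraint whose alternatives are all
compatible site pairs, the same convention as reporting "K31–K20/24".

Defaults: monoisotopic masses; singly charged [M+H]⁺ for MALDI-style
peak lists (charges 1–4 available for LC-MS); matching tolerance given
in ppm or Da by the caller (0.5 Da is a sensible MALDI default, 20 ppm
for LC-MS). The protein N-terminal α-amine can be enabled as a
reactive site but is off by default. Positions are reported in the
construct's own numbering; a single configurable integer offset maps
them onto structure numbering, because printed construct numbering
often counts the initiator methionine as residue 0.

## Structure side

Structures are read with `bio3d`; selenomethionine (MSE) records are
retained on reading and can be converted to methionine
(`edit_mse_to_met()`), matching the common practice of editing
selenomethionine derivatives before modelling. Crosslink sites are
measured at C&beta; (the field convention for lysine crosslinks), with
a warning-emitting fallback to C&alpha; for glycine or truncated side
chains. A site pair is *monomer-compatible* when its within-chain
distance fits the linker limit; a self-pair can only be
intermolecular; a pair that fits the monomer but was observed in the
dimer band is flagged *ambiguous*.

Superposition uses the standard SVD (Kabsch) solution restricted to
proper rotations; collinear point sets are rejected as degenerate.
Pose similarity is ligand-RMSD: superpose on the static chain, measure
RMSD over the mobile chain, and for homodimers take the smaller value
over the two chain labelings (swap equivalence).

## Docking model

Pose generation is a grid correlation search. Each partner is
digitized on a cubic grid (default spacing 1.0 Å, configurable). The
static partner uses a *soft two-zone* model: every voxel within
`radius − soft_margin` (default margin 1.0 Å) of an atom is a clash
zone carrying a large negative weight (−15), and the shell from there
out to `radius + surface_thickness` (default 2.0 Å) is a contact skin
of weight +1. The mobile partner is uniformly 1 inside its volume. The
correlation of the two channels over all integer translations — the
score of every placement — is computed with forward/inverse FFTs and
is identical to the direct-space sum (verified against a brute-force
oracle in the tests). Placing the attractive skin *outside* the
molecular volume and shrinking the clash zone by a soft margin keeps
contact reward and overlap penalty separated even for coarse grids and
reduced (C&alpha;/pseudo-C&beta;) models, where the classic
surface-inside-the-volume convention degenerates: with thin atoms
almost every filled voxel is "surface", and interpenetration scores
like contact.

Rotations come from a deterministic Euler sweep (default 15°) with
duplicate pruning; per rotation the best few translations are kept
(default 8), and globally the top `keep` (default 10,000, the
conventional retention of correlation docking) are retained,
preferring electrostatically non-repulsive poses, ranked by shape
score with electrostatic score and pose id as tie-breaks. The sweep
contains no randomness: identical inputs give bit-identical pose sets.
Homodimer swap duplicates (the relabelling `(R, t) → (Rᵀ, −Rᵀt)`) are
removed by canonicalizing the transform. Should fewer than `keep`
candidates be electrostatically acceptable, the list is filled from
the remainder in rank order so the retention contract holds.

Electrostatics uses a residue-level charge model (+1 on Lys/Arg, −1 on
Asp/Glu, at a representative side-chain atom) and the screened Coulomb
form `332 * qi * qj / (4 r^2)` kcal/mol with the distance-dependent dielectric
ε(r) = 4r and a 2 Å floor — the classic cheap treatment of
solvent screening in rigid docking. It filters and breaks ties; it is
not added to the shape score.

## Restraints, refinement, selection

A pose survives filtering if and only if **every** restraint has at
least one alternative site pair within its maximum distance, measured
cross-chain on the posed complex and in both chain assignments
(crosslinking cannot tell the chains of a homodimer apart). Filtering
is a pure conjunction and therefore independent of restraint order.

Survivors are pre-ranked by a *softened* interaction energy
(soft-core parameter 2.5 Å instead of 1.0 Å): the shape rank alone can
favour interpenetrating placements, while the unsoftened energy
over-punishes snug placements whose apparent overlap is grid
quantization. The best candidates (default 20) are refined by local
rigid-body minimization of the six degrees of freedom under a
soft-core van der Waals term (pair minimum near the sum of the two
contact radii) plus the screened electrostatics. Minimization runs in
bounded trust-region rounds (0.35 rad / 3 Å per round) until the
energy stops improving; the best-seen configuration is always kept, so
refinement never raises the energy. Restraints are re-checked after
refinement; a violating refined pose falls back to its unrefined
placement. The final model is the minimum-energy refined pose, ties
broken by larger buried area, then pose id. An empty survivor set is a
distinguished outcome (`no-compatible-pose`), not an error. This
rigid-body treatment deliberately replaces side-chain repacking: the
selection signal among rigid poses lives at the rigid-body level, and
rotamer optimization is out of scope.

Interface analysis computes accessible surface areas with the
Shrake–Rupley sphere-point construction (default 960 points per atom,
probe 1.4 Å, standard van der Waals radii; reduced models carry their
own united-residue radii). ΔASA = ASA(A) + ASA(B) − ASA(AB); interface
residues are those burying more than a 0.1 Å² floor. Orientation is
classified from the angle between the chains' first-to-last
C&alpha; vectors over the shared residue span (parallel < 90°), and
the two-fold quality is reported as the rotation angle and RMSD of the
optimal B→A superposition. Solvation free-energy estimates are
deliberately not computed; buried area and residue counts are the
reported interface descriptors.

## The synthetic study system

Because the experimentally derived dimer model of the motivating study
is not deposited, every pipeline stage is validated on a ground-truthed
synthetic system generated in code.

**Monomer.** A reduced-representation hairpin of two ideal α-helices
(rise 1.5 Å, 100°/residue, axes 9 Å apart), 16 residues each, with one
C&alpha; and one pseudo-C&beta; per residue. United-residue contact
radii (2.3 Å for C&alpha;, 2.7 Å for C&beta;) account for the several
heavy atoms each pseudo-atom stands for. Lysines sit at positions 2, 7,
11 and 29; glutamates beside them keep the lysine-bearing face near
charge-neutral so that the crosslinkable lysines do not
electrostatically forbid the very contact they report on. Gaussian
coordinate noise (default σ = 0.05 Å, the scale of coordinate
uncertainty in well-refined structures) makes each seed's geometry
unique; the seed fully determines every output.

**Planted dimer.** The partner copy is placed in the reference packed
arrangement of this hairpin — an approximately two-fold turn about the
bundle axis nesting the partner into the groove, i.e. a compact
four-helix bundle. That fixed transform is built into the generator; it
was located once, for the noise-free reference geometry, by exhaustive
unrestrained rigid-body search, and it is the unique strongly
attracting energy optimum of the system (all top candidates of a dense
sweep refine into it). For each seed the copy is settled by a small
bounded minimization on that seed's noisy coordinates, so the planted
contact is a genuine optimum of the generated structure. A `flip`
variant turns the partner the opposite way before packing, yielding the
opposite orientation label. The generator records the exact transform,
the set of inter-chain lysine pairs within the linker cutoff (the true
crosslinkable set) and the true orientation label.

**Observations.** A DSG-class short NHS-ester linker (bridge
+98.03678 Da, dead-end +116.04734 Da, 7.7 Å spacer) with a 12 Å
C&beta; limit is used for the toys: on a domain only a few helix
diameters across, a 12 Å restraint localizes the partner to about one
helix diameter, carrying the same relative information that an
11.4 Å-spacer reagent with a 21.3 Å limit carries on a full-size
domain. The control peak list holds the unmodified digest [M+H]⁺
masses; the crosslinked list adds the products realizable on the
planted dimer. Mass error is bounded uniform (default ±20 ppm), and
uniform decoy peaks (default 20) are sprinkled over the observed m/z
range as the simplest null for tolerance testing. Real spectra differ
in ways the generator does not emulate — isotope envelopes, charge
states, intensity structure, retention time — so passing tests
demonstrate correct bookkeeping and search behaviour, not MS signal
processing.

**Recovery study.** Across 20 seeds, the pipeline is given the three
tightest true inter-chain restraints and run at routine reduced
settings (2.0 Å grid, 30° sweep, 10,000 poses, 24 translations per
rotation, 20 refined candidates; problem sizes chosen to keep a full
20-seed study at desk scale). Success is a selected model within 5 Å
ligand-RMSD of the planted transform — the conventional "acceptable"
pose-similarity scale for a small domain — in at least 90% of seeds,
with the orientation label reproduced in at least 90% of successes.
Because the planted transform is the energy-optimal packing, this
study validates the search, filtering, refinement and selection
machinery; it does not (and cannot) validate the energy model against
real physics.

**NTD stand-in.** A 95-residue four-helix reduced model
(`synthetic_ntd_monomer()`) embeds the crosslink-bearing peptide
segments of the real construct at their construct positions (lysines
20, 24, 31, 33, 34, 68, 88, 95, 104; initiator Met counted as residue
0) with helices 1 and 4 on a common face. It is entirely synthetic —
ideal-helix geometry, not deposited coordinates — and stands in for
the crystal monomer in tests and examples when the PDB file is not
supplied. Docking it against itself with the experimentally observed
restraints {K20–K31, K24–K24, K68–K88} at 21.3 Å yields a
restraint-satisfying packed dimer; distances printed for the real
study's model apply to the real coordinates only and are not
reproduced by the stand-in.

## Numerical choices and degenerate inputs

* Grid sizes are rounded up to FFT-friendly lengths (factors 2, 3, 5);
  the box holds the static extent plus the mobile diameter plus
  padding, so cyclic wrap-around cannot create spurious overlaps.
* Each atom contributes at least its nearest voxel to the clash zone,
  so even sub-voxel atoms are never free to interpenetrate.
* Equal shape scores are ordered by electrostatic score, then pose id;
  equal refined energies by buried area, then pose id — selection is
  fully deterministic.
* Glycine (no C&beta;) and truncated side chains fall back to
  C&alpha; with a warning.
* Empty models, unknown residues, unknown proteases, empty charge
  sets, non-positive tolerances and missing chains raise immediate
  errors; an unsatisfiable restraint set is reported as the
  distinguished `no-compatible-pose` outcome.
* The multi-round trust-region refinement caps each round's step, and
  non-convergence within the iteration budget returns the best-seen
  pose with `converged = FALSE`.

## Known limitations

* Rigid-body only: no side-chain repacking, no backbone flexibility.
  Restraint distances on refined models inherit the monomer's side-chain
  conformations.
* The interaction energy is a declared stand-in for a refinement-grade
  force field; it ranks packed rigid poses and nothing more.
* The electrostatic model is residue-level with a distance-dependent
  dielectric; it cannot represent salt-bridge geometry or desolvation.
* MS1 mass matching cannot localize the linked residue within a
  peptide; ambiguity is carried into the restraints rather than
  resolved (no MS/MS scoring, no FDR model).
* The synthetic generator emulates geometry and mass bookkeeping, not
  spectral realism.
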
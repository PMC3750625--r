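# xldock

Crosslink-guided rigid-body docking of protein homodimers.

## What it does, and for whom

Chemical crosslinking with mass spectrometry (XL-MS) identifies pairs
of lysines that were within a reagent's reach when the crosslinker
bridged them. For a protein whose monomer structure is known but whose
dimer arrangement in solution is not — the motivating case is the
N-terminal domain (NTD) of a retroviral integrase, crosslinked with
BS³ — those pairs split into *looplinks* (both ends on one chain),
which validate the monomer fold, and *intermolecular* links, which
constrain how the two chains sit against each other. `xldock` is for
structural biologists and method developers who want that entire
workflow as reproducible, tested R code:

* in-silico digestion (trypsin/chymotrypsin) and enumeration of
  theoretical crosslinked products — dead-ends (+156.0786 Da for BS³),
  looplinks (+138.068 Da) and inter-peptide links — with exact mass
  arithmetic;
* peak-list matching with a crosslinked-minus-control differential
  design, plus b/y fragment-ion generation for crosslinked peptides;
* Cβ–Cβ distance validation of identified pairs against the monomer
  (the BS³ convention bounds a productive crosslink at 21.3 Å);
* rigid-body pose generation by FFT shape-complementarity correlation
  (the classic grid-correlation algorithm) with a screened
  electrostatic filter, retaining 10,000 poses by default;
* crosslink distance-restraint filtering (ambiguous site assignments
  supported), soft-core rigid-body refinement, minimum-energy model
  selection;
* interface analysis: Shrake–Rupley buried surface area, interface
  residues, parallel/antiparallel orientation, C2 residual;
* a fully seeded synthetic-data generator (toy monomers, planted
  dimers, peak lists with noise and decoys) so every stage is testable
  with known ground truth.

The score of a placement `t` of the mobile partner is the grid
correlation

    S(t) = sum_x  G_static(x) * G_mobile(x - t)

where the static grid holds a clash zone (weight −15 inside
`radius − 1 Å`) and a contact skin (weight +1 out to `radius + 2 Å`),
and the mobile grid is 1 inside the molecular volume; all translations
are scored at once by FFT. A pose satisfies a restraint when **any**
alternative site pair is within the bound in **either** chain
assignment; a model is accepted only if every restraint is satisfied,
and the final model minimizes a soft-core van der Waals plus screened
Coulomb (`332 q_i q_j / (4 r^2)`, ε(r) = 4r) interaction energy.

## A worked example

Generate a toy monomer, plant its ground-truth dimer, derive the three
tightest true crosslink restraints, and fit the dimer model:

```r
library(xldock)

spec <- toy_spec(seed = 1)
mono <- make_toy_monomer(spec)
tru  <- make_true_dimer(mono, seed = 1)
tp   <- tru$true_pairs[order(tru$true_pairs$distance), ][1:3, ]
rs   <- lapply(seq_len(3), function(i)
  restraint(tp$site1[i], tp$site2[i],
            max_distance = toy_crosslinker()$max_site_distance,
            origin = paste0(tp$site1[i], "-", tp$site2[i])))

fit <- fit_dimer(mono$model, mono$model, rs,
                 spacing = 2, angle_step = 30, keep = 10000,
                 keep_per_rotation = 24, refine_top = 20)
fit
```

```
Rigid-body dimer fit (crosslink-restrained docking)
  poses: 10000 swept, 1025 restraint-compatible
  selected pose 130, interaction energy -25.394
  restraint distances (A): 4.34, 9.54, 9.54
  interface: dASA 1078 A^2, antiparallel (163 deg)
```

Reading: of 10,000 swept poses, 1,025 satisfy all three 12 Å
restraints; the minimum-energy refined survivor has every restrained
Cβ–Cβ distance inside the bound and buries ~1100 Å² — a packed
four-helix bundle. Comparing with the planted truth:

```r
sw <- dimer_complex(tru$complex$B, tru$complex$A)   # swap labelling
min(ligand_rmsd(fitted(fit), tru$complex), ligand_rmsd(fitted(fit), sw))
#> [1] 0.07016756
```

The selected model reproduces the planted transform to 0.07 Å
ligand-RMSD. `summary()`, `coef()` (Euler angles and translation),
`fitted()` (the dimer complex), `residuals()` (restraint slack) and
`plot()` give the usual modelling-object views, and `run_pipeline()`
drives the same stages from FASTA + peak-list files (see
`?run_pipeline` and the vignette).

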
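---
title: "Characterizing paired immunoglobulin-domain interfaces"
author: "AbInterface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing paired immunoglobulin-domain interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbInterface)
```

## The problem

Antibody engineering — bispecific formats in particular — hinges on how
pairs of immunoglobulin domains associate: the CH3-CH3 homodimer at the
base of the Fc, the CH1-CL pair of the Fab, and the VH-VL pair of the
Fv. These interfaces are structurally very similar β-sandwich packings,
yet they are stabilized by different interaction chemistry (CH3-CH3 by
networks of salt bridges around a hydrophobic core, CH1-CL predominantly
by hydrophobic contacts), and engineering strategies such as
knobs-into-holes or charge-pair inversion act directly on that
chemistry. `AbInterface` provides the quantitative toolbox for
comparing such interfaces across structures and frame ensembles:

1. **contacts** — time-resolved interdomain contacts classified as
   hydrogen bond, salt bridge, hydrophobic or van der Waals;
2. **coarse-graining** — aggregation of contacts onto the β-strand/loop
   elements of the Ig fold, class averages with SEM, and normalized
   difference maps between interface classes;
3. **orientation** — a six-measure interdomain orientation coordinate
   system (torsion AB, tilts AC1/AC2/BC1/BC2, center distance dC) with
   Gaussian kernel density estimates, plus superposition RMSD and RMSF;
4. **energetics** — per-frame interdomain Coulomb energies;
5. **synthetic data** — a generator of toy two-domain complexes with
   known orientations and planted contact lifetimes, used as ground
   truth throughout the test suite.

## Structures, trajectories, selections

`readPDB()` parses a PDB file (via bio3d) into a `Structure`;
`readTrajectory()` reads a multi-model PDB as a `Trajectory`, the
package's stand-in for an MD trajectory (topology from model 1,
identical atom counts enforced). Author residue numbering is preserved
end to end: residue identities like Y407, T366, E356 or K439 in
EU-numbered constant domains keep their author numbers, and no
renumbering ever happens. Alternate locations default to the
highest-occupancy conformer (ties resolved lexicographically);
HETATM/water records are stripped unless requested, since the analyses
concern protein–protein interfaces. Crystallographic waters are assumed
stripped before contact analysis.

The two domains of an interface are named **a** and **b** (for the
constant-domain comparison: the CL domain and one CH3 copy are "a",
CH1 and the other CH3 copy are "b"). A `DomainSelection` is a set of
chain/residue ranges, e.g. `domainSelection("a", "A:341-447")`.

## Contact detection

Contacts are evaluated per frame between the two selections with
GetContacts-style geometric criteria, exposed (never hard-coded) in
`contactCriteria()`:

| channel      | default predicate                                        |
|--------------|----------------------------------------------------------|
| hydrogen bond| donor–acceptor ≤ 3.5 Å and D–H···A ≥ 110° when hydrogens exist |
| salt bridge  | cation-N to anion-O ≤ 4.0 Å                              |
| hydrophobic  | apolar-carbon pair ≤ 4.5 Å                               |
| van der Waals| d ≤ r₁ + r₂ + 0.5 Å for heavy atoms                      |

Atom typing (`assignChemRoles()`) follows standard residue chemistry:
cationic nitrogens are Lys NZ, the Arg guanidinium and protonated His
ring nitrogens; anionic oxygens the Asp/Glu carboxylates and OXT;
apolar carbons are carbons with no bonded N/O. On the same atom pair
the channels never double-count; precedence is salt bridge > hydrogen
bond > hydrophobic > van der Waals. Hydrogen bonds carry a
backbone/side-chain subtype tag (`bb-bb`, `sc-bb`, ...). X-ray inputs
usually lack hydrogens, so the heavy-atom fallback (distance-only
hydrogen bonds) is on by default for single structures and engages
automatically whenever a structure carries no hydrogens; trajectories
with hydrogens use the full angle criterion. Aromatic stacking (e.g.
the central Y407–Y407 contact of CH3-CH3) is not a separate channel; it
is captured by the hydrophobic/vdW channels. No periodic-boundary
imaging is applied: inputs are assumed whole molecules, as multi-model
PDB carries no reliable box.

The **occurrence ratio** of a contact is the fraction of frames in
which the residue pair touches through at least one atom pair
(`contactRatio()`). Coarse-grained ratios (`coarseGrain()`) are frame
*unions* per element pair, not sums — the flareplot edge is an
existence statistic — so the element-pair ratio is at least the largest
constituent residue-pair ratio and at most their capped sum.

## Elements of the Ig fold

Coarse-graining units are the β-strands A–G and the loops named by
their flanking strands (AB ... FG), prefixed `a_`/`b_` per domain.
Two routes produce an `ElementMap`:

* `canonicalElements()` loads packaged residue-range annotations per
  domain kind (CH3, CH1, CL-κ, CL-λ, VH, VL). These maps are curated
  reconstructions of the standard EU/Kabat-numbered Ig topology,
  anchored on well-described interface residues (Y407 mid-strand E;
  E356/E357 in the AB loop facing K439 in strand G; K370 in B; D399 in
  the DE loop; K392 in D; the CH1/CL charge-pair sites S183/V133 in
  E/B). They are approximations — the variable-domain maps fold the
  extra C′/C″ hairpin into the CD segment so one label set serves both
  domain classes — and can be regenerated with `assignStrands()` when a
  reference structure is at hand.
* `assignStrands()` detects strands from backbone hydrogen-bond
  ladders, scoring C=O···H–N pairs with the Kabsch–Sander electrostatic
  model (0.42/0.20 e partial charges, bond at E < −0.5 kcal/mol, amide
  H inferred from the preceding peptide plane when absent) and labeling
  ladder segments A.. in sequence order. It is a deliberately
  simplified assigner for well-formed sheets — constant domains are
  expected to yield 7 strands, and more than 7 is refused with a
  pointer to manual annotation; it is not a general secondary-structure
  method.

## The orientation coordinate system

A reference frame is built once from a reference complex
(`buildReference()`): for each domain, the first principal axis of
inertia (smallest eigenvalue of the inertia tensor about the center of
mass) is aligned to +z, then the domain is spun about z until the
interdomain center axis (a-center → b-center) has its largest possible
+x component. Mapping a sample frame (`measureFrame()`) Kabsch-aligns
each reference domain onto the frame over Cα atoms and transforms the
world unit vectors by the fitted rotations, giving A1/A2 (z/y of domain
a) and B1/B2; with Ĉ the a→b center axis the six measures are

* `AB` — signed torsion from A1 to B1 about Ĉ, right-handed, (−180, 180];
* `AC1`, `AC2` — angles of A1, A2 against Ĉ;
* `BC1`, `BC2` — angles of B1, B2 against −Ĉ;
* `dC` — |center(b) − center(a)| in Å.

Conventions that the construction leaves open were fixed as follows and
are configuration, not physics: centers and inertia tensors use
mass-weighted heavy atoms (`weighting = "CA"` switches to Cα); the
principal-axis sign is pinned by a positive dot product with the
first→last alignment-atom vector; domain b tilts are measured against
−Ĉ so that a symmetric homodimer yields AC1 ≈ BC1; the torsion is
reported signed, right-handed about the a→b axis. Measuring domain b
against −Ĉ and the torsion sign are conventions of this package; an
absolute-value view of the torsion is a trivial transform of the
output. For Fv and CH1-CL work the measures can be renamed to the
field's usual HL/LC1/LC2/HC1/HC2 and cHL/cLC1/... aliases
(`measureTrajectory(..., aliases = )`).

For a static complex measured against a reference built from itself,
AC2 and BC2 are 90° *by construction* (the y axes are orthogonal to the
center axis in the reference); they become informative once frames
depart from the reference. `kdeDensity()` estimates torsion-angle
densities with a Gaussian kernel on a 0.1° grid spanning the samples
± 4 bandwidths (Silverman's rule by default). `superpose()` is a
standard Kabsch superposition with the determinant correction (proper
rotations only), and `computeRMSF()` reports per-residue Cα
fluctuations about the time-average after superposition.

## Electrostatic interaction energies

`coulombEnergy()`/`energySeries()` compute the interdomain pairwise
Coulomb sum E = k Σ qᵢqⱼ/(ε rᵢⱼ), k = 332.0636 kcal·Å/(mol·e²), with a
12 Å cutoff and ε = 1 by default — the electrostatic half of a linear
interaction energy analysis. Charges come from a PQR file
(`readPQR()`) or, for tests and demonstrations, the coarse residue
charge table `coarseCharges()` (±1 e on Lys/Arg termini and
carboxylates split as 2 × −0.5 e); force-field parameter assignment is
out of scope, so numeric comparability with any specific force field is
not claimed. There is no distance-dependent dielectric and no vdW
term. Pair distances below 0.5 Å are treated as corrupt input.

## The synthetic generator

`buildToyDomain()` emits an idealized antiparallel β-sheet: 3.5 Å Cα
rise, 4.8 Å strand spacing, carbonyls alternating across the sheet so
the Kabsch–Sander ladder recovers every strand, 3-residue out-of-plane
loops, poly-Ala with optional Lys/Glu/Leu/Asn point mutations whose
idealized side chains support each contact kind. `assembleComplex()`
places two such domains at a requested torsion AB, tilts AC1/BC1 and
distance dC (AC2/BC2 are 90° for a self-referenced static complex, see
above); the defaults (torsion 90°, tilts 40°, dC ~28-30 Å) mirror the
geometry typical of constant-domain dimers, whose torsions cluster near
90° (variable-domain pairs sit nearer 50°). `synthTrajectory()` then
emulates a frame ensemble: per frame an optional planted torsion
(rigid rotation of domain b about the center axis), isotropic Gaussian
coordinate noise, and Bernoulli contact planting — with probability
`target_ratio` the b-side side chain is translated so the contact's tip
atoms sit 0.8 Å below the detection threshold, otherwise 1 Å beyond
it. All draws come from a single generator seeded once and are
returned as ground truth.

Numerical choices worth knowing:

* The default noise σ of 0.1 Å is small, thermal-like jitter chosen so
  that the ±0.8/+1.0 Å planting margins are many standard deviations
  wide — detection then matches the Bernoulli ground truth exactly and
  the statistics of recovered ratios are binomial by construction.
  Orientation-recovery validation deliberately uses the harsher 0.3 Å.
* Planting repositions side-chain tips relative to the *noised* a-side
  tip, so the realized tip distance is exact; the backbone is never
  touched, which keeps the orientation ground truth intact.
* Study-scale ensembles are 10,000 frames, matching the frame counts
  that interface studies typically extract from microsecond MD; most
  tests run far smaller ensembles (dozens to 1,000 frames) to keep the
  suite fast, and the statistical tolerances quoted in the tests are
  scaled to the ensemble actually used.

What the generator does **not** emulate: real side-chain rotamers,
correlated backbone dynamics, solvent, or the sequence diversity of
real antibody interfaces. A green synthetic suite therefore
demonstrates the correctness of the geometry, bookkeeping and
statistics — not that any biological conclusion transfers to a given
antibody; for that, the real structures and ensembles must be supplied.

## Validation strategy, limitations

Every detector and estimator is checked against an independent oracle:
contact detection against a brute-force double loop over all atom
pairs (exact equality on dozens of noisy frames), Coulomb sums against
a double loop (1e−9), superposition against bio3d's fit, orientation
measures against constructed rigid motions (planted torsions recovered
to 1e−4° noise-free, within 2° mean at σ = 0.3 Å; rigid-body
invariance to 1e−6), and coarse statistics against hand-computed
values (mean/SEM of {0.2, 0.4, 0.6} → 0.4 ± 0.11547).

Two acceptance checks compare against real crystal structures of a
CH3-CH3 dimer, a CH1-CL dimer and an Fv (Cα-RMSD of the two
constant-dimer folds near 1.8 Å; torsions near 90°/90°/50°). The
package does not redistribute PDB coordinate files, so these checks
require the user to place the files under `inst/extdata/reference/`
(`3ave.pdb`, `5i19.pdb`, `fv.pdb`); without them the corresponding
tests report their absence rather than silently passing.

Known limitations: the strand detector is not a general
secondary-structure assigner; π-stacking is not a named contact type;
the electrostatics is bare Coulomb without solvent screening; binary
MD trajectory formats are not read (convert to multi-model PDB); and
the packaged element maps are curated approximations of the canonical
topology, not a published table.
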
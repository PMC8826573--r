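# AbInterface

Quantitative characterization of the interface between two paired
immunoglobulin-like domains — CH3-CH3 (Fc), CH1-CL (Fab) and VH-VL
(Fv) — from crystal structures or frame ensembles (multi-model PDB
stand-ins for MD trajectories). The package is aimed at antibody
engineers comparing interface classes and variants (knobs-into-holes,
charge-pair designs) and at structural bioinformaticians who need
reproducible interface descriptors.

Four kinds of quantities are computed:

* **Time-resolved contacts** between the two domains, classified with
  GetContacts-style geometric criteria into hydrogen bonds (donor–
  acceptor ≤ 3.5 Å, D–H···A ≥ 110°), salt bridges (cation-N to anion-O
  ≤ 4.0 Å), hydrophobic contacts (apolar carbons ≤ 4.5 Å) and van der
  Waals contacts (d ≤ r₁ + r₂ + 0.5 Å), never double-counted across
  channels. The occurrence ratio of a contact is the fraction of frames
  in which it exists.
* **Coarse-grained interface maps** over the β-strands A–G and loops
  (AB … FG) of the Ig fold: element-pair occurrence ratios (flareplot
  edges), class averages with standard errors of the mean, normalized
  difference maps between interface classes (entries
  (mean₁ − mean₂)/max mean, in [−1, 1]), and per-residue duration-
  weighted open-book scores Σ_partners ratio.
* **Interdomain orientation**, a six-measure coordinate system built
  from per-domain reference frames (first principal axis of inertia on
  z, center axis toward x): torsion AB, tilt angles AC1/AC2/BC1/BC2
  against the center axis, and the center-of-mass distance dC, with
  Gaussian KDE of angle distributions, Kabsch superposition RMSD and
  per-residue RMSF.
* **Interdomain electrostatics**: per-frame Coulomb sums
  E = 332.0636 Σ qᵢqⱼ/(ε rᵢⱼ) kcal/mol with configurable cutoff and
  dielectric, charges from PQR files or a coarse residue table.

A synthetic module generates idealized two-domain β-sheet complexes at
requested orientations with planted contact lifetimes, providing exact
ground truth for every analysis; the test suite validates each detector
against independent brute-force oracles.

## Worked example

Build a synthetic constant-domain-like dimer at a 90° interdomain
torsion, plant a salt bridge present in 65% of frames, and run the
contact and orientation analyses:

```r
library(AbInterface)

dom_a <- buildToyDomain(7, 6, chain = "A", mutations = c("30" = "GLU"))
dom_b <- buildToyDomain(7, 6, chain = "B", mutations = c("30" = "LYS"))
cx <- assembleComplex(dom_a, dom_b, torsion = 90, tilt_a = 40,
                      tilt_b = 40, dC = 33)
cx$structure
#> Structure: 608 atoms, 120 residues, chains A B

sim <- synthTrajectory(cx, n_frames = 500, noise_sigma = 0.1,
  planted = list(list(residue_a = "A:30", residue_b = "B:30",
                      kind = "saltbridge", target_ratio = 0.65)),
  seed = 42)
tab <- trajectoryContacts(sim$traj, sim$sel_a, sim$sel_b)
contactRatio(tab, "A:30", "B:30", "saltbridge")
#> [1] 0.634
mean(sim$truth[[1]])          # generator ground truth
#> [1] 0.634

ref <- buildReference(cx$structure, cx$sel_a, cx$sel_b)
series <- measureTrajectory(sim$traj, ref)
round(colMeans(series[, -1]), 2)
#>    AB   AC1   AC2   BC1   BC2    dC
#> 90.10 40.24 89.84 39.84 89.76 32.55
```

The recovered occurrence ratio (0.634) equals the fraction of frames
in which the generator actually drew the contact — the detector and the
ground truth agree frame by frame — and the mean orientation matches
the assembly request (AB 90°, tilts 40°, AC2/BC2 at their 90°
reference values). Coarse-graining the table onto detected strands
places the planted bridge on its element pair:

```r
nres <- max(atoms(cx$structure)$resseq)
map_a <- assignStrands(cx$structure, domainSelection("a", paste0("A:1-", nres)))
map_b <- assignStrands(cx$structure, domainSelection("b", paste0("B:1-", nres)))
freq <- coarseGrain(tab, map_a, map_b, system = "demo")
freq$saltbridge
#> ContactFrequencyTable [demo, saltbridge]: 15 x 15 elements, 1 nonzero
#> a_D - b_D : 0.634
```

For real structures the same pipeline starts from `readPDB()` /
`readTrajectory()` with `domainSelection()` ranges (e.g.
`"A:341-447"` for an EU-numbered CH3 domain) and
`canonicalElements("CH3", ...)` element maps. `runPipeline()` wires the
stages from a YAML configuration (`contacts`, `orient`, `energy`,
`openbook`, `synth`), writing TSV/JSON outputs and a manifest of every
effective parameter; `inst/scripts/abinterface` is a shell wrapper
around it.

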
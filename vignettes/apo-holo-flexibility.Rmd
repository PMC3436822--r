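---
title: "Measuring side-chain rotamer changes upon ligand binding"
author: "ApoHoloFlex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring side-chain rotamer changes upon ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ApoHoloFlex)
```

## The model

A side-chain *rotamer* is a discrete conformational state defined by a
combination of χ dihedral-angle ranges around the modal values tabulated in
a rotamer library. Because rotamers correspond to minima of the side-chain
torsional energy, a residue observed in *different* rotamers in the unbound
(Apo) and ligand-bound (Holo) crystal forms of the same protein has crossed
an energetic barrier — a much stronger statement than an arbitrary
Cartesian-RMSD or Δχ-threshold criterion, which cannot distinguish thermal
jitter from a genuine state change. ApoHoloFlex classifies binding-site
residues as **flexible** (different rotamers, or rotameric in one form and
non-rotameric in the other) or **rigid** (same rotamer), and aggregates the
calls into a per-residue-type flexibility probability

$$P_i = \frac{N_i^R}{N_i^T} \pm \sqrt{\frac{P_i(1 - P_i)}{N_i^T}},$$

where $N_i^R$ counts flexible observations of type $i$ and $N_i^T$ all
analyzable observations. The error term is the binomial standard error of
the observed fraction; we checked it against a bootstrap over resampled
observation sets in the test suite.

Two companion analyses ask *why* side chains move:

* **Steric necessity.** Superposing the Holo structure onto the Apo form on
  the binding-site backbone (N, CA, C, O; closed-form SVD fit with a
  proper-rotation guard) and transplanting the ligand yields the
  *Apo-bound* form: the observed ligand pose confronted with the unbound
  side-chain conformation. Overlap is scored with a soft wall potential,
  summed over ligand–protein heavy-atom pairs:
  $$W = K_\mathrm{wall} \sum_{ij:\, r_{ij} < r_i + r_j}
  \left(\frac{r_i + r_j - r_{ij}}{r_i + r_j}\right)^4,
  \qquad K_\mathrm{wall} = 10^6 .$$
  The quartic of the *relative* overlap is zero at van der Waals contact
  and rises steeply with penetration: a single 0.24 Å overlap between two
  carbons scores ≈ 25, a 0.4 Å overlap ≈ 470. The Holo→Apo-bound difference
  ΔW (signed: positive means the Apo conformation is worse) is compared to
  thresholds of 150 per site and 25 per residue, above which the pose is no
  longer acceptable without the observed rearrangement.
* **Hydrogen-bond rearrangement.** Strong H-bonds only (donor and acceptor
  both N or O), detected when 1.5 Å ≤ d(H···A) ≤ 2.7 Å and
  θ(D–H···A) ≥ 90°, all boundaries inclusive. Counts per binding-site side
  chain are kept separately against water, protein and ligand and the
  Apo→Holo change per entity is called conserved (equal, including 0/0),
  gain, or loss.

## Curation gates

`validatePair()` applies the gates in a fixed order and reports the first
failure as a reason code, so verdicts are reproducible and auditable:
resolution (≤ 2.50 Å, both forms), sequence identity (100% over aligned
columns) and overlap (the identical stretch must cover ≥ 80% of either
chain — "either" so that expression-tag length differences do not discard a
pair), buffer-ligand exclusion, ligand size (≥ 5 heavy atoms), covalency
(any ligand–protein pair within covalent radii + 0.4 Å), binding-site size
(≥ 5 contacted residues) and single-chain burial, burial fraction
F<sub>c</sub> ≥ 0.70, side-chain completeness of all site residues in both
forms, extra-ligand consistency (each non-subject ligand present in both
forms with ≤ 10 residue-contact difference), and site backbone RMSD
≤ 2.50 Å.

Two definitional choices deserve a note. First, the burial fraction is
implemented as $F_c = 1 - \mathrm{SAS}_b/\mathrm{SAS}_f$ (free-ligand SASA
versus its SASA inside the complex, same conformation): a fully buried
ligand scores 1 and the ≥ 0.70 gate then means "at least 70% of the ligand
surface is sequestered", which is the only reading under which a burial
*minimum* makes sense; the raw ratio is available via
`convention = "printed"`. Second, "more than 10 different contacts" for
extra ligands is counted at residue level, consistent with the
residue-level definition of the binding pocket.

## Numerical choices

* **Angles.** All χ comparisons are circular (differences wrapped to
  (−180°, 180°]); terminal χ of 2-fold symmetric end groups (Asp χ₂, Glu
  χ₃, Phe/Tyr χ₂) are compared modulo 180° and normalized to (−90°, 90°],
  so equivalent atom namings can never masquerade as conformational change.
  The same convention feeds both the rotamer method and the legacy Δχ ≥ 60°
  method, keeping the two series comparable.
* **Boundaries.** The ±30° rotamer admission window is closed (a deviation
  of exactly 30° still admits); Δχ = 60° counts as changed; the
  minimal-rotation test is strict (< 15°); all H-bond inequalities are
  closed as stated, with a 10⁻⁹ numerical guard so that geometries
  constructed exactly on a boundary are classified deterministically.
* **Ties.** Overlapping admission windows can leave several candidate
  rotamers; the nearest by maximum per-χ deviation wins, then the higher
  library frequency. Representative selection within a redundancy group
  maximizes F<sub>c</sub> and breaks ties lexicographically by pair id.
* **SASA.** A deterministic Shrake–Rupley implementation: each solvent-
  expanded sphere (probe 1.4 Å) carries a fixed 960-point spherical
  Fibonacci lattice; a point is accessible when outside every neighbour's
  expanded sphere. 960 points keep the per-atom error well under 1% of the
  dense-sampling limit (tested against a 10⁶-point Monte-Carlo oracle)
  while one F<sub>c</sub> evaluation stays around 0.2 s; totals are stable
  to ~0.1–0.2% under rigid motion at this density, tighter at higher
  `nPoints`. The analytical alternative (exact sphere-intersection areas)
  was not pursued: the sampling error is far below every decision
  threshold that consumes a SASA value.
* **Wall form.** Only the penalty constant and the radii enter the
  published description of the clash score; the functional form here
  (quartic in relative overlap) was chosen so that the 150/25 thresholds
  sit at physically sensible overlap depths (≈ 0.37 Å and ≈ 0.24 Å for a
  C–C pair), and quadratic and hard-step alternatives are selectable
  through `wallParameters(form =)` because threshold semantics travel with
  the form. Hydrogens are excluded (crystal structures rarely resolve
  them); each pair term is credited to the protein atom's residue.
* **Hydrogen placement.** Deterministic ideal-geometry placement:
  amide/guanidinium hydrogens in plane, Lys NZ staggered, hydroxyl rotors resolved by a 12-position scan
  that maximizes realized H-bonds (ties to the smallest torsion), His ring
  nitrogens ambident with a virtual in-plane hydrogen resolved per
  contact, carboxylates and phosphates unprotonated. Asn/Gln/His flips are
  scored two-state: fewer heavy clashes, then more satisfiable H-bond
  partners, input kept on ties. Water donors present no explicit hydrogen
  and are accepted on the heavy-atom distance alone (2.5–3.5 Å), the upper
  bound being the 2.7 Å H···A limit plus a collinear O–H bond. Ligand N/O
  atoms participate as acceptors; we do not protonate ligands.
* **Thr.** The strong-H-bond residue list excludes Thr in its strictest
  reading although Thr hydroxyls plainly H-bond; inclusion is a flag
  (`includeThr`, default `TRUE`).

## The synthetic generator

`generatePair()` builds a ground-truthed pocket: residues on a spherical
Fibonacci shell around a compact 7-heavy-atom ligand (het code FLX, outside
the buffer list), side chains pointing inward, each residue moved radially
until its closest side-chain atom sits 0.5 Å outside van der Waals contact
with the ligand — a typical packing distance that buries the ligand
(F<sub>c</sub> ≈ 0.85) with zero steric overlap. Backbones are identical
between forms, isolating side-chain effects (site RMSD = 0). Plants are
exact by construction:

* *flexible*: the Apo form swaps to a different library rotamer;
* *NR*: the Apo χ₁ is placed at the angle maximizing the minimal circular
  distance to every library mean (grid search; the generator refuses types
  whose means are too dense);
* *clash*: among all rotamer pairs of the planted residue, the generator
  picks the one whose Apo conformer points most directly at the ligand
  relative to its Holo conformer, then root-finds the radial position at
  which the Apo overlap equals the requested depth while the Holo form
  stays clash-free. Short pseudo-symmetric side chains (Ser/Val/Thr/Cys,
  Leu's methyl fork) cannot stage a 0.5 Å swing and are rejected as
  infeasible rather than approximated;
* *H-bonds*: a Trp indole (single, deterministic N–H) donates to an
  acceptor placed at an exact (d, θ) from the computed hydrogen — ligand
  oxygen or water — or an Asp carboxylate accepts a water at an exact
  heavy-atom distance, so detection boundaries can be probed from both
  sides;
* *quality*: planted B-factor/occupancy/altloc exceptions exercise the NR
  filter (defaults: B = 15, occupancy 1).

`generateEnsemble(n, lambda, seed)` draws per-site flexible counts from a
Poisson(λ) (truncated at the pocket size) and is byte-stable under a fixed
seed. Default study conditions used by the tests and the acceptance script:
200 pairs, λ = 1.5, 8 residues per pocket — small enough that the full
distribution-recovery check runs in well under a minute, large enough for
the Monte-Carlo envelope comparison to have power.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: crystallographic noise and refinement
artifacts, backbone relaxation coupled to side-chain motion, correlated
neighbour rearrangements, solvent networks beyond planted waters, and
peptide connectivity (residues are spatially disconnected ideal-geometry
units, which is also why the normalized-SASA reference is the isolated
residue rather than an extended Gly-X-Gly tripeptide). The pipeline's
behaviour on those factors is exercised only through the curation gates
that exclude them.

## Reporting

`analyzeEnsemble()` feeds `siteChangeDistribution()` (change-count
histogram with cumulative fractions, for both the rotamer and the Δχ ≥ 60°
method), `flexibilityScale()` (the P scale with binomial errors; Gly and
Ala have no χ, Pro's χ is backbone-coupled, and disulfide-bonded Cys are
constrained — all are excluded before counting), `entropyCorrelation()`
(Pearson r between the scale and a user-supplied ΔS table; the shipped
`sidechain_entropy_synthetic.tsv` is a constructed stand-in, labelled as
such, ordering entropy loss by rotatable-bond count), and
`compareFlexibleVsRigid()` (two-sided Welch t-tests of Apo B-factors and
normalized SASA; Welch because group variances have no reason to be equal,
and the label travels with the output). Headline numbers of the kind
reported for curated PDB-wide datasets (e.g. the fraction of flexible
sites) depend on such an external dataset and are not reproducible from
this package alone;
every number the package reports is computed at run time from data it
generated or was given.

## Known limitations

The ideal-geometry protonation routine is deterministic but local: it does
not optimize the global H-bond network, so in dense real pockets a rotor
choice can differ from a full network optimizer's. Ligand connectivity is perceived
by distance when no dictionary is supplied. The rotamer library is a
condensed backbone-independent snapshot (modal angles, uniform ±30°
windows); a backbone-dependent library would sharpen assignments near
unusual backbone conformations but is out of scope. Water positions are
taken as given; no water orientation or placement optimization is
attempted.
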
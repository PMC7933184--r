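---
title: "Quantifying N-glycan shielding of ligand binding sites"
author: "glycanshield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying N-glycan shielding of ligand binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanshield)
```

## The scientific problem

Cell-surface receptors are usually glycosylated, and the branched
N-glycans attached to them are large, flexible and mobile enough to bury
substantial parts of the protein surface. For a receptor such as the
CD44 hyaluronan-binding domain (HABD, residues 20–169, glycosylation
sites N25/N57/N100/N110/N120), the question is not simply *whether* the
surface is covered but *which ligand binding modes* are covered: the
canonical (crystallographic) hyaluronan groove, and the weaker parallel
and upright epitopes, occupy different patches, so a glycan shield can
re-weight the binding-mode repertoire rather than switch binding off.
This package implements the trajectory analyses that quantify this —
per-residue glycan contact fractions, a per-binding-mode coverage
statistic with replica statistics, inter-glycan contact networks,
surface distance maps, ligand association/dissociation bookkeeping and
buried interface areas — together with the matching NMR-side analysis
(minimal chemical shift perturbation profiles and titration-response
classification for HSQC peak lists).

## The coverage model

Everything reduces to the per-residue **contact fraction**. For a
residue $r$ and a target group (all glycan chains, or a ligand),

$$C_r = \frac{\#\{\text{frames: } d_r < c\}}{\#\text{frames}},$$

where $d_r$ is the minimum distance between any atom of the residue and
any atom of the target in that frame, and $c$ is the contact cutoff
(0.3 nm by default — the standard heavy-atom contact criterion of
`gmx mindist`-style analyses). Contacts are strict `<` at the cutoff:
ties have measure zero in floating point but fixing the convention makes
results bit-reproducible.

A **binding-mode footprint** assigns each receptor residue a weight
$w_r \in [0,1]$ describing how strongly the ligand contacts it in that
mode. The **mode coverage** within one replica is the footprint-weighted
mean of the glycan contact fractions,

$$C^{\mathrm{mode}} =
  \Big\langle \frac{\sum_r w_r\, C_r^{(\mathrm{rep})}}
                   {\sum_r w_r} \Big\rangle_{\mathrm{rep}},$$

averaged over replicas with equal weight; the reported uncertainty is
the standard error of the replica mean (sample SD, `ddof = 1`, divided
by $\sqrt{n}$). Two consequences worth noting, both enforced by tests:
the statistic is invariant to uniform rescaling of the footprint
weights, and it is a convex combination of the per-residue coverages, so
it always lies between the smallest and largest $C_r$ entering it.

Footprints are an input artifact (TSV: `mode`, `residue_id`, `weight`).
The package ships binary membership footprints for the residue lists
that are public knowledge for this receptor — the upright-mode patch
(K38, S43, I44, Y79, G80, Y105, Q113, Y114, R162, E166) and the key
arginines of the canonical groove (R41, R78, R150, R154, R162) — in
`inst/extdata/example_footprints.tsv`. Quantitative per-residue weights
from ligand-binding simulations can be substituted transparently.

### Which replica estimator

With 15 replicas built as 3 starting configurations × 5 runs, one could
average hierarchically. We flatten to 15 equal replicas (the flat mean
is identical; the SE differs only in its effective degrees of freedom)
because that matches the replica-averaged presentation typical for this
kind of data; a grouping argument is easy to add upstream of
`modeCoverage()` by averaging coverage objects per group first.

## Distance computations

All coordinates are stored in nm and frame times in ns (GROMACS
conventions); PDB Angstroms are converted at the I/O boundary.
Minimum-image distances are applied for orthorhombic boxes only —
triclinic boxes are rejected with a clear error rather than silently
mis-wrapped. Hydrogens, when present in the topology, participate in
all distance computations ("any atom" means any atom); whether a
hydrogens-included topology was used is therefore visible in the
selection, not hidden in the engine.

Two independent kernel paths exist: an all-pairs `brute` path and a
grid (cell-list) `cell` path with an expanding-shell search whose
conservative lower bound guarantees exactness. `auto` (the default)
picks by problem size. The test suite asserts bitwise agreement of the
two paths and equality with a vectorized R reference on randomized
periodic and non-periodic systems — the cell path is an optimization,
never an approximation.

## Binding events

Association/dissociation bookkeeping uses a two-threshold hysteresis on
the ligand–receptor minimum-distance series: bound is entered when the
distance drops below `on_cutoff` (0.3 nm) and left when it rises above
`off_cutoff` (0.5 nm), which suppresses flicker around a single
threshold. A dwell filter then removes state excursions shorter than
`min_dwell` (1 ns): runs are scanned left to right and a run shorter
than the dwell is absorbed into the already-confirmed preceding state; a
too-short *leading* run is carried forward until the accumulated length
first reaches the dwell, and takes the state of the run that crossed it.
These defaults are an operationalization chosen here (reported
association/dissociation cycle tables in the literature rarely state
their criterion); all three parameters are recorded in the output
headers, and `off_cutoff = on_cutoff` with `min_dwell = 0` reduces
exactly to simple thresholding. Event durations are counted as
(frames in the bound run) × (frame spacing).

## Surface areas

`calcSASA()` is a Shrake–Rupley implementation: each atom's sphere is
expanded by the probe radius (0.14 nm, water-sized) and sampled with a
deterministic golden-section spiral (960 points by default — at that
density an isolated sphere is exact to ≪0.5% and a two-sphere system
matches the analytic spherical-cap area to ~0.03%). A sample point lying
exactly on another expanded sphere's surface is owned by the
lower-indexed atom, so coincident duplicate atoms expose the surface of
a single sphere instead of double-counting. Radii come from a bundled
Bondi table; note that `gmx sasa`-family tools use slightly different
default radii, so absolute agreement with numbers produced by those
tools is not claimed — interface *differences* are robust to this.

The buried interface between disjoint selections A and B is

$$\mathrm{interface} = \tfrac12\,[\mathrm{SASA}(A) + \mathrm{SASA}(B)
  - \mathrm{SASA}(A \cup B)]$$

with "A alone" meaning B's atoms removed entirely. The halved value is
the per-face buried area; `halved = FALSE` gives the total, since
published interface plots do not always state the convention.
`interfaceSeries()` evaluates the interface at the final frame of each
replica by default (`at = "final"`), mirroring end-of-trajectory
comparisons; a frame window can be averaged instead. SASA ignores
periodic images: selections are assumed whole and unwrapped, and waters
and ions are excluded simply by not selecting them.

## NMR side

The combined chemical shift perturbation is
$\sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}$ with $w = 0.2$, the
conventional nitrogen scaling; $w$ is configurable and recorded in all
outputs. The **minimal-shift** profile takes, for each assigned
free-state peak, the minimum combined CSP over the entire bound peak
pool (assigned peaks, populated doubled-peak slots and unassigned peaks
together) — usable when the bound spectrum has no assignments, and by
construction a lower bound on the true (assigned) CSP. The profile is
invariant under a global reference offset applied to both spectra.

`classifyTitration()` operationalizes the qualitative spectral
categories of a titration series (free + ≥2 ligand ratios):

* `instant_disappearance` — final intensity < `f_gone` (0.1) of the free
  intensity;
* `instant_shift` — CSP at the first titration point ≥ `f_inst` (0.8) of
  the final CSP, final CSP above the perturbation floor (0.02 ppm);
* `gradual_shift` — above the floor but not instant;
* `unperturbed` — below the floor;
* `doubled` (orthogonal flag) — a secondary peak slot populated at any
  point.

The thresholds are explicit operationalizations of categories that are
classically called by expert inspection of spectra; they are recorded in
every output table. Instant versus gradual maps directly onto the
strong (sub-µM) versus weak (>10 µM) interaction reading of titration
behaviour; no $K_d$ fitting is attempted.

## The synthetic generators

`genShieldedTrajectory()` builds the test bed: receptor residues on a
rigid lattice (1.2 nm spacing, so a bead touching one residue is ≥0.9 nm
from its neighbours), glycan chains parked as bead strings above their
attachment sites, and — for each residue with planted occlusion $p$ — a
designated glycan bead deployed onto that residue (0.13–0.23 nm from its
atoms) in exactly `round(p * n_frames)` frames chosen by a seeded
permutation. Contact margins are wide on both sides of the 0.3 nm
cutoff (deployed < 0.25 nm, parked > 0.4 nm), so the planted fractions
survive the 10⁻³ nm GRO round-trip unchanged and the analysis recovery
is *exact*, not approximate. A ligand chain follows a scripted
bound/unbound schedule (bound: within the cutoff of the epitope
residues; unbound: parked > 1.5 nm away). The default "toy-HABD"
scenario uses 150 residues numbered 20–169, glycans at 25/57/100/110/120,
the key residues 38/41/78/150/154/162 as the ligand epitope, 1000 frames
at 0.1 ns, and planted occlusions chosen once so that the
crystallographic-mode residues are the most and the upright-specific
residues the least occluded — carrying the qualitative
crystallographic > parallel > upright ordering in the ground truth
itself.

What the generator deliberately does **not** emulate: chain
connectivity and excluded volume, conformational kinetics,
force-field energetics, solvent, or realistic glycan geometry. Passing
tests therefore demonstrate that the *analysis pipeline* is correct
(counting, weighting, replica statistics, event logic, I/O), not that
any physical simulation is well sampled. The same division holds for
`genTitrationPeaks()`: planted perturbation schedules per category plus
Gaussian shift noise, with a warning when the noise SD exceeds the
classification floor (recovery then being statistically impossible is a
property of the data, not a bug).

Because the occlusion construction is exact, every replica has exactly
the same per-residue coverage (the frame *subsets* differ by seed, the
counts do not), so the replica SE of the planted scenario is exactly 0 —
itself a useful fixture property, tested as such.

## Problem sizes and numerical choices

The test suite and the acceptance script run the toy scenario at 15
replicas × 1000 frames (≈340 atoms), randomized kernel cross-checks at
≤100 atoms × 100 systems, SASA at 960 sphere points, and the titration
panel at 10 residues × 4 conditions — sizes chosen so the full
validation cycle completes in minutes on a single core while every
statistic still exercises its full code path. Other fixed choices:
seeds are mandatory in all generators (same seed ⇒ bit-identical
output); all tabular outputs carry their parameters and an MD5 config
hash in `#` header lines, so two runs with different cutoffs can never
share an output hash; timestamps appear only in the JSON provenance
sidecars, keeping primary outputs byte-identical across reruns.

## Known limitations

* Trajectory formats: multi-frame GRO, multi-model PDB and DCD are
  read; XTC is not (no reader in the R ecosystem this package builds
  on), so XTC trajectories should be converted on the way in.
* Orthorhombic boxes only; triclinic systems are rejected.
* SASA uses Bondi radii and no periodic images; absolute values differ
  slightly from tools with other radius tables.
* Footprint weights for the binding modes are inputs; the bundled
  examples are binary membership lists, not the quantitative weights a
  ligand-binding simulation would provide.
* The classifier thresholds are fixed operationalizations; borderline
  residues near `f_inst` or the floor inherit the usual sensitivity of
  hard thresholds.
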
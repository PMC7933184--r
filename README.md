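# glycanshield

Quantifying how a glycoprotein's own N-glycans shield its ligand
binding sites, from molecular dynamics trajectories and NMR titrations.

## The problem

The hyaluronan-binding domain of CD44 (HABD, residues 20–169) binds its
ligand in several distinct modes — the canonical crystallographic
groove and the weaker parallel and upright epitopes — and carries five
N-glycosylation sites (N25, N57, N100, N110, N120). Flexible N-glycans
sweep over large parts of the receptor surface, so the biologically
interesting quantity is mode-resolved: *how much of each binding
epitope is occluded by glycans, and with what replica-to-replica
uncertainty?* This package provides the trajectory analyses for that
question, the matching NMR chemical-shift-perturbation analyses, and
synthetic generators with exact planted ground truth so that the whole
pipeline is testable without any simulation data. It is aimed at
computational structural biologists analysing glycoprotein MD
ensembles and at NMR spectroscopists processing HSQC titration peak
lists.

## The statistic at the core

For residue *r* and a target group (the glycans), the contact fraction
over a trajectory is

    C_r = #(frames with min-distance < 0.3 nm) / #frames

with the minimum distance taken over all atom pairs (minimum-image for
orthorhombic boxes). Given per-residue footprint weights `w_r` in [0, 1]
describing a binding mode, the mode coverage is the weighted mean

    C_mode = < (Σ_r w_r · C_r(rep)) / (Σ_r w_r) >_rep

averaged over replicas, reported as mean ± SE (sample SD / √n).
Around this sit: inter-glycan contact matrices (atom pairs < 0.6 nm),
replica-averaged surface distance maps (clamped to 0.3–1.5 nm for
display), ligand association/dissociation events (0.3/0.5 nm hysteresis
with a 1 ns dwell filter), Shrake–Rupley SASA and buried interface
areas, minimal chemical shift perturbation profiles
(√(ΔδH² + (0.2·ΔδN)²), minimum over the bound peak pool) and an
instant/gradual/disappearance/doubled titration classifier.

## Worked example

The toy scenario plants known per-residue occlusion fractions by exact
frame-count construction, so every number below is known in advance:

```r
library(glycanshield)

sc   <- shieldScenario(nFrames = 1000L, seed = 1L)   # toy-HABD scenario
reps <- genShieldedReplicas(sc, nReplicas = 15L)
covs <- coveragePerReplica(lapply(reps, `[[`, "system"),
                           "entity receptor", "entity glycan_*",
                           cutoff = 0.3)

reports <- lapply(toyFootprints(), function(fp) modeCoverage(covs, fp))
for (r in reports) print(r)
#> CoverageReport 'crystallographic': 61.3% +/- 0.0% (n = 15 replicas)
#> CoverageReport 'parallel': 45.0% +/- 0.0% (n = 15 replicas)
#> CoverageReport 'upright': 23.0% +/- 0.0% (n = 15 replicas)

compareModes(unname(reports))$order
#> [1] "crystallographic" "parallel"         "upright"

ev <- bindingEvents(reps[[1]]$system, "entity ligand_HA6_1",
                    "entity receptor")
ev[, c("start_ns", "end_ns", "duration_ns")]
#>   start_ns end_ns duration_ns
#> 1       10     30          20
#> 2       45     65          20
#> 3       80     95          15
```

The three coverage numbers are exactly the footprint means of the
planted occlusions (the SE is exactly 0 because the frame-count
construction gives every replica identical fractions), and the events
table reproduces the scripted binding schedule. The
crystallographic > parallel > upright ordering is planted in the toy
ground truth and recovered by `compareModes()`.

On the NMR side:

```r
tit <- genTitrationPeaks(toyTitrationScenario(seed = 1L))
classifyTitration(tit$series)[, c("residue_id", "category", "doubled")]
combinedCSP(0.1, 0.5, w = 0.2)
#> [1] 0.1414214
```

## Command line

A thin wrapper at `exec/glycanshield` drives the same stages from a
YAML config:

```sh
Rscript exec/glycanshield simulate --config run.yaml --out out/
Rscript exec/glycanshield coverage --config run.yaml --out out/
```

Stages: `simulate`, `coverage`, `surface-map`, `contacts`, `interface`,
`events`, `csp`, `classify`. Outputs are TSV with parameter-recording
header lines (including an MD5 config hash) plus a JSON provenance
sidecar; exit codes are 2 for configuration errors and 1 for analysis
errors.

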
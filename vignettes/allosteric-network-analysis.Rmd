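---
title: "Dynamical network analysis of allosteric communication with allopath"
author: "allopath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical network analysis of allosteric communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The model

Allosteric communication in a protein–ligand complex can be read off a
coordinate ensemble (typically a molecular-dynamics trajectory) by
treating the system as a weighted graph and asking how signals travel
from the ligand to a distal functional surface — in a nuclear-receptor
ligand-binding domain, from the bound ligand to the activation-function
surface around helix 12, or to a bound coregulator peptide.

The pipeline has four stages:

1. **Nodes.** Every protein residue is one node, represented by its
   C-alpha; a bound ligand is one additional node represented by the
   geometric centroid of its heavy atoms; coregulator-peptide residues
   are nodes of their own kind.
2. **Contact filtering.** Nodes $i, j$ are connected only if their
   heavy atoms come within 4.5 Å in at least 75% of frames
   (inclusive), excluding sequence neighbours ($|i-j| \le 1$ on the
   same chain). The ligand is never a sequence neighbour of a protein
   residue. With replicate trajectories, occupancy is computed per
   replicate and averaged before the threshold is applied.
3. **Weights.** Each surviving edge gets weight $w_{ij} = -\ln |C_{ij}|$,
   where
   $C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
   (\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle)^{1/2}$
   is the normalized cross-correlation of the node representatives'
   positional fluctuations. Strong correlation makes an edge short, so
   low path length means strong communication.
4. **Paths.** Optimal path lengths between all pairs come from
   Floyd–Warshall; the *shortest distance* between two nodes is either
   the direct edge weight or the optimal multi-edge path, whichever is
   smaller. All simple source-to-sink paths within an offset $\delta$
   of the optimal length are enumerated by depth-first search with
   branch-and-bound pruning (a partial path is abandoned once its
   length plus the optimal remaining distance exceeds the cutoff).
   The optimal path is part of the enumerated set.

Per-residue summaries then mirror the standard readouts: the
**utilization** of a residue is the percentage of the top-$k$ retained
paths that pass through it (source and sinks are excluded — they are in
every path by construction); the **shortest-distance profile** is the
source row of the all-pairs matrix in residue order, whose local
minima ("wells") mark the communication conduits out of the binding
pocket.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `distanceCutoff` | 4.5 | Å | heavy-atom contact distance |
| `occupancyThreshold` | 0.75 | fraction | contact persistence (inclusive) |
| `neighborExclusion` | 1 | residues | sequence-neighbour exclusion |
| `wCap` | 20 | path length | finite weight for $|C| = 0$ edges |
| `delta` | 100 | path length | suboptimal cutoff above the optimum |
| `topK` | 1000 | paths | retained for profiles |
| `maxPaths` | 5e6 | paths | enumeration safety bound |
| H-bond distance | 3.0 | Å | donor–acceptor heavy-atom cutoff |
| H-bond angle | 135 | degrees | donor–H–acceptor cutoff |

Notes on the less obvious choices:

* `delta` is a **dimensionless offset above the optimal length**, not
  an absolute length. The classic tooling in this field phrases its
  cutoff the same way even when a length unit is (incorrectly)
  attached in prose; a default of 100 suits full-size receptor graphs
  of a couple of hundred residues. On toy graphs it would enumerate
  essentially every simple path, so the bundled study uses `delta = 3`.
* Edges whose correlation is exactly zero would have infinite weight.
  They are kept at the cap `wCap = 20` (about $e^{-20}$ in correlation)
  and flagged, so connectivity decisions stay explicit and auditable
  instead of edges silently vanishing.
* Zero-variance nodes (possible in synthetic data) are flagged, their
  off-diagonal correlations set to 0, and they receive no edges.
* Hydrogen-bond criteria are stated nowhere in most papers that report
  occupancies; the defaults here (3.0 Å heavy–heavy, D–H–A ≥ 135°,
  inclusive, distance-only when no hydrogen exists) follow the
  trajectory-analysis tooling conventions and are config-exposed.
* Fluctuations are taken at the node representative (C-alpha, or the
  ligand's geometric centroid), not at residue centers of mass: this is
  the standard dynamical-network formulation. Center-of-mass distances
  in the geometry module are mass-weighted; the two conventions serve
  different measurements and are deliberately distinct.
* Equal-length paths are ordered lexicographically by node sequence,
  so the retained top-$k$ set is deterministic.

## The synthetic-ensemble generator

MD trajectories are expensive and rarely deposited, so every stage is
validated against synthetic ensembles with *known* answers
([`syntheticSpec()`], [`sampleTrajectory()`]). The generator plants:

* a mean structure of ideal helices (rise 1.5 Å/residue, C-alpha
  radius 2.3 Å, twist 100°/residue, consecutive C-alpha distance
  3.8 Å) arranged with adjacent axes `bundleSpacing` apart, plus an
  optional single-node ligand whose ≤ 8 pseudo-atoms sit within 1.5 Å
  of its placement point and move rigidly with it;
* rank-1 fluctuations: a per-node scalar latent drawn from a
  zero-mean multivariate normal with a block correlation matrix
  (blocks = helices + ligand), scaled by `baseSD` and applied along a
  fluctuation axis.

Two design points deserve emphasis:

**Shared fluctuation axis.** With one common random axis (the
default), the correlation of the fluctuation *vectors* equals the
latent correlation exactly, because
$\langle \Delta r_i \cdot \Delta r_j \rangle \propto
\rho_{ij} (u_i \cdot u_j)$ and $u_i \cdot u_j = 1$. Independent
per-node axes would attenuate every planted correlation by the random
cosine between axes and destroy the exact oracle; that mode exists
(`directionMode = "per-node"`) for stress testing only.

**Aligned by construction.** Synthetic frames fluctuate about a fixed
mean, so they are already superposed. Running a least-squares fit on
such data would subtract the frame-mean displacement and bias every
pairwise correlation downward by roughly $1/n_{\text{nodes}}$ — enough
to defeat a ±0.02 recovery check. `superpose()` therefore exists for
raw file-based ensembles (iterative fit→re-mean→fit, two passes), and
synthetic ensembles carry an `aligned` provenance flag that
`computeCorrelation()` respects.

The generator makes no attempt at physical realism: no bonded forces,
no solvent, no anisotropic fluctuation spectra, no side chains beyond
the ligand pseudo-atoms. Consequently, passing tests demonstrate the
*machinery* (estimators, filters, enumeration, profiles) is exact and
stable — they do not validate force fields or sampling adequacy of
real trajectories.

## The planted-coupling rerouting study

The package ships a frozen desk-scale experiment
([`couplingStudySpec()`], [`runCouplingStudy()`]) emulating the
mechanism by which a ligand that strengthens coupling between two
helices redirects communication through them. The system is a
three-helix bundle (helices of 12 residues, axes 4.8 Å apart,
per-node fluctuation 0.25 Å, 3000 frames):

* **S**, the sink helix, carrying the distal sink residue near its top;
* **H5**, the relay helix, with no direct ligand contact;
* **H7**, which the ligand touches directly — the ligand sits outside
  the bundle against the S/H7 interface.

Couplings are fixed (0.9 within helices, S–H5 0.30, S–H7 0.40,
S–ligand 0.15, H5–ligand 0.55, the last having no contact and hence no
edge) except the swept pair: ligand–H7 and H5–H7 both at
$\rho \in \{0.2, 0.5, 0.8\}$. The geometry was chosen once so that the
contact ladders between all three helix pairs percolate and the sink
has robust entries from both the H5 side and the H5-free side; the
fluctuation amplitude is small enough that the contact topology is
stable across seeds. As $\rho$ grows, the H5/H7 ladder becomes the
cheap route: path counts within the cutoff rise severalfold, mean
top-$k$ path lengths fall, H5 utilization rises, and the
shortest-distance profile develops a well over the H5 block that is
absent at weak coupling.

For well comparisons the study sets `maxAbove = 1` in
[`detectWells()`]: a well must additionally come within one
path-length unit of the global profile minimum. This encodes the
field's usage — wells are the regions with the *lowest* shortest
distances — and prevents a merely *locally* dipping but globally
expensive region from counting as a conduit. The default for
`detectWells()` remains purely local (`maxAbove = Inf`), with window
7 residues and depth 0.5; both are reporting heuristics and affect no
path statistic.

Problem sizes throughout (3000-frame studies, 25,000-frame correlation
checks, 200 eight-node oracle graphs) were chosen as the smallest at
which the estimators' own convergence rates ($\sim 1/\sqrt{n}$) make
the checks sharp.

## Worked example

```{r example, eval = FALSE}
library(allopath)

spec <- couplingStudySpec(rho = 0.8, seed = 1)
ens <- sampleTrajectory(spec)
nodes <- defineNodes(ens, "protein", "ligand")
corr <- computeCorrelation(ens, nodes)
graph <- buildGraph(contactMap(ens, nodes), corr)
apd <- floydWarshall(graph)
paths <- suboptimalPaths(graph, source = nNodes(graph),
                         sinks = "A:ALA:10",
                         pathParams(delta = 3, topK = 25), apd)
paths
residueUtilization(paths, helixAnnotation = couplingStudyHelices())
```

For file-based work, `loadEnsemble()` reads single- and multi-model
PDB and DCD trajectories (solvent and monatomic ions are stripped on
load), `superpose()` aligns them, and the same chain of calls applies.
`runPipeline()` orchestrates the whole analysis — including
variant-versus-reference percent-change tables, which are refused
whenever a count was truncated by `maxPaths` — and writes
deterministic, timestamp-free reports.

## Known limitations

* XTC trajectories are not read (no R-level reader is available to
  this package); convert to DCD or multi-model PDB first.
* The suboptimal-path count is exact but exponential in the worst
  case; the `maxPaths` bound (with an explicit truncation flag) is the
  only guard. Comparisons between truncated counts are refused rather
  than estimated.
* Correlation here is the linear normalized covariance; mutual
  information and time-lagged variants are out of scope.
* Well detection is a reporting aid with heuristic window/depth
  parameters, not an inferential procedure.
* The synthetic generator's exactness rests on the shared fluctuation
  axis; its ensembles exercise the analysis machinery, not the physics
  of real proteins.
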
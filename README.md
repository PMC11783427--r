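# allopath

Dynamical network analysis of allosteric communication in molecular
coordinate ensembles.

Ligands that barely differ chemically can differ enormously in how they
activate a receptor, and the difference is often dynamical rather than
structural: the ligand re-weights the network of correlated motions
that carries signals from the binding pocket to a distal functional
surface (in nuclear receptors, the coregulator-binding AF-2 surface
around helix 12). `allopath` implements the standard
correlation-weighted residue-network analysis used to expose such
mechanisms, for structural biologists and simulation groups who have
trajectories (or want exact synthetic test beds) and need the full
chain from coordinates to communication statistics.

## The method

Given an ensemble of frames:

* each protein residue is a node (represented by its Cα), the ligand
  is one node (heavy-atom centroid), coregulator-peptide residues are
  nodes of their own kind;
* nodes are connected when their heavy atoms come within **4.5 Å in at
  least 75% of frames** (sequence neighbours excluded); replicate
  occupancies are averaged before thresholding;
* each edge is weighted **w = −ln |C_ij|**, where C_ij is the
  normalized cross-correlation of positional fluctuations, so strong
  correlation makes a short edge;
* **Floyd–Warshall** gives all-pairs optimal ("shortest-distance")
  path lengths; all simple source→sink paths within an offset δ of the
  optimum are enumerated exactly by **branch-and-bound depth-first
  search** (default δ = 100, top 1000 retained);
* per-residue **utilization** histograms, **shortest-distance
  profiles** with well detection, and geometric panels (pair/COM
  distances, contact fractions, hydrogen-bond occupancy, aromatic
  ring-centroid separations) summarize the result;
* a synthetic helical-bundle generator with planted block correlations
  provides exact oracles for every stage, and a frozen
  "planted-coupling rerouting" study reproduces, at desk scale, how
  strengthening ligand–H7 and H5–H7 coupling redirects communication
  through H5.

## Worked example

The bundled study: a three-helix bundle whose ligand contacts helices
S (sink) and H7, with coupling ρ planted on the ligand–H7 and H5–H7
pairs.

```r
library(allopath)

spec  <- couplingStudySpec(rho = 0.8, seed = 1)   # strong coupling
ens   <- sampleTrajectory(spec)
nodes <- defineNodes(ens, "protein", "ligand")
graph <- buildGraph(contactMap(ens, nodes),
                    computeCorrelation(ens, nodes))
graph
#> WeightedGraph: 37 nodes, 43 edges

apd   <- floydWarshall(graph)
paths <- suboptimalPaths(graph, source = nNodes(graph),
                         sinks = "A:ALA:10",
                         pathParams(delta = 3, topK = 25), apd)
paths
#> PathSet: L:LIG:1 -> {A:ALA:10}
#>   L_opt = 1.0536, 72 path(s) within delta = 3, 25 retained

u <- residueUtilization(paths, helixAnnotation = couplingStudyHelices())
round(attr(u, "helixUtilization"), 1)     # % of paths touching each helix
#>   S  H5  H7
#>  64  84 100
```

The optimal ligand→sink path costs 1.05 and 72 simple paths lie within
δ = 3 of it; 84% of the top 25 paths traverse the relay helix H5 even
though the ligand never touches it. Sweeping ρ down to 0.2 with the
same seed shows the rerouting collapse:

```r
low  <- runCouplingStudy(0.2, seed = 1)
high <- runCouplingStudy(0.8, seed = 1)
compareToReference(high$pathCount, low$pathCount)
#> [1] 125                      # +125% more paths at strong coupling
c(low$meanLength, high$meanLength)
#> [1] 5.22 2.74                # shorter = stronger communication
c(low$h5Well, high$h5Well)
#> [1] FALSE TRUE               # H5 well appears only at strong coupling
```

Mean top-k path length nearly halves, and the shortest-distance
profile develops a well over the H5 block that is absent at weak
coupling — the desk-scale signature of coupling-driven rerouting.

For real data, `loadEnsemble("topology.pdb", "traj.dcd")` reads the
trajectory (solvent stripped on load), `superpose()` aligns it, and
the same calls apply; `runPipeline()` orchestrates multi-variant runs
with percent-change tables against a reference complex. A thin CLI
lives at `inst/scripts/allopath.R`. The methods vignette
(`vignettes/allosteric-network-analysis.Rmd`) documents the model,
parameter choices and limitations.

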
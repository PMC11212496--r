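# complexmodules

Graph-theoretic prediction of biological modules in the quaternary
structure of protein complexes.

Large protein complexes are built from tens to hundreds of protein chains
whose function is organized in modules — groups of chains that assemble,
move, or work together. `complexmodules` predicts such modules directly
from a deposited structure (mmCIF or legacy PDB):

1. **Complex graph.** The structure is abstracted into an undirected,
   labelled, weighted graph *G = (V, E, W)*: vertices are the protein
   chains, and the weight of edge *(i, j)* counts the residue–residue
   contacts between chains *i* and *j* under a sphere model for atoms
   (radius 2.0 Å for protein atoms, 3.0 Å for ligand atoms; two atoms are
   in contact when their spheres overlap, two residues when ≥ 1 atom pair
   is, two chains when ≥ 1 residue pair is).
2. **Structural modules.** The graph is partitioned by a from-scratch
   implementation of the Leiden community-detection algorithm maximizing
   generalized weighted modularity

   *Q = Σ_c [ w_in(c)/m − γ (s(c)/2m)² ]*

   with resolution γ = 1 by default, using a best-of-N independent-runs
   protocol (default N = 2000, max-Q partition kept).
3. **Evaluation.** Predicted partitions can be scored against a reference
   chain-to-module assignment with the adjusted Rand index, and the
   inter-module interface weights (a proxy for relative rigidity vs
   flexibility of boundaries) are summarized in a module report.

The package is aimed at structural bioinformaticians who want a fast,
reproducible module hypothesis for a complex — e.g. to plan or interpret
experiments — without molecular dynamics. It includes GML graph I/O,
geometric-centre layouts for plotting, synthetic fixture generators with
planted ground truth, an exhaustive modularity oracle for small graphs,
and a command-line front end.

## Worked example

```r
library(complexmodules)

# a synthetic two-module assembly: 2 modules x 3 chains x 20 residues
fx <- generate_planted_structure(2, 3, 20, path = "planted.cif")

s <- parse_structure("planted.cif")
#> complex_structure 'SYNTH' (mmcif): 6 chains (6 polypeptide), 120 atoms

m <- chain_contact_counts(s)          # symmetric residue-contact counts
m["A", "B"]
#> [1] 20

g <- build_complex_graph(m)
#> complex_graph: 6 vertices, 4 edges, total weight 80

res <- cluster_best_of(g, n_runs = 2000, base_seed = 1)
#> clustering_result: 2 modules, best Q = 0.500000 (gamma = 1, 2000 runs, base seed 1)
#> run Q: min 0.500000 / median 0.500000 / max 0.500000

res$best
#> A B C D E F
#> 0 0 0 1 1 1

adjusted_rand_index(res$best, fx$truth)
#> [1] 1

module_report(g, res$best)
#> module_report: 2 modules, total weight 80, intra fraction 1.0000
#>
#> Per-module:
#>  module_id size intra_weight
#>          0    3           40
#>          1    3           40
#>
#> No inter-module interfaces (modules are disconnected).
```

The planted structure puts chains A–C and D–F in two spatially separated
blocks; adjacent chains within a block share exactly one contact per
residue (20), blocks share none. The pipeline recovers the planted
partition exactly (ARI 1), with Q = 0.5, the analytic optimum for two
equal disconnected modules. On a real structure the same calls apply with
`parse_structure("<entry>.cif")`, and the module report's inter-module
weights show which module boundaries are weakly coupled.

## Command line

```sh
complexmodules simulate    --out demo                      # planted mmCIF + truth
complexmodules build-graph --input demo/planted.cif --out demo
complexmodules cluster     --gml demo/graph.gml --out demo --runs 2000 --seed 1
complexmodules evaluate    --partition demo/partition.tsv \
                           --reference demo/truth.tsv --gml demo/graph.gml
complexmodules run         --input demo/planted.cif --out demo   # all of the above
```

The script lives at `inst/scripts/complexmodules` (installed under
`system.file("scripts", package = "complexmodules")`). Exit codes: 0
success, 2 input error, 3 degenerate input.

## Documentation

The methods vignette (`vignettes/complex-graph-modules.Rmd`) describes the
contact model, the Leiden implementation and its parameters, the numerical
conventions, what the synthetic generators do and do not emulate, and
known limitations.
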
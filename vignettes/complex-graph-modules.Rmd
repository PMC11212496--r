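---
title: "Predicting structural modules in protein complexes from chain contact graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting structural modules in protein complexes from chain contact graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Large protein complexes — respiratory chain complexes, chaperonins, virus
capsids — are assemblies of tens to hundreds of protein chains, and their
function is organized in modules: groups of chains that assemble together,
move together, or carry out one catalytic step. `complexmodules` predicts
such modules from nothing but the quaternary structure, by abstracting the
complex into a **complex graph** $G = (V, E, W)$: each protein chain is a
vertex, an edge connects two chains that touch, and the edge weight is the
number of residue–residue contacts across that interface.

Contacts are defined by a sphere model for atoms. Every atom of a polymer
residue carries a sphere of radius 2.0 Å, every atom of a ligand residue
3.0 Å. Two atoms are in contact when their spheres overlap (centre distance
at most the sum of the radii, so 4.0 Å for a protein–protein pair and
5.0 Å for a protein–ligand pair); two residues are in contact when at least
one of their atom pairs is; two chains are in contact when at least one of
their residue pairs is. A residue pair contributes 1 to the edge weight no
matter how many of its atom pairs overlap. The model deliberately ignores
chemistry — no per-element van der Waals radii, no hydrogen-bond typing —
because the quantity of interest is the *amount* of shared interface, for
which a uniform-radius count is a robust proxy.

Modules are then predicted by partitioning the complex graph to maximize
generalized weighted modularity

$$
Q(M) \;=\; \sum_{c \in M} \left[ \frac{w_{\mathrm{in}}(c)}{m}
  - \gamma \left( \frac{s(c)}{2m} \right)^{\!2} \right],
$$

where $m$ is the total edge weight, $w_{\mathrm{in}}(c)$ the weight inside
module $c$, $s(c)$ the summed vertex strengths of $c$, and $\gamma$ the
resolution parameter. High-$Q$ partitions group chains that share much more
interface with each other than a degree-preserving random rewiring would
predict; the hypothesis is that these well-connected groups correspond to
biological modules.

## The clustering procedure

Modularity is optimized with a from-scratch implementation of the Leiden
algorithm. Each run starts from the singleton partition and iterates three
phases:

1. **Local movement** — vertices are visited in a seeded random queue; each
   is moved to the neighbouring (or empty) module with the largest positive
   $\Delta Q$, ties broken uniformly at random. Neighbours of a moved
   vertex re-enter the queue.
2. **Refinement** — inside each module, starting again from singletons,
   still-singleton vertices that are well connected within their module
   merge into a sub-community chosen among well-connected candidates with
   $\Delta Q \ge 0$, with probability proportional to
   $\exp(\Delta Q/\theta)$.
3. **Aggregation** — the refined sub-communities become the vertices of a
   weighted aggregate graph (internal weight preserved as self-loops), and
   the aggregate starts from the partition the local move produced, not
   from singletons.

The phases repeat until no further improvement is possible. Aggregation
preserves $Q$ exactly, and the local move only ever increases it, so $Q$ is
monotone non-decreasing over the whole run; `leiden_once(check = TRUE)`
asserts both facts on every iteration and is exercised that way in the test
suite.

Vertex processing order is random, so different runs can end in different
local optima. The pipeline therefore uses a **best-of-N protocol**
(`cluster_best_of()`): N independent runs with consecutive seeds, keeping
the partition with the highest $Q$ (ties go to the earliest seed). The
default is N = 2000, which on complex-graph-sized problems (tens to
hundreds of vertices, graph diameter small) makes the protocol's output
stable across base seeds in practice.

Two design points were genuinely open and are resolved as follows. First,
the direction of randomness in the local move: we use a *greedy* best-gain
move with random tie-breaking, and keep the
probability-proportional-to-gain randomized selection in the refinement
phase only, following the original Leiden formulation; with best-of-2000
selection the two readings converge on the same optima for the graph sizes
this package targets. Second, the refinement temperature $\theta$ is not a
published parameter of the pipeline; we use 0.01, the Leiden method's
customary default. Both parameters are exposed (`theta`, `gamma`) rather
than hard-coded.

All randomness flows through R's Mersenne–Twister generator with
`sample.kind = "Rejection"`, seeded per run, and the caller's RNG state is
saved and restored, so results are bit-reproducible from
`(graph, gamma, theta, base_seed, n_runs)` alone.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r_protein` | 2.0 | Å | sphere radius of polymer-residue atoms |
| `r_ligand` | 3.0 | Å | sphere radius of ligand-residue atoms |
| `gamma` | 1.0 | — | modularity resolution; larger values favour more, smaller modules |
| `theta` | 0.01 | — | refinement randomness temperature |
| `n_runs` | 2000 | — | independent Leiden runs in the best-of protocol |
| `exclude_ligands` | `FALSE` | — | drop ligand residues from contact counting |
| `min_edge_label` | 30 | contacts | display threshold for edge labels in the layout annotation (presentation only) |

Plain modularity optimization has a resolution limit: in very large graphs
it can refuse to split a merged pair of true modules, or over-split. The
resolution parameter `gamma` is the provided handle; scanning it is left to
the user.

## Numerical choices and degenerate inputs

* **Boundary condition.** Distance exactly equal to the radius sum counts
  as contact (`<=`). Tangency is otherwise ill-defined at the 3-decimal
  coordinate precision of deposited structures.
* **Altlocs.** Within a residue the alternate-location code with the
  highest occupancy is kept (ties: lexicographically smallest code);
  atoms without a code are always kept.
* **Solvent** (HOH/DOD/WAT) never reaches contact computation. Ligand
  residues riding on a polypeptide chain's ID count toward that chain's
  edges unless `exclude_ligands` is set; detached ligand-only chains are
  dropped from the vertex set with a warning.
* **Edgeless graphs** have $Q = 0$ by convention for every partition; both
  the Leiden run and the exhaustive oracle resolve the tie to singletons.
* **Tie-breaks.** Module ids are canonicalized by the smallest contained
  vertex label (C-locale), so partitions are comparable across runs,
  sessions, and platforms.
* **ARI.** The binomial-coefficient sums of the adjusted Rand index are
  accumulated before any division; the index is evaluated on the
  intersection of the prediction's and the reference's chain sets, and a
  zero denominator (both assignments degenerate in the same way) returns
  1.0.
* The spatial grid uses cell edge $2\max(r_\mathrm{protein},
  r_\mathrm{ligand})$, which guarantees all contact partners of an atom lie
  in the 27 surrounding cells; the brute-force engine
  (`method = "brute"`) is retained as an in-package reference and the two
  are asserted equal on randomized fixtures.

## What the synthetic generators emulate

`generate_planted_structure()` builds CA-only pseudo-chains: straight
residue runs at 3.8 Å spacing (the CA–CA virtual bond length), chains of
one module stacked 3.5 Å apart (inside the 4.0 Å protein contact
threshold), module blocks 12 Å apart (outside every threshold). The
defaults therefore plant a *known* block-diagonal contact matrix: exactly
`residues_per_chain` contacts between adjacent chains of a module, zero
between modules, which makes the expected graph computable by hand. An
optional seeded jitter roughens the geometry for property tests. A
`seed` is honoured even in the deterministic default case so the fixture
interface is uniform.

`generate_planted_graph()` skips geometry and plants the partition
directly: complete intra-module cliques at weight `w_in`, inter-module
edges with probability `p_out` at weight `w_out`. The recovery tests run
in the strong-separation regime (`w_in/w_out = 10`, `p_out = 0.1`, four
modules of five vertices).

These fixtures validate the machinery, not the biology: real complexes
have irregular interface sizes spanning orders of magnitude, ligand-mediated
contacts, pseudo-symmetry, and genuinely ambiguous module boundaries.
Passing the planted-recovery tests shows the pipeline is correct and
self-consistent, not that modularity optimization recovers the "true"
biological modules of an arbitrary complex — on real structures the output
is a hypothesis to be read against experimental evidence, and the
inter-module interface weights in `module_report()` indicate which
boundaries are weakly coupled (candidate flexible regions) and which are
not.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on generated
fixtures: planted structures up to 3 modules × 3 chains × 25 residues
(hundreds of atoms), planted graphs up to 48 vertices, and random weighted
graphs of 4–9 vertices where the exhaustive oracle (at most
Bell(9) = 21147 partitions) is feasible. Best-of-200 is used against the
exhaustive oracle — already far past the point where more runs change the
outcome at these sizes — and best-of-2000, the full protocol, in the
end-to-end pipeline check. Deposited cryo-EM structures are processed with
the identical code path when the user supplies the files; the package does
not download them.

## Known limitations

* Polypeptide detection is heuristic (majority of standard amino acids
  among a chain's ATOM-record residues); exotic chimeric chains could be
  misclassified.
* Chains are identified by author chain ID; files that reuse an auth ID
  across entities merge those residues into one vertex.
* Only the first model of multi-model files is used, and no symmetry
  expansion is performed: the coordinates are taken as deposited, so the
  file must already contain the biological assembly.
* Modularity's resolution limit is inherited; `gamma` is exposed but not
  auto-tuned.
* The exhaustive oracle is limited to 10 vertices by design.
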
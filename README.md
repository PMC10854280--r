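# bncontrol

Modular decomposition, canalization analysis, and phenotype control of
synchronous Boolean network models of gene regulation.

Boolean networks are a workhorse model for intracellular regulatory
systems: each gene or protein is a binary variable `x_i`, and an update
rule `f_i` computes its next value from the current state, all variables
updating simultaneously (`F : {0,1}^n -> {0,1}^n`, `x(t+1) = F(x(t))`).
The long-run behaviours of such a model are its **attractors** — minimal
state sets `C` with `F(C) = C` — and in biological applications these
correspond to cell phenotypes (proliferation, apoptosis, ...).  The
control problem is to find interventions (edge deletions or constant
expressions, node knock-outs or constitutive expressions) after which the
network has a single attractor: the desired phenotype.

`bncontrol` makes this search tractable for structured networks by
implementing, in one package:

* **Exhaustive dynamics.** Trajectories, the state-transition graph, and
  complete attractor enumeration with basins, for networks up to a
  configurable size cap.
* **Modular decomposition.** The strongly connected components of the
  wiring diagram (the digraph of essential dependencies `x_i -> x_j`)
  define modules: restrictions of the network in which cross-module
  inputs become *external parameters*.  Modules are linked by an acyclic
  quotient graph, and the original network is recovered as a semidirect
  product `F = F1 ⋊_P F2` along the coupling `P`.
* **Compositional attractors.** Attractors of the whole network are
  direct sums `C = C1 ⊕ C2` of module attractors, where downstream
  modules are solved as non-autonomous systems `y(t+1) = H(g(t), y(t))`
  driven by the periodic trace of an upstream attractor.
* **Control operators and modular assembly.** Edge controls
  `x_i ->a x_j` (pin one input of one rule to `a`), node controls
  (knock-out / constant expression), stabilization checks, a brute-force
  minimal-control search per module, and a verified assembly of
  module-level controls into a global control with the direct-sum target.
* **Canalizing layers.** Every non-constant Boolean function has a unique
  extended monomial form
  `f = M1(M2(...(M_r p_C + 1)...) + 1) + q` over GF(2), stratifying its
  variables into dominance layers with layer structure `(k1, ..., kr)`;
  nested canalizing functions (NCFs) are those where every variable
  eventually canalizes.  The package computes this form, inverts it, and
  samples random NCFs with prescribed structure.
* **Module exclusion.** Combining layers with modularity: if the rules
  bridging an upstream module into a downstream one can be made
  independent of the upstream regulators by pinning a more dominant
  canalizing variable (node route) or a most-dominant-layer edge (edge
  route), the upstream module can be dropped from the phenotype control
  search entirely; modules with no path to any phenotype marker are
  dropped outright.

## Worked example

The bundled two-loop network couples a two-variable feedback loop
`(x1, x2)` into a second loop `(x3, x4)` through `x2`:

```r
library(bncontrol)
net <- bn_example("twoloop4")   # x1 <- x2, x2 <- x1, x3 <- x2 & x4, x4 <- x3
attractors(net)
#> [[1]] Attractor of length 1: {0000}
#> [[2]] Attractor of length 1: {1100}
#> [[3]] Attractor of length 1: {1111}
#> [[4]] Attractor of length 2: {0100, 1000}
#> [[5]] Attractor of length 2: {0101, 1010}
#> [[6]] Attractor of length 2: {1101, 1110}

d <- decompose(net)
d
#> ModularDecomposition: 2 module(s)
#>   M1: {x1, x2}
#>   M2: {x3, x4}
#>   DAG: M1->M2

# stabilize the whole network at 1111 with two edge controls found
# module by module: constant expression of x1->x2 and of x4->x3
cs <- control_set(edge_control("x1", "x2", 1), edge_control("x4", "x3", 1))
attractors(controlled_network(net, cs))
#> [[1]]
#> Attractor of length 1: {1111}
stabilizes(net, cs, as_attractor("1111"))
#> [1] TRUE
```

Canalizing layers, on the death-receptor rule of a published leukemia
model (`DISC <- Ceramide | (Fas & !FLIP)`):

```r
layer_decomposition(bn_example("disc")$functions$DISC)
#> CanalizingLayers: depth 3 of arity 3 (nested canalizing)
#>   layer 1 (output 1): Ceramide:1
#>   layer 2 (output 0): Fas:0, FLIP:1
#>   core polynomial: 1
```

Because the only variable in the most dominant layer (`Ceramide`) lies in
the upstream module, the single edge control `Ceramide ->1 DISC` pins
`DISC` to 1 and decouples the upstream module from the control search —
`excludable_modules()` reports exactly this.

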
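---
title: "Modular control of Boolean networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular control of Boolean networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bncontrol)
```

This vignette is the package's own account of the models and procedures
it implements: the synchronous Boolean network semantics, the modular
decomposition and its compositional attractor theory, the control
operators and their modular assembly, the canalizing-layer decomposition,
and the canalization-based exclusion of modules from a phenotype control
search.  It also records the numerical conventions and the design
decisions taken where more than one reasonable choice existed.

## The model and its assumptions

A Boolean network on variables `x1, ..., xn` is a map
`F = (f1, ..., fn) : {0,1}^n -> {0,1}^n`; at every time step all
variables update simultaneously (*synchronous* semantics — the only
update scheme this package implements; asynchronous and stochastic
schedules are out of scope).  Because the state space is finite and the
update deterministic, every trajectory is eventually periodic, and the
dynamics are summarised by the functional digraph on the `2^n` states
(out-degree exactly 1) and its cycles, the **attractors**.  Length-1
attractors are steady states; in regulatory-network applications the
attractors are read as cell phenotypes.

Update functions are stored as complete truth tables over an ordered
input list (first input = most significant bit; `x1` is the leftmost
character of every printed state).  Parsed rules are normalised to their
*essential* inputs — inputs whose toggling changes the output for at
least one assignment — with the removed names kept in an audit
attribute.  This matters because the **wiring diagram** is defined by
essential dependence only: an edge `xi -> xj` exists iff `fj` depends
essentially on `xi`, and all structural notions downstream (modules,
bridging nodes, controllable edges) refer to this diagram.

## Modules, couplings, and compositional attractors

The strongly connected components (SCCs) of the wiring diagram partition
the variables; connections between components run in one direction only.
Restricting the network to an SCC keeps those variables' rules and turns
every cross-component input into an **external parameter** (renamed
`e_<variable>`, a deterministic, collision-checked convention rather
than ad-hoc names like `e1, e2`).  These restrictions are
the **modules**; contracting each SCC gives the acyclic quotient graph.
The original network is recovered by the semidirect product, which
substitutes the coupled upstream variables back for the externals; the
decompose-then-recompose round trip is tested truth-table-exactly on
random two-module networks.

Module numbering follows a topological order of the quotient graph.
Among incomparable modules the one containing the smallest original
variable index comes first; this is purely a reproducibility device.

Attractors compose across modules by concatenation (direct sum): every
attractor of the full network is `C = C1 ⊕ C2 ⊕ ...` with `Ck` an
attractor of module `k` *driven by* the upstream attractor.  A driven
module is a non-autonomous system `y(t+1) = H(g(t), y(t))` with `g` the
periodic trace of upstream states.  No algorithm for the attractors of
such a system under a cyclic drive is prescribed by the theory the
package follows, so the package computes them exactly on the **product
space** of (drive phase, module state) — `p * 2^m` states for a drive of
period `p` and a module of `m` variables; each cycle of this product
system is one driven attractor, with its phase alignment recorded.  The
construction is validated against whole-network enumeration on randomly
generated decomposable networks (exact equality of attractor sets).
Two consequences worth knowing:

* under a period-1 drive the construction reduces to substituting
  constants and enumerating, as it should;
* composing two genuine cycles can yield several attractors (one per
  phase alignment, `gcd` of the periods many); composing with a steady
  state on either side always yields exactly one.  This is why the
  modular *control* assembly below insists on a steady state (or a
  verified unique orbit).

## Control operators and modular assembly

An **edge control** `xi ->a xj` replaces `xi` by the constant `a` inside
`fj` only (mod-2 form `fj(..., (mu+1)xi + mu a, ...)`); `a = 0` is edge
deletion, `a = 1` constant expression.  A **node control**
`(mu-, mu+)` maps `fj` to `(mu- + mu+ + 1) fj + mu+`: `(1,0)` knock-out,
`(0,1)` constant expression, `(0,0)` identity, `(1,1)` negation.  The
negation setting is rejected by default — it has no biologically
implementable counterpart — and can be re-enabled by a flag.  When a
control set is applied, edge controls act first and node controls
second; the order only matters formally, since a node control replaces
the whole function and dominates any edge control on the same target.

A control **stabilizes** the network at a target attractor when the
controlled network has that attractor as its *only* one.  The target may
well be a new attractor created by the control; stabilization is always
checked on the controlled network alone, never against the original
attractor list.

Module-level controls are found by exhaustive breadth-first search over
cardinalities: all node controls (variable order, knock-out before
expression), then all edge controls, combined up to `max_size`, keeping
every stabilizing set of the smallest successful cardinality.  This
deliberately substitutes brute force for the specialised module-control
algorithms of the literature (stable motifs, feedback vertex sets,
algebraic methods), which are out of scope here; any of them could be
plugged in at the module boundary, which is exactly the point of the
modular theory.

`assemble_modular_control()` implements the composition theorem as an
executable, *verified* operation: walking the modules in topological
order it checks — on the product space — that each module's control
yields a unique orbit realising its target under the drive induced by
the accumulated upstream target, concatenates the targets, lifts
module-local edge controls whose source is an external parameter back to
the original upstream variable, and finally re-verifies the assembled
claim by whole-network enumeration whenever the network is within the
cap.  A failed side condition (several orbits where one steady state was
needed) or a failed final verification raises an error; nothing is
returned silently.

## Canalizing layers

A function is *canalizing* when some variable has an input value that
forces the output on its own.  Stratifying this property gives the
unique extended monomial form over GF(2)

```
f = M1 (M2 ( ... (M_{r-1} (M_r pC + 1) + 1) ... ) + 1) + q ,
```

with each layer `Mi` a product of factors `(x + a)` (vanishing exactly
when `x` receives its canalizing input `a`) and `pC` the core
polynomial of the never-canalizing variables.  The package extracts the
layers by the standard stripping recursion: all canalizing variables of
`f` form layer 1; the variables that become canalizing once layer 1 is
excluded form layer 2; and so on.  Two mechanical facts tie the layer
outputs to the formula and are used for reconstruction:

* the canalized output of layer `i` is `q` for odd layers and `1 - q`
  for even ones (outputs of consecutive layers always differ);
* the core polynomial satisfies `pC = f_res XOR b_r`, where `f_res` is
  the restriction of `f` after all layers pass and `b_r` is the last
  layer's output.  For a nested canalizing function (depth = arity) the
  residual is constant and `pC ≡ 1` necessarily.

Degenerate and tie cases are fixed as follows.  Constant functions are
rejected with a distinct error (the form above excludes them; callers
that may produce constants — e.g. controlled rules — special-case them
before asking for layers).  An arity-one (sub)function `x` or `!x` is
canalizing in both directions; inside a recursion the output is forced
by alternation, and for a function that *is* a lonely variable the
convention `q = 0` (which the uniqueness statement's exceptional case
dictates) picks the representative.  Decomposition operates on essential
inputs only; non-essential inputs can never canalize a non-constant
function and are removed first.  Layer extraction scans whole truth
tables (the problem is NP-hard in general), so arity is capped at 16
with a clear error; published regulatory rules are far smaller.

`random_ncf()` inverts the form: it samples a layer assignment for a
prescribed structure, canalizing inputs, and the offset, honouring the
two exceptional cases (`kr >= 2` when there are several layers and
`pC ≡ 1`; `q = 0` for the lonely single-variable layer), and rebuilds
the truth table.  Recovery of the prescribed structure by
`layer_decomposition()` is a tested property, not an assumption.

## Phenotypes and module exclusion

A phenotype is a set of marker variables with required values; an
attractor matches when *every* state agrees on the markers — oscillating
markers match nothing, by the "identical on the markers" reading of the
definition.

Exclusion answers: which modules need not be searched for controls at
all?  Two routes are implemented.

1. *Reachability.*  A module with no directed path in the quotient graph
   to any marker-bearing module cannot influence the phenotype and is
   excluded outright, irrespective of canalization.
2. *Decoupling.*  For a quotient edge `i -> j`, the bridging nodes are
   the variables of `j` regulated by variables of `i`.  For each
   bridging rule the layer decomposition is computed and `ell` is the
   most dominant layer containing module-`i` regulators (`r + 1` when
   they only appear in the core).  If module-`i` regulators occupy the
   most dominant layer, pinning such a regulator's edge to its
   canalizing input decouples the modules (edge route); if some variable
   outside module `i` sits in a strictly more dominant layer, fixing it
   to its canalizing input does (node route).  Every proposal is
   verified exhaustively: the pinned bridging rule must be non-essential
   in all module-`i` regulators.  The strict single-bridge hypothesis is
   relaxed by treating each bridging node in turn, with a `strict` mode
   available.

Two design choices deserve a note.  First, when both routes offer
options, edge controls on most-dominant-layer inputs are ranked before
node controls: they pin exactly one interaction and assume nothing about
the rest of the network.  Second, the "chain" condition — that the
phenotype's dependence on module `i` runs entirely through `j` — is
implemented in `excludable_modules()` as an *edge-deletion* reachability
check: after removing the quotient edge `i -> j`, no marker module may
remain reachable from `i`.  This is deliberately stronger than requiring
every path from `i` to the markers to pass through `j` (the reading
exposed as `chain_condition()`): a path `i -> m -> j -> k` does pass
through `j`, yet decoupling only the direct bridge of `j` would leave
module `i` acting on `j` through `m`.  The edge-deletion form closes
that gap, at the price of occasionally declining an exclusion the weaker
condition would have granted.  The exported proposals additionally flag
that a dominant variable `y` may itself live in a third module; applying
a node control there shifts, rather than removes, intervention burden,
and the report keeps the module identity visible for that reason.

## Synthetic networks and what the tests do (and do not) show

`generate_modular_network()` emulates the structural situation all the
theory above addresses: a prescribed partition into modules, each
internally strongly connected (a spanning cycle plus sparse extra
edges), with at least one cross-module regulation per requested quotient
edge, and update rules drawn either uniformly (conditioned on all
regulators being essential) or from the nested canalizing family — NCFs
because published regulatory models are overwhelmingly governed by them,
uniform rules as the adversarial contrast.  Default problem sizes in the
test suite (modules of 2–4 variables, two to three modules, hundreds of
draws; random whole networks up to 8 variables against a brute-force
power-iteration oracle) were chosen so the whole suite enumerates every
case exactly in seconds on a single core.

What passing these tests shows: the implementation's decomposition,
composition, control assembly and layer algebra are mutually consistent
and agree with independent exhaustive oracles on the full distribution
of small structured instances, and the desk-scale worked examples
reproduce digit for digit.  What they do not show: behaviour of
sampling-free enumeration beyond the cap (large models need the modular
route by construction), anything about asynchronous dynamics, and
nothing about how faithfully a random ensemble represents any *specific*
biological model — for that, load the model's own rule file.

The bundled fixtures cover every small worked example; the 16-node
T-LGL leukemia case study is reproducible in its canalization part (the
DISC rule ships as a one-node fragment with external regulators) but the
full model's update rules are not bundled and must be supplied by the
user as a rule file (`bn_example("tlgl", path = ...)`).

## Numerical conventions, in one place

* Bit order: `x1` is the leftmost printed character and the most
  significant bit of state and truth-table indices.
* Attractors: rotated so the lexicographically smallest state is first;
  attractor lists sorted by (length, first state).  Driven orbits start
  at drive phase 0.
* Enumeration cap: 24 variables by default
  (`options(bncontrol.cap = ...)`), applied to `2^n` states and to
  `p * 2^m` product states; beyond it the exhaustive routes refuse with
  a pointer to the modular route.
* Layer decomposition: essential inputs only; arity cap 16; constants
  rejected; within-layer listing ordered by original input position.
* All randomised generators use R's global RNG: `set.seed()` gives
  bit-reproducible networks, functions, and searches.
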
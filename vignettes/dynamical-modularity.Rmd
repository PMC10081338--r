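---
title: "Pathway modules and dynamical modularity of Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway modules and dynamical modularity of Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynmod)
```

## The model

A Boolean network is a directed graph of automata; each node `x` holds a
binary state and is updated synchronously by a logical function of its
inputs, tabulated as a look-up table (LUT) over the `2^k` input rows.
Deterministic synchronous dynamics guarantee that every trajectory ends
in a fixed point or limit cycle; in biological models those attractors
stand for phenotypes. `dynmod` asks a different question than attractor
enumeration: *which node states are guaranteed to occur after perturbing
a small set of nodes, no matter what the rest of the network is doing?*

The answer exploits canalization. Most biological update rules are
redundant — a subset of inputs (the *enputs*) often suffices to decide
the transition. We remove this redundancy in two steps:

1. **Wildcard schemata `F′`**: Quine–McCluskey minimisation of the ON-set
   and, separately, the OFF-set of each LUT. Each prime implicant becomes
   a schema over `{0, 1, #}`; `#` marks inputs that are redundant given
   the enputs. Both polarities are redescribed because the map must
   explain how nodes turn OFF as well as ON.
2. **Two-symbol schemata `F″`**: schemata that are permutations of one
   another over symmetric input positions are merged; the permutable
   positions form a position-free *bundle* (`°`) carrying a multiset of
   required states. The regrouping is lossless — flattening `F″`
   reproduces `F′` exactly.

The schemata of all nodes assemble into the **dynamics canalization map
(DCM)**: s-units for every node state (`2n` of them), t-units for every
schema with threshold `τ` = number of enputs, and fibres connecting them
(merged fibres encode bundles). Signals travel instantly from s-units to
t-units and with a one-step delay from t-units to s-units, which
preserves the timing of the original synchronous dynamics.

### Firing semantics

The canonical firing rule is *schema certification*: a t-unit fires at
`t` exactly when the partial configuration formed by the s-units firing
at `t` guarantees its schema — every fixed position is known and equal,
and each bundle admits an injective assignment of its non-`#` states to
known matching positions. An unknown input never certifies a requirement.
The threshold representation is kept for structure and export; because a
mixed-state bundle could over-count naive signal sums, its threshold
contribution is defined as the size of the maximum such assignment
(`min(c1, r1) + min(c0, r0)` per bundle), and the test suite asserts the
two evaluations agree on every t-unit over the full `{0, 1, #}^k` input
grid. Constant nodes yield an all-`#` schema with `τ = 0` that fires
unconditionally — a constant automaton stabilizes on its own.

## Unfolding and its conventions

A *seed set* fires at `t = 0`. Under **pinning** the seeds fire at every
step (a sustained knock-out/over-expression); under **pulse** they fire
only once; mixed per-seed modes are supported. The unfolding
`μ: S^t -> S^{t+1}` iterates until termination and yields the pathway
module: slices `(S^t, θ^t)`, the module set `S` with first-fire times,
the length `T`, and a termination tag.

Conventions the formal definitions leave open were fixed as follows:

- **Termination and length.** Unfolding stops when a slice repeats.
  `T` is the index of the last *distinct* slice: a module whose second
  slice equals its first has length 0. Under pure pinning the fired set
  grows monotonically, so termination is always a fixpoint within `2n`
  steps; under pulse/mixed modes a repeated earlier slice is reported as
  a limit cycle with its period, and an empty slice terminates the module
  with the empty slice counted as `M^T`.
- **Contradictions.** A pinned seed blocks its opposite s-unit forever.
  Among derived s-units under pinning, the first-fired state wins; a
  derivation of both states of one variable cannot arise from prime
  implicants of complementary sets and raises an error if bookkeeping
  were ever wrong. Under pulse perturbation different states of a
  variable may fire at *different* steps (this is how limit cycles
  appear), but never within one slice.
- **Pulse simultaneity.** A multi-input t-unit fires only if all its
  required sources fire at exactly the same step; no temporal-window
  relaxation is applied.

Soundness is tested against an independent exhaustive oracle
(`brute_force_stabilization()`): for networks up to `n = 12`, every
completion of the unpinned variables is simulated (bit-vectorised over
integer-coded configurations) to its attractor, and every s-unit a
pinning module derives must hold at every step of every reached
attractor.

## Module algebra and covers

Interactions are decided on the unfolding of the union of seed sets:
synergy and obstruction by the set differences against the union of the
separate unfoldings, subsumption by set containment, temporal subsumption
by slice-wise containment under a shift, decoupling when there is no
overlap, obstruction, or synergy. A *maximal* module's set is not a
proper subset of any module set with seed size at most `s`; two modules
with identical sets are both retained (the containment test is proper)
and deduplicated only in the cover pool. A *complex* module is maximal
with every nonempty seed bipartition synergistic (checked over all
`2^(s-1) - 1` unordered bipartitions; `s` is capped at 6 by default).
A *core* complex module additionally has every single seed generate a
maximal `s = 1` module (the maximal seed heuristic).

On the bundled six-node example network the formal bipartition test
admits four complex modules at `s = 2`; two of them are seeded on states
of the gene `g2` whose singleton modules are not maximal, and the core
filter removes exactly those, leaving the two modules the analysis
reports. Cover optimisation therefore draws its candidates from the core
complex modules by default (`core = FALSE` widens the pool).

Covers are solved two ways:

- **Exact**: depth-first branch and bound over the candidate pool ordered
  by decreasing module size, pruning on unreachable coverage, on the
  cover-size cap `q`, and on an upper bound for the attainable mean
  (chosen modules can only lose independence as the cover grows; open
  slots score at most 1). A minimum-cardinality cover is reported
  alongside, with ties broken by higher mean and then lexicographic seed
  sets.
- **Greedy**: iteratively add the candidate with the highest independence
  from the current selection; ties go to the larger module set, then the
  smaller seed set, then lexicographic seed names. The greedy mean is a
  lower bound on the exact optimum; on the example network at `s = 2` it
  finds a four-module cover scoring 0.64 against the exact 0.83,
  illustrating the documented sub-optimality.

All unit-name orderings use C-locale (radix) sorting so results are
byte-identical across locales. Scores are reported unrounded;
`round_half_up()` matches the half-up convention of printed two-decimal
values (the example network's optimal two-seed cover scores exactly
33/40 = 0.825, printed as 0.83).

## Synthetic data

Two generators stand in for external model files:

- `generate_random_bn(n, k, bias, seed)` draws `k` distinct inputs per
  node and i.i.d. Bernoulli(`bias`) LUT outputs on a private RNG stream.
  The property suites run it at `n ≤ 12`, `k ≤ 3`, `bias = 0.5` —
  in-degree and size chosen to match the sparse logical models the
  method targets while keeping the exhaustive oracle exact. Random
  networks exercise the algebraic invariants (semantic equivalence of
  `F/F′/F″`, oracle soundness, interaction identities, greedy ≤ exact),
  not biological structure: they lack the long canalizing cascades and
  input hierarchy of curated models, so passing them shows correctness
  of the machinery, not performance on real networks.
- `load_fixture("spn_cell_synthetic")` is a *synthetic reconstruction*
  of the 17-node single-cell Drosophila segment-polarity Boolean model,
  written from the model's standard published update equations; the
  authors' distributed file is not bundled. The reconstruction
  reproduces the published pathway/complex module counts at seed sizes
  1–4 (34/14, 544/9, 5440/19, 38080/14), the module sizes
  `|S(en-1)| = 9` and `|S(nWG-1, SLP-0, nHH-1)| = 17` (a verified fixed
  point), the `s = 1` optimal cover (14 modules, `D̄ = 0.69`), and the
  input-cover infeasibility (SMO-0 and CIR-1 unreachable from input
  pinning). Two published quantities disagree with the reconstruction
  (`|S(PTC-1)|` and the `s = 3` optimal-cover score), consistent with a
  small variant in the published SMO/PTC rules; they are not asserted.
  The four-cell parasegment composition
  (`spn_parasegment_synthetic`, `n = 60`) reproduces the published
  `s = 1` analysis: 40 complex modules of 120, greedy cover of 40
  modules with `D̄ = 0.83`, and `|S(en-1)| = 13`.

## Problem sizes and numerical choices

The test suite runs the schemata equivalence property on 500 random LUTs
(`k ≤ 8`, exhaustive over input rows), unfolding soundness on 200 random
networks (all single-seed plus 50 two-seed sets each), interaction
identities on all single-seed module pairs of those networks, and the
cover bounds on 25 networks; the synthetic segment-polarity checks go to
seed size 3 (5440 modules) for the single cell and size 1 for the
parasegment. These sizes keep the whole suite in a few minutes while
leaving every property exhaustive at its scale. Plateau detection for
`s*` uses an `1e-9` tolerance on the increase of `D̄`; branch-and-bound
comparisons use `1e-12` slack so floating-point ties never flip a cover.

## Limitations

Only synchronous deterministic updates are modelled; asynchronous
robustness of modules is untested. Enumeration of seed sets is
exponential in `s` (capped, default 6), and exact covers are NP-hard —
beyond desk scale the greedy estimate is the intended tool. Two-symbol
symmetry detection is exhaustive and reverts to pass-through above
`k = 12` inputs with a warning (semantics are unaffected; only
compression is lost). Multi-valued automata are out of scope.
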
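---
title: "Methods: context-free sketching in reverse-complement space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-free sketching in reverse-complement space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmersketch)
```

## Model

A context-free sketching scheme over the alphabet Σ = {0, …, σ−1}
(σ even; DNA is A=0, C=1, G=2, T=3) is a set φ ⊆ Σ^k: the sketch of a
sequence S is the set of offsets whose k-mer lies in φ. All questions
about worst-case behaviour reduce to the de Bruijn graph B_k (nodes = all
σ^k k-mers, edge u→v when the (k−1)-suffix of u is the (k−1)-prefix of v):

* φ **decycling** (B_k∖φ a DAG) ⟺ *strong window guarantee*: on any
  sequence, consecutive selected positions are at most
  `longest_path(φ) + 1` apart.
* Only the σ homopolymer self-loops surviving ⟺ *relaxed guarantee*
  (only low-entropy runs escape).
* Any other surviving SCC ⟺ no guarantee: walking inside an SCC spells
  arbitrarily long unselected sequences (`scc_walk_sequence()` constructs
  them; `find_deserts()` finds the resulting deserts in given sequences).

Reverse complementation is the involution rc(m) = complement of the
reversed word, with a ↦ σ−1−a. A scheme is **symmetric** if φ = rc(φ) —
the property double-stranded data requires. Canonicalization
φ_c = {m : min(m, rc(m)) ∈ φ} is symmetric but can lose entire pure
cycling registers (PCRs, the rotation cycles partitioning B_k): a PCR
whose φ-members are all non-canonical is uncovered in φ_c. The union
φ_u = φ ∪ rc(φ) is symmetric and never creates new SCCs, at the price of
up to doubling the density; `greedy_sparsify()` then removes rc-orbits
while SCCs do not grow, and `solve_symmetric_mds()` designs symmetric
decycling sets of provably minimum size.

## Key algebraic facts the code relies on

* Rank encoding is base-σ, first character most significant, so integer
  order = lexicographic order and `canonical = pmin(rank, rc(rank))`.
* Successors of rank r are `(r mod σ^(k−1))·σ + a`; the graph is never
  materialized as a global edge list — induced subgraphs are built
  arithmetically from the kept ranks (SCC and DAG work is delegated to
  igraph, which uses non-recursive algorithms).
* A nonnegative matrix is nilpotent iff A^t e = 0 for some t ≤ n, and the
  smallest such t (the nilpotent index) equals longest path + 1 on a DAG.
  `nilpotency_check()` is an independent oracle for the graph route and
  the two are cross-asserted in the tests.
* Number of PCRs = number of σ-ary necklaces, computed by Burnside's
  formula; it is also the cardinality of every minimum decycling set.

## Path-length convention

`longest_path()` counts **edges**, so "nilpotent index = longest_path + 1"
is literally true and the window bound is `longest_path + 1` positions.
Published tabulations of these constructions print the number of k-mers
on the path (= edges + 1); `scripts/acceptance.R` converts accordingly.
We verified the convention independently: the exhaustive search over all
2^16 symmetric orbit subsets at σ=2, k=5 has minimum cardinality 12 with
minimum longest remaining path 5 edges = 6 k-mers.

## Embedding constructions and their fixed conventions

`mykkeltveit_set()` embeds m at W(m) = Σ_j m_j ω^j, ω = e^{2πi/k}
(left rotation multiplies W by ω^{−1}) and keeps, per PCR, the unique
rotation with Arg W ∈ (π − 2π/k, π] — the last rotation in the upper
half-plane before crossing the negative real axis. Free conventions had
to be fixed where the classical description is silent; our choices are:

* **sector boundary**: right-closed at π, anchored at π − 2π/k. Anchors
  outside a narrow window around this value produce sets that are *not*
  decycling (we scanned all distinct sector sets exhaustively at small k).
* **zero-weight PCRs** (periodic k-mers, whose embedding collapses to the
  origin): odd primitive period → minimum-rank rotation; even primitive
  period → recurse on the primitive root class in B_d with the same rule.
* **primitive zero-weight PCRs** (possible for σ=4 with composite k,
  where distinct digit patterns can cancel): first non-vanishing
  derivative weight Σ_j j^p m_j ω^j, same sector. On zero-weight classes
  this weight again rotates cleanly under rotation, so the sector picks a
  unique element.

With these conventions the construction is one-per-PCR and decycling for
every tested (σ, k) (σ=2 up to k=10, σ=4 up to k=7) and reproduces the
classic per-k statistics (cardinalities, φ_u sizes, longest paths at
σ=2, k=5..7 and σ=4, k=7). Known deviation: at σ=2, k=8 our set leaves a
longest path of 39 edges where the historical implementation reports 38;
the zero-class convention responsible could not be identified from
available sources (no single convention we enumerated reproduces the k=6,
k=8 paths and the k=8 union size simultaneously). None of the headline
quantities depends on it.

`champarnaud_set()` historically refers to a Lyndon-decomposition-based
minimum decycling set. That rotation rule is not reconstructible from the
sources available to this package (several run-recoding/Lyndon candidates
we implemented fail to decycle beyond k=4), so the function ships a
clearly documented **synthetic stand-in**: the same embedding machinery
with the opposite boundary convention ([π − 2π/k, π)) and fully recursive
zero-class handling. It is deterministic, one-per-PCR, decycling across
the supported range, and distinct from `mykkeltveit_set()` at every
tested k — adequate for every downstream use in this package (its
cardinality, the only quantity consumed elsewhere, is forced for any
MDS). Path-length statistics specific to the historical set are not
reproduced.

## Schemes

* `syncmer_set(k, σ, s, t, order)`: selected iff the left-most minimal
  s-mer sits at offset t. Ties between equal s-mers break by position
  only — this left-most rule is what yields the t = 0 strong guarantee
  and the sesqui-power relaxed guarantee for small t.
* `parameterized_syncmer_set()`: offset may fall anywhere in a mask;
  mask ∋ 0 ⇒ decycling.
* `fractional_set(k, σ, f, seed)`: the `round(f·σ^k)` first k-mers under
  a seeded permutation; exact cardinality by construction, no guarantee.
* Orders are R-native seeded permutations (`sample.int` under a locally
  saved/restored RNG state) rather than a counter-based hash; the seed is
  recorded in the returned object and in every file the CLI writes, which
  is the reproducibility property that matters here.

## Sequences, deserts, and the synthetic generator

Coordinates are 0-based half-open. A desert is a maximal base interval of
length ≥ L (default 50, the short-read anchoring regime) containing no
*selected k-mer start*; sequence ends count as boundaries, but an
interval must contain at least one possible start — the trailing k−1
bases alone never form a desert (they extend a preceding one). Ambiguous
characters (N) make a window unselectable and do **not** reset desert
accounting; an all-ambiguous desert is flagged so both interpretations
remain recoverable. Scanning is forward-strand only: strand handling
belongs to the set (use a symmetric one), and for symmetric sets the
tests assert exact mirror symmetry of offsets and desert mass.

`random_sequence()` generates i.i.d. uniform symbols — it emulates the
null model under which relative set size equals expected density. It does
not emulate repeats, composition bias, or ambiguity runs of real genomes,
so a green density test establishes calibration under the null model
only; the adversarial generator `scc_walk_sequence()` covers the opposite
extreme (worst case), and real-data behaviour lies between.

## Exact symmetric design

`nilpotent_problem()`/`build_mns_model()` formulate: maximize kept weight
subject to the kept submatrix satisfying A_Γ^{t+1} e_Γ = 0, with one
binary variable per rc-orbit (symmetry by variable identification — the
same feasible region as a basis change (v + rc(v))/2 for selection
problems) and level variables `level_j ≥ level_i + 1 − (t+1)(2 − x_i −
x_j)`, big-M exactly t+1. No MIP solver is available in the target
environment, so `solve_mns()` solves the model exactly by
branch-and-bound over the orbit variables; feasibility of partial
assignments uses the equivalent DAG/longest-path condition (keeping is
monotone, so violations prune). Stages: (1) minimize removed
cardinality with t = n; (2) fix it and minimize t by bisection with
repeated feasibility solves (t is a constraint parameter, not a
variable); (3, optional) minimize expected absorption time among stage-2
optima by enumeration. Every solution is re-verified through
`is_symmetric()`, `is_decycling()` and `longest_path()` before being
returned, and `brute_force_symmetric_mds()` provides a fully independent
exhaustive oracle (≤ 20 orbits). Practical envelope: σ=2, k ≤ 8 (k=5
solves in seconds; the cost is exponential beyond — by design, this is
the exact reference, not a scalable heuristic).

`expected_absorption_time()` implements
E = e'(Σ_{j≥1} Ã_Γ^j) p_Γ — the expected number of *unselected* k-mers a
uniform random walk visits after its start before absorption (one less
than the absorbing step index; the Monte-Carlo oracle in the tests
measures exactly this). Both start conventions are exposed because
"rescaled uniform" is ambiguous: `"remaining"` (renormalized over
unselected k-mers, the default) and `"all"` (mass on selected k-mers
absorbed at time 0).

## Numerical choices and degenerate inputs

* Ranks are doubles; exact up to 2^53, with a materialization guard at
  2^22 k-mers for whole-space operations. Closed-form quantities
  (necklace counts, relative sizes) work far beyond, e.g. σ=4, k=15.
* Sector membership uses a 1e-8 modulus tolerance and an 1e-9 angular
  nudge encoding the closed side; weight arguments of interest sit on an
  exact grid well away from these tolerances.
* Empty sets, full sets, sequences shorter than k, empty masks, and
  non-symmetric greedy inputs all error or warn explicitly rather than
  guessing.
* `sketch_density` is the spec's `density` renamed to avoid masking
  `stats::density`.

## Known limitations

* Full-scale audits (σ=4, k=15) of SCC percentages are supported by the
  code path design (arithmetic successors, no global edge list) but not
  exercised at that scale here; tests demonstrate the identical
  phenomena exhaustively at small (σ, k).
* The greedy sparsifier recomputes SCCs after each tentative removal
  (correctness over speed; runtime grows exponentially in k).
* The historical Champarnaud rotation rule, and the zero-class
  convention behind one k=8 path statistic, remain open (see above).
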
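---
title: "Posterior-probability alignment with selective consistency: models and methods"
author: "probmsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior-probability alignment with selective consistency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probmsa)
```

# The problem

Progressive multiple sequence alignment greedily merges sequences and
profiles in guide-tree order, so a mistake made low in the tree is frozen
into every later merge. Two families of countermeasures exist: *consistency*
(prevent mistakes by making each pairwise decision agree with the evidence
carried by third sequences) and *iterative refinement* (repair mistakes by
re-splitting and re-aligning the finished alignment). Both degrade on large
protein families — consistency because each pairwise matrix is averaged with
hundreds of increasingly noisy product terms, refinement because random row
splits almost never expose removable gap columns when there are many rows.
`probmsa` implements the two remedies this package is organized around:
**selective consistency**, which relaxes each posterior matrix only over
informative third sequences and re-amplifies the surviving original signal,
and **column-oriented refinement**, which splits on a gapped column so that
at least one profile is always shortened, accepting candidates under a
non-increasing alignment-length rule.

# Stage I — pairwise posterior probabilities

For every pair `x, y` the package computes the matrix `S_xy` with
`S_xy[i, j] = P(x_i ~ y_j)`, the probability that residue `i` of `x` is
aligned to residue `j` of `y`, marginalized over all global pairwise
alignments under two models, then averaged cellwise:

* a **3-state pair hidden Markov model** (match state plus one insert state
  per sequence), computed by forward–backward. Transitions are controlled by
  the gap-open probability `delta` (default 0.0199) and the gap-extension
  probability `epsilon` (default 0.7943). Match emissions are the joint
  distribution `q(a,b) = f_a f_b exp(lambda * s(a,b))` implied by the
  substitution matrix, with `lambda` solved numerically so `q` sums to one;
  insert emissions are the background frequencies `f`.
* an **affine-gap partition function**: every alignment carries the
  Boltzmann weight `exp(score / temperature)` where a gap run of length `k`
  costs `gap_open + (k - 1) * gap_extend` (defaults 22, 1, temperature 5).
  The pairing posterior is the weight fraction of the ensemble pairing
  `(i, j)`.

Both models are computed in log space; the contract, enforced by
enumeration oracles in the test suite, is per-cell absolute error below
1e-10 on short sequences. The default substitution matrix is BLOSUM62
(taken from Biostrings at run time). The original work trained
partition-function parameters against a VTML200 matrix; those trained
constants were never published and no installed package ships VTML200, so
the package defaults to the BLOSUM62/Probalign-lineage values above and
accepts any matrix in the standard plain-text format via
`read_submatrix()` for users who have a VTML200 file. Ambiguity codes
B, Z, X are retained in sequences and scored through a wildcard row/column
holding background-expected values.

Combined matrices are stored sparsely: cells below the cutoff (default
0.01) are dropped and the retained fraction is the sparsity coefficient
`beta`. `fit_sparsity()` raises the cutoff along a fixed grid
(0.01 … 0.5) until the estimated storage of all `N(N-1)/2` matrices fits a
user-given RAM budget, and refuses budgets that would need a cutoff above
0.5 rather than degrade silently.

# Stage II — guide tree

The maximum-expected-accuracy (MEA) score of a pair — the optimal sum of
posteriors along a monotone path, with unpaired residues free — is turned
into the distance `d = 1 - score / min(L_x, L_y)`, clamped to [0, 1]. The
formula is a documented package choice: only the induced order matters to
the consumers (ranking and clustering), and this form is exact at the two
ends (identical pair gives ~0, unalignable pair gives 1). Trees are built
by *weighted UPGMA* in the WPGMA/McQuitty sense: the merged cluster's
distance to any other cluster is the plain mean of its two members'
distances. Merge ties break on the lowest cluster-index pair, which makes
tree construction fully deterministic. Sequence weights follow the ClustalW
rule (each branch length divided equally among the leaves below it), and
are normalized to sum one.

# Stage III — selective consistency

One consistency transformation relaxes every matrix over its accepted third
sequences using the pre-transformation matrices (double-buffered, so the
result does not depend on pair order):

```
S'_xy = [ h_xy (w_x + w_y) S_xy + sum_z  w_z S_xz S_zy ]
        / [ h_xy (w_x + w_y) + sum_z w_z ]
```

With no accepted `z` and `h_xy = 1` this is exactly the identity, which is
the property the normalization was chosen for. Acceptance of a third
sequence `z` for the pair `{x, y}` is decided by an aggregation
`alpha(d_xz, d_yz)` (max by default; min and sum available) of either:

* **node-count tree distances** (the number of nodes in the minimal subtree
  containing both leaves), thresholded deterministically at `T`
  (`alpha <= T` accepts); or
* **rank-normalized score distances** in [0, 1], passed through a
  stochastic *filter function* `F` mapping the aggregated distance to an
  acceptance probability; a uniform `p` is drawn and the relaxation runs
  iff `p <= F(alpha0)`. The published description prints the inequality the
  other way around, which would make `F` a rejection probability and turn
  the low-pass filter into a high-pass one; the package implements the
  acceptance-probability reading and exposes `invert = TRUE` for the
  literal form. Triangle presets (`low`, `mid`, `high`) are calibrated so
  that their integral — the expected acceptance over uniformly distributed
  aggregated distances — equals the configured rate, 10% by default.

The number of relaxations `n_xy` then differs per pair, so the original
signal would be diluted unevenly. The amplification coefficient

```
h_xy = 1 + (h - 1) * min(n_xy, cap) / cap
```

scales the self-term linearly from 1 (no relaxations) to the ceiling `h`
(default 3 in the selective modes, 1 in full mode) at the per-pair cap of
200 relaxations. `h_xy` is applied on every transformation iteration; the
number of transformations defaults to 2 for families under 50 sequences and
1 otherwise.

The deterministic threshold default is `T = ceiling(2 * sqrt(N))` on the
node-count distance. The value the original study used is not recoverable
from the available text, so the default was chosen once on structural
grounds: it accepts relaxation only within clades of roughly
`sqrt(N)`-leaf scale, which keeps the mean number of accepted third
sequences flat as `N` grows (the property behind the `O(N^2 L^3)` scaling
claim, checked by the acceptance suite), while widening slowly enough that
small families are not starved. It is a config knob
(`consistency_config(T = ...)`), not a constant.

# Stage IV — progressive alignment and refinement

Profiles are merged bottom-up in guide-tree order. The merge DP maximizes
the weighted posterior mass of matched columns,
`sum over cross pairs of w_x w_y S_xy[i_x, j_y]`, with gap columns costing
nothing — posterior mass is the only signal, as in the MEA family of
aligners. Tie-breaks prefer match, then a gap in the first profile, then a
gap in the second, making every merge deterministic.

Refinement then iterates: split the alignment, strip gap-only columns from
both halves, realign them with the same profile DP (over the transformed
matrices, which are also what the progressive stage used), and accept the
candidate by rule:

* `length` (default): accept iff the column count did not grow;
* `trident`: accept iff the entropy-based trident score did not drop. The
  per-column trident score is `(1 - t)^a (1 - r)^b (1 - g)^c` with `t` the
  normalized residue-symbol entropy, `r` the normalized entropy over six
  stereochemical classes (aliphatic AVLIMC, aromatic FWYH, polar STNQ,
  positive KR, negative DE, special GP), and `g` the gap fraction;
* `always`: unconditional.

The split strategy is `column` by default: draw one column uniformly from
the columns containing at least one gap and at least one residue, and
separate the rows with a gap there from the rows with a residue. An
optional balance bias sorts candidates by `|g - N/2|` (gap count `g` close
to half the rows gives balanced halves) and restricts the draw to the most
or least balanced `p%`. `random` (fair-coin rows) and `tree` (break a
random guide-tree edge) strategies are kept for comparison. Iterations
default to 30 when two consistency transformations ran, 200 otherwise.

# Scoring

`sp_score()` is the fraction of reference residue pairs reproduced in the
test alignment; `tc_score()` the fraction of reference columns (with at
least two residues) whose residues land in a single test column;
`combined_q()` their geometric mean; `relative_length()` the column-count
ratio. Reference columns containing gaps contribute their residue pairs to
SP; columns with fewer than two residues are excluded from TC. Scores are
invariant to row order and residue case.

# The synthetic generator, and what a green test establishes

`generate_family()` evolves a background-sampled ancestor down a known tree
(shapes: random, balanced, caterpillar), with per-site per-branch
substitution probability 0.05 and indel-event probability 0.01 by default,
geometric indel lengths (mean 2), insertions drawn from the background
frequencies. Insertions open fresh columns in ancestral coordinates, so the
true multiple alignment is known exactly and every leaf degaps to its
sequence. The defaults describe a conserved single-domain family of
moderate depth; they were fixed once, before any benchmark-style checks
were run.

What the generator does *not* emulate matters for reading the tests: its
truth is **phylogeny-based**, placing independent insertions in separate
columns even when their residues are indistinguishable, whereas the
published benchmark references are **structure-based** and prefer tight
alignments. A green invariant or oracle test therefore establishes
correctness of the machinery; the refinement-behaviour check in the
acceptance suite measures the method against a truth that is
systematically *longer* than what posterior-mass maximization prefers. On
these families the suite finds that column-oriented refinement always
shortens the alignment and strictly increases the internal posterior-sum
objective while mean SP against the phylogenetic truth stays essentially
flat (slightly below the unrefined mean at the default conservation level,
slightly above it for more divergent settings) — the over-alignment
trade-off that the length rule is known to carry. The package reports this
honestly rather than recalibrating the generator around it.

# Numerical choices and degenerate inputs

* Forward/backward and partition recursions run in log space with a guarded
  log-sum-exp; posterior cells are exponentiated only at the end.
* Merge ties in WPGMA, DP traceback ties, and the stable closest-first cap
  in plan building are all fixed, so the whole pipeline is bit-reproducible
  given (input, resolved config, seed). Stochastic components (filter
  draws, refinement splits) draw from `set.seed`-scoped streams that save
  and restore the caller's RNG state.
* A gapless alignment has no candidate columns; a column-strategy iteration
  then counts but does nothing. Trees with all-zero branch lengths fall
  back to uniform sequence weights. `rank_normalize()` maps a single
  off-diagonal value to 0.5. Empty sequences, duplicate ids, non-symmetric
  distance matrices, and all-gap columns are rejected with errors naming
  the offending record.

# Limitations

* Nucleotide mode is out of scope (the published parameters for it are not
  available); inputs are protein sequences.
* The pair-HMM and partition defaults are lineage defaults, not the
  original's trained constants (unpublished); accuracy on real benchmarks
  will differ accordingly. All of them are exposed in
  `pipeline_config()` / config files.
* Everything runs single-threaded on the CPU; the original's GPU kernels
  and memory engineering are intentionally not reproduced.
* Memory still scales with `N^2` posterior matrices; the RAM cap trades
  accuracy for fit only down to a floor cutoff of 0.5.
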
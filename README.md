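# probmsa

Progressive multiple sequence alignment of protein families driven by
pairwise posterior probabilities, with **selective consistency** and
**column-oriented iterative refinement** — the two techniques that keep
consistency-style accuracy affordable as families grow from a handful to
hundreds of sequences. The package is aimed at people who align protein
families and at method developers who want a tested, fully scriptable CPU
implementation of the posterior-consistency pipeline with a synthetic
ground-truth generator for benchmarking.

## The method

For every sequence pair *x*, *y* a posterior matrix
*S<sub>xy</sub>[i, j] = P(x<sub>i</sub> ~ y<sub>j</sub>)* is computed from a
3-state pair HMM and an affine-gap partition function (forward–backward in
log space) and averaged. MEA alignment scores give distances for a weighted
UPGMA (WPGMA) guide tree with ClustalW sequence weights *w<sub>u</sub>*.
Before progressive alignment, each matrix is relaxed over accepted third
sequences *z*:

&nbsp;&nbsp;&nbsp;&nbsp;
*S′<sub>xy</sub> = [ h<sub>xy</sub>(w<sub>x</sub>+w<sub>y</sub>) S<sub>xy</sub> +
Σ<sub>z∈A<sub>xy</sub></sub> w<sub>z</sub> S<sub>xz</sub> S<sub>zy</sub> ] /
[ h<sub>xy</sub>(w<sub>x</sub>+w<sub>y</sub>) + Σ w<sub>z</sub> ]*

where the accepted set *A<sub>xy</sub>* contains only the *z* passing a
distance filter — deterministic thresholding *α(d<sub>xz</sub>, d<sub>yz</sub>) ≤ T*
on node-count guide-tree distances, or a stochastic triangle filter on
rank-normalized score distances — and the amplification coefficient
*h<sub>xy</sub> = 1 + (h−1)·min(n<sub>xy</sub>, 200)/200* restores the
weight of the original signal in proportion to how many relaxations hit the
pair (ceiling *h* = 3). Two such transformations run for *N* < 50, one
otherwise. Profiles are then merged in guide-tree order by a DP maximizing
weighted posterior mass, and the alignment is polished by column-oriented
refinement: pick a random gapped column, split rows by gap presence there,
strip gap-only columns, realign, and accept iff the alignment did not get
longer (30 iterations after two consistency transformations, 200 after
one). Supervised scoring (SP, TC, Q = √(SP·TC), relative length) and a
seeded synthetic-family generator with known true alignments round out the
toolkit.

## Worked example

```r
library(probmsa)

# a synthetic family of 8 proteins with a known true alignment
fam <- generate_family(family_spec(n = 8, length = 80, seed = 42))
fam$sequences
#> seq_set of 8 sequences; lengths 75-83

res <- align_msa(fam$sequences, pipeline_config(seed = 1, verbose = TRUE))
#> stage I: 28 pairs, mean beta 0.018 (1.2s)
#> stage II: guide tree built (0.0s)
#> stage III: 2 transformation(s), mean relaxations 0.1 (0.1s)
#> stage IV: 85 columns after 30 refinement iterations (0.2s)

print(res$alignment)
#> msa: 8 sequences x 85 columns
#> seq01        CATVYIETDLWMLKEG-TQIQERLQLGSLEELC-MAPDPVVENLIGGGKRSIYAGSQRGL...
#> seq02        CATDYIIWDAWMLKEG-TQTQERLQLGSLLELC-MAPCPVVENLINQGKRCIYQGSQRGL...
#> seq03        CATDY----AWMLKEA-TQIQERLQLGSPEELC-MAPCPVVENLINGSKRCIYQGSQRGL...
#> ...

score_alignment(res$alignment, fam$alignment)
#>          SP        TC         Q relative_length
#> 1 0.9802028 0.9166667 0.9479025       0.9659091
```

The stage lines report the pair count and mean sparsity coefficient of the
posterior matrices, the number of consistency transformations with the mean
accepted relaxations per matrix, and the final column count. The score row
says that 98.0% of the true residue pairs and 91.7% of the true columns
were recovered, and that the alignment is 3.4% shorter than the true one.

The same pipeline is available from the shell via the thin CLI in
`exec/probmsa` (`align`, `score`, `simulate`, `bulk`), including bulk
processing of many families in one run, an optional Newick dump of the
guide tree, and a RAM budget (`--memory-budget`) that raises the sparsity
cutoff to fit.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch by running the installed package — the amplification coefficient of
an unrelaxed posterior matrix, and the empirical acceptance rate of the
low-pass triangle stochastic filter calibrated to 10%, estimated from
100,000 seeded Monte-Carlo draws — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/`, `src/` — implementation (Rcpp kernels for the forward–backward,
  partition-function, and alignment DPs)
- `tests/testthat/` — unit, property, and acceptance tests, including
  exhaustive-enumeration oracles for every dynamic program
- `vignettes/selective-consistency-msa.Rmd` — the methods vignette: models,
  parameters, design decisions, and limitations
- `exec/probmsa` — command-line interface
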
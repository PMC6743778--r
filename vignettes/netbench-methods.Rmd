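---
title: "Benchmarking network propagation with complex-aware cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking network propagation with complex-aware cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbench)
```

## The problem

Guilt-by-association methods prioritise candidate disease genes by spreading
known gene–disease labels over a molecular interaction network: genes close
to many seeds receive high scores. Benchmarks of such methods typically hide
a fraction of the known positives by cross-validation and ask how well each
method recovers them. `netbench` implements a full such benchmark — a method
panel, fold construction, metrics and downstream explanatory models — with
particular care for one failure mode: known drug targets often comprise
entire protein complexes, complexes are densely wired in interaction
networks, and a fold split that separates members of one complex lets the
training labels leak into validation through one-hop edges. The resulting
estimates can be badly optimistic, and the bias hits exactly the methods a
benchmark is supposed to rank (the strongest local learners benefit most).

## Propagation substrate and method panel

All kernel methods share the regularised Laplacian kernel
$K = (I + L)^{-1}$ with $L = D - W$ the unnormalised weighted Laplacian.
Two useful identities drive the tests: $(I + L)\mathbf{1} = \mathbf{1}$
implies $K\mathbf{1} = \mathbf{1}$ (rows sum to one, so `raw` scores are
convex smoothings of the input), and on a connected graph $K$ is symmetric
positive definite with strictly positive entries. The regularisation
constant is fixed at 1 — the conventional default for this kernel family —
and a symmetric-normalised Laplacian variant is available behind an option.
The kernel is stored densely; the package targets desk-scale graphs (up to
roughly 15–20k nodes) and refuses larger inputs unless the cap is raised
explicitly.

The statistically normalised diffusion scores deserve a note. Under a
uniform permutation of a binary input with $n^+$ positives among $n$ genes,
the raw score of gene $i$ is a sum of $n^+$ entries sampled without
replacement from row $i$ of $K$; simple random sampling theory gives the
null mean $n^+ \bar K_i$ and variance
$n^+ \frac{n - n^+}{n - 1} \sigma^2(K_i)$, where $\sigma^2(K_i)$ is the
population variance of the row entries. `diffuse_z` standardises with these
closed-form moments; `diffuse_mc` estimates the same null empirically and
reports the fraction of permutations falling strictly below the observed
score — an empirical quantile in $[0,1]$, oriented so that "higher is
better" holds uniformly across the panel (rather than a p-value, which
would invert the ranking). Genes with a degenerate kernel row get z-score 0
by convention.

For the positive-unlabelled learners, `knn` averages the $k$ largest kernel
similarities to the training positives (default $k = 3$, mean aggregation
so the scale is comparable across $k$), and `wsld` uses all positives with
linear decay weights $w_m = (n^+ - m + 1)/n^+$ on the similarity-sorted
positives — the decay profile is configurable, since "linear decay" admits
several parameterisations. Both exclude a positive gene's own
self-similarity, falling back to it only when no other positive exists, so
the single-positive case of both scorers coincides. `bagsvm` draws, per
bag, $|$positives$|$ pseudo-negatives uniformly from the unlabelled genes
and trains a C-SVC directly on the precomputed kernel (30 bags by default);
decision values are sign-oriented so training positives score higher.

The embedding behind `rf` and `svm` follows the MashUp construction on a
single network: per-node random-walk-with-restart stationary distributions
(restart 0.5), a log transform with pseudocount $1/n$, and a rank-$d$
truncated SVD (default $d = \min(n/2, 100)$) with features
$U_d \,\mathrm{diag}(\sqrt{\sigma_d})$. Classifier hyperparameters are
library defaults under seed control; no tuning loop is run. Degenerate
singular values make individual embedding columns non-identifiable (only
the spanned subspace is), which the tests respect by checking symmetry
properties on non-degenerate components.

PageRank damping defaults to 0.85. All stochastic methods take an explicit
integer seed and are bit-reproducible given it; seeded operations save and
restore the session RNG state.

## Cross-validation schemes

Folds are always constructed from the drugs-stream positives, whichever
stream seeds the methods, and validation-fold genes are hidden from the
input labels in both streams. Three schemes are provided:

- **classic** — stratified $k$-fold ($k = 3$, 25 repetitions by default):
  positives and non-positives each spread as evenly as possible.
- **block** — complexes sharing at least one gene and containing at least
  one positive are merged into pseudo-complexes (connected components of
  the overlap relation, which makes the units pairwise disjoint); units are
  shuffled uniformly and $k - 1$ fold boundaries are placed on the shuffled
  sequence greedily, each cut at the position minimising the deviation of
  the cumulative positive count from the balanced value while leaving at
  least one unit per remaining fold. No unit is ever split; a dominating
  complex therefore produces deliberately imbalanced folds.
- **representative** — one positive per pseudo-complex is kept, uniformly
  at random per repetition; all other complex members are excluded from
  training *and* validation, so methods are neither misled into treating
  them as negatives nor rewarded/penalised for ranking them. With an empty
  catalog this reduces exactly to the classic scheme at the same seed.

Non-positive genes are distributed at the gene level in all schemes: the
complex constraint is about label leakage, which only positives cause.
Per-repetition seeds are `seed + repetition`, so any single repetition can
be reproduced in isolation.

## Metrics

AUROC uses the midrank (Mann–Whitney) tie convention; partial AUROC
integrates the tie-grouped ROC curve up to an FPR ceiling $p$ with linear
interpolation at the boundary and renormalises by $1/p$, so $p = 1$
recovers AUROC identically. AUPRC is the step-wise estimator (precision as
a step function of recall); it carries a small upward bias at low positive
counts, visible in the null simulations, which is why the null-mean test
uses a larger instance. Top-$k$ hits breaks boundary ties by a seeded
uniform shuffle — a hard cut requires some tie-break, and a seeded one
keeps records reproducible. Metrics are computed on validation-fold genes
only; excluded genes never enter evaluation.

## Explanatory models

Fold-averaged records are modelled additively,
`value ~ cv_scheme + network + method + disease` (or the reduced
`~ method + disease`), with quasi-binomial/logit variance for bounded
metrics and quasi-Poisson/log for hit counts; the free dispersion parameter
protects the Wald inference against over- and under-dispersion, and
quasi-Poisson point estimates coincide with plain Poisson (dispersion only
scales the standard errors). Bounded responses are nudged into the open
interval by $10^{-6}$ before the logit fit. Factors observed at a single
level are dropped with a warning rather than erroring, so reduced fixtures
(one disease, one network) remain modellable. Predictions on the response
scale average the inverse link over the levels of a chosen factor, with
delta-method confidence intervals; all-pairs method comparisons use
single-step max-$t$ (multivariate normal) adjustment with a Bonferroni
fallback.

Gene-list overlap between the two evidence streams is tested with the
one-sided hypergeometric tail (an enrichment question), corrected by
Benjamini–Hochberg across diseases; the background universe size is an
explicit argument, never guessed. Method rankings are compared by
Spearman's footrule over top-$N$ lists: genes absent from one list take
rank $N + 1$ (so a mismatch costs the largest possible displacement), and
the mismatch fraction is the symmetric difference over $2N$. Distance
matrices embed in two dimensions by classical MDS.

## What the synthetic generator emulates — and what it does not

`generate_benchmark()` draws a planted-partition graph (five modules of 300
genes by default, within-module edge probability 0.1, between 0.005, unit
edge weights), places 60 drugs-stream positives with 75% concentrated in
one module, and realises three size-8 complexes as all-positive cliques
added to both the graph and the catalog. These defaults are chosen so that
(a) positives cluster, the regime in which guilt-by-association is
meaningful and in which better-predicted diseases were observed to sit;
(b) the complexes recreate the exact leakage mechanism the block and
representative schemes exist to remove — co-labelled, fully connected,
split-prone under gene-level shuffling; and (c) a full 3-fold × 25-rep run
of all non-ML methods completes in well under a minute on one CPU. The
genetic stream samples a configurable overlap fraction (default 5%,
matching the modest overlaps seen between drug-target and genetic evidence
lists) from the drugs positives and draws the remainder with a 3:1 weight
toward modules containing drugs positives.

Passing tests on these fixtures demonstrate the *mechanisms* — leakage
under classic CV, its removal under complex-aware CV, topology bias
benefiting diffusion — not performance on real data. The generator does not
reproduce scale-free degree distributions, edge-confidence heterogeneity,
annotation incompleteness, or complexes that are only partially positive;
absolute metric values on real networks will differ.

## Numerical choices and degenerate inputs

Duplicate edges collapse to the maximum weight; self-loops are dropped;
weights are clamped to $[0,1]$. Component ties in LCC extraction go to the
component containing the lexicographically smallest gene id. Positives
absent from the network are dropped with a warning counting them. Empty
positive sets, single-class training sets, disconnected kernels and
inconsistent overlap counts raise errors early. A validation fold with no
positives is skipped with a warning rather than contributing an undefined
record.

## Problem sizes used in the checks

The package's own verification uses: exact 2-node kernels and 5–30-node
random graphs against dense-inversion oracles; a 20-node graph with 50,000
explicit label permutations for the diffusion null moments (3-standard-
error agreement); 1,000 instances of at most 12 genes for the pairwise
AUROC oracle; 500 seeded fold constructions for the no-split and
one-representative guarantees; the default 1,500-gene fixture, 3-fold × 25
repetitions, for the classic-versus-block gap and the pr-versus-random
comparison; and 100 simulated record sets for explanatory-model effect
recovery. These sizes make the full suite run in about half a minute while
leaving each check statistically meaningful.

## Known limitations

COSNet-style Hopfield classifiers and multi-network (multi-view) embeddings
are out of scope. The dense kernel limits graph size; sparse or iterative
solvers would be needed beyond ~20k nodes. The footrule mismatch penalty
(rank $N+1$) and the wsld decay profile are field conventions rather than
uniquely determined choices; both are configurable and documented where
they matter.
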
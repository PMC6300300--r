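---
title: "Predicting drug targets from perturbation-signature correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug targets from perturbation-signature correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

targetrank predicts protein targets for small molecules from L1000-style
differential-expression compendia. The working hypothesis is
pharmacological: a compound that inhibits a protein should push the cell's
transcriptional state in a direction similar to silencing that protein's
gene — and, because signaling is networked, similar to silencing genes
immediately up- or downstream of it. Both effects are measurable as
correlations between a drug-treatment signature and shRNA-knockdown (KD)
signatures collected in the same cell lines.

A *signature* here is a vector of differential-expression Z-scores over the
~978 landmark genes of the L1000 assay (one consensus vector per
perturbagen, cell line). For a drug $d$, candidate target gene $g$ and cell
line $c$, the package computes six features:

* $f_{cor}(d,g,c)$ — signed Pearson correlation between the drug consensus
  signature and the KD consensus of $g$. Signed, because inhibition is
  expected to *mimic* knockdown; anticorrelation is not evidence of
  targeting.
* $f_{PC}(d,g,c)$ — "indirect correlation": the fraction of $g$'s
  protein-interaction partners found among the top $X$ KDs most correlated
  with the drug, divided by the fraction expected from $g$'s degree,
  $X_\mathrm{eff}/N$ (where $N$ is the number of candidate KD genes and
  $X_\mathrm{eff} = \min(X, N)$). The division is the hub correction: a
  protein with hundreds of partners trivially places some of them in any
  top list. Under random top lists the expectation of $f_{PC}$ is exactly
  1 at every degree, which the test suite verifies empirically at degrees
  1, 5 and 25.
* $f_{CS}(d,c)$ — mean correlation between the drug signature and the
  cell's control (vehicle) signatures. A transcriptionally *active* drug
  moves the cell away from baseline, so the argmin over cells marks the
  most active cell line.
* $f_{DE\_mean}, f_{DE\_max}(d,g,c)$ — mean and maximum $|Z|$ of $g$'s
  interaction partners in the drug signature: drugs often dysregulate
  their target's neighbourhood even when signature-level correlation is
  weak.
* $f_{loc}(g)$ — cellular localization encoded $+1$ (intracellular), $-1$
  (transmembrane/extracellular), $0$ (unknown). Intracellular targets are
  empirically easier for this kind of screen; the $0$ default keeps the
  encoding three-valued without biasing unannotated genes either way.

Candidate spaces use an intersection policy: for each drug, the candidate
genes are those with KD consensus signatures in *every* cell line where the
drug was profiled (and where any KD exists). This keeps the feature block
dense — a $|T_d| \times |C_d|$ matrix per feature — at the cost of
discarding genes with partial cell coverage, which the source compendium
design makes rare. Replicate KD signatures are collapsed by the element-wise
mean before any correlation; the mean is the simplest unbiased combiner, and
a max-over-replicates variant was deliberately left out of scope.

## From features to rankings

Single-feature rankers order candidates within each cell line and then give
each gene its *best* (minimum) rank across cells. Scanning for the optimal
correlation across all cell lines outperforms trying to identify the single
most relevant cell first, so best-rank aggregation is the default
throughout; ties always break lexicographically by gene identifier so every
ranking is a reproducible total order.

Three learned rankers combine the features:

* **Logistic baseline** — a linear model over per-(drug, gene) aggregates
  (normalized min-rank of each ranked feature across cells, min $f_{CS}$,
  $f_{loc}$). Aggregation happens *before* the model because a linear score
  cannot express the min-over-cells nonlinearity.
* **Two-level random forest** — level 1 classifies per-(drug, gene, cell)
  feature rows pooled over all training drugs; level 2 classifies
  per-(drug, gene) aggregates of the level-1 probabilities (max, mean,
  number of cells, min $f_{CS}$). The aggregate set is this package's own
  construction — the architecture is named in the source study but its
  aggregation is not — chosen so the model can express "the best cell line
  wins". Pooling makes drugs with different cell counts trainable together.
* **On-the-fly random forest** — one forest per query drug, trained only on
  drugs profiled in (at least) the query's cell set, with per-cell features
  concatenated in canonical cell order. Training drugs profiled in a
  superset of cells are restricted to the query's cells rather than
  dropped.

Training pairs label known drug–target pairs positive and sample 50
negatives per positive by default (the full negative set, thousands per
positive, would swamp the forest); classes are re-balanced by weights.
Evaluation uses leave-one-out cross-validation per drug: the held-out
drug's examples never enter its fold's training set, and per-fold seeds are
derived deterministically as `seed + fold`.

Because no random-forest learner ships with the supported R environment,
the forest itself is implemented in compiled code inside the package: CART
trees with bootstrap resampling, per-node feature subsampling
(`mtry = floor(sqrt(p))`), a Gini-style criterion on quantile-binned
features (at most 63 cut points per feature — a standard histogram
approximation that changes little at forest level but makes leave-one-out
retraining hundreds of times cheaper), class weighting, and depth/node-size
limits (14 / 10). All randomness flows through R's RNG, so fits are
bit-reproducible under `set.seed()`.

## Structural re-ranking

The genomic screen's characteristic false positives are interaction
partners of the true target — indirect correlations cut both ways. An
orthogonal structural filter re-ranks each drug's genomic top-100 by
externally supplied docking scores (lower = better): scored candidates
sort by score, and structureless candidates are appended in genomic order,
on the rationale that structural evidence, when available, should dominate.
Hits are scored candidates strictly better than the drug's own median
docking score (the 50% cutoff, applied per drug; the strict inequality
means a lone scored candidate can never certify itself, and the
`quantile = 1` bound is treated as "no cutoff"). Actual docking is outside
this package's scope: scores arrive through a TSV provider interface, and a
mock provider with a planted-margin model stands in for the docking engine
during testing. The mock scores the planted target by default, mirroring
the published evaluation subset of drugs whose known target has a solved
structure.

## Evaluation

Per drug, the *best-target rank* is the minimum rank over the drug's known
target set. Drugs whose known targets fall outside the candidate frame are
flagged not-evaluable and excluded from counts rather than scored at the
worst rank, matching how the validation panel was constructed. Top-$k$
counts, mean best rank, and a normalized-rank ROC summarize a panel: the
false-positive rate is the fraction of the candidate list declared
positive, the true-positive rate the fraction of drugs whose best target
clears that threshold, and the trapezoid AUC (1001-point grid) equals
$1 - \overline{r/N}$ — an identity the tests verify to $10^{-3}$.
Significance is assessed against a permutation baseline that assigns each
drug's targets distinct uniform ranks (20000 permutations by default); the
closed form $1 - \binom{N-k}{t}/\binom{N}{t}$ per drug cross-checks the
Monte Carlo. Hypergeometric upper-tail enrichment supports category
analyses such as the localization split; category sets are supplied as
flat gene lists (no ontology traversal).

## The synthetic world

The generator emulates the structure the method assumes, not the marginal
statistics of any real compendium:

* a preferential-attachment interaction network over the KD genes
  (`m = 2`, hence `2n - 3` edges, connected);
* KD signatures with a strong self-effect (Z = −5 at the gene's own
  landmark slot — the first `n_kd_genes` landmarks are the KD genes' own
  transcripts), neighbour effects attenuated by `indirect_strength`
  (default 0.5), a per-(cell, gene) baseline shift (sd 0.3) shared by all
  samples of a cell, and Gaussian noise (`noise_sd`, default 0.5);
* drugs that are *direct* (signature = 0.8 × target KD consensus + noise)
  or *indirect* (signature = 0.5 × mean of the target's neighbours' KD
  consensuses + noise, zero direct term — the clean dissociation that
  motivates the indirect feature), each active in ~75% of cells
  (at least one, unless activity is switched off entirely) and
  control-like elsewhere;
* controls as baseline + unit normal noise; 200 drugs, 500 KD genes, 4
  cell lines, 2 KD replicates, 978 landmarks by default.

Defaults were chosen once for testability at desk scale: the self-effect
dominates the noise so planted targets are recoverable, noise 0.5 keeps
recovery non-trivial, and the 50/50 direct/indirect mix exercises both
feature families. What a green test establishes is that the pipeline
recovers planted structure of the assumed kind far above chance and that
each feature behaves as designed; it does *not* establish accuracy on real
compendia, whose effect-size distributions, correlated noise, batch
structure and annotation errors the generator deliberately omits. The
published headline accuracies require the real compendium and are out of
scope by design; what the package reproduces exactly is the published
evaluation arithmetic on the bundled 29-drug validation table and the
random-baseline distribution.

## Numerical choices and edge cases

* Zero-variance vectors make Pearson correlation undefined; the package
  raises an error instead of returning `NA`, because a silent `NA` inside
  a rank aggregation would corrupt orderings downstream.
* `f_PC` uses the fold form (observed/expected); a difference form
  (`k/deg − X/N`) is available via `form = "difference"`. The fold form is
  scale-free in `X` and `N` and makes the hub-correction null exactly 1.
* Degree for `f_PC` is counted against the candidate KD genes only, so the
  expected fraction matches the sampling frame of the top list.
* `X = 100` by default; 50 and 200 behave similarly on the synthetic
  world, and `X` is exposed everywhere.
* Rank-based top lists use rank only (no correlation cutoff): the source
  description is rank-based and a threshold would add a free parameter.
* Tie-breaking is a fixed cascade — model score, then best `f_cor`, then
  gene identifier — guaranteeing a total order even for constant models.
* Quantiles use R's default type-7 (linear interpolation midpoint)
  convention, so the median of (−9, −7, −5, −3) is −6.
* The published two-level top-100 per-cell-group counts sum to 64 while
  the printed total is 63; the bundled table stores the printed values
  verbatim and the tests only assert the internally consistent sums.

## Known limitations

Gene identifiers are case-sensitive symbols with no alias resolution —
annotation inputs must be pre-harmonized. Only the GCT 1.2 text dialect is
supported (no GCTX/HDF5). The synthetic cell-activity signal is weak by
construction (an active drug's signature inherits the cell baseline through
the KD consensus), so `f_CS` discriminates activity poorly in the synthetic
world even though its semantics are exactly as specified — a caveat for
interpreting `rank_in_active_cell()` on generated data. Probability
calibration, hyperparameter search and multi-label evaluation beyond the
best-target rank are non-goals.
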
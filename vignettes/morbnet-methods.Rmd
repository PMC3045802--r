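---
title: "Predicting morbid and druggable genes from an integrated gene network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting morbid and druggable genes from an integrated gene network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The problem

Morbid genes are genes whose mutations cause hereditary human diseases;
druggable genes encode proteins whose modulation by small molecules elicits
phenotypic effects. Identifying either class experimentally is slow, so
`morbnet` implements a machine-learning route: learn what distinguishes the
known members of each class from the rest of the genome, using only
systems-level data — where a gene sits in the cell's interaction networks,
where its protein localizes, and how broadly it is expressed — and then score
every gene in the network for morbidity and druggability.

Three design points carry most of the statistical weight:

1. **Positive/unlabeled learning with balanced sampling.** There is no list
   of certified non-morbid or non-druggable genes, so every gene not on the
   positive list is treated as a de facto negative. Each training dataset
   takes all positives plus an equal-size random sample of the rest, and the
   whole analysis is replicated over 10 such datasets.
2. **Shuffled-label null controls.** Every experiment is paired with a
   label-shuffled twin. A classifier trained on shuffled labels can only
   learn properties of random gene subsets, so the paired comparison
   (exact Wilcoxon signed-rank over the 10 replicates) separates real signal
   from capacity to overfit.
3. **Interpretable rule extraction.** Beyond prediction, single gain-ratio
   decision trees are trained per replicate and their root-to-leaf paths are
   read off as cellular rules; the identity of the modal root feature across
   replicates is the headline qualitative result.

## The integrated network and its twelve topological features

The network unions three layers over shared gene identifiers: undirected
protein physical interactions (`ppi`), directed transcriptional regulation
(`regulatory`, factor to target), and directed metabolic coupling
(`metabolic`). A metabolic edge g1 &rarr; g2 exists when a product of a
reaction catalyzed by g1 is a reactant of a reaction catalyzed by g2. Before
deriving these edges the eight *currency metabolites* (ADP, ATP, H+, H2O,
NADP+, NADPH, orthophosphate, pyrophosphate) are removed; being present
throughout the cell they would otherwise connect nearly every enzyme pair.
`select_currency_metabolites()` offers the data-driven alternative (top-k by
reaction participation) for models whose metabolite naming differs.

Per gene, twelve features: the five layer degrees (`ppi`, `metin`, `metout`,
`regin`, `regout`), the clustering coefficient `c` on the undirected
projection, `identicalness` (how many genes share an identical vector of the
other eleven features — a multiplicity measure of topological
indistinguishability), closeness `cent` as the *mean shortest-path length*
to reachable genes (a distance, not a reciprocal), and four unnormalized
betweenness values (`inbet` on the combined graph, `inbetppi`, `inbetmet`,
`inbetreg` per layer).

Numerical conventions, chosen once and fixed:

* Combined-graph traversal respects direction, with ppi edges walkable both
  ways; betweenness sums over ordered pairs whenever any directed edge is
  present, and over unordered pairs on a purely undirected network.
* Genes with fewer than two projection neighbours have `c = 0`; genes that
  reach nothing have `cent = 0`.
* `identicalness` includes the gene itself (so its minimum is 1) and
  compares real-valued features after rounding to 9 decimals.
* Betweenness is left unnormalized; the tree learners are insensitive to
  monotone rescaling.
* Per-layer betweenness is computed over all network genes, so genes absent
  from a layer score 0 there and every gene has all twelve features.

A note on `metin`: it is implemented as the metabolic in-degree (number of
distinct upstream enzymes), consistent with the degree-centrality definition
of the feature set; an informal reading as "number of metabolites catalyzed"
would be a different quantity.

## The remaining learning attributes

Tissue expression contributes `numtissuesexp`, the number of tissues (of 32)
with at least 5 tpm, and `avegexptec`, the mean tpm over exactly those
tissues. Averaging over the threshold-qualifying tissues (rather than all
tissues with nonzero signal) keeps the two features consistent; the
threshold is a parameter. Subcellular localization contributes ten
multi-hot flags: the eight cellular-component slim terms, `Other
localization` for any other annotated compartment, and `Unknown` for genes
with no annotation at all (`Unknown = 1` excludes every other flag). A gene
may legitimately carry several compartments, so flags are not exclusive.

The full matrix is 12 + 2 + 10 = 24 attributes in a fixed column order.
Genes missing expression data get (0, 0); genes missing localization get
`Unknown = 1`; a gene without topology is an error, because network
membership defines the analysis universe.

## The voting meta-classifier

`vote_ensemble()` fits seven tree-family learners and averages their
positive-class probabilities (the "average rule"): (1) an information-gain
pruned tree, (2) a single randomized tree on a random feature subset, (3) a
random forest, (4) a gain-ratio tree with at least 32 instances per leaf,
(5) a tree with at least 32 instances at terminal nodes, (6) a depth-limited
tree with logistic calibration of its probabilities, and (7) 25 rounds of
boosted decision stumps. Members (1)–(3) and (5)–(6) are realized with
`rpart` and `ranger`; the gain-ratio tree and the boosted stumps are
implemented in the package. Every member is bagged: trained on bootstrap
resamples of the dataset, with the member's probability being the mean over
its bags. The default is 5 bags per member — bagging with a small number of
resamples already stabilizes the probability estimates, and the replicated
cross-validation design (10 datasets x 10 folds) multiplies every fit by a
hundred, so the default keeps a full replicate family affordable on one
core. The roster, bag count, and every member parameter are configurable
through `vote_control()` and `make_member()`; the contract for the roster is
functional-class fidelity to the seven named algorithm families, not
bit-compatibility with any particular implementation of them.

Evaluation uses stratified 10-fold cross-validation per dataset; fold
measures (recall and precision at threshold 0.5 — the natural threshold for
balanced data — and the tie-aware rank AUC) are averaged per dataset and
reported as median [min, max] over the 10 replicates.

## Exact Wilcoxon signed-rank machinery

All condition comparisons (normal vs shuffled, with-feature vs
without-feature, and per-gene normal vs shuffled scores) use the Wilcoxon
signed-rank test in its classic critical-value form: zero differences are
discarded (reducing N), absolute differences are mid-ranked, W is the
smaller rank sum, and the comparison is significant at two-tailed 0.05 when
W &le; W_c. W_c is computed by exact enumeration of the 2^N equiprobable
sign assignments (a dynamic-programming convolution, equivalent to the full
enumeration), giving W_c = 8 at N = 10 and W_c = 5 at N = 9. Published
critical-value tables occasionally differ by a point at small N depending on
how the boundary is handled; this package always uses the exact enumeration.
Exact p-values (with tie handling) are computed the same way up to N = 25,
with a tie-corrected normal approximation beyond.

## Genome-wide scores and rules

The 10 models trained on the normal datasets are applied to every network
gene; the per-gene median of the 10 probabilities is the gene's morbidity
(or druggability) score, reported with its range, the matching shuffled-model
scores, and a per-gene signed-rank test over the 10 paired probabilities
(N = 10, so a gene whose normal scores beat its shuffled scores in every
replicate attains W = 0). `score_histogram()` summarizes where known
positives fall across score bins.

For rules, `c45_tree()` grows a gain-ratio tree per normal dataset (binary
midpoint splits; split candidates must hold at least average information
gain, then the best gain ratio wins; bottom-up error-based pruning at
confidence 0.25 with a minimum leaf size of 2 — both exposed as arguments,
as the original tool's exact parameter file is not available).
`extract_rules()` reads one rule per leaf with its (support/errors) counts,
and `select_representative_tree()` picks, among the replicate trees sharing
the modal root feature, the one with the highest paired cross-validation
AUC (ties: fewer leaves, then replicate order). The modal-root restriction
is this package's own definition of "best representative": the scientific
claim rests on which feature sits at the root, so the representative must
root on the feature the replicates agree on.

## The synthetic study generator

`synthetic_spec()` and `simulate_study()` generate inputs with the joint
structure the method assumes, at the scale of the real study by default:
10,241 genes; a preferential-attachment ppi layer (about 41,000 edges,
matching the order of the real 43,000); 120 transcription factors with
negative-binomially dispersed target counts (about 3,000 regulatory edges);
1,500 reactions over a 600-metabolite pool plus the currency metabolites,
whose enzyme-enzyme edges are derived by the same coupling rule used on real
data (about 18,000 metabolic edges); independent Bernoulli localization
flags; and log-normal expression with a beta-distributed per-gene tissue
breadth, expressed tissues offset above the 5-tpm threshold. Labels are
planted *on the extracted feature columns* by a logistic rule with
standardized coefficients, with the intercept calibrated by root finding to
a target prevalence — 1412/10241 for the morbidity-flavoured spec (dominant
coefficient 3 on `regin`) and 257/10241 for the druggability-flavoured spec
(dominant coefficient 3 on the plasma-membrane flag), mirroring the effect
directions the method is expected to discover.

Planting on extracted features rather than on latent variables is
deliberate: it makes ground truth exactly expressible in the classifier's
own attribute space, so rule recovery (does the tree root on the planted
feature?) and signal recovery (is normal vs shuffled significant?) are
sharp, falsifiable checks. The price is realism: the generator does not
reproduce the empirical dependence structure of real annotation data, the
correlation between degree and expression breadth observed in real genomes,
or literature-driven annotation bias. Passing tests therefore demonstrate
that the pipeline's statistics behave as designed — chance-level nulls,
signal detection, rule recovery — not that any particular biological claim
transfers to real databases. Localization draws are independent Bernoulli
per category (a gene can carry several compartments, as in real GO data)
rather than a single multinomial draw.

## Problem sizes and determinism

The test suite and the acceptance script run the replicate experiments at
the study's own sizes: 10 datasets of 2,824 rows (morbidity scale) and 10 of
514 rows (druggability scale), each under 10-fold stratified
cross-validation, on a network of 10,241 genes. Every random step — network
growth, annotation and expression draws, label planting, negative sampling,
label shuffling, fold assignment, bootstrap resampling, randomized members —
derives its seed deterministically from a single master seed via
`derive_seed()`, so any replicate can be regenerated in isolation and full
runs are bit-reproducible.

## Known limitations

* The negative class is contaminated by construction (unlabeled positives);
  the package mirrors the design rather than attempting reliable-negative
  mining.
* The seven members approximate the original algorithm families with
  different implementations; ranking behaviour is comparable, individual
  probabilities are not bit-identical.
* Betweenness and closeness are exact, not sampled; networks far larger
  than ~10^4 genes would need approximate centralities, which are out of
  scope.
* The generator's independence assumptions (localization flags, tissue
  breadth vs network position) understate real-data correlations; ablation
  effect sizes measured on synthetic data should not be read as estimates
  of real ones.

## A minimal run

```{r example, eval = FALSE}
spec <- morbidity_like_spec(seed = 1, n_genes = 600, n_tf = 30,
                            n_reactions = 150, n_metabolites = 80,
                            n_enzymes = 150)
study <- simulate_study(spec)
datasets <- build_balanced_datasets(study$features, study$positives,
                                    n_replicates = 10, seed = 1)
evals <- lapply(seq_along(datasets), function(r)
  cross_validate(datasets[[r]], folds = 10, seed = r))
summarize_evals(evals)

shuffled <- lapply(seq_along(datasets), function(r)
  shuffle_dataset_labels(datasets[[r]], seed = r))
evals_sh <- lapply(seq_along(shuffled), function(r)
  cross_validate(shuffled[[r]], folds = 10, seed = r))
compare_conditions(evals, evals_sh, "auc")

trees <- lapply(datasets, c45_tree)
best <- select_representative_tree(trees, evals)
print(best)
extract_rules(best)
```
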
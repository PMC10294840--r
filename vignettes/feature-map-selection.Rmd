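---
title: "Selecting CNN feature maps with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting CNN feature maps with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornealga)
```

## The problem and the method

Detecting a corneal ulcer on a fluorescein-stained slit-lamp photograph is a
binary image-classification task for which labelled data are scarce (a few
hundred images). The standard transfer-learning recipe freezes a network
pretrained on ImageNet — here ResNet-18 — and classifies its final pooled
descriptor with a shallow classifier. That recipe leaves two choices on the
table: *which layer* to read features from, and *which feature maps* within
that layer to keep. Deep backbones carry a great deal of redundancy; on a
small dataset, maps irrelevant to the task act as noise that the downstream
classifier has to overcome.

The pipeline implemented here makes both choices explicitly:

1. **Probe every intermediate layer.** Each tensor-producing operation from
   the first convolution to the final global pooling — convolutions,
   batch-normalizations, ReLUs, pooling, and residual elementwise sums — is a
   candidate read-out point. For ResNet-18 at a 224×224×3 input this gives
   67 layers (`enumerate_layers()`), about 8.23 million activations in
   total.
2. **Pool each map to one scalar.** A layer output of shape
   $a_i \times b_i \times w_i$ becomes a $1 \times w_i$ vector whose $j$-th
   entry is the arithmetic mean of map $j$ over all $a_i b_i$ positions
   (`pool_feature_maps()`). One image, one row of a *feature table*.
3. **Classify with a linear SVM.** Accuracy is
   $(TP + TN)/(TP + TN + FP + FN)$ on a held-out stratified 30% of the
   samples.
4. **Search map subsets with a genetic algorithm.** A chromosome is a set of
   $L$ distinct map indices (default $L = 192$ out of $w = 512$); its
   fitness is the SVM accuracy computed on exactly those columns. Uniform
   crossover (CR = 0.5), uniqueness-preserving mutation (MR = 0.1),
   fitness-proportionate selection, elitist truncation replacement,
   population 40, up to 1000 generations.
5. **Evaluate like the original protocol.** Per-layer statistics over 20
   independent 70/30 splits, percent gain of the selected-subset pipeline
   over the all-maps baseline, pairwise Wilcoxon signed-rank comparisons of
   the best layers, and wall time relative to a fixed reference benchmark.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 40 | chromosomes per generation |
| `chromosome_length` | 192 | feature maps kept (distinct indices) |
| `crossover_rate` | 0.5 | per-gene routing probability in uniform crossover |
| `mutation_rate` | 0.1 | per-gene replacement probability |
| `max_generations` | 1000 | generations (convergence typically by ~400) |
| `fitness_folds` | 5 | stratified CV folds for the fitness estimate |
| `train_fraction` | 0.7 | outer training share, floor rounding |
| `cost` | 1 | SVM regularization constant C |
| `standardize` | TRUE | train-estimated z-scaling before the SVM |

The GA defaults are the published operating point of the corneal-ulcer
application. The remaining choices are this package's own, made where the
protocol is silent:

* **Fitness data.** Fitness is *pooled stratified k-fold CV accuracy inside
  the table handed to `run_ga()`* (use the training partition). Pooling the
  fold predictions gives fitness a resolution of one misclassification in
  the whole table and keeps selection pressure alive when accuracies
  cluster. A single internal holdout (`fitness_folds = NULL`) and a fixed
  external split (`fitness_split = ...`) are available; the latter
  reproduces the literal reading in which selection sees test accuracy —
  that variant leaks information from the test set into selection and is
  provided only for replication.
* **Crossover repair.** Routing two distinct parents' genes positionwise can
  duplicate an index inside a child. Duplicates are replaced by uniform
  draws from the indices absent from that child: the set encoding is
  restored with minimal bias, and repair never removes a gene both parents
  agreed on.
* **Replacement.** Each generation produces `population_size` offspring; the
  combined pool is truncated to `population_size` by fitness, with ties
  broken by the lexicographic order of the sorted gene vectors. Truncation
  realizes both "replace the least fit" and elitism, so the best-so-far
  fitness is non-decreasing by construction.
* **Selection.** Fitness-proportionate by default; `selection = "rank"` is
  offered because proportionate selection degenerates when all accuracies
  sit in a narrow band.
* **Standardization.** Features are z-scaled with training-set statistics
  before the SVM (margins are scale-sensitive); zero-variance columns are
  passed through unscaled.
* **Split rounding.** The training size is `floor(train_fraction * n)`
  (712 samples at 0.70 → 498), apportioned across classes by largest
  remainder with deterministic tie-breaks.
* **Indexing.** Channel indices are 1-based everywhere, matching R and the
  published tables; serialized files carry an explicit `index_base: 1`
  field.
* **Determinism.** One seeded generator drives split, fold assignment,
  initialization, selection, crossover and mutation in a fixed order, so a
  run is exactly replayable; fitness is memoized per gene set within a run
  (it is a deterministic function of the genes once the estimator is
  fixed).

## The backbone and its weights

No deep-learning runtime is required: the package ships a minimal ResNet-18
*inference* path (im2col convolution via BLAS matrix multiplication,
inference-mode batch normalization, max/average pooling, residual sums)
sufficient to read activations at any of the 67 enumerated layers.
`resnet18_weights()` builds a deterministic He-initialized weight set from a
seed — random weights are a standard probe for testing extraction machinery,
and random-projection features are still class-informative for simple
contrasts. For replication against pretrained features, any weight list with
the same structure (converted from an external checkpoint) can be passed to
`extract_layer_features()`. Preprocessing is fixed: bilinear resize to
224×224, scale to [0, 1], ImageNet channel normalization.

## What the synthetic generators emulate

`planted_features()` emulates the *pooled-feature stage*: `n_samples = 712`
rows, `n_channels = 512` Gaussian channels of which `k_informative` have
their class-1 mean shifted by `effect_size * noise_sd`. The informative
identities are returned, so selection recovery can be scored exactly.
`toy_images()` emulates the *image stage*: a textured disc (the stained
cornea) with, in class 1, one bright smooth-edged blob (the lesion), written
in the same `class_0/`/`class_1/` folder layout the real-data loader reads.

Neither generator models what makes real fluorescein images hard:
correlated feature maps, heterogeneous illumination, lesion shape variety,
label noise. Passing tests therefore demonstrate that the *machinery* —
extraction arithmetic, GA invariants, protocol statistics — is correct, not
that the published accuracies transfer to other datasets.

## Numerical choices and degenerate inputs

* Wilcoxon signed-rank: zero differences are excluded before ranking;
  midranks for ties; exact null distribution (computed by shift convolution
  over doubled midranks, so exactness survives ties) for up to 25 nonzero
  pairs, normal approximation with tie and continuity corrections above;
  identical samples give p = 1. No multiple-testing correction by default,
  mirroring the original protocol; `holm = TRUE` is available.
* Mutation with `chromosome_length = n_channels` has no foreign index to
  draw: the gene is left unchanged.
* An all-zero fitness vector makes proportionate selection undefined;
  parent sampling falls back to uniform with a warning.
* A single-class training fold is scored by the majority-class predictor
  (its accuracy is that class's prevalence in the evaluation fold).
* `std` of a single run is reported as 0 by convention.
* The computational-time ratio uses a bundled arithmetic loop
  (`reference_benchmark()`) as its denominator, so ratios are comparable
  within this package's sessions, not across publications that used a
  different reference program.

## Known limitations

**Wrapper selection identifies subsets only up to accuracy equivalence.**
Once a subset classifies every evaluation sample correctly, all supersets
and siblings with the same property are exact fitness ties, and no
accuracy-driven search can prefer one over another. In the planted design
this bites at large effect sizes: at a 5-SD per-channel shift, any two
planted channels already separate the classes perfectly, a perfect-fitness
chromosome typically exists in the random initial population, and the
recovered fraction of the planted set stays near what random membership in
a tied optimum implies (~0.27 observed) rather than approaching 1. At
effect sizes where the classifier still errs (e.g. 1 SD per channel), the
same GA run recovers ≥ 0.75 of the planted channels in every seed tested.
The package reports what the search actually finds; interpret recovery
claims in light of this identifiability boundary.

Other limitations: the GA is expensive (thousands of SVM fits per run;
memoization helps only after the population starts converging); only binary
classification is supported; the backbone enumeration is pinned to
ResNet-18.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on synthetic tables of 60–2000 samples and
4–256 channels, with GA populations of 6–20 and up to 60 generations —
small enough to iterate on, large enough that the checked properties
(ranking by planted effect size, GA ≥ random search, GA ≥ all-maps baseline
when noise dominates) are stable under the frozen seeds. The acceptance
experiments use the sizes stated with each check: the 6-channel/choose-2
brute-force comparison over 10 seeds, the 64-channel/8-planted recovery
design over 5 seeds at 200 generations, and 10^4 replicates for the
signed-rank type-I calibration.
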
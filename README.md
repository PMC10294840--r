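# cornealga

Wrapper feature selection for transfer-learning image classification, built
around the corneal-ulcer detection problem: fluorescein-stained slit-lamp
photographs are classified (ulcer present / absent) by reading feature maps
from intermediate layers of a fixed ResNet-18 backbone, reducing each map to
its spatial mean, and letting a genetic algorithm (GA) pick the fixed-size
subset of maps on which a linear support-vector machine is most accurate.

It is aimed at researchers working with small labelled image sets, where a
frozen pretrained backbone is the only practical feature extractor and the
open questions are *which layer to read* and *which of its maps to keep*.

## The method

For layer *i* with output $a_i \times b_i \times w_i$, every image becomes a
$1 \times w_i$ vector of per-map means. A GA searches subsets of a fixed
size $L$ (default 192 of $w = 512$): chromosomes are sets of $L$ distinct
map indices; fitness is the accuracy

$$\mathrm{Accuracy} = \frac{TP + TN}{TP + TN + FP + FN}$$

of a linear SVM trained and evaluated on exactly those columns. Uniform
crossover (CR = 0.5) with uniqueness repair, mutation to an absent index
(MR = 0.1), fitness-proportionate selection and elitist truncation
replacement run for up to 1000 generations (population 40). The evaluation
protocol sweeps all 67 candidate layers of ResNet-18 (~8.23 M activations),
repeats everything over 20 stratified 70/30 splits, and reports descriptive
statistics, percent gain over the all-maps baseline, pairwise Wilcoxon
signed-rank p-values, and wall time relative to a fixed reference benchmark.

A synthetic-data module (`planted_features()`, `toy_images()`) generates
feature tables with known informative channels and toy stained-eye images,
so the whole pipeline is testable with no downloads and no pretrained
weights (a built-in, seeded random-weight ResNet-18 inference path serves
the extraction stage).

## Worked example

Select 8 of 64 channels on a synthetic table with 8 planted informative
channels (1-SD shift), then compare against the all-maps baseline:

```r
library(cornealga)

enumerate_layers("resnet18")[c(1, 67), ]
#>   index name  height width channels n_attributes
#> 1     1 conv1    112   112       64       802816
#> 2    67 pool5      1     1      512          512

ft <- planted_features(n_samples = 400, n_channels = 64, k_informative = 8,
                       effect_size = 1, seed = 1)
split <- split_indices(ft_labels(ft), train_fraction = 0.7, seed = 1)
svm_accuracy(ft, split)                       # all 64 maps
#> [1] 0.85

fit <- run_ga(ft_rows(ft, split$train),       # search on the training part
              ga_config(population_size = 20, chromosome_length = 8,
                        max_generations = 60), seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>   best_fitness generations chromosome_length n_selected  seed
#> 1        0.907          60                 8          8     1

selected <- svm_accuracy(ft, split, channels = fit$best_genes)
gain_report(selected, 0.85)
#> # A tibble: 1 × 4
#>   proposed_mean baseline_mean difference gain_pct
#> 1         0.892          0.85     0.0417      4.9
```

The selected subset raises held-out accuracy from 0.850 to 0.892 (gain
4.9%), and 7 of the 8 chosen maps are truly informative
(`informative_channels(ft)`). `autoplot(fit)` draws the convergence trace;
`tidy(fit)` returns it as a tibble. `layer_sweep()`, `multirun_ga()`,
`wilcoxon_matrix()` and `ct_metric()` implement the full multi-run
protocol, and `inst/cli/cornealga.R` exposes `extract` / `select` /
`evaluate` / `all` subcommands for shell use.

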
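# modulebayes

Eigengene-based Bayesian network classification of gene-expression profiles.

## The problem

Classifying disease types from expression data with individual
differentially expressed genes is brittle: single-gene features are noisy
and platform-dependent, and classifiers built on thousands of them overfit
badly. `modulebayes` targets users — computational biologists analyzing
case/control expression cohorts — who want a classifier built on
*coordinated* expression: coexpression **modules** detected by weighted
network analysis, each summarized by its **eigengene** (one value per
sample), with a discrete **Bayesian network** over the eigengenes plus a
binary disease node serving as the probabilistic classifier. The motivating
use case is separating acute myeloid leukemia (AML) from myelodysplastic
syndrome (MDS), training on microarrays and predicting RNA-seq samples.

## The method

1. **Preprocess** probes: moderated t ranking
   (s̃² = (d₀s₀² + ds²)/(d₀ + d), empirical-Bayes d₀ and s₀² from the log
   sample variances), keep the top third by p-value, drop multi-mapped
   probes, represent each gene by its lowest-p probe.
2. **Modules**: on positive-class samples, adjacency a = |cor|^β (β from
   the scale-free fit criterion), topological overlap
   TOMᵢⱼ = (Lᵢⱼ + aᵢⱼ)/(min(kᵢ,kⱼ) + 1 − aᵢⱼ), average-linkage clustering
   of 1 − TOM, size floor 20, eigengene-similarity merging.
3. **Eigengenes**: first principal component of each module's standardized
   expression on class-balanced (oversampled) data; unit-norm gene weights.
4. **Ensemble of consensus Bayesian networks**: Hartemink 3-level
   discretization; binary `Effect` node with all outgoing arcs blacklisted
   (so its Markov blanket is its parent set); hill climbing on the BDe
   score over bootstrap replicates; consensus = majority arcs of the top
   third of replicates; five models on 4/5 subsamples vote on each sample.
5. **Cross-platform prediction**: module weights are restricted to the
   genes present in the new data, renormalized, and applied to z-scores
   computed *within* the new dataset — per-gene affine platform distortions
   cancel exactly.

## A worked example

Train on synthetic data with 4 planted modules (two of them class-linked,
effect size d = 2) and predict an independent draw:

```r
library(modulebayes)
sim <- generate_expression(n_pos = 60, n_neg = 60, module_sizes = rep(25, 4),
                           n_noise_genes = 30, within_cor = 0.85,
                           effect_sizes = c(2, 2, 0, 0), seed = 11)
clf <- train_classifier(sim$expression, sim$labels, k = 5, seed = 7,
                        config = bn_config(R = 100))
clf
#> modulebayes classifier: beta = 9 | 4 modules | 5 BN models
#> Ensemble of 5 consensus Bayesian network(s) over 4 eigengene(s) + Effect
#>   model 1 - Effect parents: M1, M2
#>   model 2 - Effect parents: M1, M2
#>   model 3 - Effect parents: M1, M2
#>   model 4 - Effect parents: M1, M2
#>   model 5 - Effect parents: M1, M2
```

All five models identify the two planted class-linked modules as the
parents of `Effect` — by the Markov property, exactly the modules that are
predictive of the class. The eigengene t-tests confirm it:

```r
eigengene_differential_test(clf$eigengenes, sim$labels)
#>   module t_statistic      p_value adjusted_p_value
#> 1     M1  10.3532357 3.872833e-18     7.745665e-18
#> 2     M2  11.4532792 7.233811e-21     2.893524e-20
#> 3     M3   0.3157295 7.527660e-01     7.527660e-01
#> 4     M4   1.0294185 3.054396e-01     4.072528e-01
```

Held-out prediction by majority vote:

```r
test <- generate_expression(n_pos = 60, n_neg = 60, module_sizes = rep(25, 4),
                            n_noise_genes = 30, within_cor = 0.85,
                            effect_sizes = c(2, 2, 0, 0), seed = 12)
pred <- predict(clf, test$expression)
performance(pred$majority, test$labels, scores = pred$posterior)
#> Confusion: TP = 51 FP = 5 FN = 9 TN = 55
#> Accuracy 88.3%  Precision 91.1%  Recall 85.0%  AUC 0.939
```

88% accuracy is close to the ceiling here: the Bayes-optimal classifier on
the latent module factors attains about 92% at this effect size (see
`generative_bayes_accuracy()`), and 3-level discretization costs a few more
points. A model saved with `save_model()` can be applied unchanged to data
from another platform (`project_eigengenes()` + `predict()`); a per-gene
affine transform of the test data leaves the predictions identical.

A command-line interface wrapping these stages (`preprocess`, `modules`,
`eigengenes`, `learn`, `train`, `predict`, `cv`, `simulate`) is installed
at `system.file("cli", "modulebayes.R", package = "modulebayes")`.

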
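# goafs — grasshopper-optimized wrapper feature selection

`goafs` selects compact, discriminative feature subsets from
high-dimensional real-valued feature tables — the typical shape of deep
features extracted from histopathology images (e.g. colon adenocarcinoma vs
benign tissue activations from a pretrained CNN) — and evaluates them with
SVM / decision-tree classifiers and the full confusion-matrix diagnostic
panel. It is written for bioinformaticians and ML practitioners who need a
seeded, auditable wrapper-selection pipeline that runs offline.

## The method

The optimizer is the **grasshopper optimization algorithm (GOA)**: N
candidate solutions interact through the social force

    S(r) = f·exp(−r/l) − exp(−r)        (defaults f = 0.5, l = 1.5)

which is repulsive below the comfort distance 3·ln 2 ≈ 2.079, attractive
above it, and vanishing at long range. Each iteration every grasshopper is
re-placed around the best-so-far target Т̂:

    x_i ← c · Σ_{j≠i} c · (ub−lb)/2 · S(d̃_ij) · (x_j − x_i)/d_ij + T̂

with pairwise distances affinely mapped onto [1, 4] before entering S, and
the comfort coefficient c decayed linearly from 1 to 1e−5 over L iterations
(defaults N = 25, L = 80).

For selection, positions live in the unit cube (one coordinate per feature)
and become 0/1 masks via a stochastic transfer rule; each mask m is scored
by the wrapper fitness

    fitness(m) = α · CVerror(m) + (1 − α) · |m|/D,     α = 0.99

where CVerror is the pooled error of seeded stratified 5-fold
cross-validation (radial SVM or decision tree) on the masked columns.
Reported metrics come from a pooled confusion matrix: accuracy,
sensitivity, specificity, precision, and F1, all as percentages.

## Worked example

Generate a synthetic table with 5 informative columns planted among 20
(class-mean gap 2 SD), select features at the standard budget, and evaluate:

```r
library(goafs)

tab <- generate_features(synthetic_spec(n_per_class = 100, n_features = 20,
                                        n_informative = 5, delta = 2, seed = 42))
res <- select_features(tab, goa = goa_config(0, 1, dim = 20, seed = 42),
                       spec = fitness_spec(seed = 43))
print(res)
#> Wrapper feature-selection result
#>   selected 10 of 20 features; final fitness 0.00500
#>   fitness trace: 0.01540 -> 0.00500 over 80 iterations (1962 masks scored)

sum(res$mask == 1 & tab$informative == 1)
#> [1] 4        # planted columns recovered

train_eval(tab, mask = res$mask, classifier = "svm", seed = 43)$metrics
#> Classification metrics (%)
#>   sensitivity  100.000
#>   specificity  100.000
#>   accuracy     100.000
#>   precision    100.000
#>   f1           100.000
```

The fitness falls from 0.0154 to 0.0050 as the swarm converges: the final
subset classifies the held-out folds perfectly (the 0.005 is the
feature-fraction penalty of keeping 10/20 columns), while using *all*
features gives 99% accuracy on the same folds. `run_pipeline()` wraps the
same steps end to end and writes a report bundle (selection JSON, fitness
trace, metrics CSV/JSON, log); `inst/cli/goafs.R` exposes `synth`,
`extract`, `select`, `evaluate`, `run`, and `benchmark` subcommands for
shell use.

Feature tables are read and written as delimited text (header of feature
names plus a final `label` column) or as a bit-exact binary container;
`extract_features()` turns a directory of class-labelled images
(`colon_aca` / `colon_n` layout) into a table through a backbone adapter —
a deterministic stub for offline work, or a user-supplied pretrained CNN.

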
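---
title: "Grasshopper-optimized wrapper feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grasshopper-optimized wrapper feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goafs)
```

## The problem

Deep features extracted from histopathology images — for example, the
penultimate-layer activations of a pretrained CNN applied to colon
adenocarcinoma versus benign colon tissue slides — are high-dimensional, and
most coordinates carry little class information. Training an SVM or decision
tree on all of them wastes samples and hurts accuracy. `goafs` implements
*wrapper* feature selection: candidate feature subsets are scored by actually
cross-validating a classifier on them, and a swarm-intelligence optimizer,
the grasshopper optimization algorithm (GOA), searches the subset space.

## The optimizer

GOA is a population metaheuristic modelled on grasshopper swarms. Each of
$N$ grasshoppers is a point $x_i \in \mathbb{R}^D$ inside a box
$[lb_d, ub_d]$. Pairs interact through a signed **social force**

$$S(r) = f\,e^{-r/l} - e^{-r},$$

with attraction intensity $f$ and length scale $l$. $S$ is negative
(repulsive) at short range, crosses zero at the *comfort distance*, is mildly
attractive at medium range, and decays to zero. With the defaults $f = 0.5$,
$l = 1.5$ the comfort distance is $3\ln 2 \approx 2.079$ (solve
$f e^{-r/l} = e^{-r}$), and the attraction peak sits at $3 \ln 3 \approx
3.296$ with value $1/54$.

Each iteration, every grasshopper is re-placed around the best-so-far target
$\hat T$:

$$x_i^d \leftarrow c \sum_{j \ne i} c\,\frac{ub_d - lb_d}{2}\,
  S\big(\tilde d_{ij}\big)\,\frac{x_j^d - x_i^d}{d_{ij}} + \hat T_d,$$

clamped to the box, where $c$ is the **comfort coefficient**, decayed
linearly from $c_{\max} = 1$ to $c_{\min} = 10^{-5}$ over the run
($c = c_{\max} - t\,(c_{\max}-c_{\min})/L$; the schedule argument runs
$0\ldots L$ so both endpoints are exact). The full swarm model also contains
gravity and wind-drift terms; the production update above is the
target-guided social dynamics, which omits them, and the configuration
merely records them as inert legacy fields.

Because $S$ is numerically flat beyond distances of about 10, raw pairwise
distances are affinely rescaled each iteration onto $[1, 4]$ before entering
$S$ ($\tilde d_{ij}$ above). When every pairwise distance is identical the
affine map is undefined and the midpoint 2.5 is used. Whether $S$ should see
the mapped pairwise distance or the raw per-coordinate gap is ambiguous in
the surrounding literature; we use the mapped pairwise distance, which is
what motivates the mapping in the first place. Coincident grasshoppers
($d_{ij} < 10^{-12}$) get a seeded random interaction direction so the
update never divides by zero.

All randomness — uniform initialization in the box, then any
coincident-pair draws — flows from one seed in a fixed consumption order,
so a run is exactly reproducible. The optimizer records the best objective
value after initialization and after each iteration; this trace has length
$L + 1$ and is non-increasing by construction.

Default budget: population $N = 25$, iterations $L = 80$ — the standard
operating point of the package and the setting every acceptance-level check
uses.

## The wrapper layer

For feature selection the search box is the unit cube, one dimension per
feature. A position becomes a 0/1 mask, which is scored by

$$\mathrm{fitness}(m) = \alpha \cdot \mathrm{CVerror}(m) +
  (1 - \alpha)\,\frac{|m|}{D}, \qquad \alpha = 0.99,$$

where $\mathrm{CVerror}$ is the pooled misclassification rate of seeded
stratified 5-fold cross-validation of the chosen classifier (radial-kernel
SVM by default, or a default-depth decision tree) on the masked columns.
Fitness is affine in $\alpha$: at $\alpha \to 1$ it is the CV error, at
$\alpha \to 0$ the feature fraction. Folds are drawn once per run, so every
mask is scored on the same splits and the optimizer sees a de-noised
landscape; mask scores are cached, since the objective depends on the
position only through its mask. The error weight dominates by design — the
feature-count term breaks ties among equally accurate subsets.

### Position-to-mask transfer

Two transfer rules are provided. The deterministic rule `binarize()`
thresholds at 0.5 (boundary counts as selected), with a keep-argmax repair
that switches on the largest coordinate if every bit would be zero, so masks
are never empty.

The **default** rule in `select_features()` is stochastic: each unit-box
coordinate is the Bernoulli selection probability of its feature, drawn on
the optimizer's seeded stream. This choice was forced by implementation
experience, not taste. GOA's update re-centers the whole swarm on the target
every iteration; under a hard threshold, after one iteration essentially
every position binarizes to the target's own mask, and a
$25 \times 80$-evaluation run visits only a few dozen distinct masks — the
search degenerates to its random initialization. Stochastic transfer (the
transfer-function family standard in binary swarm optimization) keeps mask
space explored in proportion to how undecided each coordinate still is,
while the swarm dynamics still concentrate probability mass around good
subsets. The deterministic rule remains available via
`transfer = "threshold"`. Either way the result is the best mask *ever
evaluated*, its fitness trace, and the full provenance (config, seeds,
masks scored), serializable as JSON.

## Evaluation

Final reporting uses seeded stratified $k$-fold cross-validation with a
*pooled* confusion matrix: held-out predictions from all folds are tallied
into one table of integer counts TP, TN, FP, FN, from which the panel

- accuracy $= (TP+TN)/n \cdot 100$,
- sensitivity (recall) $= TP/(TP+FN) \cdot 100$,
- specificity $= TN/(TN+FP) \cdot 100$,
- precision $= TP/(TP+FP) \cdot 100$,
- $F_1 = 2\,\mathrm{Rec}\,\mathrm{Prec}/(\mathrm{Rec}+\mathrm{Prec})$

is computed exactly. The positive class is the cancerous one by default
(`colon_aca` / `"tumor"`), and is configurable. A metric whose denominator
is zero raises an error naming the metric; silently reporting 0 would be
indistinguishable from a terrible classifier. Pooling keeps the counts
integral, so the identity $F_1 = 2TP/(2TP+FP+FN) \cdot 100$ holds exactly —
the tests assert it over a thousand random confusion matrices.

## Synthetic data: what it emulates, and what it does not

`generate_features()` draws two balanced classes. The $k$ planted columns
are class-conditional Gaussians with means $\mp \delta/2$ (in noise-SD
units, benign low / tumor high); the other $D - k$ columns are
class-independent Gaussian noise. Rows are shuffled under the seed and the
ground-truth mask travels with the table.

Defaults: 100 samples per class, $D = 20$, $k = 5$, $\delta = 2$, unit
noise. $\delta = 2$ is deliberately modest: a single informative column then
has Bayes error $\Phi(-\delta/2) \approx 16\%$, so no lone feature suffices
and selection genuinely has to assemble a subset. These defaults are the
standard conditions for the recovery checks.

The generator's job is to exercise the machinery under known ground truth.
Real deep features are non-Gaussian, correlated, and nothing here transfers
any claim to a particular histopathology dataset: passing tests show the
selector finds planted structure of this kind, not that any published
accuracy is reproduced.

`make_fixture_suite()` freezes five named tables used throughout the tests:
`tiny` ($D = 6$; all 63 masks enumerable), `toy8` ($D = 8$; 255 masks),
`separable` ($\delta = 6$, certified linearly separable by an independent
perceptron certificate), `noisy` (the standard setting above), and `single`
(one strongly separating column among noise).

## Numerical and design choices

- **Oracle validation.** On $D \le 8$ tables, `enumerate_masks()` scores
  every non-empty mask on the same folds, giving the exact optimum; the
  optimizer is tested to land within 5% of it in at least 18 of 20 seeded
  runs. On the standard synthetic setting, at least 4 of the 5 planted
  columns must be recovered in at least 90% of 20 runs.
- **Fold seeding.** Folds depend only on (labels, $k$, seed), never on the
  mask, so fitness differences between masks are not confounded with split
  noise.
- **Tie-breaks and degeneracies.** Threshold ties select the feature;
  all-equal distance maps return the midpoint; empty masks are repaired to
  the argmax coordinate; a constant objective leaves the best-so-far trace
  flat rather than undefined.
- **Classifier hyperparameters.** Library defaults throughout (radial SVM
  from e1071, default rpart tree): the package compares feature subsets,
  not tuned classifiers, and fixed defaults keep the fitness landscape
  stationary.
- **Problem sizes in the test suite.** The heaviest checks run the full
  standard budget ($N = 25$, $L = 80$) twenty times on $200 \times 20$
  tables; everything else uses smaller swarms on the fixture suite. These
  sizes make the whole suite run in minutes on one core while keeping the
  acceptance-level checks at the standard operating point.

## Known limitations

- The stochastic transfer makes the *objective* evaluation stochastic
  (seeded); two runs differing only in seed can return different, similarly
  fit masks. This is inherent to wrapper selection under CV noise.
- With $\alpha = 0.99$ and 5-fold CV on a few hundred samples, the error
  term's resolution is a few misclassifications; feature-count differences
  matter only among subsets of essentially equal error. Pushing sparsity
  harder means lowering $\alpha$.
- The image-to-feature adapter ships only a stub backbone (summary
  statistics through a seeded random projection) for offline testing; real
  CNN backbones must be supplied by the user as a function over image
  arrays, and the layer choice (default: penultimate pooled activations) is
  configuration-sensitive.
- Binary classes only; multi-class selection and filter/embedded methods are
  out of scope.
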
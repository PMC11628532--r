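---
title: "Weighted probability fusion with GA-selected weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted probability fusion with GA-selected weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gafuse)
```

## The problem

Several trained classifiers — say, a vision transformer and a convolutional
network fine-tuned on the same multi-class medical-imaging task — each emit a
softmax probability vector per image. Averaging those vectors before taking
the argmax often beats every individual model, because the models err on
different samples. The question this package answers is *how much weight to
give each model*: the fused prediction for sample $i$ is

$$\hat{y}_i = \arg\max_c \sum_{k=1}^{K} w_k \, p^{(k)}_{ic},
\qquad w_k \ge 0,\; \sum_k w_k = 1,$$

and the weights $w$ (often written $\alpha, \beta$ for $K = 2$) are selected
by a genetic algorithm whose fitness is the ensemble's overall accuracy on a
labelled evaluation set. Equal weights $w_k = 1/K$ recover simple averaging.

The package takes per-model probability matrices as CSV (one `sample_id`
column plus one column per class), aligns them by sample id into a
`model_bundle`, and exposes `ga_fuse()` as the fitting function. The fitted
object answers `coef()` (the weights), `predict()` (fused probabilities or
hard labels), `plot()` (the fitness trace) and `summary()`.

## The genetic algorithm

A chromosome is a point on the $K$-simplex. The generational loop is
standard:

* **Initialisation** — `population_size` (default 30) draws from the
  symmetric Dirichlet(1), i.e. uniform on the simplex.
* **Fitness** — overall accuracy of the weighted ensemble's argmax
  predictions on the supplied bundle. The package takes no position on
  train/validation splits; fitness is computed on exactly the bundle you
  pass (the CLI's `optimize --holdout` draws a seeded subset if you want
  selection and reporting separated).
* **Selection** — tournament of size 3 by default; roulette-wheel selection
  is available, with a uniform fallback when all fitnesses are zero.
* **Crossover** (rate 0.9) — the two parents exchange a random non-empty
  proper subset of coordinates; for $K = 2$ this is exactly the classic
  exchange producing raw offspring $(\alpha_1, \beta_2)$ and
  $(\alpha_2, \beta_1)$. Because the raw offspring generally leave the
  simplex, each is divided by its coordinate sum (a raw sum of zero resets
  that offspring to uniform weights). This "minimal repair" preserves the
  parents' proportions.
* **Mutation** (rate 0.2) — one coordinate is perturbed by
  $\delta \sim U(-0.05, 0.05)$, clipped to $[0, 1]$, and the remaining
  coordinates are rescaled so the sum returns to 1; for $K = 2$ this is the
  complementary update $\alpha \to \alpha + \delta$,
  $\beta \to \beta - \delta$.
* **Elitism** — the single best chromosome is copied unchanged into the next
  generation, which makes the best-fitness trace non-decreasing — a
  contract the tests check on every run.
* **Termination** — `max_generations` (default 50) or a caller-supplied
  `fitness_target`.

Fitness ties are resolved toward the earlier-evaluated chromosome, so a run
is a pure function of the seed. All hyperparameters live in `ga_config()`;
none of the defaults is canonical, they are conventional small-GA settings.

## Verification oracles

For $K \le 3$, `grid_search_weights()` evaluates the fitness on every
simplex grid point (ties to the lexicographically smallest point). For
$K = 2$ the package goes further: the fused argmax of each sample changes
only where two classes' fused probabilities tie, so ensemble accuracy is
*piecewise constant* in the mixing weight $a$, with at most $N\binom{C}{2}$
breakpoints. `exact_max_accuracy()` enumerates all of them and evaluates the
fitness on every breakpoint and every interval midpoint, giving the exact
maximum attainable accuracy. A grid of any finite step can miss plateaus
narrower than its step — on realistic instances the landscape really does
contain plateaus narrower than $10^{-3}$ — so the exact oracle, not a fine
grid, is the correct upper reference for what any optimizer can achieve.

This piecewise-constant structure has a practical consequence worth stating
plainly: the fitness landscape is flat almost everywhere, optima are
plateaus rather than points, and on finite evaluation sets narrow
noise-driven spikes can sit a few samples above broad plateaus. A
population-based search with a local mutation scale finds the right plateau
reliably but cannot be expected to hit hairline spikes; when we compare the
GA against the grid oracle we therefore measure distance to the oracle's
*maximal plateau set*, and we treat agreement of the achieved accuracy
within half a percentage point as success.

## Evaluation metrics

`evaluate_predictions()` computes, per class in one-vs-rest terms,
$\mathrm{precision} = TP/(TP+FP)$, $\mathrm{recall} = TP/(TP+FN)$ and
$F_1 = TP/(TP + \tfrac12(FN+FP))$ — the count form, algebraically equal to
$2PR/(P+R)$ whenever $P+R>0$. Degenerate $0/0$ classes return 0 with a
warning rather than `NaN`: in many-class problems empty predicted classes
are routine and exceptions would make fitness evaluation fragile. Aggregation
offers `micro` (pooled counts), `macro` (unweighted mean) and `weighted`
(support-weighted mean, the default). Support-weighted recall is identically
the overall accuracy for single-label data, which is why published ensemble
tables often show equal accuracy and recall columns; the tests assert that
identity to $10^{-12}$. Top-$k$ accuracy ranks classes by fused probability
with ties broken toward the lowest class index, consistent with
`predict_classes()`, so top-1 equals argmax accuracy exactly.

## The simulator

`simulate_bundle()` generates what the real pipeline would obtain from $K$
fine-tuned backbones, without any images: a true label per sample from the
class priors; per model a correct/incorrect event with the model's accuracy;
on an incorrect event a wrong "intended" class drawn from a configurable
confusion matrix; and finally a Dirichlet row with concentration $\kappa$
(`sharpness`) on the intended class and 1 elsewhere. Large $\kappa$ makes
the argmax equal the intended class almost surely, so the configured
accuracy is reproduced empirically — calibration is tested at
$\kappa = 10^4$, $N = 2000$ within three binomial standard errors.
Inter-model error correlation $\rho$ couples the correct/incorrect events
through a shared latent uniform (with probability $\rho$ all models
threshold the same uniform; a Gaussian copula would add nothing here but
would cost exact analyzability). Dirichlet emission rather than one-hot
rows is deliberate: fusing degenerate one-hot rows collapses to weighted
voting and would not exercise the probability arithmetic.

`scenario_s1(seed)` is the canonical complementary-error fixture: $N = 500$,
$C = 5$, two models of accuracy 0.80 with independent errors routed to
disjoint wrong-class pairs (model 1 confuses $c$ with $c+1, c+2 \bmod 5$;
model 2 with $c+3, c+4$). One honest caveat, visible in the landscape
analysis above: because the emission model makes wrong rows exactly as
confident as correct ones, the *expected* fused accuracy of two symmetric
complementary models is nearly flat in the mixing weight — the realized
optimum on a given instance is interior but shallow. The fixture therefore
exercises interior-optimum recovery in a deliberately hard, low-signal
regime; scenarios with asymmetric accuracies give the optimizer much
stronger gradients.

What the simulator does *not* emulate: class-dependent accuracy, confidence
that is lower on errors than on correct predictions (the property that makes
real ensembles gain more than these synthetic ones), sample-level difficulty
shared across models beyond the single correlation parameter, and any
structure of real MRI backbones. Passing tests on synthetic bundles
therefore validate the arithmetic, the optimizer and the metrics — not any
claim about real imaging data.

## Numerical choices and edge cases

* Rows are accepted within $10^{-3}$ of sum 1 on ingest (serialized softmax
  is often low-precision) and made exactly row-stochastic internally;
  `renormalize = TRUE` additionally rescales arbitrary non-negative rows.
* Weights passed to fusion are validated against the simplex at $10^{-9}$
  and never silently renormalized; repairing weights is the optimizer's job.
* Argmax and top-$k$ ties break toward the lowest class index,
  deterministically.
* Class columns must match the first model's header exactly; only rows are
  reordered (by sample id). Silent column realignment is a corruption
  hazard.
* Problem sizes in the tests — $N = 500$, $C = 5$, 20 seeds per scenario
  family, $10^4$ fuzzed simplex operations — keep the full suite under half
  a minute while leaving binomial noise small relative to the tolerances.

## Known limitations

* The exact-maximum oracle covers $K = 2$ (the grid oracle $K \le 3$);
  beyond that only the GA explores the simplex.
* Fitness equals accuracy; no multi-objective or calibration-aware
  selection.
* The GA cannot distinguish weights within a fitness plateau — on flat
  landscapes the returned weight is one arbitrary point of the optimal
  plateau, not its centre or boundary.
* No ROC/AUC or confidence intervals; the report covers accuracy,
  precision/recall/$F_1$ (three aggregations) and top-$k$.
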
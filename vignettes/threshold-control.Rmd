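---
title: "Threshold parameter control in wrapper-based evolutionary feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold parameter control in wrapper-based evolutionary feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efscontrol)
```

## The problem

Wrapper-based evolutionary feature selection (EFS) searches for a feature
subset $S \subseteq X = \{F_1, \dots, F_n\}$ that minimizes a fitness
combining a classifier's error with the relative subset size,

$$f(S) = \beta\,(1 - \mathrm{Acc}) + (1 - \beta)\,\frac{L(S)}{L(X)},$$

where $\mathrm{Acc}$ is cross-validated accuracy of a classifier trained on
$S$, $L(\cdot)$ counts features and $\beta \in (0,1)$ weighs accuracy
against compactness. The optimizer works on a real-coded genotype
$x \in [0,1]^n$; the genotype–phenotype mapping thresholds each gene,

$$S = \{\,j : x_j \ge \theta\,\},$$

so the threshold $\theta$ directly controls the selection pressure on
subset size. Most of the literature fixes $\theta = 0.5$; this package
exists to study what happens when $\theta$ is *controlled* instead.

## The six control mechanisms

All mechanisms share one interface (`make_controller()` /
`controller_update()`): they consume per-generation population summaries
and emit the global threshold $\theta_t$ — or, in the self-adaptive case,
each individual carries its own $\theta_i$.

* **static** — $\theta_t \equiv \theta_0$ (default 0.5, the conventional
  baseline).
* **lr** (linear ramp) — $\theta_t = \theta_{\min} + \frac{t}{T}
  (\theta_{\max} - \theta_{\min})$: selection pressure tightens linearly
  over the horizon $T$.
* **cr** (cosine ramp) — $\theta_t = \theta_{\min} +
  \frac{\theta_{\max}-\theta_{\min}}{2}\left(1 - \cos\frac{\pi t}{T}\right)$:
  slow at both ends, fast in the middle.
* **pc** (proportional control) — regulates the realized selection rate
  $\rho_t$ (population-mean fraction of selected features) toward a target
  $\rho^\star$: $\theta_{t+1} = \Pi[\theta_t + \eta(\rho_t - \rho^\star)]$,
  with projection $\Pi$ onto $[\theta_{\min}, \theta_{\max}]$.
* **sra** (success-rate adaptation) — multiplies $\theta$ by $c_\downarrow
  = 0.85$ when the success rate $SR_t$ (fraction of population slots whose
  fitness improved this generation) exceeds its target $SR^\star$, and by
  $c_\uparrow = 1.15$ otherwise; ties take the increase branch.
* **sa** (self-adaptation) — appends $\theta_i$ to each genome; it is
  varied by the same operators as the problem genes and projected back
  into $[\theta_{\min}, \theta_{\max}]$ after every variation.

### Parameters and defaults

| parameter | meaning | default | note |
|---|---|---|---|
| $\theta_{\min}, \theta_{\max}$ | threshold bounds | 0.1, 0.9 | fixed across datasets for comparability |
| $\theta_0$ | initial/static threshold | 0.5 | the conventional baseline; also used to start pc and sra, which is our choice — the adaptive controllers' starting point is otherwise unspecified |
| $\eta$ | pc learning rate | 0.05 | unitless per-generation step |
| $\rho^\star$ | pc target selection rate | 0.2 | a package default: the mechanism requires a target but no canonical value exists; set it per study |
| $SR^\star$ | sra target success rate | 0.15 | empirically motivated |
| $c_\downarrow, c_\uparrow$ | sra factors | 0.85, 1.15 | ±15% multiplicative steps |
| $T$ | schedule horizon | `max_evals %/% np` | makes the ramps well-defined under an evaluation budget, counting the initial population against it (3000/30 → 100) |

The success-rate definition deserves a note: fitness is minimized, so a
"slot improved" means its fitness strictly *decreased*; that is the
default. `compute_success_rate(direction = "literal")` counts strict
increases instead, for studies that want the other convention — the two
differ only in which side of $SR^\star$ a generation lands on.

## Optimizers

The generic loop (initialize, then modify / evaluate / select until the
budget is spent) is optimizer-agnostic. Built-in backends:

* **jDE** — DE/rand/1/bin where each individual carries its own $F$ and
  $CR$; with probabilities $\tau_1 = \tau_2 = 0.1$ they are regenerated
  ($F \sim U[0.1, 1.0]$, $CR \sim U[0,1]$) before building the trial, and
  the regenerated values survive only if the trial replaces its parent.
* **de** — DE/rand/1/bin with fixed $F = 0.5$, $CR = 0.9$.
* **pso** — velocity/position updates with inertia $w = 0.7$, cognitive
  and social coefficients $c_1 = c_2 = 1.5$, velocities clamped to
  $[-1, 1]$.
* **rs** — random search: fresh uniform genotypes, keeping the better per
  slot.

GA, ABC and LSHADE are not implemented; `register_optimizer()` accepts
external step functions with the same contract, so they can be plugged in
without touching the loop. DE-family selection breaks fitness ties in
favour of the trial, which lets the search drift across plateaus. In
self-adaptive mode the threshold gene is varied exactly like a problem
gene and then projected into its own bounds, while problem genes are
projected into $[0,1]$.

Two policies are worth stating because the behaviour they govern is
reachable in practice:

* **Empty subsets.** At high thresholds a genotype can decode to no
  features. The default policy assigns the worst fitness (1.0, accuracy
  recorded as 0); the alternative `repair` keeps the single strongest
  gene. The default was chosen because it penalizes degenerate genotypes
  without silently changing them.
* **Stale bests.** When a global controller moves $\theta$ between
  generations, previously cached fitness values (DE parents, PSO
  personal/global bests) are *not* recomputed under the new threshold.
  Re-evaluation would spend budget on old solutions; the approximation is
  documented rather than hidden.

## Evaluation protocol

One run: a stratified 70/30 train/test split (largest-remainder
apportionment of the train quota per class); min-max normalization fitted
on the training split only, with held-out values clipped to $[0,1]$ and
zero-variance features mapped to 0; stratified 5-fold cross-validation on
the training split for the wrapper accuracy (unweighted mean of fold
accuracies), with the fold assignment fixed for the whole run so every
candidate subset is scored on identical folds; KNN with $K = 5$ and
Euclidean distance as the wrapped classifier, with deterministic
tie-breaking (distance ties by training-row index; vote ties by the tied
class with the closest member, then the smallest label). The test split
stays unseen until the final validation of the best subset. Normalization
is fitted on the training split only as a leakage-avoidance choice; an
alternative reading of the protocol would normalize the full dataset
before splitting, which we deliberately do not do.

Multi-run experiments (`run_experiment()`) re-draw the split per run —
run $r$ uses seed `base_seed + r`, from which sub-stream seeds for split,
folds and optimizer are derived, so any run replays byte-identically.
Convergence is summarized by the generation-to-convergence metric (GTC):
the generation at which the final best fitness was first attained.

## Ranking methods across datasets

`build_score_matrix()` stacks one row per (dataset, summary statistic)
pair — with the mean and the median over runs, 15 datasets give
$2 \times 15 = 30$ paired observations, ranked jointly in one matrix. The
Friedman test (classic $\chi^2$ form; the Iman–Davenport correction was
deliberately not adopted, keeping the standard test) gates the post hoc
stage: the Nemenyi critical difference
$CD = q_\alpha \sqrt{k(k+1)/(6N)}$, with $q_\alpha$ the studentized-range
quantile at infinite degrees of freedom over $\sqrt 2$ (computed from
`qtukey`, not a hard-coded table), and Wilcoxon signed-rank tests of each
method against the control (lowest average rank). The Wilcoxon
implementation drops zero differences, enumerates the exact null by
convolution for up to 25 untied pairs and otherwise uses the
tie-corrected normal approximation without continuity correction; raw
p-values are reported by default with an optional Holm correction.

## The synthetic generator

`synth_generate()` plants three feature blocks: informative columns from
class-conditional Gaussians (unit within-class sd, class means separated
by `class_separation` on scaled coordinate axes — a regular simplex up to
translation when the informative dimension admits it); redundant columns
as unit-norm random mixtures of the informative block plus Gaussian noise
(`redundancy_noise_sd`); and independent standard-Gaussian noise columns.
The ground-truth mask marks informative and redundant columns. Defaults
(`class_separation = 2`, `redundancy_noise_sd = 0.1`) give a moderately
hard problem: well above chance on the informative block, far from
saturating, chosen once as representative of the benchmark datasets'
difficulty.

What it does *not* emulate: heteroscedastic or batch-structured noise,
correlated noise features, label noise, class imbalance beyond the
remainder of integer division. Tests that pass on this generator
demonstrate the mechanics and the direction of effects — e.g. that
self-adaptive thresholds shrink subsets relative to the static baseline
at $\beta = 0.5$ — not performance claims about any particular real
dataset.

## Worked example

```{r example}
gen <- synth_generate(synth_spec(n_samples = 120, n_classes = 2,
                                 n_informative = 5, n_redundant = 5,
                                 n_noise = 40, class_separation = 3,
                                 seed = 7))
fit <- efs(gen$dataset$X, gen$dataset$y, algorithm = "jde",
           controller = "sa", beta = 0.5, max_evals = 900, seed = 1)
summary(fit)
recovery_scores(fit$selected, gen$truth_mask)
```

```{r plot, fig.width = 6, fig.height = 5}
plot(fit)
```

## Numerical choices and limitations

* Decoding is inclusive ($x_j \ge \theta$), so a gene exactly at the
  threshold selects its feature.
* Schedules queried past their horizon stay clamped at $\theta_{\max}$.
* Problem sizes in the package's own test suite are scaled to desk scale
  (hundreds of features, hundreds of samples, budgets of 1500–3000
  evaluations, 10-run experiments); the machinery itself has no such
  limits, and the directional comparisons were designed at those sizes.
* Evaluation counting: every fitness computation (initial or trial)
  consumes budget; survivor re-selection does not. When the remaining
  budget cannot fund a full generation the loop stops, leaving the
  remainder unspent — with the canonical 30/3000 configuration nothing is
  lost.
* The KNN wrapper is the only classifier; results are classifier-dependent
  by design, and alternative wrappers (SVM, random forest) or accuracy
  metrics (balanced accuracy, F1) are out of scope.
* Per-feature thresholds and hybrid global-plus-local controllers are not
  implemented.
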
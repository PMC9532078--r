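# sparrowforge

Chaos-enhanced sparrow search optimization, and swarm-trained neural
networks for binary clinical risk prediction.

## What problem this addresses

Training a small dense neural network on a few hundred tabular clinical
records is a bad fit for plain gradient descent: the MSE surface is
multimodal and gradient training stalls in poor local minima. This package
takes the metaheuristic route. It implements the sparrow search algorithm
(SSA) — a swarm optimizer whose population splits each iteration into
*discoverers* (best-ranked, wide exploration), *followers* (tracking the
best discoverer) and *scouts* (anti-predation moves) — and an improved
variant, **CGSSA**, that adds

* chaotic-map population initialization (nine maps; the *iterative* map
  `z' = sin(0.7 * pi / z)` defines the flagship "IIGSSA" variant),
* Gaussian mutation `x * (1 + G)` of better-than-average individuals, and
* chaotic perturbation `(x + x_n) / 2` of the rest, with `x_n` a fresh
  chaos-derived point in the box,

both under greedy acceptance. A 14-function benchmark suite (Sphere,
Schwefel 2.21/2.22, Rosenbrock, Step, Quartic, Alpine, Rastrigin,
Sum squares, Ackley, Matyas, Levi, Booth, Three-Hump) with a paired-seed
experiment harness compares the baseline against the nine chaotic variants.

For the clinical half, the optimizer searches the flat weight vector of a
from-scratch sigmoid feedforward network minimizing training MSE, with
optional Adam refinement; evaluation uses confusion-matrix criteria
(Acc/REC/PRE/FPR/TNR/F1/G-mean), trapezoidal ROC/AUC (= Mann–Whitney
concordance) and stratified 5-fold cross-validation. Because the motivating
esophageal-cancer cohort is private, a synthetic generator reproduces its
marginal feature summaries (398 records, 26 features, 101/297 live/dead)
with a configurable, documented feature-to-outcome signal so the entire
pipeline is testable end to end.

Who this is for: anyone studying chaotic-map improvements to swarm
optimizers, and biostatisticians who want a reproducible, self-contained
reference pipeline for metaheuristic network training on small tabular
cohorts.

## Worked example

```r
library(sparrowforge)

## 1. Improved optimizer on the 30-d Ackley function
fn  <- benchmark_fn("F10")
cfg <- sparrow_config(D = fn$dimension, lb = fn$lower, ub = fn$upper,
                      N = 30, T = 500, map = chaotic_map("iterative"),
                      seed = 1)
res <- run_cgssa(benchmark_objective(fn), cfg)
print(res$best_f)
#> [1] 4.440892e-16
```

That value is not a bug: at the exact origin the Ackley expression
evaluates in IEEE doubles to `4.440892098500626e-16` (the two `exp` terms
cancel imperfectly), so it is the practical optimum any double-precision
optimizer can report. The optimizer's positions have collapsed below
`1e-17`, where the formula plateaus at this floor.

```r
## 2. Synthetic cohort + cross-validated swarm-trained network
co  <- generate_cohort(n = 398, seed = 11, exact_counts = TRUE)
table(co$survival_status)
#> live dead
#>  101  297

cfg <- trainer_config(network_spec(c(26, 8, 1)), N = 30, T = 150, seed = 1)
cv  <- cross_validate(co, cfg, k = 5, seed = 1)
round(unlist(cv$mean[c("Acc", "REC", "PRE", "AUC")]), 3)
#>   Acc   REC   PRE   AUC
#> 0.807 0.889 0.861 0.821
```

Read: on a cohort with the default planted signal (death log-odds on TNM
stage, transfer status and tumor length; Bayes-optimal AUC about 0.91), the
swarm-trained 26-8-1 network recovers a cross-validated AUC of 0.821 —
clearly above chance and close to the planted ceiling, with death as the
positive class. On a label-permuted copy the same pipeline returns AUC near
0.5, which is the point of the control.

There is also a command-line interface:

```sh
Rscript inst/cli/sparrowforge.R simulate --n 398 --exact-counts --out cohort.csv
Rscript inst/cli/sparrowforge.R benchmark --functions F1,F10 --variants ssa,iterative --repeats 20 --out results.csv
Rscript inst/cli/sparrowforge.R train --data cohort.csv --arch 26-8-1 --iters 150 --out model.json
Rscript inst/cli/sparrowforge.R evaluate --data cohort.csv --arch 26-8-1 --iters 150 --out metrics.json
```

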
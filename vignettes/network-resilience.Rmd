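---
title: "Resilience of Ising symptom networks: models, metrics, and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience of Ising symptom networks: models, metrics, and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netresil)
library(dplyr)
```

## The model

netresil treats a set of psychiatric symptoms as nodes of an Ising network.
A configuration assigns each node $X_i \in \{0, 1\}$ (absent/present), and
its probability is

$$P(X_1, \dots, X_n) = \frac{1}{Z}\exp\Big\{\sum_i \tau_i X_i +
\sum_{i<j} W_{ij} X_i X_j\Big\},$$

where $\tau_i$ is node $i$'s threshold (its autonomous disposition toward
activation; for symptoms usually negative, i.e. hard to activate), $W_{ij}$
is the symmetric pairwise interaction weight, and $Z$ sums the potentials of
all $2^n$ states. Each unordered pair contributes once. The spin coding
$\{-1, 1\}$ is supported through `convert_domain()`, which reparameterizes
$(\tau, W)$ so the joint law is unchanged; the $\{0,1\}$ coding is the
package default because symptom data are naturally absence/presence.

Up to a configurable limit (`options(netresil.enum_limit = 20)`, default 20
nodes, about a million states) the distribution is computed exactly by full
enumeration. All potentials are handled in log space with log-sum-exp
normalization: strong risk perturbations of even a nine-node network produce
potentials as large as $e^{36}$, which would overflow a naive
exponentiation.

## The resilience metrics

Let $Y = \sum_i X_i$ be the sum score (number of active symptoms), with
distribution $P(Y = i)$ obtained by collapsing the joint law.

* **ESA** (Expected Symptom Activity) is $\mu = \sum_i i\, P(Y=i)$: how many
  symptoms the network is expected to have active. Low ESA = healthy state.
* **SAS** (Symptom Activity Stability) is $1/\sigma$ with
  $\sigma = \sqrt{\sum_i (i-\mu)^2 P(Y=i)}$. A standard deviation of 1 is
  the natural reference: SAS above 1 means activity is more stable than that
  reference, below 1 less stable. A resilient network shows low ESA *and*
  high SAS — symptoms stably absent.

SAS is connected to the model's entropy (`distribution_entropy()`, reported
in nats; no base is canonical, and orderings are base-invariant): when many
states are nearly equally probable the system wanders among them, and both
entropy and $\sigma$ are large.

From sampled or observed data the same metrics are the mean and the inverse
standard deviation of the per-row sum scores. The standard deviation uses
the population denominator ($N$, not $N-1$), mirroring the distributional
definition; `sas_from_samples()` exposes the sample denominator as an
option. A degenerate point mass ($\sigma = 0$) yields `NA` plus a typed
warning (`netresil_degenerate`) rather than an infinite SAS, so tables can
render the case explicitly; reports carry a `degenerate` flag.

## Risk and protective factors as parameter perturbations

External risk/protective (RP) factors act multiplicatively on the network's
parameters:

* **Main effects** multiply thresholds. With negative symptom thresholds, a
  constant below 1 makes activation easier (risk), above 1 harder
  (protective).
* **Moderators** multiply edge weights. For positive weights a constant
  above 1 is risk, below 1 protective. Absent edges stay absent.
* **Both** applies one constant to thresholds and edge weights
  simultaneously.

The canonical grid (`multiplier_grid()`) runs 0.5 to 1 in steps of 0.1 plus
the exact inverses of those sub-unit constants, 11 values in all, symmetric
on the log scale around the unperturbed baseline of 1. The constants above 1
are kept exact ($1/0.7 = 1.428571\dots$) rather than rounded to two decimals:
the grid's definition is "inverses of the sub-unit constants", and at two
printed decimals the distinction is invisible anyway. Perturbations compose
multiplicatively and never mutate their input network.

A useful exact property anchors the "both" sweeps: whenever
$\tau_i = -\tfrac{1}{2}\sum_j W_{ij}$ for every node, the model is invariant
under flipping all nodes, the sum-score law is symmetric, and ESA is pinned
at exactly $n/2$ for *every* constant — only SAS moves. The canonical
nine-symptom example ($\tau = -2$, $w = 0.5$, fully connected) satisfies
this identity, which is why its simultaneous perturbation rows hold ESA at
4.5 while threshold-only or edge-only perturbations move ESA monotonically
along the grid.

```{r study1, eval = FALSE}
res <- run_study1() # densities 1 / 0.5 / 0.3 x 11 constants x 3 targets
autoplot(res)
```

For densities below 1, `random_density_network()` places exactly
`round(density * n(n-1)/2)` equal-weight edges uniformly at random under a
seed. Published sparse-structure results depend on edge placements that are
not recoverable from a figure, so sparse densities are treated as trend
conditions (baseline ESA falls with density; the ESA range across the grid
compresses) rather than cell-by-cell targets; the tests check exactly those
trends over 20 seeded structures per density.

## Chain sampling beyond the enumeration limit

Networks beyond the enumeration limit (for instance a 27-item checklist
network) are simulated with a single-site Markov chain: one node at a time
is resampled from its full conditional
$P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j W_{ij} x_j)$,
in sequential sweep order, starting from random node values. Proposing the
opposite response option and accepting it with its conditional probability —
the Metropolis–Hastings phrasing — is identical to this Gibbs update for a
single-site proposal, so the two descriptions coincide. The update loop is
compiled (Rcpp) and uses R's RNG, making chains bit-reproducible under
`set.seed()`-style seeds.

"Iteration" is interpreted as **one single-node update** by default, the
most literal reading of the update rule; `update = "sweep"` makes an
iteration a full pass over all $n$ nodes, which is what reference samplers
in this field record between saved states. The distinction matters for
validation: in single-update mode consecutive kept states differ by at most
one bit, so empirical state frequencies carry heavy autocorrelation. The
package's sampler-against-enumeration checks therefore keep states one
sweep apart; with 200,000 kept sweeps on networks of 3–6 nodes (thresholds
drawn from $[-1.5, 0.5]$, weights from $[-0.5, 1]$ — the magnitudes typical
of estimated symptom networks), total-variation distance from the exact law
stays below 0.01 with a maximum around 0.0075. Burn-in defaults to 0 and one
chain of 1,000 kept states mirrors the classic chain-mode settings;
`burn_in`, `thin`, and `n_chains` are exposed for better practice in new
analyses.

Chain-mode ESA/SAS converge to their exact counterparts; the tests verify
the error decreases with chain length and that replicate-chain means land
within three Monte-Carlo standard errors of exact values.

## Centrality-targeted perturbations

`node_strength()` scores each node by the sum of absolute incident edge
weights — the most stable of the common centrality indices — with ranks tied
deterministically by label order. `run_study2()` targets the $k$ strongest
and $k$ weakest nodes ($k = 5$ by default, exposed as an argument):
thresholds of the selected nodes, plus all edges *incident* to them. The
incident-edge semantics (any edge touching a selected node) matches how
targeted parameters are usually displayed; `within_only = TRUE` restricts to
edges internal to the selected set for sensitivity analysis. The documented
qualitative expectation — perturbing strong nodes moves ESA through a wider
range than perturbing weak nodes — is asserted on a seeded synthetic 27-node
network.

## Estimating a network from data

`binarize()` recodes 5-level ordinal items by the moderate-presence rule
(levels $\{0,1,2\} \to 0$, $\{3,4\} \to 1$; the cut is configurable), and
`fit_elasso()` implements the eLasso procedure: nodewise L1-penalized
logistic regression (via glmnet) over a 100-value penalty path, log-spaced
from the smallest penalty that zeroes all coefficients down to 0.001 of it;
per-node selection by extended BIC,
$\mathrm{EBIC} = -2\ell + \mathrm{df}\,\log N + 2\gamma\,\mathrm{df}\,\log(p-1)$
with $\gamma = 0.25$; and AND-rule symmetrization (an edge requires both
directions, weight = mean of the two coefficients; OR-rule and
max-magnitude combination available). These defaults are the established
ones for this estimator. Items constant after binarization are dropped with
a logged warning rather than failing the fit. On sparse ten-node truths at
the canonical symptom scale ($\tau = -2$, unit couplings, marginal
prevalences around 0.15–0.25) and $N = 2{,}000$, sign recovery is
essentially perfect and false-positive edges exceed one in fewer than 10%
of seeds; recovery error shrinks monotonically with $N$.

## Conditioning hybrid symptom + RP networks

For datasets where RP factors are measured alongside symptoms, the model
class is a nodewise-linear hybrid network (`hybrid_model()`): every node has
an intercept and linear coefficients on all other nodes, ordinal variables
treated as continuous — the parameter set produced by nodewise-regression
estimators of mixed graphical models (the estimation of such models is out
of scope here; any nodewise-linear parameter set is accepted).

`condition_means()` fixes chosen RP factors ("presence" = scale maximum,
"absence" = scale minimum, per factor configurable), leaves the rest at
their baseline means, and propagates each symptom's nodewise prediction to
a **fixed point** (Jacobi iteration, tolerance $10^{-8}$, cap 1,000
iterations, non-convergence is an error naming the worst nodes), so effects
travel through neighboring symptoms as well as direct symptom–RP edges. A
`one_step` mode propagates direct effects only, for sensitivity analysis.

Two numerical choices deserve emphasis:

* **Anchoring.** The conditioned mean is reported as the observed baseline
  mean plus the model-implied shift (scenario fixed point minus
  baseline-RP fixed point). For regression-fitted models — which pass
  through the variable means — this equals propagating predictions
  directly; anchoring additionally guarantees that an empty scenario
  changes nothing and that symptoms with no path to any conditioned factor
  keep their baseline means exactly.
* **Clipping.** Conditioned means are clipped to each node's observed scale
  range and the clip count is reported; scenarios inside the data's convex
  hull do not clip.

ESA in this ordinal setting is the sum of (conditioned) symptom means —
with 27 items scored 0–4 the ceiling is $4 \times 27 = 108$ — and
`esa_delta()` reports the signed change from baseline. SAS is deliberately
not computed here: fixing RP factors moves symptom means but not the
residual variance structure, so sum-score variability no longer measures
activity stability in this model class.

## Synthetic data

Because the empirical checklist dataset is external, all test fixtures are
generated:

* `sample_ising_exact()` draws i.i.d. configurations from the enumerated
  joint law (inverse-CDF over state indices).
* `generate_ordinal_scl()` emulates checklist items with a single latent
  common factor and per-item thresholds placed so that binarized
  prevalences fall in a realistic 5–40% band. It exists to exercise
  binarization and estimation, not to match any empirical item set.
* `generate_hybrid_dataset()` plants a known hybrid model — protective
  factors with negative, risk factors with positive symptom coefficients, a
  weak nearest-neighbor symptom chain — and solves the structural linear
  system per person with Gaussian residuals, returning both the data and
  the generating model. The symptom side is linear-Gaussian by design,
  matching the nodewise-linear model class the conditioning module
  consumes; it does not attempt a full mixed exponential-family law.

All generators are seed-deterministic, and the caller's RNG state is always
restored.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for a single CPU: exact
work enumerates at most $2^{10}$ states; sampler validation uses 200,000
kept sweeps on 3–6-node networks and replicate chains of 100,000 states on
the nine-node example; estimation checks run 50 seeds at $N = 2{,}000$ plus
20 seeds each at $N = 500$ and $N = 4{,}000$; conditioning sign checks run
100 seeds at $N = 2{,}000$. The full suite completes in about a minute,
the estimation block dominating.

## Known limitations

* Exact analysis is exponential in $n$; beyond the enumeration limit all
  statements are Monte-Carlo.
* Perturbations are static multipliers: no additive effects, no feedback
  from symptoms to RP factors, no time-varying parameters.
* The hybrid conditioning model is linear in means; it cannot express
  moderation of symptom–symptom edges by RP factors, and SAS is undefined
  in it.
* Passing the synthetic-data tests shows the machinery is correct under the
  generators' assumptions (binary Ising states, latent-factor ordinal
  items, linear-Gaussian symptom scores); real checklist data violate these
  in ways the fixtures do not emulate (item skew, local dependence,
  missingness).
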
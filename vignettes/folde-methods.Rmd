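---
title: "Methods: model-guided low-N protein optimization with folde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-guided low-N protein optimization with folde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, the choices made
where the design was genuinely open, and what the synthetic benchmark can
and cannot show.

## The problem

Low-N protein engineering optimizes activity under a budget of a few
dozen measurements, collected in small batches over a few rounds. Every
selection plays two roles at once: it is a bet on a good mutant *and* it
is the training data for the next round's model. The package treats the
campaign as a closed loop and evaluates policies by end-of-campaign
success, not by one-shot prediction accuracy.

## Naturalness and zero-shot selection

A protein language model, given the unmasked wild-type sequence `x`,
yields per-position amino-acid distributions `P(y | x)`. The naturalness
of a mutant `x'` with mutated positions `T` is the summed log-likelihood
ratio `Σ_{i∈T} [log P(x'_i|x) − log P(x_i|x)]`. This single-pass,
wild-type-marginal formulation treats mutations independently — their
effects add in log space — and requires no biological measurement.
Round 1 selects the top 16 single mutants by naturalness. Ties are broken
lexicographically by (position, mutant letter): deterministic and
seed-free; masked-marginal variants are out of scope. In practical design
(the CLI `design` command) at most 3 mutations per locus are taken, a
diversity guard that simulations leave off.

Inside the package naturalness lives in a `LogProbMatrix` (rows must
exponentiate to probability distributions within 1e-6) and a
`NaturalnessTable` of all `L × 19` single mutants.

## The ranking ensemble

Activity prediction uses an ensemble of 5 multilayer perceptrons over
fixed-length sequence embeddings (default input 960, hidden 100 → 50,
batch-norm after each hidden layer, ReLU, dropout 0.2, no bias in the
final linear layer), trained with Adam (learning rate 3e-4, weight decay
1e-5) on the Bradley–Terry pairwise ranking loss. The loss depends only
on score *differences*, which has three consequences the design leans on:

* targets enter only through their ordering, so naturalness scores and
  activity measurements — different units, different scales — can train
  the same network in sequence;
* a final-layer bias is unidentifiable, hence `final_bias = FALSE`;
* member scores are only defined up to a shift, so each member's
  predictions are demeaned over the candidate set before the consensus
  (mean) and across-member covariance are formed. The covariance uses
  deviations from the consensus with `1/(K−1)` normalisation; members
  that agree exactly give a zero matrix, and its rank is at most `K − 1`.

**Warm-start.** Each member is pretrained (at most 50 epochs, patience
20, validation every 5) to reproduce the naturalness ordering of *all*
single mutants, then fine-tuned (at most 200 epochs, patience 40,
validation every 10) on measured activities. Warm-starting uses no
activity information — naturalness is a model output — so it may draw on
every single mutant, including the held-out half of a simulation, without
leaking assay data. The point of the warm-start is data bias: a
zero-shot round 1 measures only high-naturalness mutants, and a model
trained on those alone collapses in round 2; pretraining on the full
single-mutant spectrum preserves ranking ability (the acceptance script
reports the round-2 held-out Spearman with and without warm-start —
roughly 0.3 versus 0.0 under the default benchmark conditions).

**Pair construction and the transitivity-safe split.** All directed pairs
with strictly different targets are formed, one per unordered pair,
winner first; ties yield no pair (duplicating both directions would
double compute without information). Pairs are split 80–20 into train
and validation by a seeded shuffle that admits a pair `(a, b)` to
validation only if `b` is *not* reachable from `a` through the remaining
train pairs (breadth-first search) — otherwise the validation pair would
be trivially implied by transitivity. On dense pair sets the constraint
caps the feasible validation size (in a total order, essentially only
adjacent-rank pairs are admissible); the quota under-fill is logged, not
an error.

**Scale controls.** The pair universe grows quadratically in the record
count, and the BFS-checked split is super-quadratic, so the trainer
subsamples the pair universe to `maxPairs` (default 20,000, seeded)
before splitting, and warm-start targets are capped at `warmstartCap`
records (default 2,000). Optimisation walks minibatches of `pairBatchSize`
train pairs per Adam step (default 512; the tests use 64, which at fixed
epoch counts gives proportionally more steps), computing scores for the
unique records each minibatch touches. Batch-norm uses batch statistics
in training and running averages (momentum 0.1) at prediction; dropout is
disabled at prediction. Member `k` of an ensemble derives all of its
randomness — initial weights, pair shuffles, dropout masks — from
`baseSeed + k`, so every result in the package is bit-reproducible. The
training loop itself is compiled (RcppArmadillo) and draws its random
numbers from R's stream; the reference R implementation of the same
network remains the prediction path and is gradient-checked against
finite differences in the tests.

**Degenerate inputs.** Two measured records give a single pair: training
proceeds without validation or early stopping (logged). All-tied targets
are an error — there is nothing to rank.

## Constant-liar batch selection

Given consensus `y` and covariance `Σ` over a candidate pool,
constant-liar builds a batch greedily. Once, up front, `α · median(diag
Σ)` is added to the diagonal as observation noise. The lie is fixed at
the pool's initial minimum consensus. Each pick takes the posterior-mean
maximiser (a UCB coefficient on the posterior standard deviation is
exposed, default 0; ties break by candidate order), then conditions mean
and covariance on the imagined observation:

* `Σ' = Σ_rest − v vᵀ / σ_i²` — the Gaussian conditional covariance,
  independent of the lie's value;
* `y' = y_rest + v (y_lie − y_i) / σ_i²` — the conditional mean.

Both updates are verified against an independent precision-matrix
conditioning oracle to 1e-10 in the tests. Design choices the source
method leaves open, fixed here: the jitter is injected once before the
loop (the simplest scheme that stabilises every subsequent `σ_i²`); the
lie is not recomputed per pick; the median variance is not recomputed
after picks; rank-deficiency of `Σ` (K − 1 < N) is handled by the jitter
alone, no pseudo-inverse.

Small α makes the lie confident and the batch diverse; large α drowns it
out. A quantitative caveat worth knowing: with a 5-member ensemble the
sample covariance between unrelated candidates is itself noisy
(|v| ≈ half the median variance), so at α = 100 the accumulated mean
drift over a 16-pick batch is comparable to the consensus gap at the
batch boundary, and the selected *set* matches plain top-N only about
half the time on random score matrices — one boundary swap, typically.
Exact set equality emerges around α ≈ 10³–10⁵ (tested); α = 100 is
"near-pure exploitation", not literal top-N. Diagonal covariance (no
coupling) reproduces top-N exactly at any α.

## The campaign loop and metrics

A campaign runs `rounds × batchSize` selections (default 3 × 16) against
the accessible half of a landscape; the held-out half (50%, redrawn per
replicate) is never selected or trained on and serves only the Spearman
ranking diagnostic (capped at 2,000 seeded held-out mutants). Round 1 is
zero-shot (folde, zero_shot) or random (random, random_forest); the
round-1 candidate pool is the accessible single mutants for every
strategy, so baselines face the same universe. Later rounds expand the
pool progressively: a candidate qualifies if it is a single mutant or
extends a measured *hit* by exactly one mutation. "Hit" defaults to
measured activity strictly above the wild type (anchored at 0 in the
synthetic fixtures); top-quartile and top-k rules are available. The
constant-liar schedule is α = 6 in round 2 and α = 100 from round 3 on.

Metrics: cumulative top-10% hits (selections at or above the 90th
percentile) and whether any selection reaches the 99th percentile.
Percentiles — including the 99.375th percentile in the engineering
`difficulty` statistic — use linear interpolation between order
statistics (R's `quantile` type 7), fixed so results are reproducible;
the convention itself is a package choice, documented rather than
inherited. Thresholds are computed on the accessible half by default
(selection is restricted to it); computing on the full landscape is a
toggle. `bootstrapBenchmark` pairs strategies within a replicate (same
holdout, same seed), which the one-sided Wilcoxon signed-rank comparison
on log-transformed hit counts presupposes; when any count is zero both
sides are shifted by +1 before the log (logged). Exact p-values are used
for n ≤ 25 non-zero untied differences, the normal approximation with
continuity correction otherwise.

## The synthetic oracle

The generator emulates the statistical structure the method assumes, not
any real protein:

* **Landscape**: per-(position, amino acid) effects ~ N(0, effectScale²),
  zero at wild-type letters, so the wild type sits at activity 0 and
  additivity holds exactly; optional pairwise epistasis on a seeded 20%
  subset of position pairs, scaled so interactions carry an
  `epistasisWeight` share of double-mutant variance; i.i.d. measurement
  noise (`noiseSd`, default 0.1).
* **Log-probabilities**: row logits `β(E + ε)` with ε calibrated through
  the bivariate-normal rank-correlation relation `r = 2 sin(πρ/6)` so
  the realised Spearman between single-mutant naturalness and measured
  activity lands at `naturalnessRho` (default 0.5, matching the
  correlation regime protein language models exhibit; within ±0.1 for
  L ≥ 50). Measurement noise is accounted for in the calibration; if the
  noise alone already caps the correlation below the target, ε is zero.
* **Embeddings**: a `signalFraction` of coordinates are seeded linear
  reads of the mutant's per-position effect vector (additive across
  mutations, so a ranking model *can* learn), the rest a seeded random
  projection of one-hot sequence content. Embeddings are memoised in an
  in-memory cache keyed by sequence; the same `Embedder` contract
  (dimension, `embedSequences`, `logProbMatrix`) is what a real
  language-model adapter would implement.

What the generator does *not* emulate — rugged epistatic landscapes,
position-dependent noise, phylogenetic structure in the PLM prior,
assay-specific distributions — bounds what passing tests show: they
validate the machinery and the direction of the method's effects
(zero-shot > random in round 1; warm-start prevents the round-2 collapse;
folde > random and > random-forest on cumulative hits), not performance
on real proteins.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: landscapes of L = 30
(570 singles; L = 100 for the calibration checks), 32-dimensional
embeddings with 16 → 8 hidden units, `maxPairs` 2,000, `warmstartCap`
150, pair minibatches of 64, 20 paired bootstrap replicates for
directional comparisons and 3 seeds for recovery checks. The held-out
recovery benchmark uses L = 10 with 48 training mutants so that every
locus is sampled several times — held-out generalisation of a nonlinear
ranker is only well-posed when loci recur in training. Architecture
defaults (960 → 100 → 50 → 1) remain the real-embedding configuration.

## Known limitations

* The random-forest baseline uses `randomForest` defaults; its published
  counterpart runs far larger embeddings.
* Naturalness is strictly additive across mutations; epistatic
  naturalness formulations are out of scope.
* `splitPairs` is exact but O(quota × edges); hence the pair subsampling
  above rather than million-pair splits.
* Checkpoints are plain JSON (weights + manifest) — portable and
  diff-able, not compact.
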
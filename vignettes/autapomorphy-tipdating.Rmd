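---
title: "Ascertainment bias, autapomorphies and tip-dating: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertainment bias, autapomorphies and tip-dating: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autapodate)
```

## The problem

Morphological character matrices assembled for parsimony analysis usually
omit characters that carry no grouping information: invariant characters
and, above all, autapomorphies (states unique to a single terminal taxon).
Under parsimony this filtering is harmless; under probabilistic models it is
an ascertainment bias, because the model assigns positive probability to the
very patterns the matrix was prevented from containing.  In Bayesian
tip-dating — where serially sampled fossils enter as dated terminal taxa and
a clock model links expected character change to elapsed time — the problem
has a specific geometry: every autapomorphy sits on a terminal branch, so
excluding autapomorphies selectively starves terminal branches of evidence
of change.  `autapodate` implements the likelihood machinery, the
combinatorics, the simulators and the experiment needed to study this
effect.

## The Mk model and its corrections

Characters are modelled by the symmetric k-state Markov (Mk) model: all
transitions between the `k` states occur at the same rate, the total leaving
rate is 1, so a branch length `v` is the expected number of substitutions
per character.  The transition probabilities have the closed form

$$P_{\text{same}}(v) = \tfrac1k + \tfrac{k-1}{k}
  e^{-vk/(k-1)}, \qquad
  P_{\text{diff}}(v) = \tfrac1k - \tfrac1k e^{-vk/(k-1)},$$

with uniform root state frequencies `1/k`.  Likelihoods of site patterns on
a tree come from Felsenstein's pruning algorithm (`pruning_likelihood()`),
implemented in C++ over compressed site patterns; missing cells contribute
all-ones partials.

Conditioning on data filtering divides every pattern likelihood by the
probability of the observable class, `1 - L_unobs`:

* **Mkv** conditions on variability.  `L_unobs` is the mass of the `k`
  constant patterns; by state symmetry all `k` are equally likely, so one
  pruning evaluation suffices.
* **Mk-parsinf** conditions on parsimony informativeness.  `L_unobs` is the
  mass of every distinct pattern in which at most one state occurs in two or
  more taxa.  `unobservable_mass()` evaluates it by symmetry class: the
  likelihood of a pattern depends only on *which* taxa deviate from the
  background state, not on the state labels, so one pruning call per set of
  singleton taxa is multiplied by the number of labellings of that shape.
  For binary characters this costs `1 + n` evaluations; for multistate
  characters the class count explodes, which is the scalability point
  quantified below.

### Two counts, deliberately kept apart

`count_parsinf_terms(n, k)` evaluates

$$\sum_{j=0}^{\min(n,\,k-1)} k \binom{n}{j} \frac{(k-1)!}{(k-1-j)!},$$

the number of terms in the background-state enumeration of the correction
(choose a background state, choose `j` deviant taxa, give each a distinct
non-background state).  `count_distinct_uninformative(n, k)` counts distinct
*patterns*: the same sum truncated at `j <= n - 2` plus, when `k >= n`, the
`k!/(k-n)!` all-distinct patterns counted once.  The two agree exactly
whenever `k <= n - 2`, and the enumeration overcounts otherwise (at
`n = 4, k = 4`: 292 terms but 220 distinct patterns, verified here by brute
force over all 256 patterns).  Because a probability normalisation must sum
each pattern once, the likelihood correction uses the distinct-pattern mass.
Both counts use exact chunked-decimal integer arithmetic — the grid values
reach 5.97e15 and beyond, past the point where naive floating arithmetic is
trustworthy.

Both counts grow combinatorially in `k`; `enumerate_uninformative_patterns()`
refuses (with the required count in the error) once `k^n` passes a cap,
defaulting to 1e7.  That infeasibility is not a shortcoming of the
implementation but the substantive conclusion: the parsimony-informative
correction is impractical for many-taxon, many-state matrices.

## The synthetic benchmark

`make_benchmark()` emulates the study conditions:

1. A birth–death serial-sampling (BDSS) tree with 30 sampled fossil tips
   (`simulate_bdss_tree()`): forward Gillespie simulation with per-lineage
   birth rate λ, death rate μ and sampling rate ψ, sampling removing the
   lineage (no sampled ancestors), conditioned on the tip count by
   rejection.
2. A "strict clock" matrix of 1,000 binary characters simulated under Mk
   with branch lengths `duration × 0.05`.
3. A "non-clock" matrix: the branch *durations* are randomly permuted
   across branches (`reshuffle_branch_lengths()`), characters are simulated
   on the permuted lengths at the same rate, while the time tree — topology,
   node ages, tip dates — stays the truth.
4. Ascertainment-filtered variants of both: variable-only and
   parsimony-informative-only (`partition_matrix()`).

Defaults are λ = 1.5, μ = 0.3, ψ = 0.8 per Ma.  The generating process is
pinned down by two published quantities — 30 sampled tips and a character
rate of 0.05 low enough that roughly 58% of simulated characters come out
invariant or autapomorphic — and these rates were chosen, once, so that a
30-tip realisation reproduces that fraction (the defaults give ≈ 0.48–0.57
across seeds; trees are ~4–6 Ma deep with ~23 Ma total branch length, so
each character expects ~1.1 changes on the whole tree).  The time unit is
nominal: only the product of rate and duration matters.

What the generator does *not* emulate: missing data (real matrices are
riddled with it), among-character rate heterogeneity, correlated characters,
state-count mixtures, and tip-date uncertainty (ages are points, not
ranges).  Tests passing on these matrices therefore demonstrate the
model-facing mechanics — they do not certify behaviour on real, messier
matrices.

## The tip-dating MCMC

`tipdate()` is deliberately minimal: topology and tip dates are fixed, and
the sampler explores internal node ages and clock parameters.

* **Likelihood**: Mk/Mkv/Mk-parsinf with branch length
  `duration × clock_mean × multiplier`.
* **Clocks**: strict (all multipliers 1) or uncorrelated lognormal (UCLN),
  multipliers iid lognormal with log-mean `-σ²/2` so their expectation is 1
  and `clock_mean` stays identifiable.
* **Priors**: internal ages uniform subject to parent > child with a root
  age cap (oldest tip + 50 Ma by default); `clock_mean` lognormal(log 0.1,
  sd 2); `σ` exponential(rate 1).  All configurable.
* **Moves**: uniform-window slides of single node ages within their feasible
  interval (Hastings ratio 1), a tree-wide scale move multiplying all
  internal ages (Jacobian `f^{n-1}`), and multiplicative scale moves for
  `clock_mean`, `σ` and single branch multipliers.  Scale-move windows
  self-tune toward ~30% acceptance during burn-in (first 25% of the chain)
  and are frozen afterwards, so the post-burn-in chain is a fixed-kernel
  Metropolis–Hastings sampler.  The tree-wide scale move matters: node ages
  are mutually correlated, and without a global move the slowest mixing
  direction is the overall timescale.

Validation is simulation-based: with a zero-character matrix the sampler
must reproduce the node-age prior (checked by Kolmogorov–Smirnov against
direct rejection sampling from the prior polytope), the joint posterior
stored in the trace must equal recomputation from its components at sampled
states, and on clocklike benchmark data the strict-clock posterior must
recover the generating rate and cover true node ages at the nominal level.

## The experiment

`run_experiment()` measures the effect of autapomorphy exclusion.  Design
choices that were genuinely open:

* **The contrast is variable-only vs parsimony-informative-only, both under
  plain Mk.**  A coded morphological matrix contains no invariant
  characters, so "including autapomorphies" means the variable characters
  are all present.  Contrasting the full (invariant-containing) simulated
  matrix against filtered data instead confounds the autapomorphy effect
  with the invariant-class ascertainment distortion, which shifts node ages
  coherently even on non-clock data.
* **Calibration is measured where the model is exactly true**: the
  clock-condition full matrix under Mk, for which 95% HPDs should cover
  ~95% of true node ages.
* **Clocks per condition**: strict for the clocklike condition (the
  generating model), UCLN for the non-clock condition — branch-rate
  flexibility is precisely the mechanism by which dating decouples from
  morphology there — with a diffuse σ prior (exponential rate 1/3), since
  the reshuffled data demand rate variation that an exponential(1) prior
  pins down.
* **Root-age cap 10 Ma above the oldest tip** for these runs.  The
  benchmark trees are only a few Ma deep; a cap an order of magnitude above
  the tree's span leaves non-clock node ages prior-dominated over a
  timescale the data never occupy, and paired comparisons then measure
  sampler noise.  A proportionate cap plays the role an informative
  serial-sampling tree prior plays in full tip-dating machinery.
* **Statistics**: per-branch signed relative error of posterior-mean
  durations, split terminal/internal (the hypothesised bias is
  terminal-specific); one-sided Wilcoxon signed-rank test across terminal
  branches for downward bias under exclusion (clock condition); two-sided
  test across the 29 shared internal node ages (non-clock condition); no
  multiple-testing correction, given the handful of tests.
* **Chain lengths**: 2e5 states for the clock-condition runs and 5e5 for
  the non-clock UCLN runs, 5 replicate seeds, ~20 minutes of desk-scale
  computation in total.  The non-clock posteriors are wide, and long-run
  controls (same data, different sampler seeds, 1e6 states) show the
  per-node data signal to be ~0.26 Ma with mixed signs: the paired
  comparison only measures the data once per-node Monte-Carlo error sits
  below that, which sets the chain length.  The likelihood-neutral
  preserve moves make the longer relaxed-clock chains cheap.

The clocklikeness of each simulated dataset is checked the same way an
empiricist would: `root_to_tip_regression()` sums Fitch parsimony changes
(`fitch_steps()`, with a fixed prefer-parent tie-break for the
reconstruction) along root-to-tip paths and regresses that distance on
elapsed time; clock data show a positive significant slope, reshuffled data
do not.

## Numerical choices and degenerate inputs

* Corrections with `L_unobs >= 1 - 1e-12` (zero-length trees; parsinf with
  n ≤ 3 where no informative pattern exists) raise a degenerate-correction
  error rather than returning `-Inf` silently.
* Missing data are ignored in pattern classification (scored cells only);
  inside corrections `L_unobs` is computed as if all taxa were scored —
  a per-pattern-missingness correction is not well defined, and this
  limitation is inherited by every implementation of these models.
* Polymorphic codings `(01)` are read but treated as missing.
* Ages propagate from tip dates up the tree; two paths implying ages that
  differ by more than 1e-6 Ma are an error, and durations are recomputable
  from ages to 1e-9.
* HPD intervals are the shortest contiguous window over sorted samples with
  ties broken at the lowest start; ESS uses Geyer initial-positive-sequence
  truncation; constant chains are flagged rather than given infinite ESS.
* The exact Wilcoxon signed-rank path enumerates all `2^n` sign assignments
  up to n = 20 (valid under tied ranks, unlike the classical tables) and
  switches to a tie-corrected normal approximation with continuity
  correction beyond.

## Known limitations

Topology is never inferred (fixing it isolates the dating effect, at the
price of ignoring topology-dating interaction); the tree prior is uniform
on the age polytope, not a birth–death-serial-sampling prior, so
birth/death/sampling rates are not estimated; tip dates are points, not
ranges; no gamma rate heterogeneity across characters; no sampled
ancestors; corrections assume all taxa scored.  The UCLN sampler updates
one multiplier at a time, which is adequate at these problem sizes but
would mix slowly on much larger trees.
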
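# autapodate

Bayesian tip-dating of fossil morphologies treats serially sampled fossils
as dated terminal taxa and lets a morphological clock link expected
character change to elapsed time.  Most character matrices it is fed were
built for parsimony analysis, which discards autapomorphies (derived states
unique to one taxon) as uninformative — but every autapomorphy sits on a
terminal branch, so under a probabilistic model their exclusion is an
ascertainment bias that selectively starves terminal branches of evidence
of change.  `autapodate` is for phylogeneticists who want to quantify that
bias, apply or audit the ascertainment-bias corrections, and decide whether
a matrix without autapomorphies can be trusted for dating.

## What it implements

**The Mk likelihood and its corrections.**  Characters follow the symmetric
k-state Markov model with uniform root frequencies; a branch length `v` is
the expected number of substitutions, with transition probabilities

    P_same(v) = 1/k + (k-1)/k * exp(-v k/(k-1))
    P_diff(v) = 1/k -   1/k  * exp(-v k/(k-1))

Site-pattern likelihoods come from Felsenstein pruning (C++ over compressed
patterns).  Conditioning on data filtering divides each pattern likelihood
by `1 - L_unobs`: for **Mkv** (variable characters only) `L_unobs` is the
mass of the k constant patterns; for **Mk-parsinf** (parsimony-informative
characters only) it is the mass of every distinct pattern in which at most
one state occurs in two or more taxa, evaluated per symmetry class — one
pruning call per set of singleton taxa (`1 + n` calls for binary
characters).

**The combinatorics of infeasibility.**  `count_parsinf_terms(n, k)`
evaluates, in exact integer arithmetic,

    sum_{j=0}^{min(n, k-1)} k * C(n, j) * (k-1)! / (k-1-j)!

the number of terms in the correction's background-state enumeration;
`count_distinct_uninformative(n, k)` counts the distinct unobservable
patterns (the two agree exactly when `k <= n-2`).  The counts explode with
the state count — 4 states and 1,000 taxa already need ~4.0e9 terms — which
is why the parsimony-informative correction is impractical for typical
multistate matrices.

**Simulation and inference.**  A birth–death serial-sampling (BDSS) tree
simulator conditioned on the number of sampled fossil tips; Mk character
simulation on dated trees; branch-length reshuffling to produce "non-clock"
datasets; a fixed-topology Bayesian tip-dating MCMC (`tipdate()`) with
strict or uncorrelated-lognormal relaxed clocks returning a classed fit
with `print`/`summary`/`coef`/`plot` methods; Fitch-parsimony root-to-tip
clocklikeness regression; exact Wilcoxon signed-rank tests; and
`run_experiment()`, which measures how excluding autapomorphies biases
inferred branch durations on clocklike versus non-clock data.

## Worked example

```r
library(autapodate)

# cost of the Mk-parsinf correction for 10 taxa as states increase
sapply(2:6, function(k) as.numeric(count_parsinf_terms(10, k)))
#> [1]     22    333   4084  42505 381546

# a 30-tip benchmark: clocklike + reshuffled 1,000-character matrices
ds <- make_benchmark(seed = 1)
ds
#> <synthetic_dataset> 30 tips, 1000 chars, rate 0.05; invariant+autapomorphic: clock 0.62, nonclock 0.55

# strict-clock tip-dating on the clocklike matrix (true rate 0.05)
fit <- tipdate(ds$clock$full, ds$tree, clock = "strict",
               iterations = 2e4, thin = 20, seed = 1,
               priors = list(root_cap_offset = 10))
fit
#> <tipdate_fit> mk / strict clock, 1000 characters, 30 taxa, 20000 iterations (thin 20)
#>   acceptance: age 0.32 age_pres NA scale 0.28 scale_pres NA clock 0.32 sigma NA mult NA
#>   root age 4.082 [3.992, 4.185] Ma, clock mean 0.04665
root_age(ds$tree)   # truth
#> [1] 3.995892
```

The count row reproduces the published grid of unobservable-pattern terms;
the fit recovers the generating clock rate (0.05) and root age within the
posterior uncertainty.  `run_experiment()` scales this up: on clocklike
data, dropping the parsimony-uninformative characters drags terminal branch
durations down (one-sided signed-rank p < 0.05 in every seed), while on
reshuffled non-clock data node ages are statistically indistinguishable —
the bias matters exactly when the data are clocklike.

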
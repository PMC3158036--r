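---
title: "Quantifying evolutionary accessibility on fitness landscapes"
author: "fitpaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evolutionary accessibility on fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitpaths)
```

## The model and its assumptions

A fitness landscape assigns a non-negative scalar fitness to each of the
$2^L$ genotypes formed by the presence/absence of $L$ mutations; a fitness
of exactly 0 marks a non-viable (lethal) genotype. Under strong selection
and weak mutation (SSWM), a haploid asexual population fixes one mutation
at a time and can never cross a fitness valley. A *shortest* mutational
path between two genotypes at Hamming distance $D$ gains one of the $D$
differing mutations per step ($D!$ orderings, hence $D!$ paths), and is
*selectively accessible* when fitness strictly increases at every step.
The canonical summary statistics over an ensemble of landscapes are the
distribution $P(n)$ of the number of accessible paths between the global
fitness maximum and its antipode, its mean $E[n]$, and the probability
$P_0 = P(0)$ that no accessible path exists.

Two standing assumptions matter in practice:

* **Distinguishable fitness.** Neighboring genotypes are assumed to have
  distinct fitness. Equal-fitness steps are counted as blocking (strict
  inequality), and operations that need a unique optimum
  (`global_maximum()`, `greedy_walk()`, `basins()`) raise an explicit tie
  error rather than breaking ties silently, so degenerate empirical input
  surfaces instead of being resolved arbitrarily.
* **Shortest paths only.** Longer detours and valley crossing by double
  mutants are excluded; all accessibility measures here are therefore
  conservative lower bounds.

## Landscape ensembles

Four classical random ensembles are provided, all reproducible from an
integer seed:

* **House of Cards** (`sample_hoc()`): i.i.d. fitness values, the
  maximally rugged null model. Only ranks matter, so the uniform(0,1) base
  distribution is a free choice. The order-statistics argument gives
  $E[n] = 1$ for every $L$ (`hoc_expected_paths()`); conditioning the
  antipode of the maximum to be the global *minimum* leaves $(L-1)!$ free
  interior orderings per path and yields $E[n] = L$. The conditioned
  sampler implements the conditioning exactly by relocating the smallest
  fitness value to the antipode, which is a valid rearrangement by
  exchangeability.
* **Rough Mount Fuji** (`sample_rmf()`): $F(g) = -c\,d(g) + \eta_g$ with
  $d$ the Hamming distance to the designated optimum and $\eta$ i.i.d.
  standard normal (or Gumbel) noise; $c$ tunes the fitness correlation
  from uncorrelated ($c = 0$, the HoC limit) to additive ($c \to \infty$).
  Stored values are shifted per realization to be positive; accessibility
  depends only on fitness ranks and is unaffected.
* **LK (NK)** (`sample_lk()`): each locus contributes an i.i.d.
  uniform(0,1) amount per state of itself and its $K$ interaction
  partners; $K = 0$ is additive, $K = L - 1$ reproduces HoC. The classical
  literature uses several conventions for the partner sets; both
  `scheme = "random"` (default, resampled each realization) and
  `scheme = "adjacent"` (cyclic neighborhoods) are supported, and the two
  give visibly different $P_0$-versus-$L$ curves (adjacent neighborhoods
  behave more like independent blocks). Quantitative LK results should
  therefore always state the convention.
* **Holey landscapes** (`sample_holey()`): fitness is 1 (viable) with
  probability $p$, else 0. Accessibility degenerates to percolation:
  `count_lethal_free_paths()` counts shortest paths free of holes, with
  expectation $L!\,p^{L-1}$ between two viable antipodal endpoints
  (`holey_expected_paths()`).

## Exact counting and ensemble statistics

`count_accessible_paths()` is an iterative (explicit-stack) depth-first
backtracking search over the sublattice spanned by the endpoints, the
standard exact algorithm for this problem; recursion limits are never hit
and the traversal order (ascending locus index) is fixed for
reproducibility. `has_accessible_path()` is the same search with an early
exit on the first complete path, which makes $P_0$ estimation feasible on
much larger genotype spaces (`ensemble_stats(mode = "existence")`).
Correctness is cross-checked in the test suite against brute-force
enumeration of all $D!$ mutation orders, an oracle that shares no code
with the search.

`ensemble_stats()` derives the seed of realization $r$ as
`seed + r - 1`, so full-count and existence-only runs over the same
arguments see bit-identical landscapes, and ensembles can be reproduced
and extended without replaying earlier realizations.

## Closed forms for the RMF model

For one fixed antipodal path the $L$ non-endpoint fitness values are
i.i.d. noise plus a drift of $c$ per step (the endpoint is taken to be
the global maximum, as in the order-statistics argument). To first order
in $c$,
$$P_1(L, c) \approx \frac{1}{L!} + \frac{c}{(L-2)!}\int \phi(x)^2\,dx,$$
with $\phi$ the noise density (`rmf_path_prob_first_order()`); the
neglected remainder is $O(c^2)$, which is already comparable to
Monte-Carlo error at $c \approx 0.1$, so the form should only be used as
a small-$c$ expansion. For standard Gumbel noise the probability is exact
for every $c$:
$$P_1(L, c) = \frac{(1 - e^{-c})^L}{\prod_{k=1}^{L}(1 - e^{-ck})},$$
(`rmf_path_prob_gumbel()`), whose denominator converges to a constant as
$L$ grows, making the exponential decay of per-path accessibility
explicit. The two forms agree exactly in their first-order coefficients
($\int \phi^2 = 1/4$ for the Gumbel), and both are validated against
Monte-Carlo simulation in the tests; evaluation uses `log`/`expm1`
arithmetic so small $c$ and large $L$ do not lose precision.

The qualitative picture these forms encode: per-path accessibility decays
exponentially with $L$ whenever $c > 0$, but the $L!$ proliferation of
paths wins, so $E[n]$ grows and $P_0$ ultimately falls. Uncorrelated
landscapes ($c = 0$) are the boundary case where $E[n] \equiv 1$ and
$P_0$ keeps rising. The package's trend tests probe exactly these
directions at moderate $L$ (up to 12, with $10^3$–$10^4$ realizations
per point, sizes chosen so each test completes in seconds while the
documented trends exceed Monte-Carlo noise by a comfortable margin).

## The empirical subgraph pipeline

`read_fitness_table()` ingests a tab-separated genotype-fitness table
(header: locus names, then `fitness`, optionally `fitness_rep1/2`; absent
rows or `x` sentinels mark missing genotypes, which are assigned zero
fitness). The analysis then:

1. enumerates all $\binom{L_0}{L}$ subgraphs that share the wildtype
   (`enumerate_subgraphs()`, `subgraph()`);
2. counts viable subgraphs (VSGs, no lethal genotype) and compares with
   the two-parameter lethality model prediction
   $\binom{L_0-1}{L}(1-p)^{L 2^{L-1}}$ (`expected_vsg()`);
3. counts lethal-free and selectively accessible shortest paths per
   subgraph and summarizes $E[n]$ and $P_0$ per size
   (`subgraph_table()`).

The lethality model (`lethality_model()`, `estimate_lethality()`) assigns
a common lethality probability $p$ to ordinary mutations and $p_{\rm
focal}$ to one focal high-risk locus, combining multiplicatively across a
genotype's mutations. Estimation is by method of moments: the expected
viable count among focal-free genotypes is $(2-p)^{L_0-1}$ and the
expected total is $(2-p_{\rm focal})(2-p)^{L_0-1}$, which invert to
closed-form estimates. The expected number of lethal-free paths per
subgraph (`expected_lethal_free()`) accounts for the step at which the
focal mutation enters a path; it is verified in the tests against full
enumeration over subgraphs and mutation orders.

**Endpoint conventions.** Accessible paths in a subgraph run from the
subgraph's global maximum to its antipode within the subgraph (the
general definition; `axis = "global_max"`), which coincides with the
wildtype-to-full-mutant axis whenever the wildtype is the subgraph's
optimum. The alternative `axis = "wildtype"` forces that axis throughout.
Lethal-free counts always use the wildtype-to-full-mutant axis, matching
the fixed-endpoint structure of the analytic prediction. Subgraphs whose
maximal fitness is tied are recorded and excluded from the accessible-path
averages rather than tie-broken (`n_skipped` column and `"skipped"`
attribute).

**Resampling.** Measurement noise is propagated by redrawing each viable
genotype's fitness from a normal distribution centered on its mean with a
common standard deviation estimated from replicate disagreement,
$\hat\sigma = \sqrt{\overline{(f_1 - f_2)^2}/2}$; non-viable genotypes
stay at 0 (viability frozen). Values are not truncated; in the rare event
a viable draw falls to 0 or below, all viable values are shifted up by a
common constant, which preserves the complete fitness ranking and hence
every accessibility statistic. Summary statistics from the mean landscape
and from the resampled ensemble are both available
(`subgraph_table(resample_reps = ...)`); on synthetic data they agree
within the resampling spread.

**Missing genotypes.** `missed_genotype_stats()` gives the Poisson
probability that genotypes absent from a segregant sample of size
$N_{\rm seg}$ were missed by chance;
`simulate_heterogeneous_detection()` is the conservative variant with
uniformly distributed detection probabilities. The lower bound of that
interval is a data-dependent choice (in the motivating study it
corresponds to the detectability of the least fit observed strain); the
default here, $0.1/G$ with the upper bound chosen to keep the mean at
$1/G$, is a package default to be overridden when the relevant data
quantity is known.

## The synthetic data generator

`generate_dataset()` draws eight-locus datasets with the structure of the
classical *A. niger* segregant panel so that the entire pipeline is
testable with known ground truth: multiplicative lethality with defaults
$p = 0.02$ and $p_{\rm focal} = 0.45$ at the lysD25-like sixth locus
(values of the magnitude estimated from the published panel, ratio about
25), viable fitness from an RMF surface with slope $c = 0.3$ per mutation
in noise units (the correlation strength consistent with that panel's
subgraph statistics), rescaled affinely so the best strain has relative
fitness 1 and the least fit 0.1 (mimicking growth rates expressed
relative to the best strain; affine maps preserve all accessibility
structure), and two replicate measurements with noise
`replicate_sd = 0.02` on the relative-fitness scale, a typical
growth-rate measurement error. Non-viable genotypes appear exactly as in
the real table: absent (or `x`-marked) rows treated as fitness 0.

What the generator does *not* emulate: the segregant-sampling process
itself (all viable genotypes are observed), linkage between markers, any
non-RMF structure in the viable fitness values, and genotype-specific
measurement variance. Passing tests on synthetic data therefore validate
the pipeline's correctness and parameter recovery, not the biological
adequacy of the RMF form for any particular organism; the RMF choice is a
testing device.

## Numerical choices and degenerate inputs

* Strictly increasing fitness is required for accessibility; equal steps
  block. Empirical ties in a subgraph's maximum produce recorded,
  skipped subgraphs, never silent tie-breaks.
* Genotypes are indexed little-endian (bit $i$ = locus $i$), fixed by the
  landscape's locus-name order; all containers are dense vectors of
  length $2^L$.
* Fitness comparisons are plain floating-point comparisons; samplers draw
  from continuous distributions, so ties occur with probability zero in
  simulated ensembles.
* Per-realization seeds are derived by counter from the master seed and
  kept below $2^{31}$.
* `rmf_path_prob_gumbel()` and `missed_genotype_stats()` work in
  log-space to avoid under/overflow at large $L$ or $N_{\rm seg}$.

## Known limitations

* Path-probability weighting by fixation probabilities, population
  dynamics beyond SSWM, and non-shortest paths are out of scope by
  design.
* Exact counting is factorial-bounded; antipodal full counts are
  practical to $L \approx 14$, existence-only estimates further.
* The LK neighborhood scheme and contribution distribution are
  conventions, not canon; comparisons across implementations should match
  them explicitly.
* `estimate_lethality()` is a two-parameter moment fit; it cannot detect
  heterogeneity among the non-focal loci.
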
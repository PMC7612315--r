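---
title: "Conditional FDR with v-values: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional FDR with v-values: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a high-dimensional association study we test $n$ null hypotheses
$H_0^{(i)}$ and obtain p-values $p_i$. Often an analogous study of a
related trait supplies a second p-value $q_i$ for each hypothesis (the
*conditional* or covariate study). When associations tend to be shared
between the traits, small $q_i$ carry evidence that lowers the posterior
probability of $H_0^{(i)}$, and a bivariate rejection rule can be more
powerful than thresholding $p_i$ alone. The conditional false discovery
rate (cFDR)

$$\mathrm{cFDR}(p, q) = \Pr\bigl(H_0 \mid P \le p,\, Q \le q\bigr)$$

captures this. It is estimable from the empirical CDFs alone, without any
density estimation, but rejecting whenever an estimate of it falls below
$\alpha$ does **not** control the FDR at $\alpha$ — the realised FDR can
exceed $\alpha$ by an arbitrarily large factor (`extreme_case_limit()`
gives the closed-form worst case, and `simulate_extreme_case()` reproduces
it empirically). This package implements the remedy: transform the pairs
$(p_i, q_i)$ into *v-values* that provably behave as p-values, then hand
them to the Benjamini–Hochberg procedure (FDR) or a Šidák threshold
(FWER).

## Estimators

Working assumptions: under $H_0$, $P$ is uniform on $(0,1)$ and
independent of $Q$; pairs are i.i.d. (or block-dependent; see censoring
below). The base estimator is the ECDF ratio

$$\widehat{\mathrm{cFDR}}_X(p,q) =
  p\,\frac{\max(\#\{q_i \le q\},\,1)}{\max(\#\{p_i \le p,\ q_i \le q\},\,1)},$$

(`cfdr_hat()`), which at $q = 1$ is exactly the Benjamini–Hochberg
statistic. It conservatively treats $\Pr(H_0 \mid Q \le q)$ as 1; the
*adjusted* estimator (`cfdr_hat_adjusted()`) multiplies in an ECDF
estimate of that probability using the records with $p_i > 1/2$ as a proxy
for the null population:

$$\widehat{\Pr}(H_0 \mid Q \le q) = \min\!\left(1,\
  \frac{\max(1, \#\{q_i \le q,\ p_i > 1/2\}) / \max(1, \#\{p_i > 1/2\})}
       {\max(1, \#\{q_i \le q\}) / n}\right).$$

Every count carries a `max(1, •)` guard. The guard on the numerator
matters more than it looks: without it the factor is zero in all q-strata
below the smallest covariate value among the null-proxy records, those
strata would then be fully absorbed into every rejection region, and the
resulting v-values would be bounded below by the (non-negligible) null
mass of the extreme tail — destroying resolution exactly where discoveries
live. With the guard the factor degrades gracefully to the smallest
resolvable fraction. $\pi_0$ is fixed at 1 throughout: estimating it would
scale all estimates uniformly and cannot change any ranking or rejection
set.

Neither estimator is monotone in $p$ at fixed $q$, so `cfdr_t()` minimises
over thresholds $p' \ge p$, optionally adding the moving evaluation point
$(p', q)$ to the counts (`include_test_point`), which extends the map to
the whole unit square. Two conventions are fixed here and used
consistently everywhere: all count comparisons are closed (`<=`, ties with
multiplicity), and the adjustment factor is computed from the defining set
only — the moving point enters the numerator and denominator counts of the
base estimator, never the adjustment. The latter choice deviates by a
single count ($O(1/n)$) from the alternative of augmenting everything, and
keeps the adjustment identical to the standalone `h0q_adjustment()`
operation; the p-value property of v-values holds under either convention
because it only requires the region map to be a function of the defining
set.

## L-regions and v-values

The sub-level set $L_X(\alpha) = \{(p,q): \mathrm{cfdr\_t}_X(p,q) \le
\alpha\}$ is the *L-region*; its right boundary (`build_lcurve()`) is a
step function over q-strata delimited by the distinct observed $q_i$.
Within a stratum the estimator is linear in $p'$ between consecutive order
statistics of the relevant p-values, so the boundary is solved exactly on
each interval — no raster grid is involved, and regions are exactly nested
in $\alpha$.

The *v-value* of a point is the probability, under the estimated null
distribution $f_0$ of $(P, Q)$, of the smallest L-region containing it.
Because the region map must be independent of the point it tests, the map
for record $i$ is built from the data minus record $i$ (leave-one-out,
`mode = "loo"`) or minus its whole block (`mode = "lob"`, for
block-dependent data such as chromosomes or gene neighbourhoods — blocks
must make observations independent *between* blocks). The `"naive"` mode
keeps the record in its own map; it is demonstrably anti-conservative and
exists as a cautionary comparator. With `mode = "lob"` and no fold column,
records are split into three random equal folds; set the RNG seed for
reproducibility.

`cfdr_vvalues()` runs the whole pipeline. The per-record minimal level and
the boundary solving over all strata are implemented in C++ with shared
sorted structures, incrementally updated as strata accumulate, so that a
leave-one-out analysis of $n = 5000$ records takes about 1.5 s; the
results are identical (to floating-point rounding, and bit-identical when
the stratum partitions coincide) to recomputing each record's region from
scratch with `build_lcurve()` + `integrate_f0()`, and the test suite
asserts this.

## Estimating the null

The v-value integral needs $f_0(p,q) = f_0^q(q)$ (the p-coordinate is
uniform under the null). The covariate z-score $z = -\Phi^{-1}(q/2)$ given
$p > 1/2$ is modelled as a two-component folded-Gaussian mixture,
$|N(0,1)|$ with weight $\pi_0$ and $|N(0,\sigma_0^2)|$ with weight
$1-\pi_0$, fitted by EM (`fit_null_em()`). Defaults: initialisation
$\pi_0 = 0.75$, $\sigma_0 = 2$; relative log-likelihood tolerance $10^{-6}$;
at most 1000 iterations; at least 30 usable records; $\sigma_0$ floored at
1 so the non-null component is at least as dispersed as the null (the
floor is this package's choice; an unconstrained fit can label the
*smaller*-variance component "non-null" on pure-null data, which changes
nothing numerically but muddles interpretation). $q = 1$ maps to $z = 0$
and is retained. The resulting marginal CDF `F0q_cdf()` makes the region
integral a closed-form strip sum (`integrate_f0()`), exact because the
p-marginal is uniform.

If the true null distribution of $P$ is stochastically larger than uniform
(deflated test statistics), the integrator overestimates the null mass of
every region and v-values are conservative — validity is kept, power is
lost.

## Error control

`bh_reject()` is the standard step-up procedure (delegated to
`stats::p.adjust`); `sidak_threshold()` gives the FWER threshold
$1-(1-\alpha)^{1/n}$. Realised false/true discovery proportions are scored
by `fdp_tdp()` with the conventions: both are 0 when nothing is rejected,
and TDP is reported as missing when there are no true associations, so
that benchmark averages do not mix it with genuine zeros.

## The simulation framework

`simulate_dataset()` generates the study conditions used throughout the
package's own evaluation: $n$ hypotheses in four classes of fixed size
(shared associations `n1pq`, principal-only `n1p`, covariate-only `n1q`,
the rest null), associated z-scores $s \cdot T$ with $T$ standard normal,
t(3 df) or Cauchy, p-values $2\Phi(-|z|)$, and optional block or
equicorrelation dependence at level $\rho$ applied within class (and
block) through a one-factor construction — for the heavy-tailed families
the correlated normals are divided by a shared per-group
$\sqrt{\chi^2_\nu/\nu}$, the multivariate-t convention, so $\rho$ is the
off-diagonal of the normalised dependence matrix. `sample_sim_params()`
draws parameters from the design distribution ($n = 10^{U(3,4)}$, class
sizes $U(0,200)$, scales $U(1.5, 3)$, family uniform on the three).

Two fixed scenarios (`sim_params_preset()`) anchor the benchmark:
*reference* ($n = 5000$, all three association classes of size 100,
scales 2, t(3 df)) and *negative information* (disjoint association sets
of size 2000 each, so the covariate is informatively *unhelpful*; the
unrestricted L-curves still exploit it). `run_benchmark()` scores any
subset of: B-H on p-values, the three censoring modes, the unadjusted
leave-one-out variant, and the two oracles.

The oracle comparators (`oracle_model()`, `oracle_vvalues()`) use the
exact class-mixture distributions implied by the generating parameters:
the CDF statistic $p F(q)/F(p,q)$ (the population limit of the ECDF
estimator) and the density-ratio statistic $f_0/f$ (the optimal rejection
statistic). Their v-values are exact-null masses of sub-level contour
regions, computed by quadrature: 160 equal-mass nodes across the null
covariate distribution and, per node, inversion of the statistic on a
~1500-point principal-coordinate grid that is quantile-spaced with extra
tail refinement. Both statistics are monotone in the principal coordinate
at fixed covariate for these mixture families (monotone likelihood ratio),
which the inversion exploits; monotonicity is additionally enforced
against floating-point wiggle. The tests verify the quadrature against
brute-force Monte-Carlo integration under $f_0$.

What the generator deliberately does not emulate: composite or
mis-specified nulls for the principal study (only the
dominance-conservatism argument covers those), covariates that are not
p-values, realistic linkage-style dependence beyond
block/equicorrelation, and effect-size distributions outside the three
families. Passing benchmarks therefore demonstrate correctness of the
machinery under the stated sampling model, not robustness to everything
real data can do.

## Iterated conditioning

Because leave-out v-values retain the p-value property, they can play the
role of p-values in a second analysis against a further covariate set:
`iterate_cfdr()` applies $v_{k+1} = v(v_k, q^{(k)})$ across a list of
covariate vectors, refitting the null model each round on the current
principal values (the records with $v_k > 1/2$ form the conditioning set —
the natural reading of v-values as adjusted p-values). The packaged study
generator (`simulate_iteration_study()`) uses 1000 variables, 100
associations with $z \sim N(0, 3^2)$, and 500 covariate sets of which the
odd-numbered share associations with the principal set with probability
0.54 per association (so 54 shared on average) while the even-numbered are
uninformative; the sharing probability is calibrated to that mean overlap.
Across 500 rounds the Bonferroni rejection count among true associations
climbs from ~18 to the high 90s while null v-values stay uniform.

## Numerical choices and edge cases

* Zero p-values are clamped to the smallest positive double with a
  warning; v-values are likewise floored into $(\varepsilon, 1]$.
* Ties in `p` or `q` are counted with multiplicity under closed
  comparisons; identical pairs are legitimate.
* A single record under leave-one-out has an empty defining set; the
  count guards then give $c = p$ and $v = p$ exactly.
* If no record has $p > 1/2$ the adjustment is undefined;
  `cfdr_vvalues()` falls back to the unadjusted estimator with a warning
  (and per fold in block-out mode), while the strict `h0q_adjustment()`
  operation raises an error.
* The C++ kernels and the plain-R reference path use identical
  floating-point expression forms (including the division form of every
  feasibility comparison and extended-precision accumulation of the strip
  sums) so that the optimised and naive computations agree exactly, not
  just approximately.

## Problem sizes used in the packaged checks

The package's own acceptance checks run the two fixed scenarios at 200
replicates (the published study uses thousands; means agree within
Monte-Carlo error, which the checks quantify as $\pm\,3$ standard errors
with a floor of $\pm 0.02$), one 500-round iterated-conditioning run, EM
recovery at $n = 10^5$, convergence-rate fits over $n \in \{10^3, 10^4,
10^5\}$, and single-point-influence fits over $n \in \{250, \dots,
2000\}$. On the influence rate: the mean *absolute* shift in a v-value
from adding one observation empirically decays like $n^{-1}$ (the usual
ECDF influence scale); it is the mean *squared* shift — the scale relevant
to the pairwise dependence between leave-one-out v-values, which is a
product of two such shifts — that decays like $n^{-2}$, and that is the
slope the checks assert.

## Limitations

The ECDF-based estimator does not converge to the optimal (density-ratio)
rejection region, so for very large $n$ a well-specified parametric or
kernel density approach can overtake it; its advantage lives at the
$10^3$–$10^4$ hypotheses typical of gene- or transcript-level analyses,
and in its immunity to density mis-specification. L-curves are not forced
monotone in $q$; this loses a little power when the covariate is pure
noise but lets the method exploit both positive and negative covariate
information. Leave-one-out v-values are weakly pairwise dependent (see the
influence-rate discussion above); block-out censoring removes the
within-block part of that dependence and is the right choice when
observations are dependent in blocks.
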
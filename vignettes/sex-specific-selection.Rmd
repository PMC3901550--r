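---
title: "Sex-specific selection and the genetic architecture of disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific selection and the genetic architecture of disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexvar)
library(dplyr)
```

## The model

`sexvar` implements a deterministic two-sex population-genetic model of
disease-predisposing alleles. Each autosomal, biallelic locus carries a
wild-type allele and a disease allele at frequency $q$. Disease
susceptibility is additive (scores $0$, $\gamma$, $2\gamma$ across the three
genotypes), so a locus contributes $2pq\gamma^2$ to population variance in
disease predisposition. Fitness cost is proportional to disease effect:
relative fitnesses are $1,\ 1-s,\ 1-2s$ in the focal sex (sex 1, with
$s = c\gamma > 0$) and $1,\ 1-t,\ 1-2t$ in sex 2. The sign of $t$
distinguishes three biological situations:

* $t > 0$ — deleterious in both sexes, possibly asymmetrically;
* $t = 0$ — sex-limited cost;
* $t < 0$ — sexually antagonistic: harmful to sex 1, beneficial to sex 2.

Because an autosomal allele spends half its time in each sex, its dynamics
depend on the sex-averaged selection it experiences. One generation applies
Hardy–Weinberg genotype formation, viability selection within each sex,
equal-weight averaging of the post-selection allele frequencies (allele
frequencies are assumed equal between the sexes, reasonable under weak
selection and low mutation), and one-way mutation wild-type $\to$ disease at
rate $u$ per gamete:

$$
\Delta q \;=\; (1-u)\,\Bigl(-\tfrac{q(1-q)}{2}\Bigr)
\Bigl[\frac{s}{1-2sq} + \frac{t}{1-2tq}\Bigr] \;+\; u(1-q).
$$

This is the exact recursion, written in a cancellation-free form (see
*Numerical choices*). Its weak-selection expansion is
$\Delta q \approx u(1-q) - q(1-q)\bigl[(s+t)/2 + q(s^2+t^2)\bigr]$.

### Equilibria and regimes

Setting $\Delta q = 0$ and keeping the root in $[0,1]$ reachable from the
fate of a recurrent new mutation ($q_0 = u$) gives the equilibrium frequency
$q_{eq}$. Three regimes arise (`classify_regime()`):

* **Mutation–selection balance** ($s + t > 0$): the classical two-sex
  heuristic is $q_{eq} \approx 2u/(s+t)$ (`msb_approx()`).
* **Balancing selection** ($4st < s + t < 0$): net selection alone maintains
  the polymorphism; to second order the root is
  $q_{eq} \approx -(s+t)/\bigl(2(s^2+t^2)\bigr)$.
* **Disease fixation** ($s + t < 0$, not balancing): net selection favours
  the disease allele.

The second-order closed form used as the fast path unifies the first two
cases: solving $u = q[(s+t)/2 + q(s^2+t^2)]$ for $q$ (`q_eq_weak()`).

At equilibrium a locus carries heterozygosity $H = 2q_{eq}(1-q_{eq})$ and
contributes $v_1 = 2q_{eq}(1-q_{eq})s^2$ and $v_2 = 2q_{eq}(1-q_{eq})t^2$
to additive fitness variance in sexes 1 and 2. Two consequences drive
everything downstream:

1. For a given $s$, weaker selection in sex 2 (smaller $t/s$) raises
   $q_{eq}$ and hence the locus's variance contribution in sex 1. In the
   fully sex-limited limit $t = 0$, the contribution $\approx 4us$ is twice
   the symmetric case's $\approx 2us$ — the asymmetry doubling.
2. Sexual antagonism ($t/s < 0$) can push a locus into balancing selection
   and intermediate frequencies, inflating $H$ by orders of magnitude.

```{r equilibria}
loci_tbl(s = 0.01, t = c(0.01, 0, -0.0102), u = 1e-6) |>
  solve_equilibrium() |>
  select(s, t, q_eq, regime, H, v1)
```

## The distribution of fitness effects

To ask how much of the standing variance in sex 1 is carried by
asymmetrically selected loci, the per-locus coefficients $(s, t)$ are
treated as draws from a bivariate gamma distribution with equal
$\mathrm{Gamma}(k,\theta)$ marginals and between-sex Pearson correlation
$r_{st} \in [0,1]$. The defaults of the generator are the study conditions
used throughout the package:

* shape $k = 0.2$ — strongly leptokurtic, the range inferred for
  deleterious mutations from nonsynonymous polymorphism data;
* mean $k\theta = 0.02$ (so $\theta = 0.1$) — a few-percent average fitness
  cost;
* $r_{st} = 0.75$ — a strong but imperfect between-sex correlation;
* $u = 10^{-6}$ per locus per gamete;
* $n = 10^6$ mutations for headline Monte-Carlo summaries.

All draws are positive, so every locus is deleterious in both sexes and
equilibrates at mutation–selection balance: this deliberately *excludes*
sexual antagonism and therefore yields a conservative lower bound on the
dominance of sex-asymmetric loci.

### Which bivariate gamma? A design analysis

"Bivariate gamma with equal marginals and correlation $r_{st}$" does not
pin down a joint distribution, and for a shape as small as $k = 0.2$ the
choice of coupling matters enormously, because $\log(t/s)$ has a standard
deviation of several natural-log units. `sample_dfe()` implements three
classical constructions:

* **Kibble** (default): $s \sim \mathrm{Gamma}(k,\theta)$, then
  $N \mid s \sim \mathrm{Poisson}\bigl(r s/((1-r)\theta)\bigr)$ and
  $t = (1-r)\,\theta\,\mathrm{Gamma}(k+N)$. Exact marginals, exact Pearson
  correlation, exchangeable, smooth regression
  $E[t \mid s] = (1-r)k\theta + rs$.
* **Trivariate reduction** (Cherian): $s = G_0 + G_1$, $t = G_0 + G_2$ with
  a shared $\mathrm{Gamma}(kr,\theta)$ shock. Exact marginals and
  correlation, but for $k < 1$ the independent components
  $\mathrm{Gamma}(k(1-r),\theta)$ are nearly degenerate at 0, so most mass
  collapses onto the diagonal $t \approx s$: the coupling is effectively an
  atom at symmetry plus rare excursions.
* **Gaussian copula**: exact marginals; the normal-score correlation is
  only an upper bound on the attenuated Pearson correlation of $(s,t)$.

The choice is consequential for the variance partition:

```{r constructions, eval = FALSE}
for (constr in c("kibble", "trivariate", "copula")) {
  smp <- sample_dfe(dfe_params(0.2, 0.1, r_st = 0.75, n = 2e5, seed = 1,
                               construction = constr))
  print(glance(partition_variance(smp, u = 1e-6)))
}
```

At $r_{st} = 0.75$ the cumulative sex-1 variance fraction below
$t/s = 1/2$ is roughly 54% under Kibble, 36% under trivariate reduction and
61% under the copula; below $t/s = 1/4$ the fractions are roughly 35%, 32%
and 38%. Kibble is the default because it is the construction usually meant
by "the bivariate gamma distribution", it has exact marginals *and* exact
target correlation, and its smooth conditional structure avoids the
trivariate reduction's artificial atom at $t = s$, which for leptokurtic
shapes suppresses the asymmetric classes almost entirely. The alternatives
remain available behind `construction =` for sensitivity analysis.

## Partitioning the variance

`partition_variance()` weights each locus by
$w = q_{eq}(1-q_{eq})s^2$ (constants cancel in fractions), bins the
asymmetry ratio $t/s$ into half-open intervals $(a, b]$ — a ratio exactly
on an edge belongs to the lower bin, a deterministic and documented
tie-break — and reports per-bin and cumulative shares of loci and of
variance. The companion covariance statistic
$\mathrm{cov}[q_{eq}(1-q_{eq})s^2,\; t/s]$ formalises the hypothesis that
asymmetric loci dominate: under equal marginals with small coefficient
variance, a Taylor argument reduces the condition for a negative covariance
to $r_{st} < 1$, and `critical_correlation()` verifies that boundary by
Monte-Carlo bisection of the covariance sign.

```{r partition}
smp <- sample_dfe(dfe_params(0.2, 0.1, r_st = 0.75, n = 2e5, seed = 1))
part <- partition_variance(smp, u = 1e-6, verify_n = 5000, seed = 1)
glance(part)
```

Although exactly half of the loci have $t < s$, those loci carry over 80%
of the sex-1 variance; the share below any threshold grows as the DFE
becomes more leptokurtic (smaller $k$) and as $r_{st}$ falls — both
monotonicities are property-tested.

## Numerical choices

* **Stable recursion.** The naive genotype-bookkeeping form of $\Delta q$
  loses all significant digits near $q = 1$ (the change is
  $O((1-q)\cdot s)$ while roundoff is $O(\varepsilon)$), which corrupts
  sign-based bracketing. The implementation factors $q(1-q)$ out
  analytically; the naive form survives only in the test suite as an
  independent oracle.
* **Root finding.** Vectorised bisection on
  $[10^{-15},\, 1-10^{-15}]$ to machine precision (~100 iterations),
  residual $|\Delta q| \le 10^{-12}$ enforced. When $\Delta q$ has no
  interior sign change the attractor is a boundary: $q_{eq} = 1$ when
  mutation or net selection pushes upward everywhere, $q_{eq} = 0$ when
  $u = 0$ under purifying selection. Coefficients beyond the
  fitness-positivity bound $2s < 1$ (rare unbounded-tail draws) cap the
  bracket below the mean-fitness singularity $q = 1/(2s)$.
* **Near-neutral loci.** With one-way mutation, loci with
  $s + t \lesssim 2u$ have no interior equilibrium: the deterministic
  recursion fixes the disease allele. They are reported with
  $q_{eq} \to 1$, flagged `near_neutral`, and carry vanishing weight
  $q(1-q)s^2$, so the partition is insensitive to how they are treated
  (the tested $u$-invariance of the fractions, $<0.5$ pp across
  $u \in [10^{-7}, 10^{-5}]$, covers the movement of this boundary).
* **Fast path vs exact path.** Million-locus partitions use
  `q_eq_weak()`; `verify_n` re-solves a seeded subsample with exact
  bisection and reports the largest shift in any reported fraction
  (typically $\ll 0.01$ pp; property-tested $< 0.2$ pp).
* **Validity of the balancing closed form.** The $u$-free
  $-(s+t)/(2(s^2+t^2))$ requires mutation pressure to be negligible
  against the restoring force at the balanced root,
  $u \ll |s+t|(s^2+t^2)$ — a stronger condition than weak mutation per se.
  At $u = 10^{-6}$, $s = 0.02$, $t = -0.0201$ mutation pressure alone
  shifts the root from 0.062 to 0.078; the $u$-aware quadratic form tracks
  the exact root throughout.
* **Seeding.** One user-facing seed is expanded arithmetically into
  independent per-subtask streams, so adding a verification subsample or
  an extra bisection evaluation never perturbs the main sample. All
  sampling restores the caller's RNG state.

## What the generator does and does not emulate

The generator reproduces the *distributional* conditions of the analysis:
equal leptokurtic gamma marginals, positive correlation, independent loci,
a shared constant mutation rate. It does not emulate features of real
data: linkage disequilibrium, dominance, X-linkage, epistasis,
genotype–environment interaction, variable mutation rates, or — most
importantly — genetic drift: equilibria are deterministic expectations, so
passing tests demonstrate correctness of the model's predictions, not that
finite populations sit at those equilibria. Negative between-sex
correlations are not representable by these gamma couplings, and the
all-positive support excludes sexual antagonism from the Monte-Carlo
partition by construction (antagonistic loci are handled by the per-locus
solver, not the sampler).

## Problem sizes

Headline Monte-Carlo summaries use $10^6$ mutations (the weighted
fractions then have cross-seed standard deviations of about 0.2 pp);
property tests use $10^5$ except where a degenerate construction makes
$10^3$–$10^4$ sufficient; the critical-correlation search uses $10^5$
mutations per covariance evaluation and stops at a bracket width of 0.005.
The brute-force iteration oracle runs $10^6$ generations, which converges
for every grid point with $|s+t| \ge 100u$; the $s+t \approx 0$ points
relax on a $1/\sqrt{u(s^2+t^2)}$ timescale instead and are checked against
a Brent-root oracle.

## Limitations

Deterministic, autosomal, additive, two-allele, equal sex ratio, equal
allele frequencies between sexes, one-way mutation. The covariance
criterion's general unequal-marginal form is evaluated only by Monte
Carlo; the analytic simplification is asserted only for equal marginals.
`r_st` is restricted to $[0, 1]$.
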
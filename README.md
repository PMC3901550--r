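# sexvar

Sex-specific selection and the genetic architecture of disease.

Most disease-predisposing alleles are deleterious and persist at a balance
between recurrent mutation and purifying selection. But selection is rarely
identical in males and females: a mutation may be costlier in one sex,
sex-limited, or even sexually antagonistic (harmful in one sex, beneficial
in the other). `sexvar` is a toolkit for population geneticists and disease
geneticists who want to quantify what that asymmetry does to standing
genetic variation: it solves per-locus equilibria under two-sex viability
selection with mutation, and partitions the additive genetic variance of a
focal sex across classes of between-sex effect asymmetry for mutation sets
drawn from a correlated, leptokurtic distribution of fitness effects (DFE).

## The model

At a biallelic autosomal locus the disease allele (frequency *q*) has
additive fitness effects per copy: *s* > 0 in the focal sex (sex 1) and *t*
in sex 2 (fitnesses 1, 1−s, 1−2s and 1, 1−t, 1−2t). With Hardy–Weinberg
genotypes, viability selection in each sex, equal-weight averaging across
sexes, and one-way mutation at rate *u*, the per-generation change is

    Δq = (1−u) · (−q(1−q)/2) · [ s/(1−2sq) + t/(1−2tq) ] + u(1−q)

Setting Δq = 0 gives the equilibrium q_eq. Three regimes follow from the
sex-averaged selection: mutation–selection balance (s+t > 0, with
q_eq ≈ 2u/(s+t)), balancing selection (4st < s+t < 0, with the
polymorphism maintained indefinitely), and disease fixation (otherwise).
A locus at equilibrium contributes 2·q_eq(1−q_eq)·s² to additive fitness
variance in sex 1 — so for the *same* s, a sex-limited allele (t = 0)
contributes ~4us, twice the ~2us of a symmetrically selected one.

Treating (s, t) across loci as draws from a bivariate gamma DFE with equal
Gamma(k, θ) marginals and between-sex correlation r_st, the package
partitions total sex-1 variance by the asymmetry ratio t/s and evaluates
the covariance criterion cov[q_eq(1−q_eq)s², t/s] < 0 — the formal
statement that asymmetrically selected alleles contribute
disproportionately whenever effects are imperfectly correlated (r_st < 1).

## Worked example

Solve three loci that share the same cost in sex 1 but differ in sex 2:

```r
library(sexvar)

loci_tbl(s = 0.01, t = c(0.01, 0, -0.0102), u = 1e-6) |>
  solve_equilibrium()
#>   locus_id     s       t        u      q_eq regime                            H
#> 1 L1        0.01  0.01   0.000001 0.0001000 mutation_selection_balance 0.000200
#> 2 L2        0.01  0      0.000001 0.000200  mutation_selection_balance 0.000400
#> 3 L3        0.01 -0.0102 0.000001 0.500     balancing_selection        0.500
```

The symmetric locus (L1) equilibrates at q_eq = 2u/(s+t) = 1e-4. Halving
the sex-averaged cost by making the allele sex-limited (L2) doubles q_eq
to 2e-4 — and with it the locus's variance contribution in sex 1
(v1: 4.0e-8 vs 2.0e-8). A slight sexual antagonism (L3) satisfies
4st < s+t < 0 and jumps to a balanced polymorphism near 1/2, inflating
heterozygosity by three orders of magnitude.

Now the genome-wide picture under the default study conditions — a million
mutations from the equal-marginal bivariate gamma DFE (k = 0.2,
kθ = 0.02, r_st = 0.75; Kibble coupling) with u = 1e-6:

```r
smp  <- sample_dfe(dfe_params(shape = 0.2, scale = 0.1, r_st = 0.75,
                              n = 1e6, seed = 1))
part <- partition_variance(smp, u = 1e-6, verify_n = 1e4, seed = 2)
part
#> Partition of sex-1 additive variance by t/s class
#>   loci: 1000000   u: 1e-06   solver: weak
#>   cov[q(1-q)s^2, t/s] = -2.786849e+18
#>   weak vs exact solver shift: 2.727352e-09 pp
#>   bin_lo bin_hi n_loci locus_fraction variance_fraction
#> 1   0      0.25 324564         0.325            0.353
#> 2   0.25   0.5   73705         0.0737           0.187
#> 3   0.5    1    101583         0.102            0.277
#> 4   1      2    102321         0.102            0.152
#> 5   2      4     73274         0.0733           0.0271
#> 6   4    Inf    324553         0.325            0.00408
#> Cumulative variance fractions:
#>   threshold variance_fraction locus_fraction
#> 1      0.25             0.353          0.325
#> 2      0.5              0.540          0.398
#> 3      1                0.817          0.500
```

Reading the cumulative table: only half the loci are costlier in sex 1
(t < s), yet they carry **81.7%** of sex-1 additive variance; loci with at
least a two-fold asymmetry (t/s < 1/2) carry **54.0%**, and at least
four-fold (t/s < 1/4) **35.3%**. The negative covariance statistic is the
same fact as a single number. `tidy()`/`glance()` return these as tibbles,
`autoplot(part)` draws the class-wise columns, and
`critical_correlation()` confirms that the covariance stays negative for
every r_st < 1 (its sign change is located at r* ≈ 1).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/sexvar.R partition --shape 0.2 --scale 0.1 --corr 0.75 \
    --n 1000000 --mu 1e-6 --seed 1 --out report.tsv
```

## Package layout

- `R/selection.R`, `R/equilibrium.R` — per-locus genetics, the recursion,
  solvers, regime classification, sweeps.
- `R/dfe.R` — the bivariate-gamma DFE sampler (Kibble, trivariate
  reduction, Gaussian copula) and moment diagnostics.
- `R/partition.R` — variance partition, covariance criterion, critical
  correlation.
- `R/cli.R`, `inst/cli/sexvar.R` — subcommand interface.
- `vignettes/sex-specific-selection.Rmd` — the model, design decisions and
  numerical choices in full.
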
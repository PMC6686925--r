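# ordlvm

Association testing between an **ordinal phenotype** and an **ordinal
genotype**, adjusting for continuous covariates — for statistical
geneticists and biostatisticians whose trait is genuinely ordered (disease
severity grades, antibody titre classes) and who do not want to pretend
either the trait or the allele count is a continuous variable with a
linear dose effect.

## The model

Genotype `G` (2 or 3 ordered levels), phenotype `Y` (`m` levels) and
covariates `Z` are modelled as manifestations of a latent multivariate
normal vector `U ~ N(0, Δ)` with unit-diagonal `Δ`: `G` and `Y` are
threshold discretizations of `U1` and `U2`, and `Z = (U3, …, Uk)`. With
`ζ1 = corr(U1, Z)`, `ζ2 = corr(U2, Z)` and `δ12 = corr(U1, U2)`,
conditional independence of genotype and phenotype given covariates is
exactly

```
ϱ(δ0) = δ12 − ζ1' Δ22⁻¹ ζ2 = 0
```

— the partial latent correlation. The package estimates
`δ0 = (δ12, ζ1, ζ2)` by solving a pairwise-likelihood generalized
estimating equation, forms the M-estimation sandwich covariance
`V = J⁻¹ I J⁻¹`, and tests `ϱ = 0` with the delta-method Wald statistic
`T_W = ϱ̂ / √(ϱ̇' V ϱ̇ / n)`, asymptotically `N(0, 1)` under the null.
Ordered probit and proportional-odds logit baselines (`MASS::polr`) are
included, as are the two simulation mechanisms (latent-normal
discretization and proportional-odds) and a runner for the full
168-scenario rejection-rate grid.

## Worked example

```r
library(ordlvm)

# one dataset from the latent-normal mechanism: MAF 0.3, theta = -0.2
d <- simulate_ordinal(sim_config("nd", n = 400, maf = 0.3,
                                 effect = -0.2, seed = 2026))
fit <- lvm_test(d)       # columns g, y, z detected by name
fit
#> Latent-variable-model association test
#>   n = 400, delta12 = -0.2548, rho = -0.2783 (se 0.0662)
#>   TW = -4.2021, p = 2.644e-05
tidy(fit)
#> # A tibble: 3 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 delta12   -0.255    0.0680
#> 2 zeta1_1    0.118    0.0544
#> 3 zeta2_1    0.199    0.0569
glance(ordinal_reg_test(d, "probit"))
#> # A tibble: 1 × 7
#>   model  beta_g  se_g statistic   p.value converged     n
#>   <chr>   <dbl> <dbl>     <dbl>     <dbl> <lgl>     <int>
#> 1 probit -0.397 0.102     -3.91 0.0000916 TRUE        400
```

The latent correlation between genotype and phenotype is estimated at
`δ12 = −0.25`; after removing what the covariate explains, the partial
latent correlation is `ϱ̂ = −0.278` with standard error 0.066, giving
`T_W = −4.20` and a two-sided p-value of 2.6e-5 — the generating model had
`ϱ = −0.21`, so the test correctly rejects, and with a larger Wald
statistic than the ordered probit baseline on the same data (−3.91).

Monte-Carlo rejection grids:

```r
res <- reproduce_table(1, reps = 1000, seed = 1)  # ND mechanism, HWE
dplyr::filter(res, method == "lvm", effect_label == "null")
autoplot(res)                                     # rates vs reference
```

A thin command-line wrapper over these functions is installed at
`inst/cli/ordlvm.R` (`test`, `simulate`, `experiment` subcommands).

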
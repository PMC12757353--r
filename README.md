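# lidardbh

Genotype-aware nonlinear mixed-effects prediction of individual-tree
diameter at breast height (DBH, cm) from UAV-LiDAR canopy metrics.

## The problem

Airborne laser scanning measures tree height and crown extent over whole
plantations, but the variable foresters actually need for volume, biomass
and carbon accounting — stem diameter at 1.3 m — stays hidden under the
canopy. In clonal plantations (here, *Catalpa bungei*), trees of the same
height can differ systematically in diameter because of their genotype and
their planting density. `lidardbh` implements a prediction pipeline that
models that structure instead of averaging over it, for forest
biometricians working with per-tree tables of LiDAR height (`lh`, m),
LiDAR crown diameter (`lcd`, m), a planting-density class, and a genotype
label.

## The model

The mean function is a power-law allometry with a density shift on the
height exponent, and genotype enters through random effects on the two
height-exponent coefficients:

    DBH_ij = a1 * LH_ij^( b1 + u1_i + (b2 + u2_i) * P_ij ) * LCD_ij^c1 + e_ij

    (u1_i, u2_i)' ~ N(0, Psi)        genotype i = 1..M, unstructured Psi
    e_ij ~ N(0, sigma^2 * LH_ij^(2*gamma))   power variance function

`P = 1` marks high-density planting. Estimation is maximum likelihood via
an alternating Lindstrom–Bates scheme (penalized nonlinear least squares
in the coefficients and random effects, then a profiled linear
mixed-effects step for `Psi`, `sigma`, `gamma`, with `Psi` kept positive
semi-definite by a log-Cholesky parameterization). Candidate random-effect
subsets are searched and ranked by AIC/BIC; nested variance structures are
compared by likelihood-ratio tests.

The practical payoff is *calibration*: for a genotype with only a handful
of field-measured trees, the empirical best linear unbiased predictor
(EBLUP) of its random effects is computed by an iterative three-step
update, and every remaining tree of that genotype is then predicted with a
genotype-specific curve. The package evaluates four calibration sampling
schemes (smallest, largest, medium, random trees; k = 1..10) and
leave-one-genotype-out cross-validation.

Four base allometries (logistic, exponential, power, Richards) and the
three density-dummy power variants are provided for the model-selection
stage, with the shared fit statistics (mean error, error variance, TRE,
R², RMSE with RMSE² = bias² + variance) and information criteria
(AIC = 2k − 2lnL, BIC = k ln n − 2lnL, `k` counting every estimated
quantity).

Because per-tree trial data of this kind are rarely public, the package
ships a synthetic stand generator (`simulate_stand()`) whose defaults
reproduce the covariate marginals, group structure (78 genotypes × 37
trees), and generating parameters of the reference model
(`dbh_reference_fit()`), so the whole pipeline is testable end-to-end with
known ground truth.

## Worked example

```r
library(lidardbh)

stand <- make_fixture("small")            # 10 genotypes x 30 trees
fit <- fit_nlme(stand, model_form("power", "on_b"), c("b1", "b2"),
                variance = "power")
print(fit)
#> Genotype NLME power model (dummy: on_b)
#> Fixed effects:
#>      a1      b1      b2      c1
#>  0.8850  1.1320 -0.0478  0.2557
#> Random effects on: b1, b2
#> Psi:
#>           b1        b2
#> b1  0.007807 -0.007945
#> b2 -0.007945  0.008170
#> Residual: power variance on lh, sigma = 0.3390, gamma = 0.8336
#> logLik -438.3395  k = 9  n = 300  AIC 894.6789  BIC 928.0130

# calibrate each genotype with two random measured trees, then predict
# the remaining 280 trees with genotype-specific curves
cal_rows <- unlist(lapply(genotype_groups(stand), function(idx)
  idx[select_calibration_trees(stand[idx, ], "random", 2, seed = 42)]))
cal <- eblup(fit, stand[cal_rows, ])
holdout <- stand[-cal_rows, ]
fit_statistics(holdout$dbh, predict_dbh(fit, holdout, cal))
#> Fit statistics (n = 280)
#>   RMSE 1.2946 cm   R2 0.8385   TRE 4.5070
fit_statistics(holdout$dbh, predict_dbh(fit, holdout))   # population level
#>   RMSE 1.4335 cm   R2 0.8019   TRE 5.5260
```

Two measured trees per genotype cut the holdout RMSE from 1.43 to 1.29 cm
and lift R² from 0.80 to 0.84 — the localization gain the mixed model
exists for. The fitted exponents, variance function and `Psi` sit close to
the generator's truth (`dbh_reference_fit()` holds the reference values).

A thin command-line wrapper over the same functions is installed at
`inst/cli/lidardbh.R` (subcommands `simulate`, `fit`, `calibrate`,
`loocv`).

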
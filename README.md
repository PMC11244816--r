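# neonmort

Age- and cause-specific neonatal mortality estimation with an adapted
log-quadratic model.

## The problem

Neonatal (0–28 day) cause-of-death estimates are usually produced for the
period as a whole, yet the cause mix changes sharply with age inside it:
prematurity and birth asphyxia dominate the first days, sepsis the later
weeks. For planners deciding between facility-delivery promotion and
postnatal home visits, *when* a cause kills matters as much as how much.
`neonmort` is for epidemiologists and demographers who want cumulative
cause-specific mortality at high age resolution — by 24 h, 48 h, 1 week and
4 weeks — from the quarterly life tables of a pregnancy-surveillance cohort
in a high-mortality, verbal-autopsy setting.

## The model

For cause $c$ and cumulative age $x$, with $\mathrm{nmr}$ the quarter's
all-cause neonatal mortality rate per live birth,

$$\log {}_xq_{0,c} = a_{x,c} + b_{x,c}\log(\mathrm{nmr})
  + c_{x,c}\log(\mathrm{nmr})^2 + v_{x,c}\,k .$$

The quadratic coefficients are fit by OLS across quarters; the deviation
vector $v$ is the first right singular vector of the residual matrix,
normalized to 1 at 4 weeks; and the per-quarter shape parameter $k$ is then
available in closed form by calibrating the 4-week prediction to the
observed cause-specific rate. Zero cells enter the logs through a fixed
$10^{-5}$ offset. The package also implements the standard comparator
(constant daily cause-specific rate, i.e. linear allocation of the 28-day
risk), leave-one-quarter-out cross-validation of both against the $k=0$
model, and a synthetic surveillance-cohort generator so the entire analysis
runs without restricted data. See the methods vignette
(`vignettes/logquad-neonatal-mortality.Rmd`) for assumptions and design
choices.

## Worked example

```r
library(neonmort)

# a 25-quarter synthetic cohort at the default study conditions
coh <- generate_cohort(synthetic_config(seed = 1))
flt <- filter_analyzable(coh$records)
flt$tally
#> no_time   no_va
#>      58       3

tables <- build_quarter_tables(flt$records, coh$births,
                               quarters = coh$quarters)$tables

fit <- fit_logquad(tables, "asphyxia")
fit
#> Log-quadratic fit for cause 'asphyxia' (25 training quarters)
#>                 a       b      c      v
#> 0-23h     25.4130 16.0516 2.0720 1.3439
#> 0-47h      8.3785  6.5235 0.7773 1.3725
#> 0h-6 days  1.4068  2.3686 0.1789 1.1712
#> 0h-4weeks  3.8323  3.9685 0.4458 1.0000

# calibrate k for a quarter with all-cause NMR 30/1000 whose observed
# asphyxia-specific rate is 11/1000, then predict its age pattern
k <- calibrate_k(fit, nmr = 0.030, cause_nmr = 0.011)
round(predict(fit, nmr = 0.030, k = k), 5)
#>     0-23h     0-47h 0h-6 days 0h-4weeks
#>   0.00513   0.00813   0.01014   0.01100
```

The 4-week entry reproduces the supplied cause-specific rate exactly —
that is what the calibration does — and the younger ages carry the model's
estimate of the age pattern: here, roughly half of the 28-day asphyxia
mortality accrues in the first day.

Cross-validating all three methods:

```r
cv <- loqo_cv(tables)
cv_table(cv)[cv_table(cv)$cause == "asphyxia", ]
#>    cause age_label abs_err_k0 abs_err_bestk abs_err_standard rel_err_k0 rel_err_bestk rel_err_standard
#> asphyxia     0-23h    0.00149       0.00124          0.00463      0.296         0.214            0.922
#> asphyxia     0-47h    0.00201       0.00109          0.00683      0.266         0.147            0.899
#> asphyxia 0h-6 days    0.00243       0.00072          0.00676      0.251         0.080            0.718
#> asphyxia 0h-4weeks    0.00218       0.00000          0.00000      0.196         0.000            0.000
```

Absolute errors are probabilities per live birth (0.00072 is 0.7 deaths per
1000 live births); relative errors are dimensionless. The calibrated model
beats the $k=0$ model, which beats the constant-daily-rate standard, at
every age — and both best-$k$ and the standard are exactly zero at
0h–4weeks by construction, since each reproduces the observed 28-day rate.

## The analysis workflow

The `analysis/` scripts run the full study over the package:

```sh
Rscript analysis/01_simulate.R   # synthetic cohort -> results/data/
Rscript analysis/02_tabulate.R   # filters + quarterly life tables
Rscript analysis/03_fit.R        # per-cause log-quadratic fits (JSON)
Rscript analysis/04_crossval.R   # leave-one-quarter-out error tables
Rscript analysis/05_figures.R    # observed vs predicted, per quarter
```

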
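# tkburden

Toxicokinetics for higher-tier mammalian risk assessment: one-compartment
model fitting to blood concentration–time data, AUC-ratio bioavailability,
and a discrete-time gut/body simulator that predicts internal body burden
under arbitrary feeding scenarios.

## Why

Acute risk ratios for mammals are built on bolus-gavage LD50 values, but
toxic effect tracks the *internal* dose, and an animal eating contaminated
food over hours reaches a much lower internal peak than one force-fed the
same dose in a single bolus. For a compound with first-order kinetics —
the worked case here is the neonicotinoid thiamethoxam in laboratory rats —
a standard ADME study already contains everything needed to quantify that
difference. `tkburden` implements the chain:

1. **Per-individual one-compartment fits.** The i.v. curve is
   `C(t) = (dose/V) e^(−k_e t)`; the oral curve is the Bateman form
   `C(t) = dose/(V/F) · k_a/(k_a − k_e) · (e^(−k_e t) − e^(−k_a t))`.
   Estimation is weighted nonlinear least squares (Marquardt) with
   reciprocal weights `1/C_obs`, asymptotic 95% confidence intervals, and
   an AIC comparison (`n·ln WRSS + 2p`) against a two-compartment
   alternative. Flip-flop-ambiguous oral fits are normalised to the
   `k_a > k_e` branch.
2. **Relative bioavailability.**
   `F = (AUC_po/dose_po) / (AUC_iv/dose_iv)` per individual.
3. **Body-burden simulation.** Per-minute difference equations for the
   gut and internal pools,
   `ΔD_gut = I − k_a·D_gut·F` and `ΔD_int = k_a·D_gut·F − k_e·D_int`,
   driven by a feeding-bout schedule, with an exact closed-form companion
   (`analytic_burden()`) used to verify first-order convergence. The risk
   metric is `max D_int`, the peak body-weight-normalised internal dose.

A synthetic-study generator reproduces the reference design (3 males +
3 females per group, i.v. 0.5 and oral 0.5 / 100 mg kg⁻¹ bw, nine sampling
times from 0.25 to 48 h, lognormal between-subject variability matched to
published group means ± SD, 10% proportional measurement noise, LOQ
censoring), so the whole pipeline is testable although the original
individual-level data are unpublished.

## Worked example

```r
library(tkburden)

## synthesise a study, write/read the CSV dialect, fit one subject
study  <- generate_study(seed = 101)
series <- read_concentration_csv(write_concentration_csv(study, "study.csv"))
fit_one_compartment(series[[1]])
#> one-compartment fit (iv, subject iv_0.5_thiazol_m_1): converged after 5 iterations
#>     estimate      se ci_low ci_high
#> k_e   0.2253 0.01805 0.1789  0.2717
#> v     0.8947 0.04607 0.7762  1.0130
#> WRSS = 0.01915, AIC = -23.69, n = 7 (2 excluded)
```

The subject's elimination rate constant is estimated at 0.23 h⁻¹ (95% CI
0.18–0.27) with a distribution volume of 0.89 l kg⁻¹; two late samples
fell below the limit of quantification and were excluded from the
reciprocal-weighted objective.

```r
## group-mean bioavailability arithmetic (low-dose oral vs i.v. reference)
relative_bioavailability(auc_po = 1.49, dose_po = 0.5,
                         auc_iv = 2.30, dose_iv = 0.5)
#> Relative bioavailability F = 0.648
#>   AUC p.o. 1.49 at 0.5 mg kg^-1; AUC i.v. 2.3 at 0.5 mg kg^-1

## bolus vs dietary feeding of an LD50-sized dose, worst-case kinetics
run_feeding_comparison()$scenarios
#>   scenario max_d_int t_of_max_min pct_of_bolus
#> 1    bolus    1188.8           67       100.00
#> 2       2h    1097.3          148        92.30
#> 3       4h     933.9          254        78.56
#> 4    split     771.4          395        64.89
```

Eating the same 1563 mg kg⁻¹ bw dose over 2 h instead of as a bolus cuts
the internal peak by ~8%; two 1-h bouts separated by a 4-h break cut it by
~35%. Slower, interrupted feeding systematically lowers the internal peak,
which is the quantitative case for refining bolus-based risk ratios with
realistic feeding patterns.

## Layout

* `R/tk_model.R` — closed-form curves, half-lives, t_max, AUC
* `R/tk_fit.R` — weighted Marquardt fitting, CIs, AIC, bioavailability,
  group summaries
* `R/body_burden.R` — feeding scenarios, Euler simulator, closed-form
  reference, parameter sweeps
* `R/synthetic_data.R` — study designs, populations, series/tissue/study
  generators, bundled reference group summaries
* `R/io.R` — CSV/JSON/YAML readers and writers, run manifests, the
  reference scenario comparison
* `vignettes/body-burden-toxicokinetics.Rmd` — models, assumptions,
  numerical choices and limitations in full
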
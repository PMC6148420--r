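# agegrow

Multi-model growth estimation for exploited fish stocks, with
sampling-bias indicators and per-recruit projections.

## The problem

Growth curves underpin fisheries stock assessment: the asymptotic length
L∞ and growth coefficient K set perceived generation time, mortality, and
resilience. But age–length samples from heavily exploited stocks are
fishery-dependent and size-selective — large, old fish are missing — so
L∞ tends to be estimated low and K high, and flexible growth models can
end up describing the sample's age-frequency structure instead of the
species' biology. `agegrow` packages the full workflow for diagnosing and
quantifying this on one stock (the motivating case is the Gulf Corvina,
*Cynoscion othonopterus*, a short-lived, heavily exploited sciaenid of the
upper Gulf of California):

* **Five growth models** fit by Levenberg–Marquardt nonlinear least
  squares with seeded multi-start and Wald intervals: von Bertalanffy
  `L(t) = L∞ [1 − e^(−K (t − t₀))]`, Gompertz, logistic, Schnute (a,b ≠ 0
  family with data-fixed endpoints), and the five-parameter
  Schnute–Richards `L(t) = L∞ (1 + α e^(−a t^c))^(1/b)`.
* **Model comparison** by AICc and BIC, Akaike weights
  `wᵢ = e^(−Δᵢ/2) / Σ e^(−Δₖ/2)`, and weight-based model averaging of L∞.
* **Bias indicators**: bolstering every age class up to a common sample
  size with normal draws matched to the class moments (an ideal-sampling
  simulation), the Froese–Binohlan empirical check
  `log₁₀ L∞ = 0.044 + 0.9841 log₁₀ Lmax`, and length/age frequency
  histograms.
* **Per-recruit projections**: yield-per-recruit and female
  spawning-stock-biomass-per-recruit as functions of the old-adult
  exploitation rate, under any fitted growth scenario.
* **A synthetic-data generator** with known truth, age-specific Gaussian
  scatter, bimodal/uniform/custom age sampling and optional
  gear-selectivity truncation, so the whole pipeline is testable without
  restricted data.

## Worked example

Generate a fishery-like dataset (bimodal ages, 749 records) from a known
von Bertalanffy truth, fit all five models, and compare:

```r
library(agegrow)

truth <- list(L_inf = 916.05, K = 0.28, t0 = -0.17)
spec  <- synthetic_spec("von_bertalanffy", truth, n_total = 749,
                        sampling = "bimodal", noise_sd = 40, seed = 42)
d <- generate_dataset(spec)

fits <- lapply(growth_model_ids(), fit_growth, data = d, seed = 1)
build_selection_table(fits)
#> Model selection over 5 models (n = 749)
#>             model k    aicc delta_aicc       weight     bic delta_bic
#>   von_bertalanffy 4 7733.80    0.00000  8.03699e-01 7752.22    0.0000
#>  schnute_richards 6 7736.62    2.81926  1.96291e-01 7764.22   11.9973
#>          gompertz 4 7756.24   22.43637  1.07919e-05 7774.66   22.4364
#>          logistic 4 7799.06   65.26406  5.40982e-15 7817.49   65.2641
#>           schnute 3 8499.04  765.23876 5.44010e-167 8512.86  760.6416
```

The generating model wins, with the flexible Schnute–Richards model close
behind on AICc — exactly the near-tie that makes biological plausibility
checks necessary on real data. Bolster to 200 records per age and refit:

```r
b <- bolster_dataset(d, target_per_age = 200, seed = 42)
fit_growth("von_bertalanffy", b, seed = 1)
#> Growth fit: von_bertalanffy (n = 1600, k = 4)
#>    L_inf = 914.8, K = 0.2798, t0 = -0.169
#>   RSS = 2.88469e+06, sigma2 = 1802.93, logLik = -8268.0363, converged = TRUE
```

The refit stays on the generating curve (L∞ = 914.8 vs truth 916.05),
as it should when the raw data were unbiased to begin with. Check the
largest fish against the empirical L∞ relationship and project the fitted
growth through the per-recruit model:

```r
froese_binohlan_Linf(max(d$length_mm))
#> [1] 931.9311

cfg <- gulf_corvina_config("von_bertalanffy", fits[[1]]$params, label = "vb_raw")
per_recruit_curves(cfg)
#> Per-recruit curves (vb_raw growth, M = 0.488, E_YA = 0.000)
#>   NSSBR = 1.45391, YPRmax = 0.485226 at E = 1.000
#>   at current E_OA = 0.825: FNSSBR = 0.585, YPR/YPRmax = 0.951
```

At the current old-adult exploitation rate of 0.825/y this growth
scenario retains 58.5% of unfished female spawning biomass per recruit.
`compare_growth_scenarios()` runs the same projection for several fitted
curves at once, and `run_full_analysis()` (or the `inst/scripts/agegrow`
command-line wrapper) chains every stage — fit, select, indicators,
bolster, refit, per-recruit — into an output directory with delimited
tables and a JSON report.

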
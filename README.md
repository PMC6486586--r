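# streamlag

Credit-debt accounting for multi-stressor ecological time series.

River invertebrate communities respond to warming and to organic pollution
(biochemical oxygen demand, BOD) through a shared oxygen-stress pathway.
When water warms faster than communities re-assemble, a **climatic debt**
accumulates; when water quality improves faster than communities respond, a
**water-quality credit** appears. Expressed in common units (°C), the credit
can be set against the debt to give the **net environmental lag** — zero when
the community is at equilibrium with its environment.

`streamlag` implements the full analysis chain for long-format national
monitoring data, and a synthetic-data generator with known ground truth so
the chain can be validated end to end:

1. **Preprocessing** — censoring-aware annual chemistry medians (≥9 monthly
   samples; regression on order statistics when >50 % of values are below
   detection), nitrate from total oxidised nitrogen, discharge standardised
   to runoff (mm day⁻¹), and local ordinary kriging (25 km neighbourhood) of
   every variable-year surface to the biology locations.
2. **Classification** — Jaccard/Bray-Curtis dissimilarities, Ward or PAM
   clustering into K ordered classes (class 1 = cleanest by mean observed
   BOD), and covariate-adjusted annual prevalence with site-bootstrap CIs.
3. **Markov layer** — annual transition tallies from consecutive-year pairs,
   a loglinear hierarchy testing whether transition probabilities vary in
   space and/or time (AIC, within-2 parsimony), per-year matrices, and
   stability diagnostics: the stationary community w (wP = w), persistence,
   damping ratio ρ = λ₁/|λ₂| (return rate log ρ), Dobrushin's coefficient
   ᾱ = max_{i,j} ½Σ_k |p_ik − p_jk| (return rate −log ᾱ), and proximity to
   equilibrium.
4. **Transfer functions** — weighted-averaging partial least squares
   (ter Braak & Juggins iteration) predicting temperature or log BOD from
   log₁₀ abundance-class composition, calibrated on the first two years with
   leave-one-out component selection; a nutrient-discharge PCA composite.
5. **Accounting** — annual observed-minus-reconstructed lags anchored at the
   base year, a GAM cross-calibration converting BOD to °C equivalents,
   shared-intercept GLS trend fits with iid/AR1/MA1 selection and 400
   bootstrap SEs, and a zero-intercept trend for the net lag.

## Worked example

The `analysis/` scripts run the whole study on a synthetic national network
(300 sites, 1991–2011, warming 0.05 °C yr⁻¹, BOD declining, communities
tracking at r = 0.25 yr⁻¹, configured in `analysis/scenario.yaml`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_classify.R
Rscript analysis/04_markov.R
Rscript analysis/05_transfer.R
Rscript analysis/06_debt_credit.R
```

Outputs land in `results/` (labels, prevalence, transition matrices,
stability summary, reconstructions, lag series). With the configuration
shipped here, stages 5 and 6 printed:

```
water temperature: 2 component(s), cv R2 = 0.768 0.769 0.768 0.765 0.761
log BOD: 1 component(s), cv R2 = 0.194 0.182 0.176 0.175 0.173
Nutrient-discharge PC1 explains 38% of the variance.
Reconstructed conditions for 5023 samples.
Cross-calibration: edf 10.0, R2 1.00.
Climatic debt by 2011: +0.73 degC (SE 0.07).
Water-quality credit by 2011: -0.66 degC (SE 0.25).
Net environmental lag: +0.07 degC (trend P = 0.00).
Generator truth for the temperature lag at 2011: 0.150 degC.
```

Read: the transfer functions reconstruct temperature well (cv R² 0.77)
and BOD weakly; observed warming outran the community-implied warming
(positive debt), observed BOD improvement outran the community-implied
improvement by an equivalent amount of cooling (negative credit), and the
two nearly cancel into a small net lag. In this two-stressor demonstration
the *individual* debt and credit are inflated relative to the generator
truth (0.15 °C) because the community senses only the combined
oxygen-stress axis, so each reconstruction absorbs part of the other
stressor's trend — the reconstructed series correlate at R² ≈ 1 — while
their sum stays interpretable. This identifiability limit, and why the
quantitative validation therefore uses the single-pathway presets
`scenario_preset("warming_only")` / `"bod_only"`, is discussed in the
methods vignette.

A single call runs the same chain in memory:

```r
library(streamlag)
cfg <- scenario_preset("warming_only", seed = 1)
res <- run_pipeline(cfg, n_boot = 400)
res$debt_credit$accounting$debt_final      # GLS debt at 2011, degC
res$debt_credit$lag_temperature            # per-year lag with bootstrap SEs
```

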
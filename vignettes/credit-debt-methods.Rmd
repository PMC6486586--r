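---
title: "Methods: Markov community dynamics, transfer functions, and credit-debt accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov community dynamics, transfer functions, and credit-debt accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Stream macroinvertebrate communities integrate two stressors that act
through a common physiological pathway: rising water temperature and
organic pollution (measured as biochemical oxygen demand, BOD) both
increase oxygen stress. When temperature rises faster than communities can
respond, a *climatic debt* accumulates — the community still "looks" cooler
than the water it lives in. When water quality improves faster than the
community re-assembles, the mirror-image *water-quality credit* appears.
Because the two act on a shared axis, the credit can be expressed in
degrees Celsius and set against the debt, giving a *net environmental lag*.

`streamlag` implements the full accounting chain over long-format national
monitoring tables, plus a synthetic-data generator with known ground truth
so that every stage can be validated end-to-end without external data.

# The synthetic scenario and what it emulates

The generator (`scenario_config()`, `simulate_scenario()`) emulates the
structure of a national river-monitoring programme:

* **Sites and fields.** `n_sites` (default 300) sites uniform on a 200 km
  square; baseline water temperature and log BOD are smooth functions of
  the coordinates plus site-level noise, so spatial interpolation has real
  structure to exploit. Site attributes (altitude, slope, distance from
  source, urban fraction) are generated coherently: cold rivers sit high,
  polluted rivers drain urban land.
* **Trends.** Temperature rises linearly at `warming_slope` b (default
  0.05 °C yr⁻¹ — the magnitude of recent warming in lowland European
  rivers) and log BOD falls at `bod_slope` c (default −0.02 yr⁻¹,
  a ~35 % decline over 21 years, consistent with the large water-quality
  recovery of the 1990s–2000s).
* **The lag mechanism.** Communities respond to a *tracked* environment
  E\*(t) = (1−r) E\*(t−1) + r E(t). The tracking rate r (default 0.25) is
  the fraction of the remaining environmental change the community absorbs
  per year. Under a linear trend of slope b the lag E−E\* follows the
  closed form b(1−r)(1−(1−r)^t)/r, converging to b(1−r)/r (0.15 °C at the
  defaults). With r = 1 every lag is identically zero — the null scenario.
* **Communities.** The latent oxygen-stress axis is
  w_T·T\* + w_B·log BOD\* (defaults 1 per °C and 2 per log unit, so a
  doubling of BOD weighs like ~1.4 °C of warming). Each of 78 family-level
  taxa has a Gaussian response along that axis: optima spread evenly over
  the realised stress range, tolerances uniform on 1–2 stress units,
  heights log-normal (median 30 individuals). Counts are Poisson draws
  coarsened to log10 abundance-class midpoints (1–9 → 5.5, 10–99 → 54.5,
  …), the format of the recorded data. Sites are sampled each year with
  probability 0.8, giving the irregular coverage (with consecutive-year
  pairs) the transition tally needs.
* **Chemistry.** Twelve monthly values per site-year at chemistry points
  offset ~2 km from the biology sites: additive seasonal cycle for
  temperature, multiplicative for chemistry, orthophosphate censored at a
  detection limit, months dropped at random (default 5 %) to exercise the
  at-least-nine-months rule, and a share of site-years where nitrate is
  recorded as total oxidised nitrogen.

What the generator deliberately does **not** emulate: real taxonomy or
autecology, hydrological regimes, serially correlated environmental noise,
taxon interactions, or observation error in identification. Passing tests
therefore demonstrate that the *pipeline* recovers a known truth under the
stated mechanism — not that the mechanism is how real rivers behave.

**Single-axis identifiability.** Because the community sees only the 1-D
stress combination, temperature and BOD are not separately identifiable
from composition: any scenario in which both stressors vary independently
confounds the two reconstructions and biases their individual lags (the
net remains interpretable only insofar as the cross-calibration is exact).
The validation scenarios therefore isolate one pathway at a time
(`scenario_preset("warming_only")`, `"bod_only"`); the default two-stressor
scenario is used for demonstration, not for lag-recovery claims. This
limitation is intrinsic to a shared-axis world, and a milder version of it
affects any real multi-stressor cross-calibration.

# Preprocessing

Annual medians use the 12 monthly values of each site-year (the March to
February window preceding spring sampling); fewer than 9 months rejects
the site-year. When ≤ 50 % of values are censored, the median of the
uncensored values is used (censored ones excluded — standard practice;
the heavy-censoring case is what ROS is for). Above 50 %, the median comes
from log-normal regression on order statistics with Hirsch–Stedinger
plotting positions: ranked plotting positions account for the censored
observations, log values of the uncensored data are regressed on normal
quantiles, censored values are imputed from the fitted line, and the
median is taken over the combined set.

Nitrate recorded as total oxidised nitrogen is converted by a linear
calibration fitted where both determinands exist (nitrate is ~99 % of TON
in rivers). Discharge becomes runoff in mm day⁻¹ (Q·86.4/area). Each
variable-year surface is interpolated to the biology locations by local
ordinary kriging with a 25 km neighbourhood, an exponential variogram
fitted by weighted least squares (the variogram family is an
implementation choice; nothing in the analysis depends on it strongly),
chemistry and runoff on the log scale with back-transformation. A target
with no observation in the neighbourhood stays missing; a singular kriging
system falls back to inverse-distance weighting with a warning. Every
annual-table cell carries exactly one provenance tag
(measured / ros-imputed / kriged).

# Classification and prevalence

Samples are clustered on Jaccard (presence/absence) or Bray–Curtis
(abundance-class) dissimilarities with Ward's method or partitioning
around medoids, into K ∈ {3, 5, 7} classes (default 3 — the simplest
interpretable split and the largest per-class sample sizes). Cluster
labels are arbitrary, so classes are relabelled by ascending mean observed
BOD of their members: class 1 is the clean, well-oxygenated community,
class K the pollution-tolerant one.

Annual national prevalence of each class is estimated by a per-class
binomial GAM with year as a factor (annual transitions, not a smooth
trend, are the object of interest), log(1+x) site covariates (altitude,
slope, distance from source, urban fraction) and a low-rank thin-plate
spatial smooth of the coordinates; annual prevalence is the mean fitted
probability over that year's sites. Confidence limits come from a
nonparametric bootstrap over *sites* (keeping all of a site's years
together, respecting repeated measures; 400 resamples by default).
Per-class models are simpler to bootstrap than one multinomial model; the
per-year sum of prevalences is checked to stay within 0.02 of 1.

# The Markov layer

Only consecutive-year sample pairs contribute transitions. The loglinear
hierarchy fits Poisson models to counts cross-classified by state, fate,
year and river-type stratum; all candidates condition on the
state×year×stratum margin (the sampling design), and differ in whether the
fate distribution is homogeneous ({SF}), varies in time ({SFT}), space
({SFR}), both additively, or fully ({SFTR}). Comparison is by AIC with
likelihood-ratio tests of nested pairs; the simplest model within 2 AIC of
the minimum is selected. Strata default to an altitude cutoff (250 m,
upland/lowland); the cutoff is a configuration knob.

Annual matrices are row-wise multinomial MLEs (rows with zero totals stay
undefined, never silently filled). Diagnostics per year: the stationary
community (dominant left eigenvector; uniqueness is checked via the
eigenvalue spectrum and reducible or periodic chains are refused), the
persistence diagonal, the damping ratio ρ = λ₁/|λ₂| (ties at |λ₂| resolved
by modulus; |λ₂| = 0 gives the documented +Inf sentinel) with return rate
log ρ, Dobrushin's ergodic coefficient ᾱ = max over row pairs of half the
L1 distance with rate −log ᾱ, and the proximity to equilibrium (mean
absolute difference between observed class frequencies and the stationary
distribution). The per-year (rather than pooled) matrices are the default;
pooling is available by summing the tally first.

# Transfer functions

WA-PLS is implemented from the ter Braak & Juggins iteration: taxon scores
as abundance-weighted averages of current environmental residuals, site
scores as weighted averages of taxon scores, orthogonalisation to earlier
components under site-total weights, unit-variance scaling, then a
weighted regression of the environment on all components (the deshrinking
regression) whose residuals seed the next component. With one component
this is exactly classical weighted averaging with inverse deshrinking
(under the same weighting convention), which the tests assert to 1e−8.

Two deshrinking conventions are provided. *Inverse* (the default of
`fit_wapls()`, and the convention of the iteration itself) minimises
squared prediction error but compresses reconstructions towards the
calibration mean by a factor of about R²; a compressed reconstruction
under-states the reconstructed *trend*, which inflates the apparent lag —
the one quantity this analysis exists to estimate. The pipeline therefore
uses a *classical* rescaling (the inverse estimate regressed on the truth
and inverted) so the calibration slope of prediction on truth is exactly
1, at the cost of a little extra variance.

Component count is chosen by leave-one-out cross-validation (refit without
each sample, predict it, cv R² = squared correlation). `loo_select()`
offers a parsimony tolerance (smallest count within `tol` of the best);
the pipeline sets `tol = 0` (take the cv-optimal count) because an
under-fitted composition→environment map leaves a smooth residual that
drifts as the gradient shifts through time — a bias in the lag that LOO
prediction error is almost blind to. Taxa with fewer than 10 occurrences
in the calibration window are dropped (flag-controlled). Calibration
defaults to the first two years of the record, following the design of
calibrating on the earliest window and reconstructing forward.

The nutrient–discharge composite is the first principal component of
standardised log orthophosphate, log nitrate and log runoff, sign-fixed to
correlate positively with nitrate.

# Credit-debt accounting

Observed and reconstructed values are averaged per year over the same
samples; the environmental lag is observed − reconstructed, anchored to 0
in the base year (1991). Reconstructed temperature is regressed on
reconstructed log BOD with a penalised thin-plate spline (smoothness by
GCV) to give the map g that converts BOD to temperature equivalents; the
BOD lag mapped through g is the water-quality credit (negative when
observed quality outruns the community), and debt + credit is the net lag.

Trends are fitted by GLS on the stacked observed/reconstructed series with
a single shared intercept, so the fitted lag is zero at the base year;
error structures iid, AR1 and MA1 (optionally with per-series variance
heterogeneity) are fitted by maximum likelihood and the simplest within 2
AIC of the minimum is selected. The net-lag trend is fitted through the
origin. Slope standard errors come from a nonparametric bootstrap over
years (400 resamples; case resampling understates autocorrelation, so a
moving-block variant with block length 3 is available by flag). Per-year
lag SEs combine a within-year bootstrap over samples with a
calibration-set bootstrap that refits the transfer function, propagating
the shared reconstruction uncertainty. BOD results are computed on the log
scale and back-transformed for reporting.

# Numerical choices and degenerate inputs

* Stationarity check: exactly one eigenvalue on the unit circle (tol
  1e−8); the identity matrix and periodic chains raise errors.
* ᾱ = 0 and |λ₂| = 0 return +Inf rates as documented sentinels.
* A constant calibration environment returns the constant (the WA-PLS
  component is degenerate and the model collapses to the weighted mean).
* Exact linear fits defeat the GLS likelihood machinery; the structure
  selection then falls back to OLS, which is exact there.
* Two empty community samples get dissimilarity 0 with a warning; empty
  samples are dropped from calibration and predicted as NA.
* The even-month median of a multiplicative seasonal cycle exceeds the
  annual value by a cosh(amplitude²/2)-type convexity factor (~0.1 % at
  the default amplitude); tests use a matching tolerance.

# Validation design, problem sizes, and what the tests show

The acceptance checks run the full pipeline on the warming-only scenario
(300 sites × 21 years, b = 0.05, r = 0.25; Poisson counts, class
midpoints, kriged chemistry) and compare the per-year debt trajectory with
the closed form, each year at twice its bootstrap SE; the r = 1 variant is
the null control. Unit-level oracles cover the Markov diagnostics (power
iteration, characteristic-polynomial roots, exhaustive pairwise L1),
WA equivalence, ROS (Monte-Carlo against a known log-normal median),
kriging (exactness, held-out RMSE against nearest-neighbour) and the GLS
machinery (exact noise-free slopes).

Two honest limitations surfaced by this design are worth stating plainly.
First, a per-year 2-SE band across 20 years is a demanding simultaneous
test: even an unbiased estimator leaves the band somewhere with
substantial probability. Second, with a finite random taxon pool the
composition→environment map has realisation-specific curvature; as the
gradient shifts through time this produces a smooth drift of up to the
order of a tenth of a degree that is a *bias* for any fixed taxon draw — no
resampling of sites, samples or taxa recovers it, and the implemented SE
propagation (within-year + calibration bootstrap) accordingly cannot cover
it in every year. The trajectory itself is recovered to well under half
the asymptote everywhere, and the null scenario shows no systematic debt.
The same mechanism — reconstruction curvature interacting with a shifting
gradient — will affect real applications of the method and is, in our
view, the main caveat on lag estimates of this kind. Related: when one
stressor's transfer function has no real skill, the cross-calibration
slope is an ill-conditioned ratio and the °C-converted credit can be
arbitrarily scaled; credible credits require a skilful stressor
reconstruction (check the cv R² before believing the conversion).

Problem sizes in the shipped tests (chosen so the whole suite stays
comfortably interactive): ~5 000 samples per pipeline run, 400 bootstrap
resamples for trend SEs, 100 for calibration propagation, 50 replicates
per loglinear selection-rate estimate, 500 for the ROS Monte-Carlo.
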
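---
title: "Models and methods behind algaetox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind algaetox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaetox)
```

# The assay and its endpoints

`algaetox` analyses chronic growth-inhibition bioassays on marine
microalgae exposed to herbicides: a seawater control, optionally a solvent
control and a reference-toxicant treatment (a PSII inhibitor at a fixed,
consistently inhibiting concentration), and a geometric series of 6–8 test
concentrations, each with n = 5 replicate cultures inoculated at
3 × 10³ cells mL⁻¹ and grown for 3 days.

Two biological endpoints are computed per replicate:

* **Specific growth rate (SGR)** over 72 h,
  $\mathrm{SGR} = (\ln X_j - \ln X_i)/(t_j - t_i)$ in day⁻¹, from flow
  cytometric cell densities. Negative rates (population decline) are kept.
* **Effective quantum yield** of photosystem II at 24 h,
  $\Delta F/F_m' = (F_m' - F)/F_m'$, from a light-adapted PAM fluorescence
  pair. This photophysiological endpoint responds faster and, for PSII
  herbicides, at lower concentrations than growth.

Each endpoint is converted to **percent inhibition** relative to the mean
of the control replicates,
$\%I = 100\,(X_{control} - X_{treatment})/X_{control}$. Values below zero
(stimulation) are preserved; clipping would bias curve fits near the
no-effect region.

**Exposure** is summarised per treatment as the geometric mean of the
measured start and end concentrations, the time-weighted average under
first-order dissipation. When chemical measurements are missing the
nominal concentration is used and the fallback is flagged in the output
(`conc_source`). Measured values at or below a configured limit of
quantitation are replaced by LOQ/2 before averaging; without an LOQ the
code falls back to nominal. Both policies are deliberate choices for data
the protocol leaves unspecified, and both are visible in the serialized
results.

## Validity criteria

A test is acceptable when (i) the control mean SGR is at least
0.92 day⁻¹ (about 1.3 doublings per day), (ii) the percent coefficient of
variation of control SGR is at most 10 %, and (iii) no treatment's pH
rises by more than 1 unit between 0 h and 72 h. The pH rule is signed:
decreases never fail. The reference-toxicant inhibition is reported as a
between-assay consistency indicator but is not a gate — QC failure warns
and annotates, it never suppresses results, because acceptability
criteria govern whether an assay should be *reported*, not whether the
arithmetic can be done.

# Concentration–response model

Percent inhibition $y$ is fitted against log₁₀ concentration with the
four-parameter logistic

$$y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} EC50 - \log_{10} c)\,h}},$$

by least squares on replicate-level data (`fit_4pl()`). Controls are not
placed on the log axis; they enter only through the inhibition baseline.
Numerical choices:

* **Optimiser**: Levenberg–Marquardt with box bounds
  ($bottom \in [-30, 40]$, $top \in [40, 120]$ % inhibition,
  $h \in (0, 10]$, $\log_{10} EC50$ within the tested range ± 1 decade),
  restarted from 8 deterministic starting points (4 midpoint guesses
  spread over the tested range × slope guesses 0.5 and 2); the best
  converged fit by SSE wins. In tests the optimum is cross-checked against
  a brute-force grid search of the SSE surface.
* **$R^2$** is computed on replicate data, $1 - SSE/SST$.
* **ECx** values solve the fitted curve at an *absolute* inhibition level
  ($x$ % of the control response, control = 0 %), the reading that matches
  "inhibits the endpoint by 50 %". The relative-to-asymptote alternative
  was considered and rejected: with $bottom \approx 0$ and
  $top \approx 100$ the two coincide, and the absolute scale keeps EC
  values interpretable when the fitted asymptotes drift from 0/100.
* **Censoring**: if the requested level lies outside the open interval
  between the fitted asymptotes, or the solution exceeds the highest
  tested concentration, the ECx is reported censored as "> max tested" —
  extrapolated thresholds beyond the tested range are never printed as
  numbers.

**Confidence intervals** come from a case bootstrap (default 2000
resamples): replicates are resampled with replacement within each
concentration group, the curve is refitted from the full-data estimates,
and the 2.5/97.5 percentiles of the ECx distribution are taken. The
bootstrap was chosen over asymptotic standard errors because n = 5 per
concentration is too small to trust linearisation, and because it is
fully specified and reproducible from a seed. Resamples that fail to fit
or give censored ECx are dropped; more than 20 % failures attaches a
wide-interval warning.

## Nonresponse path

Some compounds produce no concentration response over the tested range
(in the emulated study, the ACCase-inhibiting herbicide at up to
4570 µg L⁻¹). Fitting a sigmoid to flat data yields unstable,
meaningless thresholds, so assays are first classified: **nonresponsive**
iff a one-way fixed-effects ANOVA across treatments (reference excluded)
is not significant at $\alpha = 0.05$ *and* mean inhibition at the top
concentration stays below 10 %. Both conditions must hold — a significant
ANOVA alone (for example mild stimulation at intermediate levels) keeps
the assay on the responsive path. Nonresponsive assays report EC10, EC50
and NEC censored at the maximum tested concentration, and relative
potencies as undefined (NA). Degenerate ANOVA inputs with zero
within-group variance short-circuit to exact p-values (0 under
separation, 1 otherwise) with a note.

# The Bayesian no-effect-concentration model

Threshold models answer a different question from ECx: below which
concentration is there *no* effect at all? The proportional response
$y = 1 - \%I/100$ (controls near 1) is modelled against natural-log
concentration $x$ as

$$E[Y_i \mid x_i] = \alpha\,
  \exp\!\big[-\beta\,(x_i-\gamma)\,I(x_i-\gamma)\big] - \Delta,$$

with gaussian error $\sigma$: flat at $\alpha - \Delta$ up to the
threshold $\gamma$ (the NEC on log scale), exponential decay at rate
$\beta$ above it, continuous at $\gamma$ and non-increasing for
$\beta \ge 0$. The NEC is reported as the posterior median and central
95 % credible interval of $e^\gamma$ in µg L⁻¹.

**Controls** have no finite log concentration; they are placed one decade
below the lowest test treatment (configurable to 0.5 or 2 decades for
sensitivity analysis), and the placement is recorded in the output. One
decade is far enough below any plausible threshold not to influence
$\gamma$, yet keeps the plateau well anchored.

**Priors** (all overridable through `nec_priors()`):
$\gamma \sim U(\min x - 0.5,\ \max x)$;
$\alpha \sim N(\bar y_{control},\ 10\,s_{control})$ truncated positive,
with the scale floored at 0.25 when control spread is degenerate;
$\beta \sim \mathrm{Gamma}(10^{-4}, 10^{-4})$ (vague, positive);
$\Delta \sim N(0, 1)$; $\sigma \sim$ half-Cauchy(1). These are weakly
informative and standard for threshold models on proportional data.
$\Delta$ is left free rather than fixed at 0: with responses near 1 it is
weakly identified, but the $N(0,1)$ prior keeps it bounded and the strong
high-concentration decline in responsive assays identifies it in
practice.

**Sampler.** Adaptive random-walk Metropolis-within-Gibbs, written for
exact reproducibility: the first half of burn-in updates each parameter
in turn with scalar gaussian proposals tuned toward 44 % acceptance;
the second half switches to joint multivariate proposals using the
empirical covariance of the chain so far (rescaled toward 23 %
acceptance, covariance re-estimated twice and frozen at the end of
burn-in). The sampler walks in $(\,top = \alpha - \Delta,\ \beta,\
\gamma,\ \Delta,\ \sigma)$ coordinates — $\alpha$ and $\Delta$ are nearly
collinear in the likelihood and this unit-Jacobian rotation removes the
ridge. Defaults are 4 chains × 10 000 iterations with 5 000 burn-in.
Convergence is monitored by split-chain R-hat and an
initial-positive-sequence effective sample size; R-hat > 1.05 or
ESS < 400 triggers a warning while still returning the flagged fit. The
likelihood the sampler evaluates is exported (`nec_loglik()`) and tested
against an independent direct gaussian log-density computation.

Every chain derives its RNG stream deterministically from the user seed;
identical (data, settings, seed) reproduce the posterior draws exactly.

# Potency comparisons

* **Relative potency**: $ReP = EC50_{reference}/EC50_{test}$ on a shared
  endpoint; the reference against itself is exactly 1; a censored EC50 on
  either side gives NA.
* **Endpoint ratio**: $EC50_{SGR}/EC50_{yield}$; values near 3 reproduce
  the observation that the photophysiological endpoint is roughly
  threefold more sensitive than growth for PSII herbicides.
* **Sensitivity regression**: OLS of per-treatment mean yield inhibition
  (response) on mean SGR inhibition (predictor), with intercept and 95 %
  slope CI. Per-treatment means are used because that is what the paired
  endpoint plot shows; a replicate-level regression is available by
  passing replicate vectors directly. Note the two summaries measure
  different things: the EC50 ratio compares positions of the two curves
  on the concentration axis, while the regression slope compares how the
  two inhibitions co-vary across treatments — a ~3× EC50 ratio is fully
  compatible with a slope near 1.

Display rounding to 3 significant figures (2 where conventions print 2)
happens only at serialization; internal values keep full precision.

# The synthetic-assay generator

`simulate_assay()` produces complete datasets with known truth so every
stage is testable without external data. It emulates:

* exponential growth from 3 × 10³ cells mL⁻¹ at a control rate of
  1.55 day⁻¹ (the middle of the 1.41–1.68 day⁻¹ control band of healthy
  diatom cultures) with multiplicative lognormal replicate noise at 4 %
  CV on the 72-h densities — densities are positive and CV-scaled, which
  is why the noise is lognormal, not additive;
* control quantum yield 0.46 (band 0.42–0.48) with additive gaussian
  noise, sd 0.01, encoded as an (F, Fm′) pair with Fm′ fixed at 500
  instrument units;
* first-order herbicide loss: measured start = nominal, measured end =
  0.8 × nominal, each with 5 % lognormal measurement noise (typical
  LC–MS/MS precision); the truth inhibition curve is evaluated at the
  geometric mean of these simulated measurements, so a zero-noise run
  round-trips *exactly* through `endpoint_table()`;
* a yield endpoint whose EC50 sits threefold below the growth EC50
  (`endpoint_ratio_truth = 3`);
* a reference treatment at 4 µg L⁻¹ with fixed truth inhibitions of 23 %
  (growth) and 42 % (yield), inside the observed between-assay ranges
  21–25 % and 39–45 %.

The generator does **not** simulate flow-cytometer event data,
fluorescence kinetics, solvent effects, plate-position effects, or
between-day drift; passing tests therefore demonstrate correctness of
the estimators under the assumed noise model, not robustness to
instrument artefacts. Hormesis is not simulated by default, but a
negative `bottom` in the truth curve exercises the no-clipping contract.

# Validation studies and problem sizes

The package validates itself with seeded simulation studies (in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* **4PL recovery** — noiseless curves recovered to ≤ 10⁻⁶ relative
  error; 50 simulated assays with 5 %-inhibition replicate noise, n = 5,
  7 concentrations: median EC50 error and the fraction of fits with
  R² ≥ 0.98. The study curve uses hill = 1.5 over a 3-decade series —
  slopes back-computed from printed EC10:EC50 ratios of PSII herbicides
  fall in 1.1–1.5, and a standard dilution series covers the full
  response range. On a flatter curve confined to 2 decades the R² ≥ 0.98
  regime is not reachable at 5 % noise for any estimator: the residual
  variance alone caps expected R² near 0.975.
* **ECx inversion** — closed-form agreement to ≤ 10⁻⁹ on 100 random
  parameter sets.
* **NEC calibration** — 100 datasets from the threshold model
  ($\alpha = 1$, $\beta = 1.5$, $\sigma = 0.02$, 7 × 5 design), truth
  placed at the geometric midpoint between two tested concentrations;
  coverage of the 95 % credible interval and accuracy of the posterior
  median. The study uses 2 chains × 6000 iterations, sizes at which
  spot checks reproduce the full-length intervals. A threshold lying
  *exactly on* a tested concentration is a known hard case: responses at
  that point sit on the plateau, the posterior for $\gamma$ concentrates
  just above it, and interval coverage degrades — with thresholds at
  generic positions (the realistic case) coverage is nominal. This is a
  limitation of threshold estimation on discrete designs, not of the
  sampler.
* **Bootstrap calibration** — 200 simulated assays, 200 resamples each:
  empirical coverage of the nominal 95 % EC50 interval.
* **Censoring and determinism** — flat assays censor every threshold
  end-to-end, and identical (input, config, seed) must produce
  byte-identical serialized output. Because the nonresponse
  classification is a statistical test at $\alpha = 0.05$ per endpoint, a
  flat assay has a ~0.95² ≈ 90 % probability of full censoring across
  both endpoints; a chance-significant ANOVA legitimately routes an
  endpoint to the responsive path. The fixed-seed test suite exercises
  the censoring path itself; the acceptance script reports the observed
  fraction over fresh seeds.

# Known limitations

* The NEC model is gaussian-only; binomial or Poisson response families
  and model averaging across threshold and smooth-sigmoid forms are out
  of scope.
* ECx censoring uses the maximum *TWA* concentration as the reporting
  bound, which for dissipating compounds is slightly below the nominal
  maximum.
* The nonresponse ANOVA inherits the usual fixed-effects assumptions
  (homoscedastic gaussian errors); with n = 5 per group it has limited
  power against subtle trends.
* Threshold coverage near design points degrades as described above.
* The percentile case bootstrap undercovers at n = 5 replicates per
  concentration: empirically ~88 % at nominal 95 % (pooled over 1100
  simulated assays), with symmetric misses — the usual small-sample
  variance deflation of resampling tiny groups. Replicate counts of 8–10
  would close most of the gap.
* No replicate-outlier exclusion rule is applied at any stage; all wells
  enter the statistics.
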
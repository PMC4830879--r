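---
title: "Estimating blow fly egg age from embryonic landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blow fly egg age from embryonic landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggclock)
```

## The problem

*Calliphora vicina* is commonly the first blow fly to colonise a cadaver, and
the age of its oldest immature stages bounds the minimum post-mortem interval
(PMI~min~). The egg is the shortest stage — roughly 5% of total immature
development — so egg-only evidence is usually a cool-weather scenario in which
hatching takes days and a method resolving age *within* the egg stage matters.
`eggclock` implements such a method: embryos are dechorionated, examined under
a stereo microscope, and scored for the presence of 15 external morphological
landmarks (homogeneous yolk mass, clear polar gaps, the "bright peripheral
ring" of blastoderm cells, cephalic furrow, dorsal folds, stomodeal
invagination, segmentation, gut shapes, spine bands, posterior spiracles,
cephalopharyngeal skeleton, tracheal system). The chronology of these
landmarks across eleven 10% intervals of total egg development, calibrated at
7.3 °C and 25 °C, is the package's central data object.

## The thermal model

Development is tracked in accumulated degree hours (ADH) above a lower
developmental threshold of 1 °C:

$$\mathrm{ADH}(t_0, t_1) = \int_{t_0}^{t_1} \max\{0,\; T(t) - T_{base}\}\,dt .$$

Temperature logs are interpreted piecewise-constant (left-hold, matching data
loggers), which makes the integral exact and exactly additive over
sub-intervals. Total egg development takes 120 h at 7.3 °C (756 ADH) and 16 h
at 25 °C (384 ADH): the ADH *requirement itself is temperature dependent*, so
summing ADH against a single total would misstate development under
fluctuating temperatures. The model therefore uses rate summation: a time step
$\Delta t$ at temperature $T$ advances development by

$$\Delta p = \frac{\max\{0, T - T_{base}\}\,\Delta t}{\mathrm{ADH_{total}}(T)},$$

with $\mathrm{ADH_{total}}(T)$ interpolated **linearly in temperature**
between the two calibrated values (756 ADH at 7.3 °C, 384 ADH at 25 °C). Only
two calibration temperatures exist, so any richer interpolation would be
invention; outside [7.3, 25] °C the requirement is clamped to the nearest
calibrated value and every estimate carries an explicit extrapolation
warning. The inverse problem — hours of age corresponding to a development
proportion, under an arbitrary profile ending at the collection time — is
solved by deterministic bisection to a tolerance of 0.01 h (development is
monotone in elapsed time, so the root bracket is valid; flat sub-threshold
stretches are handled by returning the *earliest* time attaining the target).

```{r thermal}
tab <- load_staging_table()
accumulate_adh(constant_profile(7.3), 0, 12)$adh    # 75.6 ADH = 12 h * 6.3 K
adh_required(0.5, 25, tab)                          # 192 ADH to mid-development
invert_age(c(0.9, 1), constant_profile(25), 16, tab)
```

## The staging likelihood

The calibration scores each landmark at each interval with an ordinal
visibility category: absent (blank), `+` (seen in <25% of individuals), `++`
(25–75%), `+++` (>75%). The estimator reads each category as a representative
presence probability

| category | range | default $q$ |
|---|---|---|
| absent | — (mis-scoring floor) | 0.01 |
| rare (`+`) | (0, 0.25) | 0.125 |
| common (`++`) | [0.25, 0.75] | 0.5 |
| prevalent (`+++`) | (0.75, 1] | 0.875 |

and scores an observation against interval $i$ as
$\log L(i) = \sum_{\ell} \log q_{\ell i}$ over landmarks recorded present plus
$\sum_{\ell} \log (1-q_{\ell i})$ over landmarks recorded absent; landmarks
not assessed contribute nothing. Recorded absences are deliberately
informative: a blank calibration cell is a genuine absence of the character
at that interval, so "looked and did not see" is evidence. The defaults are
configuration, not calibration results — each is validated against its
category's admissible range, and users probing sensitivity can move them
within those ranges. Landmark independence given the interval is assumed; the
calibration publishes only marginal frequencies, so any dependence structure
would be invention.

The posterior over the eleven intervals combines the likelihood with a prior
(uniform by default). The MAP interval breaks ties toward the *earlier*
interval — conservative for PMI~min~ use, since a younger egg implies a
shorter minimum interval claim. The 95% credible set is built by adding
intervals in order of posterior mass and is then extended to be contiguous:
development is monotone, and a disjoint age set is not forensically
actionable. The credible set's proportion range is converted to hours before
collection and to ADH through the thermal model above.

Two further policies deserve note:

* **Temperature for cell lookup.** Category frequencies exist only at the two
  calibrated temperatures, whereas ADH interpolates naturally. The likelihood
  therefore uses the *nearest* calibrated temperature (ties toward 7.3 °C,
  the slower regime), recorded in the estimate's warnings, while the age
  conversion interpolates.
* **The 20% interval** shows opposite category patterns at the two
  temperatures (early gastrulation common at 7.3 °C, the bright peripheral
  ring common at 25 °C). The estimator simply uses the per-temperature cells;
  whether the difference is sampling or biology is unresolved in the source
  data.

## Preservation modes

How the sample was killed and stored decides what can be scored:

* `living` — all 15 landmarks scorable.
* `hwk_ethanol` — hot water killing then 80% ethanol, the recommended
  protocol: 11 of 15 landmarks remain scorable. The other four (homogeneous
  yolk mass, clear gaps, dorsal folds, fully developed tracheal system) are
  destroyed by fixation, and the estimator forces them to "not assessed"
  whatever the observer recorded — so the posterior is provably invariant to
  how they were scored.
* `ethanol_direct` — live eggs placed straight into 80% ethanol decompose
  markedly; no landmark is diagnosable below the 90% interval. If the
  specimen shows first-instar larval morphology the development proportion is
  bounded to [0.9, 1.0]; otherwise the estimate is fully censored to [0, 1]
  with a strong warning. Censoring is a *result*, not an error: the front
  ends exit 0 on censored estimates and reserve non-zero codes for broken
  input.

```{r preservation}
edl <- observation_set(character(0), preservation = "ethanol_direct",
                       larval_morphology = "present", nominal_temp_c = 7.3)
estimate_age(edl, tab)$proportion_range
```

## The synthetic cohort generator

`simulate_observation()` draws each landmark present with probability $q$
from the calibration cell at a known true interval and temperature —
either the representative $q$ above (`"representative"`) or a run-level draw
uniform inside the category's frequency range (`"uniform_in_range"`) — and
then applies the same preservation masking the estimator assumes.
`simulate_cohort_timeline()` drives the full pipeline: thermal model forward
from a known oviposition time, interval assignment by half-open
$[i/10, (i+1)/10)$ bins (1.0 maps to the 100% interval), observation
simulation there, and a hatched flag for eggs that reached 1.0 before
collection. Draws are seeded per `(seed, egg index)`, so cohorts are
reproducible bit-for-bit and independent of cohort size.

What the generator emulates is the calibration's *marginal* statistical
structure. It does not emulate inter-individual developmental asynchrony (the
calibration quantifies none; an optional Gaussian jitter on proportion,
default 0 and clearly non-calibration, exists for robustness studies),
landmark co-occurrence, observer error beyond the mis-scoring floor, or
fluctuating field temperatures' effect on category frequencies. Passing
recovery tests therefore show the estimator is consistent with its own
calibration — the claim that calibration transfers to casework rests on the
underlying staging study, not on these simulations.

### Recovery under the study conditions

The validation surface mirrors the calibration study's design: for each of
the 11 true intervals, cohorts of living eggs at 25 °C are simulated with
representative frequencies and fed back through the estimator. The packaged
tests (`tests/testthat/test-acceptance.R`) assert that the modal MAP interval
equals the true interval or an adjacent one and that the 95% credible set
covers the truth in at least 90% of eggs — the "resolution of 10–20% of
total egg development" the staging claims. Test cohorts use n = 200 eggs per
interval, a size at which the modal MAP is stable across seeds while the full
suite stays fast.

## Numerical choices and edge cases

* Root tolerance 0.01 h; deterministic bisection, no randomness anywhere in
  estimation.
* Posterior normalisation is asserted to 1e-9; likelihoods are computed in
  log space and exponentiated after subtracting the maximum.
* An observation with *no* assessed landmark yields a flat likelihood plus a
  warning (never an error), so the posterior equals the prior and the
  credible set spans all 11 intervals.
* Ages requested beyond the temperature profile's start are censored at the
  profile start and flagged, not extrapolated.
* A profile entirely at or below the 1 °C threshold accrues zero ADH and zero
  development.

## Known limitations

* The interval→stage correspondence and the staging table are specific to
  *C. vicina*; interval timings are known to differ even among closely
  related Calliphoridae, so the calibration must not be applied to other
  species.
* Only two calibrated temperatures exist. The linear-in-temperature ADH
  requirement between them is a modelling choice, and estimates outside
  [7.3, 25] °C are clamped extrapolations — both conditions are always
  surfaced as warnings in reports.
* The credible set quantifies observation uncertainty under the category
  model only, not biological asynchrony between eggs of one clutch.
* Landmark scoring is a human input; the package performs no image analysis.
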
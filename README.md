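# eggclock

Morphological age estimation for blow fly eggs, for forensic entomology.

*Calliphora vicina* is typically among the first insects to colonise a
cadaver, and the age of its oldest immatures bounds the minimum post-mortem
interval (PMI_min). When eggs are the only entomological evidence — usually in
cool weather, when hatching can take days — their age must be resolved
*within* the egg stage. `eggclock` does this from embryonic morphological
landmarks: 15 externally visualisable characters (cephalic furrow, stomodeal
invagination, posterior spiracles, ...) whose chronology across eleven 10%
intervals of total egg development is calibrated at 7.3 °C (120 h oviposition
to hatching, 756 ADH) and 25 °C (16 h, 384 ADH).

The package combines:

- **a degree-hour thermal model** — ADH(t₀,t₁) = ∫ max(0, T(t) − T_base) dt
  with base threshold 1 °C, exact under piecewise-constant temperature logs.
  Because the total ADH requirement is itself temperature dependent,
  development over fluctuating profiles uses rate summation,
  Δp = Δt·max(0, T − 1)/ADH_total(T), with ADH_total(T) linear in temperature
  between the two calibrated points. Inversion (proportion → hours of age) is
  by deterministic bisection to 0.01 h.
- **an ordinal staging likelihood** — each calibration cell is an ordinal
  visibility category (blank/+/++/+++ = seen in 0, <25%, 25–75%, >75% of
  individuals), read as a representative presence probability
  q ∈ {0.01, 0.125, 0.5, 0.875}; an egg's scored landmarks give
  log L(interval) = Σ log q (present) + Σ log(1 − q) (absent), combined with
  a prior into a posterior over the 11 intervals, a MAP interval (ties break
  earlier — conservative for PMI_min), and a contiguous 95% credible set
  converted to hour and ADH bounds.
- **preservation-aware masking** — hot-water-killed + 80% ethanol samples
  retain 11 of the 15 landmarks (the other four are force-masked); eggs
  placed directly into ethanol decompose and yield censored estimates
  (bounded to ≥ 90% of development when first-instar larval morphology is
  visible, fully censored otherwise).
- **a seeded synthetic cohort simulator** used to validate interval recovery
  end-to-end.

## Worked example

An egg reared at 7.3 °C shows posterior spiracles, spine bands and a
coil-shaped gut, but no air-filled tracheal system yet:

```r
library(eggclock)
tab <- load_staging_table()
obs <- observation_set(
  c(posterior_spiracles = "present", spine_bands = "present",
    coil_shaped_gut = "present", fully_developed_tracheal_system = "absent"),
  preservation = "living", nominal_temp_c = 7.3, table = tab)
estimate_age(obs, tab)
#> Egg age estimate
#>   MAP developmental interval: 90% (index 9)
#>   95% credible set: 90%, 100%
#>   development proportion: 90% to 100% of the egg stage
#>   chronological age: 108.00 to 120.00 h before collection
#>   accumulated degree hours: 680.4 to 756.0 ADH (base 1 C)
```

The cuticle-stage landmarks place the egg at 90% of development (posterior
probability 0.89, with the remaining 0.11 on 100%); the missing tracheal
filling argues against imminent hatching. At 7.3 °C the credible development
range [0.9, 1.0] converts to an age of 108–120 h, i.e. oviposition happened
4.5–5 days before collection — the PMI_min contribution of this specimen.

A shell front end with `table`, `stage`, `age` and `simulate` subcommands is
installed at `inst/cli/eggclock.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "eggclock.R", package = "eggclock"))')" table
#> 15 landmarks, 11 intervals, 2 temperatures, 11 HWK-visible
#> ...
```

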
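---
title: "Methods: standardizing and comparing historical bioclimate series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardizing and comparing historical bioclimate series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histbioclim)
```

## The problem

Early instrumental weather registers from the Arctic record air
temperature in °F and wind as an ordinal visual force estimate, usually
twice a day (08:00 and 14:00 local time). Contemporary station series
record temperature in °C and anemometer wind in m·s⁻¹, typically
referenced to 15:00 LT for the closest afternoon match. A bioclimatic
comparison between the two eras needs (a) a lossless, declared-schema path
from transcribed registers to canonical units, (b) exposure indices that
use only temperature and wind — the sole variables the historical record
offers — and (c) climatological machinery (normals, anomalies, SD
envelopes, category frequencies) that treats both eras identically.

## Standardization

Every observation is reduced to the triple (t in °C, v₁₀, v₁.₂ in m·s⁻¹):

* `fahrenheit_to_celsius()`: (t − 32)·5/9.
* `wind_force_to_speed10()`: exact table lookup of the representative
  10 m speed for each force code. Two scales ship with the package: the
  six-point 1767-era scale (1→0.45 … 6→30.5 m·s⁻¹) and the five-point
  1789-era scale (0→0.3 … 4→30.5 m·s⁻¹). The mapping is treated as the
  operative conversion; a Beaufort intermediate is not modelled because
  the end-to-end table is what the scales define. Codes outside a scale's
  domain are rejected (a 0 on the 1767 scale is an error, not calm: the
  scale's printed domain starts at 1; users needing a calm code can supply
  a custom scale via `wind_scale()`).
* `adjust_wind_height()`: the power-law profile V_z = V_w (h_z/h_w)^α
  with α = 0.2. The exponent is an argument, so sensitivity to the
  profile assumption can be tested, but 0.2 is the default used
  throughout. Stability-dependent profiles are out of scope — the
  historical record carries nothing to drive them.

Anemometer height for contemporary files defaults to 10 m (the WMO
standard) and is declared in the schema; it is a stated assumption, not an
inference.

## The indices

**Wind chill temperature.**
WCT = 13.12 + 0.6215 t − 11.37 v₁₀^0.16 + 0.3965 t v₁₀^0.16, wind in
m·s⁻¹ at 10 m. The 10 m m·s⁻¹ convention is the one under which the
package's worked cold-extreme evaluations come out at −33.07 °C
(t = −25.2 °C, 6.1 m·s⁻¹ at 1.2 m) and −34.88 °C (t = −25.9 °C,
7.4 m·s⁻¹) — km·h⁻¹ or unadjusted chest-height winds do not reproduce
both. At v₁₀ = 1 the power term is unity and WCT = 1.75 + 1.018 t exactly;
this closed form, plus strict monotonicity (increasing in t, decreasing in
v below t = 28 °C), is property-tested. Inputs outside the index's
conventional validity (t > 10 °C or v₁₀ < 1.34 m·s⁻¹) are *flagged*
(`wct_valid`) but still evaluated: year-round series are routinely
summarized with WCT, and refusing summer values would silently bias
annual statistics.

**Insulation predicted.**
Iclp = 0.082(91.4 − (1.8 t + 32))/(0.01724 M) − 1/(0.61 + (1.9 v)^0.5),
in clo (1 clo = 0.155 K·m⁻²·W⁻¹): the total insulation required for heat
balance minus the boundary air layer's contribution. The wind argument is
the chest-height (1.2 m) speed, the convention of bioclimatological
practice; M = 135 W·m⁻² represents walking at 4 km·h⁻¹ and 70 W·m⁻²
standing. The difference Iclp(70) − Iclp(135) depends only on temperature
(the air-layer term cancels), which is verified against the closed form.
Note that the long-standing BioKlima implementation of this index is known
to produce values differing from direct evaluation of the formula by a few
hundredths of a clo under some conventions; this package evaluates the
formula exactly as written and does not tune constants toward any other
implementation's output.

**Classifiers.** Category schemes are first-class objects
(`category_scheme()`): ordered, disjoint, exhaustive intervals with a
per-break closure flag, because the published band definitions are not
uniform at their edges ("< 0.5 clo" is exclusive, "3.0–4.0 clo"
inclusive). The frostbite default is five levels (lack > 0 °C; low to
−10; moderate to −25; high to −35; very high below), with
`frostbite_scheme(levels = 4)` merging *very high* into *high* for
compatibility with four-level figure legends (0 lack, 1 low, 2 moderate,
3 high). The boundary conventions — 0 °C is *low*, each colder threshold
belongs to the milder class — are a design choice; all thresholds are
arguments.

## Interdiurnal stimuli

`interdiurnal_changes()` takes |t(day) − t(day−1)| at one fixed hour;
pairs exist only for consecutive calendar days both observed at that hour
(gaps yield no record — no interpolation across register gaps). Changes
are classified after rounding to 0.1 °C half-away-from-zero, which makes
the printed bands (≤ 2.0 / 2.1–4.0 / 4.1–6.0 / ≥ 6.1 °C) exhaustive:
2.04 → neutral, 2.05 → perceptible. The magnitude, not the sign, is
classified. Frequencies are percentages of classified pairs per group;
the number of valid pairs (`n_group`) is always reported alongside, since
a gappy month's percentage has a smaller denominator than its day count.

## Climatology and comparison

* `monthly_stats()`: mean/min/max over available days. Months with
  missing days are flagged `partial` and kept; a separate `qualifies`
  flag (coverage ≥ 0.7 by default) governs what enters seasonal means and
  anomalies. Keeping flagged partial months mirrors data-rescue practice,
  where a 22-day July is reported with a footnote rather than discarded.
* `seasonal_stats()`: unweighted mean of monthly means (the
  mean-of-monthly-means convention of climate normals), emitted only when
  every constituent month qualifies. Wrapping seasons (Dec–Feb) are
  assigned to the January year.
* `contemporary_normals()`: per-calendar-month mean/SD/min/max, and per
  day-of-year mean/SD on a fixed 366-day calendar. Daily statistics pool
  observations in a centered circular window (default 15 days) across all
  years — this both smooths the envelope and gives Feb 29 a populated row
  from its neighbours. `window = 1` disables smoothing. At least two
  distinct years are required, otherwise SDs are undefined and the call
  errors.
* `anomalies()`: historical monthly mean minus contemporary normal,
  defined only where both sides exist.
* `envelope_exceedance()`: |x − mean(doy)| > k·SD(doy), strict, so a value
  exactly on the band edge does not exceed; `percent_days_below()` is
  likewise strict.
* `build_report()`: deterministic CSV/JSON serialization with a
  provenance block (configuration hash, seed); identical inputs give
  byte-identical files.

## The synthetic generator

No public accession exists for the archival registers, so the generator
is a first-class module emulating the statistical structure the analysis
assumes, not a fixture:

* **Temperature**: a piecewise-linear annual cycle through mid-month
  knots plus stationary AR(1) daily anomalies
  (a_t = φ a_{t−1} + σ ε_t). The knots are iteratively corrected so the
  calendar-month mean of the cycle equals the configured target exactly
  (mean-preserving interpolation); plain mid-month interpolation biases
  monthly means by up to ~0.4 °C near the cycle extremes, which would
  contaminate parameter-recovery tests with a structural error. AR(1) is
  the minimal model producing realistic interdiurnal-change
  distributions — the quantity the stimulus classifier consumes — since
  day-to-day temperature is serially correlated.
* **Wind**: monthly Weibull draws (shape 2 by default; scale set from the
  monthly target mean). Historical modes discretize each draw to the
  ordinal scale by nearest representative speed, ties to the lower code,
  with bin edges at the midpoints — so force→speed→force is the identity
  on every code.
* **Historical texture**: twice-daily records; 08:00 sits a configurable
  offset (default −2.5 °C) below the 14:00 value; temperatures are
  emitted in °F rounded to 0.5 °F (plausible manuscript precision);
  missingness is applied as contiguous date blocks of 5–15 days, the gap
  structure of archival registers (voyages, illness), not i.i.d. holes.
* **Defaults** emulate a coastal sub-Arctic station like Nuuk: monthly
  afternoon temperatures from −8.2 °C (February) to +8.9 °C (July),
  10 m winds averaging ≈ 6 m·s⁻¹, φ = 0.7 and σ = 3 °C (daily anomaly
  SD ≈ 4.2 °C). Under these conditions the pipeline yields cold
  perception (WCT < 0 °C) on ≈ 58–59 % of days and a predominance of
  neutral stimuli — the regime the classifiers were designed around.

What the generator does **not** emulate: temperature–wind dependence
beyond shared monthly seasonality, weather regimes and storm clustering,
instrument drift, or any particular historical sequence. Passing tests
therefore demonstrate that the pipeline's *machinery* is correct and that
its statistics recover known generator truth; they say nothing about any
specific archive's climate.

## Numerical choices and degenerate inputs

* Force codes must be integers in the scale's domain; `standardize()`
  errors on out-of-domain codes (run `validate_series()` first to locate
  them as data).
* WCT requires v₁₀ > 0 (the power term); Iclp requires v ≥ 0 and M > 0.
* Missing fields propagate: a record with missing wind yields missing
  WCT/Iclp and missing categories, never a dropped row.
* `stimulus_category()` is idempotent under re-rounding.
* Envelope and threshold comparisons are strict inequalities.
* Generator determinism: all draws sit inside one seeded block per
  simulation, so equal seeds give identical series and different seeds
  differ.

## Problem sizes

The test suite runs the full pipeline on a 3.5-year historical register
plus 10–30 synthetic contemporary years; parameter-recovery and
envelope-convergence checks use 30 years (~11,000 afternoon
observations), with Monte-Carlo tolerances of 2·SE (AR(1)-adjusted
effective sample size) for monthly means and 1.5 percentage points for
the ±2 SD exceedance rate against its Gaussian expectation
2(1 − Φ(2)) ≈ 4.55 %. Oracle agreement for both indices is checked to
1e−9 on 1,000 random inputs against independently coded
re-implementations.

## Known limitations

* One series per location: station relocations within a settlement are
  not homogenized.
* The 14:00 (historical) vs 15:00 (contemporary) afternoon mismatch is
  accepted as-is; in polar winters the diurnal cycle is weak, in summer
  the hour difference can matter.
* Only temperature–wind indices are implemented; radiation- and
  humidity-dependent indices (e.g. UTCI) need inputs the historical
  record lacks and are out of scope.
* The ordinal-scale conversion inherits the uncertainty of visual wind
  estimates; treating the representative speeds as exact understates wind
  variance in the historical era.
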
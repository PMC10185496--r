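---
title: "Moonlight, twilight and artificial light: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moonlight, twilight and artificial light: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moontrigger)
```

## The problem

Many reef-building corals release their gametes on a small number of nights
keyed to the lunar cycle.  A candidate synchronising cue is the first night
after full moon on which an *extended period of minimum light intensity*
appears between sunset and moonrise: on the full-moon night the moon rises
with the setting sun, and each following night it rises later, so a dark
gap opens after twilight ends and widens night by night.  Artificial light
at night (ALAN) from coastal development can mask the tail of twilight, so
that a *perceived* stable-light period appears earlier in the lunar cycle —
potentially advancing the spawning trigger on lit reefs.

`moontrigger` has two halves:

1. a **sea-surface light-field simulator** that composes broadband
   (400--700 nm) irradiance from clear-sky solar, twilight, lunar,
   artificial and background components at 5-minute resolution, detects
   qualifying minimum-light periods, and quantifies the ALAN-induced
   advance of the first post-full-moon trigger night;
2. a **statistical pipeline** for spawning observation tables: exposure
   classification against a critical-ALAN-depth raster, covariate
   construction, a spatially autocorrelated Poisson mixed model, AIC
   selection over all nested models, likelihood-ratio tests, and
   per-genus lit-versus-unlit contrasts.

A synthetic-data generator emulates the statistical structure the pipeline
assumes, so every stage can be exercised end to end without downloads.

## The light-field model

### Solar component

The top-of-atmosphere (TOA) spectrum is corrected for the eccentricity of
Earth's orbit,

$$E_0(\lambda) = H_0(\lambda)\,\Big(1 + \varepsilon \cos\tfrac{2\pi(D-3)}{365}\Big)^2,
\qquad \varepsilon = 0.0167,$$

with $D$ the day of year.  The reference table $H_0(\lambda)$ shipped with
the package is a **synthetic surrogate**: a 5778 K Planck spectrum scaled
to a total solar irradiance of 1361 W m⁻²; a measured table can be dropped
in through the `h0` argument of `toa_solar()` (CSV copies of all spectral
tables live under `inst/extdata/`, each labelled synthetic).  Surface
irradiance is partitioned into direct and diffuse components by a
clear-sky marine transmittance model (Rayleigh, Ångström aerosol, and a
parametric Chappuis-band ozone term; half of the Rayleigh-scattered and a
forward fraction of the aerosol-scattered light reach the surface).  The
total is the sum of the two components, decreases monotonically with the
solar zenith angle, and the diffuse fraction grows toward the horizon.
All atmosphere parameters (`atmosphere_params()`) describe a clean marine
atmosphere and are exposed in one configuration object rather than
hard-coded.

### Twilight

Measured rural twilight lookup tables are not redistributable here, so the
package implements a **parametric surrogate** with the two properties the
trigger analysis depends on: log₁₀ broadband irradiance declines linearly
with solar depression, anchored to the clear-sky value at the horizon and
reaching the dark-sky floor (0.25 µW m⁻²) at 18° depression, and the
spectral shape blue-shifts with depression.  Below 18° the same slope
continues, so the twilight term becomes negligible against the floor about
a quarter of an hour after astronomical dusk rather than vanishing
discontinuously.  A measured table can replace the surrogate through the
`lut` argument (`depression_deg`, `broadband_w_m2`), interpolated on the
log scale.  Twilight partitions follow the civil (0 to −6°), nautical (−6
to −12°) and astronomical (−12 to −18°) bands.

### Moonlight

TOA lunar irradiance is the TOA solar spectrum times a spectral albedo
(synthetic surrogate: 0.12 with a mild red slope), the solid-angle
dilution $\sin^2(0.26^\circ) \approx 2.06\times10^{-5}$ of the lunar disc,
and an analytic phase curve $10^{-0.4(0.026|g| + 4\times10^{-9}g^4)}$
normalised to 1 at zero phase angle, which reproduces the opposition
(full-moon) brightening and makes the quarter moon roughly a tenth as
bright.  At full moon the TOA lunar-to-solar broadband ratio is
$\sim 2.5\times10^{-6}$ — five to six orders of magnitude separation.  The
same clear-sky transmittance model (the atmosphere does not care about the
source) propagates the lunar beam at the lunar zenith angle, giving
~1 mW m⁻² at the surface for a full moon near zenith.

### The dark-sky floor and the photometric chain

Air glow, zodiacal light and starlight are treated as one constant
background: a 22 mag arcsec⁻² sky.  The chain
`mag_to_luminance(22)` → $1.712\times10^{-4}$ cd m⁻² →
`luminance_to_irradiance()` → 0.25 µW m⁻² (using the peak photopic
efficacy, 683 lm W⁻¹) defines the floor, spread flat over the grid.

### Artificial light

ALAN spectra are built either from per-band irradiances in blue
(400--500 nm), green (495--560 nm) and red (640--720 nm) bands — the
printed blue/green overlap at 495--500 nm is kept in the *measurement*
bands, while the synthesis shapes avoid it so that both band integrals can
match their configured values within 1% — or from a lamp-class shape (LED,
HPS, LPS) scaled to a total.  The red band is truncated at the 700 nm grid
edge.  Lights switch on and off at configurable night events; the default
is the civil (−6°) dusk/dawn crossings, since "dusk" unqualified most
commonly means civil dusk in lighting practice.

### Ephemeris

Solar and lunar positions come from truncated trigonometric series of
standard almanac theory (46 longitude/distance terms and 30 latitude terms
for the moon, plus the classical additive corrections), with a fixed
ΔT = 70 s and a parallax-in-altitude correction for the moon.  Verified
accuracy on published benchmarks: lunar longitude within ~0.005°, the 13
full moons of 2020 within ~2 minutes of the published calendar.  Rise/set
events use −0.833° for the sun and $0.7275\pi - 0.583^\circ$ (with $\pi$
the lunar horizontal parallax) for the moon, refined by root finding to
about a second.  All times are UTC; a *night* is the local solar
noon-to-noon window (UTC + longitude/15 h), and day offsets from full moon
are signed whole days against the nearest full-moon local night, with the
rare equidistant tie broken toward the earlier full moon.

## The trigger detector

`detect_minimum_periods()` searches each night's sunset-to-moonrise window
(sunset to sunrise when the moon does not rise; no window at all when the
moon is already up at sunset) for maximal runs in which the total
irradiance stays within `1 + tolerance_rel` times *that night's own
minimum*, and reports runs of at least `min_duration` minutes.  Defaults:
`tolerance_rel = 0.05`, `min_duration = 30` min.  Because the reference is
the night's own minimum, the same detector serves natural skies (where the
minimum is the dark-sky floor) and lit skies (where the minimum is the
ALAN plateau) — exactly the sense in which ALAN "masks" natural darkness.
The extended-period definition is not sharply fixed by the phenomenon, so
the acceptance run sweeps `min_duration` over {20, 30, 45, 60} minutes and
the advance in whole nights moves by at most one night across the sweep.

`first_trigger_night()` compares a natural timeline and a lit twin
(identical but for the ALAN component) over the full-moon night plus 14
nights and reports the first night of each with a qualifying period, and
their difference (`advance_days`).

### The default ALAN scenario

The sea-surface ALAN irradiance at a particular lit reef is site-specific
and not generally known, so the package ships one documented default
scenario: broadband ALAN at **1.05 × the twilight surrogate at 6°
depression** (the brightest nautical-twilight level, ≈7.5 mW m⁻² under the
default atmosphere), as an LED source switching on at civil dusk.  This
is the regime in which bright coastal lighting truncates the latter stages
of twilight.  Under this scenario the package computes advances of one to
two nights for the two demonstration reefs in March, April, May and
November 2020 and about two to three nights for the mid-latitude reef in
September/October 2020; the advance grows with the assumed ALAN level
(`alan_config()` makes the scenario fully configurable), so these figures
are bounds under the documented scenario rather than site-calibrated
estimates.

One caveat is worth knowing.  With dusk-switched lights *brighter than the
twilight level at switch-on*, the total irradiance dips briefly just
before the lights come on; that notch becomes the night's minimum and no
stable period is detected at all.  Trigger advance is therefore monotone
in the ALAN level only up to the switch-on twilight level; for brighter
sources, switching on at sunset (`on_event = "sunset"`) restores
monotonicity.  The default scenario sits just above the civil-dusk
twilight level by design, at the edge of this regime.

## The statistical pipeline

The response is the signed day offset of spawning from the nearest full
moon, shifted to non-negative integers by subtracting the pooled minimum
(`positive_transform()`; the offset is recorded and every reported mean is
back-transformed).  Exposure classification is a pure rule: *lit* where
the critical depth of biologically important ALAN at the site (0.05°
buffer mean of the raster) exceeds the observation depth, or the species'
minimum depth when no depth was recorded; observations with neither depth
are excluded and logged.  Filters retain in-situ, 21st-century
observations, then drop genera with fewer than six observations per
exposure level and ecoregions with fewer than six observations; because
the two count rules interact, they are re-applied until the table is
stable, and an audit log counts removals per rule and pass.

Climate covariates are per-site yearly series reduced to slopes by median
(L1) regression, solved exactly by enumerating candidate lines through
point pairs — an optimal L1 line always interpolates two points, and the
series are short (about 20 years), so enumeration is both exact and cheap.
Ties in the objective prefer the smaller |slope|.

The core model is a Poisson GLMM with a site-level random effect whose
covariance follows a Matérn correlation of the site coordinates, fitted by
Laplace-approximate maximum likelihood (glmmTMB's `mat()` structure);
variance, range and smoothness are estimated jointly.  Coordinates are
projected to kilometres by a local equirectangular projection before the
correlation is evaluated — over reef latitudes (|lat| ≤ 32°) this differs
from great-circle distance by a few percent, far below the uncertainty in
the range parameter.  The Pearson dispersion is reported as
χ²/(n − k).  When the estimated spatial variance is (near) zero the
marginal likelihood coincides with a plain Poisson GLM's, which is the
package's cross-check oracle.

Model selection enumerates **all nested versions** of the global fixed
structure — ALAN crossed with genus, ΔSST, ΔKd490 and distance from the
equator, plus an ecoregion main effect.  With marginality enforced
(an interaction only ever appears with both its main effects; the
default, switchable) the global structure yields 194 models; each is
fitted with the random term retained, ranked by AIC = −2ℓ + 2k, and
assigned Akaike weights.  Terms of the selected model are then probed by
reverse-stepwise likelihood-ratio tests (χ² = 2Δℓ, df = difference in
fixed coefficients).

Per-genus contrasts fit an independent Poisson model per genus, switching
to the negative binomial when the Pearson dispersion exceeds 1.5 (a
documented operationalisation of "overdispersed"); the lit-minus-unlit
difference is estimated on the link scale and mapped to days at the unlit
mean, with 95% and 90% Wald intervals and unadjusted p-values (many
parallel tests; adjustment would inflate type-II error for this
directional question).

## The synthetic generator

`gen_dataset()` draws sites clustered into ecoregions inside reef
latitudes, designates about half as lit, and builds a one-degree
critical-depth raster whose cells at lit sites carry a critical depth
deeper than any generated observation or trait depth — so the
classification rule reproduces the designed labels exactly, by
construction.  Counts are drawn with log-mean

$$\log\mu = \log(\text{baseline}_g + \delta_g \,\text{lit}_s) +
\gamma\,(\text{DfE}_s - 16) + \text{eco}_e + b_s,$$

so the marginal lit-minus-unlit difference of genus *g* is exactly its
configured shift $\delta_g$ in days.  Defaults mirror a 12-genus community
with one-, two- and three-day shifts (three days for *Porites*, zero for
one unaffected genus), baselines of 5–8 days, ecoregion intercepts of
SD 0.1, a latitude slope of −0.01 per degree (higher-latitude corals
spawning slightly closer to full moon; the direction is configurable, as
the observational evidence is equivocal), and a Matérn site field
(ν = 1.5, range 400 km, σ² = 0.04).  Counts are Poisson by default; a
binomial-thinning option produces mild underdispersion at a configurable
target (thinned counts `Binom(round(μ/p), p)` have variance ≈ (1−p)μ).
The default table shape — 52 sites × 41 observations, 12 genera, 19
ecoregions — matches the scale of real compiled spawning datasets.

What the generator does *not* emulate: real reef biogeography, the spatial
texture of measured light-pollution atlases, depth-dependent attenuation,
observation effort gradients, or temporal autocorrelation within sites.
Passing recovery tests therefore demonstrates that the pipeline estimates
what it claims under its own assumptions, not that those assumptions hold
for any particular survey.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 15-night timelines at
5-minute resolution per site-month for trigger advances; 50 generator
replicates of 40 sites × 50 observations for confidence-interval
coverage, with per-genus lit-shift intervals taken from the spatial
mixed model (`genus_shift_ci()` on an ALAN×genus fit, smoothness held at
1.5, full delta method on the response scale) — exposure is a
*site-level* treatment, so only intervals that carry the site-level
random effect are honest, and independent per-genus models undercover by
construction; 100
null-simulated likelihood-ratio tests for calibration
(Kolmogorov–Smirnov); 1000 random step timelines against an exhaustive
O(n³) window-scan oracle for the detector (exact agreement).  Event times
are refined by bisection/`uniroot` to ~1 s on a 6-minute scan grid; the
full-moon finder brackets the 180° elongation crossing on a 6-hour grid.
Degenerate inputs are explicit: polar day/night yield NA events, nights
without a sunset-to-moonrise gap report no periods, empty filter results
raise an error carrying the audit log, and non-converged mixed models are
flagged, never silent.

## Known limitations

* The shipped TOA, albedo and twilight tables are labelled synthetic
  surrogates; absolute spectral values are approximate even though every
  property the trigger analysis uses (scales, monotonicity, anchors) is
  preserved.  Substituting measured tables is a one-argument change.
* Clear-sky only: clouds, aerosol events and polarisation are out of
  scope, as is in-water propagation.
* The advance of the trigger night under the default ALAN scenario is a
  bound, not a site-calibrated estimate; the true advance at a heavily lit
  reef grows with the local ALAN level.
* The Matérn GLMM evaluates correlations on projected coordinates;
  antipodal site pairs are effectively uncorrelated either way, but
  range estimates should be read as regional quantities.
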
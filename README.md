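# moontrigger

Coral broadcast spawning is keyed to the lunar cycle: a leading hypothesis
is that the cue is the first night after full moon with an **extended
period of minimum light intensity between sunset and moonrise** — the dark
gap that opens once the moon starts rising well after twilight ends.
Artificial light at night (ALAN) from coastal development can mask the
tail of twilight, creating a *perceived* stable-light period earlier in
the lunar cycle and potentially advancing the spawning trigger on lit
reefs.

`moontrigger` is an R package for marine photoecologists and
chronobiologists that implements both halves of this question:

* **A nocturnal sea-surface light-field simulator.**  Broadband
  (400–700 nm) irradiance at 5-minute resolution composed from clear-sky
  solar (TOA spectrum `E₀(λ) = H₀(λ)(1 + ε cos{2π(D−3)/365})²` with a
  direct/diffuse marine transmittance partition `E_d = E_dd + E_ds`),
  a twilight model spanning the civil/nautical/astronomical bands, a
  lunar model (spectral albedo × solid-angle dilution `sin²(0.26°)` × an
  opposition-brightened phase curve), configurable ALAN (RGB bands or
  LED/HPS/LPS lamp classes, dusk-to-dawn schedule), and a constant
  dark-sky floor (22 mag arcsec⁻² ≡ 1.712 × 10⁻⁴ cd m⁻² ≡ 0.25 µW m⁻²).
  Built-in ephemeris gives sun/moon positions, twilight events,
  moonrise/set and full-moon instants.  A detector finds nights with a
  qualifying minimum-light period and quantifies by how many nights ALAN
  advances the first post-full-moon trigger.

* **A spawning-timing statistical pipeline.**  Classification of
  observations as Lit/Unlit against a critical-ALAN-depth raster
  (0.05° buffer means, species minimum-depth fallback), exact median
  (L1) regression for climate trends, the documented observation filters
  with an audit log, a spatially autocorrelated Poisson mixed model
  `y ~ ALAN*Genus + ALAN*ΔSST + ALAN*ΔKd490 + ALAN*DfE + Ecoregion +
  Matérn(site coordinates)`, AIC ranking of all (marginality-respecting)
  nested models, likelihood-ratio tests, and per-genus lit-versus-unlit
  contrasts with 95%/90% intervals.

* **A synthetic-data generator** that emulates the structure the pipeline
  assumes (genus baselines and lit shifts of 0 to −3 days, ecoregion and
  latitude effects, a Matérn site field, optional underdispersion) with a
  toy raster and trait table built so the classification stage reproduces
  the designed labels exactly.

## A worked example

Sky geometry and the trigger advance for a low-latitude reef (Pulau Bara
Lompo, −5.06°S) at the March 2020 full moon, under the default ALAN
scenario (broadband ALAN just above the nautical-twilight level,
switching on at civil dusk):

```r
library(moontrigger)

sky_geometry(29.5, 34.9, as.POSIXct("2020-09-02 17:00", tz = "UTC"))
#> Sky geometry at 2020-09-02 17:00:00 UTC (29.500, 34.900)
#>   sun  altitude  -13.35 deg (zenith  103.35)
#>   moon altitude    5.25 deg, phase angle   7.35 deg, lit 0.996

trigger_advance(-5.06, 119.4, as.Date("2020-03-10"))
#> Full moon night 2020-03-10: natural trigger +2 d, lit +1 d, advance 1 d
```

Under a natural sky the first qualifying dark period falls two nights
after full moon; with the lit sky it appears one night earlier.

The statistical pipeline, end to end on synthetic data with known truth
(*Porites* generated with a −3-day lit shift):

```r
cfg <- synth_config(n_sites = 40, n_obs_per_site = 50, seed = 42)
ds  <- gen_dataset(cfg)
obs <- build_site_covariates(ds$observations, ds$raster, ds$traits)
pt  <- positive_transform(obs$DoSRtNF)
obs$y <- pt$values
flt <- apply_filters(obs)
ct  <- genus_contrasts(flt, "y", pt)
ct[ct$genus %in% c("Montipora", "Pectinia", "Porites"),
   c("genus", "n_unlit", "n_lit", "mean_unlit", "mean_lit",
     "shift_days", "ci95_lo", "ci95_hi", "p")]
#>      genus n_unlit n_lit mean_unlit mean_lit shift_days ci95_lo ci95_hi        p
#>  Montipora      76    86     0.0526   -0.360     -0.413  -1.151   0.418 3.16e-01
#>   Pectinia      70   103    -0.7857   -0.544      0.242  -0.644   1.269 6.12e-01
#>    Porites      81    89     1.5679   -1.438     -3.006  -3.612  -2.326 2.06e-13
```

`mean_unlit`/`mean_lit` are modeled mean days of spawning relative to the
full moon (back-transformed); `shift_days` is the lit-minus-unlit
difference, here recovering the designed three-day *Porites* shift toward
the full moon.  The spatial mixed model is fitted with
`fit_glmm(flt, global_model_terms(), response = "y")`, ranked against all
nested alternatives with `select_model()`, and probed with `lrt()` /
`term_tests()`.

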
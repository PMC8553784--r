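# isotoe

Nitrogen-isotope fingerprints of intensifying nitrogen limitation in the
low-latitude ocean: a 0D water-parcel isotope model, a Time-of-Emergence
(ToE) detector for gridded tracer series, and an offline biogeochemical
δ¹⁵N flux diagnostic, with a synthetic-field generator for validation.

## The problem

Nitrogen limits phytoplankton growth across the low-latitude ocean, so
changes in nitrogen supply propagate into net primary production (NPP)
and, through isotope fractionation, into the nitrogen-isotope composition
(δ¹⁵N) of nitrate and sinking organic matter. Because phytoplankton under
nitrogen stress lose their preference for the light isotope, a decline in
upwelled nitrogen leaves a quantitative, low-pass-filtered signature in
twilight-zone δ¹⁵N — often detectable decades before trends in nitrate
concentration or NPP themselves emerge from natural variability. This
package implements the three computations needed to study that chain with
full control over the inputs:

- **`parcel_params()` / `parcel_run()` / `upwelling_sweep()`** — a 0D
  model of a water parcel transiting from an upwelling zone to a gyre:
  pools DIN, PON and exported N plus enrichment-weighted heavy twins;
  Eppley growth `μ_max = 0.6 e^{T·T_growth}`, Michaelis–Menten nitrogen
  limitation, constant light/iron limitation, linear respiration and
  quadratic mortality split into temperature-dependent recycling versus
  export, and open-system uptake fractionation `ε_phy·N_lim` that shuts
  off as nitrogen becomes limiting.
- **`toe_map()` / `toe_year()` / `emerged_fraction()`** — per-cell ToE:
  detrend/normalize against the control's OLS line, smooth with an
  11-year centered boxcar, and date emergence at the first year the
  anomaly exceeds 2 control SDs *and stays outside the envelope through
  the end of the run* (temporary excursions are rejected).
- **`biogeochem_delta_tendency()`** — the per-cell signature of the net
  biogeochemical nitrate flux,
  `((¹⁵nitr − ¹⁵new − ¹⁵den)/(¹⁴nitr − ¹⁴new − ¹⁴den) − 1)·1000`,
  isolating local biogeochemical effects on nitrate δ¹⁵N from
  circulation.
- **`synth_spec()` / `gen_control()` / `gen_scenario()` /
  `gen_flux_fields()`** — AR(1) controls, ramped scenarios with known
  onset years, and flux fields with prescribed signatures, for
  parameter-recovery validation.

See the methods vignette (`vignettes/nitrogen-isotope-emergence.Rmd`) for
the model equations, numerical choices and calibration.

## Worked example

```r
library(isotoe)

# the per-10% rule of thumb: cut upwelled nitrogen, watch final POM d15N
sw <- upwelling_sweep(parcel_params())
sw[, c("reduction_pct", "integrated_npp", "delta_pom_final")]
#>   reduction_pct integrated_npp delta_pom_final
#> 1             0          8.566          10.111
#> 2            10          7.710           9.922
#> 3            20          6.854           9.730
#> 4            30          5.997           9.536
#> 5            40          5.141           9.340
#> 6            50          4.284           9.147
slope_per_10pct(sw)
#> [1] 0.193
```

Each 10 % cut in upwelled nitrogen costs ~10 % of integrated NPP
(`integrated_npp`, mmol N m⁻³ over the 100-day transit) and lowers the
final δ¹⁵N of particulate organic matter by ≈ 0.19 ‰ — the rule of thumb
that converts an observed isotopic decline into a nitrogen-supply change.

```r
# detect emergence on a synthetic scenario with ramps starting in 2000
spec <- synth_spec(nlat = 16, nlon = 32, years = 1801:2100, mean = 5,
                   phi = 0.5, innovation_sd = 0.1, onset_year = 2000,
                   ramp_rate = 0.01, seed = 1)
tm <- toe_map(gen_scenario(spec), gen_control(spec))
median(tm$toe, na.rm = TRUE)
#> [1] 2024
round(emerged_fraction(tm, c(2010, 2020, 2030)), 1)
#> [1]  1.1 26.6 82.7
```

A trend of 0.01 units yr⁻¹ against noise of SD ≈ 0.115 needs about two
decades of persistence to clear the 2-SD envelope: almost nothing is
dated before 2010, a quarter of the (cos-latitude-weighted) area has
emerged by 2020 and most of it by 2030.

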
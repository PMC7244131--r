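---
title: "cropsuit: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cropsuit: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsuit)
```

## The model

`cropsuit` scores habitat for a crop by combining per-criterion
trapezoidal fuzzy memberships under the law of the minimum. Each
criterion carries four thresholds, `ABSmin <= OPTmin <= OPTmax <= ABSmax`:
the score is 0 outside the absolute range, 100 inside the optimal range,
and linear between. The overall score of a location is the minimum of its
per-criterion scores — one failing criterion zeroes the site, matching the
agronomic intuition that yield tracks the most limiting factor.

The model's assumptions, stated plainly:

- criteria act independently; there are no interaction terms
  (e.g. heat x drought);
- annual means suffice — seasonality, frost events, and extremes are
  invisible to the model;
- the suitability score (0-100) is comparable to measured relative
  productivity on the same scale;
- the response within each ramp is linear, per the source methodology;
  no sigmoid or Gaussian shapes are offered.

### Boundary conventions

The piecewise definition uses half-open branches, which leaves two edge
cases to pin down:

- `P == ABSmax` scores **0**. Both adjacent branches (the descending ramp
  limit and the "above absolute" branch) evaluate to 0 there, so 0 is the
  continuous choice.
- Degenerate ramps (`ABSmin == OPTmin` or `OPTmax == ABSmax`) score
  **100 at the shared bound**: the optimal branch takes precedence. This
  is forced by the EcoCrop drainage set (4, 4, 6, 6), which must score
  classes 4-6 as fully suitable, and it avoids 0/0 in the ramp formulas.
- Drainage class (ordinal 1-7) is scored as a continuous value on the
  same trapezoid — class 3 under the refined profile (2, 4, 6, 7) scores
  50. No discrete rule was published; users with textual drainage classes
  must supply their own crosswalk to 1-7.
- Scores stay as reals in [0, 100]; rounding happens only at binning and
  reporting.
- Nodata (`NA`) in any used criterion propagates to nodata: a pixel with
  unknown soil cannot be scored.

## Parameters that matter

The two packaged profiles (JSON under `inst/extdata/profiles/`):

| criterion | units | ecocrop (abs/opt) | final (abs/opt) |
|---|---|---|---|
| temperature | degC | 16-40 / 21-33 | 17-40 / 21-33 |
| rainfall | mm/yr | 1000-3500 / 1500-3000 | 750-8000 / 1500-4000 |
| solar_radiation | W/m2 | 20-295 / 50-197 | 20-295 / 50-197 |
| soil_ph | pH | 4.3-8.7 / 5.5-6.5 | 4-8.7 / 5-6.5 |
| drainage_class | 1-7 | 4-6 / 4-6 | 2-7 / 4-6 |

The refined profile widens rainfall and drainage considerably and pH
slightly; temperature's absolute minimum moves 16 to 17, so the refined
profile is *stricter* there — the profiles are not pointwise ordered, and
the test suite deliberately does not assert dominance.

## Validation statistics

Modeled suitability `S` is compared to measured productivity `M` with:

- `RMSE = sqrt(mean((M - S)^2))`
- `ME = 1 - sum((M - S)^2) / sum((M - Mbar)^2)` (Nash-Sutcliffe; 1 =
  perfect, 0 = the observed mean predicts as well)
- `RSR = RMSE / sd(M)` (< 0.7 is the conventional satisfactory bar)
- `IA = 1 - sum((S - M)^2) / sum((|S - Mbar| + |M - Mbar|)^2)` (Willmott,
  in [0, 1])
- OLS of `M` on `S` (r2, slope, intercept, slope p-value).

**Denominator convention.** `sd` uses the population form (denominator
`n`). The ME and RSR definitions sum the same `n` terms in numerator and
denominator, so this choice makes `RSR^2 + ME = 1` an exact identity —
the package tests assert it to machine precision. The published RSR
equation was typographically corrupted in the source; the standard
RMSE/sd form implemented here is numerically consistent with the
published accuracy table.

**Criterion masking.** Irrigated sites are scored without rainfall,
amended sites without soil pH, both-flagged sites without either; the
"all sites" accuracy row pools residuals with each site scored under its
own mask, and the "natural" row uses only unflagged sites with all
criteria. Masking can only raise a score (dropping a term from a
minimum), which the suite checks as a property.

## Rasters, areas, and binning

Layers are plain matrices with a north-up affine transform, either
projected (metres) or geographic (degrees). Stacks are **rejected, not
resampled**, when grids disagree: harmonization is upstream, and silent
interpolation would corrupt the per-pixel join. Cells are half-open with
edge-registered coordinates; row 0 is the northernmost.

Cell areas: projected grids use `|dx * dy|`; geographic grids use the
spherical band formula `R^2 |dlon| |sin(lat_top) - sin(lat_bot)|` with
`R = 6371.0072` km, which is exact on the sphere — a coarse global grid's
cells sum to `4 pi R^2` to machine precision (asserted), where simple
cos-latitude scaling would not.

Area tables bin each pixel by its score rounded to the nearest integer
(half away from zero), into `{0}`, `[1,10]`, ..., `[91,100]` — the only
partition of [0, 100] consistent with bin labels `<1`, `1-10`, `11-20`.
Two conventions derived from the published table's own arithmetic:

- the `<1 to 30` summary group *includes* the `<1` bin;
- the reported **total excludes the `<1` bin** (the printed totals equal
  the bin sums minus the `<1` bin within print rounding) — sub-0.5 scores
  are counted as no cultivable area.

Percent changes (total, moderate 31-70, high 71-100) are reported rounded
to the nearest whole percent, with the unrounded value alongside.

## Ensembles and change maps

Future climate enters as member stacks supplying temperature and rainfall
only; solar radiation and the soil layers are held at baseline. Each
member is scored separately and the **suitabilities are averaged** —
averaging climates first would smooth away exactly the marginal-member
artifact the method is known for: a pixel suitable under one member of
seventeen gets a mean score in (0, 100/17], which the tests reproduce.
A pixel is valid only where every member and the baseline are valid.

Change maps report `future - baseline` with "unchanged" meaning
`|delta| < 0.5` (indistinguishable at integer reporting precision) and
"minimally changed" meaning `0.5 <= |delta| <= 10`. Fractions are
computed over pixels valid in both surfaces; with a shared synthetic
grid the baseline-extent and union-extent denominators coincide, so only
that one denominator is reported.

## The synthetic world

`synth_config()` defaults state the world the pipeline is exercised in,
chosen once:

- 200 x 200 projected grid at 50 m cells — the source system's mapping
  unit;
- temperature 10-24 degC along rows and rainfall 200-10,000 mm/yr along
  columns: the steep, orthogonal gradients of the Hawai'i model system;
- solar radiation decreasing linearly with rainfall (wetter = cloudier)
  in 60-190 W/m2 plus sd-3 noise — inside the optimal band most of the
  time, as in the calibration region where solar was never the binding
  criterion;
- soil pH (mean 6, sd 0.8) and drainage (mean 4.5, sd 1.2, rounded to
  1-7) as smoothed-noise patch fields, emulating substrate mosaics;
- 57 producer sites (the published validation count), irrigation
  probability 0.46 and amendment probability 0.26 (the published group
  shares), measured productivity = true masked suitability + N(0, 5)
  clipped to [0, 100];
- 17 ensemble members, temperature offset N(+2, 0.8) degC and rainfall
  multiplier N(1.05, 0.08) — a mid-century intermediate-scenario spread.

Clipping (rather than truncated-normal resampling) slightly inflates the
density at 0 and 100; it is simpler and documented. Every generator
derives a labelled sub-seed from the master seed, so adding one generator
never perturbs another's stream, and all outputs are bit-reproducible
under a fixed seed.

What the generator does **not** emulate: real spatial autocorrelation of
climate, coastlines/land masks, correlated soil-climate structure, GCM
spatial patterns (members differ only by scalar offset/multiplier), or
measurement-protocol error in producer data. A green synthetic test
therefore establishes that the pipeline's mathematics and plumbing are
correct under known truth — not that the packaged profiles are accurate
for any real landscape, which requires user-supplied layers and site
tables.

## File formats

Rasters travel as ESRI ASCII grids (`.asc`) with a JSON sidecar holding
the CRS kind (projected/geographic), criterion name, units, and the y
cell size for non-square cells. This is a deliberate substitution for
GeoTIFF: it is plain text, lossless for values/nodata/transform at
`%.17g`, round-trip tested, and needs no GDAL stack. A missing sidecar is
treated as a missing CRS and rejected. Profiles and configs are flat
JSON; sites and reports are CSV.

## Known limitations

- No reprojection, resampling, or mosaicking; inputs must be
  pre-harmonized.
- Global-scale area figures depend entirely on the nodata mask of the
  input layers; the package inherits whatever land/ocean convention the
  user's layers carry.
- Ensemble members are scalar perturbations in the synthetic world; real
  GCM anomaly fields must be supplied by the user as member stacks.
- The trapezoid is the only membership shape, by design.
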
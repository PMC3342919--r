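---
title: "Methods: watershed discharge exposures and county mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: watershed discharge exposures and county mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toxsheds)
```

## The model

The package implements an ecological exposure-outcome chain with four
stages.

**1. Record cleaning.** Permitted discharge records (facility, chemical,
coordinates, kg/yr) pass five ordered filters: restriction to the 38
chemicals of the packaged weight table; removal of zero-release records;
removal of records outside the study region; removal of records with zero
or non-finite coordinates; and removal of every record of any facility with
two or more remaining records whose release values are all identical (a
copy-paste reporting error). A record violating several rules is logged
once, under the first rule that catches it; that makes the rejection log
deterministic and the filter idempotent, at the cost of not attributing
overlapping violations. "Anomalous" coordinates are defined operationally as
zero or non-finite: a coordinate outside any plausible geographic range is
already caught by the region filter, so a separate bound check would be
redundant.

**2. Toxicity weighting and accumulation.** Within each watershed, releases
are summed per chemical, optionally multiplied by the chemical's ingestion
toxicity weight (a dimensionless multiplier on kg/yr), and summed within
carcinogen and non-carcinogen classes. Scores then accumulate downstream:

$$\pi_s = \sum_{w \ge s} \frac{\rho_w}{\mathrm{area}_{w \to s}}$$

where $\rho_w$ is the class sum in watershed $w$, $w \ge s$ indexes all
watersheds draining into $s$ (including $s$), and
$\mathrm{area}_{w \to s}$ is the acreage of every watershed on the path
from $w$ to $s$, both inclusive; for $w = s$ this is simply the watershed's
own area. The statistic assumes a forest topology — each watershed drains
into at most one other — and braided networks are rejected at load rather
than silently split, because the between-path in the denominator would
otherwise be ambiguous. Accumulation is linear in the release vector, so
accumulating the four class-by-weighting release vectors is exactly
equivalent to accumulating per chemical and summing afterwards; the class
version is used for efficiency. Whether weighting happens before or after
accumulation is likewise irrelevant by the same linearity.

**3. Areal interpolation.** Watershed scores become county exposures by
population weighting over watershed-by-county intersections:

$$e_c = \frac{\sum_{s \cap c} \mathrm{score}_s \cdot pop_{s,c}}
             {\sum_{s \cap c} pop_{s,c}}$$

so a county whose residents all live in a watershed with no releases scores
low even if another, unpopulated, corner of the county receives heavy
discharges. The onsite variant substitutes $\rho_s$ for $\pi_s$. $e_c$ is a
convex combination of the contributing watershed scores and is invariant to
uniform population rescaling; both properties are enforced by tests.
Grid cells are assigned to a watershed and county by cell-center
containment — the standard convention for ~1 km gridded population data —
rather than area-proportional splitting; ties on boundaries resolve to the
smaller identifier for determinism. Counties whose intersections hold zero
population have no defined exposure and are flagged and excluded from
regression.

**4. Analysis.** All analysis variables are $\ln(1 + e_c)$. The shifted log
is a deliberate choice: watersheds and counties with zero discharge are
common, the shift keeps them finite and at exactly zero, and it preserves
ordering. The log is applied once, at the county level, after all linear
aggregation (sum-then-log); the alternative reading (log per watershed,
then sum) is numerically different and not used. Five OLS sets pair
carcinogen exposures with cancer mortality and non-carcinogen exposures
with kidney and total non-cancer mortality: (1) onsite unweighted,
(2) onsite toxicity-weighted, (3) upstream area-weighted toxicity-weighted,
(4) set 3 with the pairing swapped as a cross-validation, and (5) set 3
within each metro class separately. Covariates are the ten county
demographic/behavioral measures plus two metro-class indicators
(non-adjacent non-metro as reference); the indicators are included in every
pooled model and necessarily dropped inside set-5 strata, where they are
constant. Standard errors are classical, and p-values are unadjusted for
multiplicity, matching the descriptive character of the staged design.
Counties with undefined exposure or a suppressed outcome are dropped
listwise per model.

Residual spatial autocorrelation is measured by Moran's I under
row-standardized inverse-distance weights ($1/d$, no cutoff — a common
default; power and cutoff are configurable through the weights object), with
inference both by permutation (999 draws) and by the normal approximation.
Geographically weighted regression refits the model at every county over
its $k = 30$ nearest neighbors. The kernel is adaptive bisquare
$(1 - (d/b)^2)^2$ with bandwidth $b$ equal to the $k$-th neighbor distance —
the standard adaptive choice — with a uniform kernel available; the uniform
kernel with $k = n$ reduces GWR exactly to global OLS, which serves as a
strong correctness oracle. Local significance uses $|t| \ge 1.96$ with no
local multiplicity correction. k-nearest-neighbor graphs are directed and
no operation assumes symmetric weights. The model comparison layer fits the
seven release variants A–G (class × weighting × accumulation) against
cancer mortality plus a covariate-only baseline with identical weights, and
reports per county the best variant, its attributes, the maximum local
$R^2$, and the improvement over baseline — which is provably non-negative
when the variant nests the baseline under the same weights. The eighth
combination (area-weighted, non-carcinogen, unweighted) is attempted and
reported with its failure reason if local collinearity defeats it.

## The synthetic generator

The generator exists so the full chain can be tested with known truth; its
defaults are fixed study conditions, not tuning knobs.

*Geometry.* The study region is a planar rectangle in km (150 × 150 by
default) — the analysis only needs relative distances, and planar geometry
keeps every spatial operation exactly testable. Watersheds (60) and
counties (150) are Voronoi regions of seed points placed at distinct cells
of the 1 km population lattice, which guarantees strictly positive areas
and lets containment, intersection and area all reduce to deterministic
nearest-seed assignment. County seeds are drawn independently of watershed
seeds, so county boundaries cross watershed boundaries as they do in
reality. Areas are lattice-cell counts converted at 247.105 acres/km².

*Drainage.* Links form a random recursive forest with spatial locality:
each watershed drains into a nearby earlier one (probability proportional
to inverse squared seed distance, child counts capped at twice the
branching factor, a 5% chance of starting a new outlet). This guarantees
the single-downstream, acyclic structure the accumulation formula assumes.

*Population.* Cell populations are Poisson draws from a log-normal
intensity built from a few Gaussian "city" bumps, giving the clustered
surface that makes population weighting non-trivial.

*Discharges.* 500 facilities report log-normal kg/yr releases
(meanlog 4, sdlog 2 — a median of ~55 kg/yr with a heavy tail; the real
release distribution is not published, so log-normal is a modeling choice)
for one-plus-Poisson(1) chemicals each. Invalid records are injected on
disjoint facility sets at configured fractions and each carries exactly one
hidden truth label, so the filter audit can demand exact agreement.

*Mortality.* Covariates come from a multivariate normal with a packaged
single-factor ("deprivation") correlation matrix — marginals match typical
county data, and the one-factor structure keeps the matrix positive
definite by construction; percentages are clamped to [0, 100] after
drawing. Age structure uses four strata with packaged standard weights, the
smallest structure that makes direct standardization non-trivial. Stratum
rates are the target age-adjusted rate times fixed multipliers whose
standard-weighted sum is exactly 1, and deaths are stored as expected
(possibly fractional) counts — so standardization returns the target rate
exactly and, with `noise_sd = 0`, OLS recovers every coefficient to machine
precision. Baseline rates (197.6, 17.6, 658.3 per 100,000 for cancer,
kidney and non-cancer) and residual SDs scaled 1 : 0.25 : 3.8 mirror the
relative dispersions of US county mortality. The default exposure effect is
2 deaths per 100,000 per unit log-exposure. Kidney rates are suppressed for
the 22% smallest-population counties by default, emulating small-cell
suppression in public mortality files; a death-count threshold rule
(default 10) is also provided.

What the generator does *not* emulate: real geography or hydrography
(meanders, braiding, closed basins), geodesic coordinates, measurement
error in discharge quantities, within-county population age structure
differences, spatially correlated covariates, or count-valued (Poisson)
death processes. Passing tests therefore demonstrate the correctness of
the pipeline's arithmetic and the statistical calibration of its estimators
under the stated linear-Gaussian conditions — not that the substantive
associations would replicate on real data.

## Verification designs and problem sizes

The suite's heavier experiments use sizes chosen to balance statistical
resolution against a fast default test run:

- *Estimator calibration:* one fixed 500-county design (250 × 250 km, 120
  watersheds, 1500 facilities); covariates and mortality are redrawn for
  200 replicates with the exposure surface held fixed — the standard
  repeated-sampling experiment. Checks: release-coefficient bias below 5%
  of truth, 95% CI coverage in [0.92, 0.98], and type-I error at
  $\alpha = .05$ in [0.03, 0.07] under a zero effect.
- *GWR limit:* 300 counties, uniform kernel, $k = n$, agreement with global
  OLS to 1e-8.
- *Spatially varying recovery:* a smooth west-east effect surface
  $\beta(x, y) = 2 + 8x/250$ on the 500-county design with residual SD 2.
  The noise is set small relative to the surface's range deliberately:
  county exposures are spatially smooth, so little release variance exists
  within a 30-neighbor window, and the experiment is designed (by the usual
  power reasoning) to isolate the estimator's ability to *track* the
  surface; calibration under realistic noise is established separately by
  the experiment above. Checked: correlation between true and estimated
  local effects above 0.7, local $R^2$ within [0, 1], non-negative
  improvement over the nested baseline.
- *Accumulation:* 50 random forests of up to 30 watersheds against an
  independent double-loop oracle at 1e-10.
- *Moran's I:* permutation null mean within Monte-Carlo error of
  $-1/(n-1)$ at $n = 100$; a two-block fixture must yield $I > 0$,
  $p < .01$.

## Known limitations

- Polygon geometry is implicit (Voronoi seeds); arbitrary external
  shapefiles are out of scope, though any network supplied as a table with
  areas, links and seed coordinates is accepted.
- The accumulation statistic ignores flow volume, velocity and chemical
  decay; area is the only dilution proxy.
- Exposure misclassification from drinking-water infrastructure (intake
  points, service areas) is not modeled.
- The regression layer is deliberately plain OLS: no spatial-error or
  hierarchical models, no bandwidth optimization for GWR (the neighbor
  count is a fixed parameter), and robust standard errors only as a
  configuration choice for future work.
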
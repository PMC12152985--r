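---
title: "Methods: spatio-temporal geographic access from routine HMIS data"
author: "hmisaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal geographic access from routine HMIS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmisaccess)
```

# The analytical problem

Routine health management information systems (HMIS, typically DHIS2
deployments) accumulate yearly service counts per health facility: outpatient
attendance, malaria treatments, antenatal registrants, facility births,
caesarean births, first-dose pentavalent vaccinations. Combined with facility
coordinates, administrative boundaries and gridded geospatial layers, these
archives support a longitudinal view of *geographic* access: how far, in
travel time, each person lives from the nearest facility actually offering a
given service in a given year, and how that changed as the facility network
expanded or contracted.

`hmisaccess` implements that analysis end to end: coordinate quality
assurance, service-provision trends, a spatio-temporal functional
classification of facilities, multimodal least-cost travel-time surfaces,
population projection with age–sex sub-groups, and population coverage by
travel-time band. Because real facility archives of this kind are usually
confidential, the package ships a seeded synthetic-region generator that
emulates their statistical structure and carries ground-truth labels, so
every stage can be tested by parameter recovery.

# Data model

The central container is the **provision cube**, a
`SummarizedExperiment`-derived object with facilities as rows, the study
years 2016–2022 as columns, and one logical assay per indicator:
`provided(f, y, i) = TRUE` exactly when facility *f* reported a count
greater than zero for indicator *i* in year *y*. Zero or absent records mean
*not provided* — no imputation is attempted. A facility is **operational**
in a year when any of the six indicators is provided that year; only these
six are observed, so "operational" is necessarily relative to them.

Rasters are planar metric grids (`GridRaster`: a matrix plus cell size and
origin). The analysis is distance-based, so geographic coordinate systems
are deliberately out of scope: real inputs are expected in a projected
metric CRS, after which the grid arithmetic is identical to the synthetic
case. Rasters are exchanged as plain-text ESRI ASCII grids and vector
layers as planar GeoJSON.

# Coordinate quality assurance

Published facility coordinates in routine registries carry characteristic
errors: transposed ordinates (x↔y swap) and misplaced decimal points. The
QA stage spatially joins each facility against its *assigned* district
polygon and, for non-matching points, tries repairs in a fixed order:

1. ordinate swap;
2. decimal shifts — each ordinate multiplied or divided by 10, singly
   first, then jointly — first in-district candidate wins;
3. points within a tolerance (default 2 000 m) of the district boundary are
   treated as boundary digitisation inaccuracies and left unchanged;
4. everything else is `unresolved`: excluded from travel-time sourcing but
   retained for the temporal and classification analyses, which need no
   coordinates.

The swap-before-decimal order and first-hit-wins tie-break are package
decisions; the error kinds themselves are the two observed in practice. An
optional gazetteer hook widens rule 3: a facility co-located with a
reference place name is tolerated unchanged. The repair is idempotent:
re-running QA on its own output leaves all statuses at `ok` or
`boundary_tolerated`.

# Functional classification

Each facility's seven-year operational pattern and indicator sets determine
one class, applied as a rule cascade:

| class | rule |
|---|---|
| `no_service` | no indicator provided in any year |
| `closed` | operational 2016, not operational 2022 |
| `newly_operational` | not operational 2016, operational 2022 |
| `oscillating` | not operational 2016 nor 2022, operational between |
| `existing_*` | operational every year (sub-classified below) |
| `other_intermittent` | operational 2016 and 2022 with a gap year between |

Existing facilities are sub-classified from the indicator sets:
`unchanged` (identical set all seven years), `increased` / `decreased`
(strictly larger / smaller set in 2022 than 2016), `varying` (equal
endpoint sets with intermediate variation). Two deliberate decisions make
the classifier total:

* "a greater range of services" is read as strictly larger indicator-set
  *cardinality*; an equal-cardinality but different endpoint set (while
  operational throughout) is assigned `existing_varying`, since its
  composition did vary;
* the five named groups are not exhaustive — a facility operational at both
  endpoints with a non-operational year in between fits none of them — so a
  residual `other_intermittent` class is reported separately rather than
  silently merged.

Totality is verified by brute force over all $2^7 = 128$ yearly
presence/absence patterns.

Provision percentages divide facilities providing an indicator by
*operational* facilities that year, optionally within a facility type.
Caesarean percentages use hospitals only in both numerator and denominator,
since surgical birth care is hospital-bound; the same restriction applies
when caesarean sources feed the travel-time stage.

The association between ownership (government / faith-based / private) and
functionality is tested with Fisher's exact test. The package computes the
p-value by full enumeration of margin-preserving tables (summing the
probabilities of tables no more probable than the observed one, with a
$1{+}10^{-7}$ relative tie tolerance — ties must be resolved identically in
floating point) whenever the enumeration stays below a configurable cap
(default 20 000 tables), and otherwise by a seeded Monte-Carlo estimate over
`r2dtable` draws, reported with its draw count and seed. Because sparse
class × ownership tables are near-degenerate, the default test collapses
the four `existing_*` sub-classes into one `existing` row.

# Travel-time model

A **friction surface** assigns each 100 m cell a traversal cost in seconds
per metre:

* off-road cells walk at the land-cover class speed (defaults: grassland
  and built-up 5 km/h, cropland 4 km/h, dense vegetation 2 km/h), moderated
  multiplicatively by Tobler's hiking function of the local slope magnitude,
  normalised to 1 on flat ground:
  $f(s) = e^{-3.5\,|s + 0.05|} / e^{-0.175}$, maximum ≈ 1.19 on a −5 %
  grade. Normalising preserves the land-cover differentiation of walking
  speeds; the slope magnitude comes from DEM finite differences (central in
  the interior, one-sided at borders), i.e. the factor is isotropic —
  direction-of-travel anisotropy is not identifiable from the data the
  model consumes;
* water cells are impassable (`Inf`);
* road cells override both with the road-class speed (defaults 80/40/20
  km/h for primary/secondary/tertiary), not slope-adjusted because
  mechanised travel is not a hiking process; a road crossing water is a
  bridge. Rasterisation priority is therefore water < land cover < roads.

These default speeds are package defaults for scenario work, clearly not
measurements; real analyses should substitute locally tracked speeds via
`speedConfig()` or a YAML speed table.

Travel time to the nearest providing facility is the exact multi-source
shortest path over the 8-connected grid (Dijkstra, implemented in C++),
with step time $d(a,b)\,(c_a + c_b)/2$ where $d$ is the cell size
orthogonally and $\sqrt2$ times that diagonally. This discretisation is
stated explicitly so that an independent oracle is well defined; the test
suite checks exact agreement (< $10^{-9}$ minutes) against an
`igraph`-based shortest path on random friction grids, plus the structural
properties: adding a source never increases any travel time, scaling all
costs by $\lambda$ scales all times by $\lambda$, and uniform friction
reduces to chamfer distance. Facilities landing on impassable cells are
snapped to the nearest passable cell within 500 m (configurable), else
dropped with a warning.

Travel times are banded as [0, 30], (30, 60], (60, 120], (120, ∞] minutes:
the two-hour bound reflects the obstetric-emergency window, and boundary
values belong to the lower band ("within 30 minutes" is inclusive).
Change surfaces are later-minus-earlier differences; cells unreachable in
either year are missing in the difference, with the reachability transition
(`gained` / `lost` / `neither`) flagged alongside rather than reported as a
signed infinity.

# Population projection and coverage

The gridded baseline population (census year 2021) is projected cell-wise
with annual geometric growth, $P_y = P_{y-1}(1 + r_y/100)$ forward and the
exact inverse backward, compounded year by year across 2016–2022. (The
source material describes a "simple arithmetic projection" with an annual
percentage growth rate but prints the formula garbled; annual geometric
compounding is the standard reading and makes back-projection the exact
inverse of forward projection, which the tests verify to $10^{-9}$
relative.) Projection is a uniform scaling, so the spatial pattern and cell
rank order are preserved exactly, and the regional total scales by exactly
$\prod_y (1 + r_y/100)$. Growth rates are required configuration — the
package ships no demographic estimates.

Age–sex sub-groups — total population, women of childbearing age 15–49
(WoCBA), children under five — are spatially uniform per-year fractions of
the projected raster (census age–sex structure is available as marginals,
not per cell). Each indicator maps to its target sub-group: outpatient and
malaria → total, antenatal/birth/caesarean → WoCBA, pentavalent dose 1 →
under-five.

Coverage tables sum the sub-group population per travel-time band and
express bands as percentages of the regional sub-group total, which
enforces conservation: band populations sum to the total to $10^{-6}$
relative, and percentages to 100. When no facility offers a service in a
year (possible for caesarean care in small scenarios), that service-year is
reported as missing rather than zero.

# The synthetic region generator

`regionScenario()` fixes the study conditions; `generateRegion()` produces
all layers deterministically from one seed (each stage draws from its own
derived RNG stream, so layers are independently reproducible). Defaults:
200 × 200 cells at 100 m (a 20 × 20 km region), 150 facilities, 70 000
people (≈ 175 persons/km², a realistic rural-regional density), growth
2 %/yr, WoCBA 24 % and under-five 13 %, 6 rectangular districts, 5 %
corrupted coordinates.

Composition knobs default to the published 2022 regional facility census:
type mix 71.0 % CHPS / 20.9 % health centre / 6.1 % hospital / 2.0 %
maternity home, ownership conditional on type (all health centres
government, all maternity homes private, hospitals mixed), and an archetype
mix with 20.9 % newly operational, 3.2 % no-service, ~2 % closed, ~1.6 %
oscillating and the existing classes split so unchanged + increased equals
60.6 %. Archetype counts are allocated by largest remainder and permuted —
the mix defines the region's composition, not a sampling distribution —
whereas facility types are sampled per facility. Yearly openings are free
parameters of the scenario (no published trajectory exists to emulate);
newly-operational facilities draw a uniform start year in 2017–2022.

Service histories follow the archetypes exactly, with services onboarded
along a type-specific ladder — immunisation first, then
outpatient + malaria, then antenatal, then birth care, caesarean last and
only in hospitals — mirroring how new community facilities typically phase
in services (outreach immunisation, then minor-illness treatment, then a
midwife). This gives the synthetic archive the correlation structure the
analysis expects (outpatient ≈ malaria; antenatal ≥ birth). Counts for
provided services are zero-truncated Poisson (inverse-CDF sampling, so the
truncation is exact) with type-dependent means, hospital ≫ health centre >
CHPS > maternity home.

Injected coordinate errors are ordinate swaps or single-ordinate decimal
shifts, with the kind recorded per facility. The generator only injects
corruptions that are *detectable* (the published point leaves its district)
and *unambiguously repairable* (the QA cascade's first in-district
candidate is the true point); otherwise another corruption variant is
chosen. Without this, a swap could land inside a square-ish district and be
invisible to any spatial join, or the swap-first repair order could
"repair" a decimal error to a wrong in-district point — failure modes of
the *error model*, not of the repair.

What the generator does **not** emulate: real geography or hydrology,
reporting noise (missing years at operating facilities, so classification
robustness to non-reporting is untested by construction), month-level
seasonality, facility-level population catchments, or dasymetric population
modelling (the baseline grid is synthetic clustered settlement mass, not a
model of census data). Passing recovery tests therefore demonstrate
algorithmic correctness under the stated error model, not robustness to
every failure of real routine data.

# Numerical choices and degenerate inputs

* Line rasterisation is exact grid traversal: a cell is burned only when a
  segment has positive-length intersection with it (grazing corner touches
  don't count); the tests compare against an independent per-cell
  Liang–Barsky clipping oracle.
* Point-in-polygon uses `mgcv::in.out`; facilities exactly on shared
  district edges are snapped to the nearest district at generation time.
* Zero denominators (no operational facilities of the eligible type) yield
  `NA` with a warning, never an exception; empty source sets yield missing
  coverage rows.
* Band boundaries are closed on the lower side; unreachable cells fall in
  the last band.
* All simulation-based tests run at fixed seeds on scenario sizes chosen to
  exercise the full pipeline quickly: 40–80-cell grids with 10–60
  facilities for property suites, 1 000 facilities for recovery, and one
  full-scale 200 × 200 / 150-facility end-to-end run. The full pipeline at
  that scale (42 travel-time surfaces) completes in well under a minute.

# Known limitations

Road travel is modelled on the raster, not as network routing on the road
graph; congestion, seasonality, monetary cost and cross-regional service
use are out of scope. Classification is sensitive to the 2016 base year
(a facility closed in 2016 that reopened later is misclassified) and to
non-reporting, which the synthetic data do not model. The Fisher test's
exact mode is exponential in table size; the Monte-Carlo fallback is an
estimate and is labelled as such in its result.
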
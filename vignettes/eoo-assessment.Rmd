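---
title: "EOO-based Red List screening across data sources: model, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EOO-based Red List screening across data sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eooassess)
```

## The screening model

For a species with georeferenced occurrence records
$p_1, \dots, p_n$ (decimal degrees, WGS84), the extent of occurrence is

$$\mathrm{EOO} = \operatorname{area}\big(\operatorname{conv}\{p_1,\dots,p_n\}\big),$$

the geodesic area of the minimum convex polygon (MCP). The hypothetical
Red List category follows criterion B1 thresholds applied with *strict*
inequalities: EOO `< 100` km² is CR, `< 5,000` EN, `< 20,000` VU,
`< 30,000` NT, otherwise LC. An EOO exactly at a threshold therefore falls
in the *less*-threatened category; that is the literal reading of the
"(CR, < 100 km²)" notation and it makes the classifier a right-continuous
step function. The NT cutoff is a screening convention, not an official
criterion-B boundary, and is kept because the comparison tables this
package reproduces use it. Only the EOO-based B1 axis is implemented — no
AOO, subcriteria, or population trends — so all categories are
"hypothetical" screening labels, not full assessments.

**The three-point rule.** An MCP needs at least three data points;
species with fewer are Data Deficient (EOO undefined, `NA`). Whether
"three data points" means three *records* or three *distinct localities*
is ambiguous in the source procedures; the package defaults to the record
count (the literal reading) and offers `rule = "distinct"` on
[eoo()] and the CLI (`--three-point-rule`). The two differ exactly for
species with three or more records at fewer than three distinct points:
under the default these get a *defined* EOO of 0 km² and classify CR,
under the distinct rule they are DD. Zero-area hulls from collinear
records are likewise a defined 0 km² (CR): "no calculated area" is read
as the fewer-than-three case only.

## Geometry: hull and geodesic area

The hull is Andrew's monotone chain over the distinct points in planar
lon/lat coordinates, returned counter-clockwise from the lexicographically
smallest vertex; collinear edge points are excluded. Planar hulls in
lon/lat are valid for sub-hemispheric extents, which covers any realistic
EOO; if a species' longitudinal span exceeds 180° the longitudes are first
recentred on their circular mean (ranges genuinely wider than a hemisphere
are an error, not silently wrong).

The area is the *exact* spherical area, on the authalic sphere
(R = 6371.0072 km, the sphere with the WGS84 ellipsoid's surface area), of
the polygon whose edges are straight segments in lon/lat space. By Green's
theorem each directed edge contributes

$$\Delta A = R^2\, \Delta\lambda \, \sin\bar\varphi\,
  \frac{\sin(\Delta\varphi/2)}{\Delta\varphi/2},$$

with $\bar\varphi$ the mean latitude of the edge (a numerically safe
series is used for $|\Delta\varphi| < 10^{-8}$). Two consequences drive
this choice over a great-circle-edge spherical-excess computation:

* for latitude-aligned rectangles it reproduces the closed-form zone
  formula $R^2\,\Delta\lambda\,(\sin\varphi_2 - \sin\varphi_1)$ to
  machine precision, which gives the test suite an exact independent
  oracle;
* it measures the area of *the same region the hull defines* (the hull is
  built with straight lon/lat edges), so containment arguments —
  monotonicity under record addition, hull-inside-range — are exact, not
  approximate.

The two edge conventions differ by roughly $10^{-5}$ relative at
1-degree extents, far below the 0.5–1% tolerances any downstream
comparison uses; parity with any particular GIS package's projection is a
non-goal. The 1° × 1° quadrilateral at the equator measures
12,363.71 km² and the half-triangle 6,182.01 km², values frozen into the
tests after being computed from the zone formula and a 10⁶-sample
Monte-Carlo point-in-spherical-polygon oracle respectively.

## Ingestion and the comparison design

CSV ingestion (comma/tab auto-detected) maps Darwin Core column names by
default (`species` with `scientificName` fallback, `decimalLatitude`,
`decimalLongitude`) and is configurable for literature files. Deliberate
choices, all aimed at using aggregator data "as is":

* no coordinate-precision or basis-of-record filtering; coordinates kept
  at input precision; longitudes normalised to (−180, 180];
* a row whose coordinate pair is not fully valid (either cell blank,
  unparseable, or out of range) is *retained* with both coordinates
  absent and counted in the ingest report — only rows with an empty
  species name are dropped. Non-georeferenced records are removed later
  by an explicit, idempotent filter whose per-species drop counts are
  logged, and species losing every record remain in the universe as DD;
* species matching is exact case-insensitive binomial matching after
  whitespace normalisation — synonymy is expert work outside the
  pipeline;
* merging sources never deduplicates across them: published comparisons
  report raw per-source record counts, and duplicated coordinates cannot
  change a hull;
* out-of-region checking *flags* records against a boundary polygon
  (inclusive on the boundary — deterministic and conservative for
  endemics) and deletes nothing.

Every species is assessed under three modes — LITERATURE-only, GBIF-only,
COMBINED — over the same species universe. Per species the comparison
reports `newly_assessable` (DD under literature, ranked under combined),
`changed_among_assessed` (ranked under both, different), their union
`shifted`, and a direction; because combined ⊇ literature and the hull is
monotone, UPGRADE (toward more threatened) is impossible and is asserted
never to occur on synthetic runs. "Downgrade" follows Red List usage for
movement toward less-threatened.

Percentages are rounded half-up to one decimal (matching how such tables
are printed; `round()`'s banker's rounding would turn 58.06 into 58.1
either way but differs at exact halves). The identity
`shifted = newly_assessable + changed_among_assessed` holds exactly
before rounding and is tested. When only a printed count table is
available (no per-species rows), `summary_table()` still derives the
classifiable percentages and the DD-reduction share from the margins —
valid because record addition never *creates* DD. Published shift
percentages from the two studies this package re-derives cannot be
reconciled exactly with their printed table margins under any single
shift definition; the package therefore reports the full decomposition
rather than targeting those figures.

## The synthetic world

The generator states a world in which truth is known:

* **Ranges are ellipses** (convex), so the true EOO equals the true range
  area and recovery is well-defined; non-convex ranges, for which
  EOO ≠ range area by design of the EOO statistic, are out of scope.
* **True areas are log-uniform over [0.1, 10^5.5] km²**, spanning all
  five ranked categories with roughly equal log-mass. Axis ratios are
  uniform on [0.3, 1], orientation uniform.
* **The region is an Iberia-like box** (36–44°N, 10°W–4°E): realistic
  mid-latitude area distortion without antimeridian complications.
  Placement resamples the centroid (then orientation, then shape) up to
  200 times before failing.
* **Record counts are Poisson**, independently per source, with
  `lambda_lit = 12` (large literature compilations average ~12 records
  per species: ~2,400 records over 200 species) and
  `lambda_gbif = 1.5`, putting most species below the three-record
  minimum in GBIF-only mode — the sparse-aggregator regime the
  comparison studies describe, where GBIF alone leaves ~85–90% of
  species DD.
* **Georeferencing probabilities** are `g_gbif = 0.88` (the reported
  georeferencing rate for spider records in aggregators) and
  `g_lit = 0.90` (chosen once as realistic for curated literature
  compilations). Blanking is i.i.d. per record, so the number of
  georeferenced records is thinned Poisson and the zero-record
  probability `exp(-(λ_lit g_lit + λ_gbif g_gbif))` is a closed-form
  property test.

Sampling inside an ellipse uses the exact polar method
(`r = sqrt(u)`, uniform angle, scaled to the semi-axes) in a local
kilometre frame, mapped to lon/lat by an equirectangular transform at the
range centroid. This was preferred over bounding-box rejection: it is
exactly uniform, has no retry loop, and keeps the containment invariant
(estimated EOO ≤ true area) exact up to boundary discretisation. The
truth area is the geodesic area of a 4096-vertex inscribed polygon of the
ellipse (relative discretisation error < 10⁻⁷; containment tests use a
10⁻⁵ slack for this reason); exported range polygons use 256 vertices.
One deterministic substream per species is derived from the run seed, so
adding species never perturbs earlier ones and identical seeds give
byte-identical output files.

**What the synthetic world does not emulate** — and hence what a green
test does not establish: spatial sampling bias and clustered collection
effort (points are uniform in the range); overdispersed per-species
effort (real literature compilations are clumped, so their DD fraction
at a given mean is much higher than Poisson predicts — the generator's
literature mode classifies nearly everything); shared specimens appearing
in both sources; taxonomic misidentification; coordinate error. Recovery
results validate the *pipeline arithmetic*, not the field realism of any
particular dataset.

## Validation strategy

Beyond per-module unit tests, the acceptance suite implements:

1. re-derivation of all eight printed percentages from the two bundled
   published count tables through `summary_table()`/`pool_summaries()`;
2. hull equality with a brute-force Carathéodory oracle on 1,000 random
   ≤12-point sets (plus `grDevices::chull` cross-checks), rectangle areas
   against the zone formula at 10⁻⁹ relative, and the fixed triangle
   against a 10⁶-sample Monte-Carlo oracle at 0.5%;
3. monotonicity over 200 seeded synthetic species: combined-mode EOO
   dominates each single source, subsets never exceed supersets, no
   category upgrades;
4. parameter recovery at `g = 1` with ~10,800 points per species:
   estimated EOO within 5% of (and never above) the true area, and
   category recovery ≥ 95% for species whose true area is ≥ 10% from
   every threshold;
5. exhaustive one-rank-step checks at every threshold boundary.

## Known limitations

* Areas are spherical (authalic), not ellipsoidal; the difference is
  below 0.5% everywhere and irrelevant at EOO-threshold granularity.
* Hulls wider than a hemisphere are rejected rather than computed.
* No GBIF API access, Darwin Core Archive parsing, georeferencing of
  textual localities, or fuzzy taxon matching.
* Config files are JSON (no YAML dependency).
* The three-point-rule ambiguity (records vs distinct localities) is
  surfaced as an option rather than resolved.
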
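---
title: "Computing geographic covariates for exposure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing geographic covariates for exposure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geocov)
```

## The problem

Cohort studies of long-term air-pollution health effects need pollutant
concentrations at locations where nothing was ever measured. Land-use
regression (LUR) and related statistical exposure models predict those
concentrations from *geographic covariates* — quantitative descriptions of
the pollution sources surrounding a point: how close the nearest major road
is, how much road length falls within 300 m, how many people live within
1 km, what fraction of the neighbourhood is industrial, how much is emitted
within 15 km, how green and how elevated the site is.

`geocov` computes such covariates at arbitrary point sites from standard GIS
inputs, organised in eight categories: traffic, demographic characteristics,
land use, transportation facilities, physical geography, emissions,
vegetation and altitude. Every variable is one of two metric types:

* a **distance** — the minimum planar Euclidean distance from the site to a
  feature class (roads of a given class, depots, rivers, a coastline, a
  derived border line); or
* a **buffer summary** — a statistic of features intersecting the circular
  disc of radius $r$ centred on the site.

## The statistics

### Clipped road-length sums

Within a buffer of radius $r$, road segments of a class are *clipped at the
buffer boundary* and their lengths summed, under three weightings: plain
length (km), length × lane count (lane-km), and length × lanes × per-lane
width (reported in $10^3\,\mathrm{m}^2$, an effective road-surface area).
Clipping, rather than all-or-nothing segment selection, makes the sum
continuous and monotone in $r$. Road classes are `ALL`; `MR1`, defined by
road type (national and metropolitan-city highways by default); and `MR2`,
which is MR1 plus any road with strictly more than six lanes (the threshold
is configurable; lane counts are consumed as the source supplies them —
whether they are per-direction or total is a property of the source data,
and the package deliberately does not guess). Hence
$\mathrm{MR1} \subseteq \mathrm{MR2} \subseteq \mathrm{ALL}$ always.

Per-lane widths come from a lookup on (highway flag, speed band, urban
flag), with half-open speed bands $[v_{\min}, v_{\max})$. A segment is
*urban* iff it intersects an urbanized-area polygon (touching counts). The
shipped default width table is a plausible stand-in (3.0–3.6 m per lane) and
is documented as non-authoritative; real deployments supply their own.

### Areal weighting

Counts attached to polygons (population, households, buildings, companies,
employees — and gridded emissions) are apportioned to a buffer $i$ by area
fraction:

$$P_i = \sum_{j=1}^{N} P_j \cdot \frac{A_{ij}}{A_j},$$

where $A_{ij}$ is the area of polygon $j$ intersected with the buffer and
$A_j$ the polygon's area. This assumes uniform density within each polygon;
that assumption is also the basis of the synthetic ground truth below. A
polygon that merely touches the buffer has $A_{ij} = 0$ and contributes
nothing. Land-use variables are the complementary ratio: class area inside
the buffer divided by buffer area, so proportions over a mosaic that
tessellates the buffer sum to 1.

Emission inventories arrive as a table keyed by the *bottom-left corner* of
1-km grid cells, split by source type (point, line, area) and pollutant
(CO, NOx, SOx, TSP, PM10, VOC, NH3). Source types are summed per cell, the
cells become square polygons tiling the grid, and buffer totals use the same
areal weighting at 3, 15 and 30 km.

### Raster metrics

The vegetation index NDVI is $(\mathrm{NIR}-\mathrm{RED}) /
(\mathrm{NIR}+\mathrm{RED})$ from band reflectances; distribution composites
carry it rescaled to bytes 0–255, and summaries are reported on that native
scale (published annual means around 140–170 are byte values). From a
36-composite annual stack the package reports the site-cell mean, minimum
and maximum (nodata composites excluded); the peak-vegetation metric is the
median of all August composites pooled over three years.

Altitude variables come from a DEM: the site's own cell value, and *relative
elevation* — the percentage of cells on a 30 m-wide annulus at 1 or 5 km
whose elevation differs from the site's cell by more than ±20 or ±50 m
(`above` and `below` counted separately). Raster lookup is strictly
half-open ($[x_0 + c(i-1), x_0 + ci)$), so a site on a shared edge belongs
to the +x/+y cell and the lookup is deterministic.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| traffic radii | 25, 50, 100, 300, 500, 1000 | m | near-road gradients are steep; small buffers capture them |
| non-traffic radii | 50, 100, 300, 500, 1000, 5000 | m | neighbourhood-scale sources; a second preset (`body_text`) omits 50 m because published radii sets differ on it |
| emission radii | 3000, 15000, 30000 | m | inventories act at regional scale |
| `mr2_lane_threshold` | 6 | lanes | "more than six lanes", strict inequality |
| `major_port_threshold` | 10000 | vessels/yr | "more than 10000", strict inequality |
| `border_northern_fraction` | 0.1 | — | fraction of the dissolved boundary's y-extent kept as the "northern end" |
| ring radius / width | 1000 or 5000 / 30 | m | relative-elevation annulus |
| `buffer_vertices` | 256 | — | buffer-disc polygon approximation |

## Numerical choices

* **Buffer discs** are inscribed regular 256-gons for polygon overlay (area
  deficit $\tfrac{(2\pi/256)^2}{6} \approx 10^{-4}$, i.e. ~0.01%);
  polylines are clipped against the *exact* circle analytically, which is
  exact and cheap. Polygon∩buffer areas use Sutherland–Hodgman clipping
  against the convex buffer polygon, summing signed ring areas so holes are
  handled.
* **Ties**: equidistant nearest features resolve to the lowest feature id;
  a site on a shared district boundary resolves to the lowest district id.
  Output is therefore deterministic byte-for-byte.
* **Missing vs zero**: an empty buffer intersection is a legitimate 0; an
  empty feature layer, a site in no district, or an all-nodata stack is a
  missing value (`NA`, empty cell in CSV), never a fabricated large number.
* **Border derivation** dissolves a polygon tessellation by edge
  cancellation (edges shared by two features vanish; vertices must match to
  1e-6 m), walks the surviving edges into rings, keeps the largest-area
  ring, and retains segments whose midpoints lie strictly in the top
  fraction of that ring's y-extent. The "northern end" of a boundary has no
  canonical geometric definition, so the fraction-of-y-extent rule is
  exposed as a parameter.
* **Ring membership** for relative elevation is by cell center within the
  closed annulus $[r - w/2,\, r + w/2]$ — the common zonal convention;
  intersection-based membership would be a different, equally defensible
  reading. The threshold comparison is against elevation *differences*
  relative to the site's cell ("above" means $e > e_0 + t$).
* **Degenerate inputs**: zero-area polygons are rejected at load with the
  offending feature id; self-intersecting polygons are not repaired.

## The synthetic world

`generate_scene()` emits every layer the pipeline consumes, built from
analytic geometries whose covariates have closed forms: an orthogonal road
grid through the extent centre (site 1 sits on the central node, so
all-roads length within $r \ll$ spacing is exactly $4r$), a square census
tessellation with uniform density $\rho$ (areally weighted population is
$\rho \pi r^2$), a half-plane land-cover mosaic split on the centre line
(proportion 0.5 at the node), a constant emission field $c$ per 1-km cell
(buffer total $c \pi r^2 / 10^6$), constant or sinusoidal byte NDVI, and
flat/ramp/half-plane/random DEM profiles. Defaults (10 km extent, 2 km road
spacing, $\rho = 0.01\ \mathrm{persons/m^2}$, NDVI 150, flat DEM at 100 m)
describe a small dense city-scale scene; they were fixed once, before
testing, and are not tuned.

What a green test establishes: that the geometry engine (clipping, areal
weighting, distances, raster indexing) is correct to the stated tolerances
on exactly-known scenes, and that the pipeline is deterministic end-to-end.
What it does not establish: fidelity to any real road network topology
(curved segments, dead ends), non-uniform within-polygon densities (the
areal-weighting assumption is untestable from geometry alone), raster
reprojection effects, or the accuracy of any real national dataset.
Monte-Carlo oracles sample the same 256-gon buffer the implementation is
specified to use — membership decided by closed-form polar geometry, not by
the package's clipping code — so the 3σ comparison isolates the weighting
logic from the separately documented disc-approximation error.

## Design decisions taken where the design was open

* **No GDAL-backed formats.** The interchange formats are WKT-geometry CSV
  for vectors and ESRI ASCII grid for rasters: plain text, stable,
  round-trip-exact to 1e-6 m. The computation is CRS-agnostic; loaders only
  *reject* declared geographic (degree-based) systems and otherwise trust
  that all inputs share one projected meter-based CRS.
* **Catalog size.** The full default catalog has 346 variables. A published
  catalog of 313 with this category structure cannot be reconstructed
  exactly: the census sub-breakdown behind it is not enumerable from public
  summaries, and the non-census blocks fix a parity that 313 cannot satisfy
  for either non-traffic radii preset. The shipped census breakdown
  (29 attributes: residents by sex and three age bands; households; housing
  by type and construction era; companies and employees by seven business
  categories) is one defensible reading; the catalog is configuration-driven
  and the 346 total is regression-tested for the default configuration only.
* **Registered vehicles** are a district-level lookup (annual mean of 12
  monthly counts for the district containing the site), not a buffer
  statistic — district units are far larger than any buffer.

## Limitations

* Pure-R geometry: fine for hundreds of sites × hundreds of variables
  (seconds to minutes), not tuned for millions of features. Spatial
  indexing is a bounding-box prefilter only.
* The border-dissolve requires topologically matching edges; layers with
  sliver gaps need cleaning upstream.
* No geodesic computation, no network (along-road) distances, no
  kernel-weighted buffers, and no exposure-model fitting — the output is
  the covariate table itself.
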
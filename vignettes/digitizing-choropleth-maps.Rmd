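---
title: "Digitizing choropleth maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing choropleth maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapreclaim)
```

## The problem

A choropleth map colours predefined spatial units (typically counties) by the
class of a thematic variable. Many such maps — wildlife density maps among
them — were published only as images, so the data they encode is effectively
locked. `mapreclaim` re-opens them: it converts a 3-band 8-bit map image into
a georeferenced class raster, per-unit class summaries and, for density-class
legends, population estimates. The worked example throughout the package is a
four-class white-tailed deer (*Odocoileus virginianus*) density legend
(<5.8, 5.8–11.6, 11.6–17.4, >17.4 deer/km²) over US counties and states.

The pipeline has five stages:

1. **Georeference.** Ground control points (pixel → projected metres) are
   fitted per axis by ordinary least squares to a polynomial of order 1–3;
   the image is warped onto an equal-area grid by nearest-neighbour
   resampling.
2. **Segment.** Multiresolution region merging partitions the image into
   homogeneous image objects, or the colour-threshold backend classifies
   pixels directly against the legend palette.
3. **Classify.** A random forest on six per-object colour statistics
   (per-band mean and standard deviation) assigns a legend class to every
   object.
4. **Clean up.** Black cartographic ink (unit borders, label text) is
   dissolved back into the surrounding thematic classes; manual overrides
   and fill-from-fallback-map corrections are applied as data.
5. **Summarize.** Class areas and percentages per polygon unit, majority
   classes under a clear-majority rule, between-map change categories, and
   population/density estimates with calibration of the open class value.

## Segmentation model

Objects start as single pixels. Merging adjacent objects $A$ and $B$ costs

$$\Delta h = \sum_b w_b \left[\, n_{A\cup B}\,\sigma_b(A\cup B)
  - n_A\,\sigma_b(A) - n_B\,\sigma_b(B) \,\right],$$

the increase in size-weighted per-band heterogeneity ($\sigma_b$ is the
population standard deviation of band $b$; $w_b$ are band weights, equal by
default). A merge executes only when $\Delta h < s^2$ (the *scale
parameter* $s$) **and** the pair is a mutual best fit — each object is the
other's minimum-cost neighbour. Passes over the objects repeat until a full
pass makes no merge. By the variance decomposition $\Delta h \ge 0$ always,
so the object count is non-increasing in $s$ and $s \to 0$ leaves every
pixel alone.

Determinism is a design goal: objects are visited in ascending id, cost ties
break to the lower neighbour id, and a merged object keeps the smaller id,
so a given image and parameter set always yields the same partition. The
merge cost is colour-only — no shape/compactness term — because palette maps
reward colour purity, not compact shapes, and a colour-only cost is exactly
reproducible. Connectivity defaults to 4 neighbours so classes cannot leak
diagonally across one-pixel border lines. The per-object standard deviation
divides by $n$ (population form), keeping object statistics and the merge
cost internally consistent; with an $n-1$ denominator single-pixel objects
would be undefined.

Two further implementations exist purely as oracles: a naive routine that
recomputes every statistic from the pixel array at each evaluation, and a
slow pure-R reference. For 8-bit inputs all three accumulate exact integer
sums in doubles, so their partitions must agree bitwise; the test suite
checks this exhaustively on every 2-colour image up to 4×4 and on random
3-colour images.

**Choosing `scale`.** The default `scale = 10` (merge threshold $s^2=100$)
suits 8-bit palette maps: merging two pixels costs roughly the sum of their
absolute band differences, so sensor-like noise of a few digital numbers
merges freely while distinct palette colours (≥65 apart in some band)
never do. Degraded scans with heavier noise may need a larger scale; a
too-large scale risks merging across faint class boundaries — the reason a
*small* scale factor is the right default for poor-resolution maps.

## Colour-threshold backend

Each pixel within `tolerance` (default 30, maximum per-band absolute
difference) of a legend colour takes that class; legend colours must be
separated by more than twice the tolerance, which is checked. Remaining
pixels form connected "holes" (4-connectivity). A hole enclosed by one class
fills to it. A hole touching several classes is resolved per pixel: each
hole pixel takes the bordering class nearest to its own colour, exact ties
going to the class with the longest shared hole boundary and then to the
lowest class id. The per-pixel rule matters because after blurring, the
unassigned pixels form long thin bands along class boundaries whose ends
touch different classes; assigning such a band wholesale to a single class
would misclassify entire boundary stretches.

## Random-forest classification

Features are the six object colour statistics. Defaults: 500 trees,
$\lfloor\sqrt{6}\rfloor = 2$ candidate features per split, unlimited depth,
and a **mandatory seed** — reproducibility of the final map is treated as
part of the method. Out-of-bag accuracy is reported on the training sample;
per-object vote fractions are exported for manual review, but every object
receives its argmax class (no probability thresholding — unclassified
objects would only push the problem downstream). Training requires at least
one example of every class to be predicted and fails naming any class with
none.

## Ink removal

Black borders and labels are detected at object level: an object is black
iff all three band means are at or below `black_max_channel` (default 60 —
palette colours on thematic maps are bright, ink is near 0, so anything
below ~60 in all bands is ink even after blurring). Removal runs in two
stages:

- **Small objects** (≤ `small_object_max_px`, default 5: label glyphs,
  specks) take the density class with the greatest *shared boundary length*
  among their non-black neighbours. Boundary length, not neighbour count — a
  one-pixel sliver should not outvote a long shared edge.
- **Line work** is dissolved by iterative boundary absorption: each pass,
  every black pixel with a density-classified 4-neighbour takes the class
  contributing the most neighbours (ties to the lowest class id); passes
  repeat until no black pixel remains. This is the geodesic-nearest-class
  completion — the natural generalisation when no explicit rule is given
  for large ink objects. Leftovers after `max_absorption_passes` become
  nodata with a warning.

Both stages only relabel pixels, so the classified-plus-nodata pixel count
is conserved and a second application is a no-op; both properties are
tested.

## Zonal summaries

Class area per unit follows the pixel-centre rule — the count of class
pixels whose centres fall in the unit polygon times the pixel ground area —
which is fast, deterministic and unbiased at equal-area resolution; exact
polygon clipping is out of scope. Percentages are relative to the unit's
*official* area, not its classified area, so partly reported units surface
as low coverage instead of inflated percentages. A unit's majority class is
trusted (`valid`) only when coverage is at least `min_coverage` (default
0.25) and the majority exceeds the runner-up by **strictly more than**
`majority_margin` percentage points (default 25). The strictness is
deliberate and tested: a 45% vs 20% unit has a margin of exactly 25 points
and is *not* a clear majority; 45.1% flips it. Only density classes compete
for the majority — nodata is an absence of information, not a competitor.
Change analysis between two maps categorises units valid in both as
`decreased`, `same`, `+1` or `>+1` by ordered class index; units valid in
only one map are reported separately rather than forced into a category.

## Population and density

Population is linear in the legend's density values, $P = \sum_c A_c v_c$.
Bounded classes take their lower bounds (5.8, 11.6, 17.4 deer/km² in the
deer legend); the open low class is calibrated against an independently
known total $T$ (30 million deer for the 2003-era US map):

$$v_{\text{free}} = \frac{T - \sum_{c \ne \text{free}} v_c A_c}{A_\text{free}},$$

an exact linear solve — substituting the solution back reproduces $T$ to
machine precision, which the tests check over random draws. The deer
legend's default low-class value 1.85 deer/km² is the calibrated value for
that map series. Statewide density divides by the state's official total
area; presence density divides by the summed area of presence classes only.
Reporting mirrors published precision — populations to the printed unit,
densities to 0.1, quotients to 0.01 — and comparisons against
agency-reported estimates use `difference = reported − map`, the mean
absolute error over matched states, and the sample standard deviation
(n−1) for multi-year agency series.

One transcription note: in the bundled 1982/2003 state table the 1982
maximum statewide density is Alabama at 7.2 deer/km², while the
accompanying published text attributes 7.2 to Georgia (whose table row reads
4.7); the package follows the table.

## The synthetic generator

`simulate_map()` produces the package's test bed: Voronoi cells of uniform
random seeds clipped to the extent (areas sum exactly to the extent area),
iid class draws with neighbour-majority smoothing for spatial coherence, a
legend-palette render with 1-pixel black borders and per-unit black glyph
blocks, then Gaussian blur and additive Gaussian noise. Per-pixel ground
truth records the *underlying* unit class everywhere, border and label
pixels included — what a perfect digitization would recover. Everything is
driven by one seed.

Default conditions (30 units on 60×40 km at 100 m/pixel = 600×400 px, four
equiprobable classes, border width 1, blur σ = 0.5 px, noise SD 4, one
glyph block expected per unit, 10% of objects labelled for training) emulate
a modest-quality published map export: palette colours survive but borders
mix with neighbouring colours and small ink marks sit on top of the fill.
At these conditions the object-based route recovers ≥99% of pixels and
every unit majority; the colour-threshold route recovers ≥98%. The
generator deliberately does **not** model JPEG block artefacts, fold lines,
moiré, hill-shading or anti-aliased text, so passing tests demonstrate
robustness to blur/noise/ink occlusion — not to every artefact of real
scans, where manual overrides (supported as data via `apply_overrides()`)
remain part of the workflow. Labels are abstract glyph blocks rather than
rendered text: what matters to the cleanup rules is small black foreign
objects, not typography.

## Numerical and interface choices

- Resampling is nearest-neighbour only; interpolation would invent colours
  absent from the legend palette.
- Pixel coordinates are 0-based `(col, row)` at pixel centres; the default
  CRS identifier is the USA Contiguous Albers Equal Area Conic, USGS
  version (EPSG:5070). CRS handling is an identifier plus an equal-area
  assumption — no datum transformations are attempted.
- Raster I/O is lossless 8-bit PNG/TIFF with ESRI world-file sidecars;
  vectors travel as GeoJSON in projected metres; class/label rasters as
  tab-separated integer grids. These text-based formats keep every fixture
  diffable and bit-reproducible.
- The number of ground control points and the warp resolution are left
  configurable (`suggest_output_grid()` defaults the resolution to the mean
  GCP-implied scale rounded to whole metres); the polynomial fit reports
  its RMS residual rather than rejecting outliers.
- Problem sizes in the test suite: exhaustive oracle equivalence up to 4×4,
  random 5×5 cross-checks, 600×400 end-to-end recovery, 100 calibration
  draws — sizes chosen so the full suite exercises every path in well under
  a minute of segmentation work.

## Known limitations

- Shapefile/GeoPackage I/O is not provided; convert unit layers to GeoJSON
  (in the map's projected CRS) first.
- TIFF output carries its georeferencing in the world-file sidecar, not in
  embedded tags.
- The colour-threshold backend requires a palette separated by more than
  twice the tolerance; closely spaced or low-contrast symbology needs the
  object-based route and more manual correction, and may defeat automation
  altogether.
- Reproducing a published map's *actual* county/state numbers requires the
  original scans and their ground control points; the bundled tables
  support regression tests of the downstream arithmetic only.
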
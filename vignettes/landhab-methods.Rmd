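---
title: "Methods: coupled land-use change and habitat-quality modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled land-use change and habitat-quality modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landhab)
```

`landhab` couples two standard models from landscape ecology on categorical
raster landscapes: a Markov-chain / cellular-automata (CA–Markov) projection
of land-use change, and an InVEST-style habitat-quality index driven by
distance-decayed threats. This vignette explains the models, their
assumptions, the tunable parameters, and the design choices made where the
underlying methods leave room.

## Data model

A landscape is a matrix of integer class codes over the eight-class legend
*farmland, woodland, grassland, water, urban, rural residential,
industrial/traffic, barren* (codes 1–8), with a cell size in metres
(default 1000 m, i.e. a 1 km × 1 km evaluation unit) and an upper-left
origin. `NA` is nodata and is excluded from every statistic. Cell area
`cell_size²` is the unit of all area accounting; reports use km² and
percentages. The three built environment classes form the "built-up"
aggregate. Rasters are read and written as Esri ASCII grids (`.asc`), a
human-writable text format; class legends travel in a YAML sidecar.
Reprojection and resampling are out of scope: all layers must already be
co-registered, and `assert_aligned()` enforces this.

## Markov transition estimation

Given two dated maps, `transition_matrix()` cross-tabulates cell pairs into
an area matrix $A_{ij}$ (area moving from class $i$ to class $j$ over the
interval) and row-normalises it into transition probabilities
$p_{ij} = A_{ij} / \sum_j A_{ij}$. The chain assumes the process is
first-order and stationary over the projection horizon: the projected state
is $S(t+1) = P^\top S(t)$, one step per estimation interval (decadal in the
intended use). Conventions chosen here, and documented because the
formulation does not fix them: rows are origin classes (row-stochastic
matrix, the standard in land-change modelling); classes absent at the start
date receive an identity row so $P$ stays stochastic; cells that are nodata
at either date are dropped. Two exact identities follow from the
construction and are enforced by tests: rows sum to 1, and projecting the
estimated matrix one step reproduces the observed end-date areas.

Continuous-time rate estimation and matrix roots for interval rescaling are
out of scope; one step means one estimation interval.

## Suitability atlas

For each class, `fit_logistic()` fits a maximum-likelihood logistic
regression of the binary presence indicator on the driver layers,
$\mathrm{logit}\,P_i = \beta_0 + \beta_1 x_1 + \dots + \beta_n x_n$, and
`predict_suitability()` maps the inverse-logit of the linear predictor.
Drivers are z-scored internally for numerical stability; coefficients are
reported on both scales. Two deliberate choices:

* **No driver screening.** Which drivers "matter" is a modelling judgement
  with no canonical criterion; all supplied drivers are fitted and Wald
  z-statistics are reported so users can screen themselves.
* **Optional seeded subsampling** (`sample_frac`) trades precision for
  speed on large grids; the default fits on every valid cell.

Degenerate inputs fail loudly with the offending driver named: constant
drivers, exactly collinear drivers, classes with no presences or no
absences. ROC validation and spatial autocorrelation corrections
(autologistic terms) are out of scope.

## CA allocation

The Markov step fixes *how much* area each class gains or loses; the CA
step fixes *where*. The widely used desktop implementations leave the
allocation rule unspecified, so `simulate_landuse()` implements a fully
specified, testable rule:

1. Demands are converted to whole-cell targets with largest-remainder
   rounding (total cell count is conserved exactly).
2. Each cycle (default 10), classes short of their target are processed in
   order of decreasing relative shortfall, each taking its per-cycle quota
   of cells; shortfalls roll into later cycles, with extra clean-up passes
   after the configured cycles.
3. A growing class takes the eligible cells with the highest score
   `suitability × neighbourhood density`, where density is the fraction of
   the class in a centred 5 × 5 window (edge-truncated and renormalised).
   Ties break on a seeded random key, making runs reproducible.
4. A cell of class $i$ may convert to $j$ only if the transition rules
   allow it ($p_{ij} > 0$) and the scenario does not forbid it, and never
   out of a class already at or below its own target — which also
   implements protected (non-decreasing) classes.

If constraints block a demand beyond the tolerance (default 0.5% of the
demanded area), the blocking class is reported rather than silently
under-allocating. Agreement between simulated and observed maps is scored
by `kappa()`: $(P_o - P_c)/(1 - P_c)$, with chance agreement from the two
maps' marginal class proportions.

Scenarios are data, not code: YAML files with per-class annual growth
rates (compounded over the horizon), absolute area targets, forbidden
transitions and protected classes. The three packaged scenarios encode the
storylines of fast urban growth (urban land expanding 5.68 %/yr, its
observed rate during a rapid-urbanisation decade), farmland conservation
(urban growth slowed to 1.45 %/yr, the urban-population growth rate;
farmland protected and growing slightly through consolidation of rural
settlement, encoded as +0.07 %/yr; rural settlement declining 1 %/yr) and
ecological conservation (urban growth halted; rural settlement and
industrial/traffic land declining; woodland, grassland and water
protected). Only the two urban rates are prescribed by the storylines; the
remaining rates are package defaults chosen to reproduce the narrative
direction and rough magnitude of each scenario, and users can edit the
YAML freely. Residual area not claimed by rate- or target-constrained
classes is shared among the remaining classes in proportion to their
Markov projection, with protected classes clamped to be non-decreasing and
the slack re-balanced.

The projection matrix is an explicit pipeline input: by default the rules
are the matrix estimated from the two input maps, but a different matrix
(an earlier interval, a blend, or a known ground truth in synthetic
studies) can be supplied in the config. The packaged fixture does exactly
that, supplying its generating matrix, because rare transitions of small
classes on a 10⁴-cell map are routinely sampled as zero and a sampled zero
would spuriously forbid a conversion the scenario needs.

## Habitat quality

Habitat quality combines an intrinsic per-class suitability $H_j$ with
accumulated threat exposure. Four threats are parameterised by default —
farmland (6 km maximum influence distance, weight 0.6, exponential decay),
urban land (10 km, 0.9, exponential), rural residential land (8 km, 0.7,
exponential) and industrial/traffic land (12 km, 1.0, linear). Degradation
at cell $x$ of class $j$ is

$$D_x = \sum_r \sum_y \frac{w_r}{\sum_r w_r}\, r_y\, i_r(d_{xy})\,
\beta_x\, S_{jr},$$

with $r_y$ binary source presence (no threat-intensity rasters are
assumed), $i_r$ the decay kernel, $\beta_x$ an optional accessibility grid
defaulting to 1, and $S_{jr}$ the sensitivity of class $j$ to threat $r$.
Weights are normalised by their sum, so only ratios matter. Decay is
linear, $1 - d/d_{max}$ clamped at zero, or exponential,
$\exp(-2.99\,d/d_{max})$ truncated at $d_{max}$ — the conventional InVEST
kernel, with the constant configurable. The source material prints the
same expression for both decay kinds, an apparent typesetting duplication,
so the exponential form here follows the standard kernel and no claim is
made that it reproduces any specific published figure. A source cell
contributes to its own degradation with full impact ($d = 0$), which only
matters for classes that are both threat and habitat (farmland).

The implementation convolves each threat's source mask with its decay
kernel, truncated at $d_{max}$ (beyond which the impact is zero under both
kernels); tests verify it against the literal double sum over all
cell/source pairs to machine precision.

Quality is the half-saturation transform
$Q_x = H_j\, k^z / (D_x^z + k^z)$ with $z = 2.5$ by default and $k$ "half
the maximum degradation". Two anchor identities pin the transform:
$Q = H_j$ where $D = 0$, and $Q = H_j/2$ where $D = k$. Built-up classes
have $H_j = 0$ and score zero everywhere. When several maps of one study
are compared (a baseline and scenario projections), $k$ is computed once
from the baseline and reused, so all maps share one transform; whether to
recompute $k$ per map is genuinely ambiguous in the method's common usage,
and comparability argues for a shared constant. If no degradation exists
anywhere, $k$ falls back to 0.5 with a warning.

Quality is graded into five equal intervals — V (worst, 0–0.2), IV
(0.2–0.4), III (0.4–0.6), II (0.6–0.8), I (best, 0.8–1) — with
lower-inclusive bins and the top bin closed at 1; bin edges are compared
with `findInterval()` so values lying exactly on an edge classify
predictably. `change_matrix()` cross-tabulates two grade maps (or two
land-use maps) into a km² change matrix, and `changed_fraction()` reports
each direction's share of the changed area.

## Synthetic landscapes and what tests show

The generator replaces the proprietary 1-km national rasters the method is
usually applied to, so every stage is exercisable at desk scale with known
ground truth:

* `generate_landscape()` thresholds a Gaussian-smoothed noise field by
  rank, giving exact class fractions and controllable spatial clustering
  (`autocorr` is the Gaussian sd in cells; 0 gives independent labels).
  The default composition mirrors a farmland-dominated river-basin
  landscape (68% farmland, 11% rural settlement, 3% urban).
* `generate_drivers()` draws class-conditional Gaussian drivers whose
  implied logistic model has exactly the requested coefficients (Gaussian
  discriminant/logistic duality); optional measurement noise attenuates
  them.
* `evolve_landscape()` resamples each cell independently from its
  transition row, so Markov estimation is exactly identifiable; spatial
  realism in projections is the CA engine's job, not the fixture's.
* `make_fixture("huaihe-mini")` writes a complete 100 × 100 pipeline input
  set (two dated maps, drivers, parameter tables, three scenario YAMLs, a
  config) that runs end-to-end in seconds.

These landscapes are single-realisation random fields: they do not carry
real topography, road networks, or the spatial coherence of actual
land-cover products, and the drivers are abstract layers rather than
elevation or climate surfaces. Passing tests therefore demonstrate the
correctness of the algorithms and their contracts (conservation,
recovery of known parameters, constraint satisfaction, oracle
equivalence), not the realism of any particular projection. Published
headline numbers tied to specific regional rasters are not reproducible
from synthetic data and are not targeted.

Problem sizes used by the test suite and the acceptance script — 40 × 40
landscapes for oracle equivalence, 100 × 100 for allocation contracts and
the packaged fixture, 200 × 200 for Markov recovery — were chosen as the
smallest sizes at which the statistical recovery tolerances (5% relative
on transition probabilities, 10% on logistic coefficients) are comfortably
identifiable.

## Numerical choices and edge cases

* Distances are exact Euclidean centre-to-centre, via a separable
  squared-distance transform (tested against brute force); nodata cells
  are neither sources nor targets.
* Demand rounding uses largest remainders, so cell totals are conserved
  exactly and per-class rounding error is below one cell.
* Row normalisation of the transition matrix is exact to floating point;
  absent classes get identity rows rather than 0/0.
* The 5 × 5 neighbourhood filter truncates at edges and renormalises by
  the actual window size.
* All stochastic steps (tie-breaks, subsampling, generators) take explicit
  seeds and restore the caller's RNG state.

## Limitations

Threat effects are additive across threats; synergistic degradation is not
modelled. Accessibility ($\beta_x$) defaults to 1 everywhere unless a grid
is supplied. Suitability fits ignore spatial autocorrelation, which
understates coefficient uncertainty (point estimates are unbiased under
the generator's conditions). The CA allocates whole cells and cannot
represent sub-cell mosaics or fuzzy class boundaries. Only `.asc` raster
I/O is provided; convert other formats externally.
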
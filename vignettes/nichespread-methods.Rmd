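---
title: "Methods: niche model calibration and invasion spread simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche model calibration and invasion spread simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichespread` implements a complete workflow for estimating the
climatically suitable area of an invasive species from presence-only
records and simulating its subsequent spread on a grid. This vignette is
the package's account of the science: the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic test
system can and cannot show.

## The study design the package encodes

The workflow mirrors the standard correlative niche-modeling pipeline used
in invasion biology: native-range occurrence records are cleaned and
spatially thinned; an accessible area *M* (the model calibration extent and
background) is defined by buffering the thinned records; predictors are
screened for collinearity or replaced by principal components fitted on
*M*; a grid of candidate Maxent-style models is evaluated by partial ROC,
omission rates and AICc; selected models are refitted with bootstrap
replicates, binarized, tested against independent records from the invaded
region, combined into consensus maps, trimmed where extrapolation risk is
detected (MOP), and finally handed to a cellular-automaton dispersal model
swept over connectivity and threshold scenarios.

Because the package is exercised entirely on synthetic virtual species, the
whole chain can be validated against known truth: the generator draws
landscapes with a known suitability function, so tests can ask whether the
pipeline *recovers* that truth rather than merely whether it runs.

## Occurrence handling

Cleaning removes records with missing coordinates, exact duplicates
(species + coordinates rounded to 6 decimal places — the natural
definition when "duplicate" is otherwise unspecified), records falling in
no country (at sea) and records whose declared country disagrees with
their location. Countries are represented as an integer-ID raster rather
than polygons; point-in-country tests become cell lookups, which keeps the
synthetic system self-contained while preserving every cleaning rule.

Two thinning schemes define the calibration data sets:

* **Distance thinning** removes records closer than `min_km` (default
  50 km) to another record. The algorithm is greedy on a seeded random
  order: shuffle, scan once, keep any record at least `min_km` from all
  previously kept records. The output always satisfies the pairwise
  constraint, is a subset of the input, is maximal under its scan order,
  and is reproducible per seed. Distances are haversine great-circle
  distances on a 6371-km sphere — adequate at the 50–500 km scales
  involved.
* **Country-density thinning** subsamples over-surveyed countries down to
  explicit per-country target counts (e.g. 30, 6, 5 records reduced to
  6, 2, 2), run after distance thinning. Targets are explicit arguments
  because no closed-form "reference density" rule reproduces such
  reductions unambiguously; the pipeline derives defaults (countries more
  than twice the median count are cut back to the median) only when the
  user supplies none.

## Accessible area and predictors

*M* is rasterized by buffering the thinned records with a great-circle
radius (default 500 km): a cell belongs to *M* iff its **center** is within
the radius of at least one record. Cell-center rasterization is the
unambiguous convention; any-overlap rasterization would differ only along
the buffer boundary.

Predictors enter the models one of two ways:

* **Correlation screening**: variables are examined in a priority order
  (the hook for expert preference) and kept iff their absolute Pearson
  correlation with every previously kept variable over *M* is at most
  `r_max` (default 0.85). Greedy screening is order-dependent by design —
  the priority *is* the user's statement of which variables matter most.
* **PCA**: fitted on the correlation matrix (center + unit variance) over
  *M*'s cells — the defensible default when predictors mix units — then
  projected to the full grid using the same centering, scaling and
  rotation, so scores are comparable between the calibration area and the
  transfer region. Component signs are fixed (largest-magnitude loading
  positive) so results are deterministic. The number of retained
  components defaults to the smallest number explaining 95% of variance
  (minimum 2), and can be pinned explicitly.

## The suitability model

The core model is a Maxent-style Gibbs density over the background cells
of *M*. Predictors are rescaled to $[0,1]$ by their background ranges and
expanded into feature classes `l` (linear), `q` (quadratic), `p` (pairwise
products), `t` (step functions at 10 equally spaced knots) and `h`
(forward hinge ramps at 20 equally spaced knots). Weights $\lambda$
minimize the convex objective

$$-\frac{1}{n}\sum_{i \in \text{pres}} \lambda^\top f_i
  + \log \sum_{b \in \text{bg}} e^{\lambda^\top f_b}
  + \sum_j \beta_j |\lambda_j|,$$

with per-feature penalties
$\beta_j = rm \cdot c_{\text{class}} \cdot \mathrm{sd}_j(\text{bg}) / \sqrt{n}$
and class coefficients $c_l = c_q = 0.05$, $c_p = 0.1$, $c_t = 1.0$,
$c_h = 0.5$. The regularization multiplier $rm$ is the single complexity
knob. These coefficients are a fixed, transparent rule of this package; no
attempt is made to reproduce any particular Maxent release's versioned
regularization tables, and bit-compatibility with Maxent is explicitly a
non-goal.

Optimization is accelerated proximal gradient descent (FISTA with restart
and backtracking), started from zero weights, stopping when the objective
decreases by less than $10^{-6}$ (cap: 10,000 iterations, which is an
error, not a silent return). Soft thresholding produces exact zeros, so
"number of parameters" for AICc is simply the count of nonzero weights.
Because the objective is convex the optimum is unique up to directions the
penalty cannot distinguish; the deterministic start makes fits exactly
reproducible.

One consequence of the smallness of $\beta$ for `l`/`q` features deserves
note: the linear and quadratic features of one variable are strongly
correlated, so a null fit (presences carrying no signal) can show
moderately large *cancelling* coefficient pairs even though the fitted
density stays essentially uniform. Null behaviour is therefore asserted at
the density level (entropy within 1% of $\ln N$), not the coefficient
level.

Outputs: `raw` is the density normalized to sum to 1 over the calibration
background; `cloglog` is $1 - \exp(-e^{H}\cdot\text{raw})$ with $H$ the
entropy of the fitted background distribution (for the uniform model every
cell gets $1 - e^{-1} \approx 0.632$). Transfers support the three
conventional extrapolation modes: `E` (free), `EC` (variables clamped to
calibration ranges first) and `NE` (out-of-range cells become nodata; the
conservative reading, since those cells are later deleted by MOP anyway).

## Candidate evaluation and selection

The candidate grid crosses every predictor subset of size ≥ 2 with the
regularization multipliers (canonically 0.10, 0.25, 0.50, 0.75, 1, 2, 3,
4, 5, 6) and eight feature-class sets (`lq`, `lp`, `lqp`, `qp`, `q`,
`lqpt`, `lqpth`, `lqph`): with 6 raw variables that is
$57 \times 10 \times 8 = 4{,}560$ candidates, with 4 components
$11 \times 10 \times 8 = 880$. The subset floor of two variables is the
arithmetic that reproduces those totals.

Records are split `k = 5` times into random 50/50 calibration/testing
halves. Each split is a separate **calibration process**: statistics and
selection are per process, not averaged — some processes may select models
while others select none, which is the expected behaviour, not a failure
mode. (The omission statistic's null expectation is slightly *above* E by
an order-statistic argument — the threshold is the
$\lfloor E n\rfloor$-th ascending calibration value, so a fresh test
sample falls below it with probability about
$(\lfloor E n\rfloor + 1)/(n + 1)$ — so averaging across processes would
sit right at the acceptance boundary about half the time, while
per-process selection succeeds in at least one process with high
probability.)

Per process and candidate:

* **Partial ROC.** The curve of sensitivity versus
  proportion-of-area-predicted-present is restricted to the band
  sensitivity ≥ 1 − E (E = 5%), and the area under it is compared with the
  1:1 random line over the same band; 500 bootstrap resamples of half the
  test records give a ratio distribution, and p is the fraction of ratios
  ≤ 1. Sensitivity along the curve is estimated by a *linearly
  interpolated* sample CDF with plotting positions $(i + 1/2)/(m + 1)$,
  anchored at the landscape extremes, rather than the raw step ECDF. This
  is a deliberate design choice: with few test records relative to $1/E$
  the step ECDF collapses the band to "above the bootstrap-sample
  minimum", which inflates every ratio above 1 and destroys the test's
  size (measured type-I error above 0.9 at 20 test records). The smoothed
  estimator restores the nominal size (measured ≈ 0.07 at α = 0.05 in a
  200-replicate null study) while leaving power on separable fixtures
  untouched. With the full band (E = 1) the statistic reduces to the
  ordinary trapezoid AUC over one half.
* **Omission rate** at the E-threshold: the fraction of testing-half
  suitabilities strictly below the
  $\lfloor E n\rfloor$-th (0-based) ascending calibration-half
  suitability. Strict inequality is consistent with the ≥-threshold
  suitability rule used in binarization.
* **AICc** from the refit on *all* records: the log-likelihood of the
  occurrence cells under raw output normalized over the landscape, with
  $k$ = nonzero weights; $2k - 2\ln L + 2k(k+1)/(n-k-1)$, infinite when
  $n - k - 1 \le 0$ or when an occurrence cell has zero suitability.

Selection per process: keep candidates with p < α (0.05) *and* omission
< E; recompute ΔAICc within that filtered set; keep ΔAICc ≤ 2. The ΔAICc
recomputation after filtering follows the workflow's "selected from those
that were statistically significant and had low omission" reading.

Selected configurations are refitted on all records with 10 bootstrap
replicates (presences resampled with replacement, background fixed). Each
replicate is binarized at the modified least-presence threshold
(E = 5%), tested against the independent invaded-region records (a
replicate must predict *every* independent record suitable to proceed),
and the survivors are combined two ways: the median of the per-candidate
median cloglog layers (continuous consensus) and the cellwise sum of the
binary maps (agreement count).

## MOP and extrapolation risk

Mobility-oriented parity measures, for every projection cell, the mean
Euclidean distance (on variables standardized by the reference range) to
the nearest 5% of the calibration cloud, rescaled to a similarity in
$[0,1]$. The strict mask flags cells where any variable leaves the
calibration range. Flagged cells are deleted from binary predictions
before interpretation, and are treated as nodata — unsuitable *and*
non-traversable — in the dispersal stage. Deleting strict-extrapolation
cells only (not low-similarity cells) is the implemented reading; a
`similarity_floor` argument covers the stricter alternative. Distances are
computed exhaustively against the reference cloud (with a seeded 10,000-
cell subsample cap for very large references), trading speed for
exactness at the scales this package targets.

## Dispersal simulation

The automaton is deliberately minimal: a cell is occupied or not; at each
step every suitable cell within Chebyshev distance `d` (a generalized
Moore neighborhood — `d` is a radius in cells, the only reading that makes
the ladder 1, 2, 4, 8, 10, 12 a distance ladder) of an occupied cell
becomes occupied; occupation is permanent. There is no carrying capacity,
no stochastic colonization, no long-distance jumps — those belong to
parameter-hungry contagion models that presence-only data cannot inform.
Under these rules the steady state is exactly graph reachability: the
connected components (radius-`d` adjacency among suitable cells)
containing the seeds. The test suite verifies this equivalence against an
independent igraph flood-fill oracle, cell for cell.

The scenario sweep runs every combination of connectivity radius
(1, 2, 4, 8, 10, 12) and binarization level (10 equidistant values from 3%
to 10%, i.e. $E_i = 0.03 + 0.07i/9$), 200 steps each (far beyond any
convergence time on these grids), and reports the percentage of scenarios
in which each cell was reached — 100 means reached always, 0 never.

## The synthetic study system

`generate_env()` draws spatially autocorrelated surfaces (sinusoid
mixtures plus Gaussian-smoothed noise, standardized per layer); the
`smoothness` parameter is the smoothing length scale in cells (default 4,
giving lag-1 autocorrelation ≈ 0.9, the right order for coarse bioclimatic
layers). The virtual species' truth is
$\text{logistic}(\sum_j a_j x_j + b_j x_j^2 + c)$ — unimodal in each
predictor for $b_j < 0$, so an `lq`-class model can represent it exactly.
Defaults: a 60×60 grid of 1/6° cells, 3 predictors, 200 presence records,
5 independent records. Records are sampled with probability proportional
to truth × per-country sampling weight (emulating uneven survey effort)
and jittered uniformly within their cell so sub-cell geometry (e.g.
distance thinning) is exercised; "countries" are a seeded Voronoi
partition with a configurable sea fraction. Everything is bit-reproducible
per seed, with independent substreams per pipeline stage derived from one
master seed.

`make_invasion_fixture()` builds a two-band landscape whose true response
is an exact quadratic of the first predictor: two vertical suitable bands
separated by an unsuitable gap, giving a *known* bridging radius (the
Chebyshev distance between the bands' facing columns, 8 cells by default).
Below that radius the automaton must stay in the seeded band; at or above
it, the far band must be colonized — a sharp, fully predictable
end-to-end check on the dispersal stage.

### What the synthetic system does not show

The generator produces smooth, stationary, low-dimensional landscapes with
exactly the response family the model class can express. Passing tests
therefore demonstrate that the machinery is correct and that the pipeline
recovers truth *when its assumptions hold* — they say nothing about
performance under real-data pathologies: non-stationary sampling bias,
niche truncation at range edges, predictor measurement artifacts,
dispersal barriers unrelated to climate, or the covariance structure of
real bioclimatic archives. Real geographic results (continental suitable
areas, specific invasion routes, richness overlays for real taxa) depend
on external occurrence and climate archives and are out of scope by
design; the property-based checks here are the substitute.

## Numerical choices and degenerate inputs

* Grids are row-major from the upper-left corner; cell centers at
  `origin + (index − 0.5)·cell_size`; all point-in-cell tests use cell
  centers; presence–absence binning uses half-open
  `[west, east) × [south, north)` intervals so grid-line points count
  once.
* Raster I/O uses the plain-text ESRI ASCII grid format with 17
  significant digits, so doubles round-trip exactly and every output is
  inspectable with a text editor or any GIS.
* A constant predictor over the mask is an error naming the variable
  (correlation and standardized PCA are undefined), not a silent drop.
* A constant landscape in partial ROC returns ratio 1, p 1, flagged
  degenerate.
* Bootstrap p-values can be exactly 0, so "impossible" significance
  levels for forcing an empty selection must be α = 0.
* Unsuitable seed cells are dropped from the automaton with a warning;
  losing all seeds is an error.
* The fitting-problem sizes used in tests and the acceptance analysis
  (60×60 grids, 200 presences, reduced candidate grids of 2–3 multipliers
  × 2 class sets for the recovery study, 80 candidates per scheme in the
  analysis scripts) are the package's desk-scale choices: large enough
  for the statistical properties being asserted, small enough to iterate
  on. The enumeration arithmetic of the full 4,560/880-candidate grid is
  asserted directly.

## Known limitations

* The regularization-coefficient rule is fixed and transparent but not
  Maxent-compatible; absolute AICc values are comparable within this
  package only.
* Country-density thinning needs explicit targets to be exactly
  reproducible; the automatic fallback (cut countries above twice the
  median back to the median) is a heuristic.
* MOP's brute-force distances scale as reference × projection cells;
  beyond the subsample cap the statistic becomes a seeded approximation.
* The dispersal model's determinism means occupancy percentages express
  scenario disagreement, not colonization probability.
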
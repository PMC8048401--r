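---
title: "Methods: standardized home-range estimation in homerange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized home-range estimation in homerange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

A *home range* is the area an animal traverses in its normal activities.
Telemetry studies operationalize it with an estimator evaluated at an
*isopleth level*: a fraction (conventionally 95%) of either the located
points (geometric estimators) or of the *utilization distribution* (UD),
the two-dimensional relative frequency distribution of the animal's
positions (probabilistic estimators). This package implements one common
contract for both families, so that several estimators can be swapped in
and out of the same analysis and their sensitivity compared:

* every estimate carries `levels`, an EPSG `crs`, the source `data`, and
  isopleth polygons with areas (`hr_area()`, `hr_isopleths()`,
  `hr_overlap()`);
* probabilistic estimates additionally carry a template raster and the UD
  itself (`hr_ud()`, `hr_cud()`).

Everything operates on projected planar coordinates in metres; geographic
(longitude/latitude) input must be projected first (`read_tracks()` does
this for the Movebank dialect; EPSG:5070 and WGS84 UTM zones are
supported from closed-form projection equations).

# Geometric estimators

**Minimum convex polygon (MCP).** For level $a$, fixes are ranked by
Euclidean distance to the arithmetic-mean centroid and only those within
the $a$-quantile of distances are kept; the estimate is their convex
hull. The quantile uses linear interpolation (R's type-7 convention) —
the choice matters at small $n$ and is fixed so results are reproducible
across software. Degenerate retained sets (fewer than three distinct
non-collinear fixes) raise an error naming the level.

**Local convex hulls (k-LoCoH).** Each fix forms a hull together with its
$n-1$ nearest neighbours ($n$ points per hull, focal point included; the
square-root heuristic $n = \lceil\sqrt{N}\rceil$ is available as
`n = "auto"`). Hulls are accumulated in order of increasing area — ties
broken by fix index so output is deterministic — and the level-$a$
isopleth is the first running union covering at least $\lceil a N\rceil$
fixes, with boundary-inclusive point counting. Only k-LoCoH is
implemented; the adaptive (a-) and radius (r-) variants are out of scope.

# Continuous-time movement models

Probabilistic estimation of the *range distribution* from modern GPS data
must deal with autocorrelation. Three stationary, isotropic models are
fitted by exact maximum likelihood:

| model | parameters | position autocovariance at lag $h$ |
|---|---|---|
| iid | $\mu, \sigma^2$ | $\sigma^2\,[h = 0]$ |
| OU | $\mu, \sigma^2, \tau_p$ | $\sigma^2 e^{-h/\tau_p}$ |
| OUF | $\mu, \sigma^2, \tau_p, \tau_v$ | $\sigma^2\frac{\tau_p e^{-h/\tau_p} - \tau_v e^{-h/\tau_v}}{\tau_p - \tau_v}$ |

$\tau_p$ is the positional autocorrelation timescale (range residency);
the OUF model adds a velocity timescale $\tau_v < \tau_p$ and is realized
as the CAR(2) position–velocity state space whose characteristic roots
are $-1/\tau_p$ and $-1/\tau_v$; its exact discretization is used both
for simulation (no Euler error) and for likelihood evaluation. GPS error
enters as independent per-fix noise with per-axis variance
$(\mathrm{uere}\cdot\mathrm{HDOP})^2/2$, so `uere` is the two-dimensional
RMS error in metres per unit HDOP; fixes without HDOP use HDOP = 1, and
`uere` is always supplied (e.g. from receiver calibration), never
estimated. The likelihood is evaluated in $O(n)$ by Kalman filtering (in
compiled code), one axis at a time with shared parameters; the test suite
verifies it against a dense multivariate-normal log-density built from
the autocovariance functions, to $10^{-8}$.

Fitting notes:

* the stationary mean $\mu$ is profiled as the sample mean and counted as
  two parameters in the AICc parameter totals (iid 3, OU 4, OUF 5);
* positive parameters are optimized on the log scale by Nelder–Mead with
  a relative tolerance of $10^{-8}$ and three starts: an empirical
  variogram initialization (sill $\to\sigma^2$; lag reaching 63% of the
  sill $\to\tau_p$; $\tau_v$ starts at $\tau_p/10$) plus the timescales
  scaled by 0.1 and 10;
* `model = "auto"` fits all three and returns the lowest AICc. OUF nests
  OU, so on genuinely OU data "auto" occasionally prefers OUF with a tiny
  $\tau_v$; the positional parameters remain close in that case;
* the *effective sample size for area estimation* is
  $\hat n = n / \bigl(1 + 2\sum_{k\ge 1}(1 - k/n)\,\rho(k\bar{\Delta t})\bigr)$,
  with $\rho$ the fitted normalized position ACF, $\bar{\Delta t}$ the
  median sampling interval, and the sum truncated where $\rho < 10^{-3}$.
  For an iid fit $\hat n = n$ exactly. This is the standard
  autocorrelation-inflation formula; other implementations use different
  effective-sample-size constructions, so aKDE areas are comparable
  across software only to within several percent.

# Probabilistic estimators

**Template raster.** UDs are evaluated at the cell centres of a square-cell
grid. By default the extent is the bounding box of the fixes buffered on
every side by half the larger span, with 200 columns; all tolerances
quoted in the tests refer to this resolution. The buffer keeps truncated
kernel mass below $10^{-6}$ for the bandwidths that arise in practice.

**KDE.** Equally weighted product-Gaussian kernels with the bivariate
normal reference ("ad hoc") bandwidth $h_i = s_i\,n^{-1/6}$ per axis,
where $s_i$ is the maximum-likelihood (divisor $n$) standard deviation.
Kernels are truncated at five bandwidths. The UD is stored as cell
probability *masses* normalized to total 1 (divide by cell area for a
density).

**Cumulative UD and isopleths.** Cells ranked by density receive the
cumulative mass of all cells at least as dense (tied densities share the
larger value), giving the cumulative UD in $(0, 1]$. Isopleths are
marching-squares contours of this *cumulative* surface (holes preserved),
so polygon areas match the mass interpretation directly; the smallest
cell set holding a target mass is used wherever a discrete mask is needed
(e.g. the PHR overlap index). Contour areas agree with cell counting to a
few percent at the default grid.

**aKDE.** The reference rule with $n$ replaced by the effective sample
size: $h_i^2 = s_i^2\,\frac{\hat\sigma^2}{\bar{s}^2}\,\hat n^{-1/3}$,
i.e. the fitted isotropic variance distributed over axes proportionally
to the per-axis sample variances (so an iid fit reproduces the KDE
bandwidth exactly). With an error model, the per-fix error variance is
added to $h_i^2$ fix-wise. Because convolving data with a kernel inflates
the UD variance by $h_i^2$, reported isopleths carry a first-order *area
debias*: polygons are shrunk about the UD centre so areas scale by
$\sqrt{\prod_i s_i^2/(s_i^2 + \overline{h_i^2})}$. Without it, areas at
effective sample sizes of order $10^2$ would be biased upward by roughly
$1 + \hat n^{-1/3}$ (20%+); with it, the 95% area on simulated
Ornstein–Uhlenbeck tracks recovers the bivariate-normal closed form
$-2\pi\sigma^2\ln(0.05)$ to within sampling noise. The correction is
exact for Gaussian UDs and first-order otherwise; a consequence is that
an aKDE with an iid fit equals the KDE area divided by $1 + n^{-1/3}$
rather than matching it identically.

Area confidence intervals use a chi-squared sampling model for the
variance: $\mathrm{bound} = \hat A\,\nu/\chi^2_{\nu,q}$ with
$\nu = 2\hat n$ and $q \in \{0.975, 0.025\}$ for the lower/upper 95%
bounds. This is a deliberate simplification of the reference ecosystem's
CI construction and is labelled as such.

# Overlap indices

`hr_overlap(a, b, type)` implements the standard catalogue: the
directional polygon fraction HR
($\mathrm{area}(A_l\cap B_l)/\mathrm{area}(A_l)$), PHR (mass of $A$'s UD
inside $B$'s level mask), VI ($\sum\min(u_A, u_B)$), BA
($\sum\sqrt{u_A u_B}$), UDOI
($\mathrm{area}(A_l\cap B_l)\sum u_A u_B / \mathrm{cellarea}$), and the
Hellinger-style distance HD defined here as $2(1-\mathrm{BA})$ (note:
some authors use $\sqrt{2(1-\mathrm{BA})}$; HD is therefore 2, its
maximum, for disjoint UDs). HR and PHR may change under argument swap;
VI, BA, UDOI and HD are symmetric. When two UDs live on different
template rasters, the second is resampled onto the first's raster by
cell-centre sampling and renormalized — documented here because grid
alignment is otherwise unspecified; symmetric indices are exactly
symmetric only on a shared raster. `conditional = TRUE` truncates each UD
to its own level mask (renormalized) first.

# Grouped workflows

`group_tracks()` nests a relocation table by arbitrary keys;
`batch_home_ranges()` maps any subset of the five standard estimator
specifications (`hr_mcp`, `hr_kde`, `hr_locoh` with $n$ = "auto",
`hr_akde`, `hr_akde_error`) over the groups and flattens everything to
one long table of (keys, estimator, level, what, area). Failures in one
group (degenerate geometry, non-convergence) become error rows carrying
the message; they never abort the batch, and summaries skip them with a
note. `weekly_home_ranges()` floors timestamps to the week (Monday start
by default, configurable — lubridate's default is Sunday, so this is
stated explicitly) and keeps only weeks with strictly more than 10 fixes
(`min_n = 11`), matching common practice of discarding data-sparse
weeks. Sex comparisons average *natural-log* areas per animal, with
two-sided 95% t-intervals on $n-1$ df and a Welch interval for the
male–female difference.

# Synthetic data: what it emulates, what it does not

`simulate_track()` draws exact stationary samples of the three models
(OU via the exact AR(1) transition, OUF via the exact CAR(2)
discretization), optionally adding GPS error scaled by HDOP values drawn
from a constant or log-normal law. `make_fixture_suite()` writes a
6-animal, 2-sex population — per-animal OU parameters drawn from a
log-normal around $\sigma^2 = 10^6\,\mathrm{m}^2$ (home ranges of a few
km², mid-size carnivore scale) and $\tau_p = 6$ h, hourly fixes, HDOP
log-normal around 2, `uere` 1.67 m — in both CSV dialects plus a
thresholded-noise binary landscape with a 50% forest fraction. These
defaults emulate the structure of multi-animal GPS studies: positive
autocorrelation at the sampling interval, heteroscedastic location error,
unbalanced durations are *not* emulated, and neither are habitat-biased
movement, behavioural switching, fix failures, nor irregular duty
cycles. Passing tests on these data therefore demonstrates correctness
of the estimators under their own assumptions, not robustness to every
field-data pathology.

Every stochastic routine takes an explicit `seed` and restores the
caller's RNG state; identical seeds give bit-identical tracks.

# Numerical choices and edge cases

* Quantiles: type 7 everywhere (MCP peeling, landscape threshold).
* Duplicate timestamps: first fix kept, rest dropped with a warning.
* Resampling: windows anchored at the first fix's floor to the interval;
  the first fix at most `tolerance` *after* the window anchor is kept; no
  interpolation ever.
* Kernel evaluation truncated at $5h$ (mass error $<10^{-6}$).
* Polygon boolean operations use the Clipper library (via polyclip),
  which snaps coordinates to an integer grain near $10^{-9}$ relative;
  self-overlap is special-cased to be exactly 1, and containment checks
  in the tests use intersection areas rather than vertex membership.
* Geometry ties: LoCoH hull ordering ties break by fix index;
  nearest-neighbour ties by index; cumulative-UD ties share the larger
  cumulative value.
* Optimizer non-convergence raises a condition carrying the best
  parameters found; batch workflows convert it to an error row.
* Rasters are exchanged as ESRI ASCII grids (`.asc`), a plain-text
  single-band format readable by standard GIS tooling; the EPSG code is
  supplied on read since the format carries no CRS.

Test problem sizes were chosen to make every property measurable in
seconds on one core: closed-form Gaussian recovery uses 10,000 fixes
(KDE) and 1,000 (aKDE on OU with $\Delta t = 10$ min, $\tau_p = 1$ h);
oracle comparisons use $n \le 50$ (dense likelihood) and 100 random
point sets (hull areas); model-selection specificity uses 20 replicates
of 500 fixes.

# Known limitations

* Isotropic covariance only; anisotropic, drift, and periodic movement
  models are out of scope, as are occurrence-distribution estimators
  (Brownian bridges, kriging).
* The effective-sample-size and CI constructions are documented
  approximations, not reproductions of any other package's internals;
  absolute aKDE areas can differ across software at the several-percent
  level.
* Only the reference KDE bandwidth is provided (no cross-validation or
  plug-in selectors); no boundary-corrected kernels.
* Projection support covers CONUS Albers (EPSG:5070) and WGS84 UTM; the
  inverse direction (writing longitude/latitude) is Albers-only.
* LoCoH is k-LoCoH only, and its neighbour count convention ($n$ points
  per hull *including* the focal point) may differ by one from other
  software.
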
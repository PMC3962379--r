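---
title: "Spatial early-warning signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial early-warning signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Ecosystems with alternative stable states — drylands, shallow lakes, mussel
beds — can shift abruptly when a slowly changing driver (rainfall, grazing,
nutrient load) crosses a tipping point. Near such a bifurcation the dominant
restoring force weakens ("critical slowing down"), and that weakening leaves
fingerprints in spatial snapshots taken before the shift: neighbouring sites
become more alike, fluctuations grow and become asymmetric, spectral power
drifts to long wavelengths, and the architecture of vegetation patches
reorganises. `spatialews` computes these indicators from 2D raster
snapshots, attaches null models that say when a value is more than chance,
quantifies trends along a degradation gradient, and bundles three classic
stochastic simulators that generate the canonical test gradients.

This vignette records the package's modelling conventions and the design
decisions taken where the methodology is genuinely open. It states no
empirical result that the test suite does not itself compute.

## Indicators and their conventions

**Moments.** Spatial variance is the second moment about the spatial mean
and skewness the third central moment over the standard deviation cubed,
both with *population* (biased, 1/N) estimators: the literature of this
field uses them, they are scale-free for trend detection, and they make the
moment-conservation property of the reshuffle null exact. Skewness of a
constant grid is reported as an explicit undefined flag, never as 0 — a zero
would fabricate symmetry information.

**Moran's I.** The near-neighbour spatial correlation
\[
I \;=\; \frac{N}{\sum_{ij} w_{ij}} \,
\frac{\sum_{ij} w_{ij}\,(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},
\]
with binary weights selecting cell pairs at a given lag. Lag is a Manhattan
ring for rook weights and a Chebyshev ring for queen weights; lag-1 rook is
the headline statistic. Defaults: open boundaries for field data, periodic
for grids produced by the built-in simulators (matching their topology).
The normalisation allows values slightly outside [-1, 1] on small grids, a
known property of the weights convention.

**Spectra.** The periodogram is the squared magnitude of the 2D DFT of the
mean-removed field, divided by the cell count N, so the unscaled ordinates
obey Parseval's identity (total = N·variance); dividing further by
N·variance gives the scaled spectrum (total 1) used everywhere — it makes
snapshots of different variance comparable. Squared magnitude (rather than
raw magnitude) is used so that Parseval and the chi-squared band theory
hold; for peak detection the two differ only by a monotone rescaling. The
r-spectrum sums ordinates over unit-width rings of radial wavenumber, the
theta-spectrum over equal sectors of [0°, 180°) (12 by default; the point
symmetry of real-input spectra makes the other half redundant). Both are
exact partitions of the retained power. Non-square grids bin on normalised
wavenumbers. No tapering is applied by default — the simulators are
periodic so none is needed; a taper only matters for strongly non-periodic
empirical scenes and can be applied upstream.

**Reddening.** The reddening index is the fraction of total spectral power
in rings at or below 20% of the Nyquist ring. Any fixed low-wavenumber
fraction works for trend detection; 0.2 keeps the band well inside the
resolved range for grids of 50 cells and up.

## Classifying periodicity and isotropy

The decision flow needs binary calls from continuous spectra, and the
operational rules deserve care because ring *sums* are misleading: the
number of ordinates in a ring grows with its radius, so summed white-noise
spectra *rise* with wavenumber. Classification therefore works on the mean
power per ordinate. A snapshot is called **periodic** when the ring with
the largest mean power

* sits at wavenumber ≥ 3 (at least three pattern repetitions across the
  extent — fewer cannot meaningfully be called a periodic pattern),
* exceeds its null-band upper limit, and
* is *prominent*: at least twice the mean power of every ring in the
  long-wavelength baseline (wavenumbers up to half the peak).

The prominence condition separates a discrete spectral peak from the broad
low-wavenumber excess of reddened-but-aperiodic data, which otherwise
produces spurious interior maxima by sampling jitter. Null bands are
analytic chi-squared bands by default, with the per-ring level
Bonferroni-tightened across rings so the *family-wise* false-positive rate
of the periodicity call is held at the stated level; with ~30 rings, a
pointwise 97.5th-percentile rule would flag over half of all white-noise
grids. The calibration tests hold the realised false-positive rate below
5% plus Monte-Carlo slack on 500 white-noise grids.

A snapshot is called **anisotropic** when some sector both exceeds its
null band and carries more than twice the mean sector power. The second
condition matters: any patterned field beats a white-noise band in some
sector because realised patterns fluctuate between sectors far more than
white noise, even with no preferred orientation; requiring concentration
(a sector with at least double the average power) matches what "a strong
amplitude at a specific orientation" means in practice. Banded patterns
put essentially all power in one sector and pass easily.

The router applies these calls per snapshot and takes a majority vote
across the gradient (per-snapshot detail is kept in the report, and
conflicts are flagged). Patchiness is decided by a two-phase criterion:
occupancy data are patchy by definition; continuous data are patchy when
the pixel histogram is bimodal in a majority of snapshots.

## Null models

* **Reshuffling** permutes cell values uniformly: it removes all spatial
  structure while conserving the value multiset — hence spatial variance
  and skewness exactly. It is the null for correlation, spectra and patch
  structure, and deliberately *cannot* test variance/skewness (requesting
  that combination warns and returns a degenerate band).
* **Gaussian surrogates** draw iid normals with the original grid's mean
  and variance: a null for skewness, correlation and spectra of continuous
  data; refused as a variance null (variance is matched by construction)
  and refused on occupancy data.
* **Coarse-graining test** for variance and skewness: the statistic of the
  coarse-grained observed grid is compared against coarse-grained
  *reshuffles*. Averaging sub-blocks of a random matrix shrinks
  variability toward sigma²/sub², while genuine spatial structure
  survives aggregation, so structured grids land above the band. Block
  size 5 follows the worked analysis convention; the report carries a
  reminder that the block size can affect indicator behaviour.
* **Chi-squared spectral bands.** For a structureless grid, a conjugate
  pair of periodogram ordinates contributes weight 2 and 2 degrees of
  freedom and a self-conjugate (real) ordinate weight 1 and 1 df, so a
  bin holding m ordinates has summed power distributed as a scaled
  chi-squared with m df. On the scaled-power convention the bin sum is
  approximately chi-squared(m)/(N-1). This df bookkeeping is
  cross-validated in the tests against the reshuffle ensemble and against
  empirical coverage on white noise (95% ± 3 percentage points).

Bands are empirical (or analytic) quantile bands, not mean ± z·sd —
indicator nulls are visibly skewed on small grids. Defaults are 200
surrogates and a 95% level.

## Patch analysis

Patches are connected components of foreground cells, 4-connectivity by
default (matching the simulators' interaction neighbourhood), with optional
8-connectivity and periodic wrap merging. Patch-size distributions are
fitted by *discrete* maximum likelihood on integer sizes — patch sizes are
cell counts, and continuous approximations bias the exponent. Families:
pure power law (Hurwitz-zeta normalisation), power law with exponential
cutoff (normalised by direct convergent summation), discrete exponential
(geometric; closed-form MLE) and an integer-discretised lognormal (CDF
differences). All families are fitted to the identical tail (sizes ≥
xmin; default xmin = 1, with a Clauset-style KS-minimising scan available)
and ranked by AIC, which handles the non-nested family set uniformly. A
least-squares fit of the log inverse-cumulative is reported for comparison
only, never for ranking.

Morphology of periodic patterns is read from the pixel-value histogram:
skewness beyond ±0.2 calls spots (+) or gaps (−); within the threshold, a
bimodality coefficient (skewness² + 1)/kurtosis above 5/9 calls labyrinth,
otherwise homogeneous. The 0.2 threshold is calibrated so that white noise
classifies as homogeneous in at least 95% of replicates; the bimodality
coefficient is a deterministic, moment-based two-component criterion (5/9
is the uniform distribution's value, the usual reference point).

## Trends

Indicator trajectories along a gradient are summarised by Kendall's tau-b
(tie-corrected — discrete-data indicators tie frequently) or Pearson's r,
with p-values from `stats::cor.test` (exact for small untied samples,
tie-corrected asymptotic otherwise). Stress values are used when given and
ranks otherwise; tau is rank-based, so the two agree on monotone gradients.
Undefined indicator values are excluded pairwise with the valid count
reported.

## The three simulators

The simulators generate the package's study gradients: ten driver values,
unequally spaced and denser near the transition, with the lattice state
carried from one driver value to the next (as under a slowly drifting
driver) and a relaxation period before each snapshot. All are deterministic
under a fixed seed, with periodic boundaries and 4-neighbour coupling.

**Local positive feedback (data set 1)** — continuous biomass V coupled to
water W on each site:
dW = R − r_w W − λWV + D_w ∇²W,
dV = ρWV(1 − V/K) − cV²/(V² + h²) + D_v ∇²V + σV dξ.
Logistic growth at a water-set rate, saturating grazing loss, diffusive
exchange of both biomass and water, multiplicative noise. The non-spatial
skeleton is the grazed-logistic fold: with the defaults (r_w = 1,
λ = 0.12, ρ = 0.7, K = 10, c = 2, h² = 0.25, D_v = D_w = 0.05, σ = 0.05)
the vegetated state vanishes near R ≈ 1.75, and the default gradient runs
from R = 3.0 down to 1.85, just short of the fold. Diffusion is kept weak
so the slowing-down signal is not averaged away: with strong mixing, the
modes that feel the softening mode are a vanishing fraction of the
lattice and the variance trend inverts. Multiplicative noise is the
stochasticity model (amplitude configurable); Euler–Maruyama with
dt = 0.1, well inside stability for rates of order one.

**Facilitation cellular automaton (data set 2)** — three states per cell:
vegetated (+), empty (o), degraded (−). Per step: empty cells are
colonised with probability (δρ₊ + (1−δ)q₊)(b − cρ₊)⁺ (global seed rain δ
plus local dispersal, capped by environmental quality b net of global
competition), vegetated cells die (m), empty cells erode to degraded (d),
degraded cells regenerate (r + f·q₊ — the facilitation term, q₊ the
vegetated fraction among 4 neighbours). Defaults m = 0.1, d = 0.2,
r = 0.01, f = 0.9, δ = 0.1, c = 0.3; vegetation collapses near b ≈ 0.2 and
the default gradient runs b = 0.90 → 0.39. Updates are synchronous on the
previous state (reproducible and standard for this family); an
asynchronous mode is available behind a flag, with the global density
refreshed once per sweep. Colonisation is clamped at zero when global
competition exceeds b (a negative rate product is not a probability);
computed probabilities above 1 are a parameterisation error. Note that
*both* facilitation and local dispersal cluster vegetation: a spatially
random arrangement requires f = 0 *and* δ = 1, which is the configuration
the no-local-structure test uses.

**Scale-dependent feedback model (data set 3)** — three PDEs for plant
biomass P, soil water W and surface water O with the standard
parameterisation (c = 10, g_max = 0.05, k₁ = 5, d = 0.25, α = 0.2,
W₀ = 0.2, k₂ = 5, r_w = 0.2, D_P = 0.1, D_W = 0.1, D_O = 100 m²/day).
Vegetation-enhanced infiltration (short-range facilitation) plus fast
surface-water diffusion (long-range competition) is the Turing mechanism.
Explicit Euler with a 5-point Laplacian, dx = 5 m — the emergent
wavelength is ~40–60 m, so a 100-cell grid spans ~8–10 repetitions — and
dt = 0.05 day, safely inside the diffusion stability bound
dx²/(4·max D) = 0.0625 (violating it is a configuration error, checked
before integration). A weak multiplicative noise (σ = 0.01) on biomass
seeds and maintains pattern selection. Along the default gradient
(R = 1.30 → 0.85 mm/day) the biomass field passes through gaps,
labyrinth and spot morphologies before the desert collapse below
R ≈ 0.8.

**What the generators emulate and what they do not.** They reproduce the
three canonical spatial-organisation regimes (unstructured, scale-free
patchy, periodic), abrupt collapse under a drifting driver, and
demographic-scale stochasticity. They do not emulate observational noise,
missing data, irregular sampling footprints, anisotropic environments
(slopes producing banded patterns), or underlying habitat heterogeneity —
so passing tests demonstrate that the indicators behave as catalogued on
clean model output, not that they are robust to the confounders of real
remote-sensing scenes (the known major caveat of this methodology).

## Numerical choices and degenerate inputs

* Coarse-graining truncates trailing rows/columns that do not fill a
  block, keeping blocks non-overlapping and equal-sized; outputs smaller
  than 2×2 are an error.
* Constant grids: variance 0, skewness undefined-flagged; Moran's I and
  scaled spectra raise typed errors; morphology returns homogeneous.
* Grids are written at 17 significant digits so read∘write is lossless.
* The truncated power-law normalisation is summed until the geometric
  tail bound drops below 1e−12 of the running total; the lognormal uses
  CDF differences with probabilities floored at 1e−300.
* Power-law sampling inverts a CDF table up to 10⁶ with a continuous
  Pareto tail beyond (tail mass < 1e−6 at the exponents used).
* Problem sizes in the test suite: oracle comparisons run on 15–30 cell
  grids where brute force is exact and fast; calibration uses 500
  replicates of 64×64 (classification) and 24×24 (coverage); the gradient
  reproduction study uses 100×100 lattices, 10 snapshots and 20 seeds per
  model, a scale at which every qualitative behaviour above is stable.

## Known limitations

* The router's patchiness call for continuous data (histogram bimodality)
  is one reasonable operationalisation of "two-phase"; mixed scenes with
  gradual phase boundaries can fall either way.
* Null models are spatially unstructured; testing against
  correlation-matched surrogates (e.g. Gaussian random fields with fitted
  covariance) is an open research direction and out of scope.
* Kendall trends over ten snapshots have low power; the package reports
  p-values but the indicators are screening tools, not tests.
* The dominant wavelength is read from unit-width rings, so its
  resolution is one ring; sub-ring interpolation is not attempted.
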
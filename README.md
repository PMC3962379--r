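# spatialews

Spatial early-warning signals of ecological transitions, computed from 2D
raster snapshots.

Ecosystems with alternative stable states (drylands, shallow lakes, mussel
beds) can shift abruptly at a tipping point. Near the bifurcation, critical
slowing down leaves fingerprints in spatial pattern *before* the shift:

* **generic leading indicators** — spatial variance, spatial skewness and
  near-neighbour spatial correlation (Moran's I at lag 1),

  `I = (N / ΣW) · Σᵢⱼ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / Σᵢ (xᵢ − x̄)²`

* **spectral indicators** — the 2D periodogram with its radial
  (r-) and angular (θ-) spectra, spectral reddening (power shifting to low
  wavenumbers), periodicity and isotropy classification,
* **patch-based indicators** — connected-component patch sizes, discrete
  maximum-likelihood fits of heavy-tailed size distributions (power law,
  truncated power law, exponential, lognormal) ranked by AIC, and the
  gaps → labyrinth → spots morphology sequence of periodic (Turing-type)
  vegetation.

Every indicator comes with a null model that gives it statistical meaning
(value reshuffling, matched-moment Gaussian surrogates, the coarse-graining
test for variance/skewness, analytic χ² bands for spectra), and indicator
trajectories along a degradation gradient are summarised by Kendall τ-b /
Pearson trend statistics. A workflow router implements the standard decision
flow (periodic? isotropic? patchy?) and runs the appropriate battery. Three
stochastic simulators — a local positive-feedback lattice, a three-state
facilitation cellular automaton, and the three-PDE scale-dependent feedback
(Turing) model — generate the canonical test gradients.

The package is written for ecologists and methodologists who have snapshots
of a state variable (biomass, occupancy, greyscale imagery already
rasterised) along a stress gradient or time series and want to screen them
for warning signals with honest significance statements.

## Worked example

Simulate the facilitation-automaton gradient (ten occupancy snapshots,
harshening conditions) and run the full analysis:

```r
library(spatialews)

sim    <- simulate_facilitation_ca(grid_size = 100, seed = 421)
report <- run_ews(sim, seed = 1)
report
#> <ews_report> periodic=FALSE isotropic=TRUE patchy=TRUE
#> Trends (Kendall):
#>   variance             tau = +0.867  (p = 0.000115, n = 10)
#>   skewness             tau = +0.778  (p = 0.000946, n = 10)
#>   morans_i             tau = +0.822  (p = 0.000358, n = 10)
#>   reddening            tau = -0.156  (p = 0.601, n = 10)
```

The router classified the data set as non-periodic and patchy, so the
generic indicator battery ran on 5×5 coarse-grained local-abundance grids
and patch-size distributions were fitted per snapshot. The strong positive
Kendall τ for variance, skewness and lag-1 Moran's I are exactly the
catalogued early-warning trends for this kind of system as it approaches
collapse. Tables are tibbles throughout:

```r
glance(report)
#> # A tibble: 1 × 5
#>   periodic isotropic patchy n_indicators  seed
#>   <lgl>    <lgl>     <lgl>         <int> <int>
#> 1 FALSE    TRUE      TRUE              4     1

head(tidy(report), 5)
#> # A tibble: 5 × 9
#>    rank stress value valid lower upper significant null          indicator
#>   <int>  <dbl> <dbl> <lgl> <dbl> <dbl> <lgl>       <chr>         <chr>
#> 1     1      1  4.26 TRUE     NA    NA NA          no valid null variance
#> 2     2      2  6.12 TRUE     NA    NA NA          no valid null variance
#> 3     3      3  7.58 TRUE     NA    NA NA          no valid null variance
#> 4     4      4  8.89 TRUE     NA    NA NA          no valid null variance
#> 5     5      5 10.6  TRUE     NA    NA NA          no valid null variance
```

(Variance has no valid reshuffle null — reshuffling conserves it exactly —
so its rows carry the explicit marker; the report's `coarse_null` table
holds the coarse-graining test that does apply.) Individual pieces compose
with the pipe:

```r
g <- sim$snapshots[[1]]
g |> coarse_grain(5, "count") |> spatial_moments()
g |> label_patches() |> inverse_cumulative() |> plot_inverse_cumulative()
autoplot(report)   # all indicator trajectories with their bands
```

A thin command-line wrapper for shell pipelines lives at
`inst/scripts/ews-cli.R` (subcommands `simulate`, `indicators`, `ews`).

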
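# aquashift

Can bird-dispersed aquatic plants keep pace with climate change? Species
distribution models tell us where habitat will be; they rarely tell us
whether a species can get there. For aquatic plants the gap matters:
their habitat is patchy, but waterfowl disperse their seeds by
endozoochory — tens of kilometres on daily movements, and occasionally
hundreds to thousands of kilometres during migration (long-distance
dispersal, LDD).

`aquashift` is an R package for ecologists and biogeographers that couples
the three pieces needed to answer the question quantitatively:

* a **presence–background habitat-suitability model** (L1-penalized
  logistic regression on linear + quadratic climate features — the
  Maxent-equivalent family), with backward collinearity pruning at
  |r| ≥ 0.70, cross-validated ROC/Somers' Dxy evaluation, and the
  constraint that only water cells are habitat;
* **mechanistic dispersal kernels** built by Monte Carlo from bird
  movement and seed gut-retention time: with probability *p* a seed rides
  a migratory flight (distance = min(speed · T, max leg)), otherwise it
  moves locally (< 100 km); kernels are discretized onto grid-cell rings,
  and the local kernel is the full kernel conditioned on ≤ 100 km;
* a **stochastic cellular automaton** stepping annually over 80 years
  with decadal climate updates, age-dependent propagule production,
  arrival probability q = 1 − Π(1 − m·K) over sources, establishment
  probability q × suitability, and deterministic extinction where habitat
  degrades — run under four dispersal scenarios (`no_dispersal`, `local`,
  `full_ldd`, `unlimited`) with seeded replicates.

From the simulations it reports colonization, extinction and expansion
rates in km·yr⁻¹ (colonization rate = √(mean annual colonized area)) and
compares them to the 0.42 km·yr⁻¹ climate-velocity benchmark.

A synthetic-landscape generator (correlated Gaussian random fields, water
mask, decadal warming trend, occurrences sampled from a known logistic
truth) makes the whole chain testable without any data downloads; real
rasters (ESRI ASCII grid) and occurrence CSVs plug into the same pipeline.

## Worked example

```r
library(aquashift)

# a full-LDD kernel for the club-rush archetype on a 10-km grid
kp <- reference_kernel_params("clubrush")
kernel <- build_kernel(kp$movement, kp$retention, cell_size = 10,
                       n_samples = 1e5, seed = 2)
print(kernel)
#> <dispersal_kernel> cell 10 km, 131 rings, total mass 1.000000
#>   empirical max distance 1300.0 km; P(>100 km) = 0.194%

# the whole pipeline on the shipped synthetic reference configuration
out <- run_pipeline(default_config(seed = 1), out_dir = tempfile())
#> stage 1/5: inputs (synthetic mode)
#>   100 x 100 grid, 2500 water cells, 200 occurrences
#> stage 2/5: species distribution model
#>   retained bio1,bio3,bio4,bio5,bio6,bio7; CV AUC 0.927 (Dxy 0.854), theta 0.088
#> stage 3/5: dispersal kernels
#>   full kernel: max 1300 km, LDD>100km 0.169%
#> stage 4/5: range-shift simulation
#>   no_dispersal final occupied 7200 +/- 0 km^2
#>   local        final occupied 94460 +/- 2268 km^2
#>   full_ldd     final occupied 95020 +/- 2796 km^2
#>   unlimited    final occupied 136900 +/- 0 km^2
#> stage 5/5: rates
print(out$rates)
#> <rate_summary> rates in km/yr (mean +/- sd across replicates)
#>   no_dispersal  colonization 0.00+/-0.00  extinction 10.55+/-0.00  expansion -10.55+/-0.00
#>   local         colonization 38.91+/-0.42  extinction 23.13+/-0.16  expansion 31.29+/-0.45
#>   full_ldd      colonization 38.97+/-0.45  extinction 23.07+/-0.14  expansion 31.40+/-0.55
#>   unlimited     colonization 46.10+/-0.00  extinction 24.80+/-0.00  expansion 38.86+/-0.00
#>   climate-velocity benchmark 0.42 km/yr; colonization/benchmark: no_dispersal 0.0x, local 92.7x, full_ldd 92.8x, unlimited 109.8x

plot_trajectories(out$results)   # occupied area vs year, per scenario
```

Reading the numbers: variable selection dropped `bio2`, the
variable built to be collinear (r = 0.9) with `bio1`; cross-validated AUC
0.927 means held-out presences rank above background 93% of the time.
Without dispersal the simulated range contracts (expansion −10.6 km·yr⁻¹)
because warming degrades the originally occupied cells, while any
dispersal scenario colonizes orders of magnitude faster than the
0.42 km·yr⁻¹ benchmark — the dispersal-limited scenarios end at ~69% of
the habitat an unlimited disperser would occupy. On this synthetic
landscape habitat is dense, so local and full-LDD dispersal perform
similarly; sparse real landscapes separate them more.

Every run writes its artifacts (config, occurrence CSV, water mask and
climate rasters, model JSON, kernel CSVs, tidy per-year results, rates,
manifest with seeds and hashes) to `out_dir`, and reruns with the same
config are hash-identical.

A thin CLI over the same functions lives at `inst/cli/aquashift.R`
(`run`, `synth`, `kernel`, `plot` verbs).

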
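# retinapop

Virtual populations of the macular retinal vasculature with network
hemodynamics, OCTA-style morphometrics, and structure–function analysis.

Each virtual individual is built end to end:

- **arcade shape model** — PCA over landmark chains of the four major
  temporal arcades; new anatomies sampled from the retained modes;
- **staged CCO growth** — arterial and venous trees grown by constrained
  constructive optimization along the sampled arcades, radii by Murray's
  law, per-stage pressure calibration;
- **capillary plexuses** — Voronoi meshes for the superficial (SVP),
  intermediate (ICP) and deep (DCP) plexuses, pruned around
  macrovessels, wired to the trees with interplexus descenders and an
  extramacular compartment closure;
- **hemodynamics** — Poiseuille resistances with the Pries–Secomb
  diameter-dependent apparent viscosity, sparse Kirchhoff pressure
  solve, Laplace-potential capillary flow orientation (acyclic by
  construction);
- **morphometrics** — vessel area/skeleton density, diameter and
  complexity indices from exact clipped geometry; fractal dimension and
  intervessel distance from rasterized angiograms; Horton–Strahler
  orders and arteriole:venule diameter ratios.

Population tooling: cohort simulation with Spearman + bootstrap
structure–function correlation tables, Sobol sensitivity analysis
(Saltelli design with bootstrap CIs and convergence audit), and a
45-scenario uncertainty grid over blood-volume fraction, compartment
resistance, and perfusion-pressure scaling.

## Worked example

```r
library(retinapop)

cfg <- modify_config(default_config(), list(
  plexus = list(SVP = list(N_seeds = 2750), ICP = list(N_seeds = 8000),
                DCP = list(N_seeds = 5250))))   # 50% seeds: ~10x faster

set.seed(1)
pop <- sample_population(1, cfg)
#>    r_CRA v_CRA    MAP   IOP    OPP
#> 1 75.988  6.52 78.986 14.45 38.207

net <- generate_vasculature(pop, cfg)
#> <vascular_network> 61268 nodes, 90350 segments
#>   segments by kind: artery=2078, artificial=547, capillary=85645, vein=2080

sol <- solve_flow(net, 2/3 * pop$MAP, pop$IOP, cfg$hemo)
sol$retinal_blood_flow     #> 33.73  (uL/min through the CRA)
sol$macular_flow_fraction  #> 14.08  (% entering the 3 mm perifoveal disk)
sol$v_CRA                  #> 3.10   (cm/s)
sol$kirchhoff_residual     #> 2.2e-12

morphometrics_report(net, fov_radius = 1.5, px_size = 10, raster = TRUE)
#> $VAD_SVP 0.5912   $VSD_SVP 24.74   $VDI_SVP 23.89 (um)
#> $VCI_SVP 2330.0   $FD_SVP  1.6123  $IVD_SVP 44.50 (um)  ...
```

Cohorts and analyses:

```r
params <- sample_population(20, cfg)
co  <- run_cohort(params, cfg, base_seed = 1)
correlation_table(co)                       # Spearman rho + bootstrap CI

sens <- run_sensitivity_study(sobol_ranges("plausible"), N_base = 64, cfg)
sens$VAD_SVP$indices                        # S, ST with bootstrap CIs

uq <- run_uq_grid(cfg, cohort_n = 10, base_seed = 1)
uq_linearity(uq)                            # r2(OPP->RBF), r2(OPP->MFF) per R
```

## Command line

A thin CLI ships in `inst/cli/retinapop`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","retinapop",package="retinapop"))')" \
  solve --seed 1 --out out/
# also: generate | metrics | cohort | sobol | uq, with --config <yaml>, --n
```

`scripts/acceptance.R` reproduces the headline cohort statistics and
linearity diagnostics as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "retinapop",
                   load_package = "installed")
```

The suite is oracle-driven: Murray residuals, series/parallel resistor
networks, Laplace chain potentials, Sierpinski-carpet fractal
dimension, Ishigami Sobol indices, and brute-force distance transforms,
plus property checks (Kirchhoff balance, capillary DAG, OPP linearity,
monotone compartment response, correlation sign pattern) and
reduced-scale cohort statistics. See
`vignettes/retinapop-methods.Rmd` for the methods and the documented
design decisions, including known deviations at reduced test scale.
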
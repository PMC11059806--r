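---
title: "retinapop: image-based virtual populations of the retinal vasculature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retinapop: image-based virtual populations of the retinal vasculature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`retinapop` generates virtual populations of the macular retinal
vasculature and links their structure to their function. Each individual
is built by a five-stage pipeline:

1. **Arcade shape model.** The superior and inferior temporal arcades
   (artery and vein each) are represented by landmark chains. A PCA
   statistical shape model is fitted to aligned training landmarks;
   new arcade geometries are drawn by sampling the retained principal
   components (clamped at ±3 SD) and converting from degrees of visual
   angle to millimetres.
2. **Staged CCO tree growth.** Four vascular trees (two arteries, two
   veins) grow from the optic-disc stubs along the sampled arcades by
   constrained constructive optimization: terminals are added one at a
   time in staged, shrinking perfusion regions; each candidate
   bifurcation must satisfy minimum-separation, length-ratio and
   bifurcation-angle constraints; radii obey Murray's law
   $r_p^\gamma = r_1^\gamma + r_2^\gamma$; each stage is calibrated so
   the mean root-to-terminal pressure drop matches the stage target.
3. **Voronoi capillary plexuses.** Three capillary beds (SVP at 0 µm,
   ICP at 135 µm, DCP at 180 µm depth) are Voronoi tessellations of
   uniformly seeded points in the perifoveal disk, clipped to the
   3 mm-radius domain and the foveal avascular zone. SVP edges inside
   a macrovessel stadium are pruned. Arterial terminals feed the SVP;
   a fraction `frac_deep` of terminals instead descends to the deep
   plexuses; interplexus descenders connect the layers; venous
   terminals drain them.
4. **Poiseuille hemodynamics.** Segment resistances use Poiseuille's
   law with the Pries–Secomb in-vivo apparent viscosity
   (Fåhræus–Lindqvist effect). Boundary pressures are
   $p_{CRA} = \tfrac{2}{3}\,\mathrm{MAP}$ and $p_{CRV}=\mathrm{IOP}$,
   so the driving pressure equals the ocular perfusion pressure
   OPP $= \tfrac{2}{3}\mathrm{MAP} - \mathrm{IOP}$. Nodal pressures
   come from a sparse Kirchhoff solve; capillary flow directions come
   from a Laplace potential (arterial nodes 1, venous nodes 0) that
   orients the capillary graph into a DAG.
5. **OCTA morphometrics.** Per plexus the package reports vessel area
   density (VAD), vessel skeleton density (VSD), vessel diameter index
   (VDI), vessel complexity index (VCI) from exact clipped geometry,
   plus fractal dimension (box counting) and intervessel distance
   (distance transform) from rasterized angiograms, and Horton–Strahler
   ordering with per-order arteriole:venule diameter ratios.

On top of single individuals the package provides cohort simulation
with Spearman/bootstrap structure–function correlation tables, Sobol
sensitivity analysis (Saltelli design, Jansen/Saltelli estimators with
bootstrap CIs and a convergence audit), and a 45-scenario uncertainty
grid over blood-volume fraction `alpha`, compartment resistance `R`,
and OPP scaling.

## Quick start

```{r quickstart}
library(retinapop)

cfg <- default_config()
set.seed(1)
pop <- sample_population(1, cfg)
net <- generate_vasculature(pop, cfg)
sol <- solve_flow(net, 2 / 3 * pop$MAP, pop$IOP, cfg$hemo)
sol$retinal_blood_flow      # uL/min through the CRA
sol$macular_flow_fraction   # % of it entering the 3 mm perifoveal disk

rep <- morphometrics_report(net, fov_radius = 1.5, px_size = 10)
rep$VAD_SVP; rep$FD_SVP
```

Cohorts, sensitivity and UQ:

```{r cohort}
params <- sample_population(20, cfg)
co <- run_cohort(params, cfg, base_seed = 1)
correlation_table(co)

sens <- run_sensitivity_study(sobol_ranges("plausible"), N_base = 64, cfg)
sens$VAD_SVP$indices

uq <- run_uq_grid(cfg, cohort_n = 10, base_seed = 1)
uq_linearity(uq)
```

## Design decisions

The published description of this class of models leaves several
details open; the choices made here, and their measurable consequences,
are documented below.

**Per-stage pressure calibration.** After each growth stage the tree
radii are rescaled so the mean root-to-terminal pressure drop of that
stage's terminals matches the stage target. Calibrating per stage
(rather than once at the end) keeps intermediate stages inside their
geometric constraint envelopes but leaves the final pressure profile a
compromise across stages.

**Terminal counts and flow splits.** Stage terminal counts `N_terms`
apply to each of the four trees, and the CRA flow
$Q = v_{CRA}\,\pi r_{CRA}^2/2$ is split equally between the superior
and inferior arteries.

**Same-kind diameter smoothing with stub exemption.** The
post-assembly diameter smoothing averages only over neighbours of the
same vessel kind, so capillary radii stay within
$[r_{cap}, 2 r_{cap}]$ and tree radii are not dragged toward capillary
scale. The CRA/CRV feeding stubs are exempt entirely: their radii are
boundary data (the individual's sampled central-vessel calibres), and
the reported CRA velocity $v = Q/(\pi r_{CRA}^2)$ must use the sampled
radius.

**Net macular flow fraction.** The macular flow fraction is the *net*
flow crossing into the perifoveal disk (inflow minus backflow across
the boundary, plus compartment exchange inside), expressed as a
percentage of CRA flow. A gross-inflow definition would double-count
vessels that cross the boundary twice.

**Macular terminals classified by tip.** Whether a terminal segment
receives a compartment closure or a capillary connection is decided by
the position of its *tip* (the node that gets wired), not its
midpoint. A terminal whose midpoint lies outside the 3 mm disk but
whose tip lies inside must not receive a compartment closure: such a
closure would carry flow across the macular boundary through the
artificial compartment and break the physical invariant that
increasing the compartment resistance shunts more flow into the
macula.

**Capillary-orientation audit.** Flow orientation clamps all boundary
nodes (not only those adjacent to capillaries) and audits at
generation time that the oriented capillary subgraph is acyclic; exact
potential ties are broken by node index to give a strict total order.

**CRA length.** The feeding stub length is an anatomical 10 mm, so
the central-vessel resistance is realistic rather than a nominal
epsilon.

**Known deviations at reduced scale.** At the 50% capillary-seed
scale used in the test suite, mean total retinal blood flow and CRA
velocity run ~1.8–2x above their full-scale reference values (sparser
meshes have lower total resistance) and the all-orders macular
arteriole:venule diameter ratio runs low (~0.80 vs ~0.94 reference;
the order-5 ratio is on target). At reduced scale the macular flow
fraction also couples measurably to macular structure
(|Spearman rho| up to ~0.4 vs < 0.25 at full scale), because the
compartment path's resistance is tree-dominated while the macular
path is capillary-dominated, so sampled vessel calibres move the flow
split; and skeleton-based fractal dimension anticorrelates with flow,
since thicker vessels prune more capillaries without adding skeleton.
These are scale artefacts of the test budget, not tuned away; the
invariants (Murray residuals, Kirchhoff balance, DAG orientation, OPP
linearity, monotone compartment response) hold at every scale.

## Reproducibility

All stochastic entry points take explicit seeds; `run_cohort` derives
per-individual seeds from `base_seed` so cohorts are reproducible
member-by-member and insensitive to failures elsewhere in the batch.
Networks round-trip losslessly through `save_network()` /
`load_network()` (JSON metadata + full-precision CSV tables), and
`export_artifacts()` writes VTK polydata and per-segment solution
tables for external visualization.
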
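# cmzclone

Quantitative tools for clonal dynamics in the ciliary marginal zone (CMZ),
the proliferative annulus at the periphery of the fish retina that keeps
adding new retina throughout life. The CMZ contains two cell populations
with sharply different behaviour: retinal stem cells (RSCs) at the extreme
periphery (rings 1–2 of cells counted from the edge), which self-renew and
divide predominantly along the radial axis, and retinal progenitor cells
(RPCs) further in, which produce finite clones of differentiated neurons
much like embryonic progenitors do.

`cmzclone` implements, end to end and with synthetic ground truth for
validation:

- **A stochastic branching-process simulator of progenitor clones.** Cell
  cycles are shifted-gamma distributed (refractory period `r = 4` h, total
  mean `6` h, sd `1` h; so the gamma part has shape
  `((6−4)/1)² = 4` and scale `1²/(6−4) = 0.5`). Division modes follow a
  piecewise-constant schedule on an internal clock started at the founder's
  first mitosis: pure PP (both daughters proliferate) in 0–8 h, then
  20/40/40 % PP/PD/DD in 8–15 h, then 20/0/80 % after 15 h. The CMZ variant
  selects a clone founder uniformly from the progenitors resident in the
  first 17 h of the lineage and excludes single-cell clones, yielding the
  CMZ clone-size distribution with bootstrap 95 % plausible intervals.
- **A stem-cell niche division model.** RSCs divide at rate α (per day),
  asymmetrically (RSC + RPC) with probability `p_asym`, which by default
  ramps from 0.7 at 5 dpf to 1 at 8 dpf; RPCs divide at rate β and
  differentiate following the mode schedule. The model reproduces early
  clone detachment from the niche followed by late stability, the
  detachment-rate statistic (detachments / survivors / days), and the
  constancy of rings 1–2 counts under pure asymmetry.
- **Annulus geometry.** Ring assignment from the distance to the peripheral
  edge (`ring = floor(d / cell diameter) + 1`), division angles as
  `acos(|axis · tangent|)` after projection into the CMZ plane (0° =
  circumferential, 90° = radial), per-ring division rates with one-sigma
  Garwood Poisson intervals, and box-plot angle summaries.
- **Division detection in 4D movies.** Frames are Gaussian-smoothed and
  differenced; the difference image is standardised by its median/MAD and
  voxels with |z| ≥ 4 form contiguous significant volumes (26-connectivity,
  ≥ 30 voxels) that become division events; the daughter-separation axis is
  the principal axis of the change region.
- **Synthetic-data generators** for every input: fate-labelled clone
  tables, polyclone tracking cohorts, division events on an annulus, and
  noisy multi-page TIFF movies with planted divisions of known position and
  orientation.

## Worked example

```r
library(cmzclone)

# mean clone size of embryonic progenitors under the default model
set.seed(1)
sizes <- vapply(1:10000, function(i) n_leaves(simulate_embryonic_lineage()),
                integer(1))
mean(sizes)
#> 13.05

# CMZ clone-size distribution (singletons excluded) with plausible intervals
set.seed(2)
head(clone_size_distribution(2000), 5)
#>   size frequency   lo95  hi95
#> 1    2    0.4255 0.4030 0.447
#> 2    3    0.1160 0.1035 0.130
#> 3    4    0.1335 0.1190 0.148
#> 4    5    0.0645 0.0535 0.075
#> 5    6    0.0630 0.0520 0.075

# niche model: early detachment, none after the asymmetry ramp completes
set.seed(3)
tracks <- simulate_polyclone_cohort(100, niche_params(), c(5, 6, 8, 12, 16))
detachment_rate(tracks, c(5, 8))   # per day
#> 0.0267
detachment_rate(tracks, c(8, 16))
#> 0

# division orientation against the local CMZ tangent
g <- cmz_geometry(edge_radius = 100, cell_diameter = 8)
division_angle(c(1, 1, 0) / sqrt(2), c(80, 0, 0), g)
#> 45
```

The simulated mean of ~13 differentiated cells per initial progenitor sits
between the observed "about 12" and the idealised fixed-6-h-cycle closed
form of 13.33; a 12-cell clone is always the outcome of 11 divisions. The
CMZ distribution is dominated by small clones (mode at size 2) with a long
right tail.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","cmzclone",package="cmzclone"))')" \
    simulate-cmz --n 1000 --seed 1 --out sizes.tsv
```

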
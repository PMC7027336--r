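# tracer3d

Serial-section 3D reconstruction and tracer-spread quantification for
fluorescence histology.

## The problem

After an intraparenchymal injection of a fluorescent tracer (e.g. a 10 kDa
fluorescein-dextran), whole brains are cut into thick serial sections,
slide-scanned, and the per-slice exports must be turned back into a
volumetric dataset before the tracer distribution can be quantified. The
scientific question is how far, and along which routes, the tracer spread —
in particular whether circulation-driven transport (perivascular /
glymphatic flow in living tissue) carries it farther than passive diffusion
(sacrificed tissue), and whether it drains to cervical lymph nodes.

`tracer3d` implements that pipeline end to end:

1. **Registration & reconstruction** — rigid (rotation + translation)
   intensity-based alignment of the slice stack by a coarse-to-fine
   normalized-cross-correlation search, per-slice brightness equalization,
   assembly into an anisotropic voxel grid (default 70 µm axial × 10.4 µm
   in-plane), and maximum projections along the coronal, sagittal and
   horizontal axes.
2. **Segmentation** — Otsu binarization of the tracer channel inside a
   nuclei-derived brain mask, and positive-voxel counts split into ipsi- and
   contralateral hemispheres along a user-drawn separation polyline.
3. **Spread statistic** — for every non-positive voxel, the exact Euclidean
   distance (in µm, anisotropic spacing respected) to the nearest
   tracer-positive voxel, computed by an exact feature-transform-style
   distance transform. Shorter distances = higher spread. Distances are
   pooled by group (L30/L90/S30/S90: living/sacrificed × 30/90 min) and
   compared by Kruskal-Wallis with Dunn-Bonferroni post hocs.
4. **Lymph-node quantification** — brightness-matched subtraction of the red
   (autofluorescence) channel from the green (tracer) channel, Otsu
   thresholding with a noise-floor guard, and tracer-pixel counts per node.
5. **Vessel vs. parenchyma intensity** — normalized (total/area) intensity
   over manually masked vessel and surrounding-tissue regions, compared by
   paired t-test.

Because the original slide scans are not publicly deposited, the package
ships a **synthetic phantom generator** with exact ground truth (true
per-slice transforms, true tracer field, true particle counts): a diffusive
mode following the 3-D point-source Green's function
`c(r,t) = M (4πDt)^{-3/2} exp(-r²/4Dt)` ("sacrificed" pattern) and an
advective mode depositing tracer along a branching vessel skeleton that
crosses the midline ("living" pattern). Every pipeline stage is validated
against this ground truth or against brute-force oracles.

## Worked example

Two phantom brains — one "living" (advective), one "sacrificed"
(diffusive) — through the full pipeline:

```r
library(tracer3d)
library(dplyr)

spec_live <- phantom_spec(mode = "advective", seed = 1)
spec_dead <- phantom_spec(mode = "diffusive", seed = 1)

quantify <- function(spec, id, group) {
  ph  <- generate_phantom(spec)              # slices + ground truth
  reg <- register_stack(ph$stack)            # undo mounting misalignment
  vol <- assemble_volume(equalize_brightness(reg$stack))
  bin <- binarize_tracer(vol, threshold = "auto")
  split <- split_hemispheres(bin, midline_polyline(
    phantom_midline(spec), spec$shape[2]))
  # matched positive-voxel count for the spread comparison
  tr <- vol$channels$tracer[vol$mask]
  bin_k <- binarize_tracer(vol, threshold = sort(tr, decreasing = TRUE)[2001])
  list(split = split,
       sample = distance_sample(bin_k, id, group, n = 3450, seed = 1))
}

live <- quantify(spec_live, "brain_L30", "L30")
dead <- quantify(spec_dead, "brain_S30", "S30")

bind_rows(L30 = live$split, S30 = dead$split, .id = "group")
#> # A tibble: 2 × 5
#>   group  ipsi contra on_surface total
#>   <chr> <int>  <int>      <int> <int>
#> 1 L30     202    118          0   320
#> 2 S30    6383      3          0  6386

summ <- summarize_spread(bind_rows(live$sample, dead$sample))
summ$by_group
#> # A tibble: 2 × 8
#>   group n_voxels n_brains   min   q25 median   q75   max
#>   <chr>    <int>    <int> <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1 L30       3450        1  10.4  32.9   62.4  75.9  164.
#> 2 S30       3450        1  10.4 234.   361.  479.   744.

compare_spread(bind_rows(live$sample, dead$sample))$omnibus
#> Kruskal-Wallis rank sum test: statistic = 4559.48, df = 1, p = 0 *
```

Reading the numbers: the hemisphere table shows the living phantom carrying
a substantial fraction of its positive voxels across the midline
(118/320 contralateral) while the sacrificed phantom stays almost entirely
ipsilateral (3/6386). At matched positive-voxel count (2000 voxels each,
3450 sampled query voxels per brain), the living brain's median
nearest-positive distance (62 µm) is far below the sacrificed brain's
(361 µm): shorter distances mean the tracer reached more of the brain. The
Kruskal-Wallis test on the pooled voxel-level distances confirms the group
difference — with the caveat, flagged by `summarize_spread()`, that pooled
voxels from one brain are pseudo-replicates; per-brain medians are reported
alongside.

A full multi-brain run (phantoms → registration → reconstruction →
segmentation → spread → lymph nodes → statistics, with all CSV outputs) is
driven by a YAML configuration:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "tracer3d"),
             outdir = "demo_out")
```

A thin command-line wrapper is at `inst/cli/tracer3d`.

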
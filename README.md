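# marrowmap

Quantitative spatial analysis of blood production in bone marrow, from
segmented whole-mount imaging coordinates.

Confocal imaging of whole-mounted marrow (sternum, tibia, skull, ...)
yields tables of segmented cells — one row per cell with a stage label, a
3D centroid in µm and a radius — plus surface segmentations of sinusoids,
arterioles and megakaryocytes. marrowmap turns those exports into the
quantities that describe the anatomy of haematopoiesis:

* **Radius-corrected 3D distances.** Every distance is a
  surface-to-surface gap, `g(a,b) = ‖c_a − c_b‖ − r_a − r_b` for cells and
  `g(a,V) = min_{p∈P} ‖c_a − p‖ − R − r_a` against a vessel capsule
  (polyline `P`, radius `R`); `g ≤ 0` means contact. A per-type catalogue
  of imaging-measured mean diameters (22 types, LT-HSC through
  erythrocyte) fills in missing radii.
* **Empirical random-placement nulls.** Enrichment of a cell type near a
  structure is judged against pseudo-cells resampled from the positions of
  *all* segmented haematopoietic cells (typically 49,000–81,000 per 35-µm
  slice) at the observed per-type frequencies, 150 replicates by default,
  through the identical distance code path.
* **Production-site detection and census.** Rule-based detectors for the
  four lineage production sites — sinusoid-attached CFU-E strings with
  budding erythroblast clusters, CLP-anchored B-cell clusters (150 µm
  capture), and neutrophil / monocyte-dendritic sites (focal GP or MDP on
  a sinusoid with progeny within 50 µm) — plus densities per mm² and
  per-site output.
* **Confetti clonality.** Dump-channel (green) filtering, monoclonal /
  oligoclonal site classification, and same-colour distance statistics
  tested against a colour-permutation null (exact on small inputs).
* **Vessel morphometry** (length, diameter, branch points) and the
  associated statistical procedures: normality-gated t / Mann–Whitney
  dispatch and the Yates-corrected two-proportion chi-square.
* **A synthetic marrow generator** (`simulate_marrow()`) that emulates a
  35-µm sternal optical slice with ground truth for every planted
  structure, used to validate every stage of the pipeline.

It is written for imaging labs quantifying haematopoietic niches and for
methodologists who need a ground-truthed testbed for 3D point-pattern
analyses in vascularised tissue.

## Worked example

```r
library(marrowmap)

scene <- simulate_marrow(marrow_config(), seed = 42)
scene
#> <synthetic_marrow> 61336 cells, 66 vessel segments, 2.88 mm^2 x 35 um (seed 42)
#>   planted sites: B 10, erythroid 10, monoDC 6, neutrophil 8

strings <- detect_cfu_e_strings(scene$cells, scene$vessels)
mean(table(strings$string_id))
#> [1] 8.8

ery    <- assemble_erythroid_sites(strings, scene$cells)
bsites <- detect_b_sites(scene$cells, scene$vessels)
neu    <- detect_myeloid_sites(scene$cells, scene$vessels, lineage = "neutrophil")
mdc    <- detect_myeloid_sites(scene$cells, scene$vessels, lineage = "monoDC")
site_census(list(erythroid = ery, B = bsites, neutrophil = neu, monoDC = mdc),
            scene$volume)
#> # A tibble: 4 × 5
#>   lineage    n_sites density_per_mm2 mean_output sem_output
#>   <chr>        <int>           <dbl>       <dbl>      <dbl>
#> 1 erythroid       10            3.47       79         5.05
#> 2 B               10            3.47       20.9       2.72
#> 3 neutrophil       8            2.78        7.88      0.972
#> 4 monoDC           6            2.08        5.17      0.946
```

The census reads: this 2.88 mm² slab carries 3.5 erythroid and B sites
per mm², each erythroid site feeding on average 79 maturing erythroid
cells (erythroblasts, reticulocytes, erythrocytes) and each B site ~21
developing B cells.

Enrichment against the random-placement null — here, multipotent HSPCs
versus arterioles:

```r
pool   <- build_pool(scene$cells)
hspc   <- multipotent_types()
counts <- table(scene$cells$cell_type[scene$cells$cell_type %in% hspc])
reps   <- sample_random_cells(pool, setNames(as.integer(counts), names(counts)),
                              n_reps = 150, seed = 43)
obs    <- distance_to_vessel(scene$cells[scene$cells$cell_type %in% hspc, ],
                             scene$vessels, "arteriole")
nul    <- null_distances(reps, "arteriole", vessels = scene$vessels)
compare_to_null(obs, nul)
#> <enrichment_result> ns (p = 0.0758, mann-whitney): observed median 174.5 vs null 141.7 um
```

The 29 HSPCs in this single scene sit farther from arterioles than random
cells (median 175 vs 142 µm, the direction the generator's
arteriole-avoidance encodes) but a single slab at steady-state densities
is underpowered for significance — pooling segments, as one would with
real data, is what gives such calls their power.

The published transplant-homing comparison (4 of 5 single transplanted
HSCs found vs 1 of 73 co-transplanted cells) reproduces exactly:

```r
chi_square_two_proportions(4, 5, 1, 73)
#> <mm_test_result> chi-square-yates: statistic 36.01, p = 1.964e-09 (n = 5, 73)
```

`plot_marrow_map()`, `plot_null_comparison()`, `plot_site_census()` and
`autoplot()` methods give ggplot views of scenes, nulls and censuses;
`tidy()` / `glance()` methods return test and enrichment results as
tibbles. A thin command-line wrapper lives at `inst/exec/marrowmap`
(`simulate` / `analyze` / `sites` / `clonality` / `report` over a YAML
config).

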
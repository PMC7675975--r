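# cardiohist

Automated quantification of structural remodeling in cardiac histology.

Structural remodeling of the myocardium — fibrosis between individual
cardiomyocytes, myocyte hypertrophy, capillary rarefaction, fibroblast
proliferation — is a substrate for atrial fibrillation and is classically
measured by hand from stained sections, at a cost of hours per image for a
trained analyst. cardiohist measures it automatically from calibrated
three-channel fluorescence micrographs of transversely sectioned
myocardium: a WGA (wheat germ agglutinin) channel staining membranes and
extracellular matrix, an endothelial channel (CD31 / GS-IB4) labelling
capillaries, and a vimentin channel labelling fibroblasts. It is intended
for cardiovascular researchers quantifying remodeling across animal models
and patient cohorts, and for methodologists who need a scriptable,
auditable alternative to interactive image analysis.

## What it measures

From the WGA channel, with intensities thresholded by the Phansalkar local
adaptive rule `t = m (1 + p e^{-qm} + k(s/r − 1))`:

* **fibrosis fraction** — WGA-positive pixels over total pixels;
* **myocyte count and size** — cells segmented by seeded Voronoi
  watershedding of the blurred intensity (seeds = regional minima with
  contrast-derived prominence, dim pockets inside fibrosis rejected by a
  red-surround rule), sized by the **minimal Feret diameter**, the smallest
  caliper width — robust to approximately-transverse sectioning;
* **endomysial septum widths** — for each pair of neighbouring myocytes,
  the width of the WGA-positive profile between them, measured
  perpendicular to the septum with sub-pixel edge refinement;
* **cardiomyocyte dissociation index (CDI)** — per cell, the fraction of
  its septa wider than a reference mean + 2 SD ("enhanced"); 0 = closely
  apposed, 1 = fully dissociated;
* **spatial clustering of enhanced fibrosis** — the average local
  clustering coefficient of the enhanced-septum graph against a
  1000-permutation null that shuffles the measured widths over the fixed
  tissue adjacency; reported as observed CC, expected CC and a p-score
  (the proportion of permuted coefficients smaller than the observed one).

From the colour channels, after HSB colour thresholding: **capillary
count, size and per-myocyte density** (components ≥ 1.5 µm²; circularity
≥ 0.35 selects transversely cut capillaries for Feret sizing, non-circular
objects are counted but not sized) and **fibroblasts per myocyte** after
subtracting the endothelial mask from the vimentin mask (vimentin
cross-reacts with endothelium).

For validation against manual annotation it provides greedy
minimal-centroid-distance matching (`d = √(ΔCx² + ΔCy²)`), the standard
sensitivity / precision / FNR / F1 metrics, and Bland–Altman agreement;
and a synthetic-tissue generator (`generate_tissue()`) that renders
Voronoi myocyte mosaics with known septum widths, capillaries and
fibroblasts, so the whole pipeline is testable without tissue data.

## Worked example

```r
library(cardiohist)

# a synthetic micrograph triple with a planted patch of enhanced fibrosis
tis <- generate_tissue(synthetic_spec(
  seed = 42,
  enhanced_patch = list(center_px = c(160, 160), radius_px = 70,
                        added_width_um = 4)))

# reference septum statistics (e.g. from a healthy cohort)
ref <- reference_stats(2.5, 0.6, "reference cohort")

res <- analyze_image(wga = tis$wga, endothelial = tis$endothelial,
                     fibroblast = tis$fibroblast, reference = ref,
                     image_id = "example")
dplyr::glimpse(res$summary)
#> $ image_id                  <chr> "example"
#> $ fibrosis_fraction         <dbl> 0.3263086
#> $ myocyte_count             <int> 100
#> $ median_min_feret_um       <dbl> 13.3634
#> $ median_septum_width_um    <dbl> 2.694093
#> $ mean_cdi                  <dbl> 0.1835595
#> $ observed_cc               <dbl> 0.09866667
#> $ expected_cc               <dbl> 0.02298267
#> $ cc_p_score                <dbl> 0.998
#> $ capillary_count           <int> 43
#> $ capillaries_per_myocyte   <dbl> 0.43
#> $ median_capillary_feret_um <dbl> 6
#> $ fibroblast_count          <int> 50
#> $ fibroblasts_per_myocyte   <dbl> 0.5

res$clustering_result
#> <clustering_result> observed CC 0.0987, expected 0.0230 (+329.3%), p-score 0.998 (1000 permutations)

glance(res$cdi_result)
#> # A tibble: 1 × 4
#>   n_cells mean_cdi frac_cdi_ge_50 threshold_um
#>     <int>    <dbl>          <dbl>        <dbl>
#> 1     100    0.184           0.15          3.7
```

Reading the numbers: a third of the tissue area is WGA-positive matrix;
the 100 myocytes have a median transverse diameter of 13.4 µm and sit a
median 2.7 µm apart; 18 % of inter-myocyte distances around an average
cell exceed the reference threshold of 3.7 µm (mean + 2 SD), and 15 % of
cells are at least half dissociated. The observed clustering coefficient
of the enhanced-septum graph (0.099) is four times its permutation
expectation with a p-score of 0.998 — the planted patch of enhanced
fibrosis is detected as spatial clustering, not scattered noise.

Per-structure tables are tibbles (`res$myocytes`, `res$septa`, `res$cdi`,
`res$capillaries`, `res$fibroblasts`), result objects have
`tidy()`/`glance()`/`autoplot()` methods, and `write_overlay()` renders
the control images (segmentation overlay and CDI heat map) used for
visual quality control.

Folder-level batch analysis (channels matched by base filename, CSV and
overlay outputs, unattended):

```r
run_batch(wga_dir = "wga/", endothelial_dir = "cd31/",
          fibroblast_dir = "vimentin/", out_dir = "results/",
          resolution_px_per_mm = 2000)
```

or from a shell: `Rscript inst/cli/cardiohist.R run --wga wga/ --endo
cd31/ --out results/ --px-per-mm 2000`. `simulate` and `validate`
subcommands generate synthetic tissue and compare manual vs automatic
centroid CSVs.

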
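# micropattern

Image-to-phenotype analysis of micropatterned iPSC germ-layer
differentiation assays, with a ground-truthed synthetic-data generator in
place of microscope and exome data.

Human iPSCs confined on 1000-µm circular micropatterned islands and
differentiated with BMP4/NODAL form radially ordered germ-layer domains —
an ectoderm core (SOX2), a mesoderm mid-ring (BRA) and an outer endoderm
ring (SOX17). `micropattern` is for researchers who want to quantify that
radial phenotype per cell line and relate it to genetic variants. It:

* segments nuclei in the DAPI channel (Gaussian smoothing → Otsu →
  distance-transform watershed) and measures mean nuclear intensity per
  channel;
* groups nuclei into colonies and applies morphology QC (well-edge
  exclusion, area window, isoperimetric roundness 4πA/P²);
* computes each nucleus's distance from its colony centroid,
  D = √((xᵢ−x)² + (yᵢ−y)²), and assigns it to one of **20 concentric
  25-µm rings** tiling the 500-µm colony radius;
* applies the normalization cascade: marker/DAPI ratio per nucleus →
  mixture-model background subtraction per well → per-ring colony means →
  scaling to the within-well maximum;
* quantifies **percent-positive cells per colony** and calls phenotypic
  outlier lines: Kruskal–Wallis + Dunn's post hoc across lines (α = 0.05),
  pooled two-tailed Student's t per line (α = 0.001), and
  Kolmogorov–Smirnov comparison of the radial positions of marker-positive
  nuclei against a control line (α = 0.01), plus Spearman marker
  correlations and PCA of line-level features;
* filters annotated nsSNV tables to rare (MAF < 0.005 in both 1000 Genomes
  and ExAC, fewer than five carrier HipSci lines) and Condel-deleterious
  variants, and classifies lines into adhesion / germ-layer / both /
  control categories;
* simulates whole plates of multi-channel well images with known ground
  truth (`generate_well()`, `generate_plate()`, `generate_variant_table()`)
  so every stage is testable end to end.

## Worked example

Simulate a four-well plate with two lines — a control (`uoxz_4`) and a
line whose expression rings are shifted 150 µm toward the colony centre
(`ffdc_5`, emulating an endoderm-expansion phenotype) — then run the full
pipeline:

```r
library(micropattern)
library(dplyr)

layout <- plate_layout(
  wells = c("A1", "A2", "B1", "B2"),
  lines = rep(c("uoxz_4", "ffdc_5"), each = 2),
  experiment = "exp1", replicate = c(1, 2, 1, 2))

cfg <- sim_config(
  n_colonies_per_well = 2, plate_layout = layout,
  donor_effects = list(ffdc_5 = list(center_shift_um = -150)))

plate <- generate_plate(cfg, seed = 5)
run <- run_pipeline(plate, control_line = "uoxz_4")
run
#> <mp_run> 4 wells, 4794 nuclei, 8 colonies (8 qualified)

run$percent_positive |>
  group_by(line, marker) |>
  summarise(mean_pct = mean(percent_positive), .groups = "drop")
#> # A tibble: 6 × 3
#>   line   marker mean_pct
#>   <chr>  <chr>     <dbl>
#> 1 ffdc_5 BRA        14.6
#> 2 ffdc_5 SOX17      15.0
#> 3 ffdc_5 SOX2       14.5
#> 4 uoxz_4 BRA        29.0
#> 5 uoxz_4 SOX17      23.6
#> 6 uoxz_4 SOX2       14.6

run$stats |> select(test, marker, line, statistic, p_value, significant)
#> # A tibble: 3 × 6
#>   test  marker line   statistic p_value significant
#>   <chr> <chr>  <chr>      <dbl>   <dbl> <lgl>
#> 1 ks    SOX17  ffdc_5    0.980    0     TRUE
#> 2 ks    BRA    ffdc_5    0.803    0     TRUE
#> 3 ks    SOX2   ffdc_5    0.0827   0.184 FALSE
```

Reading the output: all eight complete colonies pass QC; the shifted line
shows depressed BRA/SOX17 percent-positive (its rings moved inward, where
annulus area is smaller); and the KS radial-outlier test flags exactly the
two ring markers whose spatial distribution was shifted (huge D
statistics, p ≈ 0) while leaving the centre-dome marker SOX2
non-significant — the patterning phenotype, not just the expression level,
is what is being detected.

`plot_radial_profiles(run$line_profiles, unit = "line")`,
`plot_percent_positive(run$percent_positive)` and
`autoplot(pca_lines(...))` give the standard radial-trend, per-line
scatter and PCA views; `write_results(run, dir)` writes every result
table as CSV; `write_well_image()` / `read_well_image()` +
`read_plate_layout()` round-trip 16-bit multi-channel TIFFs under a YAML
plate layout.

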
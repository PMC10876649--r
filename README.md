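# tilecyte

Voronoi tile-based quantification of cell-type composition in multiplexed
immunofluorescence tissue images.

## The problem

Multiplexed imaging platforms (Cell DIVE, ChipCytometry and similar
stain–image–bleach protocols) deliver co-registered channel images of a
tissue section: a nuclear stain (DAPI) plus one channel per protein marker.
In dense connective tissue — the motivating case is fibrotic joint-capsule
biopsies, where CD31 marks vascular endothelium, CD68 macrophages and DKK3
fibroblasts — true cell segmentation is unreliable because cell borders are
invisible. `tilecyte` sidesteps segmentation with a nucleus-anchored tiling:

1. detect nucleus centroids in the DAPI channel;
2. partition the region of interest (ROI) into one **Voronoi tile per
   nucleus**: every ROI pixel `p` is assigned to the nucleus `i` minimizing
   the Euclidean distance `‖p − c_i‖`, so tile borders are equidistant
   between neighbouring nuclei and differences in apparent cell size cannot
   bias the counts;
3. normalize each marker channel to [0, 1] by its 1st/99th ROI percentiles,
   `x' = clip((x − q₁)/(q₉₉ − q₁), 0, 1)`, then call each tile
   `argmaxₘ mean(x'ₘ over tile pixels)` — the highest normalized intensity
   wins;
4. tabulate compositions stratified by tissue region (synovial-like
   *lining* vs deeper *sub-lining*), cellularity (nuclei/mm²) and % area
   immunopositivity for chromogenic stains;
5. compare two groups of samples per endpoint with an exact, tie-aware
   two-sided Mann-Whitney test,
   `U = #{(i,j): aᵢ > bⱼ} + ½·#ties`, two-sided p by full enumeration of
   all `C(n₁+n₂, n₁)` group assignments for pooled n ≤ 20.

Because no public images of this tissue type exist, the package includes a
synthetic tissue generator with known per-nucleus ground truth (hard-core
nucleus placement, region-tilted multinomial cell types, tile-constant
marker signal + noise), against which every stage is validated end to end.
See the methods vignette (`vignettes/tilecyte-methods.Rmd`) for the model
choices and their rationale.

## Worked example

```r
library(tilecyte)

# two-group study at the default conditions: 5 + 5 samples here shortened
# to 2 + 2; each sample is a 384x384 px ROI with 1000 nuclei, a lining band,
# and known ground truth
study <- simulate_study(n_samples_per_group = 2, seed = 42)
s <- study$comparator_1
s$image
#> <multiplex_image> 384 x 384 px, 0.65 um/px, 4 channels: DAPI, CD31, CD68, DKK3 (DAPI = DAPI)

res <- quantify_sample(s$image, s$mask, run_config(), "comparator_1")
subset(res$composition, region == "combined")
#>        sample   region       type count proportion_pct n_tiles
#>  comparator_1 combined       CD31   143           14.3    1000
#>  comparator_1 combined       CD68   190           19.0    1000
#>  comparator_1 combined       DKK3   667           66.7    1000
#>  comparator_1 combined unassigned     0            0.0    1000
```

The pipeline detected all 1000 nuclei, tiled the ROI and called every tile;
the estimated composition (14.3/19.0/66.7% CD31/CD68/DKK3) equals this
sample's ground-truth type proportions exactly. Cellularity converts region
pixel areas to mm² at the recorded pixel size:

```r
res$cellularity
#>        sample    region count   area_mm2 density_per_mm2
#>  comparator_1    lining   114 0.00778752        14638.81
#>  comparator_1 sublining   886 0.05451264        16253.11
#>  comparator_1     total  1000 0.06230016        16051.32
```

Group comparison uses the exact Mann-Whitney test; with 5 samples per group
the smallest attainable two-sided p is 2/252:

```r
mann_whitney_u(c(65.2, 66.8, 68.1, 64.9, 67.5),   # e.g. %DKK3, group A
               c(50.1, 52.3, 49.8, 51.0, 48.6))   #        ... group B
#> Mann-Whitney U = 25 (n1 = 5, n2 = 5), two-sided p = 0.007937 [exact]
#>   medians: 66.8 vs 50.1
```

`run_pipeline()` runs simulate → quantify → compare in one call and writes
byte-reproducible CSVs; the `exec/tilecyte` Rscript exposes the same
functions as `tilecyte simulate|quantify|run` subcommands.

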
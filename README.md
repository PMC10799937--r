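# snagmap

Individual dead tree (snag) mapping from 4-band (RGB + near-infrared)
sub-metre aerial imagery, in R.

Forest mortality from drought, bark beetles, disease and fire is routinely
mapped at 30 m or coarser, which misses the isolated and scattered dead
trees that make up a large share of total mortality. snagmap implements a
tree-level pipeline for imagery at ~0.6 m ground sample distance:

1. **Instance segmentation by ordinal deep watershed.** A compact
   encoder–decoder network predicts quantised distance-to-boundary
   "energy" levels per pixel. The levels are ordinal — level *j* can only
   be present where level *j−1* is, enforced by a cumulative product over
   per-level sigmoid outputs, `q_j = Π p_i`, decoded as
   `max{ j : q_j ≥ 0.5 }` — and a marker-based watershed floods the energy
   surface from the level-K cores so that touching crowns split at the
   energy valley between them. Training uses the Focal Tversky loss
   `L = mean_j (1 − TI_j)^γ`, `TI = TP / (TP + αFP + βFN)` with
   `(α, β, γ) = (0.4, 0.6, 2)`, and model selection keeps the epoch with
   the lowest *validation count MAE* (the decoded instance count is the
   quantity of interest, not the pixel loss).
2. **Crown structure.** Per instance: hole-filled area, centroid,
   moment-ellipse semi-axes and eccentricity `e = c/a` (0 = circular,
   →1 = elongated, a proxy for off-nadir view-angle distortion; 500 m
   cells with median e > 0.8 are flagged).
3. **Mortality staging.** Mean crown colour (after a one-pixel inner
   erosion) is scored in HSV space into brown-stage (recent death, dried
   foliage) vs grey-stage (long-dead, defoliated) with the bounded
   exponential scores `X = (C^x − 1)/(C − 1)` and constants
   `(5, 5, 1e7, 1e4)`; the argmax wins.
4. **Grid products with bias correction.** Centroid counts at 30/100/240 m,
   percent mortality against a baseline live-tree raster, dead-canopy
   percent, median crown size, brown-stage percent (with the
   single-brown-tree noise rule), cluster-size profiles, and a three-band
   hotspot composite. Counts are corrected by the mean error
   `ME = F · mean(Y_obs − Y_pred)` per hectare (never at 30 m).
5. **Damage agents.** Survey polygons (≤3 coded agents + year) and fire
   perimeters resolve by year precedence — later survey wins; fire is
   added when the fire year ≥ survey year — and crowns take the agents at
   their centroid, with configurable level 4→3→2→1 rollups.
6. **Evaluation.** Count MAE, relative total error, percent bias
   (positive = underestimation), per-class IoU/mIoU, tree-level matching
   with 6 m buffers and the >50% crown-polygon coverage rule, and
   plot-level comparisons with optional DBH ≥ 40 cm filtering.

A synthetic scene generator (ellipse crowns from brown/grey palettes on
live canopy, clustered and isolated placement, affine off-nadir
distortion, field-survey and agent-polygon fixtures) provides exhaustive
ground truth, so the entire pipeline is tested end to end without any
external data.

## Worked example

```r
library(snagmap)

# a 76.8 m synthetic scene (128 x 128 px at 0.6 m) with 25 dead crowns
b <- generate_scene(scene_params(extent_m = 76.8, n_crowns = 25), seed = 42)
#> <scene_bundle> 128 x 128 px @ 0.6 m, 25 truth crowns, seed 42

# truth labels -> ordinal energy -> watershed -> crown records
e      <- instances_to_energy(b$truth_instances, K = 5)
lab    <- watershed_instances(e)
crowns <- extract_crowns(lab, b$image) |> stage_crowns(lab, b$image)

dplyr::count(tibble::as_tibble(crowns), stage)
#>   stage     n
#> 1 brown     7
#> 2 grey     18
median(crowns$ecc)
#> [1] 0.66

# raw 30 m counts and the cluster-size profile
cg <- count_grid(crowns, grid_for_tile(b$image, 30))
cluster_size_profile(cg)
#>       k n_cells n_trees cum_pct
#> 1     1       3       3      12
#> 2     2       1       2      20
#> 3     3       1       3      32
#> 4     5       1       5      52
#> 5     6       2      12     100

glance(count_comparison(obs = nrow(b$truth_crowns), pred = nrow(crowns)))
#>       n obs_total pred_total   mae   rte bias_pct
#> 1     1        25         25     0     0        0
```

All 25 planted crowns are recovered as distinct instances (the clumps are
split by the watershed), 7 of 25 are brown-stage — matching the planted
stage mix within this scene — three trees are isolated singletons within
their 30 m cells (12% of trees), and the count error against truth is
zero, so MAE, relative total error and bias all sit at their ideal values.
The median eccentricity of 0.66 reflects the scene's simulated off-nadir
shear plus rasterisation of small ellipses.

To train the network itself (minutes on one CPU at this scale):

```r
cfg <- run_config(patch_size = 128L)
patches <- make_patch_set(200, cfg, seed = 1)
ts <- train_network(patches, cfg, epochs = 15, seed = 1)
glance(ts)           # best epoch, validation count MAE
autoplot(ts)         # loss / val-MAE curves
e <- predict_energy(ts$net, b$image, cfg)
```

A thin CLI over the same functions is included at
`inst/cli/snagmap.R` with subcommands `simulate`, `encode`, `train`,
`predict`, `extract`, `stage`, `aggregate`, `attribute`, `evaluate`.

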
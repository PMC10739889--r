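# zygopolar

Quantitative analysis of intracellular-structure polarity along the
apical–basal axis of elongating plant zygotes.

After fertilization, the *Arabidopsis thaliana* zygote elongates and
divides asymmetrically. Different intracellular structures — actin
filaments, mitochondria, microtubules, vacuolar membranes — occupy
different territories along the apical–basal axis, and this polarity
appears to set the position of the asymmetric division plane. `zygopolar`
turns time-lapse 3D fluorescence movies of single zygotes (one probe per
movie) into comparable 1-D axial intensity profiles and quantifies the
zygote's compartmentalization:

1. **Normalization chain** — event-anchored selection of `k = 10` time
   points; maximum intensity Z-projection; moment-ellipse fit of the cell
   mask (orientation `θ = ½·atan2(2μ₁₁, μ₂₀ − μ₀₂)`); rotation apex-up;
   row-wise mean intensity over the mask; length standardization to
   `L = 110` px by linear interpolation; z-scoring to mean 0, sd 1.
2. **Compartmentalization** — the 110 × 120 position-by-feature matrix
   (4 probes × 10 time points × 3 replicates) is clustered with Euclidean
   distance and Ward `ward.D2` linkage; cutting into two clusters locates
   the apical/basal boundary as the minimal-disagreement two-segment
   split, reported in % of cell length from the tip.
3. **Classification** — a random forest (500 trees, mtry 10) classifies
   positions into apical/basal; accuracy is the out-of-bag error from the
   confusion matrix, and mean-decrease-Gini importance (percent of total,
   averaged per structure per replicate) ranks the structures, compared
   with a Tukey–Kramer test (α = 0.01) and compact letter display.
4. **Division plane** — annotated division-plane points are expressed in
   % of cell length from the tip and compared with half the compartment
   boundary.

Because the original imaging data are not redistributable, the package
includes a first-class synthetic-data generator producing elongating,
rotated, noisy capsule-shaped zygote movies with planted axial densities
and a known compartment boundary, so every stage is testable end to end.

## Worked example

```r
library(zygopolar)

# default design: 4 probes x 3 replicates x 10 time points,
# boundary planted at 43.6% of cell length, 10% Gaussian noise
ds  <- simulate_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds, seed = 1)
res
#> <zp_analysis>
#> <zp_compartment> 110 positions x 120 features
#>   apical/basal boundary: position 46 of 110 (41.8% from tip), 0 contiguity violation(s)
#>   random forest OOB error: 0.9%
#>   division plane: 22.8% +/- 1.95% from tip (n = 12); half-boundary 20.9%, delta 1.9

glance(res$compartment)
#> # A tibble: 1 × 5
#>   n_positions n_features boundary_index boundary_pct contiguity_violations
#>         <int>      <int>          <int>        <dbl>                 <int>
#> 1         110        120             46         41.8                     0
```

The recovered boundary (41.8% from the tip) is within rasterization and
noise tolerance of the planted 43.6%; the out-of-bag error of 0.9% means
1 of 110 axial positions was misclassified; the planted division plane
(half the apical compartment, with 2.15-point jitter) is measured at
22.8 ± 1.95% from the tip. `tidy()` and `glance()` methods return tidy
tables for every result type, `autoplot()` draws the clustered heatmap
and importance boxplots, and `write_report()` emits CSV tables plus a
JSON run report. A thin command-line wrapper lives in
`inst/cli/zygopolar.R` (`frames`, `simulate`, `run`).

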
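# morphosignal

Locate **where** on a 3D landmark/semilandmark configuration a binary
biological signal is expressed — the motivating case being sexual
dimorphism of the human cranium. Instead of one whole-configuration
discriminant analysis, `morphosignal` runs an independent local analysis
around every point and renders the result as a per-point accuracy map.

The package is aimed at geometric morphometricians and biological/forensic
anthropologists working with dense landmark + surface-semilandmark data
(from 3D Slicer, TPS files, or plain CSV), and at methodologists who want a
fully synthetic, ground-truthed test bed for local shape classification.

## The method

Specimens are ordered point sets \(X_i \in \mathbb{R}^{k\times 3}\) with
labels \(y_i \in \{F, M\}\). Size is measured by centroid size
\(CS(X) = \sqrt{\sum_j \lVert x_j - \bar x \rVert^2}\). After a generalized
Procrustes analysis (GPA: translate, scale to unit \(CS\), rotate to the
consensus), the per-point map in a feature space
\(s \in \{\text{shape}, \text{form}, \text{size}\}\) is built as:

1. neighborhoods: each point plus its \(k - 1 = 9\) nearest neighbors on
   the consensus;
2. for each neighborhood and each of \(n_{perm} = 100\) permutations:
   stratified 70/30 train/test split; GPA of the *training*
   subconfigurations only; features = aligned coordinates (shape), aligned
   coordinates + \(\log CS\) of the neighborhood (form), or \(\log CS\)
   alone (size); PCA fitted on training features, retained to 90% variance;
   two-class LDA with pooled within-class covariance; test specimens
   projected by ordinary Procrustes superimposition and the training PCA
   axes, then classified;
3. the map value at a point is the mean held-out accuracy (total and per
   class) over permutations — `n_points × n_perm` independent LDA fits per
   map.

Supporting statistics: Procrustes linear models (sequential variance
fractions for size/sex/interaction with Freedman–Lane permutation p-values),
per-group allometric regressions with the trajectory angle
\(\theta = \arccos(\hat\beta_F^\top \hat\beta_M)\) and its label-permutation
test, Procrustes-ANOVA repeatability for replicate digitizations,
symmetrization, thin-plate-spline warps and per-vertex area-change maps.

## Worked example

Simulate a cranium-scale sample (80 specimens, ~120 points, ~975 mm
centroid size) with a 12-point patch displaced by 2.5 mm in group M, then
map the signal:

```r
library(morphosignal)

base  <- make_base_shape(120, seed = 1)
d     <- as.matrix(dist(base$coordinates))
patch <- order(d[25, ])[1:12]                      # a contiguous 12-point patch
spacing_mm <- base$mean_spacing / centroid_size(base$coordinates) * 975

crania <- simulate_landmarks(
  n_f = 40, n_m = 40, n_points = 120,
  effect_indices = patch, effect_size = 2.5 / spacing_mm,  # 2.5 mm, 5x noise
  noise_sd = 0.5, seed = 7
)
crania
#> <specimen_set> 80 specimens x 119 points
#>   sex: F=40 M=40  paired points: 106  midline: 13

fit <- gpa(crania)
glance(fit)
#> # A tibble: 1 x 6
#>   n_specimens n_points scaled iterations final_change mean_csize
#> 1          80      119 TRUE            3     5.05e-12       975.

map <- map_signal(crania, space = "shape", k = 10, n_perm = 50, seed = 1)
map
#> <accuracy_map> space=shape k=10 n_perm=50 seed=1
#>   acc_total: min 0.383, max 0.998 at p52
```

Accuracy peaks at ~1.0 on and around the planted patch (every neighborhood
that contains displaced points carries signal, so the hot region is the
patch dilated by the neighborhood radius) and hovers near 0.5 far from it.
`autoplot(map)` draws the map on a 2D projection of the consensus;
`write_accuracy_map()` exports CSV plus a color-ramped ASCII PLY mesh.

Select the high-accuracy modules and score them jointly at the
module-level permutation count:

```r
mods <- extract_top_modules(map, top_quantile = 0.9)
tidy(combined_module_accuracy(crania, mods[1], space = "shape",
                              n_perm = 200, seed = 2))
#>   class accuracy     sd
#> 1 total    0.956 0.0376
#> 2 F        0.929 0.0708
#> 3 M        0.983 0.0357

sexes <- specimen_info(crania)$sex
procrustes_lm(form_matrix(fit),
              data.frame(size = fit$csize, sex = factor(sexes)),
              ~ size + sex, n_perm = 199, seed = 3)
#>       term df       ss fraction statistic p_value
#> 1     size  1 0.134927  0.94311   1440.88   0.005
#> 2      sex  1 0.000929  0.00649      9.92   0.005
#> 3 residual 77 0.007210  0.05040        NA      NA
```

In form space the size column dominates the variance (fraction 0.94 here),
which is exactly why the shape/form/size contrast of the maps is
informative: regions hot in form but cold in shape carry size, not shape,
signal.

A thin CLI wraps the same functions
(`inst/cli/morphosignal simulate|gpa|map|combined|allometry|repeatability|compare-maps`),
reading YAML configs with flag overrides and deriving all randomness from
one `--seed`.

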
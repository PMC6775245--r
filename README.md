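# earcount

Automatic counting of wheat ears (spikes) in overhead canopy RGB images, and
conversion to ears per square metre via an in-image ground standard. Ear
density is a yield component; counting it manually across a breeding trial
is slow and error-prone, and images taken in the field bring blur, shadows,
overlapping awned ears and strong illumination changes. `earcount` is aimed
at phenotyping groups who have such images and want plot-level ear counts
without hand annotation of every image.

## Method

The pipeline combines superpixel partitioning with pixel-wise deep
segmentation:

1. **SLIC superpixels.** The image is clustered in CIELAB + position space
   $C_i = (l_i, a_i, b_i, x_i, y_i)$ by localized k-means with distance
   $D^2 = d_{lab}^2 + (m/S)^2 d_{xy}^2$ ($S$ the seed spacing, $m$ the
   compactness), giving $N \approx 3000$ homogeneous candidate regions per
   full-resolution image.
2. **Encoder-decoder segmentation.** Each candidate region is resized and
   classified per pixel (ear / background) by a U-Net-style network with a
   VGG-16-style encoder (four 2/2/3/3 convolution stages with 2×2 pooling),
   a single 512-channel bottleneck convolution, and a skip-concatenating
   decoder, trained with binary cross-entropy (default recipe: 15 epochs,
   learning rate 1e-4, Adam). The network is implemented natively in this
   package (Rcpp/Armadillo), including training.
3. **Counting.** Region predictions are stitched back, thresholded at 0.5,
   denoised with a 7×7 median filter, and touching ears are separated by a
   marker-based watershed on the Euclidean distance transform; contours are
   traced, numbered and counted.
4. **Density.** With an A4 sheet (0.210 m × 0.297 m) visible in the frame —
   auto-detected or with manually supplied corners — counts become
   ears/m²: $\text{scale}^2 = A_{phys}/P$ for standard pixel area $P$, and
   density = count / ($HW \cdot \text{scale}^2$).

A handcrafted baseline (`edge_count()`: Sobel gradient → Otsu threshold →
dilation → hole filling → small-object removal → erosion → contour count)
and the evaluation statistics
$\mathrm{RMSE} = \sqrt{\tfrac1N\sum (r_i-e_i)^2}$,
$\mathrm{rRMSE} = \sqrt{\tfrac1N\sum ((r_i-e_i)/r_i)^2}$,
$\mathrm{Bias} = \tfrac1N\sum (r_i-e_i)$, plus $R^2$ and the regression
line, are included (`compare_counts()`). A synthetic-canopy generator
(`generate_scene()`, `generate_patchset()`) provides scenes with exact
ground truth so the whole pipeline runs and is tested without field data.

## Worked example

Count ears in synthetic scenes with the edge baseline and score the counts
against the generator's ground truth:

```r
library(earcount)

scenes <- lapply(1:5, function(i) generate_scene(sparse_scene_params(i)))
est  <- sapply(scenes, function(s) edge_count(s$image)$count)
true <- sapply(scenes, function(s) s$true_count)
compare_counts(true, est)
#> n = 5 images
#> RMSE  = 0.00
#> rRMSE = 0.0%
#> bias  = 0.00
```

Zero error here means the baseline counted every well-separated ear in all
five sparse scenes; rRMSE is the per-image relative error (printed as a
percentage of the reference count) and a negative bias would indicate
overcounting. Density from a scene containing a ground standard:

```r
sc  <- generate_scene(scene_params(include_standard = TRUE, seed = 5))
gs  <- detect_ground_standard(sc$image)
ears_per_m2(sc$true_count, gs, dim(sc$image)[1:2])
#> [1] 9.261178
```

Training and running the full segmentation pipeline at desk scale:

```r
model <- run_train(out_dir = "run", synthetic_n = 100,
                   config = model_config(input_size = c(32, 32), width_multiplier = 0.125),
                   cfg = train_config(epochs = 30, learning_rate = 1e-3,
                                      target_val_accuracy = 0.985),
                   augment_each = 2, aug = augment_params(zoom_range = c(0.5, 1.5)),
                   seed = 1)
sc    <- generate_scene(scene_params(seed = 101))   # held-out scene, 12 ears
map   <- slic_segment(sc$image, slic_params(200))
regs  <- extract_regions(sc$image, map)
prob  <- stitch_predictions(regs, lapply(regs, predict_region, model = model),
                            dim(sc$image)[1:2])
count_ears(binarize(prob))
#> count_result: 10 ears
```

Desk-scale counts land within a couple of ears of the truth; the residual
undercount comes from strongly overlapping pairs that the watershed cannot
split, the same failure mode field images show.

A thin command-line front end is installed with the package
(`inst/cli/earcount`): `earcount count --images DIR --method edge --out OUT`,
`earcount train ...`, `earcount evaluate --pred F --ref F`,
`earcount make-fixtures --out DIR`.

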
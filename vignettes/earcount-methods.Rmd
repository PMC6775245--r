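---
title: "Counting wheat ears in canopy images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting wheat ears in canopy images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The number of ears (spikes) per square metre is a yield component that
breeders estimate by manually counting ears in field plots — slow, costly and
error-prone at the scale of modern trials. `earcount` implements an automatic
pipeline for overhead RGB images of wheat canopies: it segments ears at the
pixel level, separates touching ears, counts them, and converts the count to
ears/m² when an object of known physical size (an A4 sheet laid on the
canopy) is visible in the frame. A handcrafted edge-detection counter is
included as the classical baseline, together with the evaluation statistics
used to compare counters against reference counts.

## Pipeline

1. **Superpixel partition (SLIC).** The image is converted to CIELAB and
   clustered by localized k-means in the 5-D space $(l, a, b, x, y)$ with
   distance $D^2 = d_{lab}^2 + (m/S)^2\, d_{xy}^2$, where
   $S = \sqrt{HW/N}$ is the grid spacing of the $N$ requested superpixels
   and $m$ the compactness weight. Each center searches a $2S \times 2S$
   window; after 10 rounds, 4-connectivity is enforced and fragments smaller
   than a quarter of the average superpixel area are merged into their
   dominant neighbour. Defaults: $N = 3000$ for full-resolution canopy
   images (chosen to avoid oversegmentation while keeping superpixels
   ear-scale), $m = 10$, 10 iterations — the reference-algorithm defaults;
   desk-scale fixtures use proportionally smaller $N$.
2. **Pixel-wise classification.** Each superpixel, cropped at its bounding
   box and resized to the network input, is classified per pixel by an
   encoder-decoder network: a VGG-style encoder (stages of 2, 2, 3, 3
   stacked 3×3 convolutions with widths 64/128/256/512, each followed by
   2×2 max-pooling), a single 512-channel 3×3 bottleneck convolution, and a
   U-Net decoder (2× nearest-neighbour upsampling, concatenation with the
   matching encoder output, two 3×3 convolutions per stage) ending in a 1×1
   convolution with a sigmoid. Training minimizes mean binary cross-entropy
   with Adam; the full-scale recipe is 15 epochs at learning rate $10^{-4}$.
   Region predictions are written back through the superpixel ownership
   masks, so every image pixel is predicted exactly once.
3. **Counting.** The stitched probability map is thresholded at 0.5 (the
   sigmoid midpoint), denoised with a 7×7 median filter, and split into
   individual ears by a marker-based watershed on the Euclidean distance
   transform. Components smaller than 0.02% of the image are discarded;
   remaining objects are outlined, numbered and counted.
4. **Density.** The pixel area $P$ of the ground standard's quadrilateral
   (shoelace formula) gives the metric scale $s^2 = A_{phys}/P$; the imaged
   ground area is $HW s^2$ and the density is count divided by that area.
   The result is invariant to uniform rescaling of the image. Perspective of
   the sheet is deliberately ignored (nadir-view assumption); improper sheet
   placement is a known error source of the field protocol itself.

## Design choices where the design was open

* **Median filter geometry.** "Window size of seven pixels" is read as a
  7×7 square window with reflected borders; a 7-element cross would barely
  denoise and is not what common imaging libraries mean by a 7-pixel median
  window.
* **Grayscale weights** are ITU-R BT.601 (0.299, 0.587, 0.114), the default
  of mainstream imaging libraries.
* **Watershed marker policy.** Markers are the regional maxima of the
  distance transform. Flooded regions are re-merged when the ridge between
  them has prominence below 1 distance unit — this absorbs the sub-pixel
  fluctuation of the discrete distance transform along the ridge of an
  elongated ear, which would otherwise oversplit — or when their peaks lie
  closer than 0.6× the median equivalent object diameter (two maxima inside
  one ear). The 0.6 factor adapts the separation floor to the ear size
  actually present. Two overlapping convex ears produce a saddle much deeper
  than 1, so they stay separate up to roughly 40% radial overlap; beyond
  that the method, like any distance-transform watershed, merges them.
* **Decoder upsampling** is nearest-neighbour followed by convolution rather
  than transposed convolution, avoiding checkerboard artifacts.
* **Loss clipping** at $\varepsilon = 10^{-7}$; the loss at a perfect
  prediction is bounded by $2\varepsilon|\log\varepsilon|$.
* **Optimizer.** Adam with standard moments (0.9/0.999); only the learning
  rate is part of the published recipe.
* **Regression orientation.** The evaluation regresses reference on
  estimate (reference as ordinate), matching how counts are usually plotted
  against an automatic method; $R^2$ is orientation-independent, and the
  orientation only affects the reported slope/offset.
* **Inference granularity.** Prediction runs per superpixel with mask-owned
  write-back rather than on the whole image; the candidate-region wording of
  the source architecture indicates region-wise inference, and it keeps the
  network input aspect fixed.
* **VIA class attribute.** The annotation reader takes the class from a
  configurable region attribute (default `class`, values `ear`/
  `background`); ears are polygons, background regions boxes.

## The synthetic canopy generator

Field images cannot ship with the package, so every stage is exercised on
generated scenes with exact ground truth: a low-frequency green/brown
background texture, golden elliptical ears with spikelet-like intensity
banding and optional thin awn strokes, a linear illumination gradient, soft
shadows, Gaussian blur, and optionally a white A4-like quadrilateral whose
corners are recorded exactly. Masks and instance labels are captured before
blurring, so ground truth stays crisp (an idealization — real annotation
boundaries are themselves uncertain). Awns are drawn in the image but not in
the masks, mirroring expert annotation practice that outlines the ear body;
the 7×7 median filter is expected to remove their 1-px-wide responses.

Default geometry scales mature field ears to desk size: 160×160 px scenes
with 12 ears of 20–28 px major and 9–13 px minor axis, up to 30% pairwise
overlap. Ear minor axes are kept above the 7-px median window so the
denoising step cannot erase a legitimate ear. The exact-count fixture family
(`sparse_scene_params()`) uses 224×224 scenes with 10 plain ears and a
14 px placement clearance: the edge baseline dilates its Sobel band (which
reaches ~3 px outside an ear) by two passes of a 5 px disc, so gaps below
~14 px would fuse neighbouring ears for reasons unrelated to the property
under test.

What passing on these scenes does **not** show: robustness to real canopy
texture (leaves and stems share the ears' hue at senescence), to motion
blur, to perspective distortion at short focal lengths, or to the severe
mutual occlusion of dense high-nitrogen plots. The generator's separability
guard (a fixed color threshold must reach 0.8 IoU against the ear mask)
deliberately keeps the fixtures easier than hard field images; the tests
validate the machinery, not field-level accuracy.

## Desk-scale problem sizes

The bundled experiments train a width-multiplier-0.125 network (widths
8/16/32/64) on 32×32 inputs with 200 synthetic patches plus two augmented
copies of each training patch (flips, rotation, zoom 0.5–1.5, HSV/
brightness/gamma jitter), 30 epochs at learning rate $10^{-3}$, batch 16 —
a few CPU-minutes while exercising the identical architecture, loss and
optimizer as the full-scale configuration. The augmentation is not optional
polish here: annotation-style training crops are ear-centred while inference
sees off-centre superpixel fragments at other scales, and without the
geometric variety the network under-covers ears at inference even at equal
validation accuracy. End-to-end evaluation uses 10 held-out scenes at 200
superpixels each. The learning rate is raised from the full-scale $10^{-4}$
because the desk-scale task is far smaller; the package defaults keep the
full-scale values.

## Numerical notes and degenerate inputs

* CIELAB uses the sRGB D65 matrices; agreement with `grDevices::convertColor`
  is within ~0.3 of an Lab unit (that function derives its matrix from
  chromaticities, so the last digits differ).
* SLIC assignment ties break toward the lower center index; relabeling after
  connectivity enforcement is row-major, making segmentations byte-stable.
* Tiny images fall back to global center search when $2S$ reaches the image
  size, which is also what makes the k-means oracle comparison exact.
* Empty masks count zero ears without error; empty cluster centers keep
  their previous position; gamma is validated positive; even median windows
  are rejected.
* All randomness (generator, augmentation, weight init, shuffling, splits)
  flows through R's RNG from explicit seeds; repeated runs are
  byte-identical on one CPU.

## Limitations

* The watershed merges ears overlapping beyond ~40% of their radius — a
  limitation shared with the original postprocessing, whose false negatives
  were attributed to exactly this failure mode.
* Ground-standard detection assumes the brightest low-saturation region is
  the sheet; scenes with specular highlights need manual corners
  (`ground_standard()`).
* No perspective rectification of the ground standard; densities from
  oblique sheets are biased.
* The network trains from random initialization; pretrained encoder weights
  are supported in principle by the architecture but not shipped.
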
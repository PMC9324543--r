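# musarch

Automatic extraction of skeletal-muscle architecture parameters from
longitudinal B-mode ultrasound images, for researchers and clinicians who
measure muscle geometry: rehabilitation and sports-science groups, muscle
physiologists, and anyone validating automatic ultrasound measurement
pipelines.

In a longitudinal scan a muscle is bounded by two bright aponeuroses with
oblique fascicle stripes between them. `musarch` measures the three standard
architecture parameters:

* **muscle thickness** `d` — mean perpendicular distance between the
  superficial and deep aponeurosis, from perpendicular chords cast along a
  centerline and averaged over five equal-arc-length sectors;
* **pennation angle** `θ` — acute angle between the fascicles and the deep
  aponeurosis, from an unsupervised extraction chain (CLAHE, multiscale
  Hessian ridge filter, 2-means binarisation, skeleton line fitting,
  collinearity merging, dominant-orientation clustering, extension with
  anatomical intersection pruning);
* **fascicle length** `L_F = d / sin θ`.

The aponeuroses come from a compact attention U-Net (weighted soft-Dice
loss, Adam, stepwise learning-rate decay, boundary-aware random erasing) —
fully bypassable by supplying a label mask — followed by a refinement step
that keeps the two largest connected components, bridges band gaps by
fitting a degree-2 polynomial through skeletonised fragments lying along
each candidate's x-axis band, and discards artifacts. Agreement metrics
(Dice, IoU, RMSE, ICC(2,1), Bland–Altman) are included.

Every stage is validated against a synthetic phantom generator with exactly
known geometry; see `vignettes/musarch-methods.Rmd` for the methods and the
design decisions.

## Worked example

Generate a phantom with known geometry (18 mm thick, 20° pennation,
moderate speckle), punch no gaps, and measure it end to end:

```r
library(musarch)

spec <- phantom_spec(width_px = 480, height_px = 420, pixel_spacing_mm = 0.1,
                     superficial_curve = c(50, 0.03, 0),
                     deep_curve = c(230, 0.03, 0),
                     fascicle_angle_deg = 20, noise_level = 0.2, seed = 42)
ph <- generate_phantom(spec)
ph$truth[c("thickness_mm", "pennation_deg", "fascicle_length_mm")]
#> d = 17.992 mm, theta = 20 deg, LF = 52.605 mm

report <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                        pixel_spacing_mm = 0.1, image_id = "phantom42")
report
#> <measurement_report> phantom42 [GCM]: d = 18.09 mm, theta = 20.03 deg, LF = 52.79 mm
#>   flags: aponeurosis_extended
```

The report recovers the true thickness within 0.1 mm and the true angle
within 0.03°; `LF` is the exact trigonometric estimate from the two, and the
flag records that some fascicle lines met the deep aponeurosis on its linear
extension beyond the image. With a trained model instead of a mask, pass
`model = train_segnet(...)` (or a checkpoint via `load_segnet()`); a
supplied mask always bypasses the model with identical downstream results.

A thin command-line front end with `simulate | train | segment | refine |
thickness | fascicles | measure | evaluate` subcommands is installed at
`inst/cli/musarch`.

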
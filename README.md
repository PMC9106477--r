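# FDCNet

Detection and classification of tumor-like objects in 2D and 3D grayscale
images, for image-analysis researchers who need a fully testable,
dependency-light reference implementation of a morphology + eigenimage +
fuzzy-CNN pipeline.

The package implements, end to end:

* **Preprocessing** — resize, classical histogram equalization, median
  filtering, Gaussian high-pass, and landmark-based de-rotation with
  `BASE = sqrt(((x5−x10)/2)² + ((y5−y10)/2)²)` normalization,
  origin `((x5−x10)/2, (y5−y10)/2)` and baseline angle
  `θ = arctan((y5−y10)/(x5−x10))`.
* **Set-theoretic morphology** — erosion `A⊖B = {z : B_z ⊆ A}`, dilation
  `A⊕B = {z : B̂_z ∩ A ≠ ∅}`, boundary `β(A) = A − (A⊖B)`, exact against
  brute-force definitions, with an edge-seeded segmentation stage
  thresholded at `3.5·σₙ`, `σₙ = median(|x|)/0.6745` (the MAD noise
  estimator).
* **Eigenimage features** — snapshot PCA: diagonalize the small `AᵀA`,
  lift via `Uᵢ = A·Vᵢ`, project `y = W(x − ψ)`, and match by strict
  Euclidean threshold `τ`.
* **FDCNet** — a 20-channel dilated (atrous) 3×3 convolution (rate 3), a
  10-unit Gaussian fuzzy layer (rate 7) fused as
  `x = tanh(w_d·y_d + w_f·y_f + b)`, dual stochastic + max pooling
  (rate 11), and a softmax head over benign / malignant / suspicious,
  trained by gradient descent with stopping rule `E = ½Σ|eᵢ|² < ε`.
* **Metrics** — accuracy, sensitivity, MSE, PSNR, SNR, ROC/AUC (trapezoid
  = pairwise rank statistic).
* **Synthetic phantoms** — a deterministic generator of labeled 2D/3D
  tumor phantoms with ground-truth masks, so every stage is testable
  without external data.

## Worked example

```r
library(FDCNet)

ph <- generatePhantom(phantomSpec(shape = c(64, 64), tumorRadius = 12,
                                  classLabel = "malignant", seed = 7))
ph
#> PhantomSample: 64x64, malignant, 429 tumor px (seed 7)

seg <- segmentFractal(medianFilter(ph$image))
seg
#> SegmentationResult: 397 mask px, 102 boundary px, threshold 8.306
maskIoU(seg$mask, ph$mask)
#> [1] 0.9209302
```

The segmentation recovers the 429-pixel tumor as a 397-pixel mask at
IoU 0.921; `threshold 8.306` is the MAD-based spike threshold computed
from the gradient map. `segmentationDescriptors(seg)` then summarizes the
region (area 397, compactness 2.08, within-region texture mean 11.2, …) —
the descriptors the classifier consumes alongside the pooled network
activations and eigen projection.

The full benchmark — 300 balanced phantoms, stratified 70/30 split,
gradient-descent training — runs in about ten seconds:

```r
bench <- runBenchmark()
bench$report
#> MetricsReport
#>   accuracy:     93.3333 %
#>   sensitivity:  93.3333 %
#>   ...
#>   AUC:           0.9876
```

A config-driven pipeline (`runPipeline()`) and a thin CLI
(`inst/scripts/fdcnet.R` with `synth`, `run`, `train`, `predict`, `eval`,
`search` subcommands; see `inst/extdata/example-config.yaml`) wrap the
same functions.

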
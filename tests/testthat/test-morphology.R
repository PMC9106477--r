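test_that("erosion and dilation match both set-theoretic brute-force routes", {
  full <- matrix(TRUE, 5, 5)
  expect_equal(sum(imgData(erodeMask(full))), 9)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(sum(imgData(dilateMask(one))), 9)
  expect_true(all(imgData(dilateMask(one))[2:4, 2:4]))

  empty <- matrix(FALSE, 6, 6)
  expect_false(any(imgData(erodeMask(empty))))
  expect_false(any(imgData(dilateMask(empty))))

  set.seed(61)
  for (i in 1:40) {
    A <- randomMask(12)
    expect_equal(imgData(erodeMask(A)), bruteErode(A))
    expect_equal(imgData(erodeMask(A)), bruteErodeComplement(A))
    expect_equal(imgData(dilateMask(A)), bruteDilate(A))
  }
})

test_that("morphology works with asymmetric structuring elements", {
  fp <- matrix(c(TRUE, TRUE, FALSE,
                 FALSE, TRUE, FALSE,
                 FALSE, TRUE, TRUE), 3, 3, byrow = TRUE)
  se <- StructuringElement(fp)
  set.seed(62)
  for (i in 1:20) {
    A <- randomMask(10)
    expect_equal(imgData(erodeMask(A, se)), bruteErode(A, fp, se@origin))
    expect_equal(imgData(dilateMask(A, se)), bruteDilate(A, fp, se@origin))
  }
})

test_that("boundary extraction is the mask minus its erosion", {
  sq <- matrix(FALSE, 8, 8); sq[3:6, 3:6] <- TRUE
  b <- imgData(maskBoundary(sq))
  expect_equal(sum(b), 12)                       # all but the 2x2 interior
  expect_false(any(b[4:5, 4:5]))

  px <- matrix(FALSE, 5, 5); px[2, 4] <- TRUE
  expect_equal(imgData(maskBoundary(px)), px)    # erosion empty

  full <- matrix(TRUE, 7, 7)
  bf <- imgData(maskBoundary(full))
  ring <- matrix(TRUE, 7, 7); ring[2:6, 2:6] <- FALSE
  expect_equal(bf, ring)                         # border-as-background
})

test_that("duality, monotonicity and the boundary partition hold", {
  set.seed(63)
  for (i in 1:30) {
    A <- randomMask(12)
    se <- boxSE(3, 2)
    # duality: the complement's outside is foreground for the complement
    dual <- !imgData(erodeMask(!A, se, pad = "foreground"))
    expect_equal(imgData(dilateMask(A, se)), dual)

    # monotonicity under adding foreground
    A2 <- A; A2[sample(length(A2), 8)] <- TRUE
    expect_true(all(imgData(erodeMask(A, se)) <= imgData(erodeMask(A2, se))))
    expect_true(all(imgData(dilateMask(A, se)) <= imgData(dilateMask(A2, se))))

    # partition: boundary and erosion are disjoint and union to A
    er <- imgData(erodeMask(A, se)); bd <- imgData(maskBoundary(A, se))
    expect_false(any(er & bd))
    expect_equal(er | bd, A)
  }
})

test_that("3D morphology agrees with a 3D brute-force check", {
  set.seed(64)
  A <- array(runif(6 * 6 * 6) < 0.5, c(6, 6, 6))
  er <- imgData(erodeMask(A))
  # spot-check every voxel against the definition
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    taps <- expand.grid(i + (-1:1), j + (-1:1), k + (-1:1))
    inside <- apply(taps, 1, function(t)
      all(t >= 1 & t <= 6) && A[t[1], t[2], t[3]])
    expect_identical(er[i, j, k], all(inside))
  }
})

test_that("noise sigma and spike threshold follow the MAD formula", {
  x <- c(-0.6745, 0.6745, 0.6745)
  expect_equal(noiseSigma(x), 1.0)
  expect_equal(spikeThreshold(x), 3.5)
  expect_equal(spikeThreshold(rep(0, 10)), 0)
  expect_error(noiseSigma(numeric(0)), "empty")
  expect_error(noiseSigma(c(1, NA)), "finite")

  set.seed(65)
  z <- rnorm(1e5)
  expect_lt(abs(noiseSigma(z) - 1), 0.02)

  # scale equivariance
  y <- rnorm(100)
  for (c in c(0.5, 3, 20))
    expect_equal(spikeThreshold(c * y), c * spikeThreshold(y))
})

test_that("segmentFractal recovers phantoms and degrades gracefully", {
  cst <- RawImage(matrix(128, 32, 32))
  seg <- segmentFractal(cst)
  expect_false(any(imgData(seg$mask)))
  expect_false(any(imgData(seg$boundary)))

  ph <- generatePhantom(phantomSpec(shape = c(64, 64), tumorRadius = 12,
                                    classLabel = "benign", contrast = 180,
                                    noiseSigma = 0, saltPepperRate = 0,
                                    seed = 41))
  seg <- segmentFractal(ph$image)
  expect_gte(maskIoU(seg$mask, ph$mask), 0.9)
  # boundary is a subset of the mask and feature maps share the shape
  expect_true(all(imgData(seg$boundary) <= imgData(seg$mask)))
  expect_equal(dim(seg$featureMaps$texture), c(64, 64))

  phn <- generatePhantom(phantomSpec(shape = c(64, 64), tumorRadius = 12,
                                     classLabel = "benign", contrast = 180,
                                     noiseSigma = 5, saltPepperRate = 0,
                                     seed = 42))
  expect_gte(maskIoU(segmentFractal(phn$image)$mask, phn$mask), 0.8)
})

test_that("segmentation descriptors track texture and boundary irregularity", {
  smooth <- generatePhantom(phantomSpec(shape = c(48, 48), tumorRadius = 10,
                                        irregularity = 0, textureAmplitude = 0,
                                        noiseSigma = 2, seed = 7))
  rough <- generatePhantom(phantomSpec(shape = c(48, 48), tumorRadius = 10,
                                       irregularity = 0.5,
                                       textureAmplitude = 45,
                                       noiseSigma = 2, seed = 7))
  ds <- segmentationDescriptors(smooth$image)
  dr <- segmentationDescriptors(rough$image)
  expect_named(ds, c("area", "perimeter", "compactness", "radialCV",
                     "radialMADratio", "textureMean", "textureQ75",
                     "intensitySD", "contrast", "edgeStrength"))
  expect_gt(dr[["textureMean"]], ds[["textureMean"]])
  expect_gt(dr[["radialCV"]], ds[["radialCV"]])
  # empty segmentation yields the zero vector
  expect_equal(unname(segmentationDescriptors(RawImage(matrix(3, 32, 32)))),
               numeric(10))
})
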
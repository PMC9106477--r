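test_that("phantom generation is bit-deterministic under spec + seed", {
  spec <- phantomSpec(shape = c(32, 32), tumorRadius = 7, seed = 123)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(imgData(a$image), imgData(b$image))
  expect_identical(imgData(a$mask), imgData(b$mask))

  c2 <- generatePhantom(phantomSpec(shape = c(32, 32), tumorRadius = 7,
                                    seed = 124))
  expect_false(identical(imgData(a$image), imgData(c2$image)))
})

test_that("zero contrast keeps the mask but removes the tumor signal", {
  spec0 <- phantomSpec(shape = c(48, 48), tumorRadius = 9, contrast = 0,
                       noiseSigma = 0, saltPepperRate = 0, seed = 5)
  ph <- generatePhantom(spec0)
  expect_gt(sum(imgData(ph$mask)), 0)
  inside <- imgData(ph$image)[imgData(ph$mask)]
  outside <- imgData(ph$image)[!imgData(ph$mask)]
  # background field only: means agree within its small amplitude
  expect_lt(abs(mean(inside) - mean(outside)), 10)
})

test_that("a zero-irregularity phantom is an exact ellipse", {
  spec <- phantomSpec(shape = c(64, 64), tumorRadius = 12, irregularity = 0,
                      noiseSigma = 0, saltPepperRate = 0, seed = 9)
  ph <- generatePhantom(spec)
  m <- imgData(ph$mask)
  # analytic area of the realized ellipse
  expected <- pi * ph$tumorRadius^2 * prod(ph$axisRatio)
  expect_lt(abs(sum(m) - expected) / expected, 0.05)
  # boundary pixel count scales with the analytic perimeter (the
  # chebyshev-thickness rim of a digital ellipse carries a geometric
  # factor; assert the stable empirical band)
  ab <- ph$tumorRadius * ph$axisRatio
  perim <- pi * (3 * (ab[1] + ab[2]) -
                 sqrt((3 * ab[1] + ab[2]) * (ab[1] + 3 * ab[2])))
  bcount <- sum(imgData(maskBoundary(ph$mask)))
  expect_gt(bcount / perim, 0.8)
  expect_lt(bcount / perim, 1.45)
})

test_that("datasets honor the class mix, master seed and radius jitter", {
  expect_length(generateDataset(0), 0)

  ds <- generateDataset(300, seed = 17,
                        baseSpec = phantomSpec(shape = c(32, 32),
                                               tumorRadius = 7))
  labels <- vapply(ds, `[[`, character(1), "label")
  expect_equal(unname(table(labels)["benign"]), 100, ignore_attr = TRUE)
  expect_equal(unname(table(labels)["malignant"]), 100, ignore_attr = TRUE)

  skew <- generateDataset(10, classMix = c(benign = 0.5, malignant = 0.3,
                                           suspicious = 0.2), seed = 1,
                          baseSpec = phantomSpec(shape = c(32, 32),
                                                 tumorRadius = 6))
  expect_equal(sum(vapply(skew, `[[`, character(1), "label") == "benign"), 5)

  ds2 <- generateDataset(10, seed = 18,
                         baseSpec = phantomSpec(shape = c(32, 32),
                                                tumorRadius = 7))
  ds1 <- generateDataset(10, seed = 17,
                         baseSpec = phantomSpec(shape = c(32, 32),
                                                tumorRadius = 7))
  expect_false(identical(imgData(ds1[[1]]$image), imgData(ds2[[1]]$image)))
  # same master seed is reproducible
  ds1b <- generateDataset(10, seed = 17,
                          baseSpec = phantomSpec(shape = c(32, 32),
                                                 tumorRadius = 7))
  expect_identical(imgData(ds1[[3]]$image), imgData(ds1b[[3]]$image))
})

test_that("tumor area tracks the analytic ellipse expectation over a dataset", {
  ds <- generateDataset(200, seed = 29,
                        baseSpec = phantomSpec(shape = c(48, 48),
                                               tumorRadius = 9,
                                               irregularity = 0))
  areas <- vapply(ds, function(s) sum(imgData(s$mask)), numeric(1))
  expected <- vapply(ds, function(s)
    pi * s$tumorRadius^2 * prod(s$axisRatio), numeric(1))
  expect_lt(abs(mean(areas) - mean(expected)) / mean(expected), 0.1)
})

test_that("class encodings are graded in irregularity and texture", {
  ds <- generateDataset(90, seed = 33,
                        baseSpec = phantomSpec(shape = c(32, 32),
                                               tumorRadius = 7))
  irr <- vapply(ds, `[[`, numeric(1), "irregularity")
  tex <- vapply(ds, `[[`, numeric(1), "textureAmplitude")
  lab <- vapply(ds, `[[`, character(1), "label")
  expect_lt(max(irr[lab == "benign"]), min(irr[lab == "suspicious"]))
  expect_lt(max(irr[lab == "suspicious"]), min(irr[lab == "malignant"]))
  expect_lt(max(tex[lab == "benign"]), min(tex[lab == "suspicious"]))
  expect_lt(max(tex[lab == "suspicious"]), min(tex[lab == "malignant"]))
})

test_that("oversized tumors are rejected and 3D phantoms work", {
  expect_error(phantomSpec(shape = c(16, 16), tumorRadius = 12), "too large")

  ph <- generatePhantom(phantomSpec(shape = c(24, 24, 12), tumorRadius = 5,
                                    seed = 2))
  expect_equal(dim(imgData(ph$image)), c(24, 24, 12))
  expect_gt(sum(imgData(ph$mask)), 0)
  expect_true(validObject(ph$image))
})

test_that("phantom datasets round-trip through disk", {
  ds <- generateDataset(4, seed = 3,
                        baseSpec = phantomSpec(shape = c(24, 24),
                                               tumorRadius = 5))
  dir <- tempfile("phantoms_")
  writePhantomDataset(ds, dir)
  tab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(tab), 4)
  back <- loadImage(file.path(dir, tab$filename[1]))
  expect_equal(dim(imgData(back)), c(24, 24))
  expect_lt(max(abs(imgData(back) - imgData(ds[[1]]$image))), 1)
  unlink(dir, recursive = TRUE)
})
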
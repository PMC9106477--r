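test_that("BASE is half the Euclidean landmark distance", {
  expect_equal(computeBase(landmarkPair(c(6, 8), c(0, 0))), 5)
  expect_equal(computeBase(landmarkPair(c(3, 4), c(3, 4))), 0)

  set.seed(21)
  for (i in 1:25) {
    p5 <- runif(2, 0, 100); p10 <- runif(2, 0, 100)
    expect_equal(computeBase(landmarkPair(p5, p10)),
                 sqrt(sum((p5 - p10)^2)) / 2)
  }
})

test_that("origin and angle follow the landmark formulas exactly", {
  lm <- landmarkPair(c(6, 8), c(0, 0))
  expect_equal(computeOrigin(lm), c(3, 4))
  expect_equal(computeOrigin(landmarkPair(c(1, 1), c(1, 1))), c(0, 0))
  # half-integer origins are not rounded
  expect_equal(computeOrigin(landmarkPair(c(2, 0), c(1, 0))), c(0.5, 0))

  expect_equal(rotationAngle(landmarkPair(c(1, 1), c(0, 0))), pi / 4)
  expect_equal(rotationAngle(landmarkPair(c(5, 3), c(1, 3))), 0)
  expect_equal(rotationAngle(landmarkPair(c(1, -1), c(0, 0))), -pi / 4)
  expect_error(rotationAngle(landmarkPair(c(2, 5), c(2, 0))), "vertical")
})

test_that("deskew inverts rotation away from borders and fixes symmetric disks", {
  # build a smooth test image so interpolation error is small
  g <- outer(1:48, 1:48, function(y, x) 100 + 60 * sin(x / 8) * cos(y / 9))
  img <- RawImage(g, maxValue = 255)
  expect_equal(imgData(deskew(img, 0)), imgData(img))

  th <- 0.3
  rt <- rotateImage(img, th)
  back <- deskew(rt, th)
  inner <- 13:36
  expect_lt(max(abs(imgData(back)[inner, inner] - g[inner, inner])), 2)

  # centered disk is rotation-invariant (1-px anti-aliased edge, so the
  # check isolates rotational symmetry from binarization aliasing)
  rho <- outer(1:63, 1:63, function(y, x) sqrt((x - 32)^2 + (y - 32)^2))
  disk <- RawImage(200 * pmin(pmax(20.5 - rho, 0), 1))
  d <- rho <= 20
  for (th in c(0.3, 0.7, 1.2)) {
    got <- imgData(deskew(disk, th)) > 100
    expect_gte(maskIoU(got, d), 0.98)
  }
})

test_that("resize preserves constants, no-ops at target, and keeps means", {
  cst <- RawImage(matrix(55, 17, 17))
  out <- resizeToStandard(cst, 32)
  expect_equal(dim(imgData(out)), c(32, 32))
  expect_true(all(abs(imgData(out) - 55) < 1e-6))

  img <- RawImage(matrix(runif(256 * 256) * 255, 256, 256))
  expect_identical(imgData(resizeToStandard(img, 256)), imgData(img))

  chk <- RawImage(255 * outer(1:128, 1:128, function(y, x) (x + y) %% 2))
  up <- resizeToStandard(chk, 256)
  expect_lt(abs(mean(imgData(up)) - mean(imgData(chk))) / mean(imgData(chk)),
            0.01)
})

test_that("histogram equalization maps the CDF and preserves rank order", {
  cst <- RawImage(matrix(77, 8, 8))
  expect_equal(imgData(equalizeHistogram(cst)), imgData(cst))

  # two-level image {10: 50%, 200: 50%}: CDF 0.5 and 1.0 -> levels 0 and 255
  two <- RawImage(matrix(c(rep(10, 32), rep(200, 32)), 8, 8))
  eq <- equalizeHistogram(two)
  lv <- sort(unique(as.numeric(imgData(eq))))
  expect_equal(lv, c(0, 255))
  expect_true(all((imgData(eq) == 0) == (imgData(two) == 10)))

  set.seed(5)
  img <- RawImage(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  eq <- equalizeHistogram(img)
  a <- as.numeric(imgData(img)); b <- as.numeric(imgData(eq))
  for (k in 1:200) {
    ij <- sample(length(a), 2)
    if (a[ij[1]] < a[ij[2]]) expect_lte(b[ij[1]], b[ij[2]])
  }
})

test_that("median filter matches the brute-force neighborhood oracle", {
  cst <- RawImage(matrix(9, 6, 6))
  expect_equal(imgData(medianFilter(cst)), imgData(cst))

  salt <- matrix(0, 5, 5); salt[3, 3] <- 255
  expect_true(all(imgData(medianFilter(RawImage(salt))) == 0))

  set.seed(31)
  for (k in c(3L, 5L)) {
    a <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    expect_equal(imgData(medianFilter(RawImage(a), k)),
                 bruteMedianFilter(a, k))
  }
  expect_error(medianFilter(RawImage(salt), 4), "odd")
})

test_that("high-pass filtering is a decomposition with maximal edge response", {
  cst <- RawImage(matrix(100, 16, 16))
  expect_true(all(imgData(highpassFilter(cst)) == 0))

  step <- RawImage(255 * outer(1:32, 1:32, function(y, x) x > 16))
  raw <- highpassFilter(step, rescale = FALSE)
  colResp <- colSums(abs(raw))
  expect_true(which.max(colResp) %in% c(16, 17))

  img <- RawImage(matrix(runif(100) * 255, 10, 10))
  a <- imgData(img)
  hp <- highpassFilter(img, sigma = 2, rescale = FALSE)
  lp <- a - hp
  expect_lt(max(abs((lp + hp) - a)), 1e-6)
})

test_that("the preprocessing chain preserves RawImage validity", {
  set.seed(8)
  img <- RawImage(matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24))
  out <- preprocessImage(img, preprocessConfig(targetSize = 24,
                                               derotate = TRUE))
  expect_s4_class(out, "RawImage")
  expect_true(all(is.finite(imgData(out))))
  expect_true(min(imgData(out)) >= 0 && max(imgData(out)) <= 255)
  expect_true(validObject(out))
})

test_that("foreground landmarks are detected and degenerate images give NULL", {
  a <- matrix(10, 32, 32); a[10:24, 14:18] <- 200   # vertical bar
  lm <- detectLandmarks(RawImage(a))
  expect_false(is.null(lm))
  expect_gt(computeBase(lm), 4)
  expect_null(detectLandmarks(RawImage(matrix(7, 16, 16))))
})
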
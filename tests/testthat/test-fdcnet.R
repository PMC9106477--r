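test_that("Gaussian basis and RBF forward evaluate their closed forms", {
  expect_equal(gaussianBasis(c(1, 2), c(1, 2), 3), 1)
  expect_equal(gaussianBasis(c(1, 1), c(0, 0), 1), exp(-1))
  expect_equal(gaussianBasis(2, 5, 1.7), gaussianBasis(5, 2, 1.7))
  expect_error(gaussianBasis(1, 1, 0), "sigma")

  expect_equal(rbfForward(c(0, 0), c(0, 0), rbind(c(1, 1), c(2, 2)), 1), 0)
  expect_equal(rbfForward(c(1, 1), 2, rbind(c(1, 1)), 1), 2)

  set.seed(81)
  v <- rnorm(3); w <- rnorm(4); Cm <- matrix(rnorm(12), 4, 3); s <- 1.3
  byHand <- 0
  for (i in 1:4) byHand <- byHand + w[i] * exp(-sum((v - Cm[i, ])^2) / (2 * s^2))
  expect_equal(rbfForward(v, w, Cm, s), byHand)
  expect_error(rbfForward(v, w[1:2], Cm, s), "weight")
})

test_that("training error follows E = half the squared residual norm", {
  expect_equal(trainingError(c(1, 2, 3), c(1, 2, 3))$E, 0)
  expect_equal(trainingError(c(3, 4), c(0, 0))$E, 12.5)
  set.seed(82)
  t0 <- rnorm(10); y0 <- rnorm(10)
  p <- sample(10)
  expect_equal(trainingError(t0, y0)$E, trainingError(t0[p], y0[p])$E)
})

test_that("gradient descent on the RBF head converges and respects zero gradients", {
  params <- list(weights = c(0.5), centers = rbind(c(0, 0)), sigma = 1)
  # already-perfect fit: zero residual, parameters unchanged
  batch0 <- list(inputs = rbind(c(0, 0)), targets = 0.5)
  expect_equal(gradientStep(params, batch0, 0.1)$weights, params$weights)

  # single sample, single unit: converges to near-zero error
  batch <- list(inputs = rbind(c(0.2, -0.1)), targets = 2)
  p <- params
  for (i in 1:500) p <- gradientStep(p, batch, 0.1)
  out <- rbfForward(batch$inputs[1, ], p$weights, p$centers, p$sigma)
  expect_lt(trainingError(batch$targets, out)$E, 1e-6)
  expect_error(gradientStep(params, batch, 0), "positive")
})

test_that("E is non-increasing under small-step descent on the linear head", {
  set.seed(83)
  V <- matrix(rnorm(20), 10, 2)
  tgt <- rnorm(10)
  p <- list(weights = rnorm(4), centers = matrix(rnorm(8), 4, 2), sigma = 1)
  batch <- list(inputs = V, targets = tgt)
  Ehist <- numeric(50)
  for (i in 1:50) {
    Phi <- vapply(seq_len(nrow(p$centers)), function(j)
      exp(-rowSums(sweep(V, 2, p$centers[j, ])^2) / (2 * p$sigma^2)),
      numeric(10))
    Ehist[i] <- trainingError(tgt, drop(Phi %*% p$weights))$E
    p <- gradientStep(p, batch, 0.05)
  }
  expect_true(all(diff(Ehist) <= 1e-10))
})

test_that("fuzzy fusion reduces correctly and stays inside (-1, 1)", {
  expect_equal(fuzzyFusionForward(0.01, 5, list(wd = 1, wf = 0, b = 0)),
               tanh(0.01))
  expect_equal(fuzzyFusionForward(3, 7, list(wd = 0, wf = 0, b = 0.4)),
               tanh(0.4))
  expect_equal(fuzzyFusionForward(1, 2, list(wd = 0.5, wf = 0.25, b = 0)),
               tanh(1))
  set.seed(84)
  yd <- matrix(rnorm(12), 3, 4); yf <- matrix(rnorm(12), 3, 4)
  out <- fuzzyFusionForward(yd, yf, list(wd = 0.7, wf = 0.2, b = 0.1))
  expect_true(all(abs(out) < 1))
  expect_error(fuzzyFusionForward(yd, yf[1:2, ], list(wd = 1, wf = 1, b = 0)),
               "shape")
})

test_that("pooling operators obey their degenerate and expectation contracts", {
  expect_equal(maxPool(c(4, 4, 4)), 4)
  expect_equal(stochasticPool(c(4, 4, 4)), 4)
  expect_equal(stochasticPool(c(4, 4, 4), "training"), 4)
  expect_equal(stochasticPool(c(0, 0, 5, 0)), 5)   # one-hot: probability 1
  expect_equal(stochasticPool(c(1, 3)), 2.5)       # (1*1 + 3*3) / 4
  expect_error(maxPool(numeric(0)), "empty")
})

test_that("network construction validates input size and counts parameters", {
  cfg <- fdcnetConfig(inputShape = c(16, 16))
  expect_error(buildNetwork(cfg), "minimum side is 23")

  cfg <- fdcnetConfig(inputShape = c(32, 32))
  net <- buildNetwork(cfg, seed = 9)
  # hand-computed: conv 9*20+20, mix 9, centers 10*20, widths 10,
  # fuzzy mixing 10*20, fusion 3
  expect_equal(parameterCount(net), 9 * 20 + 20 + 9 + 200 + 10 + 200 + 3)
  # identical seeds give bit-identical parameters, different seeds differ
  expect_identical(buildNetwork(cfg, seed = 9)$params, net$params)
  expect_false(identical(buildNetwork(cfg, seed = 10)$params, net$params))
})

test_that("forward features are deterministic and reduce to a plain CNN at wf = 0", {
  cfg <- fdcnetConfig(inputShape = c(32, 32))
  set.seed(85)
  imgs <- lapply(1:10, function(i)
    RawImage(matrix(runif(1024) * 255, 32, 32)))

  plain <- buildNetwork(cfg, seed = 4, fuzzy = FALSE)
  expect_equal(plain$params$wf, 0)
  for (im in imgs) {
    f1 <- fdcnetFeatures(plain, im, useFuzzy = TRUE)
    f2 <- fdcnetFeatures(plain, im, useFuzzy = FALSE)
    expect_identical(f1, f2)
  }
  # identically-seeded fuzzy network with wf forced to 0 matches the plain one
  fuz <- buildNetwork(cfg, seed = 4, fuzzy = TRUE)
  fuz$params$wf <- 0
  expect_identical(fdcnetFeatures(fuz, imgs[[1]]),
                   fdcnetFeatures(plain, imgs[[1]], useFuzzy = FALSE))
  # bit-stable across repeated forward passes
  expect_identical(fdcnetFeatures(fuz, imgs[[2]]),
                   fdcnetFeatures(fuz, imgs[[2]]))
})

test_that("maxConnectedLayer is the printed product and homogeneous in alpha", {
  expect_equal(maxConnectedLayer(1, 5, 5, 1.5, 0.5), 1)
  expect_equal(maxConnectedLayer(2, 1, 2, 10, 0), 10)
  set.seed(86)
  for (i in 1:10) {
    a <- runif(1, 0.1, 3); nc <- sample(1:5, 1); vh <- runif(1, 2, 5)
    expect_equal(maxConnectedLayer(2 * a, nc, 5, vh, 1),
                 2 * maxConnectedLayer(a, nc, 5, vh, 1))
  }
})

test_that("objective J and its gradient match brute force and finite differences", {
  # perfect fit with lambda 0
  X <- rbind(c(1, 0), c(0, 1)); Th <- rbind(c(2, 3))
  Y <- X %*% t(Th); R <- matrix(1, 2, 1)
  expect_equal(objectiveJ(X, Th, Y, R, 0), 0)

  # pure-regularization case
  expect_equal(objectiveJ(X, Th, Y, R, 0.5),
               0.5 / 2 * (sum(X^2) + sum(Th^2)))

  set.seed(87)
  X <- matrix(rnorm(6), 3, 2); Th <- matrix(rnorm(8), 4, 2)
  Y <- matrix(rnorm(12), 3, 4); R <- matrix(rbinom(12, 1, 0.6), 3, 4)
  lam <- 0.3
  # double-loop brute force
  J <- 0
  for (i in 1:3) for (j in 1:4) if (R[i, j] == 1)
    J <- J + 0.5 * (sum(Th[j, ] * X[i, ]) - Y[i, j])^2
  J <- J + lam / 2 * (sum(X^2) + sum(Th^2))
  expect_equal(objectiveJ(X, Th, Y, R, lam), J)
})

test_that("layer search recovers a planted optimum and is seed-stable", {
  cost <- function(cand) (cand$poolCount - 2)^2 + 0.01 * cand$budget

  one <- layerSearch(layerSearchConfig(nCandidates = 1, seed = 3), cost)
  expect_s3_class(one, "LayerSearchResult")

  res <- layerSearch(layerSearchConfig(nCandidates = 20, seed = 5), cost)
  expect_equal(res$candidate$poolCount, 2)
  expect_equal(res$config$poolLayers, 2L)

  res2 <- layerSearch(layerSearchConfig(nCandidates = 20, seed = 5), cost)
  expect_identical(res$candidate, res2$candidate)

  expect_error(layerSearch(layerSearchConfig(nCandidates = 0), cost),
               "candidate")
})

test_that("stratified split is deterministic, disjoint and class-balanced", {
  labels <- rep(c("benign", "malignant", "suspicious"), times = c(30, 40, 30))
  s1 <- stratifiedSplit(labels, 0.7, seed = 19)
  s2 <- stratifiedSplit(labels, 0.7, seed = 19)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_equal(sort(c(s1$train, s1$test)), seq_along(labels))
  expect_equal(sum(labels[s1$train] == "benign"), 21)
  expect_equal(sum(labels[s1$train] == "malignant"), 28)
})

test_that("training respects the stopping rule and produces sane predictions", {
  ds <- generateDataset(36, baseSpec = phantomSpec(shape = c(32, 32),
                                                   tumorRadius = 7),
                        seed = 23)
  samples <- lapply(ds, function(s) list(image = s$image, label = s$label))
  net <- buildNetwork(fdcnetConfig(inputShape = c(32, 32)), seed = 1)

  # an enormous threshold stops after the first epoch's bookkeeping
  t1 <- trainFDCNet(net, samples, trainConfig(epochs = 50, lossThreshold = 1e9,
                                              seed = 7))
  expect_equal(nrow(t1$history), 1)

  t2 <- trainFDCNet(net, samples, trainConfig(epochs = 120, seed = 7))
  expect_lt(t2$history$E[nrow(t2$history)], t2$history$E[1])

  p <- predictFDCNet(t2, samples[[1]]$image)
  expect_true(p$label %in% t2$classes)
  expect_equal(sum(p$scores), 1, tolerance = 1e-6)

  # single-class data refuses to train
  mono <- samples[vapply(samples, function(s) s$label == "benign", logical(1))]
  expect_error(trainFDCNet(net, mono, trainConfig()), "two classes")

  # a converged model memorizes a training image
  trIdx <- t2$split$train[1]
  expect_equal(predictFDCNet(t2, samples[[trIdx]]$image)$label,
               as.character(samples[[trIdx]]$label))
})

test_that("model checkpoints round-trip and predict identically", {
  ds <- generateDataset(24, baseSpec = phantomSpec(shape = c(32, 32),
                                                   tumorRadius = 7),
                        seed = 55)
  samples <- lapply(ds, function(s) list(image = s$image, label = s$label))
  net <- buildNetwork(fdcnetConfig(inputShape = c(32, 32)), seed = 2)
  tr <- trainFDCNet(net, samples, trainConfig(epochs = 60, seed = 7))
  dir <- tempfile("ckpt_")
  saveFDCNetModel(tr, dir)
  back <- loadFDCNetModel(dir)
  unlink(dir, recursive = TRUE)
  for (i in c(1, 5, 9)) {
    p1 <- predictFDCNet(tr, samples[[i]]$image)
    p2 <- predictFDCNet(back, samples[[i]]$image)
    expect_equal(p1$label, p2$label)
    expect_equal(p1$scores, p2$scores, tolerance = 1e-12)
  }
  # shape validation catches a mismatched config
  dir2 <- tempfile("ckpt_")
  saveFDCNetModel(tr, dir2)
  meta <- jsonlite::read_json(file.path(dir2, "model.json"),
                              simplifyVector = TRUE)
  meta$config$convChannels <- 7L
  jsonlite::write_json(meta, file.path(dir2, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(loadFDCNetModel(dir2), "shape")
  unlink(dir2, recursive = TRUE)
})
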
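#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run: phantom
#' generation (or input images), preprocessing, segmentation, eigen
#' features, the FDCNet classifier, and training. May be read from a YAML
#' file with top-level blocks \code{synth}, \code{preprocess}, \code{model},
#' \code{train}, and \code{seed}.
#'
#' @param nSamples phantoms to generate when no input images are given.
#' @param imageShape phantom shape (default \code{c(32, 32)}).
#' @param tumorRadius base phantom radius (default 7).
#' @param preprocess a [preprocessConfig()].
#' @param model an [fdcnetConfig()]; its input shape must match the images
#'   after preprocessing.
#' @param train a [trainConfig()].
#' @param seed master seed; stage seeds are derived from it.
#' @param inputDir optional directory of images + labels.csv to use instead
#'   of generated phantoms.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(nSamples = 60L, imageShape = c(32L, 32L),
                           tumorRadius = 7,
                           preprocess = preprocessConfig(
                             targetSize = imageShape[1], highpass = FALSE,
                             equalize = FALSE),
                           model = fdcnetConfig(inputShape = imageShape),
                           train = trainConfig(),
                           seed = 17L, inputDir = NULL) {
  structure(list(nSamples = as.integer(nSamples),
                 imageShape = as.integer(imageShape),
                 tumorRadius = tumorRadius, preprocess = preprocess,
                 model = model, train = train, seed = as.integer(seed),
                 inputDir = inputDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with optional blocks \code{synth} (nSamples, shape,
#'   tumorRadius), \code{preprocess} (fields of [preprocessConfig()]),
#'   \code{train} (fields of [trainConfig()]) and a scalar \code{seed}.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  shape <- as.integer(y$synth$shape %||% c(32L, 32L))
  pp <- do.call(preprocessConfig,
                c(list(targetSize = shape[1]),
                  y$preprocess[intersect(names(y$preprocess),
                    c("medianKernel", "highpassSigma", "equalize", "median",
                      "highpass", "derotate"))]))
  tr <- do.call(trainConfig,
                y$train[intersect(names(y$train),
                  c("learningRate", "epochs", "trainFraction",
                    "lossThreshold", "seed", "ridge"))] %||% list())
  pipelineConfig(nSamples = as.integer(y$synth$nSamples %||% 60L),
                 imageShape = shape,
                 tumorRadius = y$synth$tumorRadius %||% 7,
                 preprocess = pp, train = tr,
                 model = fdcnetConfig(inputShape = shape),
                 seed = as.integer(y$seed %||% 17L),
                 inputDir = y$io$inputDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes the stages in order: data (generate phantoms or load a labeled
#' directory), preprocessing, segmentation (per-image masks and IoU against
#' ground truth when available), FDCNet training with eigen features, test
#' prediction, and metric computation. Writes per-image masks, the eigen
#' model archive, the metrics JSON, and a manifest with the configuration
#' hash, seeds, and per-stage timings. The manifest's \code{contentHash}
#' (computed over everything except timings) is identical across runs with
#' the same config and seed.
#'
#' @param config a [pipelineConfig()] or path to a YAML file.
#' @param outDir output directory.
#' @return The manifest, invisibly (a list; also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("fdcnet_run_")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); tic <- function() proc.time()[["elapsed"]]

  stage <- "data"; t0 <- tic()
  dataset <- tryCatch({
    if (!is.null(config$inputDir)) loadLabeledDataset(config$inputDir)
    else generateDataset(config$nSamples,
                         baseSpec = phantomSpec(shape = config$imageShape,
                                                tumorRadius = config$tumorRadius),
                         seed = deriveSeed(config$seed, 1L))
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e)))
  timings$data <- tic() - t0
  if (length(dataset) == 0L) {
    warning("runPipeline: empty input; writing an empty manifest")
    manifest <- list(nSamples = 0L, seed = config$seed, contentHash = contentHash(list()))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
    return(invisible(manifest))
  }

  stage <- "preprocess"; t0 <- tic()
  images <- tryCatch(
    lapply(dataset, function(s) preprocessImage(s$image, config$preprocess)),
    error = function(e) stop("pipeline stage '", stage, "' failed: ",
                             conditionMessage(e)))
  timings$preprocess <- tic() - t0

  stage <- "segment"; t0 <- tic()
  maskDir <- file.path(outDir, "masks")
  dir.create(maskDir, showWarnings = FALSE)
  ious <- tryCatch(vapply(seq_along(dataset), function(i) {
    seg <- segmentFractal(images[[i]])
    saveMask(seg$mask, file.path(maskDir, sprintf("mask_%04d.png", i)))
    if (!is.null(dataset[[i]]$mask)) maskIoU(seg$mask, dataset[[i]]$mask)
    else NA_real_
  }, numeric(1)),
  error = function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e)))
  timings$segment <- tic() - t0

  stage <- "train"; t0 <- tic()
  samples <- lapply(seq_along(dataset), function(i)
    list(image = images[[i]], label = dataset[[i]]$label))
  net <- buildNetwork(config$model, seed = deriveSeed(config$seed, 2L))
  trained <- tryCatch(trainFDCNet(net, samples, config$train),
                      error = function(e) stop("pipeline stage '", stage,
                                               "' failed: ",
                                               conditionMessage(e)))
  saveEigenModel(trained$eigenModel, file.path(outDir, "eigen_model"),
                 provenance = list(seed = config$seed,
                                   M = length(trained$split$train)))
  timings$train <- tic() - t0

  stage <- "evaluate"; t0 <- tic()
  testIdx <- trained$split$test
  truth <- vapply(samples[testIdx], function(s) as.character(s$label),
                  character(1))
  pred <- predictFDCNetBatch(trained, lapply(samples[testIdx], `[[`, "image"))
  noisy <- imgData(dataset[[1]]$image)
  den <- imgData(medianFilter(dataset[[1]]$image))
  report <- metricsReport(truth, pred$labels, scores = pred$scores,
                          reference = den, degraded = noisy)
  writeMetricsReport(report, file.path(outDir, "metrics.json"))
  timings$evaluate <- tic() - t0

  manifest <- list(
    nSamples = length(dataset),
    seed = config$seed,
    classes = trained$classes,
    testAccuracy = report@accuracy,
    meanSegmentationIoU = mean(ious, na.rm = TRUE),
    epochsRun = nrow(trained$history),
    finalE = trained$history$E[nrow(trained$history)]
  )
  manifest$contentHash <- contentHash(manifest)
  manifest$timings <- timings
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Read a directory written by writePhantomDataset(): images + labels.csv.
loadLabeledDataset <- function(dir) {
  csv <- file.path(dir, "labels.csv")
  if (!file.exists(csv)) stop("no labels.csv in ", dir)
  tab <- utils::read.csv(csv)
  lapply(seq_len(nrow(tab)), function(i)
    list(image = loadImage(file.path(dir, tab$filename[i])),
         label = tab$label[i], mask = NULL))
}

#' Run the canonical synthetic benchmark
#'
#' The package's reference evaluation: a balanced 3-class phantom dataset
#' (default n = 300, generator seed 17), median-filtered, used to train the
#' default FDCNet (training seed 42, stratified 70/30 split) and scored on
#' the held-out third. Deterministic for fixed seeds.
#'
#' @param n dataset size (default 300, balanced classes).
#' @param shape phantom shape (default \code{c(32, 32)}).
#' @param tumorRadius base radius (default 7).
#' @param generatorSeed phantom-generation seed (default 17).
#' @param trainSeed split/training seed (default 42).
#' @param networkSeed parameter-initialization seed (default 42).
#' @param epochs training epochs (default 600).
#' @return List with \code{accuracy} (fraction), \code{report}
#'   (a [MetricsReport-class]), \code{model}, \code{truth}, \code{pred},
#'   and \code{meanIoU} of [segmentFractal()] over the test images.
#' @export
runBenchmark <- function(n = 300L, shape = c(32L, 32L), tumorRadius = 7,
                         generatorSeed = 17L, trainSeed = 42L,
                         networkSeed = 42L, epochs = 600L) {
  ds <- generateDataset(n, baseSpec = phantomSpec(shape = shape,
                                                  tumorRadius = tumorRadius),
                        seed = generatorSeed)
  samples <- lapply(ds, function(s)
    list(image = medianFilter(s$image), label = s$label))
  net <- buildNetwork(fdcnetConfig(inputShape = shape), seed = networkSeed)
  trained <- trainFDCNet(net, samples,
                         trainConfig(seed = trainSeed, epochs = epochs))
  testIdx <- trained$split$test
  truth <- vapply(samples[testIdx], function(s) as.character(s$label),
                  character(1))
  pred <- predictFDCNetBatch(trained, lapply(samples[testIdx], `[[`, "image"))
  ious <- vapply(testIdx, function(i)
    maskIoU(segmentFractal(samples[[i]]$image)$mask, ds[[i]]$mask),
    numeric(1))
  report <- metricsReport(truth, pred$labels, scores = pred$scores)
  list(accuracy = mean(pred$labels == truth), report = report,
       model = trained, truth = truth, pred = pred, meanIoU = mean(ious))
}
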
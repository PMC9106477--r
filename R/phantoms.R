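#' Phantom specification
#'
#' Parameters of one synthetic tumor phantom: a smooth low-frequency
#' background, a radially perturbed elliptical (2D) or ellipsoidal (3D)
#' tumor of the given radius and contrast, within-tumor texture modulation,
#' and Gaussian-then-salt-and-pepper noise. The three class labels encode
#' graded boundary irregularity and texture: benign is smooth and
#' homogeneous, malignant is irregular and strongly textured, suspicious is
#' intermediate and overlaps both.
#'
#' @param shape integer image shape, e.g. \code{c(64, 64)} or
#'   \code{c(32, 32, 16)}.
#' @param classLabel one of \code{"benign"}, \code{"malignant"},
#'   \code{"suspicious"}.
#' @param tumorRadius nominal radius in pixels; the perturbed tumor must fit
#'   inside the frame.
#' @param irregularity radial perturbation amplitude in [0, 1]
#'   (\code{NULL}: drawn from the class-specific range).
#' @param contrast tumor-minus-background intensity gap (default 120).
#' @param textureAmplitude within-tumor intensity modulation SD
#'   (\code{NULL}: class-specific).
#' @param noiseSigma additive Gaussian noise SD (default 5).
#' @param saltPepperRate fraction of pixels replaced by 0 or 255
#'   (default 0.002).
#' @param seed RNG seed; identical spec + seed gives a bit-identical sample.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(shape = c(64L, 64L), classLabel = "benign",
                        tumorRadius = 12, irregularity = NULL,
                        contrast = 120, textureAmplitude = NULL,
                        noiseSigma = 5, saltPepperRate = 0.002,
                        seed = 1L) {
  classLabel <- match.arg(classLabel, c("benign", "malignant", "suspicious"))
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 8),
            saltPepperRate >= 0, saltPepperRate <= 1, noiseSigma >= 0,
            tumorRadius > 0)
  if (!is.null(irregularity))
    stopifnot(irregularity >= 0, irregularity <= 1)
  if (tumorRadius * 1.6 >= min(shape))
    stop("tumorRadius ", tumorRadius, " is too large for shape ",
         paste(shape, collapse = "x"))
  structure(list(shape = as.integer(shape), classLabel = classLabel,
                 tumorRadius = tumorRadius, irregularity = irregularity,
                 contrast = contrast, textureAmplitude = textureAmplitude,
                 noiseSigma = noiseSigma, saltPepperRate = saltPepperRate,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Class-conditional parameter ranges: benign smooth/homogeneous, malignant
# irregular/textured, suspicious intermediate with overlap into both.
classRanges <- list(
  benign     = list(irregularity = c(0.00, 0.10), texture = c(0, 10)),
  malignant  = list(irregularity = c(0.35, 0.55), texture = c(30, 50)),
  suspicious = list(irregularity = c(0.12, 0.30), texture = c(10, 30))
)

# Smooth low-frequency random field: a sum of low-frequency cosines.
smoothField <- function(d, amplitude, nWaves = 3L) {
  nd <- length(d)
  coords <- lapply(d, seq_len)
  g <- do.call(expand.grid, coords)
  field <- 0
  for (w in seq_len(nWaves)) {
    freq <- stats::runif(nd, 0.2, 1) / d     # 0.2 to 1 cycles per axis
    phase <- stats::runif(1, 0, 2 * pi)
    arg <- 2 * pi * as.matrix(g) %*% freq + phase
    field <- field + cos(arg)
  }
  array(amplitude * field / sqrt(nWaves), d)
}

#' Generate one labeled phantom
#'
#' Draws (deterministically under the spec's seed) a background field, a
#' radially perturbed ellipse/ellipsoid at a random interior location, a
#' within-tumor texture field, and finally Gaussian and salt-and-pepper
#' noise. The ground-truth mask records the noise-free tumor support; with
#' \code{contrast = 0} the mask is still recorded but the image carries no
#' tumor signal (a hard negative).
#'
#' @param spec a [phantomSpec()].
#' @return A list of class \code{"PhantomSample"}: \code{image}
#'   ([RawImage-class]), \code{mask} ([BinaryMask-class]), \code{label},
#'   \code{seed}, and the realized \code{irregularity} and
#'   \code{textureAmplitude}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' ph$image
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$shape; nd <- length(d)
  withSeed(spec$seed, {
    rng <- classRanges[[spec$classLabel]]
    irr <- if (is.null(spec$irregularity))
      stats::runif(1, rng$irregularity[1], rng$irregularity[2])
      else spec$irregularity
    tex <- if (is.null(spec$textureAmplitude))
      stats::runif(1, rng$texture[1], rng$texture[2])
      else spec$textureAmplitude

    bg <- 60 + smoothField(d, amplitude = 10)

    margin <- ceiling(spec$tumorRadius * (1 + irr) + 2)
    center <- vapply(d, function(n) {
      if (margin + 1 >= n - margin) (n + 1) / 2
      else stats::runif(1, margin + 1, n - margin)
    }, numeric(1))
    axisRatio <- stats::runif(nd, 0.75, 1)
    axisRatio <- axisRatio / max(axisRatio)
    nHarm <- 4L
    amps <- stats::rnorm(nHarm)
    phases <- stats::runif(nHarm, 0, 2 * pi)
    ampNorm <- sum(abs(amps))

    coords <- do.call(expand.grid, lapply(d, seq_len))
    cc <- sweep(as.matrix(coords), 2L, center)
    cs <- sweep(cc, 2L, spec$tumorRadius * axisRatio, `/`)
    rad <- sqrt(rowSums(cs^2))
    theta <- atan2(cs[, 2], cs[, 1])
    pert <- if (ampNorm > 0 && irr > 0) {
      p <- 0
      for (k in seq_len(nHarm))
        p <- p + amps[k] * cos((k + 1) * theta + phases[k])
      1 + irr * p / ampNorm
    } else 1
    mask <- array(rad <= pert, d)

    img <- bg
    if (spec$contrast != 0) {
      img[mask] <- img[mask] + spec$contrast
      if (tex > 0)
        img[mask] <- img[mask] + stats::rnorm(sum(mask), sd = tex)
    }
    if (spec$noiseSigma > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noiseSigma)
    if (spec$saltPepperRate > 0) {
      n <- length(img)
      hit <- which(stats::runif(n) < spec$saltPepperRate)
      if (length(hit))
        img[hit] <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
    }
    img <- array(pmin(pmax(img, 0), 255), d)
    structure(list(image = RawImage(img, maxValue = 255),
                   mask = BinaryMask(mask), label = spec$classLabel,
                   seed = spec$seed, irregularity = irr,
                   textureAmplitude = tex, tumorRadius = spec$tumorRadius,
                   axisRatio = axisRatio, center = center),
              class = "PhantomSample")
  })
}

#' @export
print.PhantomSample <- function(x, ...) {
  cat(sprintf("PhantomSample: %s, %s, %d tumor px (seed %d)\n",
              paste(dim(imgData(x$image)), collapse = "x"), x$label,
              sum(imgData(x$mask)), x$seed))
  invisible(x)
}

#' Generate a labeled phantom dataset
#'
#' Produces \code{n} samples whose class counts follow \code{classMix}
#' (largest-remainder rounding); per-sample seeds are derived
#' deterministically from the master seed, and per-sample tumor radius is
#' jittered ±30% around the base spec's radius.
#'
#' @param n number of samples (0 gives an empty list).
#' @param classMix named proportions over the three classes, summing to 1.
#' @param baseSpec template [phantomSpec()]; per-sample fields
#'   (class, seed, radius) are overridden.
#' @param seed master seed.
#' @return List of \code{PhantomSample} objects.
#' @examples
#' ds <- generateDataset(6, seed = 17)
#' table(vapply(ds, `[[`, character(1), "label"))
#' @export
generateDataset <- function(n,
                            classMix = c(benign = 1/3, malignant = 1/3,
                                         suspicious = 1/3),
                            baseSpec = phantomSpec(), seed = 17L) {
  stopifnot(n >= 0, abs(sum(classMix) - 1) < 1e-8)
  if (n == 0L) return(list())
  counts <- largestRemainder(n, classMix)
  labels <- rep(names(counts), counts)
  lapply(seq_len(n), function(i) {
    s <- deriveSeed(seed, i)
    radius <- withSeed(deriveSeed(seed, 100000L + i),
                       baseSpec$tumorRadius * stats::runif(1, 0.7, 1.3))
    spec <- phantomSpec(shape = baseSpec$shape, classLabel = labels[i],
                        tumorRadius = radius,
                        irregularity = baseSpec$irregularity,
                        contrast = baseSpec$contrast,
                        textureAmplitude = baseSpec$textureAmplitude,
                        noiseSigma = baseSpec$noiseSigma,
                        saltPepperRate = baseSpec$saltPepperRate,
                        seed = s)
    generatePhantom(spec)
  })
}

# Largest-remainder apportionment of n into the given proportions.
largestRemainder <- function(n, mix) {
  q <- n * mix
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Write a phantom dataset to disk
#'
#' Writes each image (PNG for 2D, NIfTI for 3D), its ground-truth mask, and
#' a labels CSV (filename, label, seed).
#'
#' @param dataset list from [generateDataset()].
#' @param dir output directory (created if absent).
#' @return Path of the labels CSV, invisibly.
#' @export
writePhantomDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- function(s) if (length(dim(imgData(s$image))) == 2L) ".png" else ".nii.gz"
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    fn <- sprintf("phantom_%04d%s", i, ext(s))
    saveImage(s$image, file.path(dir, fn))
    saveMask(s$mask, file.path(dir, sub("phantom_", "mask_", fn)))
    data.frame(filename = fn, label = s$label, seed = s$seed)
  })
  csv <- file.path(dir, "labels.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
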
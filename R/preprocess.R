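#' Landmark pair for BASE normalization and de-rotation
#'
#' Two reference points (in pixel coordinates, x = column, y = row) whose
#' half-distance defines the BASE normalization constant and whose baseline
#' angle drives de-rotation.
#'
#' @param p5,p10 numeric length-2 vectors \code{c(x, y)}.
#' @return An object of class \code{"LandmarkPair"}.
#' @examples
#' landmarkPair(c(6, 8), c(0, 0))
#' @export
landmarkPair <- function(p5, p10) {
  stopifnot(length(p5) == 2L, length(p10) == 2L,
            all(is.finite(p5)), all(is.finite(p10)))
  structure(list(p5 = as.numeric(p5), p10 = as.numeric(p10)),
            class = "LandmarkPair")
}

#' @export
print.LandmarkPair <- function(x, ...) {
  cat(sprintf("LandmarkPair: p5 = (%g, %g), p10 = (%g, %g)\n",
              x$p5[1], x$p5[2], x$p10[1], x$p10[2]))
  invisible(x)
}

#' BASE normalization constant
#'
#' \code{BASE = sqrt(((x5 - x10)/2)^2 + ((y5 - y10)/2)^2)}: half the
#' Euclidean distance between the two landmarks. Zero iff the landmarks
#' coincide; downstream normalization must reject a zero BASE.
#'
#' @param landmarks a [landmarkPair()].
#' @return Non-negative scalar.
#' @examples
#' computeBase(landmarkPair(c(6, 8), c(0, 0)))  # 5
#' @export
computeBase <- function(landmarks) {
  stopifnot(inherits(landmarks, "LandmarkPair"))
  d <- (landmarks$p5 - landmarks$p10) / 2
  sqrt(sum(d^2))
}

#' Coordinate origin from landmarks
#'
#' \code{x0 = (x5 - x10)/2}, \code{y0 = (y5 - y10)/2}, exactly as defined;
#' half-integer results are not rounded.
#'
#' @param landmarks a [landmarkPair()].
#' @return Numeric \code{c(x0, y0)}.
#' @export
computeOrigin <- function(landmarks) {
  stopifnot(inherits(landmarks, "LandmarkPair"))
  (landmarks$p5 - landmarks$p10) / 2
}

#' Baseline rotation angle
#'
#' \code{theta = arctan((y5 - y10) / (x5 - x10))}, the angle of the landmark
#' baseline relative to the horizon, in \code{(-pi/2, pi/2)}. A vertical
#' baseline (x5 = x10) is an error: the formula is undefined there.
#'
#' @param landmarks a [landmarkPair()].
#' @return Angle in radians.
#' @export
rotationAngle <- function(landmarks) {
  stopifnot(inherits(landmarks, "LandmarkPair"))
  dx <- landmarks$p5[1] - landmarks$p10[1]
  dy <- landmarks$p5[2] - landmarks$p10[2]
  if (dx == 0) stop("vertical baseline: rotation angle undefined (x5 = x10)")
  atan(dy / dx)
}

#' Default landmarks from the image foreground
#'
#' When no anatomical landmarks are supplied, the two extremal points of the
#' Otsu-thresholded foreground along its principal (major) axis are used.
#' Returns \code{NULL} when no foreground is found (BASE normalization is
#' then skipped).
#'
#' @param image a grayscale [RawImage-class].
#' @return A [landmarkPair()] or \code{NULL}.
#' @export
detectLandmarks <- function(image) {
  a <- asImageArray(image)
  if (length(dim(a)) == 3L) a <- a[, , (dim(a)[3] + 1L) %/% 2L]
  mx <- if (is(image, "RawImage")) maxValue(image) else max(1, max(a))
  u <- a / mx
  thr <- tryCatch(EBImage::otsu(EBImage::Image(u)), error = function(e) NA)
  if (!is.finite(thr)) return(NULL)
  fg <- which(u > thr, arr.ind = TRUE)
  if (nrow(fg) < 2L) return(NULL)
  xy <- cbind(x = fg[, 2], y = fg[, 1])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% v
  landmarkPair(xy[which.max(proj), ], xy[which.min(proj), ])
}

#' Rotate an image about an arbitrary origin
#'
#' Bilinear inverse-mapped rotation; pixels sampled from outside the frame
#' are filled with 0 and the output shape equals the input shape. 3D volumes
#' are rotated slice by slice (in-plane).
#'
#' @param image [RawImage-class] or array.
#' @param angle rotation in radians (counter-clockwise in x/y coordinates).
#' @param origin center of rotation \code{c(x, y)}; defaults to the image center.
#' @return A [RawImage-class].
#' @export
rotateImage <- function(image, angle, origin = NULL) {
  img <- if (is(image, "RawImage")) image else RawImage(image)
  a <- imgData(img)
  nd <- length(dim(a))
  if (nd == 3L && img@channels != "rgb") {
    out <- a
    for (k in seq_len(dim(a)[3]))
      out[, , k] <- rotatePlane(a[, , k], angle, origin)
    return(RawImage(pmin(pmax(out, 0), img@maxValue), img@maxValue,
                    spacing = img@spacing))
  }
  RawImage(pmin(pmax(rotatePlane(a, angle, origin), 0), img@maxValue),
           img@maxValue, spacing = img@spacing)
}

rotatePlane <- function(m, angle, origin = NULL) {
  h <- nrow(m); w <- ncol(m)
  if (is.null(origin)) origin <- c((w + 1) / 2, (h + 1) / 2)
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  dx <- g$x - origin[1]; dy <- g$y - origin[2]
  sx <- origin[1] + cos(angle) * dx + sin(angle) * dy
  sy <- origin[2] - sin(angle) * dx + cos(angle) * dy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(y0, x0) +
         fx * (1 - fy) * val(y0, x0 + 1) +
         (1 - fx) * fy * val(y0 + 1, x0) +
         fx * fy * val(y0 + 1, x0 + 1)
  matrix(out, h, w)
}

#' Remove the baseline rotation from an image
#'
#' Rotates by \code{-angle} about \code{origin}, undoing the rotation
#' measured by [rotationAngle()]; bilinear interpolation, zero fill,
#' shape preserved.
#'
#' @inheritParams rotateImage
#' @return A [RawImage-class].
#' @export
deskew <- function(image, angle, origin = NULL) {
  stopifnot(is.finite(angle))
  rotateImage(image, -angle, origin)
}

#' Resize to the standard square size
#'
#' Bilinear resize to \code{targetSize x targetSize} (per slice for 3D
#' volumes); the intensity range is preserved.
#'
#' @param image [RawImage-class] or array.
#' @param targetSize side length in pixels (default 256).
#' @return A [RawImage-class].
#' @export
resizeToStandard <- function(image, targetSize = 256L) {
  stopifnot(targetSize > 0)
  img <- if (is(image, "RawImage")) image else RawImage(image)
  a <- imgData(img)
  nd <- length(dim(a))
  rs <- function(m) as.array(EBImage::resize(EBImage::Image(m),
                                             w = targetSize, h = targetSize))
  if (nd == 2L) {
    if (all(dim(a) == targetSize)) return(img)
    out <- matrix(rs(t(a)), targetSize, targetSize)  # EBImage is x-major
    out <- t(out)
  } else {
    out <- array(0, c(targetSize, targetSize, dim(a)[3]))
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(matrix(rs(t(a[, , k])),
                                                         targetSize, targetSize))
  }
  RawImage(pmin(pmax(out, 0), img@maxValue), img@maxValue,
           channels = img@channels, spacing = img@spacing)
}

#' Classical histogram equalization
#'
#' 256-bin CDF remapping over \code{[0, maxValue]}. The mapping is monotone
#' (pixel rank order is preserved) and spreads the occupied bins across the
#' full range; a constant image is returned unchanged.
#'
#' @param image grayscale [RawImage-class] or array.
#' @param nbins number of histogram bins (default 256).
#' @return A [RawImage-class].
#' @export
equalizeHistogram <- function(image, nbins = 256L) {
  img <- if (is(image, "RawImage")) image else RawImage(image)
  if (img@channels == "rgb") stop("equalizeHistogram expects grayscale input")
  a <- imgData(img); mx <- img@maxValue
  bin <- pmin(floor(a / mx * nbins), nbins - 1L) + 1L
  counts <- tabulate(bin, nbins)
  cdf <- cumsum(counts) / length(a)
  cdfMin <- cdf[which(counts > 0)[1]]
  if (cdfMin >= 1) return(img)                       # constant image
  mapped <- (cdf - cdfMin) / (1 - cdfMin) * mx
  out <- array(mapped[bin], dim = dim(a))
  RawImage(pmin(pmax(out, 0), mx), mx, spacing = img@spacing)
}

#' Median filter with reflect padding
#'
#' Per-pixel median over a \code{kernel^ndim} neighborhood (square for 2D,
#' cubic for 3D), with mirror-reflected edges.
#'
#' @param image grayscale [RawImage-class] or array.
#' @param kernel odd window side length (default 3).
#' @return A [RawImage-class].
#' @export
medianFilter <- function(image, kernel = 3L) {
  if (kernel %% 2L != 1L || kernel < 1L) stop("kernel must be an odd integer >= 1")
  img <- if (is(image, "RawImage")) image else RawImage(image, maxValue = max(1, max(image)))
  a <- imgData(img); d <- dim(a)
  r <- (kernel - 1L) %/% 2L
  offs <- as.matrix(do.call(expand.grid, rep(list(-r:r), length(d))))
  nb <- vapply(seq_len(nrow(offs)),
               function(i) a[reflectShiftIndex(d, offs[i, ])],
               numeric(length(a)))
  med <- apply(nb, 1L, stats::median.default)
  RawImage(array(med, d), img@maxValue, spacing = img@spacing)
}

#' High-pass filter (unsharp residual)
#'
#' Subtracts a Gaussian low-pass version (sigma default 2) from the image,
#' emphasizing edges and fine detail. With \code{rescale = TRUE} the residual
#' is linearly rescaled to \code{[0, maxValue]}; with \code{rescale = FALSE}
#' the raw residual is returned (so that low-pass + high-pass reconstructs
#' the input exactly). 3D volumes are filtered slice by slice.
#'
#' @param image grayscale [RawImage-class] or array.
#' @param sigma Gaussian low-pass standard deviation in pixels.
#' @param rescale rescale the residual into the image range (default TRUE).
#' @return A [RawImage-class] (rescaled) or numeric array (raw residual).
#' @export
highpassFilter <- function(image, sigma = 2, rescale = TRUE) {
  img <- if (is(image, "RawImage")) image else RawImage(image, maxValue = max(1, max(image)))
  if (img@channels == "rgb") stop("highpassFilter expects grayscale input")
  a <- imgData(img); d <- dim(a)
  lp <- gaussianLowpass(a, sigma)
  hp <- a - lp
  if (!rescale) return(hp)
  rng <- range(hp)
  out <- if (diff(rng) <= 0) array(0, d)
         else (hp - rng[1]) / diff(rng) * img@maxValue
  RawImage(out, img@maxValue, spacing = img@spacing)
}

gaussianLowpass <- function(a, sigma) {
  d <- dim(a)
  # keep the Gaussian brush inside small images
  radius <- min(2 * ceiling(3 * sigma) + 1, 2 * ((min(d[1:2]) - 1) %/% 2) + 1)
  blur <- function(m) {
    t(as.array(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma,
                              radius = radius, boundary = "replicate")))
  }
  if (length(d) == 2L) return(blur(a))
  out <- a
  for (k in seq_len(d[3])) out[, , k] <- blur(a[, , k])
  out
}

#' Preprocessing configuration
#'
#' Bundles the switches of the standard preprocessing chain, applied in the
#' fixed order resize, equalize, median, high-pass, de-rotation.
#'
#' @param targetSize square side in pixels (default 256).
#' @param medianKernel odd median window (default 3).
#' @param highpassSigma Gaussian sigma of the high-pass stage (default 2).
#' @param equalize,median,highpass,derotate stage switches.
#' @param landmarks optional [landmarkPair()]; auto-detected when NULL and
#'   de-rotation is enabled.
#' @return A list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(targetSize = 256L, medianKernel = 3L,
                             highpassSigma = 2, equalize = TRUE,
                             median = TRUE, highpass = TRUE,
                             derotate = FALSE, landmarks = NULL) {
  stopifnot(targetSize > 0, medianKernel %% 2 == 1)
  structure(list(targetSize = as.integer(targetSize),
                 medianKernel = as.integer(medianKernel),
                 highpassSigma = highpassSigma, equalize = equalize,
                 median = median, highpass = highpass,
                 derotate = derotate, landmarks = landmarks),
            class = "PreprocessConfig")
}

#' Run the preprocessing chain
#'
#' Applies, in order: RGB-to-gray conversion (when needed), resize to the
#' standard size, histogram equalization, median filtering, high-pass
#' filtering, and landmark-based de-rotation. Every stage is individually
#' switchable through [preprocessConfig()].
#'
#' @param image a [RawImage-class].
#' @param config a [preprocessConfig()].
#' @return A preprocessed grayscale [RawImage-class].
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  stopifnot(is(image, "RawImage"), inherits(config, "PreprocessConfig"))
  img <- if (image@channels == "rgb") suppressWarnings(rgbToGray(image)) else image
  img <- resizeToStandard(img, config$targetSize)
  if (config$equalize) img <- equalizeHistogram(img)
  if (config$median)   img <- medianFilter(img, config$medianKernel)
  if (config$highpass) img <- highpassFilter(img, config$highpassSigma)
  if (config$derotate) {
    lm <- config$landmarks
    if (is.null(lm)) lm <- detectLandmarks(img)
    if (!is.null(lm) && computeBase(lm) > 0 &&
        lm$p5[1] != lm$p10[1]) {
      img <- deskew(img, rotationAngle(lm), computeOrigin(lm))
    }
  }
  img
}
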
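#' Binary erosion
#'
#' The erosion \eqn{A \ominus B = \{z : B_z \subseteq A\}}: all translations
#' of the structuring element that fit entirely inside the mask (equivalently
#' \eqn{\{z : B_z \cap A^c = \emptyset\}}). By default pixels outside the
#' frame count as background, so positions where B overhangs the border are
#' excluded. \code{pad = "foreground"} treats the outside as foreground
#' instead — the convention needed when eroding the complement of a finite
#' set, e.g. in the erosion/dilation duality identity.
#'
#' @param A a [BinaryMask-class] (or logical array).
#' @param B a [StructuringElement-class]; default 3x3 (3x3x3 for volumes) box.
#' @param pad \code{"background"} (default) or \code{"foreground"}.
#' @return A [BinaryMask-class].
#' @examples
#' m <- BinaryMask(matrix(TRUE, 5, 5))
#' sum(imgData(erodeMask(m)))  # 9: the interior 3x3
#' @export
erodeMask <- function(A, B = NULL, pad = c("background", "foreground")) {
  pad <- match.arg(pad)
  a <- asMaskArray(A)
  if (is.null(B)) B <- boxSE(3L, length(dim(a)))
  offs <- seOffsets(B)
  if (nrow(offs) == 0L) stop("structuring element footprint is empty")
  fill <- pad == "foreground"
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offs)))
    out <- out & shiftArray(a, offs[i, ], fill = fill)
  BinaryMask(out)
}

#' Binary dilation
#'
#' The dilation \eqn{A \oplus B = \{z : \hat{B}_z \cap A \neq \emptyset\}}
#' (reflected structuring element), clipped to the image frame; pixels
#' outside the frame contribute nothing.
#'
#' @inheritParams erodeMask
#' @return A [BinaryMask-class].
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(imgData(dilateMask(BinaryMask(m))))  # 9: a 3x3 block
#' @export
dilateMask <- function(A, B = NULL) {
  a <- asMaskArray(A)
  if (is.null(B)) B <- boxSE(3L, length(dim(a)))
  offs <- seOffsets(B)
  if (nrow(offs) == 0L) stop("structuring element footprint is empty")
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offs)))
    out <- out | shiftArray(a, -offs[i, ], fill = FALSE)
  BinaryMask(out)
}

#' Boundary extraction
#'
#' \eqn{\beta(A) = A \setminus (A \ominus B)}: the mask minus its erosion,
#' i.e. the rim of the region at the structuring-element scale.
#'
#' @inheritParams erodeMask
#' @return A [BinaryMask-class]; a subset of \code{A}.
#' @export
maskBoundary <- function(A, B = NULL) {
  a <- asMaskArray(A)
  er <- imgData(erodeMask(a, B))
  BinaryMask(a & !er)
}

#' Morphological closing
#'
#' Dilation followed by erosion with the same structuring element; fills
#' gaps narrower than the footprint.
#'
#' @inheritParams erodeMask
#' @return A [BinaryMask-class].
#' @export
closeMask <- function(A, B = NULL) {
  erodeMask(dilateMask(A, B), B)
}

#' Morphological opening
#'
#' Erosion followed by dilation; removes specks smaller than the footprint.
#'
#' @inheritParams erodeMask
#' @return A [BinaryMask-class].
#' @export
openMask <- function(A, B = NULL) {
  dilateMask(erodeMask(A, B), B)
}

#' Robust noise level of a signal
#'
#' The MAD-style estimator \code{sigma_n = median(|x|) / 0.6745}, the
#' standard robust estimate of the noise standard deviation used to
#' threshold spike-like responses.
#'
#' @param x non-empty finite numeric vector (or array).
#' @return Non-negative scalar.
#' @export
noiseSigma <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("noiseSigma: empty input")
  if (!all(is.finite(x))) stop("noiseSigma: input must be finite")
  stats::median(abs(x)) / 0.6745
}

#' Spike threshold
#'
#' \code{Threshold = 3.5 * sigma_n} with \code{sigma_n} from [noiseSigma()]:
#' responses above it are treated as genuine (edge/spike) activity rather
#' than noise. Scale-equivariant: \code{spikeThreshold(c * x) =
#' c * spikeThreshold(x)} for \code{c > 0}.
#'
#' @inheritParams noiseSigma
#' @return Non-negative scalar.
#' @export
spikeThreshold <- function(x) {
  3.5 * noiseSigma(x)
}

#' Gradient magnitude map
#'
#' Central-difference gradient magnitude, dimension-generic (2D or 3D),
#' reflect padding at the edges.
#'
#' @param a numeric array.
#' @return Numeric array of the same shape.
#' @export
gradientMagnitude <- function(a) {
  a <- asImageArray(a)
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in seq_along(d)) {
    off <- rep(0L, length(d))
    off[ax] <- 1L
    fwd <- array(a[reflectShiftIndex(d, off)], d)
    bwd <- array(a[reflectShiftIndex(d, -off)], d)
    g2 <- g2 + ((fwd - bwd) / 2)^2
  }
  sqrt(g2)
}

# Local standard deviation over the structuring-element footprint,
# reflect padding (the texture feature map).
localSD <- function(a, se) {
  d <- dim(a)
  offs <- seOffsets(se)
  n <- nrow(offs)
  s <- array(0, d); s2 <- array(0, d)
  for (i in seq_len(n)) {
    v <- array(a[reflectShiftIndex(d, offs[i, ])], d)
    s <- s + v; s2 <- s2 + v^2
  }
  v <- s2 / n - (s / n)^2
  sqrt(pmax(v, 0))
}

#' Texture / intensity / edge segmentation
#'
#' The morphology-based segmentation stage: three feature maps are computed
#' from a preprocessed grayscale image — normalized intensity, gradient
#' magnitude (edge), and local standard deviation over the structuring
#' element footprint (texture). Pixels whose edge response exceeds the
#' spike threshold \code{3.5 * sigma_n} of the gradient map seed the
#' candidate mask, which is regularized by morphological closing, hole
#' filling, and opening (to drop isolated specks), then eroded once: the
#' edge band straddles the true contour by the gradient-operator radius,
#' and the final erosion compensates that outward bias. The region boundary
#' is attached via [maskBoundary()]. A constant image yields an empty mask.
#'
#' @param image a preprocessed grayscale [RawImage-class] (or array).
#' @param se [StructuringElement-class]; default 3x3 (3x3x3) box.
#' @param fillHoles fill enclosed background holes after closing (default TRUE).
#' @return A list of class \code{"SegmentationResult"} with elements
#'   \code{mask}, \code{boundary} (both [BinaryMask-class]),
#'   \code{featureMaps} (list \code{intensity}, \code{edge}, \code{texture})
#'   and \code{thresholdUsed}.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(32, 32), tumorRadius = 8,
#'                                   noiseSigma = 0, seed = 1))
#' seg <- segmentFractal(ph$image)
#' sum(imgData(seg$mask))
#' @export
segmentFractal <- function(image, se = NULL, fillHoles = TRUE) {
  a <- asImageArray(image)
  mx <- if (is(image, "RawImage")) maxValue(image) else max(1, max(a))
  d <- dim(a)
  if (is.null(se)) se <- boxSE(3L, length(d))
  intensity <- a / mx
  edge <- gradientMagnitude(a)
  texture <- localSD(a, se)
  thr <- spikeThreshold(as.numeric(edge))
  if (max(edge) <= thr || max(a) == min(a)) {
    empty <- BinaryMask(array(FALSE, d))
    return(structure(list(mask = empty, boundary = empty,
                          featureMaps = list(intensity = intensity,
                                             edge = edge, texture = texture),
                          thresholdUsed = thr),
                     class = "SegmentationResult"))
  }
  seed <- BinaryMask(edge > thr)
  mask <- closeMask(seed, se)
  if (fillHoles) {
    m <- imgData(mask)
    if (length(d) == 2L) {
      m <- as.array(EBImage::fillHull(EBImage::Image(m * 1))) > 0
    } else {
      for (k in seq_len(d[3]))
        m[, , k] <- as.array(EBImage::fillHull(EBImage::Image(m[, , k] * 1))) > 0
    }
    mask <- BinaryMask(m)
  }
  mask <- erodeMask(openMask(mask, se), se)
  structure(list(mask = mask, boundary = maskBoundary(mask, se),
                 featureMaps = list(intensity = intensity, edge = edge,
                                    texture = texture),
                 thresholdUsed = thr),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: %d mask px, %d boundary px, threshold %.4g\n",
              sum(imgData(x$mask)), sum(imgData(x$boundary)), x$thresholdUsed))
  invisible(x)
}

#' Intersection-over-union of two masks
#'
#' @param a,b [BinaryMask-class] or logical arrays of identical shape.
#' @return Scalar in [0, 1]; 1 when both masks are empty.
#' @export
maskIoU <- function(a, b) {
  ma <- asMaskArray(a); mb <- asMaskArray(b)
  stopifnot(identical(dim(ma), dim(mb)))
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}

#' Region descriptors from a segmentation
#'
#' Summarizes a [segmentFractal()] result into a fixed-length descriptor
#' vector used by the classifier: mask area and perimeter, the compactness
#' ratio \eqn{P^2 / (4\pi A)} (1 for a disk, larger for irregular
#' boundaries), the radial spread of the boundary about the region centroid
#' (SD/mean and MAD/median of boundary radii), within-region texture level
#' (mean and upper-quartile local SD over the region core), the intensity
#' SD inside the region, the region-vs-background intensity contrast, and
#' the mean boundary edge strength. An (near-)empty mask yields all zeros.
#'
#' @param x a \code{SegmentationResult} from [segmentFractal()], or an
#'   image to segment first.
#' @param minArea masks smaller than this return the zero vector (default 5).
#' @return Named numeric vector of length 10.
#' @export
segmentationDescriptors <- function(x, minArea = 5L) {
  seg <- if (inherits(x, "SegmentationResult")) x else segmentFractal(x)
  nm <- c("area", "perimeter", "compactness", "radialCV", "radialMADratio",
          "textureMean", "textureQ75", "intensitySD", "contrast",
          "edgeStrength")
  m <- imgData(seg$mask); b <- imgData(seg$boundary)
  A <- sum(m); P <- sum(b)
  if (A < minArea || P == 0L)
    return(stats::setNames(numeric(10), nm))
  tex <- seg$featureMaps$texture
  inten <- seg$featureMaps$intensity
  core <- m & !b
  texIn <- if (sum(core) > 5) tex[core] else tex[m]
  bidx <- which(b, arr.ind = TRUE)
  ctr <- colMeans(which(m, arr.ind = TRUE))
  rr <- sqrt(rowSums(sweep(bidx, 2L, ctr)^2))
  stats::setNames(c(
    A, P, P^2 / (4 * pi * A),
    stats::sd(rr) / mean(rr),
    stats::mad(rr) / max(stats::median(rr), 1e-8),
    mean(texIn), stats::quantile(texIn, 0.75),
    stats::sd(inten[m]),
    mean(inten[m]) - mean(inten[!m]),
    mean(seg$featureMaps$edge[b])), nm)
}
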
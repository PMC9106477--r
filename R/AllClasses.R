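#' @import methods
NULL

#' RawImage: a 2D image or 3D volume with a recorded intensity range
#'
#' The container every pipeline stage consumes and produces. Intensities are
#' stored as a numeric array of dimension H x W (2D), H x W x D (3D volume),
#' or H x W x 3 with \code{channels = "rgb"} (color image). All values must
#' be finite and lie in \code{[0, maxValue]}.
#'
#' @slot data numeric array of intensities.
#' @slot maxValue scalar upper bound of the intensity range (e.g. 255).
#' @slot channels either \code{"gray"} or \code{"rgb"}.
#' @slot spacing optional per-axis physical spacing; \code{numeric(0)} if unknown.
#'
#' @seealso [RawImage()], [loadImage()]
#' @exportClass RawImage
setClass("RawImage",
  representation(
    data     = "array",
    maxValue = "numeric",
    channels = "character",
    spacing  = "numeric"
  ),
  prototype(
    data     = array(0, c(1, 1)),
    maxValue = 255,
    channels = "gray",
    spacing  = numeric(0)
  )
)

setValidity("RawImage", function(object) {
  msg <- character(0)
  nd <- length(dim(object@data))
  if (!(nd %in% c(2L, 3L)))
    msg <- c(msg, "data must be a 2D or 3D array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all intensities must be finite")
  if (length(object@maxValue) != 1L || !is.finite(object@maxValue) ||
      object@maxValue <= 0)
    msg <- c(msg, "maxValue must be a positive finite scalar")
  else if (length(object@data) && all(is.finite(object@data)) &&
           (min(object@data) < 0 || max(object@data) > object@maxValue))
    msg <- c(msg, "intensities must lie in [0, maxValue]")
  if (!(object@channels %in% c("gray", "rgb")))
    msg <- c(msg, "channels must be 'gray' or 'rgb'")
  if (object@channels == "rgb" && (nd != 3L || dim(object@data)[3] != 3L))
    msg <- c(msg, "rgb images must be H x W x 3")
  if (length(msg)) msg else TRUE
})

#' Construct a RawImage
#'
#' @param data numeric matrix or array (2D image, 3D volume, or H x W x 3 RGB).
#' @param maxValue intensity upper bound; defaults to 255.
#' @param channels \code{"gray"} (default) or \code{"rgb"}.
#' @param spacing optional numeric per-axis spacing.
#' @return A [RawImage-class] object.
#' @examples
#' img <- RawImage(matrix(0:255, 16, 16))
#' img
#' @export
RawImage <- function(data, maxValue = 255, channels = "gray",
                     spacing = numeric(0)) {
  if (is.null(dim(data))) stop("data must be a matrix or array")
  new("RawImage", data = as.array(data * 1.0), maxValue = as.numeric(maxValue),
      channels = channels, spacing = as.numeric(spacing))
}

#' BinaryMask: a boolean image or volume
#'
#' Holds a segmented region (the set A of binary morphology). Same shape
#' family as [RawImage-class].
#'
#' @slot data logical array (2D or 3D).
#' @exportClass BinaryMask
setClass("BinaryMask", representation(data = "array"),
         prototype(data = array(FALSE, c(1, 1))))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  if (!(length(dim(object@data)) %in% c(2L, 3L)))
    return("mask must be a 2D or 3D array")
  if (anyNA(object@data)) return("mask must not contain NA")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param data logical (or coercible) matrix or array.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data) {
  if (is.null(dim(data))) stop("data must be a matrix or array")
  d <- array(as.logical(data), dim = dim(data))
  new("BinaryMask", data = d)
}

#' StructuringElement: a morphological footprint
#'
#' A small boolean neighborhood B with a designated origin, used by
#' [erodeMask()], [dilateMask()] and [maskBoundary()].
#'
#' @slot footprint logical array, non-empty.
#' @slot origin integer index of the origin inside the footprint (per axis).
#' @exportClass StructuringElement
setClass("StructuringElement",
  representation(footprint = "array", origin = "integer"),
  prototype(footprint = array(TRUE, c(3, 3)), origin = c(2L, 2L)))

setValidity("StructuringElement", function(object) {
  fp <- object@footprint
  if (!is.logical(fp)) return("footprint must be logical")
  if (!any(fp)) return("footprint must be non-empty")
  if (length(object@origin) != length(dim(fp)))
    return("origin must have one index per footprint axis")
  if (any(object@origin < 1L) || any(object@origin > dim(fp)))
    return("origin must lie inside the footprint")
  TRUE
})

#' Construct a structuring element
#'
#' @param footprint logical matrix/array; default 3x3 all-true (use
#'   \code{boxSE(3, ndim = 3)} for volumes).
#' @param origin integer center index; defaults to the geometric center.
#' @return A [StructuringElement-class].
#' @export
StructuringElement <- function(footprint = matrix(TRUE, 3, 3), origin = NULL) {
  fp <- array(as.logical(footprint), dim = dim(footprint))
  if (is.null(origin)) origin <- as.integer((dim(fp) + 1L) %/% 2L)
  new("StructuringElement", footprint = fp, origin = as.integer(origin))
}

#' All-true box structuring element
#'
#' @param size odd side length (default 3).
#' @param ndim 2 for images, 3 for volumes.
#' @return A [StructuringElement-class].
#' @export
boxSE <- function(size = 3L, ndim = 2L) {
  StructuringElement(array(TRUE, rep(as.integer(size), ndim)))
}

#' EigenModel: snapshot-PCA eigenimage basis
#'
#' The trained eigenimage model: mean image psi, the top-f orthonormal
#' eigenimages (rows of \code{components}), their eigenvalues, and the
#' Euclidean detection threshold tau.
#'
#' @slot mean numeric vector of length d (the average training image).
#' @slot components f x d matrix with orthonormal rows (eigenimages).
#' @slot eigenvalues non-increasing, non-negative, length f.
#' @slot f retained dimension (f <= M - 1).
#' @slot tau detection threshold in feature-space distance units.
#' @seealso [trainEigenModel()], [projectImage()], [matchFeature()]
#' @exportClass EigenModel
setClass("EigenModel",
  representation(mean = "numeric", components = "matrix",
                 eigenvalues = "numeric", f = "integer", tau = "numeric"))

setValidity("EigenModel", function(object) {
  msg <- character(0)
  f <- object@f
  if (nrow(object@components) != f)
    msg <- c(msg, "components must have f rows")
  if (ncol(object@components) != length(object@mean))
    msg <- c(msg, "components and mean disagree on d")
  if (length(object@eigenvalues) != f)
    msg <- c(msg, "need one eigenvalue per component")
  else {
    if (any(object@eigenvalues < -1e-8))
      msg <- c(msg, "eigenvalues must be non-negative")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      msg <- c(msg, "eigenvalues must be non-increasing")
  }
  if (f > 0) {
    G <- tcrossprod(object@components)
    if (max(abs(G - diag(f))) > 1e-6)
      msg <- c(msg, "component rows must be orthonormal")
  }
  if (length(object@tau) != 1L || object@tau <= 0)
    msg <- c(msg, "tau must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: the standard evaluation summary
#'
#' Accuracy and sensitivity in percent, MSE in squared intensity units,
#' PSNR and SNR in dB, AUC in [0, 1].
#'
#' @slot accuracy,sensitivity percentages in [0, 100].
#' @slot mse mean squared error.
#' @slot psnr,snr decibel fidelity measures.
#' @slot auc area under the ROC curve.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 mse = "numeric", psnr = "numeric", snr = "numeric",
                 auc = "numeric"))

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  pct <- c(object@accuracy, object@sensitivity)
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    msg <- c(msg, "accuracy/sensitivity must be percentages in [0, 100]")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
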
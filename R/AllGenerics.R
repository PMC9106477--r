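#' Extract the intensity or mask array
#'
#' @param x a [RawImage-class] or [BinaryMask-class].
#' @return The underlying array.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "RawImage", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("imgData", "BinaryMask", function(x) x@data)

#' Intensity upper bound of an image
#'
#' @param x a [RawImage-class].
#' @return The scalar \code{maxValue}.
#' @export
setGeneric("maxValue", function(x) standardGeneric("maxValue"))

#' @rdname maxValue
#' @export
setMethod("maxValue", "RawImage", function(x) x@maxValue)

setMethod("show", "RawImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("RawImage: %s %s, range [%.4g, %.4g] of [0, %g]\n",
              paste(d, collapse = " x "),
              if (object@channels == "rgb") "(rgb)" else
                if (length(d) == 3L) "(volume)" else "(grayscale)",
              if (length(object@data)) min(object@data) else NA,
              if (length(object@data)) max(object@data) else NA,
              object@maxValue))
  invisible(object)
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %s, %d foreground of %d pixels\n",
              paste(dim(object@data), collapse = " x "),
              sum(object@data), length(object@data)))
  invisible(object)
})

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: %s footprint, %d active, origin (%s)\n",
              paste(dim(object@footprint), collapse = " x "),
              sum(object@footprint),
              paste(object@origin, collapse = ", ")))
  invisible(object)
})

setMethod("show", "EigenModel", function(object) {
  cat(sprintf(
    "EigenModel: d = %d, f = %d components, tau = %.4g\n",
    length(object@mean), object@f, object@tau))
  if (object@f)
    cat("  eigenvalues:", paste(signif(utils::head(object@eigenvalues, 5), 4),
                                collapse = ", "),
        if (object@f > 5) "...\n" else "\n")
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  accuracy:    %8.4f %%\n", object@accuracy))
  cat(sprintf("  sensitivity: %8.4f %%\n", object@sensitivity))
  cat(sprintf("  MSE:         %8.4f\n", object@mse))
  cat(sprintf("  PSNR:        %8.4f dB\n", object@psnr))
  cat(sprintf("  SNR:         %8.4f dB\n", object@snr))
  cat(sprintf("  AUC:         %8.4f\n", object@auc))
  invisible(object)
})
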
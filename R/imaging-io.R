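#' Read an image or volume from disk
#'
#' Reads 8/16-bit PNG, JPEG-free TIFF, or NIfTI (.nii / .nii.gz) into a
#' [RawImage-class]. PNG and TIFF images are rescaled to the 0--255 range
#' (bit depth is normalized on read); NIfTI volumes keep their stored
#' values and axis order (H, W, D). DICOM files are recognized but not
#' supported.
#'
#' @param path file to read.
#' @param formatHint optional one of \code{"png"}, \code{"tiff"},
#'   \code{"nifti"}; inferred from the extension when missing.
#' @return A [RawImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' saveImage(RawImage(matrix(0, 4, 4)), f)
#' loadImage(f)
#' @export
loadImage <- function(path, formatHint = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  fmt <- formatHint
  if (is.null(fmt)) {
    low <- tolower(path)
    fmt <- if (grepl("\\.png$", low)) "png"
      else if (grepl("\\.(tif|tiff)$", low)) "tiff"
      else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
      else if (grepl("\\.(dcm|dicom)$", low)) "dicom"
      else if (grepl("\\.(jpg|jpeg)$", low)) "jpeg"
      else stop("unsupported image format: ", path)
  }
  switch(fmt,
    png = {
      a <- tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot read PNG ", path, ": ",
                                             conditionMessage(e)))
      fromUnitArray(a)
    },
    tiff = {
      a <- tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
      fromUnitArray(a)
    },
    nifti = {
      v <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot read NIfTI ", path, ": ",
                                             conditionMessage(e)))
      a <- array(as.numeric(v), dim = dim(v))
      sp <- tryCatch(RNifti::pixdim(v), error = function(e) numeric(0))
      RawImage(a, maxValue = max(1, max(a)), spacing = sp)
    },
    dicom = stop("DICOM input is not supported by this build; ",
                 "convert to NIfTI or PNG first: ", path),
    jpeg = stop("JPEG reading is not supported by this build; ",
                "convert to PNG or TIFF first: ", path),
    stop("unsupported image format: ", fmt)
  )
}

# PNG/TIFF readers return values in [0, 1]; restore an 8-bit-style range.
fromUnitArray <- function(a) {
  a <- as.array(a)
  nd <- length(dim(a))
  if (nd == 3L && dim(a)[3] %in% c(2L, 4L))   # drop alpha
    a <- a[, , seq_len(dim(a)[3] - 1L), drop = FALSE]
  if (nd == 3L && dim(a)[3] == 1L) { d <- dim(a)[1:2]; a <- array(a, d) }
  ch <- if (length(dim(a)) == 3L && dim(a)[3] == 3L) "rgb" else "gray"
  RawImage(a * 255, maxValue = 255, channels = ch)
}

#' Write an image or volume to disk
#'
#' Writes PNG for 2D images (intensities scaled by \code{maxValue}) and
#' NIfTI for anything else (or when the path ends in .nii/.nii.gz).
#'
#' @param image a [RawImage-class] or numeric array.
#' @param path destination; extension selects the format.
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(image, path) {
  img <- if (is(image, "RawImage")) image else RawImage(image)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    RNifti::writeNifti(RNifti::asNifti(imgData(img)), path)
  } else if (grepl("\\.png$", low)) {
    a <- imgData(img)
    if (length(dim(a)) == 3L && img@channels != "rgb")
      stop("cannot write a 3D volume as PNG; use .nii: ", path)
    png::writePNG(pmin(pmax(a / img@maxValue, 0), 1), path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Write a binary mask to disk
#'
#' 2D masks become 8-bit PNG (0/255); 3D masks become uint8 NIfTI.
#'
#' @param mask a [BinaryMask-class].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
saveMask <- function(mask, path) {
  m <- asMaskArray(mask)
  if (length(dim(m)) == 2L && grepl("\\.png$", tolower(path)))
    png::writePNG(array(as.numeric(m), dim(m)), path)
  else if (grepl("\\.nii(\\.gz)?$", tolower(path)))
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(m), dim(m))), path)
  else stop("unsupported mask format: ", path)
  invisible(path)
}

#' Convert an RGB image to luminance grayscale
#'
#' Applies the standard luminance weights 0.2989 R + 0.5870 G + 0.1140 B.
#' Grayscale input is passed through with a warning.
#'
#' @param image a [RawImage-class] (H x W x 3, \code{channels = "rgb"}).
#' @return A grayscale [RawImage-class].
#' @examples
#' rgb <- RawImage(array(c(255, 0, 0), c(1, 1, 3)), channels = "rgb")
#' imgData(rgbToGray(rgb))  # 0.2989 * 255
#' @export
rgbToGray <- function(image) {
  stopifnot(is(image, "RawImage"))
  if (image@channels != "rgb") {
    warning("image is already grayscale; returning unchanged")
    return(image)
  }
  a <- imgData(image)
  g <- 0.2989 * a[, , 1] + 0.5870 * a[, , 2] + 0.1140 * a[, , 3]
  g <- array(g, dim(a)[1:2])
  RawImage(pmin(g, image@maxValue), maxValue = image@maxValue,
           spacing = image@spacing)
}
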
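# PNG (8-bit grayscale) and NIfTI (float32) readers/writers for images and
# label masks. PNG image round-trips are exact to 1/255 quantization; NIfTI
# float round-trips are exact to float32 precision; masks round-trip exactly
# in both formats.

imageFormat <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return("png")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("format error: unsupported file '", basename(path),
       "'; supported formats are PNG (.png) and NIfTI (.nii, .nii.gz)",
       call. = FALSE)
}

asMatrix2D <- function(x, path) {
  d <- dim(x)
  if (length(d) == 3L && d[3] %in% c(1L, 3L)) return(toGrayscale(unclass(x)))
  if (length(d) == 3L && d[3] == 4L) return(toGrayscale(unclass(x)[, , 1:3]))
  if (length(d) == 2L) return(matrix(as.numeric(x), d[1], d[2]))
  stop("format error: '", basename(path), "' is not a 2-D image", call. = FALSE)
}

#' Read a 2-D image
#'
#' @param path a `.png`, `.nii` or `.nii.gz` file.
#' @return a numeric matrix; PNG intensities are on \[0, 1\].
#' @export
readImage2D <- function(path) {
  fmt <- imageFormat(path)
  x <- tryCatch(
    if (fmt == "png") png::readPNG(path) else RNifti::readNifti(path),
    error = function(e) stop("format error reading '", basename(path), "': ",
                             conditionMessage(e), call. = FALSE))
  asMatrix2D(x, path)
}

#' Write a 2-D image
#'
#' PNG output is 8-bit grayscale (intensities clipped to \[0, 1\]); NIfTI
#' output is float32.
#'
#' @param image a numeric matrix.
#' @param path destination `.png`, `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
writeImage2D <- function(image, path) {
  assertImage2D(image)
  fmt <- imageFormat(path)
  if (fmt == "png") png::writePNG(pmin(pmax(image, 0), 1), path)
  else RNifti::writeNifti(image, path, datatype = "float")
  invisible(path)
}

#' Read a label mask
#'
#' @param path a `.png`, `.nii` or `.nii.gz` file written by
#'   [writeMaskImage()].
#' @return an integer matrix (labels round-trip exactly).
#' @export
readMaskImage <- function(path) {
  fmt <- imageFormat(path)
  if (fmt == "png") {
    m <- asMatrix2D(tryCatch(png::readPNG(path), error = function(e)
      stop("format error reading '", basename(path), "': ",
           conditionMessage(e), call. = FALSE)), path)
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  } else {
    m <- asMatrix2D(RNifti::readNifti(path), path)
    matrix(as.integer(round(m)), nrow(m), ncol(m))
  }
}

#' Write a label mask
#'
#' PNG masks store the label directly as the 8-bit gray level (labels must
#' lie in 0..255); NIfTI masks are int16.
#'
#' @param mask an integer matrix of labels.
#' @param path destination `.png`, `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
writeMaskImage <- function(mask, path) {
  if (!is.matrix(mask) || any(mask != round(mask)))
    stop("'mask' must be an integer label matrix", call. = FALSE)
  fmt <- imageFormat(path)
  if (fmt == "png") {
    if (any(mask < 0 | mask > 255))
      stop("PNG masks support labels 0..255 only", call. = FALSE)
    png::writePNG(mask / 255, path)
  } else {
    RNifti::writeNifti(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                       path, datatype = "int16")
  }
  invisible(path)
}
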
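#' Two-channel microscopy scene
#'
#' Container for a registered pair of single-plane grayscale images:
#' the endogenous (mCherry-tagged) channel and the exogenous
#' (GFP-variant) channel, with pixel calibration and the detector
#' saturation value that the intensity-fraction thresholds refer to.
#'
#' @param endogenous,exogenous Numeric matrices of identical dimensions,
#'   intensities in `[0, bit_saturation]`.
#' @param pixel_size_um Pixel size in micrometres (default 0.19).
#' @param bit_saturation Maximum representable intensity (default 65535,
#'   i.e. 16-bit).
#' @return An object of class `image_scene`.
#' @export
image_scene <- function(endogenous, exogenous, pixel_size_um = 0.19,
                        bit_saturation = 65535) {
  if (!is.matrix(endogenous) || !is.matrix(exogenous))
    stop("channels must be matrices", call. = FALSE)
  if (!identical(dim(endogenous), dim(exogenous)))
    stop("channels must have identical dimensions", call. = FALSE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(bit_saturation, "bit_saturation", positive = TRUE)
  structure(
    list(endogenous = endogenous, exogenous = exogenous,
         pixel_size_um = pixel_size_um, bit_saturation = bit_saturation),
    class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  cat(sprintf("image_scene: %d x %d px (%.1f x %.1f um), %.2f um/px, saturation %g\n",
              nrow(x$endogenous), ncol(x$endogenous),
              nrow(x$endogenous) * x$pixel_size_um,
              ncol(x$endogenous) * x$pixel_size_um,
              x$pixel_size_um, x$bit_saturation))
  invisible(x)
}

#' @export
dim.image_scene <- function(x) dim(x$endogenous)
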
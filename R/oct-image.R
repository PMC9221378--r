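#' OCT B-scan container
#'
#' Wraps a single grayscale OCT B-scan as a matrix of 8-bit intensities with
#' pixel-size metadata. Row 1 is the top of the image (the background side,
#' above the tissue surface); depth increases with the row index.
#'
#' @param pixels Integer/numeric matrix of intensities in `[0, bit_range]`.
#' @param pixel_size_um Numeric length-2 vector, microns per pixel
#'   (lateral, axial). The default matches a 15 px ~ 53 um scanning window.
#' @param sample_id Optional sample identifier.
#' @param class_label Optional tissue class (see [tissue_classes()]).
#' @param bit_range Maximum representable intensity (default 255, 8-bit).
#' @return An object of class `oct_image`.
#' @export
oct_image <- function(pixels, pixel_size_um = c(53 / 15, 53 / 15),
                      sample_id = NULL, class_label = NULL, bit_range = 255) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 16L)
    stop("oct_image: image height must be >= 16 rows (top-row artifact rule needs row 15)")
  if (anyNA(pixels)) stop("oct_image: pixel intensities contain NA")
  if (min(pixels) < 0 || max(pixels) > bit_range)
    stop("oct_image: intensities outside [0, ", bit_range, "]")
  if (!is.null(class_label) && !class_label %in% CANONICAL_CLASSES)
    stop("oct_image: unknown class label '", class_label, "'")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         sample_id = sample_id, class_label = class_label,
         bit_range = bit_range),
    class = "oct_image")
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d x %d px", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$sample_id)) cat(", sample", x$sample_id)
  if (!is.null(x$class_label)) cat(", class", x$class_label)
  cat(sprintf(", intensities [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.oct_image <- function(x) dim(x$pixels)

#' Read an OCT B-scan from a grayscale TIFF
#'
#' @param path Path to a single-page grayscale TIFF.
#' @inheritParams oct_image
#' @return An [oct_image()].
#' @export
read_oct_tiff <- function(path, pixel_size_um = c(53 / 15, 53 / 15),
                          sample_id = NULL, class_label = NULL) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale-as-RGB
  oct_image(px, pixel_size_um = pixel_size_um, sample_id = sample_id,
            class_label = class_label)
}

#' Write an OCT B-scan to an 8-bit grayscale TIFF
#'
#' @param image An [oct_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oct_tiff <- function(image, path) {
  stopifnot(inherits(image, "oct_image"))
  tiff::writeTIFF(image$pixels / image$bit_range, path, bits.per.sample = 8L)
  invisible(path)
}
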
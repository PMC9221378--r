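#' Binary tissue mask container
#'
#' A binary mask aligned with an OCT B-scan, with provenance flags recording
#' which processing stages (threshold, void filling, saturation-column
#' removal) have been applied, and the indices of removed artifact columns.
#'
#' @param mask Logical matrix.
#' @param thresholded,voids_filled,saturation_removed Provenance flags.
#' @param removed_columns Integer vector of zeroed artifact columns.
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(mask, thresholded = FALSE, voids_filled = FALSE,
                       saturation_removed = FALSE, removed_columns = integer(0)) {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask_image: mask must be binary")
    mask <- mask > 0
  }
  structure(
    list(mask = mask,
         flags = c(thresholded = thresholded, voids_filled = voids_filled,
                   saturation_removed = saturation_removed),
         removed_columns = as.integer(removed_columns)),
    class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> %d x %d, %.1f%% masked, stages: %s",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              paste(names(x$flags)[x$flags], collapse = " -> ")))
  if (length(x$removed_columns))
    cat(sprintf(", %d column(s) removed", length(x$removed_columns)))
  cat("\n")
  invisible(x)
}

#' @export
dim.mask_image <- function(x) dim(x$mask)

#' Otsu threshold of an intensity matrix
#'
#' Exhaustive search over integer levels for the split maximizing the
#' between-class variance of the intensity histogram. Returns the effective
#' threshold level `t` such that foreground is `pixels >= t` (i.e. one more
#' than the optimal upper bound of the background class; the smallest
#' optimal split is taken when several are equivalent).
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_range Maximum representable intensity (default 255).
#' @return The effective threshold level, or `Inf` for a constant image
#'   (nothing is foreground).
#' @export
otsu_threshold <- function(pixels, bit_range = 255) {
  v <- round(as.vector(pixels))
  if (min(v) == max(v)) return(Inf)
  counts <- tabulate(v + 1L, nbins = bit_range + 1L)
  levels <- 0:bit_range
  w0 <- cumsum(counts)
  n <- w0[length(w0)]
  s0 <- cumsum(counts * levels)
  stot <- s0[length(s0)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / pmax(w0, 1)
  mu1 <- (stot - s0) / pmax(w1, 1)
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  levels[which.max(bcv)] + 1
}

#' Threshold an OCT B-scan into a binary mask
#'
#' @param image An [oct_image()].
#' @param method `"otsu"` (default; automatic, robust to gain differences)
#'   or `"fixed"`.
#' @param level Required for `method = "fixed"`: pixels `>= level` are
#'   foreground. Must lie in the image's bit-depth range.
#' @return A [mask_image()] with `thresholded = TRUE`.
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed"), level = NULL) {
  stopifnot(inherits(image, "oct_image"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(level)) stop("threshold_mask: fixed method requires a level")
    if (level < 0 || level > image$bit_range)
      stop("threshold_mask: fixed level ", level, " outside [0, ",
           image$bit_range, "]")
  } else {
    level <- otsu_threshold(image$pixels, image$bit_range)
  }
  mask_image(image$pixels >= level, thresholded = TRUE)
}

#' Fill interior voids of a tissue mask
#'
#' Background (zero) regions not 4-connected to the image border become
#' tissue, so that voids inside the tissue structure are treated as part of
#' it; border-connected background is untouched. Idempotent, and never
#' removes mask pixels.
#'
#' @param m A thresholded [mask_image()].
#' @return A [mask_image()] with `voids_filled = TRUE`.
#' @export
fill_voids <- function(m) {
  stopifnot(inherits(m, "mask_image"))
  if (!m$flags[["thresholded"]])
    stop("fill_voids: mask must be thresholded first")
  bg <- !m$mask
  h <- nrow(bg); w <- ncol(bg)
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- bg[, 1]; reach[, w] <- bg[, w]
  # Breadth-first growth of border-connected background, one 4-neighbour
  # ring per iteration, until a fixed point.
  repeat {
    grown <- (reach | shift_up(reach) | shift_down(reach) |
                shift_left(reach) | shift_right(reach)) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  filled <- m$mask | (bg & !reach)
  mask_image(filled, thresholded = TRUE, voids_filled = TRUE,
             saturation_removed = m$flags[["saturation_removed"]],
             removed_columns = m$removed_columns)
}

#' Remove saturation-artifact columns from a mask
#'
#' The top `n_top_rows` rows of the mask should image only background; any
#' mask pixel there betrays a saturation line. The top rows are summed per
#' column (the matrix product S = J B of a row of ones with the top block),
#' and every column with a positive sum is zeroed over the full mask height.
#'
#' @param m A void-filled [mask_image()].
#' @param n_top_rows Number of top rows inspected (default 15); must be
#'   smaller than the image height.
#' @return A [mask_image()] with `saturation_removed = TRUE` and
#'   `removed_columns` recording the zeroed columns.
#' @export
remove_saturation_columns <- function(m, n_top_rows = 15) {
  stopifnot(inherits(m, "mask_image"))
  if (!m$flags[["voids_filled"]])
    stop("remove_saturation_columns: fill voids before removing saturation lines")
  if (n_top_rows >= nrow(m$mask))
    stop("remove_saturation_columns: n_top_rows (", n_top_rows,
         ") must be smaller than the image height (", nrow(m$mask), ")")
  S <- colSums(m$mask[seq_len(n_top_rows), , drop = FALSE])
  cols <- which(S > 0)
  out <- m$mask
  if (length(cols)) out[, cols] <- FALSE
  mask_image(out, thresholded = TRUE, voids_filled = TRUE,
             saturation_removed = TRUE,
             removed_columns = sort(unique(c(m$removed_columns, cols))))
}

#' Build the full tissue mask for a B-scan
#'
#' Composition of the three masking stages in their normative order:
#' threshold, fill interior voids, remove saturation-artifact columns.
#'
#' @inheritParams threshold_mask
#' @inheritParams remove_saturation_columns
#' @return A fully processed [mask_image()] (all provenance flags set).
#' @export
build_mask <- function(image, method = c("otsu", "fixed"), level = NULL,
                       n_top_rows = 15) {
  remove_saturation_columns(
    fill_voids(threshold_mask(image, method = method, level = level)),
    n_top_rows = n_top_rows)
}

#' Mask quality-control summary
#'
#' The automated stand-in for manual mask inspection: the fraction of pixels
#' retained and the number of artifact columns removed.
#'
#' @param m A [mask_image()].
#' @param image_id Optional identifier for the log row.
#' @return One-row data frame: `image`, `masked_fraction`, `n_removed_columns`.
#' @export
mask_qc <- function(m, image_id = NA_character_) {
  stopifnot(inherits(m, "mask_image"))
  data.frame(image = image_id, masked_fraction = mean(m$mask),
             n_removed_columns = length(m$removed_columns))
}
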
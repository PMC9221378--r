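#' Raman spectrum container
#'
#' @param wavenumber Strictly increasing wavenumbers in cm^-1.
#' @param intensity Intensities (arbitrary counts), same length.
#' @param state Processing state: `"raw"`, `"baseline_subtracted"`, or
#'   `"normalized"`.
#' @param sample_id Optional sample identifier.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, state = "raw",
                           sample_id = NULL) {
  wavenumber <- as.numeric(wavenumber); intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("raman_spectrum: wavenumber and intensity lengths differ")
  if (anyNA(wavenumber) || anyNA(intensity))
    stop("raman_spectrum: NA values not allowed")
  if (any(diff(wavenumber) <= 0))
    stop("raman_spectrum: wavenumbers must be strictly increasing")
  state <- match.arg(state, c("raw", "baseline_subtracted", "normalized"))
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 state = state, sample_id = sample_id),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm-1, state: %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$state))
  invisible(x)
}

#' Read a two-column spectrum CSV (wavenumber_cm1, intensity)
#'
#' @param path CSV file path.
#' @param sample_id Optional sample identifier.
#' @return A raw [raman_spectrum()].
#' @export
read_spectrum_csv <- function(path, sample_id = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("read_spectrum_csv: expected two columns in ", path)
  raman_spectrum(d[[1]], d[[2]], state = "raw", sample_id = sample_id)
}

#' Write a spectrum to CSV
#' @param s A [raman_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  utils::write.csv(data.frame(wavenumber_cm1 = s$wavenumber,
                              intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto the canonical 1 cm^-1 grid
#'
#' Linear interpolation onto a uniform grid; features are always computed on
#' this grid so band averages are comparable across instruments.
#'
#' @param s A [raman_spectrum()].
#' @param grid Target wavenumber grid (default 920-2070 cm^-1, 1 cm^-1 step).
#' @return A [raman_spectrum()] on `grid`, same state.
#' @export
resample_spectrum <- function(s, grid = seq(920, 2070, by = 1)) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (identical(s$wavenumber, as.numeric(grid))) return(s)
  y <- stats::approx(s$wavenumber, s$intensity, xout = grid, rule = 2)$y
  raman_spectrum(grid, y, state = s$state, sample_id = s$sample_id)
}

#' Iterative polynomial autofluorescence baseline subtraction
#'
#' Modified polynomial fitting: a polynomial of the given order is fitted to
#' the working spectrum, points above the fit are replaced by the fit, and
#' the procedure iterates until the maximum absolute change falls below
#' `tol` or `max_iter` is reached. Because the converged envelope is biased
#' low by the clipping (it hugs the lower noise/wiggle envelope), it is used
#' only to flag peak regions: the final baseline is an ordinary polynomial
#' fit to the original intensities of the non-peak points, with flagging and
#' refitting repeated until the flagged set stabilizes. The returned
#' intensities are input minus baseline, clipped at zero.
#'
#' @param s A raw [raman_spectrum()].
#' @param order Polynomial order (default 7; 7-9 are typical for tissue
#'   autofluorescence over a ~1000 cm^-1 window).
#' @param max_iter Maximum number of clip-and-refit iterations.
#' @param tol Convergence tolerance on the working spectrum; default
#'   `1e-6 * max(intensity)`.
#' @return A [raman_spectrum()] with `state = "baseline_subtracted"`.
#' @export
subtract_baseline <- function(s, order = 7, max_iter = 100, tol = NULL) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (s$state != "raw")
    stop("subtract_baseline: expected a raw spectrum, got state '", s$state, "'")
  order <- as.integer(order)
  if (order < 1) stop("subtract_baseline: order must be >= 1")
  n <- length(s$wavenumber)
  if (n < order + 2)
    stop("subtract_baseline: spectrum has fewer points than order + 1 allows")
  tol <- tol %||% (1e-6 * max(abs(s$intensity), 1e-12))

  # Orthogonal polynomial basis on the wavenumber axis keeps the high-order
  # fit numerically stable; the QR factorization is reused across iterations.
  X <- cbind(1, stats::poly(s$wavenumber, degree = order))
  qx <- qr(X)
  y0 <- s$intensity
  y <- y0
  fit <- qr.fitted(qx, y)
  for (i in seq_len(max_iter)) {
    y_new <- pmin(y, fit)
    if (max(abs(y_new - y)) < tol) break
    y <- y_new
    fit <- qr.fitted(qx, y)
  }
  # Peak flagging from the envelope, then unbiased refits on the remaining
  # (baseline) points, repeated until the flagged set stabilizes.
  keep_prev <- rep(FALSE, n)
  for (i in seq_len(10)) {
    resid <- y0 - fit
    keep <- resid <= stats::median(resid) + 3 * max(stats::mad(resid), tol)
    if (sum(keep) <= 2 * (order + 1) || identical(keep, keep_prev)) break
    fit <- drop(X %*% qr.coef(qr(X[keep, , drop = FALSE]), y0[keep]))
    keep_prev <- keep
  }
  raman_spectrum(s$wavenumber, pmax(s$intensity - fit, 0),
                 state = "baseline_subtracted", sample_id = s$sample_id)
}

#' Normalize a spectrum by its CH2/CH3 anchor-band maximum
#'
#' Divides all intensities by the maximum within the anchor window
#' (default 1425-1460 cm^-1). The window covers both the lipid 1437 cm^-1
#' and the protein 1446-1448 cm^-1 deformation peaks, so the anchor is
#' selected automatically without knowing the tissue class.
#'
#' @param s A baseline-subtracted (or already normalized) [raman_spectrum()].
#' @param anchor_lo,anchor_hi Anchor window bounds in cm^-1.
#' @return A [raman_spectrum()] with `state = "normalized"`.
#' @export
normalize_spectrum <- function(s, anchor_lo = 1425, anchor_hi = 1460) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (s$state == "raw")
    stop("normalize_spectrum: subtract the baseline before normalizing")
  sel <- s$wavenumber >= anchor_lo & s$wavenumber <= anchor_hi
  if (!any(sel))
    stop("normalize_spectrum: no grid points in the anchor window")
  m <- max(s$intensity[sel])
  if (m <= 0)
    stop("normalize_spectrum: unnormalizable spectrum (anchor-window max <= 0)")
  raman_spectrum(s$wavenumber, s$intensity / m, state = "normalized",
                 sample_id = s$sample_id)
}

#' Default Raman band set (p1-p7)
#'
#' The seven wavenumber intervals whose mean normalized intensities form the
#' band parameters p1-p7: 925-970, 1060-1160, 1180-1280, 1310-1380,
#' 1451-1509, 1845-1880, and 2050-2080 cm^-1.
#'
#' @return Data frame with columns `label`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(label = paste0("p", 1:7),
             lo = c(925, 1060, 1180, 1310, 1451, 1845, 2050),
             hi = c(970, 1160, 1280, 1380, 1509, 1880, 2080))
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("label", "lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) stop("bands: lo must be < hi")
  bands
}

#' Band parameters p1-p8 of a processed spectrum
#'
#' `p1`-`p7` are arithmetic means of the normalized intensity over the grid
#' points falling in each band (endpoints inclusive). `p8` is the mean
#' absolute (baseline-subtracted, unnormalized) intensity over the full
#' grid, so it retains overall signal strength that normalization removes.
#'
#' @param norm A normalized [raman_spectrum()].
#' @param raw_bs The matching baseline-subtracted spectrum on the same grid.
#' @param bands Band definitions, as from [default_bands()].
#' @return Named numeric vector `p1`..`p8` with a `sample_id` attribute.
#' @export
band_parameters <- function(norm, raw_bs, bands = default_bands()) {
  stopifnot(inherits(norm, "raman_spectrum"), inherits(raw_bs, "raman_spectrum"))
  if (norm$state != "normalized")
    stop("band_parameters: 'norm' must be normalized")
  if (raw_bs$state != "baseline_subtracted")
    stop("band_parameters: 'raw_bs' must be baseline-subtracted")
  if (!isTRUE(all.equal(norm$wavenumber, raw_bs$wavenumber)))
    stop("band_parameters: spectra are on different grids")
  bands <- validate_bands(bands)
  p <- vapply(seq_len(nrow(bands)), function(k) {
    sel <- norm$wavenumber >= bands$lo[k] & norm$wavenumber <= bands$hi[k]
    if (!any(sel))
      stop("band_parameters: band ", bands$label[k], " contains no grid points")
    mean(norm$intensity[sel])
  }, numeric(1))
  names(p) <- bands$label
  out <- c(p, p8 = mean(raw_bs$intensity))
  attr(out, "sample_id") <- norm$sample_id
  out
}

#' Full Raman feature extraction for one raw spectrum
#'
#' Resamples to the canonical grid, subtracts the autofluorescence baseline,
#' normalizes by the anchor-band maximum, and computes p1-p8.
#'
#' @param s A raw [raman_spectrum()].
#' @param order Baseline polynomial order.
#' @param bands Band definitions.
#' @param anchor_lo,anchor_hi Normalization anchor window (cm^-1).
#' @param grid Canonical wavenumber grid.
#' @return Named numeric vector `p1`..`p8`.
#' @export
raman_features <- function(s, order = 7, bands = default_bands(),
                           anchor_lo = 1425, anchor_hi = 1460,
                           grid = seq(920, 2070, by = 1)) {
  bs <- subtract_baseline(resample_spectrum(s, grid), order = order)
  nm <- normalize_spectrum(bs, anchor_lo, anchor_hi)
  band_parameters(nm, bs, bands)
}

#' Average Raman feature vectors over a sample's spectra
#'
#' @param vectors List of `p1`..`p8` vectors from [band_parameters()] or
#'   [raman_features()], all from the same sample.
#' @return Feature-wise arithmetic mean, with the shared `sample_id`.
#' @export
aggregate_sample_spectra <- function(vectors) {
  if (length(vectors) == 0)
    stop("aggregate_sample_spectra: empty input")
  ids <- unique(unlist(lapply(vectors, function(v) attr(v, "sample_id") %||% NA)))
  if (length(ids) > 1)
    stop("aggregate_sample_spectra: mixed sample ids: ",
         paste(ids, collapse = ", "))
  m <- do.call(rbind, vectors)
  out <- colMeans(m)
  attr(out, "sample_id") <- ids[[1]]
  out
}
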
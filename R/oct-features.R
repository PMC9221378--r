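#' Statistics of one scanning-window's intensities
#'
#' For the 225 values of a 15 x 15 window (or any non-empty value set):
#' arithmetic mean `mu`, population standard deviation `sigma` (divisor n),
#' `range` = max - min, and the coefficient of variation `cv` = sigma / mu,
#' defined as 0 when `mu` = 0.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `mu`, `sigma`, `range`, `cv`.
#' @export
window_stats <- function(values) {
  if (length(values) == 0) stop("window_stats: empty input")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  rng <- max(values) - min(values)
  cv <- if (mu == 0) 0 else sigma / mu
  c(mu = mu, sigma = sigma, range = rng, cv = cv)
}

#' Scanning-window statistic distributions of a masked B-scan
#'
#' Slides a `window` x `window` pixel window over the image at the given
#' stride and computes `mu`, `sigma` (population), `range` and `cv` from the
#' intensities of every admissible window. A window position is admissible
#' only if all of its pixels lie inside the image and inside the mask, so no
#' statistic ever mixes tissue and background populations. Windows are
#' enumerated in column-major order of their top-left pixel.
#'
#' @param image An [oct_image()].
#' @param mask A fully processed [mask_image()] (all provenance flags set)
#'   of the same shape.
#' @param window Odd window side length >= 3 (default 15).
#' @param stride Step between window anchors (default 1).
#' @return An object of class `stat_distributions`: list with numeric
#'   vectors `mu`, `sigma`, `range`, `cv` and the count `n_windows`. If the
#'   window does not fit in the image, all distributions are empty and
#'   `n_windows` is 0.
#' @export
scan_image <- function(image, mask, window = 15, stride = 1) {
  stopifnot(inherits(image, "oct_image"), inherits(mask, "mask_image"))
  if (!all(mask$flags))
    stop("scan_image: mask must be fully processed (threshold, fill, line removal)")
  if (!identical(dim(image$pixels), dim(mask$mask)))
    stop("scan_image: image and mask shapes differ")
  if (window %% 2 == 0 || window < 3)
    stop("scan_image: window must be odd and >= 3")
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  empty <- structure(list(mu = numeric(0), sigma = numeric(0),
                          range = numeric(0), cv = numeric(0),
                          n_windows = 0L, window = window),
                     class = "stat_distributions")
  if (window > h || window > w) {
    warning("scan_image: window larger than image; no admissible positions")
    return(empty)
  }

  px <- image$pixels
  msum <- window_sums(mask$mask * 1, window)
  ri <- seq(1, nrow(msum), by = stride)
  ci <- seq(1, ncol(msum), by = stride)
  adm <- msum[ri, ci, drop = FALSE] > window * window - 0.5
  if (!any(adm)) return(empty)

  n <- window * window
  s1 <- window_sums(px, window)[ri, ci, drop = FALSE][adm]
  s2 <- window_sums(px * px, window)[ri, ci, drop = FALSE][adm]
  mu <- s1 / n
  sigma <- sqrt(pmax((s2 - s1 * s1 / n) / n, 0))
  mx <- window_extreme(px, window, pmax)[ri, ci, drop = FALSE][adm]
  mn <- window_extreme(px, window, pmin)[ri, ci, drop = FALSE][adm]
  cv <- ifelse(mu == 0, 0, sigma / mu)
  structure(list(mu = mu, sigma = sigma, range = mx - mn, cv = cv,
                 n_windows = length(mu), window = window),
            class = "stat_distributions")
}

#' @export
print.stat_distributions <- function(x, ...) {
  cat(sprintf("<stat_distributions> %d admissible %dx%d windows\n",
              x$n_windows, x$window, x$window))
  invisible(x)
}

oct_feature_names <- function() {
  as.vector(t(outer(c("m", "s", "md"), c("mu", "sigma", "range", "cv"),
                    function(a, b) paste(a, b, sep = "_"))))
}

#' Summarize window-statistic distributions into 12 image features
#'
#' Each of the four per-window distributions (`mu`, `sigma`, `range`, `cv`)
#' is reduced to its mean (`m_`), standard deviation (`s_`, sample sd), and
#' median (`md_`; the mean of the middle pair for even counts), yielding 12
#' named features per image.
#'
#' @param d A [scan_image()] result with `n_windows >= 1`.
#' @return Named numeric vector of 12 finite features.
#' @export
summarize_distributions <- function(d) {
  stopifnot(inherits(d, "stat_distributions"))
  if (d$n_windows < 1)
    stop("summarize_distributions: unfeaturable image (no admissible windows)")
  out <- unlist(lapply(c("mu", "sigma", "range", "cv"), function(par) {
    v <- d[[par]]
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0, stats::median(v))
  }))
  names(out) <- as.vector(vapply(c("mu", "sigma", "range", "cv"),
                                 function(p) paste(c("m", "s", "md"), p, sep = "_"),
                                 character(3)))
  out
}

#' 12 scanning-window features of one masked B-scan
#'
#' Convenience composition of [scan_image()] and [summarize_distributions()].
#'
#' @inheritParams scan_image
#' @return Named numeric vector of 12 features with a `sample_id` attribute.
#' @export
oct_image_features <- function(image, mask, window = 15, stride = 1) {
  f <- summarize_distributions(scan_image(image, mask, window, stride))
  attr(f, "sample_id") <- image$sample_id
  f
}

#' Average image feature vectors over a sample
#'
#' @param vectors List of 12-feature vectors from [oct_image_features()],
#'   all from the same sample.
#' @return Feature-wise arithmetic mean with attributes `sample_id` and
#'   `n_images`.
#' @export
aggregate_sample <- function(vectors) {
  if (length(vectors) == 0) stop("aggregate_sample: empty input")
  ids <- unique(unlist(lapply(vectors, function(v) attr(v, "sample_id") %||% NA)))
  if (length(ids) > 1)
    stop("aggregate_sample: mixed sample ids: ", paste(ids, collapse = ", "))
  m <- do.call(rbind, vectors)
  out <- colMeans(m)
  attr(out, "sample_id") <- ids[[1]]
  attr(out, "n_images") <- length(vectors)
  out
}
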
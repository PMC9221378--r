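# Effective texture parameters after applying the class-separation knob:
# class_gap = 1 keeps the configured values; smaller values pull each class's
# tissue mean, spread, void density and surface-line boost toward the pooled
# cross-class average.
gap_texture <- function(cfg, class_label) {
  tx <- cfg$texture
  g <- cfg$class_gap
  pull <- function(field) vapply(tx, function(p) p[[field]], numeric(1))
  means <- pull("tissue_mean"); sds <- pull("tissue_std")
  vd <- pull("void_density")
  boost <- vapply(tx, function(p) if (isTRUE(p$surface_line)) 120 else 0, numeric(1))
  p <- tx[[class_label]]
  p$tissue_mean   <- mean(means) + g * (p$tissue_mean - mean(means))
  p$tissue_std    <- mean(sds)   + g * (p$tissue_std - mean(sds))
  p$void_density  <- max(0, mean(vd) + g * (vd[[class_label]] - mean(vd)))
  p$surface_boost <- mean(boost) + g * (boost[[class_label]] - mean(boost))
  p
}

#' Generate a synthetic OCT B-scan
#'
#' Draws one 8-bit grayscale B-scan with the texture of the requested tissue
#' class: near-background rows above the tissue surface, Gaussian speckle in
#' the tissue region, dark circular voids for lipoma (honeycomb), a bright
#' surface band for skin (stratum corneum), and, with probability
#' `saturation_line_prob`, a full-height bright artifact column (1-3 px wide,
#' with random vertical gaps) that the masking stage must remove.
#'
#' The returned image carries the generator's ground truth as extra fields:
#' `truth_mask` (logical tissue region, voids included as tissue),
#' `void_mask`, and `saturation_columns`.
#'
#' @param class_label One of [tissue_classes()].
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed (sets the RNG before drawing).
#' @param mean_shift Additive between-sample shift of the tissue mean.
#' @return An [oct_image()] with ground-truth fields attached.
#' @export
generate_oct_image <- function(class_label, cfg, seed = NULL, mean_shift = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!class_label %in% names(cfg$texture))
    stop("generate_oct_image: unknown class label '", class_label, "'")
  if (!is.null(seed)) set.seed(seed)
  p <- gap_texture(cfg, class_label)
  H <- cfg$image_height; W <- cfg$image_width
  srow <- p$surface_row

  img <- matrix(stats::rnorm(H * W, p$background_level, 3), H, W)
  tissue_rows <- srow:H
  img[tissue_rows, ] <- stats::rnorm(length(tissue_rows) * W,
                                     p$tissue_mean + mean_shift, p$tissue_std)
  if (p$surface_boost > 0) {
    band <- srow:min(srow + 2L, H)
    img[band, ] <- stats::rnorm(length(band) * W,
                                p$tissue_mean + mean_shift + p$surface_boost, 8)
  }

  void_mask <- matrix(FALSE, H, W)
  r <- p$void_radius_px
  if (p$void_density > 0 && r > 0) {
    n_tissue <- length(tissue_rows) * W
    n_voids <- stats::rpois(1, p$void_density * n_tissue)
    if (n_voids > 0) {
      rlo <- srow + r + 2L; rhi <- H - r
      clo <- r + 1L; chi <- W - r
      if (rlo < rhi && clo < chi) {
        cy <- sample(rlo:rhi, n_voids, replace = TRUE)
        cx <- sample(clo:chi, n_voids, replace = TRUE)
        off <- expand.grid(dy = -r:r, dx = -r:r)
        off <- off[off$dy^2 + off$dx^2 <= r^2, ]
        for (k in seq_len(n_voids)) {
          rows <- cy[k] + off$dy; cols <- cx[k] + off$dx
          idx <- cbind(rows, cols)
          img[idx] <- stats::rnorm(nrow(idx), p$background_level, 2)
          void_mask[idx] <- TRUE
        }
      }
    }
  }

  sat_cols <- integer(0)
  if (stats::runif(1) < p$saturation_line_prob) {
    width <- sample(1:3, 1)
    start <- sample(seq_len(W - width), 1)
    cols <- start:(start + width - 1L)
    rows_on <- stats::runif(H) < 0.7          # periodic patches, not solid
    rows_on[sample(1:12, 3)] <- TRUE          # always reaches the top rows
    img[rows_on, cols] <- cfg$texture[[class_label]]$background_level + 247
    sat_cols <- cols
  }

  img <- pmin(pmax(round(img), 0), 255)
  out <- oct_image(img, sample_id = NULL, class_label = class_label)
  truth <- matrix(FALSE, H, W)
  truth[tissue_rows, ] <- TRUE
  out$truth_mask <- truth
  out$void_mask <- void_mask
  out$saturation_columns <- sat_cols
  out
}
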
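#' Generate a synthetic multimodal dataset on disk
#'
#' Draws `n_samples_per_class` samples per tissue class, each with
#' `images_per_sample` OCT B-scans (written as 8-bit grayscale TIFF) and
#' `spectra_per_sample` Raman spectra (written as two-column CSV), plus a
#' manifest CSV with columns `sample_id`, `class`, `modality`, `path`
#' (paths relative to `out_dir`). Between-sample variability is injected as
#' a Gaussian shift of the tissue mean (OCT) and lognormal gain and
#' peak-width factors (Raman), shared by all of a sample's measurements.
#'
#' The full dataset is a pure function of the configuration including its
#' seed: two runs with the same `cfg` produce byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, a list with `manifest` (data frame), `dir`, and
#'   `truth_masks` (named list of ground-truth tissue masks, one per image
#'   file, for validation against the masking stage).
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0)
    stop("generate_dataset: output directory not writable: ", out_dir)
  set.seed(cfg$seed)

  rows <- list()
  truth <- list()
  for (cl in names(cfg$texture)) {
    tx <- cfg$texture[[cl]]; sp <- cfg$spectra[[cl]]
    for (i in seq_len(cfg$n_samples_per_class)) {
      sid <- sprintf("%s_%02d", cl, i)
      mean_shift <- stats::rnorm(1, 0, tx$sample_mean_sd)
      gain_factor <- stats::rlnorm(1, 0, sp$gain_jitter_sdlog)
      width_factor <- stats::rlnorm(1, 0, sp$width_jitter_sdlog)
      for (j in seq_len(cfg$images_per_sample)) {
        img <- generate_oct_image(cl, cfg, mean_shift = mean_shift)
        img$sample_id <- sid
        rel <- sprintf("%s_img%02d.tiff", sid, j)
        write_oct_tiff(img, file.path(out_dir, rel))
        truth[[rel]] <- img$truth_mask
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, class = cl, modality = "OCT", path = rel)
      }
      for (j in seq_len(cfg$spectra_per_sample)) {
        s <- generate_raman_spectrum(cl, cfg, gain_factor = gain_factor,
                                     width_factor = width_factor)
        s$sample_id <- sid
        rel <- sprintf("%s_spec%02d.csv", sid, j)
        write_spectrum_csv(s, file.path(out_dir, rel))
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, class = cl, modality = "Raman", path = rel)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, dir = out_dir, truth_masks = truth))
}
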
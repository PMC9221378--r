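#' Synthetic dataset configuration
#'
#' Builds the configuration for the synthetic OCT/Raman data generator. The
#' defaults define the study conditions used throughout the package's tests:
#' ten samples per class, four B-scans and eight Raman spectra per sample,
#' with per-class texture and spectral parameters that emulate the published
#' qualitative contrasts: low-reflectance honeycomb lipoma with dark voids,
#' dense highly scattering MCT/STS, layered skin with a bright surface line,
#' occasional full-height saturation artifact columns, and class-specific
#' Raman peaks on a smooth fluorescence background.
#'
#' @param n_samples_per_class Samples generated per tissue class (>= 1).
#' @param images_per_sample B-scans per sample (>= 1).
#' @param spectra_per_sample Raman spectra per sample (>= 1).
#' @param image_height,image_width Image dimensions in pixels; both must be
#'   >= 31 so at least one 15 x 15 window fits with margin.
#' @param class_gap Class-separation knob in `[0, 1]`: 1 keeps the per-class
#'   parameters as configured; smaller values shrink every class's texture
#'   means, void densities, spectral signal and log-gain toward the pooled
#'   cross-class average, degrading downstream separability.
#' @param seed Integer seed; the full dataset is a pure function of the
#'   configuration including this seed.
#' @param texture Named list (one entry per class) of texture parameters;
#'   see Details. `NULL` uses the defaults.
#' @param spectra Named list (one entry per class) of spectral parameters;
#'   `NULL` uses the defaults.
#' @param wavenumber Wavenumber grid in cm^-1 (default 920-2070, 1 cm^-1
#'   spacing, the canonical internal grid).
#'
#' @details Texture parameters per class: `background_level`, `tissue_mean`,
#' `tissue_std`, `sample_mean_sd` (between-sample jitter of the tissue mean),
#' `void_density` (expected void centers per tissue pixel), `void_radius_px`,
#' `surface_line` (bright stratum-corneum band), `surface_row` (first tissue
#' row; must exceed 15 so the top rows image only background),
#' `saturation_line_prob` (per-image probability of a saturation artifact).
#'
#' Spectral parameters per class: `peak_centers` (cm^-1), `peak_heights`,
#' `peak_widths` (Gaussian sd, cm^-1), `baseline_coeffs` (polynomial in the
#' scaled wavenumber, fluorescence background), `noise_sd`, `overall_gain`,
#' `gain_jitter_sdlog` (between-sample lognormal gain jitter),
#' `width_jitter_sdlog` (between-sample lognormal peak-width jitter).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_samples_per_class = 10,
                         images_per_sample = 4,
                         spectra_per_sample = 8,
                         image_height = 100,
                         image_width = 140,
                         class_gap = 1,
                         seed = 42,
                         texture = NULL,
                         spectra = NULL,
                         wavenumber = seq(920, 2070, by = 1)) {
  counts <- c(n_samples_per_class, images_per_sample, spectra_per_sample)
  if (any(counts < 1)) stop("synth_config: all counts must be >= 1")
  if (image_height < 31 || image_width < 31)
    stop("synth_config: image dims must be >= 31 so a 15x15 window fits with margin")
  if (class_gap < 0 || class_gap > 1)
    stop("synth_config: class_gap must lie in [0, 1]")
  stopifnot(is.numeric(seed), length(seed) == 1)

  texture <- texture %||% default_texture_params()
  spectra <- spectra %||% default_spectrum_params()
  missing_tex <- setdiff(CANONICAL_CLASSES, names(texture))
  if (length(missing_tex))
    stop("synth_config: texture parameters missing for class(es): ",
         paste(missing_tex, collapse = ", "))
  missing_sp <- setdiff(CANONICAL_CLASSES, names(spectra))
  if (length(missing_sp))
    stop("synth_config: spectrum parameters missing for class(es): ",
         paste(missing_sp, collapse = ", "))
  for (cl in names(spectra)) {
    sp <- spectra[[cl]]
    if (length(sp$peak_centers) < 1)
      stop("synth_config: class '", cl, "' defines no Raman peaks")
    if (any(sp$peak_centers < min(wavenumber) | sp$peak_centers > max(wavenumber)))
      stop("synth_config: class '", cl, "' has peak centers outside the wavenumber range")
  }
  for (cl in names(texture)) {
    if (texture[[cl]]$surface_row <= 15)
      stop("synth_config: surface_row must exceed 15 (top rows must image only background)")
  }

  structure(
    list(n_samples_per_class = as.integer(n_samples_per_class),
         images_per_sample = as.integer(images_per_sample),
         spectra_per_sample = as.integer(spectra_per_sample),
         image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         class_gap = class_gap, seed = as.integer(seed),
         texture = texture, spectra = spectra, wavenumber = wavenumber),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>",
      x$n_samples_per_class, "samples/class,",
      x$images_per_sample, "images +", x$spectra_per_sample, "spectra each,",
      sprintf("%dx%d px, gap %.2f, seed %d\n",
              x$image_height, x$image_width, x$class_gap, x$seed))
  invisible(x)
}

#' Default per-class OCT texture parameters
#'
#' Skin: mid reflectance, heterogeneous, bright surface line. Lipoma: low
#' reflectance honeycomb with dark voids. MCT/STS: dense, bright, homogeneous
#' speckle. Intensities are 8-bit.
#'
#' @return Named list with one parameter list per class.
#' @export
default_texture_params <- function() {
  base <- function(background_level, tissue_mean, tissue_std, sample_mean_sd,
                   void_density, void_radius_px, surface_line,
                   saturation_line_prob, surface_row = 22) {
    list(background_level = background_level, tissue_mean = tissue_mean,
         tissue_std = tissue_std, sample_mean_sd = sample_mean_sd,
         void_density = void_density, void_radius_px = void_radius_px,
         surface_line = surface_line,
         saturation_line_prob = saturation_line_prob,
         surface_row = surface_row)
  }
  list(
    skin   = base(8, 120, 16, 8, 0,      0, TRUE,  0.15),
    lipoma = base(8,  70, 22, 8, 0.004,  4, FALSE, 0.15),
    MCT    = base(8, 150, 12, 8, 0,      0, FALSE, 0.20),
    STS    = base(8, 142, 13, 8, 0,      0, FALSE, 0.20)
  )
}

#' Default per-class Raman spectral parameters
#'
#' Peak sets follow the fingerprint-region assignments reported for these
#' tissues: lipoma is lipid-dominated (1076, 1300, 1437, 1656 cm^-1); skin
#' carries dermal protein/collagen bands (935, 1000, 1031, 1127, 1343, 1448,
#' 1544, 1586, 1656, 1885, 2067 cm^-1); MCT and STS share the protein set
#' plus an elevated nucleic-acid band at 1241 cm^-1 and a 1480 cm^-1 band,
#' with the lipid 1437 cm^-1 shoulder reduced and the CH2/CH3 anchor at
#' 1446 cm^-1. MCT and STS are given identical normalized spectral shapes
#' (their band features differ only by overall intensity), mirroring the
#' absence of significant MCT-STS band contrasts. `overall_gain` separates
#' classes in absolute intensity only (the p8 feature).
#'
#' @return Named list with one parameter list per class.
#' @export
default_spectrum_params <- function() {
  protein_centers <- c(935, 1000, 1031, 1127, 1343, 1544, 1586, 1656, 1885, 2067)
  protein_heights <- c(0.50, 0.45, 0.40, 0.38, 0.50, 0.38, 0.32, 0.85, 0.28, 0.35)
  malignant <- list(
    peak_centers = c(protein_centers, 1241, 1446, 1480, 1437),
    peak_heights = c(protein_heights, 0.45, 1.00, 0.50, 0.15),
    peak_widths  = rep(9, length(protein_centers) + 4),
    baseline_coeffs = c(4, 0.8, -1.8),
    noise_sd = 0.02, gain_jitter_sdlog = 0.10, width_jitter_sdlog = 0.06)
  mct <- c(malignant, list(overall_gain = 1.6))
  sts <- c(malignant, list(overall_gain = 0.7))
  list(
    skin = list(
      peak_centers = c(protein_centers, 1448),
      peak_heights = c(protein_heights, 1.00),
      peak_widths  = rep(9, length(protein_centers) + 1),
      baseline_coeffs = c(4, 0.8, -1.8),
      noise_sd = 0.02, overall_gain = 1.0,
      gain_jitter_sdlog = 0.10, width_jitter_sdlog = 0.06),
    lipoma = list(
      peak_centers = c(1076, 1300, 1437, 1656),
      peak_heights = c(0.70, 0.60, 1.00, 0.55),
      peak_widths  = rep(10, 4),
      baseline_coeffs = c(3.5, 0.6, -1.5),
      noise_sd = 0.02, overall_gain = 2.2,
      gain_jitter_sdlog = 0.10, width_jitter_sdlog = 0.06),
    MCT = mct,
    STS = sts
  )
}
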
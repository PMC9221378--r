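# Clean (noise- and baseline-free, unit-gain) class signal on the grid.
class_signal <- function(cfg, class_label, width_factor = 1) {
  sp <- cfg$spectra[[class_label]]
  nu <- cfg$wavenumber
  sig <- numeric(length(nu))
  for (k in seq_along(sp$peak_centers)) {
    w <- sp$peak_widths[k] * width_factor
    sig <- sig + sp$peak_heights[k] * exp(-0.5 * ((nu - sp$peak_centers[k]) / w)^2)
  }
  sig
}

# Class-separation knob for spectra: blend each class's clean signal and
# log-gain toward the pooled cross-class average.
gap_signal <- function(cfg, class_label, width_factor = 1) {
  g <- cfg$class_gap
  own <- class_signal(cfg, class_label, width_factor)
  if (g == 1) return(own)
  all_sig <- vapply(names(cfg$spectra), function(cl) class_signal(cfg, cl),
                    numeric(length(cfg$wavenumber)))
  pooled <- rowMeans(all_sig)
  pooled + g * (own - pooled)
}

gap_gain <- function(cfg, class_label) {
  gains <- vapply(cfg$spectra, function(p) p$overall_gain, numeric(1))
  lg <- log(gains)
  exp(mean(lg) + cfg$class_gap * (lg[[class_label]] - mean(lg)))
}

# Polynomial fluorescence background evaluated on the grid, in the scaled
# coordinate u in [-1, 1].
baseline_curve <- function(cfg, class_label) {
  nu <- cfg$wavenumber
  u <- 2 * (nu - mean(range(nu))) / diff(range(nu))
  cf <- cfg$spectra[[class_label]]$baseline_coeffs
  drop(outer(u, seq_along(cf) - 1, `^`) %*% cf)
}

#' Generate a synthetic Raman spectrum
#'
#' Intensity = gain * (sum of class Gaussian peaks + polynomial fluorescence
#' baseline) + Gaussian shot-like noise, clipped at zero, on the canonical
#' 920-2070 cm^-1 grid. The returned spectrum carries the generator truth as
#' attributes `clean_signal` (gain x peak sum, no baseline/noise) and
#' `baseline` (gain x fluorescence curve).
#'
#' @param class_label One of [tissue_classes()].
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed.
#' @param gain_factor Multiplicative between-sample gain jitter.
#' @param width_factor Multiplicative between-sample peak-width jitter.
#' @return A raw [raman_spectrum()].
#' @export
generate_raman_spectrum <- function(class_label, cfg, seed = NULL,
                                    gain_factor = 1, width_factor = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!class_label %in% names(cfg$spectra))
    stop("generate_raman_spectrum: unknown class label '", class_label, "'")
  sp <- cfg$spectra[[class_label]]
  if (length(sp$peak_centers) < 1)
    stop("generate_raman_spectrum: class '", class_label, "' defines no peaks")
  if (!is.null(seed)) set.seed(seed)
  gain <- gap_gain(cfg, class_label) * gain_factor
  signal <- gap_signal(cfg, class_label, width_factor)
  base <- baseline_curve(cfg, class_label)
  noise <- stats::rnorm(length(signal), 0, sp$noise_sd * gain)
  y <- pmax(gain * (signal + base) + noise, 0)
  out <- raman_spectrum(cfg$wavenumber, y, state = "raw")
  attr(out, "clean_signal") <- gain * signal
  attr(out, "baseline") <- gain * base
  out
}
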
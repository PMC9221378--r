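# Independent brute-force oracles used to validate the vectorized
# implementations, plus small fixture factories.

# Naive per-position scanning-window recomputation (full-coverage
# admissibility, column-major anchor order, population sd).
oracle_scan <- function(px, mask, w = 15) {
  h <- nrow(px); wd <- ncol(px)
  mu <- sigma <- rng <- cv <- numeric(0)
  for (j in seq_len(wd - w + 1)) {
    for (i in seq_len(h - w + 1)) {
      if (all(mask[i:(i + w - 1), j:(j + w - 1)])) {
        v <- as.vector(px[i:(i + w - 1), j:(j + w - 1)])
        m <- sum(v) / length(v)
        s <- sqrt(sum((v - m)^2) / length(v))
        mu <- c(mu, m); sigma <- c(sigma, s)
        rng <- c(rng, max(v) - min(v))
        cv <- c(cv, if (m == 0) 0 else s / m)
      }
    }
  }
  list(mu = mu, sigma = sigma, range = rng, cv = cv, n_windows = length(mu))
}

# Stack-based 4-connected component labelling of the zero pixels; returns
# the expected void-filled mask: zero components not touching the border
# become TRUE.
oracle_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(!mask & lab == 0L)) {
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[q] != 0L || mask[q]) next
      lab[q] <- nxt
      i <- (q - 1L) %% h + 1L; j <- (q - 1L) %/% h + 1L
      if (i > 1) stack <- c(stack, q - 1L)
      if (i < h) stack <- c(stack, q + 1L)
      if (j > 1) stack <- c(stack, q - h)
      if (j < w) stack <- c(stack, q + h)
    }
  }
  border_labs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labs <- setdiff(border_labs, 0L)
  mask | (lab != 0L & !(lab %in% border_labs))
}

# Exhaustive Mann-Whitney permutation enumeration; two-sided p as twice the
# smaller tail, capped at 1 (the convention of the exact Wilcoxon test).
oracle_mw <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force Otsu: try every split level, maximize between-class variance.
oracle_otsu <- function(px) {
  v <- round(as.vector(px))
  best <- -Inf; best_t <- Inf
  for (t in sort(unique(v))) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t + 1 }
  }
  best_t
}

# A fully processed mask wrapper for hand-built masks.
processed_mask <- function(m) {
  mask_image(m, thresholded = TRUE, voids_filled = TRUE,
             saturation_removed = TRUE)
}

# Small, fast study configuration for property tests.
small_cfg <- function(...) {
  synth_config(n_samples_per_class = 5, images_per_sample = 2,
               spectra_per_sample = 3, image_height = 60, image_width = 80,
               ...)
}

# Per-sample Raman feature rows generated in memory (mirrors the dataset
# generator's sample-effect structure without touching the disk).
raman_sample_features <- function(cl, cfg, n_samples, n_spectra) {
  sp <- cfg$spectra[[cl]]
  rows <- lapply(seq_len(n_samples), function(i) {
    gf <- stats::rlnorm(1, 0, sp$gain_jitter_sdlog)
    wf <- stats::rlnorm(1, 0, sp$width_jitter_sdlog)
    vecs <- lapply(seq_len(n_spectra), function(j) {
      v <- raman_features(generate_raman_spectrum(cl, cfg, gain_factor = gf,
                                                  width_factor = wf))
      attr(v, "sample_id") <- sprintf("%s_%02d", cl, i)
      v
    })
    f <- aggregate_sample_spectra(vecs)
    cbind(data.frame(sample_id = attr(f, "sample_id"), class = cl),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

# Default-conditions dataset + pipeline report, computed once per test run.
.octraman_cache <- new.env(parent = emptyenv())
default_report <- function() {
  if (is.null(.octraman_cache$report)) {
    cfg <- synth_config()
    dir <- file.path(tempdir(), "octraman-default-ds")
    d <- generate_dataset(cfg, dir)
    .octraman_cache$dataset <- d
    .octraman_cache$report <- suppressWarnings(
      run_pipeline(d$manifest, data_dir = d$dir))
  }
  .octraman_cache$report
}
default_dataset <- function() {
  default_report()
  .octraman_cache$dataset
}
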
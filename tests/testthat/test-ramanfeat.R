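grid_920 <- seq(920, 2070, by = 1)
gauss <- function(nu, center, height, width) {
  height * exp(-0.5 * ((nu - center) / width)^2)
}

test_that("a pure polynomial background is removed to numerical zero", {
  u <- 2 * (grid_920 - mean(range(grid_920))) / diff(range(grid_920))
  y <- 100 * (2 + u - 0.5 * u^2 + 0.3 * u^3 - u^5 + 0.2 * u^7)
  y <- y - min(y) + 5                       # keep it a positive "spectrum"
  s <- raman_spectrum(grid_920, y)
  out <- subtract_baseline(s, order = 7)
  expect_equal(out$state, "baseline_subtracted")
  expect_lt(max(abs(out$intensity)), 1e-6 * max(y))
})

test_that("baseline subtraction recovers a known peak area on a zero baseline", {
  peak <- gauss(grid_920, 1300, 10, 12)
  s <- raman_spectrum(grid_920, peak)
  out <- subtract_baseline(s, order = 7)
  expect_lt(abs(sum(out$intensity) - sum(peak)) / sum(peak), 0.02)
})

test_that("order-7 correction of a degree-5 background preserves band features", {
  # one peak per band plus the 1437 anchor, on a smooth degree-5 background
  centers <- c(945, 1110, 1240, 1340, 1480, 1860, 2065, 1437)
  heights <- c(0.5, 0.6, 0.45, 0.5, 0.5, 0.3, 0.35, 1.0)
  peaks <- Reduce(`+`, Map(function(c, h) gauss(grid_920, c, h, 9),
                           centers, heights))
  u <- 2 * (grid_920 - mean(range(grid_920))) / diff(range(grid_920))
  base <- 5 + 0.8 * u - 1.5 * u^2 + 0.4 * u^3 - 0.3 * u^5
  with_base <- raman_spectrum(grid_920, peaks + base)
  got <- raman_features(with_base, order = 7)
  # truth: band means of the anchor-normalized pure peak sum
  truth_norm <- peaks / max(peaks[grid_920 >= 1425 & grid_920 <= 1460])
  bands <- default_bands()
  for (k in 1:7) {
    sel <- grid_920 >= bands$lo[k] & grid_920 <= bands$hi[k]
    expect_lt(abs(got[[paste0("p", k)]] - mean(truth_norm[sel])) /
                mean(truth_norm[sel]), 0.05)
  }
  expect_error(subtract_baseline(raman_spectrum(1:8, rnorm(8)), order = 9),
               "fewer points")
  expect_error(subtract_baseline(subtract_baseline(raman_spectrum(grid_920, peaks))),
               "raw spectrum")
})

test_that("anchor-window normalization scales by the window maximum and is idempotent", {
  y <- gauss(grid_920, 1437, 500, 9) + gauss(grid_920, 1000, 120, 9)
  s <- raman_spectrum(grid_920, y, state = "baseline_subtracted")
  n1 <- normalize_spectrum(s)
  expect_equal(n1$state, "normalized")
  expect_equal(n1$intensity[grid_920 == 1437], 1)
  expect_equal(n1$intensity, y / y[grid_920 == 1437])
  expect_equal(normalize_spectrum(n1)$intensity, n1$intensity)
  expect_error(normalize_spectrum(raman_spectrum(grid_920, y)), "baseline")
  flat <- raman_spectrum(grid_920, rep(0, length(grid_920)),
                         state = "baseline_subtracted")
  expect_error(normalize_spectrum(flat), "unnormalizable")
})

test_that("synthetic MCT spectra normalize at the 1446 protein anchor", {
  cfg <- synth_config()
  s <- generate_raman_spectrum("MCT", cfg, seed = 8)
  bs <- subtract_baseline(s)
  sel <- bs$wavenumber >= 1425 & bs$wavenumber <= 1460
  anchor <- bs$wavenumber[sel][which.max(bs$intensity[sel])]
  expect_lte(abs(anchor - 1446), 1)
})

test_that("band parameters average the configured intervals inclusively", {
  n <- length(grid_920)
  norm_const <- raman_spectrum(grid_920, rep(0.4, n), state = "normalized")
  bs_any <- raman_spectrum(grid_920, rep(2, n), state = "baseline_subtracted")
  p <- band_parameters(norm_const, bs_any)
  expect_equal(unname(p[paste0("p", 1:7)]), rep(0.4, 7))
  expect_equal(p[["p8"]], 2)

  ind <- ifelse(grid_920 >= 1451 & grid_920 <= 1509, 1, 0)
  p2 <- band_parameters(raman_spectrum(grid_920, ind, state = "normalized"),
                        bs_any)
  expect_equal(p2[["p5"]], 1)
  expect_equal(unname(p2[paste0("p", c(1:4, 6, 7))]), rep(0, 6))

  set.seed(51)
  y <- runif(n); z <- runif(n) * 10
  p3 <- band_parameters(raman_spectrum(grid_920, y, state = "normalized"),
                        raman_spectrum(grid_920, z, state = "baseline_subtracted"))
  bands <- default_bands()
  for (k in 1:7) {
    acc <- c(); for (i in seq_len(n))
      if (grid_920[i] >= bands$lo[k] && grid_920[i] <= bands$hi[k])
        acc <- c(acc, y[i])
    expect_equal(p3[[paste0("p", k)]], mean(acc))
  }
  expect_equal(p3[["p8"]], sum(z) / n)

  empty_band <- data.frame(label = "px", lo = 1000.2, hi = 1000.8)
  expect_error(band_parameters(norm_const, bs_any, empty_band),
               "no grid points")
})

test_that("sample aggregation of spectral features is the column mean", {
  tag <- function(v, id = "s1") { attr(v, "sample_id") <- id; v }
  a <- tag(setNames(1:8, c(paste0("p", 1:7), "p8")))
  b <- tag(setNames(9:16, c(paste0("p", 1:7), "p8")))
  expect_equal(as.vector(aggregate_sample_spectra(list(a))), 1:8)
  expect_equal(as.vector(aggregate_sample_spectra(list(a, b))), (1:8 + 9:16) / 2)
  set.seed(52)
  vs <- lapply(1:8, function(i) tag(setNames(runif(8), names(a))))
  expect_equal(as.vector(aggregate_sample_spectra(vs)),
               unname(colMeans(do.call(rbind, vs))))
  expect_error(aggregate_sample_spectra(list()), "empty")
  expect_error(aggregate_sample_spectra(list(a, tag(b, "s2"))), "mixed")
})

test_that("gain invariance: p1-p7 ignore overall gain, p8 scales with it", {
  cfg <- synth_config()
  s <- generate_raman_spectrum("skin", cfg, seed = 9)
  g <- 3.7
  scaled <- raman_spectrum(s$wavenumber, g * s$intensity)
  f1 <- raman_features(s); f2 <- raman_features(scaled)
  expect_equal(f2[paste0("p", 1:7)], f1[paste0("p", 1:7)], tolerance = 1e-8)
  expect_equal(f2[["p8"]], g * f1[["p8"]], tolerance = 1e-8)
})

test_that("band means are monotone under pointwise spectrum dominance", {
  set.seed(53)
  lo <- runif(length(grid_920))
  hi <- lo + runif(length(grid_920), 0, 0.5)
  bs <- raman_spectrum(grid_920, rep(1, length(grid_920)),
                       state = "baseline_subtracted")
  p_lo <- band_parameters(raman_spectrum(grid_920, lo, state = "normalized"), bs)
  p_hi <- band_parameters(raman_spectrum(grid_920, hi, state = "normalized"), bs)
  expect_true(all(p_hi[paste0("p", 1:7)] >= p_lo[paste0("p", 1:7)]))
})

test_that("the 1451-1509 band separates malignant tissue from skin but not MCT from STS", {
  cfg <- synth_config()
  set.seed(54)
  feats <- do.call(rbind, lapply(c("skin", "MCT", "STS"), function(cl)
    raman_sample_features(cl, cfg, n_samples = 10, n_spectra = 8)))
  sig <- mann_whitney_matrix(feats["p5"], feats$class)
  get <- function(a, b) sig$p_value[sig$group1 == a & sig$group2 == b]
  expect_lt(get("skin", "MCT"), 0.05)
  expect_lt(get("skin", "STS"), 0.05)
  expect_gte(get("MCT", "STS"), 0.05)
})
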
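make_gaussians <- function(n_per, means, sd = 0.5, p = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(means), function(k)
    matrix(rnorm(n_per * p, means[k], sd), n_per, p)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, g = rep(names(means), each = n_per))
}

test_that("well-separated classes are fit perfectly and project to K-1 axes", {
  d <- make_gaussians(20, c(skin = -5, MCT = 5), sd = 0.5, p = 1)
  fit <- tissue_lda(d$x, d$g)
  expect_equal(mean(as.character(predict(fit, d$x)$class) == d$g), 1.0)
  expect_equal(ncol(fit$scaling), 1L)

  d4 <- make_gaussians(5, c(skin = 0, lipoma = 6, MCT = 12, STS = 18), p = 3)
  fit4 <- tissue_lda(d4$x, d4$g)
  expect_equal(ncol(predict(fit4, d4$x)$x), 3L)
  expect_identical(fit4$classes, c("skin", "lipoma", "MCT", "STS"))
})

test_that("permuted labels carry no signal beyond small-sample optimism", {
  d <- make_gaussians(20, c(skin = 0, MCT = 0), sd = 1, p = 1, seed = 2)
  set.seed(3)
  train_acc <- replicate(100, {
    g <- sample(d$g)
    fit <- tissue_lda(d$x, g)
    mean(as.character(predict(fit, d$x)$class) == g)
  })
  # resubstitution on noise: at/above chance but bounded by optimism
  expect_gt(mean(train_acc), 0.5 - 3 * sqrt(0.25 / (100 * 40)))
  expect_lt(mean(train_acc), 0.70)
  # held-out predictions sit at or below chance on permuted labels
  set.seed(4)
  cv_acc <- replicate(20, {
    g <- sample(d$g)
    p <- loocv_lda(d$x, g)
    mean(p$true_label == p$predicted_label)
  })
  expect_lt(mean(cv_acc), 0.5 + 3 * sqrt(0.25 / (20 * 40)))
})

test_that("discriminant projections and predictions agree with an independent LDA", {
  d <- make_gaussians(15, c(skin = 0, lipoma = 3, MCT = 6), sd = 1.2, p = 4,
                      seed = 5)
  fit <- tissue_lda(d$x, d$g)
  ref <- MASS::lda(d$x, grouping = factor(d$g, levels = unique(d$g)),
                   prior = rep(1 / 3, 3))
  expect_identical(as.character(predict(fit, d$x)$class),
                   as.character(predict(ref, d$x)$class))
  # axes agree up to sign/scale
  mine <- predict(fit, d$x)$x
  theirs <- predict(ref, d$x)$x
  for (j in 1:2) expect_gt(abs(cor(mine[, j], theirs[, j])), 0.999)
})

test_that("singular scatter triggers the documented ridge fallback or a named failure", {
  d <- make_gaussians(10, c(skin = 0, MCT = 4), sd = 1, p = 2, seed = 6)
  x <- cbind(d$x, dead = rep(3, nrow(d$x)))  # zero-variance feature
  expect_error(tissue_lda(x, d$g, regularize = FALSE), "dead")
  fit <- tissue_lda(x, d$g)
  expect_true(fit$regularized)
  expect_equal(mean(as.character(predict(fit, x)$class) == d$g), 1.0)
})

test_that("LOOCV produces one held-out prediction per sample", {
  d <- make_gaussians(6, c(skin = -6, lipoma = 0, MCT = 6), sd = 0.5, p = 2,
                      seed = 7)
  p <- loocv_lda(d$x, d$g)
  expect_s3_class(p, "prediction_table")
  expect_equal(nrow(p), 18L)
  expect_equal(sum(grepl("^LD", names(p))), 2L)
  expect_identical(p$predicted_label, p$true_label)  # separable => perfect

  expect_error(loocv_lda(d$x[c(1, 7, 8, 13, 14), ], d$g[c(1, 7, 8, 13, 14)]),
               "skin")
})

test_that("LOOCV is invariant to sample order and improves with duplication", {
  d <- make_gaussians(8, c(skin = -3, MCT = 3), sd = 1.5, p = 2, seed = 8)
  ids <- sprintf("s%02d", seq_len(16))
  p1 <- loocv_lda(d$x, d$g, sample_ids = ids)
  perm <- sample(16)
  p2 <- loocv_lda(d$x[perm, ], d$g[perm], sample_ids = ids[perm])
  expect_identical(p1$predicted_label[match(ids, p1$sample_id)],
                   p2$predicted_label[match(ids, p2$sample_id)])

  acc1 <- mean(p1$true_label == p1$predicted_label)
  dup <- loocv_lda(rbind(d$x, d$x), c(d$g, d$g))
  expect_gte(mean(dup$true_label == dup$predicted_label), acc1)
})

test_that("malignant merging counts cross-malignant confusion as correct", {
  p <- data.frame(sample_id = as.character(1:4),
                  true_label = c("MCT", "skin", "MCT", "MCT"),
                  predicted_label = c("STS", "skin", "MCT", "MCT"))
  class(p) <- c("prediction_table", "data.frame")
  m <- merge_malignant(p)
  expect_identical(m$true_label, c("malignant", "skin", "malignant", "malignant"))
  expect_identical(m$predicted_label[1], "malignant")
  expect_identical(m$predicted_label[2], "skin")
  expect_equal(confusion_metrics(m, "malignant")$sensitivity, 1.0)
})

test_that("confusion metrics reproduce hand-counted tables", {
  p <- data.frame(sample_id = as.character(1:10),
                  true_label = c(rep("lipoma", 4), rep("MCT", 6)),
                  predicted_label = c("lipoma", "lipoma", "lipoma", "MCT",
                                      rep("MCT", 6)))
  class(p) <- c("prediction_table", "data.frame")
  cm <- confusion_metrics(p, "lipoma")
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 1.0)
  expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, 10)
  perfect <- p; perfect$predicted_label <- perfect$true_label
  for (cl in c("lipoma", "MCT")) {
    cmp <- confusion_metrics(perfect, cl)
    expect_equal(c(cmp$sensitivity, cmp$specificity), c(1, 1))
  }
  expect_error(confusion_metrics(p, "STS"), "absent")
})

test_that("merged-malignant sensitivity dominates the per-class minimum", {
  set.seed(9)
  for (i in 1:20) {
    labs <- c("skin", "lipoma", "MCT", "STS")
    p <- data.frame(sample_id = as.character(1:40),
                    true_label = rep(labs, each = 10),
                    predicted_label = sample(labs, 40, replace = TRUE))
    class(p) <- c("prediction_table", "data.frame")
    m <- confusion_metrics(merge_malignant(p), "malignant")
    lo <- min(confusion_metrics(p, "MCT")$sensitivity,
              confusion_metrics(p, "STS")$sensitivity)
    expect_gte(m$sensitivity, lo)
    acc4 <- mean(p$true_label == p$predicted_label)
    accm <- mean(merge_malignant(p)$true_label ==
                   merge_malignant(p)$predicted_label)
    expect_gte(accm, acc4)
  }
})

test_that("Mann-Whitney U and exact p-values match the textbook case", {
  t <- mw_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(t$U, 0)
  expect_equal(t$p, 0.1)
  expect_true(t$exact)
  expect_identical(t$stars, "NS")

  same <- mw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_identical(same$stars, "NS")
  expect_error(mw_test(c(1, 2), c(3, 4, 5)), "untestable")
})

test_that("exact Mann-Whitney p-values agree with exhaustive enumeration", {
  set.seed(10)
  for (i in 1:30) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- runif(n1); y <- runif(n2) + runif(1, -0.5, 0.5)
    t <- mw_test(x, y)
    expect_equal(t$p, oracle_mw(x, y), tolerance = 1e-12)
  }
})

test_that("significance matrices label star thresholds over all class pairs", {
  set.seed(11)
  f <- data.frame(a = c(rnorm(10), rnorm(10, 10), rnorm(10, 20)),
                  b = rnorm(30))
  g <- rep(c("skin", "MCT", "STS"), each = 10)
  sig <- mann_whitney_matrix(f, g)
  expect_equal(nrow(sig), 2 * 3)
  a_rows <- sig[sig$feature == "a", ]
  expect_true(all(a_rows$signif == "***"))
  expect_true(all(sig$p_value >= 0 & sig$p_value <= 1))
  expect_error(mann_whitney_matrix(f[1:12, ], c(rep("skin", 10), "MCT", "MCT")),
               "untestable")
})

test_that("the pipeline report covers the three datasets deterministically", {
  cfg <- small_cfg(seed = 123)
  d <- generate_dataset(cfg, file.path(tempdir(), "pipe-ds"))
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  r1 <- suppressWarnings(run_pipeline(d$manifest, data_dir = d$dir, out_dir = out1))
  r2 <- suppressWarnings(run_pipeline(d$manifest, data_dir = d$dir, out_dir = out2))
  expect_named(r1$datasets, c("OCT", "Raman", "combined"))
  expect_identical(readBin(file.path(out1, "metrics.json"), "raw", 1e6),
                   readBin(file.path(out2, "metrics.json"), "raw", 1e6))
  expect_true(all(c("metrics.json", "features_OCT.csv", "predictions_combined.csv",
                    "significance_Raman.csv", "ld_scatter_combined.csv") %in%
                    list.files(out1)))
  expect_equal(nrow(r1$datasets$combined$features), 20L)
  expect_equal(ncol(r1$datasets$combined$predictions) - 3L, 3L)  # LD1..LD3

  oct_only <- suppressWarnings(run_pipeline(d$manifest, data_dir = d$dir,
                                            modalities = "Raman"))
  expect_named(oct_only$datasets, "Raman")
})

test_that("unreadable files drop samples gracefully until the abort threshold", {
  cfg <- small_cfg(seed = 124)
  d <- generate_dataset(cfg, file.path(tempdir(), "drop-ds"))
  m <- d$manifest
  # corrupt one sample's images: sample dropped, pipeline still runs
  bad <- m$sample_id == "skin_01" & m$modality == "OCT"
  for (pth in m$path[bad]) writeLines("not a tiff", file.path(d$dir, pth))
  w <- capture_warnings(r <- run_pipeline(m, data_dir = d$dir))
  expect_true(any(grepl("skipped", w)))
  expect_false("skin_01" %in% r$datasets$OCT$features$sample_id)
  # corrupting >20% of samples aborts
  worse <- m$modality == "OCT" & m$sample_id %in%
    unique(m$sample_id)[1:6]
  for (pth in m$path[worse]) writeLines("not a tiff", file.path(d$dir, pth))
  expect_error(suppressWarnings(run_pipeline(m, data_dir = d$dir)), "dropped")
})
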
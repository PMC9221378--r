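#' Linear discriminant tissue classifier
#'
#' Fits a classic Fisher linear discriminant model: features are z-scored
#' (center and scale estimated from the training data), the pooled
#' within-class covariance and the between-class scatter are formed, and the
#' discriminant axes are the leading generalized eigenvectors, at most
#' `n_classes - 1` of them. Classification uses the shared-covariance
#' Gaussian discriminant score with equal class priors; ties are broken
#' toward the earliest class in the canonical order (skin, lipoma, MCT,
#' STS). If the pooled covariance is singular (e.g. a feature is constant
#' within classes), a small ridge (`ridge_frac` times the mean diagonal) is
#' added and the fit is flagged `regularized`; with `regularize = FALSE` the
#' fit fails instead, naming the degenerate features.
#'
#' @param x Numeric matrix or data frame, rows = samples, named feature
#'   columns, no missing values.
#' @param grouping Class label per row (>= 2 classes, >= 2 samples each).
#' @param standardize Z-score features before fitting (default TRUE; OCT
#'   intensity features and Raman band ratios live on incommensurate scales).
#' @param regularize Allow the ridge fallback on a singular pooled
#'   covariance (default TRUE).
#' @param ridge_frac Ridge size as a fraction of the mean pooled variance.
#' @return An object of class `tissue_lda` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
tissue_lda <- function(x, grouping, standardize = TRUE, regularize = TRUE,
                       ridge_frac = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("tissue_lda: feature matrix contains missing values")
  grouping <- as_class_factor(grouping)
  if (length(grouping) != nrow(x))
    stop("tissue_lda: grouping length does not match rows of x")
  classes <- levels(grouping)
  K <- length(classes)
  if (K < 2) stop("tissue_lda: need at least 2 classes")
  nk <- table(grouping)
  if (any(nk < 2))
    stop("tissue_lda: class(es) with fewer than 2 samples: ",
         paste(names(nk)[nk < 2], collapse = ", "))
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  degenerate_scale <- scl < 1e-12
  scl[degenerate_scale] <- 1
  if (!standardize) { center <- rep(0, p); scl <- rep(1, p) }
  z <- sweep(sweep(x, 2, center), 2, scl, "/")

  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(z[grouping == cl, , drop = FALSE])))
  rownames(means) <- classes
  Sw <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (cl in classes) {
    zc <- sweep(z[grouping == cl, , drop = FALSE], 2, means[cl, ])
    Sw <- Sw + crossprod(zc)
  }
  Sw <- Sw / (n - K)  # pooled within-class covariance

  regularized <- FALSE
  ev <- eigen(Sw, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values, 1e-300)) {
    if (!regularize) {
      wv <- diag(Sw)
      bad <- colnames(x)[degenerate_scale | wv < 1e-10 * max(wv, 1e-300)]
      if (!length(bad)) bad <- "(collinear feature set)"
      stop("tissue_lda: singular within-class scatter; degenerate features: ",
           paste(bad, collapse = ", "))
    }
    lambda <- ridge_frac * mean(diag(Sw)) + 1e-12
    Sw <- Sw + diag(lambda, p)
    ev <- eigen(Sw, symmetric = TRUE)
    regularized <- TRUE
  }

  # Discriminant axes: eigenvectors of Sw^-1 B via the symmetric form
  # Sw^-1/2 B Sw^-1/2.
  isqrt <- ev$vectors %*% diag(1 / sqrt(ev$values), p) %*% t(ev$vectors)
  zbar <- colMeans(z)
  B <- matrix(0, p, p)
  for (cl in classes) {
    d <- means[cl, ] - zbar
    B <- B + as.integer(nk[[cl]]) * tcrossprod(d)
  }
  eb <- eigen(isqrt %*% B %*% isqrt, symmetric = TRUE)
  r <- min(K - 1L, p)
  scaling <- isqrt %*% eb$vectors[, seq_len(r), drop = FALSE]
  # Deterministic sign: largest-magnitude loading positive.
  for (j in seq_len(r)) {
    i <- which.max(abs(scaling[, j]))
    if (scaling[i, j] < 0) scaling[, j] <- -scaling[, j]
  }
  dimnames(scaling) <- list(colnames(x), paste0("LD", seq_len(r)))

  Sw_inv <- isqrt %*% isqrt
  fit <- structure(
    list(classes = classes, prior = rep(1 / K, K), center = center,
         scale = scl, means = means, Sw_inv = Sw_inv, scaling = scaling,
         eigenvalues = pmax(eb$values[seq_len(r)], 0),
         regularized = regularized, standardize = standardize,
         n = n, counts = as.vector(nk), grouping = grouping,
         call = match.call()),
    class = "tissue_lda")
  fit$x_ld <- z %*% scaling
  fit
}

#' Predict tissue classes and discriminant coordinates
#'
#' @param object A [tissue_lda()] fit.
#' @param newdata Matrix or data frame with the training feature columns.
#' @param ... Unused.
#' @return List with `class` (factor of predicted labels), `x` (matrix of
#'   discriminant coordinates, `n_classes - 1` columns), and `scores`
#'   (per-class linear discriminant scores).
#' @export
predict.tissue_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != length(object$center))
    stop("predict.tissue_lda: feature count mismatch")
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  # Equal-prior Gaussian score: z' Sw^-1 m_k - 0.5 m_k' Sw^-1 m_k
  A <- object$means %*% object$Sw_inv          # K x p
  scores <- z %*% t(A) - matrix(0.5 * rowSums(A * object$means),
                                nrow(z), length(object$classes), byrow = TRUE)
  colnames(scores) <- object$classes
  idx <- apply(scores, 1, which.max)           # first max = canonical tie-break
  list(class = factor(object$classes[idx], levels = object$classes),
       x = z %*% object$scaling, scores = scores)
}

#' @export
print.tissue_lda <- function(x, ...) {
  cat("Linear discriminant tissue classifier\n")
  cat("  classes:", paste(sprintf("%s (n=%d)", x$classes, x$counts),
                          collapse = ", "), "\n")
  cat(sprintf("  %d features, %d discriminant axes%s\n",
              length(x$center), ncol(x$scaling),
              if (x$regularized) " [ridge-regularized]" else ""))
  invisible(x)
}

#' @export
summary.tissue_lda <- function(object, ...) {
  tr <- object$eigenvalues / sum(object$eigenvalues)
  cat("Linear discriminant tissue classifier\n\n")
  cat("Proportion of between-class trace:\n")
  print(round(stats::setNames(tr, colnames(object$scaling)), 4))
  cat("\nGroup means (standardized feature space):\n")
  print(round(object$means, 3))
  invisible(object)
}

#' @export
coef.tissue_lda <- function(object, ...) object$scaling

#' Scatter of training samples on the leading discriminants
#'
#' @param x A [tissue_lda()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tissue_lda <- function(x, ...) {
  ld <- x$x_ld
  if (ncol(ld) == 1) ld <- cbind(ld, 0)
  cols <- seq_along(x$classes)[as.integer(x$grouping)]
  graphics::plot(ld[, 1], ld[, 2], col = cols, pch = 19,
                 xlab = "LD1", ylab = if (ncol(x$x_ld) > 1) "LD2" else "",
                 ...)
  graphics::legend("topright", legend = x$classes,
                   col = seq_along(x$classes), pch = 19, bty = "n")
  invisible(x)
}
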
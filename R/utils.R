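# Internal helpers shared across modules.

# Canonical class order; ties in prediction are broken toward the first match.
CANONICAL_CLASSES <- c("skin", "lipoma", "MCT", "STS")

#' Canonical tissue class labels
#'
#' Returns the four tissue classes in their canonical order: skin, lipoma,
#' MCT (mast cell tumor), STS (soft tissue sarcoma). This order also defines
#' deterministic tie-breaking in classification.
#'
#' @return Character vector of length 4.
#' @export
tissue_classes <- function() CANONICAL_CLASSES

# Coerce labels to a factor in canonical order where possible.
as_class_factor <- function(labels) {
  labels <- as.character(labels)
  lev <- if (all(labels %in% CANONICAL_CLASSES)) {
    CANONICAL_CLASSES[CANONICAL_CLASSES %in% labels]
  } else {
    unique(labels)
  }
  factor(labels, levels = lev)
}

# Summed-area table with a zero border, so that the sum of M[i:(i+w-1),
# j:(j+w-1)] is S[i+w, j+w] - S[i, j+w] - S[i+w, j] + S[i, j].
integral_image <- function(M) {
  S <- apply(M, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  rbind(0, cbind(0, S))
}

# All w x w window sums at stride 1; result is (h-w+1) x (w'-w+1).
window_sums <- function(M, w) {
  S <- integral_image(M)
  h <- nrow(M); wd <- ncol(M)
  ri <- 1:(h - w + 1); ci <- 1:(wd - w + 1)
  S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

# Windowed extreme (pmin/pmax) along rows; returns (nrow - w + 1) rows.
roll_extreme_rows <- function(M, w, f) {
  n <- nrow(M)
  out <- M[1:(n - w + 1), , drop = FALSE]
  if (w > 1L) for (k in 1:(w - 1L)) {
    out <- f(out, M[(1L + k):(n - w + 1L + k), , drop = FALSE])
  }
  out
}

# All w x w windowed minima / maxima at stride 1.
window_extreme <- function(M, w, f) {
  t(roll_extreme_rows(t(roll_extreme_rows(M, w, f)), w, f))
}

# Shift a logical matrix by one pixel with FALSE padding (4-neighbourhood).
shift_up    <- function(M) rbind(M[-1, , drop = FALSE], FALSE)
shift_down  <- function(M) rbind(FALSE, M[-nrow(M), , drop = FALSE])
shift_left  <- function(M) cbind(M[, -1, drop = FALSE], FALSE)
shift_right <- function(M) cbind(FALSE, M[, -ncol(M), drop = FALSE])

#' Significance star labels
#'
#' Maps p-values to the conventional star labels: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, `NS` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
signif_stars <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
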
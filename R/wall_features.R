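# Per-A-line features of the wall region R (lumen to 300 um below the AP
# contour): co-occurrence texture, gradient, profile-shape and layer
# statistics, plus min-max normalisation with training-set statistics.

#' Extract the per-column region R
#'
#' For every column of the sub-image, region R spans row 1 (the luminal
#' interface) down to `ceil(margin_um / pixel_size)` pixels below the AP
#' contour, clamped at the image bottom (clamped columns are flagged).
#' Guidewire columns keep their region but are flagged excluded.
#'
#' @param sub An `oct_subimage`.
#' @param contours Matching `oct_contours`.
#' @param margin_um Margin below the AP interface, micrometres.
#' @return An `oct_region`: integer `rows_end` per column (1-based,
#'   inclusive), `clamped` and `excluded` logical flags.
#' @export
extract_region <- function(sub, contours, margin_um = 300) {
  stopifnot(inherits(sub, "oct_subimage"), inherits(contours, "oct_contours"))
  if (contours$n_angles != sub$n_angles)
    stop("contours are not defined on the sub-image columns")
  margin_px <- as.integer(ceiling(margin_um / sub$pixel_size_axial))
  raw_end <- as.integer(round(contours$y3)) + 1L + margin_px
  rows_end <- pmin(sub$depth_px, raw_end)
  structure(list(rows_end = rows_end, clamped = raw_end > sub$depth_px,
                 excluded = sub$guidewire_mask, margin_px = margin_px),
            class = "oct_region")
}

#' Gray-level co-occurrence matrix with a 1-pixel depth offset
#'
#' Symmetric, normalised co-occurrence counts of vertically adjacent
#' pixel pairs (offset 1 along depth, within each column for matrix
#' input).
#'
#' @param q Quantised integer vector or matrix (levels `0..levels-1`).
#' @param levels Number of gray levels.
#' @return A `levels x levels` matrix summing to 1 (all zeros when no
#'   pair exists).
#' @export
glcm_cooccurrence <- function(q, levels = 16L) {
  q <- as.matrix(q)
  n <- nrow(q)
  M <- matrix(0, levels, levels)
  if (n >= 2) {
    i <- as.vector(q[-n, , drop = FALSE]) + 1L
    j <- as.vector(q[-1, , drop = FALSE]) + 1L
    counts <- tabulate((j - 1L) * levels + i, nbins = levels * levels)
    M <- matrix(counts, levels, levels)
    M <- M + t(M)
    M <- M / sum(M)
  }
  M
}

#' Haralick features of a co-occurrence matrix
#'
#' Contrast, homogeneity (inverse difference moment), correlation
#' (defined as 0 for zero marginal variance), entropy (natural log) and
#' energy (angular second moment).
#'
#' @param P Normalised co-occurrence matrix.
#' @return Named numeric vector of the five texture features.
#' @export
glcm_features <- function(P) {
  levels <- nrow(P)
  ii <- matrix(0:(levels - 1), levels, levels)
  jj <- t(ii)
  contrast <- sum(P * (ii - jj)^2)
  homogeneity <- sum(P / (1 + (ii - jj)^2))
  energy <- sum(P^2)
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mi <- sum((0:(levels - 1)) * pi_); mj <- sum((0:(levels - 1)) * pj_)
  vi <- sum(((0:(levels - 1)) - mi)^2 * pi_)
  vj <- sum(((0:(levels - 1)) - mj)^2 * pj_)
  correlation <- if (vi <= 0 || vj <= 0) 0 else
    sum((ii - mi) * (jj - mj) * P) / sqrt(vi * vj)
  c(contrast = contrast, homogeneity = homogeneity, correlation = correlation,
    entropy = entropy, energy = energy)
}

#' Monotony index of an intensity profile
#'
#' Median absolute index displacement needed to sort the profile in
#' descending order (stable sort; the median of an even count is the mean
#' of the middle two). Zero for an already monotone decreasing profile;
#' invariant under strictly monotone intensity rescaling.
#'
#' @param v Numeric vector.
#' @return The monotony index.
#' @export
monotony_index <- function(v) {
  n <- length(v)
  if (n < 2) return(0)
  ord <- order(-v)            # stable: ties keep original order
  iprime <- integer(n)
  iprime[ord] <- seq_len(n)
  median(abs(seq_len(n) - iprime))
}

mse_linear_fit <- function(v) {
  n <- length(v)
  if (n < 3) return(0)
  x <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, x), v)
  mean(fit$residuals^2)
}

#' Compute the 17 per-column features
#'
#' Texture features (contrast, homogeneity, correlation, entropy, energy)
#' come from a symmetric, normalised 16-level gray co-occurrence matrix
#' of the column's region-R profile with a 1-pixel offset along depth.
#' Gradient features are the derivative-of-Gaussian response at the
#' flattened luminal interface (row 1), at the IM depth and at the MA
#' depth. Shape features are the mean squared residual of a degree-1
#' least-squares fit to the profile, the monotony index and the sum of
#' negative gradient values over R. Layer statistics are median
#' intensities between consecutive interfaces (interface rows inclusive)
#' and the LI-to-interface distances in micrometres.
#'
#' @param sub An `oct_subimage`.
#' @param contours Matching `oct_contours`.
#' @param grad Gradient matrix of `sub` (defaults to recomputing with
#'   `sigma_um`).
#' @param region An `oct_region` (defaults to [extract_region()] with
#'   `margin_um`).
#' @param margin_um,sigma_um Used for the defaults above.
#' @return A numeric `n_angles x 17` matrix with canonical column names
#'   (see [feature_names()]) and attributes `excluded` / `clamped`.
#' @export
compute_features <- function(sub, contours, grad = NULL, region = NULL,
                             margin_um = 300, sigma_um = 30) {
  if (is.null(grad)) grad <- gradient_image(sub, sigma_um)
  if (is.null(region)) region <- extract_region(sub, contours, margin_um)
  W <- sub$n_angles
  px <- sub$pixel_size_axial
  F <- matrix(NA_real_, W, 17,
              dimnames = list(NULL, .octwall_canonical_features))
  y1 <- as.integer(round(contours$y1))
  y2 <- as.integer(round(contours$y2))
  y3 <- as.integer(round(contours$y3))
  for (c in seq_len(W)) {
    rows <- seq_len(region$rows_end[c])
    prof <- sub$I[rows, c]
    g <- grad[rows, c]
    q <- pmin(as.integer(floor(prof * 16)), 15L)
    gl <- glcm_features(glcm_cooccurrence(q))
    r1 <- min(y1[c] + 1L, length(prof))
    r2 <- min(y2[c] + 1L, length(prof))
    r3 <- min(y3[c] + 1L, length(prof))
    F[c, ] <- c(
      gl["contrast"],
      mse_linear_fit(prof),
      gl["homogeneity"],
      grad[min(y2[c] + 1L, nrow(grad)), c],
      gl["correlation"],
      grad[min(y1[c] + 1L, nrow(grad)), c],
      grad[1, c],
      monotony_index(prof),
      sum(pmin(g, 0)),
      gl["entropy"],
      median(prof[r1:r2]),
      gl["energy"],
      median(prof[r2:r3]),
      median(prof[1:r1]),
      y1[c] * px,
      y3[c] * px,
      y2[c] * px)
  }
  attr(F, "excluded") <- region$excluded
  attr(F, "clamped") <- region$clamped
  F
}

#' Min-max feature normalisation with training statistics
#'
#' In training mode (`stats = NULL`) per-feature minima and maxima are
#' computed from the data; in inference mode the supplied training
#' statistics are reused and out-of-range values are clipped to
#' `[0, 1]`. A zero-range feature maps to 0.5 everywhere, with a warning
#' in training mode.
#'
#' @param F Feature matrix (columns = features).
#' @param stats Optional list with numeric vectors `min` and `max`.
#' @return List with the normalised `features` matrix and the `stats`
#'   used.
#' @export
normalize_features <- function(F, stats = NULL) {
  F <- as.matrix(F)
  if (is.null(stats)) {
    stats <- list(min = apply(F, 2, min), max = apply(F, 2, max))
    if (any(stats$max - stats$min <= 0))
      warning("constant feature(s) in training data mapped to 0.5")
  }
  rng <- stats$max - stats$min
  out <- F
  for (k in seq_len(ncol(F))) {
    if (rng[k] <= 0) out[, k] <- 0.5
    else out[, k] <- pmin(1, pmax(0, (F[, k] - stats$min[k]) / rng[k]))
  }
  attr(out, "excluded") <- attr(F, "excluded")
  attr(out, "clamped") <- attr(F, "clamped")
  list(features = out, stats = stats)
}
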
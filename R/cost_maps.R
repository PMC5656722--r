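# Derivative-of-Gaussian edge costs: gradient image, triple replication
# and the complementary positive cost pair driving the front propagation.

# sampled first-derivative-of-Gaussian kernel, truncated at +/- 4 sigma,
# sum-to-zero corrected, scaled so a unit upward step responds with 1
dog_kernel <- function(sigma_px) {
  L <- max(1L, ceiling(4 * sigma_px))
  t <- (-L):L
  k <- -t * exp(-t^2 / (2 * sigma_px^2))
  k <- k - mean(k)
  s <- sum(k[t < 0])   # response of the convolution to a unit rising step
  k / s
}

# column-wise convolution with reflect padding along depth
gradient_image_matrix <- function(I, sigma_um, pixel_size_axial) {
  sigma_px <- sigma_um / pixel_size_axial
  if (sigma_px < 0.5) stop("sigma below resolution")
  k <- dog_kernel(sigma_px)
  L <- (length(k) - 1L) / 2L
  n <- nrow(I)
  pad_top <- pmin(n, rev(seq_len(L)) + 1L)    # reflect: rows 2,3,... mirrored
  pad_bot <- pmax(1L, n - seq_len(L))
  idx <- c(pad_top, seq_len(n), pad_bot)
  P <- I[idx, , drop = FALSE]
  F <- stats::filter(P, filter = k, method = "convolution", sides = 2)
  out <- as.matrix(F)[L + seq_len(n), , drop = FALSE]
  matrix(out, nrow = n, ncol = ncol(I))
}

#' Column-wise derivative-of-Gaussian gradient image
#'
#' Convolves every column (A-line) of the sub-image with the first
#' derivative of a Gaussian of scale `sigma_um`. The sign convention is
#' positive on dark-to-bright transitions with increasing depth, so the
#' media-adventitia interface responds positively and the intima-media /
#' adventitia-periadventitia interfaces negatively. The kernel is scaled
#' so an ideal unit step responds with magnitude 1.
#'
#' @param sub An `oct_subimage` (or plain matrix together with
#'   `pixel_size_axial`).
#' @param sigma_um Gaussian scale in micrometres.
#' @param pixel_size_axial Only needed when `sub` is a plain matrix.
#' @return Gradient matrix of the same shape as the input.
#' @export
gradient_image <- function(sub, sigma_um = 30, pixel_size_axial = NULL) {
  if (inherits(sub, "oct_subimage")) {
    gradient_image_matrix(sub$I, sigma_um, sub$pixel_size_axial)
  } else {
    if (is.null(pixel_size_axial))
      stop("pixel_size_axial required for a plain matrix")
    gradient_image_matrix(as.matrix(sub), sigma_um, pixel_size_axial)
  }
}

#' Replicate the gradient image three times horizontally
#'
#' Horizontal concatenation `[I_G, I_G, I_G]`; retaining the central third
#' of a path over the replicated width yields approximately closed
#' contours in the Cartesian plane.
#'
#' @param I_G Gradient matrix.
#' @return Matrix of width `3 * ncol(I_G)`.
#' @export
replicate_gradient <- function(I_G) {
  I_G <- as.matrix(I_G)
  cbind(I_G, I_G, I_G)
}

normalize_cost <- function(M) {
  rng <- range(M)
  if (diff(rng) < .Machine$double.eps * 10) {
    warning("degenerate frame: constant gradient, costs set to 0.5")
    return(matrix(0.5, nrow(M), ncol(M)))
  }
  (M - rng[1]) / (rng[2] - rng[1])
}

#' Build the complementary cost pair
#'
#' Min-max normalisation of `+I''' _G` and `-I'''_G` to `[0, 1]` over one
#' shared global range, so `C_plus + C_minus == 1` elementwise. Minima of
#' `C_plus` sit on the strongest negative gradients (IM / AP candidates),
#' minima of `C_minus` on the strongest positive gradients (MA
#' candidates). A constant input degenerates to both maps uniformly 0.5,
#' with a warning.
#'
#' @param I_G_rep Replicated gradient matrix.
#' @return List with matrices `C_plus` and `C_minus`.
#' @export
build_costs <- function(I_G_rep) {
  M <- as.matrix(I_G_rep)
  rng <- range(M)
  if (diff(rng) < .Machine$double.eps * 10) {
    warning("degenerate frame: constant gradient, costs set to 0.5")
    h <- matrix(0.5, nrow(M), ncol(M))
    return(list(C_plus = h, C_minus = h))
  }
  Cp <- (M - rng[1]) / (rng[2] - rng[1])
  list(C_plus = Cp, C_minus = 1 - Cp)
}

#' Compute all cost maps for a sub-image
#'
#' Composes [gradient_image()], [replicate_gradient()] and
#' [build_costs()]. Guidewire-shadowed columns carry no wall signal, so
#' their costs (in all three replicas) are replaced by the row-wise mean
#' cost of the unmasked columns, letting the optimal path interpolate
#' smoothly through the shadow.
#'
#' @param sub An `oct_subimage`.
#' @param sigma_um Gaussian derivative scale in micrometres.
#' @return An `oct_costmaps` object with `I_G`, `I_G_rep`, `C_plus`,
#'   `C_minus`, `sigma_um` and `sigma_px`.
#' @export
cost_maps <- function(sub, sigma_um = 30) {
  stopifnot(inherits(sub, "oct_subimage"))
  I_G <- gradient_image(sub, sigma_um)
  I_G_rep <- replicate_gradient(I_G)
  cm <- build_costs(I_G_rep)
  W <- sub$n_angles
  mask <- sub$guidewire_mask
  if (any(mask) && !all(mask)) {
    rep_mask <- rep(mask, 3)
    fill_p <- rowMeans(cm$C_plus[, !rep_mask, drop = FALSE])
    fill_m <- rowMeans(cm$C_minus[, !rep_mask, drop = FALSE])
    cm$C_plus[, rep_mask] <- fill_p
    cm$C_minus[, rep_mask] <- fill_m
  }
  structure(list(I_G = I_G, I_G_rep = I_G_rep, C_plus = cm$C_plus,
                 C_minus = cm$C_minus, sigma_um = sigma_um,
                 sigma_px = sigma_um / sub$pixel_size_axial,
                 width = W), class = "oct_costmaps")
}
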
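# Lumen-referenced polar geometry: frames, lumen extraction, guidewire
# shadow detection, sub-image construction and Cartesian back-mapping.

#' OCT frame container
#'
#' Wraps a single cross-sectional frame. For polar frames rows are depth
#' (radius, one pixel per `pixel_size_axial` micrometres, row `i` at radius
#' `i` pixels from the catheter axis) and columns are A-lines spanning
#' 360 degrees, column `j` at angle `(j-1) * 2*pi/ncol`. Intensities are
#' normalised to `[0, 1]` on construction.
#'
#' @param pixels Numeric intensity matrix.
#' @param geometry `"polar"` or `"cartesian"`.
#' @param pixel_size_axial Axial pixel size in micrometres (> 0).
#' @param frame_index Non-negative integer frame index.
#' @return An object of class `oct_frame`.
#' @export
oct_frame <- function(pixels, geometry = c("polar", "cartesian"),
                      pixel_size_axial, frame_index = 0L) {
  geometry <- match.arg(geometry)
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("frame intensities must be finite")
  if (pixel_size_axial <= 0) stop("pixel_size_axial must be > 0")
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / mx
  if (min(pixels) < 0) stop("frame intensities must be non-negative")
  structure(list(pixels = pixels, geometry = geometry,
                 pixel_size_axial = pixel_size_axial,
                 frame_index = as.integer(frame_index)),
            class = "oct_frame")
}

#' @export
print.oct_frame <- function(x, ...) {
  cat(sprintf("<oct_frame #%d> %s, %d x %d px, %.2f um/px\n",
              x$frame_index, x$geometry, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_axial))
  invisible(x)
}

#' Segment the lumen-intima interface
#'
#' Single-contour stand-in for a dedicated lumen segmentation method: the
#' lumen boundary is the minimal-cost closed path on the negated axial
#' gradient (the lumen-to-tissue transition is a rising edge, so its cost
#' minimum sits on strongly positive gradients). Closure uses the same
#' triple-replication trick as the multi-layer scheme.
#'
#' @param frame A polar-geometry [oct_frame].
#' @param sigma_um Gaussian derivative scale in micrometres.
#' @param kappa Smoothness coefficient.
#' @param N Half-neighbourhood of reachable row displacements per column.
#' @param intensity_floor Frames whose maximum intensity or dynamic range
#'   falls below this value raise a "no lumen detected" error.
#' @return An `oct_lumen` object: `depth_per_aline` gives the lumen
#'   boundary row per native A-line.
#' @export
segment_lumen <- function(frame, sigma_um = 30, kappa = 0.1, N = 3L,
                          intensity_floor = 0.05) {
  stopifnot(inherits(frame, "oct_frame"))
  if (frame$geometry != "polar") stop("segment_lumen requires a polar frame")
  I <- frame$pixels
  if (max(I) < intensity_floor || diff(range(I)) < intensity_floor)
    stop("no lumen detected")
  g <- gradient_image_matrix(I, sigma_um, frame$pixel_size_axial)
  C <- normalize_cost(-g)  # rising edges become low cost
  W <- ncol(C)
  Crep <- cbind(C, C, C)
  full <- rep(-1L, ncol(Crep))
  res <- .band_dp(Crep, integer(ncol(Crep)), -1L, full, 1.0, kappa,
                  as.integer(N))
  path <- res$path + 1L          # row indices, 1-based
  depth <- path[(W + 1):(2 * W)] # central replica
  structure(list(depth_per_aline = as.numeric(depth), n_alines = W,
                 cost = res$cost), class = "oct_lumen")
}

#' Mean below-lumen intensity profile of a pullback
#'
#' Averages, per native A-line, the intensity over a fixed band of rows
#' below the lumen boundary across all frames; the guidewire shadow shows
#' up as a contiguous dark dip in this profile.
#'
#' @param frames List of polar [oct_frame]s.
#' @param lumens List of matching `oct_lumen` contours.
#' @param band_px Number of rows below the lumen to average.
#' @return Numeric vector, one mean intensity per A-line.
#' @export
pullback_profile <- function(frames, lumens, band_px = 60L) {
  stopifnot(length(frames) == length(lumens), length(frames) >= 1)
  W <- lumens[[1]]$n_alines
  acc <- numeric(W); n <- 0L
  for (k in seq_along(frames)) {
    I <- frames[[k]]$pixels
    lum <- lumens[[k]]$depth_per_aline
    prof <- vapply(seq_len(W), function(j) {
      r0 <- min(nrow(I), floor(lum[j]) + 1L)
      r1 <- min(nrow(I), r0 + band_px - 1L)
      mean(I[r0:r1, j])
    }, numeric(1))
    acc <- acc + prof; n <- n + 1L
  }
  acc / n
}

#' Detect the guidewire shadow band
#'
#' Flags the single contiguous (circular) run of A-lines whose
#' pullback-averaged below-lumen intensity drops under
#' `threshold * median(profile)`. Runs shorter than `min_run` columns are
#' ignored; among several candidate runs the one with the darkest mean is
#' kept, ties broken by lower start index. Absence of a dark band yields
#' an all-`FALSE` mask.
#'
#' @param frame A polar [oct_frame] (used for validation only).
#' @param lumen Matching `oct_lumen`.
#' @param pullback_profile Mean intensity per A-line over the pullback.
#' @param threshold Fraction of the median profile intensity below which a
#'   column counts as dark.
#' @param min_run Minimum run length in columns.
#' @return Logical mask per A-line (`TRUE` = shadowed).
#' @export
detect_guidewire <- function(frame, lumen, pullback_profile,
                             threshold = 0.5, min_run = 3L) {
  W <- length(pullback_profile)
  if (!is.null(lumen) && lumen$n_alines != W)
    stop("profile length must equal the A-line count")
  dark <- pullback_profile < threshold * median(pullback_profile)
  runs <- circular_runs(dark)
  runs <- runs[vapply(runs, length, integer(1)) >= min_run]
  mask <- rep(FALSE, W)
  if (length(runs) == 0) return(mask)
  means <- vapply(runs, function(r) mean(pullback_profile[r]), numeric(1))
  starts <- vapply(runs, function(r) r[1], integer(1))
  best <- order(means, starts)[1]
  mask[runs[[best]]] <- TRUE
  mask
}

# contiguous TRUE runs on a circular vector, as lists of indices
circular_runs <- function(x) {
  n <- length(x)
  if (!any(x)) return(list())
  if (all(x)) return(list(seq_len(n)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(which(r$values), function(i) starts[i]:ends[i])
  # merge wrap-around run
  if (x[1] && x[n] && length(runs) > 1) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    runs[[1]] <- c(last, first)
    runs[[length(runs)]] <- NULL
  }
  runs
}

# Bilinear intensity sampler at Cartesian points (px units, origin at the
# catheter axis for polar frames, at the image centre for Cartesian ones).
# Rows are edge-padded beyond the image; returns intensity and a flag for
# points beyond the outer image bound.
sample_intensity <- function(frame, x, y) {
  I <- frame$pixels
  if (frame$geometry == "polar") {
    nr <- nrow(I); nc <- ncol(I)
    rho <- sqrt(x^2 + y^2)
    ang <- atan2(y, x) %% (2 * pi)
    col <- ang / (2 * pi) * nc           # 0-based fractional column
    row <- rho                            # row i at radius i -> 0-based i-1
    out_of_range <- row > nr
    r0 <- pmax(1, pmin(nr, floor(row)))
    r1 <- pmax(1, pmin(nr, r0 + 1))
    fr <- pmax(0, pmin(1, row - r0))
    c0 <- floor(col); fc <- col - c0
    c0 <- (c0 %% nc) + 1L
    c1 <- (c0 %% nc) + 1L
    v <- (1 - fr) * ((1 - fc) * I[cbind(r0, c0)] + fc * I[cbind(r0, c1)]) +
      fr * ((1 - fc) * I[cbind(r1, c0)] + fc * I[cbind(r1, c1)])
    list(value = v, clamped = out_of_range)
  } else {
    nr <- nrow(I); nc <- ncol(I)
    cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
    px <- x + cx; py <- cy - y
    out_of_range <- px < 1 | px > nc | py < 1 | py > nr
    px <- pmax(1, pmin(nc, px)); py <- pmax(1, pmin(nr, py))
    x0 <- pmax(1, pmin(nc, floor(px))); x1 <- pmax(1, pmin(nc, x0 + 1))
    y0 <- pmax(1, pmin(nr, floor(py))); y1 <- pmax(1, pmin(nr, y0 + 1))
    fx <- pmax(0, pmin(1, px - x0)); fy <- pmax(0, pmin(1, py - y0))
    v <- (1 - fy) * ((1 - fx) * I[cbind(y0, x0)] + fx * I[cbind(y0, x1)]) +
      fy * ((1 - fx) * I[cbind(y1, x0)] + fx * I[cbind(y1, x1)])
    list(value = v, clamped = out_of_range)
  }
}

#' Build the lumen-flattened polar sub-image
#'
#' Casts `n_angles` equiangular rays from the lumen centroid, starting at
#' the lumen boundary, and stacks the bilinearly resampled radial
#' intensity profiles as columns. Column `c` (0-based) covers the
#' half-open arc `[c, c+1) * 360/n_angles` degrees with column 0 on the
#' image +x axis; row 1 sits on the luminal interface and rows advance by
#' one axial pixel. The sampled depth always covers at least `depth_um`.
#'
#' @param frame Source [oct_frame].
#' @param lumen `oct_lumen` for the frame.
#' @param gw_mask Optional native-resolution guidewire mask (logical per
#'   A-line); resampled to the sub-image columns by angular nearest
#'   neighbour.
#' @param n_angles Number of angular steps (>= 8).
#' @param depth_um Depth below the lumen to sample, in micrometres.
#' @return An `oct_subimage`: intensity matrix `I` (`depth_px x n_angles`),
#'   guidewire mask, per-column quality flag (`TRUE` where sampling was
#'   clamped at the image edge) and the lumen reference used for
#'   back-mapping.
#' @export
build_subimage <- function(frame, lumen, gw_mask = NULL, n_angles = 100L,
                           depth_um = 1000) {
  stopifnot(inherits(frame, "oct_frame"))
  if (n_angles < 8) stop("n_angles must be >= 8")
  px <- frame$pixel_size_axial
  depth_px <- as.integer(ceiling(depth_um / px))
  W <- lumen$n_alines
  phi <- (seq_len(W) - 1) * 2 * pi / W
  lx <- lumen$depth_per_aline * cos(phi)
  ly <- lumen$depth_per_aline * sin(phi)
  ctr <- polygon_centroid(lx, ly)
  # star-shaped radius of the lumen polygon around its centroid
  psi <- atan2(ly - ctr[2], lx - ctr[1]) %% (2 * pi)
  rho <- sqrt((lx - ctr[1])^2 + (ly - ctr[2])^2)
  o <- order(psi)
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  r_start <- circular_interp(psi[o], rho[o], theta, period = 2 * pi)

  I <- matrix(0, nrow = depth_px, ncol = n_angles)
  clamped <- rep(FALSE, n_angles)
  depths <- seq_len(depth_px) - 1L
  for (c in seq_len(n_angles)) {
    r <- r_start[c] + depths
    s <- sample_intensity(frame, ctr[1] + r * cos(theta[c]),
                          ctr[2] + r * sin(theta[c]))
    I[, c] <- s$value
    clamped[c] <- any(s$clamped)
  }
  mask <- rep(FALSE, n_angles)
  if (!is.null(gw_mask)) {
    j <- (round(theta / (2 * pi) * W) %% W) + 1L
    mask <- gw_mask[j]
  }
  structure(list(I = I, n_angles = as.integer(n_angles),
                 depth_px = depth_px, pixel_size_axial = px,
                 guidewire_mask = mask, quality_clamped = clamped,
                 lumen_ref = list(center = ctr, r_start = r_start,
                                  theta = theta, lumen = lumen),
                 frame_index = frame$frame_index),
            class = "oct_subimage")
}

#' @export
print.oct_subimage <- function(x, ...) {
  cat(sprintf("<oct_subimage #%d> %d x %d (depth x angles), %.2f um/px, %d masked columns\n",
              x$frame_index, x$depth_px, x$n_angles, x$pixel_size_axial,
              sum(x$guidewire_mask)))
  invisible(x)
}

polygon_centroid <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# periodic linear interpolation of (xs, ys) at points xout
circular_interp <- function(xs, ys, xout, period) {
  xs2 <- c(xs, xs[1] + period)
  ys2 <- c(ys, ys[1])
  xout2 <- ifelse(xout < xs[1], xout + period, xout)
  stats::approx(xs2, ys2, xout = xout2, rule = 2)$y
}

#' Map layer contours back to Cartesian frame coordinates
#'
#' Point `k` of interface `n` is placed at
#' `center + (r_start(theta_k) + y_n(k)) * (cos theta_k, sin theta_k)`
#' in frame pixel units (origin at the catheter axis for polar frames).
#' Each polyline is closed by repeating its first vertex.
#'
#' @param contours `oct_contours` defined on `sub`'s columns.
#' @param sub The `oct_subimage` the contours were extracted from.
#' @return Named list `IM`, `MA`, `AP` of closed `(n_angles+1) x 2`
#'   coordinate matrices.
#' @export
map_contours_to_cartesian <- function(contours, sub) {
  stopifnot(inherits(contours, "oct_contours"),
            inherits(sub, "oct_subimage"))
  if (length(contours$y1) != sub$n_angles)
    stop("contours are not defined on the sub-image columns")
  ref <- sub$lumen_ref
  one <- function(y) {
    r <- ref$r_start + y
    m <- cbind(x = ref$center[1] + r * cos(ref$theta),
               y = ref$center[2] + r * sin(ref$theta))
    rbind(m, m[1, , drop = FALSE])
  }
  list(IM = one(contours$y1), MA = one(contours$y2), AP = one(contours$y3))
}
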
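# 4D front propagation: simultaneous extraction of the IM, MA and AP
# interfaces as one globally optimal multi-parametric path.

#' Parameters of the multi-layer dynamic program
#'
#' Defaults reproduce the operating point used throughout the package:
#' interface weights `omega = (0.2, 1, 1)`, smoothness `kappa = 0.1`,
#' `2N + 1 = 7` reachable neighbours, minimal inter-contour gap 45 um.
#' The displacement penalty is symmetric, `(1 + kappa * |dy|)`, so upward
#' and downward moves are penalised alike.
#'
#' @param omega Three non-negative interface weights (IM, MA, AP).
#' @param kappa Non-negative smoothness coefficient.
#' @param N Half-neighbourhood; reachable per-column displacements are
#'   `-N..N`.
#' @param gap_um Minimal gap between consecutive interfaces, micrometres.
#' @param gap_px Gap in pixels; when `NULL` it is resolved at use time as
#'   `max(1, round(gap_um / pixel_size_axial))`.
#' @param max_dp_depth Depth cap for the dense 4D state space. Deeper
#'   sub-images are block-min pooled along depth by the smallest integer
#'   factor bringing the DP depth under the cap, and each interface is
#'   then refined by a full-resolution banded 1D pass (see
#'   [segment_layers()]).
#' @return A `dp_params` list.
#' @export
dp_params <- function(omega = c(0.2, 1, 1), kappa = 0.1, N = 3L,
                      gap_um = 45, gap_px = NULL, max_dp_depth = 48L) {
  stopifnot(length(omega) == 3, all(omega >= 0), kappa >= 0, N >= 1)
  if (!is.null(gap_px)) stopifnot(gap_px >= 1)
  structure(list(omega = as.numeric(omega), kappa = kappa, N = as.integer(N),
                 gap_um = gap_um, gap_px = gap_px,
                 max_dp_depth = as.integer(max_dp_depth)),
            class = "dp_params")
}

resolve_gap_px <- function(params, pixel_size_axial) {
  if (!is.null(params$gap_px)) return(as.integer(params$gap_px))
  max(1L, as.integer(round(params$gap_um / pixel_size_axial)))
}

as_cost_pair <- function(costs) {
  if (inherits(costs, "oct_costmaps"))
    list(C_plus = costs$C_plus, C_minus = costs$C_minus)
  else if (is.list(costs) && !is.null(costs$C_plus))
    list(C_plus = as.matrix(costs$C_plus), C_minus = as.matrix(costs$C_minus))
  else stop("costs must be an oct_costmaps or a list(C_plus, C_minus)")
}

#' Front propagation of the 4D cumulative cost
#'
#' Builds the cumulative cost over states `(x, y1, y2, y3)` restricted to
#' `y1 + gap <= y2 <= y3 - gap`, column by column. The first column is
#' initialised to zero; each later state takes the minimum over the
#' `(2N+1)^3` predecessor displacements of the predecessor value plus the
#' three weighted transition terms
#' `omega_n * (1 + kappa * |dy_n|) * (C(x, y_n) + C(x - 1, y_n + dy_n))`,
#' with `C_plus` for interfaces 1 and 3 and `C_minus` for interface 2.
#'
#' @param costs An `oct_costmaps` object or a `list(C_plus, C_minus)` of
#'   equally shaped matrices (depth x width).
#' @param params [dp_params()].
#' @param gap_px Gap in pixels; required when `costs` carries no pixel
#'   size and `params$gap_px` is `NULL`.
#' @return An `oct_cumcost` object holding the final-column value cube
#'   and the predecessor record for backtracking.
#' @export
propagate_front <- function(costs, params = dp_params(), gap_px = NULL) {
  cp <- as_cost_pair(costs)
  if (is.null(gap_px)) gap_px <- params$gap_px
  if (is.null(gap_px)) stop("gap_px could not be resolved")
  d <- nrow(cp$C_plus)
  if (d < 2 * gap_px + 1) stop("depth too small for gap constraint")
  res <- .ml_dp_forward(cp$C_plus, cp$C_minus, params$omega, params$kappa,
                        params$N, as.integer(gap_px))
  structure(c(res, list(params = params)), class = "oct_cumcost")
}

#' Backtrack the globally optimal multi-parametric path
#'
#' Starts from the admissible final-column state of minimal cumulative
#' cost (ties resolved to the lexicographically smallest `(y1, y2, y3)`)
#' and follows the stored predecessors, which were recorded with a
#' smallest-`(dy1, dy2, dy3)` tie rule, back to the first column.
#'
#' @param cum An `oct_cumcost` from [propagate_front()].
#' @return List with `path` (3 x width matrix of 0-based depths, rows =
#'   IM, MA, AP) and the optimal total `cost`.
#' @export
backtrack <- function(cum) {
  stopifnot(inherits(cum, "oct_cumcost"))
  .ml_dp_backtrack(cum$final, cum$a1, cum$a2, cum$a3, cum$depth, cum$width,
                   cum$gap)
}

#' Keep the central replica of a path over the replicated width
#'
#' The path over `3W` columns is cut into three equal parts and the
#' central one is kept, re-indexed to columns `1..W`; thanks to the
#' replication trick this central part is approximately closed. A wrap
#' step larger than `N` between the last and first retained columns
#' triggers a warning (it indicates a degenerate frame, not expected in
#' normal operation).
#'
#' @param path 3 x (3W) matrix of 0-based depths.
#' @param W Width of the original sub-image.
#' @param N Half-neighbourhood used for the closure check (`NULL` skips
#'   the check).
#' @param pixel_size_axial,n_angles Metadata stored on the result.
#' @return An `oct_contours` object with per-column depths `y1`, `y2`,
#'   `y3` (pixels below the lumen, 0-based).
#' @export
truncate_central <- function(path, W, N = NULL, pixel_size_axial = NA_real_,
                             n_angles = W) {
  if (ncol(path) != 3 * W) stop("path length must equal 3 * W")
  cols <- (W + 1):(2 * W)
  y <- path[, cols, drop = FALSE]
  if (!is.null(N)) {
    wrap <- abs(y[, 1] - y[, W])
    if (any(wrap > N)) warning("closure violated")
  }
  structure(list(y1 = as.numeric(y[1, ]), y2 = as.numeric(y[2, ]),
                 y3 = as.numeric(y[3, ]), n_angles = as.integer(n_angles),
                 pixel_size_axial = pixel_size_axial),
            class = "oct_contours")
}

#' @export
print.oct_contours <- function(x, ...) {
  cat(sprintf("<oct_contours> %d columns; mean depths IM %.1f, MA %.1f, AP %.1f px\n",
              x$n_angles, mean(x$y1), mean(x$y2), mean(x$y3)))
  invisible(x)
}

#' Plot layer contours over the sub-image
#'
#' @param x An `oct_contours`.
#' @param sub Optional `oct_subimage` to draw underneath.
#' @param ... Passed to [graphics::image()].
#' @export
plot.oct_contours <- function(x, sub = NULL, ...) {
  W <- x$n_angles
  if (!is.null(sub)) {
    image(x = seq_len(W), y = seq_len(sub$depth_px), z = t(sub$I[rev(seq_len(sub$depth_px)), ]),
          col = gray(seq(0, 1, length.out = 128)), xlab = "angular step",
          ylab = "depth (px)", ...)
    d <- sub$depth_px
    lines(seq_len(W), d - x$y1, col = "yellow")
    lines(seq_len(W), d - x$y2, col = "green")
    lines(seq_len(W), d - x$y3, col = "magenta")
  } else {
    plot(seq_len(W), x$y1, type = "l", col = "yellow", ylim = rev(range(c(x$y1, x$y3))),
         xlab = "angular step", ylab = "depth below lumen (px)")
    lines(seq_len(W), x$y2, col = "green")
    lines(seq_len(W), x$y3, col = "magenta")
  }
  invisible(x)
}

#' Recompute the cost of a multi-parametric path
#'
#' Forward evaluation of the transition sum along an explicit path;
#' independent check that backtracking attains the propagated minimum.
#'
#' @param costs `oct_costmaps` or `list(C_plus, C_minus)`.
#' @param path 3 x width matrix of 0-based depths.
#' @param params [dp_params()].
#' @return Total path cost.
#' @export
path_cost <- function(costs, path, params = dp_params()) {
  cp <- as_cost_pair(costs)
  Cp <- cp$C_plus; Cm <- cp$C_minus
  w <- ncol(path)
  if (w < 2) return(0)
  total <- 0
  om <- params$omega; kap <- params$kappa
  Cs <- list(Cp, Cm, Cp)
  for (x in 2:w) {
    for (n in 1:3) {
      yn <- path[n, x]; yp <- path[n, x - 1]
      dy <- yp - yn
      C <- Cs[[n]]
      total <- total + om[n] * (1 + kap * abs(dy)) *
        (C[yn + 1, x] + C[yp + 1, x - 1])
    }
  }
  total
}

#' Exhaustive-enumeration oracle for small instances
#'
#' Enumerates every admissible non-crossing triple path with per-step
#' displacements bounded by `N` and returns the exact global minimum,
#' with the same tie rule as [backtrack()]. Intended as an independent
#' correctness reference on tiny cost maps; aborts with
#' `"oracle bound exceeded"` once the number of path extensions passes
#' `bound`.
#'
#' @param costs `oct_costmaps` or `list(C_plus, C_minus)`.
#' @param params [dp_params()].
#' @param gap_px Gap in pixels.
#' @param bound Maximum number of path extensions.
#' @return List with `path` (3 x width, 0-based), `cost` and the number
#'   of `extensions` explored.
#' @export
brute_force_oracle <- function(costs, params = dp_params(), gap_px = 1L,
                               bound = 1e7) {
  cp <- as_cost_pair(costs)
  .ml_dp_oracle(cp$C_plus, cp$C_minus, params$omega, params$kappa,
                params$N, as.integer(gap_px), bound)
}

# block-min pooling along depth by integer factor f (pads the last block
# by repeating the final row)
pool_min_depth <- function(M, f) {
  d <- nrow(M)
  dc <- ceiling(d / f)
  idx <- pmin(d, rep((seq_len(dc) - 1) * f, each = f) + seq_len(f))
  A <- M[idx, , drop = FALSE]
  grp <- rep(seq_len(dc), each = f)
  out <- matrix(0, dc, ncol(M))
  for (i in seq_len(dc)) {
    rows <- which(grp == i)
    out[i, ] <- do.call(pmin, lapply(rows, function(r) A[r, ]))
  }
  out
}

#' Simultaneous segmentation of the three wall interfaces
#'
#' End-to-end contour stage on one sub-image: gradient image, triple
#' replication, cost pair, 4D front propagation, backtracking and central
#' truncation. When the sub-image is deeper than
#' `params$max_dp_depth`, the cost maps are block-min pooled along depth
#' by the smallest sufficient integer factor, the 4D program runs at the
#' pooled resolution, and each interface is then refined at full
#' resolution by a banded single-contour pass (band half-width
#' `N + factor`) chained with the full-resolution gap constraint so the
#' returned contours always satisfy `y1 + gap <= y2 <= y3 - gap` and
#' `|dy| <= N`.
#'
#' @param sub An `oct_subimage`.
#' @param params [dp_params()].
#' @param sigma_um Gaussian derivative scale in micrometres.
#' @return An `oct_contours` with attributes `cost` (coarse optimal path
#'   cost) and `gap_px`.
#' @export
segment_layers <- function(sub, params = dp_params(), sigma_um = 30) {
  stopifnot(inherits(sub, "oct_subimage"))
  cm <- cost_maps(sub, sigma_um)
  gap_px <- resolve_gap_px(params, sub$pixel_size_axial)
  d <- sub$depth_px
  W <- sub$n_angles
  f <- max(1L, as.integer(ceiling(d / params$max_dp_depth)))

  if (f == 1L) {
    cum <- propagate_front(cm, params, gap_px = gap_px)
    bt <- backtrack(cum)
    contours <- truncate_central(bt$path, W, N = params$N,
                                 pixel_size_axial = sub$pixel_size_axial)
    attr(contours, "cost") <- bt$cost
    attr(contours, "gap_px") <- gap_px
    return(contours)
  }

  Cp_c <- pool_min_depth(cm$C_plus, f)
  Cm_c <- pool_min_depth(cm$C_minus, f)
  gap_c <- max(1L, as.integer(round(gap_px / f)))
  if (nrow(Cp_c) < 2 * gap_c + 1) stop("depth too small for gap constraint")
  res <- .ml_dp_forward(Cp_c, Cm_c, params$omega, params$kappa, params$N,
                        gap_c)
  bt <- .ml_dp_backtrack(res$final, res$a1, res$a2, res$a3, res$depth,
                         res$width, res$gap)
  # full-resolution banded refinement, gap-chained across interfaces
  centers <- bt$path * f + (f - 1L) %/% 2L   # coarse cell centres
  centers <- pmin(centers, d - 1L)
  half <- params$N + f
  w3 <- ncol(centers)
  none <- rep(-1L, w3)
  Cfull <- list(cm$C_plus, cm$C_minus, cm$C_plus)
  paths <- matrix(0L, 3, w3)
  lower <- none
  for (n in 1:3) {
    # the pooled program bounds steps per pooled column (N * f full-res
    # pixels), so its upsampled path may be unreachable under the
    # full-resolution step bound N; widen the band until feasible
    h <- half
    repeat {
      r <- tryCatch(
        .band_dp(Cfull[[n]], as.integer(centers[n, ]), as.integer(h),
                 as.integer(lower), params$omega[n], params$kappa,
                 params$N),
        error = function(e) e)
      if (!inherits(r, "error")) break
      if (h >= d) stop(r)
      h <- min(d, 2L * h)
    }
    paths[n, ] <- r$path
    lower <- r$path + gap_px
  }
  contours <- truncate_central(paths, W, N = params$N,
                               pixel_size_axial = sub$pixel_size_axial)
  attr(contours, "cost") <- bt$cost
  attr(contours, "gap_px") <- gap_px
  contours
}
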
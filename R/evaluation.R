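# Evaluation metrics: point-to-point contour error, layer-thickness
# agreement, Dice overlap and the confusion-matrix triplet.

#' Point-to-point contour error
#'
#' Per-column absolute distance, along the ray through the lumen centre,
#' between automatic and reference interface depths, reported in
#' micrometres as mean +/- SD per interface. Columns outside the
#' annotated arc or under the guidewire are skipped.
#'
#' @param auto,ref `oct_contours` on the same angular grid (reference
#'   depths may be fractional).
#' @param pixel_size_axial Micrometres per pixel (defaults to the value
#'   stored on `auto`).
#' @param columns Optional integer vector of annotated columns.
#' @param mask Optional logical exclusion mask (e.g. guidewire).
#' @return List with a per-interface summary data frame and the matrix of
#'   per-column absolute errors (um).
#' @export
point_distance_error <- function(auto, ref, pixel_size_axial = NULL,
                                 columns = NULL, mask = NULL) {
  stopifnot(auto$n_angles == ref$n_angles)
  if (is.null(pixel_size_axial)) pixel_size_axial <- auto$pixel_size_axial
  W <- auto$n_angles
  keep <- rep(TRUE, W)
  if (!is.null(columns)) keep <- keep & (seq_len(W) %in% columns)
  if (!is.null(mask)) keep <- keep & !mask
  if (!any(keep)) stop("no comparable columns")
  E <- cbind(IM = abs(auto$y1 - ref$y1), MA = abs(auto$y2 - ref$y2),
             AP = abs(auto$y3 - ref$y3))[keep, , drop = FALSE] *
    pixel_size_axial
  summary <- data.frame(interface = c("IM", "MA", "AP"),
                        mean_um = colMeans(E),
                        sd_um = apply(E, 2, sd),
                        n = sum(keep), row.names = NULL)
  list(summary = summary, errors_um = E)
}

#' Layer-thickness error with bias and limits of agreement
#'
#' Layer thicknesses are differences of consecutive interface depths
#' (intima: `y1 - 0`, media: `y2 - y1`, adventitia: `y3 - y2`) in
#' micrometres. Reports per layer the mean absolute error, signed bias,
#' 95% limits of agreement (`bias +/- 1.96 SD` of the signed error) and
#' the mean relative error against the reference thickness (columns with
#' zero reference thickness are excluded from the relative error, with
#' their count logged).
#'
#' @inheritParams point_distance_error
#' @return List with the per-layer summary data frame and signed error
#'   matrices.
#' @export
thickness_error <- function(auto, ref, pixel_size_axial = NULL,
                            columns = NULL, mask = NULL) {
  stopifnot(auto$n_angles == ref$n_angles)
  if (is.null(pixel_size_axial)) pixel_size_axial <- auto$pixel_size_axial
  W <- auto$n_angles
  keep <- rep(TRUE, W)
  if (!is.null(columns)) keep <- keep & (seq_len(W) %in% columns)
  if (!is.null(mask)) keep <- keep & !mask
  if (!any(keep)) stop("no comparable columns")
  th <- function(ct) cbind(intima = ct$y1, media = ct$y2 - ct$y1,
                           adventitia = ct$y3 - ct$y2) * pixel_size_axial
  A <- th(auto)[keep, , drop = FALSE]
  R <- th(ref)[keep, , drop = FALSE]
  D <- A - R
  rel <- matrix(NA_real_, nrow(D), 3, dimnames = list(NULL, colnames(D)))
  nz <- R > 0
  rel[nz] <- abs(D[nz]) / R[nz]
  summary <- data.frame(
    layer = colnames(D),
    mean_abs_um = colMeans(abs(D)),
    sd_abs_um = apply(abs(D), 2, sd),
    bias_um = colMeans(D),
    loa_low_um = colMeans(D) - 1.96 * apply(D, 2, sd),
    loa_high_um = colMeans(D) + 1.96 * apply(D, 2, sd),
    rel_error = colMeans(rel, na.rm = TRUE),
    n_zero_ref = colSums(!nz), row.names = NULL)
  list(summary = summary, signed_error_um = D)
}

#' Dice overlap of two healthy-column regions
#'
#' `D = 2 |A intersect B| / (|A| + |B|)` on column counts. Two empty
#' regions are defined as identical (`D = 1`).
#'
#' @param region_a,region_b Logical membership vectors over the same
#'   column universe, or integer column indices.
#' @param exclude Optional logical mask of columns to drop (e.g.
#'   guidewire).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(region_a, region_b, exclude = NULL) {
  to_logical <- function(r, n) {
    if (is.logical(r)) r else {
      v <- rep(FALSE, n); v[r] <- TRUE; v
    }
  }
  n <- if (is.logical(region_a)) length(region_a) else
    max(c(region_a, region_b, 0)) + 1
  a <- to_logical(region_a, n)
  b <- to_logical(region_b, n)
  if (length(a) != length(b)) stop("regions live on different universes")
  if (!is.null(exclude)) {
    a <- a[!exclude]; b <- b[!exclude]
  }
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Accuracy, sensitivity and specificity of per-column labels
#'
#' Healthy (1) is the positive class; masked (`NA`) columns are excluded.
#' A metric with a zero denominator (no positives, or no negatives, in
#' the reference/prediction as appropriate) is reported as `NA` with the
#' counts intact.
#'
#' @param auto,ref Integer label vectors (1 = healthy, 0 = diseased,
#'   `NA` = masked).
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_metrics <- function(auto, ref) {
  keep <- !is.na(auto) & !is.na(ref)
  a <- auto[keep]; r <- ref[keep]
  TP <- sum(a == 1 & r == 1); TN <- sum(a == 0 & r == 0)
  FP <- sum(a == 1 & r == 0); FN <- sum(a == 0 & r == 1)
  tot <- TP + TN + FP + FN
  list(accuracy = if (tot > 0) (TP + TN) / tot else NA_real_,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Evaluate automatic against reference labels over a pullback
#'
#' Per-frame Dice and confusion metrics plus pooled-column aggregates.
#'
#' @param auto,ref Label matrices (`n_angles x n_frames`, `NA` masked).
#' @return An `oct_eval` list with per-frame and pooled summaries.
#' @export
evaluate_labels <- function(auto, ref) {
  stopifnot(all(dim(auto) == dim(ref)))
  nfr <- ncol(auto)
  per <- data.frame(frame = seq_len(nfr), dice = NA_real_,
                    accuracy = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_)
  for (k in seq_len(nfr)) {
    a <- auto[, k]; r <- ref[, k]
    keep <- !is.na(a) & !is.na(r)
    per$dice[k] <- dice(a[keep] == 1, r[keep] == 1)
    cm <- confusion_metrics(a, r)
    per$accuracy[k] <- cm$accuracy
    per$sensitivity[k] <- cm$sensitivity
    per$specificity[k] <- cm$specificity
  }
  pooled <- confusion_metrics(as.vector(auto), as.vector(ref))
  structure(list(per_frame = per, pooled = pooled), class = "oct_eval")
}

#' @export
print.oct_eval <- function(x, ...) {
  cat("<oct_eval>\n  per-frame medians:",
      sprintf("dice %.3f, accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              median(x$per_frame$dice, na.rm = TRUE),
              median(x$per_frame$accuracy, na.rm = TRUE),
              median(x$per_frame$sensitivity, na.rm = TRUE),
              median(x$per_frame$specificity, na.rm = TRUE)))
  invisible(x)
}
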
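# Pipeline configuration and the command-level entry points tying the
# two stages together (segment -> features -> classify -> evaluate).

#' Pipeline configuration
#'
#' Defaults are the package's operating point: derivative-of-Gaussian
#' scale 30 um, interface weights (0.2, 1, 1), minimal gap 45 um, seven
#' reachable neighbours (`N = 3`), smoothness 0.1, 100 angular steps over
#' a 1-mm sub-image, a 300-um feature margin below the AP contour, 100
#' boosting rounds and morphology kernels (4, 9).
#'
#' @param sigma_um Gradient scale (um).
#' @param omega Interface weights.
#' @param kappa Smoothness coefficient.
#' @param N Half-neighbourhood.
#' @param gap_um Minimal inter-contour gap (um).
#' @param n_angles Angular steps of the sub-image.
#' @param depth_um Sub-image depth (um).
#' @param margin_um Feature-region margin below the AP contour (um).
#' @param n_rounds Boosting rounds.
#' @param K_E,K_D Morphology kernel lengths.
#' @param features `"relevant8"` or `"all17"`.
#' @param seed Pipeline seed.
#' @param max_dp_depth Depth cap of the dense 4D state space.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sigma_um = 30, omega = c(0.2, 1, 1),
                            kappa = 0.1, N = 3L, gap_um = 45,
                            n_angles = 100L, depth_um = 1000,
                            margin_um = 300, n_rounds = 100L, K_E = 4L,
                            K_D = 9L, features = "relevant8", seed = 1L,
                            max_dp_depth = 48L) {
  structure(list(sigma_um = sigma_um, omega = as.numeric(omega),
                 kappa = kappa, N = as.integer(N), gap_um = gap_um,
                 n_angles = as.integer(n_angles), depth_um = depth_um,
                 margin_um = margin_um, n_rounds = as.integer(n_rounds),
                 K_E = as.integer(K_E), K_D = as.integer(K_D),
                 features = features, seed = as.integer(seed),
                 max_dp_depth = as.integer(max_dp_depth)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config A `pipeline_config`.
#' @return The configuration (read) or `path` (write, invisibly).
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_dp_params <- function(config) {
  dp_params(omega = config$omega, kappa = config$kappa, N = config$N,
            gap_um = config$gap_um, max_dp_depth = config$max_dp_depth)
}

#' Segment a whole pullback
#'
#' Lumen extraction (or user-supplied lumen contours), guidewire
#' detection on the pullback-averaged profile, sub-image construction and
#' simultaneous three-interface segmentation for every frame.
#'
#' @param frames List of [oct_frame]s.
#' @param config [pipeline_config()].
#' @param lumens Optional list of `oct_lumen` (bypasses lumen
#'   segmentation).
#' @return List with `subs`, `contours`, `lumens` and the native
#'   guidewire mask `gw_mask`.
#' @export
segment_pullback <- function(frames, config = pipeline_config(),
                             lumens = NULL) {
  if (is.null(lumens))
    lumens <- lapply(frames, segment_lumen, sigma_um = config$sigma_um,
                     kappa = config$kappa, N = config$N)
  prof <- pullback_profile(frames, lumens)
  gw <- detect_guidewire(frames[[1]], lumens[[1]], prof)
  params <- config_dp_params(config)
  subs <- vector("list", length(frames))
  contours <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    subs[[k]] <- build_subimage(frames[[k]], lumens[[k]], gw,
                                n_angles = config$n_angles,
                                depth_um = config$depth_um)
    contours[[k]] <- segment_layers(subs[[k]], params,
                                    sigma_um = config$sigma_um)
  }
  list(subs = subs, contours = contours, lumens = lumens, gw_mask = gw)
}

#' Raw feature matrices for every frame of a segmented pullback
#'
#' @param seg Result of [segment_pullback()].
#' @param config [pipeline_config()].
#' @return List with `features` (raw, all 17 per frame) and `masks`
#'   (guidewire mask per frame on the sub-image grid).
#' @export
features_for_pullback <- function(seg, config = pipeline_config()) {
  feats <- vector("list", length(seg$subs))
  masks <- vector("list", length(seg$subs))
  for (k in seq_along(seg$subs)) {
    feats[[k]] <- compute_features(seg$subs[[k]], seg$contours[[k]],
                                   margin_um = config$margin_um,
                                   sigma_um = config$sigma_um)
    masks[[k]] <- seg$subs[[k]]$guidewire_mask
  }
  list(features = feats, masks = masks)
}

overlay_png <- function(sub, contours, path) {
  I <- sub$I
  img <- array(rep(I, 3), dim = c(nrow(I), ncol(I), 3))
  mark <- function(y, ch) {
    r <- pmin(nrow(I), as.integer(round(y)) + 1L)
    for (c in seq_along(r)) {
      img[r[c], c, ] <<- 0
      img[r[c], c, ch] <<- 1
    }
  }
  mark(contours$y1, 1)
  mark(contours$y2, 2)
  mark(contours$y3, 3)
  png::writePNG(img, path)
  invisible(path)
}

#' Segment command: frames in, contour tables out
#'
#' Writes `contours.csv`, `contours.json` and (optionally) per-frame
#' overlay PNGs to `out_dir`; logs per-frame path cost and timing.
#'
#' @param input List of [oct_frame]s or a path readable by
#'   [read_pullback()].
#' @param config [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param lumen_csv Optional lumen CSV bypassing lumen segmentation.
#' @param overlays Write overlay PNGs.
#' @param quiet Suppress per-frame log lines.
#' @return The segmentation result of [segment_pullback()], invisibly.
#' @export
oct_cmd_segment <- function(input, config = pipeline_config(), out_dir,
                            lumen_csv = NULL, overlays = FALSE,
                            quiet = FALSE) {
  frames <- if (is.character(input)) read_pullback(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lumens <- if (!is.null(lumen_csv)) read_lumen_csv(lumen_csv) else NULL
  seg <- segment_pullback(frames, config, lumens)
  for (k in seq_along(seg$contours)) {
    if (!quiet)
      message(sprintf("frame %d: path cost %.4f", k - 1L,
                      attr(seg$contours[[k]], "cost")))
    if (overlays)
      overlay_png(seg$subs[[k]], seg$contours[[k]],
                  file.path(out_dir, sprintf("overlay_%03d.png", k - 1L)))
  }
  write_contours_csv(seg$contours, file.path(out_dir, "contours.csv"))
  jsonlite::write_json(
    lapply(seg$contours, function(ct) ct[c("y1", "y2", "y3")]),
    file.path(out_dir, "contours.json"), digits = NA)
  invisible(seg)
}

#' Train command: labelled pullbacks in, model bundle out
#'
#' Segments every training pullback, extracts and pools the per-column
#' features with their labels, optionally screens features with
#' [boruta_select()], normalises with training statistics and fits the
#' boosted-stump model. Guidewire columns are excluded from training.
#'
#' @param pullbacks List of entries, each a list with `frames` and
#'   `labels` (`n_angles x n_frames` reference label matrix) or a
#'   phantom pullback carrying `truth`.
#' @param config [pipeline_config()]; `config$features` selects the
#'   relevant-8 subset or all 17.
#' @param out Optional path for the JSON model bundle.
#' @param run_boruta Run relevance selection and use its outcome instead
#'   of the fixed subset.
#' @return The trained `oct_adaboost`, invisibly.
#' @export
oct_cmd_train <- function(pullbacks, config = pipeline_config(),
                          out = NULL, run_boruta = FALSE) {
  Xs <- list(); ys <- list()
  for (pb in pullbacks) {
    seg <- segment_pullback(pb$frames, config)
    fe <- features_for_pullback(seg, config)
    labels <- pullback_reference_labels(pb, config)
    for (k in seq_along(fe$features)) {
      keep <- !fe$masks[[k]] & !is.na(labels[, k])
      Xs[[length(Xs) + 1L]] <- fe$features[[k]][keep, , drop = FALSE]
      ys[[length(ys) + 1L]] <- labels[keep, k]
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2) stop("single-class training cohort")
  active <- if (run_boruta) {
    sel <- boruta_select(X, y, seed = config$seed)
    if (length(sel$relevant) < 1) feature_names("relevant8") else sel$relevant
  } else feature_names(if (identical(config$features, "all17")) "all17"
                       else "relevant8")
  Xa <- X[, active, drop = FALSE]
  norm <- normalize_features(Xa)
  model <- train_adaboost(norm$features, y, n_rounds = config$n_rounds,
                          seed = config$seed)
  model$norm_stats <- norm$stats
  if (!is.null(out)) save_model_bundle(model, out)
  invisible(model)
}

# reference labels on the sub-image grid for a training pullback entry
pullback_reference_labels <- function(pb, config) {
  if (!is.null(pb$labels)) return(pb$labels)
  if (is.null(pb$truth)) stop("pullback carries neither labels nor truth")
  W <- config$n_angles
  n_alines <- pb$spec$n_alines
  sapply(pb$truth, function(tr)
    truth_at_angles(tr, W, n_alines)$labels)
}

#' Classify command: frames plus model in, labels and carpet map out
#'
#' @param input List of [oct_frame]s or a readable path.
#' @param model An `oct_adaboost` or a bundle path.
#' @param config [pipeline_config()].
#' @param out_dir Output directory for `labels.csv` and `carpet.png`.
#' @param seg Optional precomputed segmentation (skips re-segmentation).
#' @return Label matrix (`n_angles x n_frames`), invisibly.
#' @export
oct_cmd_classify <- function(input, model, config = pipeline_config(),
                             out_dir = NULL, seg = NULL) {
  frames <- if (is.character(input)) read_pullback(input) else input
  if (is.character(model)) model <- load_model_bundle(model)
  if (!all(model$feature_names %in% .octwall_canonical_features))
    stop("model/feature mismatch")
  if (is.null(seg)) seg <- segment_pullback(frames, config)
  fe <- features_for_pullback(seg, config)
  labels <- classify_pullback(model, fe$features, fe$masks,
                              K_E = config$K_E, K_D = config$K_D)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_labels_csv(labels, file.path(out_dir, "labels.csv"))
    write_carpet_png(labels, file.path(out_dir, "carpet.png"))
  }
  invisible(labels)
}

#' Evaluate command: automatic vs reference outputs
#'
#' Contour errors (when reference contours are given) and label
#' agreement (when reference labels are given), written as JSON.
#'
#' @param auto_contours,ref_contours Lists of `oct_contours` per frame
#'   (or `NULL`).
#' @param auto_labels,ref_labels Label matrices (or `NULL`).
#' @param pixel_size_axial Micrometres per pixel for contour errors.
#' @param out Optional JSON report path.
#' @param eval_columns Optional list (per frame) of annotated columns.
#' @return An `oct_eval_report` list, invisibly.
#' @export
oct_cmd_evaluate <- function(auto_contours = NULL, ref_contours = NULL,
                             auto_labels = NULL, ref_labels = NULL,
                             pixel_size_axial = NULL, out = NULL,
                             eval_columns = NULL) {
  report <- list()
  if (!is.null(auto_contours) && !is.null(ref_contours)) {
    if (length(auto_contours) != length(ref_contours))
      stop(sprintf("frame index mismatch: %d vs %d frames",
                   length(auto_contours), length(ref_contours)))
    errs <- lapply(seq_along(auto_contours), function(k) {
      cols <- if (is.null(eval_columns)) NULL else eval_columns[[k]]
      point_distance_error(auto_contours[[k]], ref_contours[[k]],
                           pixel_size_axial, columns = cols)$errors_um
    })
    E <- do.call(rbind, errs)
    report$contours <- list(
      mean_um = colMeans(E), sd_um = apply(E, 2, sd), n_points = nrow(E))
    th <- lapply(seq_along(auto_contours), function(k) {
      cols <- if (is.null(eval_columns)) NULL else eval_columns[[k]]
      thickness_error(auto_contours[[k]], ref_contours[[k]],
                      pixel_size_axial, columns = cols)$signed_error_um
    })
    TH <- do.call(rbind, th)
    report$thickness <- list(
      mean_abs_um = colMeans(abs(TH)), bias_um = colMeans(TH),
      loa_low_um = colMeans(TH) - 1.96 * apply(TH, 2, sd),
      loa_high_um = colMeans(TH) + 1.96 * apply(TH, 2, sd))
  }
  if (!is.null(auto_labels) && !is.null(ref_labels)) {
    ev <- evaluate_labels(auto_labels, ref_labels)
    report$labels <- list(per_frame = ev$per_frame, pooled = ev$pooled)
  }
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(structure(report, class = "oct_eval_report"))
}
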
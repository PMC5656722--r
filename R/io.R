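# Readers and writers for the raster / sidecar formats the pipeline
# consumes: multi-page TIFF stacks with YAML metadata, lumen and contour
# CSV, label CSV, model bundles (JSON) and carpet-map PNG.

#' Write a pullback as a TIFF stack with YAML sidecar
#'
#' @param frames List of [oct_frame]s.
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @param extra Extra fields merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_pullback <- function(frames, path, extra = list()) {
  mats <- lapply(frames, function(f) f$pixels)
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  meta <- c(list(geometry = frames[[1]]$geometry,
                 pixel_size_axial_um = frames[[1]]$pixel_size_axial,
                 n_frames = length(frames)), extra)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a pullback from a TIFF stack (or directory of rasters)
#'
#' The sidecar `<path>.yaml` must provide `geometry` and
#' `pixel_size_axial_um`; alternatively pass them explicitly.
#'
#' @param path TIFF file or directory of PNG/TIFF frames.
#' @param geometry,pixel_size_axial Override / replace sidecar metadata.
#' @return List of [oct_frame]s.
#' @export
read_pullback <- function(path, geometry = NULL, pixel_size_axial = NULL) {
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  if (is.null(geometry)) geometry <- meta$geometry
  if (is.null(pixel_size_axial)) pixel_size_axial <- meta$pixel_size_axial_um
  if (is.null(pixel_size_axial)) stop("pixel_size_axial required")
  if (is.null(geometry)) geometry <- "polar"
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else tiff::readTIFF(f, all = TRUE)
  }
  mats <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    unlist(lapply(files, function(f) {
      m <- read_one(f)
      if (is.list(m)) m else list(m)
    }), recursive = FALSE)
  } else {
    m <- tiff::readTIFF(path, all = TRUE)
    if (is.list(m)) m else list(m)
  }
  lapply(seq_along(mats), function(k) {
    M <- mats[[k]]
    if (length(dim(M)) == 3) M <- M[, , 1]
    oct_frame(M, geometry, pixel_size_axial, k - 1L)
  })
}

#' Write per-frame layer contours to CSV
#'
#' One row per (frame, column) with depths in pixels and micrometres.
#'
#' @param contours List of `oct_contours`, one per frame.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(k) {
    ct <- contours[[k]]
    px <- ct$pixel_size_axial
    data.frame(frame_index = k - 1L, column = seq_len(ct$n_angles) - 1L,
               y1_px = ct$y1, y2_px = ct$y2, y3_px = ct$y3,
               y1_um = ct$y1 * px, y2_um = ct$y2 * px, y3_um = ct$y3 * px)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read layer contours from CSV
#'
#' @param path CSV written by [write_contours_csv()].
#' @return List of `oct_contours` per frame.
#' @export
read_contours_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$frame_index), function(d) {
    d <- d[order(d$column), ]
    px <- if (any(d$y1_px > 0)) d$y1_um[which(d$y1_px > 0)[1]] /
      d$y1_px[which(d$y1_px > 0)[1]] else NA_real_
    structure(list(y1 = d$y1_px, y2 = d$y2_px, y3 = d$y3_px,
                   n_angles = nrow(d), pixel_size_axial = px),
              class = "oct_contours")
  })
}

#' Write per-frame labels to CSV
#'
#' @param labels Label matrix (`n_angles x n_frames`; `NA` = masked).
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(
    frame_index = rep(seq_len(ncol(labels)) - 1L, each = nrow(labels)),
    column = rep(seq_len(nrow(labels)) - 1L, times = ncol(labels)),
    label = as.vector(labels))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read labels from CSV
#'
#' @param path CSV written by [write_labels_csv()].
#' @return Integer label matrix (`n_angles x n_frames`).
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path)
  W <- max(df$column) + 1L
  nf <- max(df$frame_index) + 1L
  M <- matrix(NA_integer_, W, nf)
  M[cbind(df$column + 1L, df$frame_index + 1L)] <- df$label
  M
}

#' Read a per-frame lumen contour CSV
#'
#' One row per frame, columns = per-A-line lumen depth in pixels.
#'
#' @param path CSV path (no header).
#' @return List of `oct_lumen` objects.
#' @export
read_lumen_csv <- function(path) {
  M <- as.matrix(read.csv(path, header = FALSE))
  lapply(seq_len(nrow(M)), function(k)
    structure(list(depth_per_aline = as.numeric(M[k, ]),
                   n_alines = ncol(M)), class = "oct_lumen"))
}

#' Save / load a classifier model bundle as JSON
#'
#' The bundle stores the stump ensemble, the normalisation statistics,
#' the active feature names and the training seed.
#'
#' @param model An `oct_adaboost`.
#' @param path JSON path.
#' @return `path` (save) or the restored `oct_adaboost` (load).
#' @export
save_model_bundle <- function(model, path) {
  bundle <- list(stumps = model$stumps,
                 feature_names = model$feature_names,
                 n_rounds = model$n_rounds,
                 norm_stats = model$norm_stats,
                 meta = model$meta)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  ns <- b$norm_stats
  if (!is.null(ns)) ns <- list(min = unlist(ns$min), max = unlist(ns$max))
  structure(list(stumps = as.data.frame(b$stumps),
                 feature_names = b$feature_names,
                 n_rounds = b$n_rounds, norm_stats = ns, meta = b$meta),
            class = "oct_adaboost")
}

#' Render a carpet map of per-column labels
#'
#' Angle-by-frame summary image: healthy green, diseased red, guidewire
#' gray.
#'
#' @param labels Label matrix (`n_angles x n_frames`, `NA` = masked).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_carpet_png <- function(labels, path) {
  W <- nrow(labels); nf <- ncol(labels)
  img <- array(0, dim = c(W, nf, 3))
  healthy <- !is.na(labels) & labels == 1
  diseased <- !is.na(labels) & labels == 0
  masked <- is.na(labels)
  img[, , 1][diseased] <- 0.8
  img[, , 2][healthy] <- 0.7
  for (ch in 1:3) img[, , ch][masked] <- 0.5
  png::writePNG(img, path)
  invisible(path)
}
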
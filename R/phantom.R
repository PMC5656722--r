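# Synthetic OCT phantom: lumen-centred vessel wall with a
# bright/dark/bright three-layer structure in healthy arcs, layerless
# attenuating plaque in diseased arcs, multiplicative speckle and a
# guidewire shadow, with exact ground truth recorded before noise.

#' Specification of a synthetic pullback
#'
#' Defaults emulate a coronary cross-section at the coarser of the two
#' scanner presets (8.8 um/px; 4.5 um/px is the other): lumen radius
#' 1.3 mm with a gentle second-harmonic perturbation, layer thicknesses
#' 130 / 95 / 105 um (intima / media / adventitia) with smooth angular
#' variation, bright/dark/bright layer intensities with exponential
#' periadventitial decay, an 800-um layerless attenuating slab in
#' diseased arcs, multiplicative gamma speckle of standard deviation 0.2
#' and a 24-A-line guidewire shadow.
#'
#' @param n_frames Frames in the pullback.
#' @param n_alines Native A-lines per frame.
#' @param pixel_size_axial Micrometres per pixel (presets: 4.5 or 8.8).
#' @param lumen_radius_um Mean lumen radius.
#' @param lumen_harmonic `list(amp, k, phase)`: relative amplitude,
#'   angular order and phase of the lumen radius perturbation.
#' @param healthy_arcs List of half-open native-column intervals
#'   `c(a, b)` (`0 <= a < b <= n_alines`) labelled healthy; everything
#'   else is diseased. `NULL` means fully healthy, `list()` fully
#'   diseased.
#' @param thickness_um Named mean layer thicknesses (intima, media,
#'   adventitia); healthy arcs must keep intima + media < 500 um.
#' @param thickness_angular_amp Relative amplitude of the smooth angular
#'   thickness variation.
#' @param drift_sd Frame-to-frame relative thickness drift (bounded
#'   random walk), as a fraction per frame.
#' @param intensities Named template intensities (lumen, intima, media,
#'   adventitia, peri).
#' @param peri_decay_um Exponential decay constant of the
#'   periadventitial signal.
#' @param plaque `list(intensity, attenuation_um, thickness_um)` for the
#'   diseased slab (thickness must be >= 600 um).
#' @param speckle_sd Standard deviation of the multiplicative gamma
#'   speckle (0 disables noise).
#' @param guidewire `list(width, start)`: shadow arc width in A-lines and
#'   start column (`NULL` = drawn at random once per pullback; width 0
#'   disables it).
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(n_frames = 10L, n_alines = 360L,
                         pixel_size_axial = 8.8, lumen_radius_um = 1300,
                         lumen_harmonic = list(amp = 0.04, k = 2, phase = 0),
                         healthy_arcs = NULL,
                         thickness_um = c(intima = 130, media = 95,
                                          adventitia = 105),
                         thickness_angular_amp = 0.08, drift_sd = 0.01,
                         intensities = c(lumen = 0.04, intima = 0.80,
                                         media = 0.22, adventitia = 0.70,
                                         peri = 0.45),
                         peri_decay_um = 250,
                         plaque = list(intensity = 0.85,
                                       attenuation_um = 350,
                                       thickness_um = 800),
                         speckle_sd = 0.2,
                         guidewire = list(width = 24L, start = NULL),
                         seed = 1L) {
  stopifnot(n_frames >= 1, n_alines >= 16, pixel_size_axial > 0,
            all(thickness_um > 0), plaque$thickness_um >= 600,
            speckle_sd >= 0)
  if (is.null(healthy_arcs)) healthy_arcs <- list(c(0L, n_alines))
  for (arc in healthy_arcs) {
    if (length(arc) != 2 || arc[1] < 0 || arc[2] > n_alines ||
        arc[1] >= arc[2])
      stop("healthy arcs must be half-open intervals within [0, n_alines)")
  }
  if (length(healthy_arcs) > 0 &&
      thickness_um[["intima"]] + thickness_um[["media"]] >= 500)
    stop("healthy arcs require intima + media thickness < 500 um")
  structure(list(n_frames = as.integer(n_frames),
                 n_alines = as.integer(n_alines),
                 pixel_size_axial = pixel_size_axial,
                 lumen_radius_um = lumen_radius_um,
                 lumen_harmonic = lumen_harmonic,
                 healthy_arcs = healthy_arcs,
                 thickness_um = thickness_um,
                 thickness_angular_amp = thickness_angular_amp,
                 drift_sd = drift_sd, intensities = intensities,
                 peri_decay_um = peri_decay_um, plaque = plaque,
                 speckle_sd = speckle_sd, guidewire = guidewire,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-frame deterministic parameters (drift etc.) shared by all A-lines
phantom_frame_params <- function(spec, frame_index, drift_mult, gw_start) {
  px <- spec$pixel_size_axial
  W <- spec$n_alines
  phi <- (seq_len(W) - 1) * 2 * pi / W
  lh <- spec$lumen_harmonic
  r_lum <- spec$lumen_radius_um / px *
    (1 + lh$amp * sin(lh$k * phi + lh$phase))
  amp <- spec$thickness_angular_amp
  th <- sapply(1:3, function(n) {
    spec$thickness_um[n] / px * drift_mult[n] *
      (1 + amp * sin(phi + n))
  })
  healthy <- rep(FALSE, W)
  for (arc in spec$healthy_arcs) {
    cols <- seq.int(arc[1], arc[2] - 1L) + 1L
    healthy[cols] <- TRUE
  }
  gw <- rep(FALSE, W)
  if (spec$guidewire$width > 0) {
    cols <- ((gw_start + seq_len(spec$guidewire$width) - 1L) %% W) + 1L
    gw[cols] <- TRUE
  }
  list(phi = phi, r_lum = r_lum, th = th, healthy = healthy, gw = gw)
}

#' Generate one phantom frame with its ground truth
#'
#' Renders the polar frame row-wise: dark lumen interior; in healthy arcs
#' a bright intima, dark media, bright adventitia and exponentially
#' decaying periadventitial tail; in diseased arcs a single bright
#' attenuating slab without layering. Multiplicative gamma speckle (mean
#' 1, sd `speckle_sd`) is applied after the ground truth is recorded; the
#' guidewire arc is zeroed below the lumen.
#'
#' @param spec A [phantom_spec()].
#' @param frame_index 1-based frame number (used for metadata).
#' @param drift_mult Per-layer relative thickness multipliers for this
#'   frame (defaults to 1).
#' @param gw_start 0-based start column of the guidewire arc.
#' @return List with the `frame` ([oct_frame]) and `truth` (native-grid
#'   lumen radius, interface depths below the lumen in pixels, per-A-line
#'   healthy labels and guidewire mask).
#' @export
generate_frame <- function(spec, frame_index = 1L,
                           drift_mult = c(1, 1, 1), gw_start = 0L) {
  px <- spec$pixel_size_axial
  p <- phantom_frame_params(spec, frame_index, drift_mult, gw_start)
  W <- spec$n_alines
  ints <- spec$intensities
  max_r <- max(p$r_lum)
  depth_px <- ceiling(1000 / px)
  n_rows <- as.integer(ceiling(max_r + depth_px + 400 / px))
  I <- matrix(ints[["lumen"]], n_rows, W)
  slab_px <- spec$plaque$thickness_um / px
  atten_px <- spec$plaque$attenuation_um / px
  peri_px <- spec$peri_decay_um / px
  rows <- seq_len(n_rows)
  for (j in seq_len(W)) {
    r <- p$r_lum[j]
    depth <- rows - r               # pixels below the lumen boundary
    col <- rep(ints[["lumen"]], n_rows)
    inside <- depth >= 0
    if (p$healthy[j]) {
      t1 <- p$th[j, 1]; t2 <- p$th[j, 2]; t3 <- p$th[j, 3]
      col[inside & depth < t1] <- ints[["intima"]]
      col[inside & depth >= t1 & depth < t1 + t2] <- ints[["media"]]
      col[inside & depth >= t1 + t2 & depth < t1 + t2 + t3] <-
        ints[["adventitia"]]
      tail_idx <- inside & depth >= t1 + t2 + t3
      col[tail_idx] <- 0.03 +
        ints[["peri"]] * exp(-(depth[tail_idx] - (t1 + t2 + t3)) / peri_px)
    } else {
      slab <- inside & depth < slab_px
      col[slab] <- spec$plaque$intensity * exp(-depth[slab] / atten_px)
      col[inside & depth >= slab_px] <- 0.04
    }
    I[, j] <- col
  }
  truth <- list(
    lumen_px = p$r_lum,
    y1 = ifelse(p$healthy, p$th[, 1], NA_real_),
    y2 = ifelse(p$healthy, p$th[, 1] + p$th[, 2], NA_real_),
    y3 = ifelse(p$healthy, rowSums(p$th), NA_real_),
    healthy = p$healthy, gw_mask = p$gw)
  if (spec$speckle_sd > 0) {
    shp <- 1 / spec$speckle_sd^2
    noise <- matrix(rgamma(length(I), shape = shp, rate = shp), n_rows, W)
    I <- I * noise
  }
  if (any(p$gw)) {
    for (j in which(p$gw)) {
      I[rows >= p$r_lum[j], j] <- 0
    }
  }
  I <- pmin(I, 1)
  list(frame = oct_frame(I, "polar", px, frame_index - 1L), truth = truth)
}

#' Generate a full phantom pullback
#'
#' Frames share the spec's geometry with a bounded random-walk drift of
#' the layer thicknesses along the pullback, so adjacent-frame voting is
#' meaningful. Seeded generation is bit-reproducible.
#'
#' @param spec A [phantom_spec()].
#' @return List with `frames`, per-frame `truth`, and a `manifest`
#'   recording the spec and seed.
#' @export
generate_pullback <- function(spec) {
  set.seed(spec$seed)
  gw_start <- spec$guidewire$start
  if (is.null(gw_start))
    gw_start <- sample.int(spec$n_alines, 1L) - 1L
  drift <- c(1, 1, 1)
  frames <- vector("list", spec$n_frames)
  truths <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    g <- generate_frame(spec, k, drift, gw_start)
    frames[[k]] <- g$frame
    truths[[k]] <- g$truth
    step <- rnorm(3, 0, spec$drift_sd)
    drift <- pmin(1.2, pmax(0.8, drift * (1 + step)))
  }
  manifest <- list(spec = unclass(spec), gw_start = gw_start,
                   generator = "octwall phantom")
  list(frames = frames, truth = truths, spec = spec, manifest = manifest)
}

#' Ground truth resampled onto the sub-image angular grid
#'
#' Interface depths are interpolated circularly at the `n_angles` ray
#' angles; labels and the guidewire mask are taken from the native
#' A-line whose half-open arc contains the ray angle.
#'
#' @param truth One frame's truth entry from [generate_pullback()].
#' @param n_angles Angular steps of the sub-image.
#' @param n_alines Native A-line count.
#' @param pixel_size_axial Stored on the returned contours.
#' @return List with reference `contours` (`oct_contours`, fractional
#'   depths; `NA` in diseased arcs), integer `labels` and logical
#'   `gw_mask` per sub-image column.
#' @export
truth_at_angles <- function(truth, n_angles, n_alines,
                            pixel_size_axial = NA_real_) {
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  phi <- (seq_len(n_alines) - 1) * 2 * pi / n_alines
  # linear interpolation between adjacent native A-lines, NA-propagating
  # (diseased arcs keep NA reference depths)
  interp <- function(v) {
    pos <- theta / (2 * pi) * n_alines
    j0 <- floor(pos)
    fr <- pos - j0
    i0 <- (j0 %% n_alines) + 1L
    i1 <- ((j0 + 1L) %% n_alines) + 1L
    (1 - fr) * v[i0] + fr * v[i1]
  }
  j <- floor(theta / (2 * pi) * n_alines) + 1L   # half-open native arcs
  contours <- structure(list(y1 = interp(truth$y1), y2 = interp(truth$y2),
                             y3 = interp(truth$y3),
                             n_angles = as.integer(n_angles),
                             pixel_size_axial = pixel_size_axial),
                        class = "oct_contours")
  list(contours = contours,
       labels = as.integer(truth$healthy[j]),
       gw_mask = truth$gw_mask[j])
}

#' Generate a cohort of phantom pullbacks
#'
#' Draws per-pullback geometry (lumen size and phase, guidewire
#' position, healthy-arc pattern) at random. Arc patterns mix fully
#' healthy, fully diseased and partly diseased vessels.
#'
#' @param n_pullbacks Number of pullbacks.
#' @param n_frames Frames per pullback.
#' @param seed Cohort seed; pullback `i` uses `seed * 1000 + i`.
#' @param speckle_sd Speckle level passed to every spec.
#' @param n_alines,pixel_size_axial Geometry shared by the cohort.
#' @return List of `generate_pullback()` results; each carries its
#'   `spec`.
#' @export
generate_cohort <- function(n_pullbacks, n_frames = 10L, seed = 1L,
                            speckle_sd = 0.2, n_alines = 360L,
                            pixel_size_axial = 8.8) {
  out <- vector("list", n_pullbacks)
  for (i in seq_len(n_pullbacks)) {
    set.seed(seed * 1000L + i)
    kind <- sample(c("healthy", "diseased", "mixed"), 1,
                   prob = c(0.3, 0.2, 0.5))
    arcs <- if (kind == "healthy") list(c(0L, n_alines))
    else if (kind == "diseased") list()
    else {
      a <- sample.int(n_alines, 1L) - 1L
      len <- sample(seq.int(n_alines %/% 4, (3 * n_alines) %/% 4), 1L)
      if (a + len <= n_alines) list(c(a, a + len))
      else list(c(0L, (a + len) %% n_alines), c(a, n_alines))
    }
    spec <- phantom_spec(
      n_frames = n_frames, n_alines = n_alines,
      pixel_size_axial = pixel_size_axial,
      lumen_radius_um = runif(1, 1100, 1500),
      lumen_harmonic = list(amp = runif(1, 0.02, 0.06), k = sample(1:3, 1),
                            phase = runif(1, 0, 2 * pi)),
      healthy_arcs = arcs, speckle_sd = speckle_sd,
      seed = seed * 1000L + i)
    pb <- generate_pullback(spec)
    pb$spec <- spec
    pb$kind <- kind
    out[[i]] <- pb
  }
  out
}
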
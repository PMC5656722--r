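# Shared fixtures, memoised so expensive phantom runs happen once per
# test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# noise-free, fully healthy single-frame phantom with guidewire
nf_phantom <- function() fixture("nf_phantom", function() {
  spec <- phantom_spec(n_frames = 1, speckle_sd = 0)
  pb <- generate_pullback(spec)
  lum <- segment_lumen(pb$frames[[1]])
  sub <- build_subimage(pb$frames[[1]], lum, pb$truth[[1]]$gw_mask)
  ct <- segment_layers(sub, dp_params())
  tr <- truth_at_angles(pb$truth[[1]], sub$n_angles, spec$n_alines,
                        spec$pixel_size_axial)
  list(spec = spec, pb = pb, lumen = lum, sub = sub, contours = ct,
       truth = tr)
})

# noise-free fully diseased single frame
nf_diseased <- function() fixture("nf_diseased", function() {
  spec <- phantom_spec(n_frames = 1, speckle_sd = 0, healthy_arcs = list())
  pb <- generate_pullback(spec)
  lum <- segment_lumen(pb$frames[[1]])
  sub <- build_subimage(pb$frames[[1]], lum, pb$truth[[1]]$gw_mask)
  ct <- segment_layers(sub, dp_params())
  list(spec = spec, pb = pb, lumen = lum, sub = sub, contours = ct)
})

# minimal oct_subimage wrapper around a plain matrix (unit tests of the
# cost/feature machinery that need no phantom geometry)
sub_from_matrix <- function(I, pixel_size_axial = 8.8, mask = NULL) {
  I <- as.matrix(I)
  W <- ncol(I)
  if (is.null(mask)) mask <- rep(FALSE, W)
  structure(list(I = I, n_angles = W, depth_px = nrow(I),
                 pixel_size_axial = pixel_size_axial,
                 guidewire_mask = mask,
                 quality_clamped = rep(FALSE, W),
                 lumen_ref = list(center = c(0, 0),
                                  r_start = rep(100, W),
                                  theta = (seq_len(W) - 1) * 2 * pi / W,
                                  lumen = NULL),
                 frame_index = 0L),
            class = "oct_subimage")
}

# small trained model on a deterministic mini-cohort
mini_model <- function() fixture("mini_model", function() {
  config <- pipeline_config()
  train <- generate_cohort(4, n_frames = 3, seed = 401)
  oct_cmd_train(train, config)
})

# reference labels (with guidewire NAs) for a phantom pullback on the
# sub-image grid
reference_labels <- function(pb, n_angles = 100L) {
  sapply(pb$truth, function(tr) {
    ta <- truth_at_angles(tr, n_angles, pb$spec$n_alines)
    lab <- ta$labels
    lab[ta$gw_mask] <- NA_integer_
    lab
  })
}
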
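# Lumen extraction, guidewire detection, sub-image construction and
# Cartesian back-mapping.

test_that("lumen contour recovers phantom radii and rejects flat frames", {
  ring <- generate_pullback(phantom_spec(
    n_frames = 1, speckle_sd = 0,
    lumen_harmonic = list(amp = 0, k = 2, phase = 0),
    guidewire = list(width = 0, start = 0)))
  lum <- segment_lumen(ring$frames[[1]])
  expect_lt(max(abs(lum$depth_per_aline - ring$truth[[1]]$lumen_px)), 1 + 1e-6)

  # sinusoidally varying radius, amplitude 10 px
  amp10 <- 10 * 8.8 / 1300
  wav <- generate_pullback(phantom_spec(
    n_frames = 1, speckle_sd = 0,
    lumen_harmonic = list(amp = amp10, k = 2, phase = 0.3),
    guidewire = list(width = 0, start = 0)))
  lum2 <- segment_lumen(wav$frames[[1]])
  expect_lte(max(abs(lum2$depth_per_aline - wav$truth[[1]]$lumen_px)), 2)

  dark <- oct_frame(matrix(0.01, 120, 90), "polar", 8.8)
  expect_error(segment_lumen(dark), "no lumen detected")
  flat <- oct_frame(matrix(0.5, 120, 90), "polar", 8.8)
  expect_error(segment_lumen(flat), "no lumen detected")
})

test_that("guidewire detection flags the single darkest circular band", {
  W <- 120
  prof <- rep(1, W)
  prof[41:70] <- 0.1
  mask <- detect_guidewire(NULL, NULL, prof)
  expect_identical(which(mask), 41:70)

  expect_false(any(detect_guidewire(NULL, NULL, rep(0.8, W))))

  # two dark runs: darker mean wins
  prof2 <- rep(1, W)
  prof2[11:20] <- 0.30
  prof2[61:70] <- 0.10
  expect_identical(which(detect_guidewire(NULL, NULL, prof2)), 61:70)

  # exact tie -> lower start index
  prof3 <- rep(1, W)
  prof3[11:20] <- 0.2
  prof3[61:70] <- 0.2
  expect_identical(which(detect_guidewire(NULL, NULL, prof3)), 11:20)

  # runs shorter than the minimum length are ignored
  prof4 <- rep(1, W)
  prof4[5:6] <- 0.01
  expect_false(any(detect_guidewire(NULL, NULL, prof4)))

  # wrap-around band is one circular run
  prof5 <- rep(1, W)
  prof5[c(115:120, 1:6)] <- 0.1
  m5 <- detect_guidewire(NULL, NULL, prof5)
  expect_setequal(which(m5), c(115:120, 1:6))

  # at most one circular run of TRUE on random profiles
  for (s in 1:20) {
    set.seed(s)
    p <- runif(60, 0.2, 1)
    p[sample(60, 15)] <- runif(15, 0, 0.3)
    m <- detect_guidewire(NULL, NULL, p)
    runs <- octwall:::circular_runs(m)
    expect_lte(length(runs), 1)
  }
})

test_that("sub-image depth covers 1 mm with ceil rounding", {
  ph <- nf_phantom()
  expect_equal(ph$sub$depth_px, 114)  # ceil(1000 / 8.8)
  fine <- generate_pullback(phantom_spec(
    n_frames = 1, speckle_sd = 0, pixel_size_axial = 4.5, n_alines = 180,
    guidewire = list(width = 0, start = 0)))
  lum <- segment_lumen(fine$frames[[1]])
  sub <- build_subimage(fine$frames[[1]], lum, NULL, n_angles = 36)
  expect_equal(sub$depth_px, 223)     # ceil(1000 / 4.5)
  expect_error(build_subimage(fine$frames[[1]], lum, NULL, n_angles = 4),
               "n_angles")
})

test_that("rotationally symmetric phantom yields near-identical columns", {
  ring <- generate_pullback(phantom_spec(
    n_frames = 1, speckle_sd = 0,
    lumen_harmonic = list(amp = 0, k = 2, phase = 0),
    thickness_angular_amp = 0,
    guidewire = list(width = 0, start = 0)))
  lum <- segment_lumen(ring$frames[[1]])
  sub <- build_subimage(ring$frames[[1]], lum, NULL)
  spread <- apply(sub$I, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 0.02 * diff(range(sub$I)))
})

test_that("guidewire mask is resampled to sub-image columns", {
  ph <- nf_phantom()
  expect_equal(length(ph$sub$guidewire_mask), 100)
  expect_gt(sum(ph$sub$guidewire_mask), 0)
  # masked sub columns point at masked native A-lines
  native_frac <- mean(ph$pb$truth[[1]]$gw_mask)
  expect_equal(mean(ph$sub$guidewire_mask), native_frac, tolerance = 0.3)
})

test_that("Cartesian mapping round-trips and preserves radial ordering", {
  ph <- nf_phantom()
  sub <- ph$sub
  zero <- structure(list(y1 = rep(0, 100), y2 = rep(5, 100),
                         y3 = rep(12, 100), n_angles = 100L,
                         pixel_size_axial = sub$pixel_size_axial),
                    class = "oct_contours")
  polys <- map_contours_to_cartesian(zero, sub)
  expect_equal(nrow(polys$IM), 101)
  expect_equal(polys$IM[1, ], polys$IM[101, ])
  # y = 0 lies on the lumen boundary polygon
  r_im <- sqrt(rowSums((polys$IM[1:100, ] -
                          matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  expect_equal(r_im, sub$lumen_ref$r_start, tolerance = 1e-9)
  # constant offset -> constant radius increment
  r_ma <- sqrt(rowSums((polys$MA[1:100, ] -
                          matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  expect_equal(r_ma - r_im, rep(5, 100), tolerance = 1e-9)

  # segmented contours: mapped radius matches true layer radius within ~1 px
  tr <- ph$truth
  keep <- !sub$guidewire_mask
  mapped <- map_contours_to_cartesian(ph$contours, sub)
  r_map <- sqrt(rowSums((mapped$MA[1:100, ] -
                           matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  theta <- sub$lumen_ref$theta
  phi <- (seq_len(ph$spec$n_alines) - 1) * 2 * pi / ph$spec$n_alines
  r_lum_true <- octwall:::circular_interp(phi, ph$pb$truth[[1]]$lumen_px,
                                          theta, 2 * pi)
  r_true <- r_lum_true + tr$contours$y2
  expect_lt(mean(abs(r_map - r_true)[keep]), 1.6)

  # ordering: IM < MA < AP radius wherever y1 < y2 < y3
  r_ap <- sqrt(rowSums((mapped$AP[1:100, ] -
                          matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  r_im2 <- sqrt(rowSums((mapped$IM[1:100, ] -
                           matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  r_ma2 <- sqrt(rowSums((mapped$MA[1:100, ] -
                           matrix(sub$lumen_ref$center, 100, 2, byrow = TRUE))^2))
  expect_true(all(r_im2 < r_ma2 & r_ma2 < r_ap))
})
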
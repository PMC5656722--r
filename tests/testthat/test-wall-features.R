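# Region extraction, the 17 per-column features and their normalisation.

test_that("region R spans the lumen to 300 um below the AP contour", {
  I <- matrix(0.5, 223, 4)
  sub <- sub_from_matrix(I, pixel_size_axial = 4.5)
  ct <- structure(list(y1 = rep(20, 4), y2 = rep(35, 4), y3 = rep(50, 4),
                       n_angles = 4L, pixel_size_axial = 4.5),
                  class = "oct_contours")
  reg <- extract_region(sub, ct)
  # ceil(300 / 4.5) = 67 rows below the AP row
  expect_equal(reg$margin_px, 67L)
  expect_equal(reg$rows_end, rep(50L + 1L + 67L, 4))
  expect_false(any(reg$clamped))

  # clamped at the image bottom
  ct2 <- ct; ct2$y3 <- rep(200, 4)
  reg2 <- extract_region(sub, ct2)
  expect_equal(reg2$rows_end, rep(223L, 4))
  expect_true(all(reg2$clamped))

  # guidewire columns flagged excluded but still extracted
  sub3 <- sub_from_matrix(I, 4.5, mask = c(TRUE, FALSE, FALSE, FALSE))
  reg3 <- extract_region(sub3, ct)
  expect_identical(reg3$excluded, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(reg3$rows_end[1], 118L)
})

test_that("profile-shape features match hand computations", {
  # exact linear profile -> zero residual
  expect_equal(octwall:::mse_linear_fit(seq(1, 0.2, length.out = 30)), 0,
               tolerance = 1e-12)
  # independent least-squares residual via lm()
  set.seed(10)
  v <- runif(25)
  fit <- lm(v ~ seq_along(v))
  expect_equal(octwall:::mse_linear_fit(v), mean(residuals(fit)^2),
               tolerance = 1e-10)

  expect_equal(monotony_index(c(9, 7, 5, 2)), 0)       # already sorted
  expect_equal(monotony_index(c(5, 3, 4, 1)), 0.5)     # printed example
  # invariance under strictly monotone rescaling
  set.seed(11)
  x <- runif(40)
  expect_equal(monotony_index(x), monotony_index(exp(3 * x)))
  expect_equal(monotony_index(x), monotony_index(x^3))

  expect_equal(sum(pmin(c(0.2, 0, 1.5), 0)), 0)        # non-negative gradient
  g <- c(-0.3, 0.2, -0.1, 0.4)
  expect_equal(sum(pmin(g, 0)), -0.4)
})

test_that("co-occurrence features match an independent reference on a toy region", {
  toy <- matrix(c(0.05, 0.15, 0.55, 0.75,
                  0.10, 0.10, 0.30, 0.90,
                  0.95, 0.80, 0.60, 0.20,
                  0.40, 0.42, 0.44, 0.46), 4, 4)
  q <- pmin(matrix(as.integer(floor(toy * 16)), 4, 4), 15L)
  P <- glcm_cooccurrence(q)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  f <- glcm_features(P)
  # reference values from scikit-image graycomatrix/graycoprops
  # (distance 1, vertical offset, 16 levels, symmetric, normalised)
  expect_equal(unname(f["contrast"]), 18.333333333333332, tolerance = 1e-10)
  expect_equal(unname(f["homogeneity"]), 0.3435648811304024, tolerance = 1e-10)
  expect_equal(unname(f["correlation"]), 0.49541284403669733, tolerance = 1e-10)
  expect_equal(unname(f["energy"]), 0.052083333333333336, tolerance = 1e-10)
  expect_equal(unname(f["entropy"]), 3.0047670352079603, tolerance = 1e-10)
  # degenerate constant region: correlation defined as 0
  fz <- glcm_features(glcm_cooccurrence(matrix(3L, 10, 1)))
  expect_equal(unname(fz["correlation"]), 0)
  expect_equal(unname(fz["contrast"]), 0)
})

test_that("feature normalisation uses training statistics with clipping", {
  F <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  expect_warning(norm <- normalize_features(F), "constant")
  expect_equal(norm$features[, "a"], c(0, 0.5, 1))
  expect_equal(norm$features[, "b"], c(0.5, 0.5, 0.5))
  # inference mode: clip to the training range
  inf <- normalize_features(cbind(a = c(8, -1), b = c(2, 0)), norm$stats)
  expect_equal(inf$features[, "a"], c(1, 0))
})

test_that("all 17 features are finite on phantom frames including shadows", {
  ph <- nf_phantom()
  F <- compute_features(ph$sub, ph$contours)
  expect_equal(dim(F), c(100L, 17L))
  expect_identical(colnames(F), feature_names("all17"))
  expect_true(all(is.finite(F)))
  expect_identical(attr(F, "excluded"), ph$sub$guidewire_mask)

  spk <- generate_pullback(phantom_spec(n_frames = 1, speckle_sd = 0.2,
                                        seed = 5))
  lum <- segment_lumen(spk$frames[[1]])
  sub <- build_subimage(spk$frames[[1]], lum, spk$truth[[1]]$gw_mask)
  F2 <- compute_features(sub, segment_layers(sub, dp_params()))
  expect_true(all(is.finite(F2)))
})

test_that("key features separate healthy from diseased columns (AUC > 0.8)", {
  ph <- nf_phantom()
  dis <- nf_diseased()
  Fh <- compute_features(ph$sub, ph$contours)
  Fd <- compute_features(dis$sub, dis$contours)
  kh <- !ph$sub$guidewire_mask
  kd <- !dis$sub$guidewire_mask
  auc <- function(pos, neg) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  # healthy walls are layered: higher contrast, stronger (more negative)
  # IM gradient, larger deviation from a straight decay
  expect_gt(auc(Fh[kh, "contrast"], Fd[kd, "contrast"]), 0.8)
  expect_gt(auc(abs(Fh[kh, "gradient_at_IM"]), abs(Fd[kd, "gradient_at_IM"])),
            0.8)
  expect_gt(auc(Fh[kh, "mse_linear_fit"], Fd[kd, "mse_linear_fit"]), 0.8)
})
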
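# Front propagation, backtracking, truncation and the enumeration oracle.

rand_instance <- function(seed, d, w) {
  set.seed(seed)
  list(C_plus = matrix(runif(d * w), d, w),
       C_minus = matrix(runif(d * w), d, w))
}

test_that("zero weights make the cumulative cost vanish everywhere", {
  inst <- rand_instance(1, 6, 5)
  p <- dp_params(omega = c(0, 0, 0), kappa = 0, N = 1)
  cum <- propagate_front(inst, p, gap_px = 1)
  fin <- cum$final[is.finite(cum$final)]
  expect_true(all(fin == 0))
  expect_equal(backtrack(cum)$cost, 0)
})

test_that("a single admissible state accumulates the forced transition costs", {
  # depth 3, gap 1: only state is (0, 1, 2)
  inst <- rand_instance(2, 3, 4)
  p <- dp_params(omega = c(0.2, 1, 1), kappa = 0.1, N = 1)
  bt <- backtrack(propagate_front(inst, p, gap_px = 1))
  expect_true(all(bt$path == matrix(c(0, 1, 2), 3, 4)))
  hand <- 0
  for (x in 2:4) {
    hand <- hand + 0.2 * (inst$C_plus[1, x] + inst$C_plus[1, x - 1]) +
      1.0 * (inst$C_minus[2, x] + inst$C_minus[2, x - 1]) +
      1.0 * (inst$C_plus[3, x] + inst$C_plus[3, x - 1])
  }
  expect_equal(bt$cost, hand)
})

test_that("DP equals the exhaustive oracle on random instances", {
  for (s in 1:20) {
    d <- 5 + (s %% 3)
    w <- 4 + (s %% 2)
    inst <- rand_instance(100 + s, d, w)
    p <- dp_params(N = 1, kappa = 0.1)
    bt <- backtrack(propagate_front(inst, p, gap_px = 1))
    or <- brute_force_oracle(inst, p, gap_px = 1)
    expect_equal(bt$cost, or$cost, tolerance = 1e-10)
    expect_identical(bt$path, or$path)
    # recomputation check: forward cost of the returned path
    expect_equal(path_cost(inst, bt$path, p), bt$cost, tolerance = 1e-10)
  }
})

test_that("uniform costs give the analytic total and the lexicographic tie path", {
  d <- 6; w <- 5; cval <- 0.37
  inst <- list(C_plus = matrix(cval, d, w), C_minus = matrix(cval, d, w))
  p <- dp_params(omega = c(0.2, 1, 1), kappa = 0, N = 1)
  bt <- backtrack(propagate_front(inst, p, gap_px = 1))
  or <- brute_force_oracle(inst, p, gap_px = 1)
  closed <- (w - 1) * 2 * cval * sum(p$omega)
  expect_equal(bt$cost, closed)
  expect_equal(or$cost, closed)
  # all paths tie; the lexicographically smallest is constant (0, 1, 2)
  expect_true(all(bt$path == matrix(c(0, 1, 2), 3, w)))
  expect_identical(bt$path, or$path)
})

test_that("oracle aborts when the enumeration bound is exceeded", {
  inst <- rand_instance(7, 10, 8)
  expect_error(brute_force_oracle(inst, dp_params(N = 2), gap_px = 1,
                                  bound = 1000),
               "oracle bound exceeded")
})

test_that("truncation keeps the central replica and checks closure", {
  path <- matrix(c(3, 8, 15), 3, 30)
  ct <- truncate_central(path, 10, N = 3)
  expect_equal(ct$n_angles, 10L)
  expect_equal(ct$y1, rep(3, 10))
  expect_equal(ct$y3, rep(15, 10))
  # a wrap jump beyond N warns
  bad <- path
  bad[1, 20] <- 30   # last retained column jumps
  expect_warning(truncate_central(bad, 10, N = 3), "closure violated")
})

test_that("empty admissible state space is rejected", {
  inst <- rand_instance(8, 4, 4)
  expect_error(propagate_front(inst, dp_params(N = 1), gap_px = 2),
               "depth too small")
})

test_that("zero MA/AP weights reduce to the single-contour program", {
  set.seed(42)
  d <- 20; w <- 24
  Cp <- matrix(runif(d * w), d, w)
  Cp[15:d, ] <- Cp[15:d, ] + 0.5   # keep the optimum away from the bottom
  Cm <- matrix(runif(d * w), d, w)
  p <- dp_params(omega = c(1, 0, 0), kappa = 0.1, N = 2)
  bt <- backtrack(propagate_front(list(C_plus = Cp, C_minus = Cm), p,
                                  gap_px = 1))
  single <- octwall:::.band_dp(Cp, integer(w), -1L, rep(-1L, w), 1.0, 0.1, 2L)
  expect_equal(bt$path[1, ], as.integer(single$path))
  expect_equal(bt$cost, single$cost, tolerance = 1e-10)
})

test_that("increasing smoothness never increases path roughness", {
  roughness <- function(path) sum(abs(path[, -1] - path[, -ncol(path)]))
  for (s in 1:5) {
    inst <- rand_instance(300 + s, 10, 12)
    prev <- Inf
    for (kap in c(0, 0.05, 0.1, 0.3, 1, 3)) {
      p <- dp_params(kappa = kap, N = 2)
      bt <- backtrack(propagate_front(inst, p, gap_px = 1))
      r <- roughness(bt$path)
      expect_lte(r, prev + 1e-9)
      prev <- r
    }
  }
})

test_that("contours shift with the sub-image content (translation equivariance)", {
  set.seed(9)
  d <- 40; W <- 20
  base <- matrix(0.7, d, W)      # bright wall below a flat top margin
  base[12:16, ] <- 0.15          # dark band (IM edge at its top)
  base[17:23, ] <- 0.90          # bright band (MA edge at its top)
  base[24:30, ] <- 0.10          # dark band (AP edge at its top)
  base[31:40, ] <- 0.65
  base <- base + matrix(rnorm(d * W, 0, 0.005), d, W)
  shift <- 3
  shifted <- rbind(matrix(0.3, shift, W), base[1:(d - shift), ])
  p <- dp_params(N = 2, gap_px = 2, max_dp_depth = 64)
  ct1 <- segment_layers(sub_from_matrix(base), p)
  ct2 <- segment_layers(sub_from_matrix(shifted), p)
  expect_equal(ct2$y1, ct1$y1 + shift, tolerance = 1e-9)
  expect_equal(ct2$y2, ct1$y2 + shift, tolerance = 1e-9)
  expect_equal(ct2$y3, ct1$y3 + shift, tolerance = 1e-9)
})

test_that("segment_layers recovers the noise-free phantom and keeps constraints", {
  ph <- nf_phantom()
  ct <- ph$contours
  tr <- ph$truth$contours
  keep <- !ph$sub$guidewire_mask & !is.na(tr$y1)
  expect_lt(mean(abs(ct$y1 - tr$y1)[keep]), 2)
  expect_lt(mean(abs(ct$y2 - tr$y2)[keep]), 2)
  expect_lt(mean(abs(ct$y3 - tr$y3)[keep]), 2)
  gap <- attr(ct, "gap_px")
  expect_true(all(ct$y1 + gap <= ct$y2 & ct$y2 + gap <= ct$y3))
  N <- 3
  steps <- function(y) max(abs(diff(c(y, y[1]))))
  expect_lte(steps(ct$y1), N)
  expect_lte(steps(ct$y2), N)
  expect_lte(steps(ct$y3), N)
})

test_that("diseased frames still yield admissible tentative contours", {
  dis <- nf_diseased()
  ct <- dis$contours
  gap <- attr(ct, "gap_px")
  expect_true(all(ct$y1 + gap <= ct$y2 & ct$y2 + gap <= ct$y3))
  expect_true(all(ct$y3 < dis$sub$depth_px))
})
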
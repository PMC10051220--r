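# tomographic forward model, losses, and alignment bookkeeping

test_that("forward projection respects zeros, symmetry, and the axis", {
  geom <- projection_geometry(c(0, 45, 90), c(32, 32, 1))
  expect_equal(tomo_forward(matrix(0, 32, 32), geom, 1),
               matrix(0, 1, 32))
  expect_error(tomo_forward(matrix(0, 32, 32), geom, 4), "out of range")
  # spherically symmetric phantom projects identically at all angles
  blob <- outer(1:32, 1:32, function(i, j)
    exp(-((i - 16.5)^2 + (j - 16.5)^2) / 18))
  cf <- dwt2(blob, 3)
  p1 <- tomo_forward(cf, geom, 1)
  p2 <- tomo_forward(cf, geom, 2)
  expect_lt(max(abs(p1 - p2)) / max(abs(p1)), 1e-2)
  # a small feature on the rotation axis keeps its projected position
  spot <- matrix(0, 32, 32)
  spot[16:17, 16:17] <- 1   # around the default axis (16.5, 16.5)
  cs <- dwt2(blur2d(spot, gaussian_kernel(5, 1)), 3)
  peaks <- sapply(1:3, function(i) which.max(tomo_forward(cs, geom, i)[1, ]))
  expect_lt(max(peaks) - min(peaks), 1.5)
})

test_that("tomography loss matches a from-scratch evaluator on one slice", {
  set.seed(70)
  geom <- projection_geometry(c(0, 60, 120), c(16, 16, 1))
  x <- matrix(rnorm(256, sd = 0.3), 16)
  projections <- lapply(1:3, function(i) matrix(rnorm(16), 1, 16))
  lam1 <- 0.02; lam2 <- 0.03
  val <- tomo_loss(x, projections, geom, loss_weights(lam1, lam2), levels = 2)
  img <- ad_val(idwt2(x, 2))
  direct <- 0
  for (i in 1:3) {
    rot <- ad_val(rotate_slice(img, geom$angles_deg[i], geom$axis))
    direct <- direct + sum((rowSums(rot) - projections[[i]][1, ])^2)
  }
  direct <- direct + lam1 * sum(abs(x)) + lam2 * ad_val(tv2d(img))
  expect_lt(abs(val - direct), 1e-8)
})

test_that("loss at simulated truth is forward-consistent; empty data leaves regularizers", {
  truth <- smooth_blob(32, seed = 7)
  geom <- projection_geometry(seq(0, 120, length.out = 10), c(32, 32, 1))
  sino <- simulate_sinogram(truth, geom)
  cf <- ad_val(dwt2(truth, 3))
  v_truth <- tomo_loss(cf, sino$projections, geom, loss_weights())
  v_zero <- tomo_loss(matrix(0, 32, 32), sino$projections, geom, loss_weights())
  expect_lt(v_truth / v_zero, 1e-6)
  geom0 <- projection_geometry(numeric(0), c(16, 16, 1))
  lamval <- tomo_loss(matrix(1, 16, 16), list(), geom0,
                      loss_weights(lambda1 = 0.5), levels = 2)
  expect_equal(lamval, 0.5 * 256)
})

test_that("zero alignment reduces the aligned loss to the plain loss exactly", {
  set.seed(71)
  geom <- projection_geometry(c(0, 40, 80, 120), c(16, 16, 2))
  x <- list(matrix(rnorm(256, sd = 0.2), 16), matrix(rnorm(256, sd = 0.2), 16))
  projections <- lapply(1:4, function(i) matrix(rnorm(32), 2, 16))
  a0 <- alignment_params(matrix(0, 4, 2), 0)
  expect_equal(tomo_loss_aligned(x, projections, geom, a0,
                                 loss_weights(0.01, 0.01), levels = 2),
               tomo_loss(x, projections, geom,
                         loss_weights(0.01, 0.01), levels = 2))
})

test_that("alignment parameters that undo an injected warp restore the clean loss", {
  # empty stack margins keep shifted content on the detector frame
  slices <- make_volume_phantom(32, 12, 3, seed = 21)
  geom <- projection_geometry(c(0, 30, 60, 90, 120), c(32, 32, 12))
  warped <- simulate_sinogram(slices, geom, shift_px = 2, tilt_deg = 1.5,
                              seed = 3)
  cf <- lapply(slices, function(s) ad_val(dwt2(s, 3)))
  v_undone <- tomo_loss_aligned(cf, warped$projections, geom,
                                warped$correcting, loss_weights())
  v_raw <- tomo_loss(cf, warped$projections, geom, loss_weights())
  expect_lt(v_undone, 0.25 * v_raw)   # interpolation residue only
})

test_that("the alignment census is exactly 2N + 1 refinable reals", {
  ap <- alignment_params(matrix(0, 7, 2), 1.2)
  expect_identical(ap$n_refinable, 15L)
  truth <- smooth_blob(16, seed = 9)
  geom <- projection_geometry(seq(0, 120, length.out = 5), c(16, 16, 1))
  sino <- simulate_sinogram(truth, geom)
  rec <- reconstruct_tomo(sino$projections, geom, refine_alignment = TRUE,
                          max_iter = 2, levels = 2)
  expect_identical(unname(rec$census["alignment"]), 2L * 5L + 1L)
  expect_identical(unname(rec$census["coefficients"]), 16L * 16L * 1L)
  expect_identical(rec$align$n_refinable, 11L)
})

test_that("reconstruction from two starts is deterministic without misalignment", {
  truth <- smooth_blob(16, seed = 10)
  geom <- projection_geometry(seq(0, 120, length.out = 8), c(16, 16, 1))
  sino <- simulate_sinogram(truth, geom)
  r1 <- reconstruct_tomo(sino$projections, geom, lambda1 = 1e-3,
                         max_iter = 60, levels = 2)
  r2 <- reconstruct_tomo(sino$projections, geom, lambda1 = 1e-3,
                         max_iter = 60, levels = 2)
  expect_lt(rmse(r1$volume, r2$volume), 1e-4)
})

test_that("loss is invariant to a joint rotation of phantom and angle origin", {
  blob <- smooth_blob(32, seed = 11)
  # compact support so the rotation does not clip
  win <- outer(1:32, 1:32, function(i, j)
    exp(-((i - 16.5)^2 + (j - 16.5)^2) / 60))
  img <- blob * win
  geom1 <- projection_geometry(c(0, 30, 75), c(32, 32, 1))
  geom2 <- projection_geometry(c(0, 30, 75) + 10, c(32, 32, 1))
  sino1 <- simulate_sinogram(img, geom1)
  img_rot <- ad_val(rotate_slice(img, -10, NULL))
  cf_rot <- ad_val(dwt2(img_rot, 3))
  v12 <- tomo_loss(cf_rot, sino1$projections, geom2, loss_weights())
  ref <- tomo_loss(matrix(0, 32, 32), sino1$projections, geom2, loss_weights())
  expect_lt(v12 / ref, 1e-2)
})
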
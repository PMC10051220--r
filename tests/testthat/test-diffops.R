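# operator primitives: exactness, adjoints, and reference oracles

test_that("orthonormal DCT is a perfect-reconstruction, norm-preserving pair", {
  set.seed(10)
  x <- matrix(rnorm(32 * 32), 32)
  expect_lt(max(abs(idct2(dct2(x)) - x)), 1e-6)
  expect_lt(abs(sqrt(sum(dct2(x)^2)) - sqrt(sum(x^2))), 1e-6)
  # constant image concentrates on the DC coefficient
  cimg <- matrix(3.7, 16, 16)
  co <- dct2(cimg)
  expect_equal(co[1, 1], 3.7 * 16, tolerance = 1e-10)
  expect_lt(max(abs(co[-1])), 1e-10)
  expect_error(dct2(array(0, c(2, 2, 2))), "2D")
})

test_that("periodized biorthogonal-4.4 DWT reconstructs perfectly", {
  set.seed(11)
  x <- matrix(rnorm(64 * 64), 64)
  expect_lt(max(abs(idwt2(dwt2(x, 3), 3) - x)), 1e-8)
  expect_equal(idwt2(matrix(0, 32, 32), 2), matrix(0, 32, 32))
  expect_error(dwt2(matrix(0, 64, 64), levels = 7), "exceeds")
  # odd intermediate size is a configuration error
  expect_error(dwt2(matrix(0, 100, 100), levels = 3), "even")
})

test_that("DWT subband shapes match the reference periodized convention", {
  # packed layout on 100x100 at 2 levels: level-1 detail blocks are 50x50,
  # level-2 blocks 25x25 (reference transform: 100 -> 50 -> 25 per level)
  x <- matrix(rnorm(100 * 100), 100)
  cf <- dwt2(x, 2)
  expect_equal(dim(cf), c(100, 100))
  # level-2 approximation occupies the 25x25 top-left corner: zeroing all
  # other coefficients leaves a smooth (coarse) image with the same mean
  cf2 <- matrix(0, 100, 100)
  cf2[1:25, 1:25] <- cf[1:25, 1:25]
  coarse <- idwt2(cf2, 2)
  expect_equal(mean(coarse), mean(x), tolerance = 1e-6)
})

test_that("affine warp reproduces identity, integer shifts, and zero rotation", {
  set.seed(12)
  img <- matrix(rnorm(100), 10)
  expect_lt(max(abs(affine_warp(img, affine_map()) - img)), 1e-6)
  expect_lt(max(abs(affine_warp(img, affine_rotation(0)) - img)), 1e-6)
  # integer translation oracle: output(r, c) = input(r + 3, c - 2), zero fill
  w <- affine_warp(img, affine_shift(3, -2))
  ref <- matrix(0, 10, 10)
  ref[1:7, 3:10] <- img[4:10, 1:8]
  expect_equal(w, ref)
  expect_error(affine_map(matrix(c(1, 2, 2, 4), 2)), "invertible")
})

test_that("volume rotation matches the 90-degree permutation and inverts", {
  set.seed(13)
  s <- matrix(rnorm(49), 7)
  r90 <- rotate_volume(s, 90)
  ctr <- 4
  perm <- matrix(0, 7, 7)
  for (r in 1:7) for (c in 1:7) perm[r, c] <- s[ctr - (c - ctr), ctr + (r - ctr)]
  expect_lt(max(abs(r90 - perm)), 1e-3)
  expect_equal(rotate_volume(s, 0), s, tolerance = 1e-12)
  g <- outer(1:64, 1:64, function(i, j) exp(-((i - 32)^2 + (j - 34)^2) / 120))
  back <- rotate_volume(rotate_volume(g, 23.7), -23.7)
  expect_lt(max(abs((back - g)[3:62, 3:62])), 1e-2)
})

test_that("Riemann projector integrates, is linear, and has an exact adjoint", {
  vol <- lapply(1:3, function(k) matrix(1, 5, 6))  # 6 voxels deep along beam
  proj <- riemann_project(vol, step = 1)
  expect_equal(proj, matrix(6, 3, 5))
  expect_error(riemann_project(vol, step = 0), "positive")
  set.seed(14)
  v1 <- matrix(rnorm(30), 5); v2 <- matrix(rnorm(30), 5)
  expect_equal(riemann_project(2 * v1 + 3 * v2, step = 0.5),
               2 * riemann_project(v1, 0.5) + 3 * riemann_project(v2, 0.5))
  gap <- adjoint_gap(function(v) project_slice(v, step = 0.7), c(8, 12))
  expect_lt(gap, 1e-6)
})

test_that("mask application keeps sampled pixels, zeroes the rest, idempotently", {
  set.seed(15)
  img <- matrix(rnorm(64), 8)
  m <- make_mask(c(8, 8), 0.4, "random", seed = 1)
  expect_equal(apply_mask(img, matrix(TRUE, 8, 8)), img)
  once <- apply_mask(img, m)
  expect_identical(apply_mask(once, m), once)
  expect_error(apply_mask(img, matrix(TRUE, 4, 4)), "shape")
  # regular stride mask retains exactly N * fraction pixels
  big <- make_mask(c(400, 400), 0.10, "regular")
  expect_identical(sum(big$keep), 16000L)
})

test_that("blur2d matches a dense-matrix convolution oracle", {
  set.seed(16)
  img <- matrix(rnorm(64), 8)
  ker <- matrix(rnorm(9), 3)
  dense <- matrix(0, 64, 64)
  for (j in 1:64) {
    e <- matrix(0, 8, 8); e[j] <- 1
    dense[, j] <- as.vector(blur2d(e, ker))
  }
  expect_lt(max(abs(as.vector(blur2d(img, ker)) - dense %*% as.vector(img))), 1e-6)
  # delta kernel is the identity; unit-sum kernel preserves constants inside
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  expect_equal(blur2d(img, delta), img)
  k1 <- matrix(1 / 9, 3, 3)
  cimg <- matrix(2.5, 8, 8)
  expect_equal(blur2d(cimg, k1)[2:7, 2:7], cimg[2:7, 2:7], tolerance = 1e-12)
  expect_error(blur2d(img, matrix(0, 2, 2)), "odd")
  expect_lt(adjoint_gap(function(v) blur2d(v, ker), c(8, 8)), 1e-6)
})

test_that("downsample is factor-squared mean binning with exact adjoint", {
  m <- matrix(as.numeric(1:16), 4)
  expect_equal(downsample(m, 2),
               matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                        mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2))
  cimg <- matrix(4.2, 8, 8)
  expect_equal(downsample(cimg, 4), matrix(4.2, 2, 2))
  expect_identical(dim(downsample(matrix(0, 12, 8), 4)), c(3L, 2L))
  expect_error(downsample(matrix(0, 9, 9), 2), "divisible")
  expect_lt(adjoint_gap(function(v) downsample(v, 2), c(8, 8)), 1e-6)
})

test_that("far-field propagation is unitary and an involution up to reversal", {
  f <- random_field(16, seed = 17)
  pf <- farfield_propagate(f)
  e0 <- sum(ad_val(f$re)^2 + ad_val(f$im)^2)
  e1 <- sum(ad_val(pf$re)^2 + ad_val(pf$im)^2)
  expect_lt(abs(e1 - e0) / e0, 1e-6)
  # centered point source gives flat magnitude
  pt <- complex_field(local({ m <- matrix(0, 16, 16); m[9, 9] <- 1; m }),
                      matrix(0, 16, 16))
  mag <- sqrt(ad_val(ad_cplx_mod2(farfield_propagate(pt))))
  expect_lt(max(mag) - min(mag), 1e-10)
  # applying twice reverses coordinates about the center
  ff <- farfield_propagate(pf)
  rev_idx <- function(n) c(1, n:2)  # center-preserving reversal on even grids
  expect_lt(max(abs(ad_val(ff$re) - ad_val(f$re)[rev_idx(16), rev_idx(16)])), 1e-8)
})

test_that("angular spectrum propagation is unitary with exact inverse and z = 0 identity", {
  f <- random_field(16, seed = 18)
  spec <- propagation_spec(1e-3, 1e-6, energy_ev = 1000,
                           regime = "angular-spectrum")
  g0 <- angular_spectrum_propagate(f, spec, z = 0)
  expect_lt(max(abs(ad_val(g0$re) - ad_val(f$re))), 1e-6)
  fwd <- angular_spectrum_propagate(f, spec)
  back <- angular_spectrum_propagate(fwd, spec, z = -spec$distance_m)
  expect_lt(max(abs(ad_val(back$re) - ad_val(f$re))), 1e-6)
  expect_lt(max(abs(ad_val(back$im) - ad_val(f$im))), 1e-6)
  e0 <- sum(ad_val(f$re)^2 + ad_val(f$im)^2)
  e1 <- sum(ad_val(fwd$re)^2 + ad_val(fwd$im)^2)
  expect_lt(abs(e1 - e0) / e0, 1e-6)
  expect_error(propagation_spec(1, -1, wavelength_m = 1e-9), "pixel")
  expect_error(propagation_spec(1, 1e-6, wavelength_m = -1), "wavelength")
})

test_that("subpixel crop equals slicing at integer positions and interpolates ramps", {
  set.seed(19)
  obj <- matrix(rnorm(400), 20)
  cr <- subpixel_crop(obj, c(3, 5), 8)
  expect_lt(max(abs(cr - obj[4:11, 6:13])), 1e-6)
  # half-pixel shift of a linear ramp gives exact midpoints
  ramp <- matrix(seq_len(12), 12, 12)
  half <- subpixel_crop(ramp, c(2.5, 3), 6)
  expect_equal(half, (ramp[3:8, 4:9] + ramp[4:9, 4:9]) / 2, tolerance = 1e-12)
  expect_error(subpixel_crop(obj, c(15, 15), 8), "outside")
})

test_that("linear operators and transforms pass taped adjoint checks", {
  m <- make_mask(c(8, 8), 0.5, "random", seed = 3)
  expect_lt(adjoint_gap(function(v) apply_mask(v, m), c(8, 8)), 1e-6)
  expect_lt(adjoint_gap(function(v) dct2(v), c(8, 8)), 1e-6)
  expect_lt(adjoint_gap(function(v) idwt2(v, 2), c(16, 16)), 1e-6)
  expect_lt(adjoint_gap(function(v) rotate_slice(v, 33.3, NULL), c(16, 16)), 1e-6)
})

test_that("operator gradients agree with central finite differences", {
  set.seed(20)
  img <- matrix(rnorm(64, sd = 0.5), 8)
  tgt <- matrix(0.3, 8, 8)
  cases <- list(
    blur = function(p) l2_fidelity(blur2d(p$x, gaussian_kernel(3, 1)), tgt),
    kernel = function(p) l2_fidelity(blur2d(img, p$h), tgt),
    bin = function(p) l2_fidelity(downsample(p$x, 2), matrix(0.1, 4, 4)),
    dct = function(p) l2_fidelity(idct2(p$x), tgt),
    dwt = function(p) l2_fidelity(idwt2(p$x, 2), tgt)
  )
  params <- list(blur = list(x = img), kernel = list(h = gaussian_kernel(3, 1.2)),
                 bin = list(x = img), dct = list(x = img), dwt = list(x = img))
  for (nm in names(cases)) {
    rep <- verify_gradients(cases[[nm]], params[[nm]])
    expect_lt(max(rep$max_rel), 1e-4)
  }
})
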
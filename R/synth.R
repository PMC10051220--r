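# Synthetic phantoms and forward simulators.  Every generator is a pure
# function of its inputs and seed, giving each modality test data with known
# ground truth and controlled degradations.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

#' Noise model specification
#'
#' @param model `"none"`, `"gaussian"` (additive, `level` = standard
#'   deviation) or `"poisson"` (`level` = expected total counts over the
#'   pattern/projection, modelling dose-limited acquisition).
#' @param level nonnegative noise level.
#' @param seed integer seed for the noise draw.
#' @return a `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "gaussian", "poisson"), level = 0,
                       seed = NULL) {
  model <- match.arg(model)
  if (level < 0) stop("noise level must be nonnegative")
  structure(list(model = model, level = level, seed = seed),
            class = "noise_spec")
}

add_noise <- function(x, noise) {
  if (is.null(noise) || noise$model == "none" || noise$level == 0) return(x)
  with_seed(noise$seed, {
    if (noise$model == "gaussian") {
      x + matrix(stats::rnorm(length(x), sd = noise$level), nrow(x))
    } else {
      # scale so the expected total equals `level` counts, draw, scale back
      tot <- sum(pmax(x, 0))
      if (tot <= 0) return(x)
      lam <- pmax(x, 0) * noise$level / tot
      matrix(stats::rpois(length(x), as.vector(lam)), nrow(x)) * tot / noise$level
    }
  })
}

#' Synthetic test phantoms
#'
#' Deterministic per seed.  Kinds: `"sparse-dct"` is exactly `K`-sparse in
#' the orthonormal DCT basis (the compressible-signal model of compressive
#' sensing); `"ellipses"` is piecewise constant with at most 8 distinct grey
#' levels in [0, 1]; `"blobs"` is a smooth sum of Gaussian bumps in [0, 1]
#' emulating cell-like soft structure.
#'
#' @param kind phantom family.
#' @param size image side length (>= 16).
#' @param K sparsity for `"sparse-dct"` (number of nonzero coefficients).
#' @param seed integer seed.
#' @return `size x size` numeric matrix.
#' @export
make_phantom <- function(kind = c("sparse-dct", "ellipses", "blobs"),
                         size = 64, K = 40, seed = 1) {
  kind <- match.arg(kind)
  if (size < 16) stop("size must be >= 16")
  if (K > size^2) stop("K cannot exceed size^2")
  with_seed(seed, {
    if (kind == "sparse-dct") {
      coeffs <- matrix(0, size, size)
      # low frequencies favoured, as in natural compressible images
      idx <- sample.int(size^2, K, prob = as.vector(
        outer(seq_len(size), seq_len(size), function(i, j) exp(-(i + j) / (size / 2)))))
      coeffs[idx] <- stats::rnorm(K, sd = 1)
      idct2(coeffs)
    } else if (kind == "ellipses") {
      img <- matrix(0, size, size)
      levels <- seq(0.125, 1, length.out = 7)
      cx <- stats::runif(6, 0.25, 0.75) * size
      cy <- stats::runif(6, 0.25, 0.75) * size
      a <- stats::runif(6, 0.08, 0.3) * size
      b <- stats::runif(6, 0.08, 0.3) * size
      val <- sample(levels, 6, replace = TRUE)
      gi <- matrix(seq_len(size), size, size)
      gj <- matrix(seq_len(size), size, size, byrow = TRUE)
      for (e in 1:6) {
        inside <- ((gi - cx[e]) / a[e])^2 + ((gj - cy[e]) / b[e])^2 <= 1
        img[inside] <- val[e]
      }
      img
    } else {
      img <- matrix(0, size, size)
      gi <- matrix(seq_len(size), size, size)
      gj <- matrix(seq_len(size), size, size, byrow = TRUE)
      for (e in 1:8) {
        cx <- stats::runif(1, 0.2, 0.8) * size
        cy <- stats::runif(1, 0.2, 0.8) * size
        s <- stats::runif(1, 0.03, 0.12) * size
        img <- img + stats::runif(1, 0.3, 1) * exp(-((gi - cx)^2 + (gj - cy)^2) / (2 * s^2))
      }
      img / max(img)
    }
  })
}

#' Windowed multi-slice volume phantom
#'
#' Stack of smooth-plus-piecewise-constant slices apodized by a Gaussian
#' window, with empty slices at the top and bottom of the stack.  The empty
#' margins keep the projections compactly supported on the detector, so that
#' per-projection shifts of a few pixels do not push real content off the
#' frame — the geometry any alignment study needs.
#'
#' @param size slice side length.
#' @param n_slices total slices in the stack.
#' @param pad_slices empty slices at each end of the stack.
#' @param seed integer seed.
#' @return list of `size x size` slice matrices (length `n_slices`).
#' @export
make_volume_phantom <- function(size = 64, n_slices = 16, pad_slices = 4,
                                seed = 1) {
  c0 <- (size + 1) / 2
  win <- outer(seq_len(size), seq_len(size), function(i, j)
    exp(-((i - c0)^2 + (j - c0)^2) / (2 * (size / 4.5)^2)))
  # keyframe slices blended along z: specimens are continuous along the
  # vertical axis, and that continuity is what makes marker-free alignment
  # of the slice-axis shifts identifiable
  keys <- lapply(1:3, function(k)
    win * (0.5 * make_phantom("blobs", size, seed = seed * 1000 + k) +
             0.5 * make_phantom("ellipses", size, seed = seed * 2000 + k)))
  inner <- n_slices - 2 * pad_slices
  # high-contrast bead-like point features, as added to real tomography
  # samples: they anchor the self-consistent alignment
  nb <- 10L
  beads <- with_seed(seed + 7, cbind(
    x = stats::runif(nb, 0.3, 0.7) * size,
    y = stats::runif(nb, 0.3, 0.7) * size,
    z = stats::runif(nb, pad_slices + 1.5, n_slices - pad_slices - 0.5)))
  gi <- matrix(seq_len(size), size, size)
  gj <- matrix(seq_len(size), size, size, byrow = TRUE)
  lapply(seq_len(n_slices), function(k) {
    if (k <= pad_slices || k > n_slices - pad_slices) return(matrix(0, size, size))
    u <- (k - pad_slices - 0.5) / inner          # position in (0, 1)
    env <- sin(pi * u)^2                          # rises from and falls to 0
    t2 <- u * 2                                   # blend across the keyframes
    sl <- if (t2 <= 1) env * ((1 - t2) * keys[[1]] + t2 * keys[[2]])
          else env * ((2 - t2) * keys[[2]] + (t2 - 1) * keys[[3]])
    for (b in seq_len(nb)) {
      wz <- exp(-(k - beads[b, "z"])^2 / (2 * 0.8^2))
      if (wz > 1e-3)
        sl <- sl + 1.5 * wz *
          exp(-((gi - beads[b, "x"])^2 + (gj - beads[b, "y"])^2) / (2 * 1.2^2))
    }
    sl
  })
}

#' Sparse sampling masks
#'
#' `"regular"` keeps pixel (i, j) (0-based) when `(i * W + j) mod
#' round(1/fraction) == 0`, matching a sorted-coordinate raster scan;
#' `"random"` keeps a uniform random subset of exactly
#' `round(fraction * N)` pixels.
#'
#' @param shape length-2 integer (rows, cols).
#' @param fraction sampling fraction in (0, 1].
#' @param scheme `"regular"` or `"random"`.
#' @param seed seed for the random scheme.
#' @return a `sampling_mask` with elements `keep` (logical matrix),
#'   `fraction` (realized) and `scheme`.
#' @export
make_mask <- function(shape, fraction, scheme = c("regular", "random"),
                      seed = 1) {
  scheme <- match.arg(scheme)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  H <- shape[1]; W <- shape[2]
  keep <- if (fraction == 1) {
    matrix(TRUE, H, W)
  } else if (scheme == "regular") {
    stride <- round(1 / fraction)
    gi <- matrix(seq_len(H) - 1, H, W)
    gj <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
    (gi * W + gj) %% stride == 0
  } else {
    m <- matrix(FALSE, H, W)
    with_seed(seed, m[sample.int(H * W, round(fraction * H * W))] <- TRUE)
    m
  }
  structure(list(keep = keep, fraction = mean(keep), scheme = scheme),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask: %dx%d, %s scheme, fraction %.4f\n",
              nrow(x$keep), ncol(x$keep), x$scheme, x$fraction))
  invisible(x)
}

# bounded smooth random walk of length n in [1 - amplitude, 1 + amplitude];
# used as the slowly varying beam-intensity profile along the scan raster
smooth_gain_walk <- function(n, amplitude, seed) {
  with_seed(seed, {
    steps <- stats::rnorm(n)
    walk <- cumsum(steps)
    k <- max(5, round(n / 50))
    kern <- stats::dnorm(seq(-3, 3, length.out = 2 * k + 1))
    kern <- kern / sum(kern)
    sm <- stats::filter(c(rep(walk[1], k), walk, rep(walk[n], k)), kern, sides = 2)
    sm <- as.numeric(sm[(k + 1):(k + n)])
    sm <- sm - mean(sm)
    span <- max(abs(sm))
    if (span > 0) sm <- sm / span
    1 + amplitude * sm
  })
}

#' Simulate a sparse STXM scan
#'
#' Forward model of a sparse raster scan: the image is modulated by a slowly
#' varying beam-intensity gain along the (column-major) scan raster, masked,
#' and optionally degraded by noise on the sampled pixels:
#' `y = Phi(image * gain) + noise`.
#'
#' @param image ground-truth 2D image.
#' @param mask a [sampling_mask] (or logical matrix).
#' @param gain_model `"none"` or `"smooth-random-walk"`.
#' @param gain_amplitude half-range of the gain around 1 (e.g. 0.2 gives a
#'   gain in [0.8, 1.2]).
#' @param noise a [noise_spec] or NULL.
#' @param seed seed for the gain draw.
#' @return list with `y` (measured image, zero off-mask) and `gain` (the
#'   true per-pixel gain field).
#' @export
simulate_cs_scan <- function(image, mask, gain_model = c("none", "smooth-random-walk"),
                             gain_amplitude = 0.2, noise = NULL, seed = 1) {
  gain_model <- match.arg(gain_model)
  m <- mask_values(mask)
  gain <- if (gain_model == "none") matrix(1, nrow(image), ncol(image))
          else matrix(smooth_gain_walk(length(image), gain_amplitude, seed),
                      nrow(image))
  y <- apply_mask(image * gain, m)
  y <- apply_mask(add_noise(y, noise), m)
  list(y = y, gain = gain)
}

#' Simulate a low-resolution acquisition
#'
#' The degradation model `y = B H x + n`: blur with the kernel, bin by the
#' downscale factor, add noise.
#'
#' @param hr high-resolution ground truth (dims divisible by the factor).
#' @param kernel blur kernel (odd-sized stencil).
#' @param spec a [degradation_spec].
#' @param noise a [noise_spec] or NULL.
#' @return low-resolution image.
#' @export
simulate_lr <- function(hr, kernel, spec, noise = NULL) {
  add_noise(degrade(hr, kernel, spec), noise)
}

#' Simulate a misaligned limited-angle sinogram
#'
#' Projects the ground-truth volume at the geometry's angles, then warps each
#' projection by a drawn per-projection shift (uniform in +/- `shift_px`)
#' and a common detector tilt, then adds noise.  Returns both the injected
#' warp parameters and the correcting alignment parameters (the exact warp
#' that undoes the injected one), for recovery scoring.
#'
#' @param volume ground-truth volume (matrix, 3D array, or list of slices).
#' @param geometry a [projection_geometry].
#' @param shift_px half-range of the per-projection detector shifts (pixels).
#' @param tilt_deg common detector tilt (degrees).
#' @param noise a [noise_spec] or NULL.
#' @param seed seed for the shift draw.
#' @return list with `projections` (list of detector images), `injected`
#'   (an [alignment_params] of the applied warps) and `correcting` (the
#'   [alignment_params] that undo them).
#' @export
simulate_sinogram <- function(volume, geometry, shift_px = 0, tilt_deg = 0,
                              noise = NULL, seed = 1) {
  slices <- as_slice_list(volume)
  N <- length(geometry$angles_deg)
  clean <- lapply(seq_len(N), function(i)
    project_volume_plain(slices, geometry, i))
  shifts <- with_seed(seed, matrix(stats::runif(2 * N, -shift_px, shift_px), N, 2))
  if (shift_px == 0) shifts[] <- 0
  projections <- lapply(seq_len(N), function(i) {
    p <- clean[[i]]
    if (tilt_deg != 0 || any(shifts[i, ] != 0))
      p <- ad_val(warp_shift_rot(p, shifts[i, 1], shifts[i, 2], tilt_deg))
    add_noise(p, noise)
  })
  # the correcting warp is the inverse: rotate by -tilt, shift by -R(-tilt) s
  phi <- -tilt_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  corr <- t(apply(shifts, 1, function(s) -as.vector(R %*% s)))
  list(projections = projections,
       injected = alignment_params(shifts, tilt_deg),
       correcting = alignment_params(corr, -tilt_deg))
}

#' Simulate a ptychographic scan
#'
#' Raster-grid scan with optional uniform position jitter emulating
#' mechanical stage errors: intensities are computed at the actual
#' (jittered) positions while the returned dataset stores the nominal grid,
#' so position-refinement recovery can be scored against the truth record.
#'
#' @param object ground-truth [complex_field] transmission function.
#' @param probes list of probe-mode [complex_field]s (or a single one).
#' @param grid list(rows, cols, step): raster grid of top-left box corners,
#'   step in object pixels.
#' @param jitter_px half-range of the uniform position jitter (pixels).
#' @param spec a [propagation_spec].
#' @param noise a [noise_spec] or NULL.
#' @param seed seed for the jitter draw.
#' @return list with `dataset` (a [ptycho_dataset] holding nominal
#'   positions) and `truth` (list: `positions` actually scanned, `object`,
#'   `probes`).
#' @export
simulate_ptycho <- function(object, probes, grid, jitter_px = 0, spec,
                            noise = NULL, seed = 1) {
  if (is_complex_field(probes)) probes <- list(probes)
  box <- nrow(ad_val(probes[[1]]$re))
  nr <- nrow(ad_val(object$re)); nc <- ncol(ad_val(object$re))
  r0 <- rep((seq_len(grid$rows) - 1) * grid$step, times = grid$cols)
  c0 <- rep((seq_len(grid$cols) - 1) * grid$step, each = grid$rows)
  nominal <- cbind(r0, c0)
  N <- nrow(nominal)
  actual <- nominal + with_seed(seed, matrix(stats::runif(2 * N, -jitter_px, jitter_px), N, 2))
  if (jitter_px == 0) actual <- nominal
  actual[, 1] <- pmin(pmax(actual[, 1], 0), nr - box)
  actual[, 2] <- pmin(pmax(actual[, 2], 0), nc - box)
  if (any(nominal[, 1] < 0 | nominal[, 1] + box > nr |
          nominal[, 2] < 0 | nominal[, 2] + box > nc))
    stop("scan grid extends outside the object")
  intensities <- lapply(seq_len(N), function(i) {
    I <- ptycho_forward_intensity(object, probes, actual[i, ], spec)
    add_noise(ad_val(I), noise)
  })
  list(dataset = ptycho_dataset(intensities, nominal, spec),
       truth = list(positions = actual, object = object, probes = probes))
}
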
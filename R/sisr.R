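# Blind single-image super-resolution: joint recovery of the HR image and
# the unknown blur kernel, with Fourier ring correlation for resolution
# assessment.

#' Degradation model specification
#'
#' @param factor integer downscale factor (detector pixel-size increase).
#' @param kernel_size odd blur-kernel side length (default 13).
#' @param noise_sd standard deviation of additive noise (simulation only).
#' @return a `degradation_spec`.
#' @export
degradation_spec <- function(factor = 4L, kernel_size = 13L, noise_sd = 0) {
  if (kernel_size %% 2L == 0L) stop("kernel size must be odd")
  if (factor < 1L) stop("factor must be a positive integer")
  structure(list(factor = as.integer(factor),
                 kernel_size = as.integer(kernel_size),
                 noise_sd = noise_sd),
            class = "degradation_spec")
}

#' Apply the degradation model
#'
#' `y = B H x`: same-size blur with the kernel followed by factor-binning
#' (noise is added only by the simulator, never here).
#'
#' @param x HR image (tape node allowed).
#' @param h blur kernel (tape node allowed).
#' @param spec a [degradation_spec].
#' @return LR image of shape `dim(x) / factor`.
#' @export
degrade <- function(x, h, spec) {
  b <- blur2d(x, h)
  if (spec$factor > 1L) downsample(b, spec$factor) else b
}

#' Normalized Gaussian blur kernel
#'
#' @param size odd side length; `sigma` standard deviation in pixels.
#' @param sigma Gaussian width.
#' @return unit-sum `size x size` kernel.
#' @export
gaussian_kernel <- function(size, sigma) {
  if (size %% 2L == 0L) stop("kernel size must be odd")
  c0 <- (size + 1) / 2
  g <- outer(seq_len(size), seq_len(size),
             function(i, j) exp(-((i - c0)^2 + (j - c0)^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Super-resolution loss
#'
#' `Huber(B H x, y; delta) + lambda1 TV(x) + lambda2 ||h||_1`: robust data
#' fidelity on the degraded simulation, edge-preserving smoothness on the HR
#' image, and sparsity on the kernel.
#'
#' @param x HR image estimate; `h` kernel estimate (tape nodes allowed).
#' @param h blur kernel estimate.
#' @param y measured LR image.
#' @param weights a [loss_weights] (`lambda1` = TV weight, `lambda2` =
#'   kernel-L1 weight, `delta` = Huber knee).
#' @param spec a [degradation_spec].
#' @return scalar loss.
#' @export
sisr_loss <- function(x, h, y, weights, spec) {
  total <- huber(degrade(x, h, spec), y, weights$delta)
  if (weights$lambda1 > 0)
    total <- ad_add(total, ad_mul(tv2d(x), weights$lambda1))
  if (weights$lambda2 > 0)
    total <- ad_add(total, ad_mul(l1_norm(h), weights$lambda2))
  total
}

#' Blind super-resolution reconstruction
#'
#' Joint minimization over the HR image and the blur kernel.  The image is
#' initialized by bilinear upsampling of the data; the kernel by a unit-sum
#' centered Gaussian of width `factor / 2`.
#'
#' @param y LR measured image.
#' @param spec a [degradation_spec].
#' @param lambda1 TV weight (default `1e-3 * max(|y|)`).
#' @param lambda2 kernel L1 weight (default `1e-2 * max(|y|)`).
#' @param delta Huber knee (default 1).
#' @param method,max_iter,tol optimizer settings.
#' @param nonneg_kernel optionally reparameterize the kernel to be
#'   nonnegative (softplus); off by default (the model constrains the kernel
#'   only through its L1 norm).
#' @return list: `image` (HR estimate), `kernel`, `result`.
#' @export
super_resolve <- function(y, spec, lambda1 = 1e-3 * max(abs(y)),
                          lambda2 = 1e-2 * max(abs(y)), delta = 1,
                          method = "lbfgs", max_iter = 600L, tol = 1e-10,
                          nonneg_kernel = FALSE) {
  w <- loss_weights(lambda1 = lambda1, lambda2 = lambda2, delta = delta)
  x0 <- bilinear_upsample(y, spec$factor)
  h0 <- gaussian_kernel(spec$kernel_size, spec$factor / 2)
  # warm-up: sharpen the image under the initial kernel before the joint
  # refinement; starting the joint problem cold lets the (much smaller)
  # kernel absorb the whole residual while the image stays at its
  # interpolation initialization
  warm <- run_or_partial(function(p) sisr_loss(p$x, h0, y, w, spec),
                         list(x = x0), method, max_iter, tol)
  x0 <- warm$par$x
  if (nonneg_kernel) {
    v0 <- matrix(softplus_inv(pmax(h0, 1e-8)), spec$kernel_size)
    loss <- function(p) sisr_loss(p$x, ad_softplus(p$h), y, w, spec)
    res <- run_or_partial(loss, list(x = x0, h = v0), method, max_iter, tol)
    kernel <- ad_val(ad_softplus(res$par$h))
  } else {
    loss <- function(p) sisr_loss(p$x, p$h, y, w, spec)
    res <- run_or_partial(loss, list(x = x0, h = h0), method, max_iter, tol)
    kernel <- res$par$h
  }
  res$trace <- c(warm$trace, res$trace)
  res$iterations <- length(res$trace)
  list(image = res$par$x, kernel = kernel, result = res)
}

#' Peak signal-to-noise ratio
#'
#' @param x,ref congruent images; the peak defaults to the reference range.
#' @param peak optional peak value.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, peak = max(ref) - min(ref)) {
  mse <- mean((x - ref)^2)
  10 * log10(peak^2 / mse)
}

#' Normalized kernel cross-correlation after center alignment
#'
#' Maximum normalized cross-correlation between two kernels over all integer
#' relative shifts, removing the shift ambiguity inherent to joint
#' image/kernel recovery.
#'
#' @param h,ref kernels of identical odd size.
#' @return correlation in [-1, 1].
#' @export
kernel_correlation <- function(h, ref) {
  k <- nrow(h)
  m <- k %/% 2
  pad <- matrix(0, k + 2 * m, k + 2 * m)
  pad[m + seq_len(k), m + seq_len(k)] <- h
  # cross-correlation over all relative shifts with the reference fully
  # inside the padded support
  num <- conv2d_plain(pad, rot180(ref))
  max(num) / sqrt(sum(h^2) * sum(ref^2))
}

#' Fourier ring correlation
#'
#' Per-ring normalized cross-correlation of the two images' spectra, with
#' the one-bit information threshold per ring,
#' `T(n) = (0.5 + 2.4142/sqrt(n)) / (1.5 + 1.4142/sqrt(n))`
#' where `n` counts the Fourier pixels in the ring.  The crossing is the
#' first ring frequency at which the correlation falls below the threshold.
#'
#' @param a,b congruent square images.
#' @param n_rings number of rings (default: half the image side).
#' @return an `frc_curve`: data.frame columns `freq` (cycles/pixel),
#'   `correlation`, `threshold`, `n_pixels`, with attribute `crossing`.
#' @export
frc <- function(a, b, n_rings = floor(nrow(a) / 2)) {
  if (!identical(dim(a), dim(b)) || nrow(a) != ncol(a))
    stop("frc requires two congruent square images")
  n <- nrow(a)
  Fa <- fftshift2(stats::fft(a))
  Fb <- fftshift2(stats::fft(b))
  c0 <- floor(n / 2) + 1
  ri <- matrix(seq_len(n) - c0, n, n)
  rj <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  rad <- sqrt(ri^2 + rj^2) / n            # cycles / pixel
  edges <- seq(0, 0.5, length.out = n_rings + 1)
  freq <- numeric(n_rings); corr <- numeric(n_rings)
  thr <- numeric(n_rings); npx <- integer(n_rings)
  for (k in seq_len(n_rings)) {
    sel <- rad > edges[k] & rad <= edges[k + 1]
    npx[k] <- sum(sel)
    freq[k] <- (edges[k] + edges[k + 1]) / 2
    if (npx[k] == 0) { corr[k] <- NA; thr[k] <- NA; next }
    num <- Re(sum(Fa[sel] * Conj(Fb[sel])))
    den <- sqrt(sum(Mod(Fa[sel])^2) * sum(Mod(Fb[sel])^2))
    corr[k] <- if (den > 0) num / den else 0
    thr[k] <- (0.5 + 2.4142 / sqrt(npx[k])) / (1.5 + 1.4142 / sqrt(npx[k]))
  }
  out <- data.frame(freq = freq, correlation = corr, threshold = thr,
                    n_pixels = npx)
  below <- which(!is.na(corr) & corr < thr)
  attr(out, "crossing") <- if (length(below)) freq[min(below)] else 0.5
  class(out) <- c("frc_curve", "data.frame")
  out
}

#' @rdname frc
#' @param curve an `frc_curve`.
#' @export
frc_crossing <- function(curve) attr(curve, "crossing")
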
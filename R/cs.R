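# Compressive-sensing reconstruction of sparsely sampled scan images, with
# an optional co-estimated slowly varying beam-intensity background.

synth_basis <- function(x, basis, levels) {
  if (basis == "dct") idct2(x) else idwt2(x, levels)
}

#' Compressive-sensing loss
#'
#' `||Phi Psi x - y||^2 + lambda1 ||x||_1`, where `Psi` synthesizes the image
#' from transform coefficients (orthonormal DCT by default, wavelet by
#' config) and `Phi` keeps only the sampled pixels.
#'
#' @param x coefficient matrix (tape node allowed), congruent with `y`.
#' @param mask a [sampling_mask] or logical matrix.
#' @param y measured image, zero-filled outside the mask support.
#' @param weights a [loss_weights] (uses `lambda1`).
#' @param basis `"dct"` or `"wavelet"`.
#' @param levels wavelet decomposition levels.
#' @return scalar loss (tape node if `x` is taped).
#' @export
cs_loss <- function(x, mask, y, weights = loss_weights(), basis = c("dct", "wavelet"),
                    levels = 3L) {
  basis <- match.arg(basis)
  sim <- apply_mask(synth_basis(x, basis, levels), mask)
  total <- l2_fidelity(sim, y)
  if (weights$lambda1 > 0)
    total <- ad_add(total, ad_mul(l1_norm(x), weights$lambda1))
  total
}

#' Background-corrected compressive-sensing loss
#'
#' Joint model of the latent coefficients and a slowly varying beam-intensity
#' field `w`: `||Phi Psi x - y * Phi w||^2 + lambda1 ||x||_1 + lambda2
#' TV1D(w)` with `w` serialized in raster (column-major) order.  The data are
#' modulated on the measurement side, so the recovered `w` estimates the
#' reciprocal of the true gain (see the methods vignette).
#'
#' @param x coefficient matrix; `w` background field congruent with `y`.
#' @inheritParams cs_loss
#' @param w background field (tape node allowed).
#' @return scalar loss.
#' @export
cs_background_loss <- function(x, w, mask, y, weights = loss_weights(),
                               basis = c("dct", "wavelet"), levels = 3L) {
  basis <- match.arg(basis)
  sim <- apply_mask(synth_basis(x, basis, levels), mask)
  data_side <- ad_mul(y, apply_mask(w, mask))
  total <- l2_fidelity(sim, data_side)
  if (weights$lambda1 > 0)
    total <- ad_add(total, ad_mul(l1_norm(x), weights$lambda1))
  if (weights$lambda2 > 0)
    total <- ad_add(total, ad_mul(tv1d(w), weights$lambda2))
  total
}

#' Reconstruct a sparsely sampled image
#'
#' Minimizes the compressive-sensing loss from zero-initialized coefficients
#' and returns the synthesized image.  As `lambda1 -> 0` the measured pixels
#' of the reconstruction approach the data.
#'
#' @param y measured image (zero off-mask).
#' @param mask a [sampling_mask].
#' @param lambda1 L1 weight on the coefficients; default `1e-3 * max(|y|)`.
#' @param basis,levels sparsifying basis configuration.
#' @param method,max_iter,tol optimizer settings (see [minimize()]).
#' @return list: `image` (the synthesized reconstruction), `coeffs`,
#'   `result` (an `optim_result`).  An optimizer abort returns the partial
#'   best-so-far state with a warning.
#' @export
reconstruct_cs <- function(y, mask, lambda1 = 1e-3 * max(abs(y)),
                           basis = c("dct", "wavelet"), levels = 3L,
                           method = "lbfgs", max_iter = 500L, tol = 1e-10) {
  basis <- match.arg(basis)
  m <- mask_values(mask)
  if (!any(m)) stop("mask fraction must be positive")
  w <- loss_weights(lambda1 = lambda1)
  loss <- function(p) cs_loss(p$x, m, y, w, basis, levels)
  res <- run_or_partial(loss, list(x = zeros_like(y)), method, max_iter, tol)
  img <- ad_val(synth_basis(res$par$x, basis, levels))
  list(image = img, coeffs = res$par$x, result = res)
}

# softplus reparameterization keeping the background strictly positive
softplus_inv <- function(y) log(expm1(y))

#' Reconstruct with joint background estimation
#'
#' Joint minimization over the coefficients and the beam-intensity field
#' from `x0 = 0`, `w0 = 1`; `w` is kept strictly positive through a softplus
#' reparameterization and is reported normalized to `median(w) = 1` (the
#' model fixes the image/background product, not their individual scales).
#'
#' @inheritParams reconstruct_cs
#' @param lambda2 TV weight on the serialized background; default
#'   `1e-2 * max(|y|)`.
#' @return list: `image` (de-striped reconstruction, rescaled to the
#'   median-normalized background), `background` (`w`, median 1), `coeffs`,
#'   `result`.
#' @export
reconstruct_cs_background <- function(y, mask, lambda1 = 1e-3 * max(abs(y)),
                                      lambda2 = 3e-3 * max(abs(y)),
                                      basis = c("dct", "wavelet"), levels = 3L,
                                      method = "lbfgs", max_iter = 1500L,
                                      tol = 1e-10) {
  basis <- match.arg(basis)
  m <- mask_values(mask)
  if (!any(m)) stop("mask fraction must be positive")
  w <- loss_weights(lambda1 = lambda1, lambda2 = lambda2)
  v0 <- matrix(softplus_inv(1), nrow(y), ncol(y))  # w0 = softplus(v0) = 1
  loss <- function(p) {
    wfield <- ad_add(ad_softplus(p$v), 1e-6)
    cs_background_loss(p$x, wfield, m, y, w, basis, levels)
  }
  res <- run_or_partial(loss, list(x = zeros_like(y), v = v0), method, max_iter, tol)
  wfield <- ad_val(ad_softplus(res$par$v)) + 1e-6
  s <- stats::median(wfield)
  img <- ad_val(synth_basis(res$par$x, basis, levels)) / s
  list(image = img, background = wfield / s, coeffs = res$par$x, result = res)
}

run_or_partial <- function(loss, params, method, max_iter, tol, ...) {
  tryCatch(
    minimize(loss, params, method = method, max_iter = max_iter, tol = tol, ...),
    adxray_optim_abort = function(e) {
      warning("optimizer aborted (", conditionMessage(e),
              "); returning best partial state")
      e$partial
    })
}
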
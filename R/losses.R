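# Fidelity terms and regularizers as differentiable scalar functionals.
# All reductions are sums (not means), so regularization weights follow the
# composite-loss conventions of the reconstruction models.

#' Loss weights
#'
#' Container for the regularization weights of the composite losses:
#' `lambda1` (L1 weight on transform coefficients / TV weight on the image),
#' `lambda2` (TV or kernel-L1 weight) and the Huber knee `delta` (default 1).
#'
#' @param lambda1,lambda2 nonnegative reals.
#' @param delta positive Huber threshold.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 0, lambda2 = 0, delta = 1) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be nonnegative")
  if (delta <= 0) stop("delta must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, delta = delta),
            class = "loss_weights")
}

#' Squared-error data fidelity
#'
#' Sum of squared elementwise differences between a simulation and the data.
#'
#' @param sim,data congruent 2D arrays (tape nodes allowed).
#' @return scalar (tape node if any input is taped).
#' @export
l2_fidelity <- function(sim, data) {
  sv <- ad_val(sim); dv <- ad_val(data)
  if (!identical(dim_or_len(sv), dim_or_len(dv)))
    stop("simulation and data shapes differ")
  d <- ad_sub(sim, data)
  ad_sum(ad_mul(d, d))
}

#' L1 norm
#'
#' Sum of absolute values; for a [complex_field], sum of moduli.  The
#' subgradient at zero is taken as 0.
#'
#' @param x array, tape node, or [complex_field].
#' @return scalar.
#' @export
l1_norm <- function(x) {
  if (is_complex_field(x)) {
    return(ad_sum(ad_cplx_modulus(x)))
  }
  ad_sum(ad_abs(x))
}

# elementwise complex modulus with the subgradient 0 at the origin
ad_cplx_modulus <- function(field) {
  m2 <- ad_cplx_mod2(field)
  m2v <- ad_val(m2)
  m <- sqrt(m2v)
  inv <- ifelse(m > 0, 0.5 / pmax(m, 1e-300), 0)
  ad_make(m, list(m2), list(function(g) g * inv))
}

#' Huber fidelity
#'
#' Elementwise symmetric Huber loss on the residual, summed: quadratic
#' (`r^2 / 2`) for `|r| < delta`, linear (`delta * (|r| - delta/2)`) beyond,
#' continuously differentiable at the knee.  As `delta -> Inf` it approaches
#' half the squared-error fidelity.
#'
#' @param sim,data congruent arrays (tape nodes allowed).
#' @param delta positive knee parameter (default 1).
#' @return scalar.
#' @export
huber <- function(sim, data, delta = 1) {
  if (delta <= 0) stop("delta must be positive")
  r <- ad_sub(sim, data)
  rv <- ad_val(r)
  quad <- abs(rv) < delta            # branch mask, constant on the tape
  m <- quad * 1
  q <- ad_mul(ad_mul(r, r), 0.5)
  l <- ad_sub(ad_mul(ad_abs(r), delta), delta^2 / 2)
  ad_sum(ad_add(ad_mul(q, m), ad_mul(l, 1 - m)))
}

#' Isotropic 2D total variation
#'
#' `sum over interior pixels of sqrt(epsilon + dr^2 + dc^2)` with forward
#' row/column differences.  `epsilon > 0` keeps the gradient finite on flat
#' regions (default 1e-8).  `squared = TRUE` switches to the anisotropic
#' squared variant `sum(dr^2 + dc^2)`.
#'
#' @param image 2D matrix (tape node allowed).
#' @param epsilon nonnegative smoothing constant.
#' @param squared use the squared (anisotropic) variant.
#' @return scalar.
#' @export
tv2d <- function(image, epsilon = 1e-8, squared = FALSE) {
  if (epsilon < 0) stop("epsilon must be nonnegative")
  v <- check_image_2d(image, "tv2d input")
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2 || nc < 2) stop("tv2d needs at least a 2x2 image")
  dr <- ad_sub(ad_block(image, 2:nr, 1:(nc - 1)), ad_block(image, 1:(nr - 1), 1:(nc - 1)))
  dc <- ad_sub(ad_block(image, 1:(nr - 1), 2:nc), ad_block(image, 1:(nr - 1), 1:(nc - 1)))
  s <- ad_add(ad_mul(dr, dr), ad_mul(dc, dc))
  if (squared) return(ad_sum(s))
  ad_sum(ad_sqrt(ad_add(s, epsilon)))
}

#' 1D total variation of a serialized array
#'
#' Sum of absolute successive differences of the raster-serialized (column
#' stacked, matching R's array order) input; the smoothness penalty of the
#' beam-intensity background model.
#'
#' @param x vector or matrix (tape node allowed); length >= 2.
#' @return scalar.
#' @export
tv1d <- function(x) {
  v <- ad_val(x)
  n <- length(v)
  if (n < 2) stop("tv1d needs at least two elements")
  flat <- ad_linear(x, fwd = function(u) as.vector(u),
                    adj = function(g) { z <- v; z[] <- g; z })
  d <- ad_sub(ad_linear(flat, function(u) u[-1], function(g) c(0, g)),
              ad_linear(flat, function(u) u[-n], function(g) c(g, 0)))
  ad_sum(ad_abs(d))
}

#' Magnitude-excess L1 penalty
#'
#' Energy-conservation regularizer for a transmission function: sums the
#' moduli of exactly those elements whose modulus exceeds 1, so compliant
#' elements contribute neither value nor gradient.
#'
#' @param field a [complex_field] (tape nodes allowed in its parts).
#' @return scalar.
#' @export
magnitude_excess_l1 <- function(field) {
  stopifnot(is_complex_field(field))
  m2 <- ad_cplx_mod2(field)
  sel <- (ad_val(m2) > 1) * 1     # selection mask, constant on the tape
  if (all(sel == 0)) {
    # keep a taped zero so gradients exist (and are exactly zero)
    return(ad_mul(ad_sum(ad_mul(m2, 0)), 1))
  }
  ad_sum(ad_mul(ad_cplx_modulus(field), sel))
}
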
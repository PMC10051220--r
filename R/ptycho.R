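# Differentiable far-/near-field ptychography: multimode-probe forward
# model, magnitude-excess regularized loss, and reconstruction with optional
# refinement of probe, scan positions and propagation distance.

#' Ptychography dataset
#'
#' Measured diffraction intensities with their nominal scan positions and
#' the propagation geometry.  Positions are top-left corners of the probe
#' box in object pixels (0-based, real-valued).
#'
#' @param intensities list of nonnegative detector-box matrices (or an
#'   H x W x N array).
#' @param positions N x 2 matrix of nominal scan positions.
#' @param spec a [propagation_spec] (its `regime` selects the propagator).
#' @return a `ptycho_dataset`.
#' @export
ptycho_dataset <- function(intensities, positions, spec) {
  if (is.array(intensities) && length(dim(intensities)) == 3L)
    intensities <- lapply(seq_len(dim(intensities)[3]),
                          function(k) intensities[, , k])
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (length(intensities) != nrow(positions))
    stop("pattern count must equal position count")
  if (any(vapply(intensities, function(m) any(m < 0), logical(1))))
    stop("intensities must be nonnegative")
  structure(list(intensities = intensities, positions = positions,
                 spec = spec),
            class = "ptycho_dataset")
}

#' Circular illumination probe
#'
#' A disk of the given radius with a soft (feathered) edge, unit phase, with
#' total power normalized to `power`.  A reasonable initial estimate for a
#' pinhole or zone-plate illumination.
#'
#' @param box probe box side length (pixels).
#' @param radius disk radius in pixels (default `box / 4`).
#' @param power total intensity (sum of squared moduli).
#' @return a [complex_field].
#' @export
disk_probe <- function(box, radius = box / 4, power = 1) {
  c0 <- (box + 1) / 2
  r <- sqrt(outer(seq_len(box), seq_len(box),
                  function(i, j) (i - c0)^2 + (j - c0)^2))
  amp <- 1 / (1 + exp((r - radius) / 1.5))   # feathered edge
  amp <- amp * sqrt(power / sum(amp^2))
  complex_field(amp, matrix(0, box, box))
}

propagate_by <- function(field, spec, z = NULL) {
  if (spec$regime == "far-field") farfield_propagate(field)
  else angular_spectrum_propagate(field, spec, z = z)
}

#' Ptychographic forward intensity
#'
#' Simulated diffraction pattern at one scan position: the object is cropped
#' at the (real-valued) position, modulated by each probe mode, propagated
#' to the detector, and the per-mode intensities are summed incoherently.
#'
#' @param object [complex_field] transmission function (tape nodes allowed).
#' @param probes list of probe-mode [complex_field]s (or a single one).
#' @param position length-2 `(rx, ry)` or a list of two tape scalars.
#' @param spec a [propagation_spec].
#' @param z optional distance override (tape scalar for refinement).
#' @return detector-box intensity matrix (taped if any input is).
#' @export
ptycho_forward_intensity <- function(object, probes, position, spec, z = NULL) {
  if (is_complex_field(probes)) probes <- list(probes)
  box <- nrow(ad_val(probes[[1]]$re))
  view <- subpixel_crop(object, position, box)
  total <- 0
  for (p in probes) {
    ex <- ad_cplx_mul(p, view)
    d <- propagate_by(complex_field(ex$re, ex$im), spec, z = z)
    total <- ad_add(total, ad_cplx_mod2(d))
  }
  total
}

#' Ptychography loss
#'
#' `sum_i || I_i(object, probes, r_i, z) - y_i ||^2 + lambda1 * magnitude
#' excess L1(object)`: intensity fidelity over all scan positions plus the
#' energy-conservation penalty on object moduli above 1.
#'
#' @param object,probes as in [ptycho_forward_intensity()].
#' @param dataset a [ptycho_dataset].
#' @param positions optional override of the dataset positions: an N x 2
#'   matrix or a list with taped vectors `rx`, `ry`.
#' @param z optional distance override (tape scalar).
#' @param weights a [loss_weights] (uses `lambda1`).
#' @return scalar loss.
#' @export
ptycho_loss <- function(object, probes, dataset, positions = NULL, z = NULL,
                        weights = loss_weights()) {
  if (is_complex_field(probes)) probes <- list(probes)
  N <- length(dataset$intensities)
  total <- 0
  for (i in seq_len(N)) {
    pos <- if (is.null(positions)) dataset$positions[i, ]
           else if (is.list(positions)) list(ad_pick(positions$rx, i),
                                             ad_pick(positions$ry, i))
           else positions[i, ]
    I <- ptycho_forward_intensity(object, probes, pos, dataset$spec, z = z)
    total <- ad_add(total, l2_fidelity(I, dataset$intensities[[i]]))
  }
  if (weights$lambda1 > 0)
    total <- ad_add(total, ad_mul(magnitude_excess_l1(object), weights$lambda1))
  total
}

# normalize total probe power to `target` (differentiable), fixing the
# probe/object scale ambiguity during probe refinement
normalize_probe_power <- function(probes, target) {
  pw <- 0
  for (p in probes) pw <- ad_add(pw, ad_sum(ad_cplx_mod2(p)))
  s <- ad_sqrt(ad_div(target, pw))
  lapply(probes, function(p) complex_field(ad_mul(p$re, s), ad_mul(p$im, s)))
}

#' Ptychographic reconstruction
#'
#' Minimizes the ptychography loss over the object duplet and, per the
#' `refine` flags, the probe modes, the scan positions and the propagation
#' distance.  The object starts at unit magnitude and zero phase; positions
#' and distance start at the dataset's nominal values.  During probe
#' refinement the total probe power is renormalized (differentiably) to the
#' dataset's mean total intensity, fixing the probe/object scale ambiguity.
#'
#' @param dataset a [ptycho_dataset].
#' @param object_shape length-2 object field-of-view (pixels); default just
#'   covers the scan extent plus the probe box.
#' @param probe_init list of probe-mode [complex_field]s, a single one, or
#'   NULL for a disk estimate scaled to the data power.
#' @param refine list of flags: `probe`, `positions`, `distance`.
#' @param lambda1 magnitude-excess weight.
#' @param method,max_iter,tol,lr optimizer settings (`"adam"` default; the
#'   quasi-Newton path suits small instances).
#' @return list: `object` ([complex_field]), `probes`, `positions` (N x 2),
#'   `z`, `result`.
#' @export
reconstruct_ptycho <- function(dataset, object_shape = NULL, probe_init = NULL,
                               refine = list(probe = FALSE, positions = FALSE,
                                             distance = FALSE),
                               lambda1 = 0, method = "adam", max_iter = 300L,
                               tol = 1e-10, lr = 0.05) {
  N <- length(dataset$intensities)
  if (N < 4) stop("need at least 4 overlapping positions (diversity)")
  box <- nrow(dataset$intensities[[1]])
  # with position refinement the estimates may wander a few pixels past the
  # nominal scan extent; pad the default field of view and shift positions
  # into the padded frame, undoing both on output
  margin <- if (isTRUE(refine$positions)) 4L else 0L
  pad_frame <- is.null(object_shape)
  if (pad_frame) {
    extent <- c(ceiling(max(dataset$positions[, 1])) + box,
                ceiling(max(dataset$positions[, 2])) + box)
    object_shape <- extent + 2L * margin
    dataset$positions <- dataset$positions + margin
  } else margin <- 0L
  mean_power <- mean(vapply(dataset$intensities, sum, numeric(1)))
  if (is.null(probe_init)) probe_init <- disk_probe(box, power = mean_power)
  if (is_complex_field(probe_init)) probe_init <- list(probe_init)
  M <- length(probe_init)
  w <- loss_weights(lambda1 = max(lambda1, 0), lambda2 = 0)

  params <- list(obj_re = matrix(1, object_shape[1], object_shape[2]),
                 obj_im = matrix(0, object_shape[1], object_shape[2]))
  if (isTRUE(refine$probe)) {
    for (m in seq_len(M)) {
      params[[paste0("probe_re", m)]] <- ad_val(probe_init[[m]]$re)
      params[[paste0("probe_im", m)]] <- ad_val(probe_init[[m]]$im)
    }
  }
  if (isTRUE(refine$positions)) {
    params$rx <- dataset$positions[, 1]
    params$ry <- dataset$positions[, 2]
  }
  # distance is refined as a dimensionless multiplier of the nominal value:
  # a raw coordinate in meters is orders of magnitude out of scale with the
  # object duplet and derails the quasi-Newton line search
  z0 <- dataset$spec$distance_m
  if (isTRUE(refine$distance)) params$zmul <- 1

  loss <- function(p) {
    object <- complex_field(p$obj_re, p$obj_im)
    probes <- if (isTRUE(refine$probe)) {
      pr <- lapply(seq_len(M), function(m)
        complex_field(p[[paste0("probe_re", m)]], p[[paste0("probe_im", m)]]))
      normalize_probe_power(pr, mean_power)
    } else probe_init
    positions <- if (isTRUE(refine$positions)) list(rx = p$rx, ry = p$ry) else NULL
    z <- if (isTRUE(refine$distance)) ad_mul(p$zmul, z0) else NULL
    ptycho_loss(object, probes, dataset, positions = positions, z = z, weights = w)
  }
  any_refine <- isTRUE(refine$probe) || isTRUE(refine$positions) ||
    isTRUE(refine$distance)
  warm_trace <- numeric(0)
  if (any_refine) {
    # warm-up: settle the object at the nominal geometry before opening the
    # geometry parameters, which otherwise chase the transient of a cold
    # object estimate
    warm_loss <- function(p) {
      object <- complex_field(p$obj_re, p$obj_im)
      z <- if (isTRUE(refine$distance)) z0 else NULL
      ptycho_loss(object, probe_init, dataset, z = z, weights = w)
    }
    # keep the warm-up short when the distance starts off-nominal: fitting
    # the object hard at a wrong distance entrenches the error
    warm_iter <- if (isTRUE(refine$distance)) max(20L, max_iter %/% 5L)
                 else max_iter
    warm <- run_or_partial(warm_loss,
                           params[c("obj_re", "obj_im")],
                           method, warm_iter, tol)
    params$obj_re <- warm$par$obj_re
    params$obj_im <- warm$par$obj_im
    warm_trace <- warm$trace
  }
  # with geometry refinement the object and the refined parameters chase
  # each other; restarted quasi-Newton blocks (fresh limited-memory state)
  # keep making progress where one long run stalls
  n_blocks <- if (isTRUE(refine$distance)) 5L else if (any_refine) 2L else 1L
  res <- NULL
  for (blk in seq_len(n_blocks)) {
    res <- run_or_partial(loss, params, method, max_iter, tol)
    params <- res$par
    warm_trace <- c(warm_trace, if (blk < n_blocks) res$trace)
  }
  res$trace <- c(warm_trace, res$trace)
  res$iterations <- length(res$trace)
  probes_out <- if (isTRUE(refine$probe)) {
    pr <- lapply(seq_len(M), function(m)
      complex_field(res$par[[paste0("probe_re", m)]],
                    res$par[[paste0("probe_im", m)]]))
    lapply(normalize_probe_power(pr, mean_power), function(p)
      complex_field(ad_val(p$re), ad_val(p$im)))
  } else probe_init
  obj_re <- res$par$obj_re; obj_im <- res$par$obj_im
  positions <- if (isTRUE(refine$positions)) cbind(res$par$rx, res$par$ry)
               else dataset$positions
  if (margin > 0L) {
    keep_r <- margin + seq_len(object_shape[1] - 2L * margin)
    keep_c <- margin + seq_len(object_shape[2] - 2L * margin)
    obj_re <- obj_re[keep_r, keep_c]
    obj_im <- obj_im[keep_r, keep_c]
    positions <- positions - margin
  }
  list(object = complex_field(obj_re, obj_im),
       probes = probes_out,
       positions = positions,
       z = if (isTRUE(refine$distance)) res$par$zmul * z0 else z0,
       result = res)
}

#' Masked complex correlation up to a global phase
#'
#' `|sum(mask * a * conj(b))| / sqrt(sum(mask |a|^2) sum(mask |b|^2))`: the
#' modulus of the normalized complex inner product, which is invariant to
#' the global phase ambiguity of phase retrieval.
#'
#' @param a,b [complex_field]s (or complex matrices).
#' @param mask optional logical/0-1 weight matrix (e.g. the illuminated
#'   region).
#' @return correlation in [0, 1].
#' @export
complex_correlation <- function(a, b, mask = NULL) {
  ca <- if (is_complex_field(a)) as.complex.complex_field(a) else a
  cb <- if (is_complex_field(b)) as.complex.complex_field(b) else b
  m <- if (is.null(mask)) 1 else (mask != 0) * 1
  num <- Mod(sum(m * ca * Conj(cb)))
  den <- sqrt(sum(m * Mod(ca)^2) * sum(m * Mod(cb)^2))
  if (den == 0) return(0)
  num / den
}

#' Illumination coverage mask
#'
#' Total probe intensity deposited over all scan positions, thresholded at a
#' fraction of its maximum; the region where the object is actually
#' constrained by the data.
#'
#' @param object_shape length-2 field-of-view.
#' @param probes probe mode(s).
#' @param positions N x 2 scan positions (top-left corners).
#' @param threshold fraction of the peak coverage (default 0.1).
#' @return logical matrix.
#' @export
coverage_mask <- function(object_shape, probes, positions, threshold = 0.1) {
  if (is_complex_field(probes)) probes <- list(probes)
  box <- nrow(ad_val(probes[[1]]$re))
  footprint <- Reduce(`+`, lapply(probes, function(p) ad_val(ad_cplx_mod2(p))))
  cov <- matrix(0, object_shape[1], object_shape[2])
  for (i in seq_len(nrow(positions))) {
    r <- round(positions[i, 1]); c_ <- round(positions[i, 2])
    cov[r + seq_len(box), c_ + seq_len(box)] <-
      cov[r + seq_len(box), c_ + seq_len(box)] + footprint
  }
  cov >= threshold * max(cov)
}
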
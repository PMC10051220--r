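# Differentiable operator primitives.  Each operator accepts plain numeric
# arrays (eager evaluation) or tape nodes (gradient propagation); complex
# fields travel as (real, imaginary) duplets.  All coordinates are pixel
# centered, with the affine origin at the image center.

## ---- complex field container ----------------------------------------------

#' Complex field as a real/imaginary duplet
#'
#' The package carries complex 2D fields as two congruent real grids so that
#' the real-valued tape differentiates through them (Wirtinger calculus
#' realized as ordinary differentiation of the paired coordinates).
#'
#' @param re,im real matrices of identical shape (tape nodes allowed).
#' @return object of class `complex_field` with elements `re` and `im`.
#' @export
complex_field <- function(re, im = NULL) {
  if (is.null(im)) im <- zeros_like(ad_val(re))
  rv <- ad_val(re); iv <- ad_val(im)
  if (!identical(dim(rv), dim(iv)))
    stop("real and imaginary parts must have identical shapes")
  if (!is_ad_node(re) && !is_ad_node(im) && (any(!is.finite(rv)) || any(!is.finite(iv))))
    stop("complex field values must be finite")
  structure(list(re = re, im = im), class = "complex_field")
}

is_complex_field <- function(x) inherits(x, "complex_field")

#' @export
as.complex.complex_field <- function(x, ...) {
  matrix(complex(real = as.vector(ad_val(x$re)), imaginary = as.vector(ad_val(x$im))),
         nrow = nrow(ad_val(x$re)))
}

#' @rdname complex_field
#' @param z complex matrix to split into a duplet.
#' @export
field_from_complex <- function(z) complex_field(Re(z), Im(z))

## ---- orthonormal 2D DCT ----------------------------------------------------

.op_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- paste0("dct", n)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  j <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(j, 2 * j + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  .op_cache[[key]] <- C
  C
}

check_image_2d <- function(x, what = "input") {
  v <- ad_val(x)
  if (is.null(dim(v)) || length(dim(v)) != 2L)
    stop(what, " must be a 2D array")
  invisible(v)
}

#' Orthonormal 2D discrete cosine transform
#'
#' Type-II DCT with orthonormal scaling, so `idct2(dct2(x)) == x` to
#' floating tolerance and Parseval's identity holds exactly.  `dct2` is the
#' analysis direction (image to coefficients); `idct2` is the synthesis used
#' as the sparsifying basis of the compressive-sensing model.
#'
#' @param x 2D image (for `dct2`) or coefficient grid (for `idct2`); tape
#'   nodes allowed.
#' @return transformed 2D array (or tape node).
#' @export
dct2 <- function(x) {
  v <- check_image_2d(x, "dct2 input")
  Cr <- dct_matrix(nrow(v)); Cc <- dct_matrix(ncol(v))
  ad_matmul2(x, A = Cr, B = t(Cc))
}

#' @rdname dct2
#' @export
idct2 <- function(x) {
  v <- check_image_2d(x, "idct2 input")
  Cr <- dct_matrix(nrow(v)); Cc <- dct_matrix(ncol(v))
  ad_matmul2(x, A = t(Cr), B = Cc)
}

## ---- periodized biorthogonal-4.4 DWT ---------------------------------------

# Analysis filter bank of the biorthogonal 4.4 (9/7) wavelet.
bior44_dec_lo <- c(0, 0.03782845550726404, -0.023849465019556843,
                   -0.11062440441843718, 0.37740285561283066, 0.85269867900889385,
                   0.37740285561283066, -0.11062440441843718, -0.023849465019556843,
                   0.03782845550726404)
bior44_dec_hi <- c(0, -0.064538882628697058, 0.040689417609164058,
                   0.41809227322161724, -0.7884856164055829, 0.41809227322161724,
                   0.040689417609164058, -0.064538882628697058, 0, 0)

# One-level periodized analysis matrix for even signal length n: the first
# n/2 rows decimate the circular lowpass correlation, the rest the highpass.
# The synthesis matrix is its exact inverse, so perfect reconstruction and
# the adjoint are exact by construction; both are cached per length.
dwt_matrices <- function(n) {
  if (n %% 2L != 0L) stop("periodized DWT requires even length, got ", n)
  key <- paste0("dwt", n)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  L <- length(bior44_dec_lo)
  center <- L %/% 2  # filter alignment; any fixed phase preserves PR
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (t in seq_len(L)) {
      j <- ((2 * (k - 1) + (t - 1) - center) %% n) + 1
      W[k, j] <- W[k, j] + bior44_dec_lo[t]
      W[n / 2 + k, j] <- W[n / 2 + k, j] + bior44_dec_hi[t]
    }
  }
  S <- solve(W)
  .op_cache[[key]] <- list(W = W, S = S)
  .op_cache[[key]]
}

check_dwt_levels <- function(nr, nc, levels) {
  if (levels < 1L) stop("levels must be >= 1")
  if (levels > floor(log2(min(nr, nc))))
    stop("level count ", levels, " exceeds log2 of the smallest dimension")
  r <- nr; c <- nc
  for (l in seq_len(levels)) {
    if (r %% 2L != 0L || c %% 2L != 0L)
      stop("dimension becomes odd at level ", l,
           " (", r, "x", c, "); periodized DWT needs even sizes at every level")
    r <- r / 2; c <- c / 2
  }
  invisible(TRUE)
}

#' Multi-level 2D biorthogonal-4.4 wavelet transform
#'
#' Periodized separable filter-bank transform with the coefficients stored
#' in the classic packed layout: at each level the running top-left block is
#' replaced by `[LL LH; HL HH]`.  `idwt2(dwt2(x)) == x` to machine precision
#' (the synthesis bank is the exact inverse of the analysis bank).  Used as
#' the per-slice sparsifying basis of the tomography model.
#'
#' @param x 2D image (`dwt2`) or packed coefficient matrix (`idwt2`); tape
#'   nodes allowed.  Every intermediate dimension must be even.
#' @param levels number of decomposition levels (default 3).
#' @return packed coefficient matrix (`dwt2`) or image (`idwt2`).
#' @export
dwt2 <- function(x, levels = 3L) {
  v <- check_image_2d(x, "dwt2 input")
  check_dwt_levels(nrow(v), ncol(v), levels)
  out <- x
  r <- nrow(v); c <- ncol(v)
  for (l in seq_len(levels)) {
    blk <- if (r == nrow(v) && c == ncol(v)) out else ad_block(out, 1:r, 1:c)
    Wr <- dwt_matrices(r)$W; Wc <- dwt_matrices(c)$W
    tr <- ad_matmul2(blk, A = Wr, B = t(Wc))
    out <- if (r == nrow(v) && c == ncol(v)) tr else
      block_paste(out, tr, 1:r, 1:c)
    r <- r / 2; c <- c / 2
  }
  out
}

#' @rdname dwt2
#' @export
idwt2 <- function(x, levels = 3L) {
  v <- check_image_2d(x, "idwt2 input")
  check_dwt_levels(nrow(v), ncol(v), levels)
  nr <- nrow(v); nc <- ncol(v)
  sizes <- cbind(nr / 2^(seq_len(levels) - 1), nc / 2^(seq_len(levels) - 1))
  out <- x
  for (l in seq(levels, 1L)) {
    r <- sizes[l, 1]; c <- sizes[l, 2]
    blk <- if (r == nr && c == nc) out else ad_block(out, 1:r, 1:c)
    Sr <- dwt_matrices(r)$S; Sc <- dwt_matrices(c)$S
    tr <- ad_matmul2(blk, A = Sr, B = t(Sc))
    out <- if (r == nr && c == nc) tr else block_paste(out, tr, 1:r, 1:c)
  }
  out
}

# replace a block of `base` with `blk` (both possibly nodes):
# out = base - embed(block(base)) + embed(blk)
block_paste <- function(base, blk, rows, cols) {
  bv <- ad_val(base)
  shape <- dim(bv)
  hole <- ad_embed(ad_block(base, rows, cols), shape, rows, cols)
  ad_add(ad_sub(base, hole), ad_embed(blk, shape, rows, cols))
}

## ---- affine warps ----------------------------------------------------------

#' Affine maps on centered pixel coordinates
#'
#' A 2x3 matrix `[L | t]` sending output pixel offsets `(dr, dc)` from the
#' image center to input sampling coordinates `L %*% c(dr, dc) + t` (also
#' relative to the center).  Units are pixels; rotations are in degrees,
#' counterclockwise in (row, col) index space.
#'
#' @param linear 2x2 linear part (must be invertible, |det| > 1e-12).
#' @param offset length-2 translation (pixels).
#' @return an `affine_map` (2x3 numeric matrix).
#' @export
affine_map <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (any(!is.finite(linear)) || any(!is.finite(offset)))
    stop("affine map entries must be finite")
  if (abs(linear[1, 1] * linear[2, 2] - linear[1, 2] * linear[2, 1]) <= 1e-12)
    stop("affine map linear part is not invertible")
  structure(cbind(linear, as.numeric(offset)), class = "affine_map")
}

#' @rdname affine_map
#' @param theta_deg rotation angle in degrees.
#' @export
affine_rotation <- function(theta_deg) {
  th <- theta_deg * pi / 180
  affine_map(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
}

#' @rdname affine_map
#' @param dx,dy shift in rows and columns (pixels).
#' @export
affine_shift <- function(dx, dy) affine_map(diag(2), c(dx, dy))

#' @rdname affine_map
#' @param a,b two affine maps; returns the map applying `b` then `a`.
#' @export
affine_compose <- function(a, b) {
  La <- a[, 1:2]; Lb <- b[, 1:2]
  affine_map(La %*% Lb, La %*% b[, 3] + a[, 3])
}

# copy the overlap of `src` shifted so that dst[r, c] = src[r0 + r - 1,
# c0 + c - 1], zero outside; pure block move (no per-pixel indexing)
shift_gather <- function(src, r0, c0, nro, nco) {
  nr <- nrow(src); nc <- ncol(src)
  out <- matrix(0, nro, nco)
  rd <- max(1, 2 - r0):min(nro, nr - r0 + 1)
  cd <- max(1, 2 - c0):min(nco, nc - c0 + 1)
  if (length(rd) > 0 && length(cd) > 0 && rd[1] <= rd[length(rd)] &&
      cd[1] <= cd[length(cd)])
    out[rd, cd] <- src[rd + r0 - 1, cd + c0 - 1]
  out
}

# adjoint of shift_gather: add g into an (nr x nc) zero matrix at the offset
shift_scatter <- function(g, r0, c0, nr, nc) {
  nro <- nrow(g); nco <- ncol(g)
  out <- matrix(0, nr, nc)
  rd <- max(1, 2 - r0):min(nro, nr - r0 + 1)
  cd <- max(1, 2 - c0):min(nco, nc - c0 + 1)
  if (length(rd) > 0 && length(cd) > 0 && rd[1] <= rd[length(rd)] &&
      cd[1] <= cd[length(cd)])
    out[rd + r0 - 1, cd + c0 - 1] <- g[rd, cd]
  out
}

# accumulate vals at (possibly duplicated) linear indices: radix order +
# grouped cumsum, avoiding any character conversion
index_accumulate <- function(acc, idx, vals) {
  n <- length(idx)
  if (n == 0L) return(acc)
  o <- order(idx)
  si <- idx[o]; sv <- vals[o]
  cs <- cumsum(sv)
  last <- which(c(si[-1] != si[-n], TRUE))
  sums <- cs[last] - c(0, cs[last[-length(last)]])
  at <- si[last]
  acc[at] <- acc[at] + sums
  acc
}

# Core taped warp: bilinear sampling of `img` at 1-based real coordinates
# (xs = row, ys = col), zero outside support.  Differentiable in the image
# and in the sampling coordinates.  Pure translations (constant fractional
# offset, unit-spaced grid) take a block-copy fast path.
ad_warp_core <- function(img, xs, ys) {
  iv <- ad_val(img)
  nr <- nrow(iv); nc <- ncol(iv)
  xv <- ad_val(xs); yv <- ad_val(ys)
  nro <- nrow(xv); nco <- ncol(xv)

  # translation detection: xs depends only on the row index with unit steps,
  # ys only on the column index with unit steps
  base_r <- xv[1, 1] + matrix(seq_len(nro) - 1, nro, nco)
  base_c <- yv[1, 1] + matrix(seq_len(nco) - 1, nro, nco, byrow = TRUE)
  if (max(abs(xv - base_r)) == 0 && max(abs(yv - base_c)) == 0) {
    x0 <- floor(xv[1, 1]); y0 <- floor(yv[1, 1])
    fx <- xv[1, 1] - x0;   fy <- yv[1, 1] - y0
    v00 <- shift_gather(iv, x0, y0, nro, nco)
    v10 <- shift_gather(iv, x0 + 1, y0, nro, nco)
    v01 <- shift_gather(iv, x0, y0 + 1, nro, nco)
    v11 <- shift_gather(iv, x0 + 1, y0 + 1, nro, nco)
    w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
    w01 <- (1 - fx) * fy;       w11 <- fx * fy
    out <- v00 * w00 + v10 * w10 + v01 * w01 + v11 * w11
    vjp_img <- function(g) {
      shift_scatter(g * w00, x0, y0, nr, nc) +
        shift_scatter(g * w10, x0 + 1, y0, nr, nc) +
        shift_scatter(g * w01, x0, y0 + 1, nr, nc) +
        shift_scatter(g * w11, x0 + 1, y0 + 1, nr, nc)
    }
    vjp_xs <- function(g) g * ((v10 - v00) * (1 - fy) + (v11 - v01) * fy)
    vjp_ys <- function(g) g * ((v01 - v00) * (1 - fx) + (v11 - v10) * fx)
    return(ad_make(out, list(img, xs, ys), list(vjp_img, vjp_xs, vjp_ys)))
  }

  x0 <- floor(xv); y0 <- floor(yv)
  fx <- xv - x0; fy <- yv - y0
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nr & yi >= 1 & yi <= nc
    idx <- pmin(pmax(xi, 1), nr) + (pmin(pmax(yi, 1), nc) - 1) * nr
    v <- iv[idx]
    v[!ok] <- 0
    list(v = v, ok = ok, idx = idx)
  }
  g00 <- gather(x0, y0);     g10 <- gather(x0 + 1, y0)
  g01 <- gather(x0, y0 + 1); g11 <- gather(x0 + 1, y0 + 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  out <- g00$v * w00 + g10$v * w10 + g01$v * w01 + g11$v * w11
  dim(out) <- dim(xv)

  vjp_img <- function(g) {
    acc <- numeric(nr * nc)
    gv <- as.vector(g)
    sel <- g00$ok
    acc <- index_accumulate(acc, g00$idx[sel], (gv * as.vector(w00))[sel])
    sel <- g10$ok
    acc <- index_accumulate(acc, g10$idx[sel], (gv * as.vector(w10))[sel])
    sel <- g01$ok
    acc <- index_accumulate(acc, g01$idx[sel], (gv * as.vector(w01))[sel])
    sel <- g11$ok
    acc <- index_accumulate(acc, g11$idx[sel], (gv * as.vector(w11))[sel])
    matrix(acc, nr, nc)
  }
  vjp_xs <- function(g) {
    d <- (g10$v - g00$v) * (1 - fy) + (g11$v - g01$v) * fy
    out <- g * d
    dim(out) <- dim(xv)
    out
  }
  vjp_ys <- function(g) {
    d <- (g01$v - g00$v) * (1 - fx) + (g11$v - g10$v) * fx
    out <- g * d
    dim(out) <- dim(xv)
    out
  }
  ad_make(out, list(img, xs, ys), list(vjp_img, vjp_xs, vjp_ys))
}

# Build sampling coordinate grids for an affine map whose six entries may be
# tape scalars; output grid congruent with the input image.
warp_by_entries <- function(img, a11, a12, a21, a22, tx, ty) {
  iv <- ad_val(img)
  nr <- nrow(iv); nc <- ncol(iv)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  U <- matrix(seq_len(nr) - cr, nr, nc)
  V <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)
  xs <- ad_add(ad_add(ad_mul(a11, U), ad_mul(a12, V)), ad_add(tx, cr))
  ys <- ad_add(ad_add(ad_mul(a21, U), ad_mul(a22, V)), ad_add(ty, cc))
  ad_warp_core(img, xs, ys)
}

#' Bilinear affine resampling
#'
#' Resamples the input at affinely mapped coordinates (bilinear, zero-filled
#' outside support), with the affine origin at the image center.  For a
#' [complex_field] the two duplet parts are warped independently.
#' Differentiable with respect to the image values; for gradients with
#' respect to map parameters see the taped construction used by
#' [rotate_volume()] and the alignment losses.
#'
#' @param image 2D matrix or [complex_field] (tape nodes allowed).
#' @param map an [affine_map].
#' @return warped image of the same type.
#' @export
affine_warp <- function(image, map) {
  if (!inherits(map, "affine_map")) map <- affine_map(map[, 1:2], map[, 3])
  if (is_complex_field(image)) {
    return(complex_field(affine_warp(image$re, map), affine_warp(image$im, map)))
  }
  check_image_2d(image, "affine_warp input")
  warp_by_entries(image, map[1, 1], map[1, 2], map[2, 1], map[2, 2],
                  map[1, 3], map[2, 3])
}

# taped warp with shift (dx, dy) and rotation phi_deg (about the center),
# all three possibly tape scalars: sampling coords rotate by phi then shift.
warp_shift_rot <- function(img, dx, dy, phi_deg) {
  phi <- ad_mul(phi_deg, pi / 180)
  c_ <- ad_cos(phi); s_ <- ad_sin(phi)
  warp_by_entries(img, c_, ad_neg(s_), s_, c_, dx, dy)
}

#' In-plane rotation of a volume about a vertical axis
#'
#' Applies the same 2D rotation to every horizontal slice, about the axis
#' point `center` (1-based pixel coordinates in the slice; defaults to the
#' slice center).  Differentiable in the slice values and in `theta_deg`
#' when these are tape nodes.
#'
#' @param volume list of 2D slices, a single matrix, or a 3D array with the
#'   slice index last.
#' @param theta_deg rotation angle, degrees (tape scalar allowed).
#' @param center optional axis coordinates `(rx, ry)` in pixels.
#' @return same container type as the input.
#' @export
rotate_volume <- function(volume, theta_deg, center = NULL) {
  single <- is.matrix(volume) || is_ad_node(volume)
  slices <- as_slice_list(volume)
  out <- lapply(slices, function(s) rotate_slice(s, theta_deg, center))
  if (single) out[[1]] else restore_volume(out, volume)
}

rotate_slice <- function(slice, theta_deg, center) {
  sv <- ad_val(slice)
  nr <- nrow(sv); nc <- ncol(sv)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  if (is.null(center)) center <- c(cr, cc)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("rotation center must lie inside the slice bounds")
  if (!is_ad_node(theta_deg)) {
    # fixed-geometry fast path: the bilinear resampling at a constant angle
    # is a constant sparse linear operator, cached per (shape, angle, center)
    W <- rotation_operator(nr, nc, theta_deg, center)
    return(ad_linear(slice,
                     fwd = function(v) matrix(as.numeric(W %*% as.vector(v)), nr, nc),
                     adj = function(g) matrix(as.numeric(Matrix::crossprod(W, as.vector(g))), nr, nc)))
  }
  th <- ad_mul(theta_deg, pi / 180)
  c_ <- ad_cos(th); s_ <- ad_sin(th)
  U <- matrix(seq_len(nr) - center[1], nr, nc)
  V <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  xs <- ad_add(ad_sub(ad_mul(c_, U), ad_mul(s_, V)), center[1])
  ys <- ad_add(ad_add(ad_mul(s_, U), ad_mul(c_, V)), center[2])
  ad_warp_core(slice, xs, ys)
}

# sparse bilinear-interpolation matrix for an in-plane rotation
rotation_operator <- function(nr, nc, theta_deg, center) {
  key <- sprintf("rot_%d_%d_%.12g_%.12g_%.12g", nr, nc, theta_deg,
                 center[1], center[2])
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  th <- theta_deg * pi / 180
  U <- matrix(seq_len(nr) - center[1], nr, nc)
  V <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  xs <- cos(th) * U - sin(th) * V + center[1]
  ys <- sin(th) * U + cos(th) * V + center[2]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- as.vector(xs - x0); fy <- as.vector(ys - y0)
  n <- nr * nc
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(xi, yi, w) {
    ok <- as.vector(xi >= 1 & xi <= nr & yi >= 1 & yi <= nc) & w > 0
    rows <<- c(rows, which(ok))
    cols <<- c(cols, (as.vector(xi)[ok] + (as.vector(yi)[ok] - 1) * nr))
    vals <<- c(vals, w[ok])
  }
  add(x0, y0, (1 - fx) * (1 - fy))
  add(x0 + 1, y0, fx * (1 - fy))
  add(x0, y0 + 1, (1 - fx) * fy)
  add(x0 + 1, y0 + 1, fx * fy)
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  .op_cache[[key]] <- W
  W
}

as_slice_list <- function(volume) {
  if (is.list(volume) && !is_complex_field(volume)) return(volume)
  if (is.matrix(volume) || is_ad_node(volume)) return(list(volume))
  if (is.array(volume) && length(dim(volume)) == 3L)
    return(lapply(seq_len(dim(volume)[3]), function(k) volume[, , k]))
  stop("volume must be a matrix, a 3D array, or a list of slices")
}

restore_volume <- function(slices, template) {
  if (is.array(template) && length(dim(template)) == 3L) {
    vals <- lapply(slices, ad_val)
    array(unlist(vals), dim = c(dim(vals[[1]]), length(vals)))
  } else slices
}

## ---- projector, mask, blur, binning ----------------------------------------

#' Riemann-sum projection along the beam axis
#'
#' Line-integral projector of the parallel-beam model: each slice is summed
#' along its columns (the beam axis) and scaled by the integration `step`.
#' Linear, with the exact adjoint (back-smearing) used by the tape.
#'
#' @param volume list of slices, matrix, or 3D array (slice index last).
#' @param step integration step length (> 0).
#' @return matrix of shape (n_slices x n_rows); a single slice gives 1 row.
#' @export
riemann_project <- function(volume, step = 1) {
  if (step <= 0) stop("step must be positive")
  slices <- as_slice_list(volume)
  rows <- lapply(slices, function(s) project_slice(s, step))
  if (any(vapply(rows, is_ad_node, logical(1)))) return(rows)
  do.call(rbind, rows)
}

#' @rdname riemann_project
#' @param slice single 2D slice (tape node allowed); returns the projected
#'   row vector.
#' @export
project_slice <- function(slice, step = 1) {
  sv <- ad_val(slice)
  nc <- ncol(sv)
  ad_linear(slice,
            fwd = function(v) step * rowSums(v),
            adj = function(g) matrix(rep(step * g, nc), ncol = nc))
}

#' Sparse-sampling mask application
#'
#' Keeps image values where the mask is true and zeroes the rest (the
#' measurement operator of the sparse-scan model).  Idempotent.
#'
#' @param image 2D matrix (tape node allowed).
#' @param mask logical or 0/1 matrix congruent with `image`.
#' @return masked image.
#' @export
apply_mask <- function(image, mask) {
  iv <- ad_val(image)
  m <- mask_values(mask)
  if (!identical(dim(iv), dim(m))) stop("image and mask shapes differ")
  mnum <- m * 1
  ad_linear(image, fwd = function(v) v * mnum, adj = function(g) g * mnum)
}

#' @rdname apply_mask
#' @details `mask_values()` extracts the logical keep-matrix from a
#'   `sampling_mask` or plain logical/0-1 matrix.
#' @export
mask_values <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$keep else (mask != 0)
}

# plain same-size zero-padded 2D correlation
conv2d_plain <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  P <- matrix(0, nr + kr - 1, nc + kc - 1)
  P[pr + seq_len(nr), pc + seq_len(nc)] <- img
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      k <- ker[a, b]
      if (k != 0) out <- out + k * P[a:(a + nr - 1), b:(b + nc - 1)]
    }
  }
  out
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

#' Same-size 2D blur (correlation)
#'
#' Zero-padded correlation with an odd-sized stencil, differentiable in both
#' the image and the kernel (the system-blur operator of the degradation
#' model).
#'
#' @param image 2D matrix (tape node allowed).
#' @param kernel odd-sized 2D stencil (tape node allowed).
#' @return blurred image, same shape as the input.
#' @export
blur2d <- function(image, kernel) {
  iv <- ad_val(image); kv <- ad_val(kernel)
  if (nrow(kv) %% 2L == 0L || ncol(kv) %% 2L == 0L)
    stop("blur kernel dimensions must be odd")
  nr <- nrow(iv); nc <- ncol(iv)
  kr <- nrow(kv); kc <- ncol(kv)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  out <- conv2d_plain(iv, kv)
  vjp_img <- function(g) conv2d_plain(g, rot180(kv))
  vjp_ker <- function(g) {
    P <- matrix(0, nr + kr - 1, nc + kc - 1)
    P[pr + seq_len(nr), pc + seq_len(nc)] <- iv
    K <- matrix(0, kr, kc)
    for (a in seq_len(kr)) for (b in seq_len(kc))
      K[a, b] <- sum(g * P[a:(a + nr - 1), b:(b + nc - 1)])
    K
  }
  ad_make(out, list(image, kernel), list(vjp_img, vjp_ker))
}

#' Mean-binning downsample
#'
#' factor x factor block averaging, modelling detector pixel integration
#' (the pixel-size-increase operator of the degradation model).  Linear,
#' with the exact adjoint used by the tape.
#'
#' @param image 2D matrix with dimensions divisible by `factor`.
#' @param factor positive integer binning factor.
#' @return binned image of shape `dim(image) / factor`.
#' @export
downsample <- function(image, factor) {
  iv <- ad_val(image)
  f <- as.integer(factor)
  nr <- nrow(iv); nc <- ncol(iv)
  if (nr %% f != 0L || nc %% f != 0L)
    stop("image dimensions must be divisible by the binning factor")
  fwd <- function(v) {
    m <- colMeans(array(v, dim = c(f, nr %/% f, nc)), dims = 1)
    t(colMeans(array(t(m), dim = c(f, nc %/% f, nr %/% f)), dims = 1))
  }
  adj <- function(g) {
    g[rep(seq_len(nr %/% f), each = f), rep(seq_len(nc %/% f), each = f)] / (f * f)
  }
  ad_linear(image, fwd, adj)
}

#' Bilinear upsampling by an integer factor
#'
#' Center-aligned bilinear interpolation with replicated borders; the
#' interpolation baseline (and initialization) for super-resolution.
#'
#' @param image 2D matrix (plain values).
#' @param factor integer upsampling factor.
#' @return `factor`-times larger image.
#' @export
bilinear_upsample <- function(image, factor) {
  nr <- nrow(image); nc <- ncol(image)
  f <- as.integer(factor)
  # output pixel centers mapped into input pixel units (center-aligned)
  xs_out <- ((seq_len(nr * f) - 0.5) / f) + 0.5 - 0.5
  ys_out <- ((seq_len(nc * f) - 0.5) / f) + 0.5 - 0.5
  xs <- matrix(xs_out, nr * f, nc * f)
  ys <- matrix(ys_out, nr * f, nc * f, byrow = TRUE)
  # clamp to the support so borders replicate rather than fade to zero
  xs <- pmin(pmax(xs, 1), nr)
  ys <- pmin(pmax(ys, 1), nc)
  ad_val(ad_warp_core(image, xs, ys))
}

## ---- propagators ------------------------------------------------------------

fftshift_idx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2)))

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

centered_fft <- function(cm, inverse = FALSE) {
  n <- sqrt(length(cm))
  if (!inverse) fftshift2(stats::fft(ifftshift2(cm))) / sqrt(length(cm))
  else fftshift2(stats::fft(ifftshift2(cm), inverse = TRUE)) / sqrt(length(cm))
}

#' Far-field (Fraunhofer) propagation
#'
#' Centered, orthonormal 2D Fourier transform of the duplet field: the
#' zero-frequency component sits at the array center and total intensity is
#' conserved exactly.  Set `inverse = TRUE` for back-propagation.
#'
#' @param field a [complex_field] (tape nodes allowed in its parts).
#' @param inverse propagate backwards (inverse transform).
#' @return propagated [complex_field].
#' @export
farfield_propagate <- function(field, inverse = FALSE) {
  stopifnot(is_complex_field(field))
  out <- ad_complex_linear(field$re, field$im,
                           fwd = function(cm) centered_fft(cm, inverse = inverse),
                           adjc = function(g) centered_fft(g, inverse = !inverse))
  complex_field(out$re, out$im)
}

#' Propagation geometry
#'
#' Wavelength may be given directly or via photon energy
#' (`lambda = hc / E`, with `hc = 1.23984193e-6` eV m).
#'
#' @param distance_m propagation distance z in meters (finite; sign allowed).
#' @param pixel_size_m detector/object pixel size in meters (> 0).
#' @param wavelength_m wavelength in meters (> 0), or NULL to derive from
#'   `energy_ev`.
#' @param energy_ev photon energy in eV.
#' @param regime `"far-field"` (single Fourier transform) or
#'   `"angular-spectrum"` (transfer-function propagation).
#' @return a `propagation_spec`.
#' @export
propagation_spec <- function(distance_m, pixel_size_m, wavelength_m = NULL,
                             energy_ev = NULL,
                             regime = c("far-field", "angular-spectrum")) {
  regime <- match.arg(regime)
  if (is.null(wavelength_m)) {
    if (is.null(energy_ev)) stop("give wavelength_m or energy_ev")
    wavelength_m <- 1.23984193e-6 / energy_ev
  }
  if (wavelength_m <= 0) stop("wavelength must be positive")
  if (pixel_size_m <= 0) stop("pixel size must be positive")
  if (!is.finite(distance_m)) stop("distance must be finite")
  structure(list(distance_m = distance_m, pixel_size_m = pixel_size_m,
                 wavelength_m = wavelength_m,
                 energy_ev = if (is.null(energy_ev)) 1.23984193e-6 / wavelength_m else energy_ev,
                 regime = regime),
            class = "propagation_spec")
}

# z-independent angular-spectrum prefactors, cached per (n, wavelength,
# pixel): only the transforms and one elementwise product remain per call.
as_prefactors <- function(n, wavelength, pixel) {
  key <- sprintf("as_%d_%.17g_%.17g", n, wavelength, pixel)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  f <- (seq_len(n) - 1 - floor(n / 2)) / (n * pixel)   # centered frequencies
  fx <- matrix(f, n, n)
  fy <- matrix(f, n, n, byrow = TRUE)
  arg <- 1 / wavelength^2 - fx^2 - fy^2
  prop <- arg > 0
  kz <- matrix(0, n, n)
  kz[prop] <- 2 * pi * sqrt(arg[prop])
  .op_cache[[key]] <- list(kz = kz, mask = prop * 1)
  .op_cache[[key]]
}

#' Angular-spectrum (near-field) propagation
#'
#' Transfer-function propagation `IF{ exp(i kz z) . F{field} }` on a square
#' grid, with evanescent components suppressed.  The z-independent spatial
#' frequency factors are precomputed and cached; only the two transforms and
#' one elementwise product run per call.  Differentiable in the field and,
#' when `z` is a tape scalar, in the propagation distance.
#'
#' @param field square [complex_field].
#' @param spec a [propagation_spec].
#' @param z optional override of `spec$distance_m` (tape scalar allowed).
#' @return propagated [complex_field].
#' @export
angular_spectrum_propagate <- function(field, spec, z = NULL) {
  stopifnot(is_complex_field(field), inherits(spec, "propagation_spec"))
  n <- nrow(ad_val(field$re))
  if (n != ncol(ad_val(field$re))) stop("angular-spectrum propagation requires a square field")
  if (is.null(z)) z <- spec$distance_m
  pf <- as_prefactors(n, spec$wavelength_m, spec$pixel_size_m)
  F <- ad_complex_linear(field$re, field$im,
                         fwd = function(cm) centered_fft(cm),
                         adjc = function(g) centered_fft(g, inverse = TRUE))
  phase <- ad_mul(z, pf$kz)
  Hre <- ad_mul(ad_cos(phase), pf$mask)
  Him <- ad_mul(ad_sin(phase), pf$mask)
  prod <- ad_cplx_mul(F, list(re = Hre, im = Him))
  out <- ad_complex_linear(prod$re, prod$im,
                           fwd = function(cm) centered_fft(cm, inverse = TRUE),
                           adjc = function(g) centered_fft(g))
  complex_field(out$re, out$im)
}

#' Differentiable sub-pixel crop
#'
#' Extracts a `box x box` window of the object whose top-left corner sits at
#' the real-valued position `(rx, ry)` (0-based pixels), by bilinear affine
#' resampling.  At integer positions it equals plain slicing; unlike
#' slicing, it is differentiable with respect to the position, which is what
#' makes scan-position refinement possible.
#'
#' @param object 2D matrix or [complex_field].
#' @param position length-2 numeric `(rx, ry)`, or a list of two tape
#'   scalars for position refinement.
#' @param box window side length in pixels.
#' @return cropped window of the same type as `object`.
#' @export
subpixel_crop <- function(object, position, box) {
  if (is_complex_field(object)) {
    return(complex_field(subpixel_crop(object$re, position, box),
                         subpixel_crop(object$im, position, box)))
  }
  ov <- ad_val(object)
  nr <- nrow(ov); nc <- ncol(ov)
  rx <- if (is.list(position)) position[[1]] else position[1]
  ry <- if (is.list(position)) position[[2]] else position[2]
  rxv <- ad_val(rx); ryv <- ad_val(ry)
  if (rxv < 0 || ryv < 0 || rxv + box > nr || ryv + box > nc)
    stop("crop box extends outside the object support")
  base_r <- matrix(seq_len(box), box, box)         # 1-based within the box
  base_c <- matrix(seq_len(box), box, box, byrow = TRUE)
  xs <- ad_add(rx, base_r)
  ys <- ad_add(ry, base_c)
  ad_warp_core(object, xs, ys)
}
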
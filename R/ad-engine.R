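# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every differentiable operator in the package is composed from the taped
# primitives below.  A node records its value, the parent nodes it was
# computed from and one vector-Jacobian product (VJP) per parent; the
# backward sweep walks the tape in reverse creation order and accumulates
# gradients by the chain rule.  Operations called on plain numeric arrays
# (no node among the arguments, or no active tape) evaluate eagerly and
# return plain arrays, so the same forward code serves both simulation and
# differentiation.

.ad <- new.env(parent = emptyenv())
.ad$last <- NULL
.ad$active <- FALSE

ad_tape_begin <- function() {
  .ad$last <- NULL
  .ad$active <- TRUE
  invisible(NULL)
}

ad_tape_end <- function() {
  .ad$active <- FALSE
  .ad$last <- NULL
  invisible(NULL)
}

#' Test whether an object is a tape node; read a node-or-array's value
#'
#' @param x any object.
#' @return `is_ad_node`: logical. `ad_val`: the plain numeric value.
#' @export
is_ad_node <- function(x) inherits(x, "ad_node")

#' @rdname is_ad_node
#' @export
ad_val <- function(x) if (is_ad_node(x)) x$value else x

# the tape is an intrusive linked list in reverse creation order: O(1)
# registration, and the backward sweep simply follows `prev` pointers
ad_register <- function(node) {
  node$prev <- .ad$last
  .ad$last <- node
  node
}

# Create a tape node.  `parents` may mix nodes and plain arrays; VJPs of
# non-node parents are dropped.  Returns a plain value when nothing needs
# differentiating.
ad_make <- function(value, parents, vjps) {
  if (!.ad$active) return(value)
  keep <- vapply(parents, is_ad_node, logical(1))
  if (!any(keep)) return(value)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents[keep]
  node$vjps <- vjps[keep]
  class(node) <- "ad_node"
  ad_register(node)
}

#' Create an optimizable tape parameter
#'
#' Registers `value` as a leaf node on the active tape so that gradients of
#' any downstream scalar can be read back from it.  Used internally by
#' [ad_grad()]; exposed for building custom differentiable expressions.
#'
#' @param value numeric array (any shape).
#' @return a tape node carrying `value`.
#' @keywords internal
ad_param <- function(value) {
  if (!.ad$active) stop("no active tape; ad_param() must run inside ad_grad()")
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$vjps <- list()
  class(node) <- "ad_node"
  ad_register(node)
}

ad_backward <- function(root) {
  if (length(ad_val(root)) != 1L)
    stop("backward pass requires a scalar root")
  if (!is_ad_node(root)) stop("root is a constant; nothing to differentiate")
  root$grad <- 1
  nd <- root
  while (!is.null(nd)) {
    g <- nd$grad
    if (!is.null(g)) {
      ps <- nd$parents
      vs <- nd$vjps
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        contrib <- vs[[j]](g)
        p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
      }
    }
    nd <- nd$prev
  }
  invisible(NULL)
}

#' Evaluate a scalar loss and its gradients
#'
#' Runs `f` on a fresh tape with every element of `params` registered as a
#' leaf, performs the backward sweep, and returns the loss value together
#' with one gradient array per parameter (zero where the loss does not
#' depend on a parameter).
#'
#' @param f function taking a named list of tape nodes and returning a
#'   scalar tape node (or plain scalar if independent of all parameters).
#' @param params named list of numeric arrays.
#' @return list with `value` (scalar) and `grads` (named list of arrays,
#'   congruent with `params`).
#' @examples
#' g <- ad_grad(function(p) ad_sum(ad_mul(p$x, p$x)), list(x = c(1, -2)))
#' g$grads$x  # 2 * x
#' @export
ad_grad <- function(f, params) {
  stopifnot(is.list(params), !is.null(names(params)))
  ad_tape_begin()
  on.exit(ad_tape_end(), add = TRUE)
  leaves <- lapply(params, ad_param)
  out <- f(leaves)
  value <- ad_val(out)
  if (!is.finite(value)) {
    stop(structure(
      class = c("adxray_nonfinite_loss", "error", "condition"),
      list(message = "loss is non-finite at the evaluation point", call = NULL)
    ))
  }
  grads <- if (is_ad_node(out)) {
    ad_backward(out)
    lapply(leaves, function(l) {
      if (is.null(l$grad)) zeros_like(l$value) else l$grad
    })
  } else {
    lapply(params, zeros_like)
  }
  list(value = as.numeric(value), grads = grads)
}

zeros_like <- function(x) {
  z <- x
  z[] <- 0
  z
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

## ---- elementwise primitives ---------------------------------------------

# broadcast helper: scalar-vs-array products/sums; VJP of the scalar side sums
bc_vjp <- function(a_val, g) {
  if (length(a_val) == 1L && length(g) > 1L) sum(g) else g
}

#' @rdname ad_ops
#' @export
ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av + bv, list(a, b), list(
    function(g) bc_vjp(av, g),
    function(g) bc_vjp(bv, g)
  ))
}

#' @rdname ad_ops
#' @export
ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av - bv, list(a, b), list(
    function(g) bc_vjp(av, g),
    function(g) -bc_vjp(bv, g)
  ))
}

#' @rdname ad_ops
#' @export
ad_neg <- function(a) {
  ad_make(-ad_val(a), list(a), list(function(g) -g))
}

#' @rdname ad_ops
#' @export
ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av * bv, list(a, b), list(
    function(g) bc_vjp(av, g * bv),
    function(g) bc_vjp(bv, g * av)
  ))
}

#' @rdname ad_ops
#' @export
ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av / bv, list(a, b), list(
    function(g) bc_vjp(av, g / bv),
    function(g) bc_vjp(bv, -g * av / (bv * bv))
  ))
}

#' Taped array primitives
#'
#' Elementwise and reduction primitives that build the reverse-mode tape.
#' Each accepts tape nodes or plain numeric arrays and returns a node when
#' any argument is a node on an active tape, otherwise a plain array.
#' `ad_abs` uses the subgradient convention sign(0) = 0.
#'
#' @param a,b node or numeric array.
#' @param x node or numeric array.
#' @name ad_ops
#' @return node or numeric array of the operation's value.
#' @export
ad_sum <- function(x) {
  xv <- ad_val(x)
  ad_make(sum(xv), list(x), list(function(g) {
    z <- xv
    z[] <- g
    z
  }))
}

#' @rdname ad_ops
#' @export
ad_abs <- function(x) {
  xv <- ad_val(x)
  s <- sign(xv)  # sign(0) = 0: L1 subgradient convention
  ad_make(abs(xv), list(x), list(function(g) g * s))
}

#' @rdname ad_ops
#' @export
ad_sqrt <- function(x) {
  xv <- ad_val(x)
  r <- sqrt(xv)
  ad_make(r, list(x), list(function(g) g / (2 * r)))
}

#' @rdname ad_ops
#' @export
ad_sin <- function(x) {
  xv <- ad_val(x)
  ad_make(sin(xv), list(x), list(function(g) g * cos(xv)))
}

#' @rdname ad_ops
#' @export
ad_cos <- function(x) {
  xv <- ad_val(x)
  ad_make(cos(xv), list(x), list(function(g) -g * sin(xv)))
}

#' @rdname ad_ops
#' @export
ad_exp <- function(x) {
  xv <- ad_val(x)
  e <- exp(xv)
  ad_make(e, list(x), list(function(g) g * e))
}

# numerically stable softplus: log(1 + exp(x)); derivative = sigmoid(x)
#' @rdname ad_ops
#' @export
ad_softplus <- function(x) {
  xv <- ad_val(x)
  v <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  sig <- 1 / (1 + exp(-xv))
  ad_make(v, list(x), list(function(g) g * sig))
}

## ---- linear / structural primitives -------------------------------------

# Generic linear operator with explicit adjoint: out = fwd(x), VJP = adj(g).
ad_linear <- function(x, fwd, adj) {
  ad_make(fwd(ad_val(x)), list(x), list(function(g) adj(g)))
}

#' @rdname ad_ops
#' @param A,B constant matrices of a two-sided product `A %*% x %*% B`
#'   (either NULL for identity); the workhorse behind the separable
#'   transforms.
#' @export
ad_matmul2 <- function(x, A = NULL, B = NULL) {
  fwd <- function(v) {
    if (!is.null(A)) v <- A %*% v
    if (!is.null(B)) v <- v %*% B
    v
  }
  adj <- function(g) {
    if (!is.null(A)) g <- crossprod(A, g)   # t(A) %*% g
    if (!is.null(B)) g <- tcrossprod(g, B)  # g %*% t(B)
    g
  }
  ad_linear(x, fwd, adj)
}

# extract one element of a vector; adjoint scatters the gradient back
ad_pick <- function(x, i) {
  xv <- ad_val(x)
  ad_linear(x,
            fwd = function(v) v[i],
            adj = function(g) { z <- zeros_like(xv); z[i] <- g; z })
}

# extract a contiguous block; adjoint embeds the gradient back with zeros
ad_block <- function(x, rows, cols) {
  xv <- ad_val(x)
  nr <- nrow(xv); nc <- ncol(xv)
  ad_make(xv[rows, cols, drop = FALSE], list(x), list(function(g) {
    z <- matrix(0, nr, nc)
    z[rows, cols] <- g
    z
  }))
}

# embed a block into a zero matrix of the given shape
ad_embed <- function(x, shape, rows, cols) {
  xv <- ad_val(x)
  out <- matrix(0, shape[1], shape[2])
  out[rows, cols] <- xv
  ad_make(out, list(x), list(function(g) g[rows, cols, drop = FALSE]))
}

## ---- complex duplet helpers ----------------------------------------------

# A complex-linear map L applied to a duplet (re, im).  `fwd` maps a complex
# matrix to a complex matrix; `adjc` is its conjugate adjoint L^H.  The VJP
# of (re, im) -> (Re L(c), Im L(c)) under the real inner product follows
# from  T^t(g_re, g_im) = (Re L^H(g_re + i g_im), Im L^H(g_re + i g_im)).
ad_complex_linear <- function(re, im, fwd, adjc) {
  cval <- complex(real = as.vector(ad_val(re)),
                  imaginary = as.vector(ad_val(im)))
  dimv <- dim_or_len(ad_val(re))
  cm <- array(cval, dim = dimv)
  w <- fwd(cm)
  out_re <- ad_make(Re(w), list(re, im), list(
    function(g) Re(adjc(g)),
    function(g) Im(adjc(g))
  ))
  out_im <- ad_make(Im(w), list(re, im), list(
    function(g) -Im(adjc(g)),
    function(g) Re(adjc(g))
  ))
  list(re = out_re, im = out_im)
}

# duplet complex product: (a.re + i a.im)(b.re + i b.im)
ad_cplx_mul <- function(a, b) {
  list(
    re = ad_sub(ad_mul(a$re, b$re), ad_mul(a$im, b$im)),
    im = ad_add(ad_mul(a$re, b$im), ad_mul(a$im, b$re))
  )
}

#' @rdname ad_ops
#' @export
ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_make(av %*% bv, list(a, b), list(
    function(g) g %*% t(bv),
    function(g) t(av) %*% g))
}

#' @rdname ad_ops
#' @export
ad_cplx_mod2 <- function(a) {
  ad_add(ad_mul(a$re, a$re), ad_mul(a$im, a$im))
}
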
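# Optimization harness with closure semantics, plus the analytic and
# finite-difference gradient oracles used to validate the tape.

#' Linear operator with explicit adjoint
#'
#' @param forward function mapping a domain array to a range array.
#' @param adjoint function mapping a range array back to the domain.
#' @param domain_shape,range_shape integer shape vectors.
#' @return a `linear_operator`.
#' @export
linear_operator <- function(forward, adjoint, domain_shape, range_shape) {
  structure(list(forward = forward, adjoint = adjoint,
                 domain_shape = domain_shape, range_shape = range_shape),
            class = "linear_operator")
}

op_forward <- function(A, x) {
  if (is.matrix(A)) as.vector(A %*% as.vector(x)) else A$forward(x)
}
op_adjoint <- function(A, y) {
  if (is.matrix(A)) as.vector(crossprod(A, as.vector(y))) else A$adjoint(y)
}

flatten_params <- function(params) {
  unlist(lapply(params, as.vector), use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[pos + seq_len(n)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

optim_result <- function(par, trace, converged, stop_reason) {
  structure(list(par = par, trace = trace, iterations = length(trace),
                 converged = converged, stop_reason = stop_reason),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("optim_result: %d evaluations, final loss %.6g, %s (%s)\n",
              x$iterations,
              if (x$iterations) x$trace[x$iterations] else NA_real_,
              if (x$converged) "converged" else "not converged",
              x$stop_reason))
  invisible(x)
}

abort_optim <- function(message, partial) {
  cond <- structure(
    class = c("adxray_optim_abort", "error", "condition"),
    list(message = message, call = NULL, partial = partial))
  stop(cond)
}

#' Minimize a differentiable loss closure
#'
#' Gradient-based minimization of a scalar loss over a named set of array
#' parameters.  Each iteration rebuilds the computational graph (closure
#' semantics): gradients are cleared, the forward model is simulated, the
#' tape is differentiated, and the parameters are updated.  Two methods are
#' provided: `"lbfgs"` (limited-memory quasi-Newton with line search, via
#' [stats::optim]) and `"adam"` (first-order adaptive, for large complex
#' duplet problems).  Runs are deterministic given identical inputs and
#' seed.
#'
#' @param loss function taking the named parameter list (as tape nodes) and
#'   returning a scalar tape node.
#' @param params named list of numeric starting arrays.
#' @param method `"lbfgs"` or `"adam"`.
#' @param max_iter iteration budget (`lbfgs`: optimizer iterations; the
#'   recorded trace holds one entry per loss evaluation).
#' @param tol relative loss-change tolerance; `adam` stops when the relative
#'   change stays below `tol` for 5 consecutive iterations.
#' @param lr adam step size.
#' @param seed optional integer seed (sets the RNG for any stochastic
#'   closure; the built-in methods are deterministic).
#' @return an `optim_result`: `par` (named list), `trace` (loss per recorded
#'   evaluation), `iterations`, `converged`, `stop_reason`.  A non-finite
#'   loss mid-run aborts with a classed condition (`adxray_optim_abort`)
#'   carrying the partial result.
#' @export
minimize <- function(loss, params, method = c("lbfgs", "adam"),
                     max_iter = 200L, tol = 1e-8, lr = 0.05, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(params), !is.null(names(params)))
  if (!is.null(seed)) set.seed(seed)
  v0 <- ad_grad(loss, params)$value  # pre: finite at the initial point
  if (max_iter <= 0L)
    return(optim_result(params, numeric(0), FALSE, "max_iter = 0"))
  if (method == "lbfgs") minimize_lbfgs(loss, params, max_iter, tol)
  else minimize_adam(loss, params, max_iter, tol, lr)
}

minimize_lbfgs <- function(loss, params, max_iter, tol) {
  st <- new.env(parent = emptyenv())
  st$trace <- numeric(0)
  st$last_p <- NULL
  st$last <- NULL
  st$best_par <- params
  st$best <- Inf
  evaluate <- function(p) {
    if (!is.null(st$last_p) && identical(p, st$last_p)) return(st$last)
    pl <- unflatten_params(p, params)
    res <- tryCatch(ad_grad(loss, pl), adxray_nonfinite_loss = function(e) e)
    if (inherits(res, "condition")) {
      abort_optim("non-finite loss during optimization",
                  optim_result(st$best_par, st$trace, FALSE, "nonfinite-loss"))
    }
    st$last_p <- p
    st$last <- res
    st$trace <- c(st$trace, res$value)
    if (res$value < st$best) {
      st$best <- res$value
      st$best_par <- pl
    }
    res
  }
  fn <- function(p) evaluate(p)$value
  gr <- function(p) flatten_params(evaluate(p)$grads)
  ans <- tryCatch(
    stats::optim(flatten_params(params), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter,
                                factr = max(tol / .Machine$double.eps, 10))),
    adxray_optim_abort = function(e) e)
  if (inherits(ans, "adxray_optim_abort")) stop(ans)
  par <- unflatten_params(ans$par, params)
  converged <- ans$convergence == 0
  reason <- if (converged) "relative loss change below tolerance"
            else if (ans$convergence == 1) "max_iter reached"
            else paste0("optim: ", ans$message)
  optim_result(par, st$trace, converged, reason)
}

minimize_adam <- function(loss, params, max_iter, tol, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- flatten_params(params)
  m <- numeric(length(p)); v <- numeric(length(p))
  trace <- numeric(max_iter)
  best_par <- params; best <- Inf
  calm <- 0L
  it <- 0L
  for (it in seq_len(max_iter)) {
    pl <- unflatten_params(p, params)
    res <- tryCatch(ad_grad(loss, pl), adxray_nonfinite_loss = function(e) e)
    if (inherits(res, "condition")) {
      abort_optim("non-finite loss during optimization",
                  optim_result(best_par, trace[seq_len(it - 1L)], FALSE, "nonfinite-loss"))
    }
    trace[it] <- res$value
    if (res$value < best) { best <- res$value; best_par <- pl }
    g <- flatten_params(res$grads)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^it)
    vh <- v / (1 - beta2^it)
    p <- p - lr * mh / (sqrt(vh) + eps)
    if (it > 1) {
      rel <- abs(trace[it] - trace[it - 1]) / max(abs(trace[it - 1]), 1e-300)
      calm <- if (rel < tol) calm + 1L else 0L
      if (calm >= 5L) {
        return(optim_result(unflatten_params(p, params), trace[seq_len(it)],
                            TRUE, "relative loss change below tolerance"))
      }
    }
  }
  optim_result(unflatten_params(p, params), trace, FALSE, "max_iter reached")
}

#' Analytic gradients of the generic linear-model loss
#'
#' For `L(x) = ||Ax - y||^2 + ||x||_1`, the gradient with respect to the
#' latent vector is `2 A^T (Ax - y) + sign(x)` (with sign(0) = 0), and the
#' gradient with respect to a dense operator matrix is the outer product
#' `2 (Ax - y) x^T`.  These serve as independent oracles for the tape.
#'
#' @param A dense matrix or [linear_operator] (`analytic_grad_A` requires a
#'   dense matrix).
#' @param x latent vector; `y` data vector.
#' @return gradient array congruent with `x` (resp. `A`).
#' @export
analytic_grad_x <- function(A, x, y) {
  r <- op_forward(A, x) - as.vector(y)
  g <- 2 * op_adjoint(A, r) + sign(as.vector(x))
  if (!is.null(dim(x))) dim(g) <- dim(x)
  g
}

#' @rdname analytic_grad_x
#' @export
analytic_grad_A <- function(A, x, y) {
  if (!is.matrix(A)) stop("analytic_grad_A requires a dense matrix")
  r <- as.vector(A %*% as.vector(x)) - as.vector(y)
  2 * tcrossprod(r, as.vector(x))
}

#' Central finite-difference gradient
#'
#' The independent oracle for every gradient check: one central difference
#' per coordinate, with the step scaled to the coordinate's magnitude.
#'
#' @param f scalar function of a numeric array.
#' @param x evaluation point.
#' @param eps base step (applied as `eps * max(1, |x_i|)` per coordinate).
#' @return gradient array congruent with `x`.
#' @export
fd_gradient <- function(f, x, eps = 1e-5) {
  if (eps <= 0) stop("eps must be positive")
  g <- x
  g[] <- 0
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fp <- f(xp); fm <- f(xm)
    if (!is.finite(fp) || !is.finite(fm)) stop("non-finite loss evaluation in fd_gradient")
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

#' Compare tape gradients against finite differences
#'
#' Evaluates the closure's tape gradients and central finite differences for
#' every parameter and reports the maximum absolute and relative
#' discrepancies (relative to the larger of the two gradient magnitudes).
#'
#' @param loss closure as in [minimize()].
#' @param params named list of numeric arrays (total dimension <= 1e4).
#' @param eps finite-difference base step.
#' @return data.frame with one row per parameter: `parameter`, `max_abs`,
#'   `max_rel`, `grad_norm`.
#' @export
verify_gradients <- function(loss, params, eps = 1e-5) {
  ntot <- sum(vapply(params, length, numeric(1)))
  if (ntot > 1e4) stop("total parameter dimension exceeds 1e4 (oracle cost)")
  ad <- ad_grad(loss, params)$grads
  rows <- lapply(names(params), function(nm) {
    f <- function(v) {
      pl <- params
      if (!is.null(dim(params[[nm]]))) dim(v) <- dim(params[[nm]])
      pl[[nm]] <- v
      # evaluate eagerly: with no active tape the operators return plain arrays
      as.numeric(ad_val(loss(pl)))
    }
    fd <- fd_gradient(f, params[[nm]], eps)
    ga <- ad[[nm]]
    scale <- max(max(abs(fd)), max(abs(ga)), 1e-8)
    data.frame(parameter = nm,
               max_abs = max(abs(ga - fd)),
               max_rel = max(abs(ga - fd)) / scale,
               grad_norm = sqrt(sum(ga^2)))
  })
  do.call(rbind, rows)
}
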
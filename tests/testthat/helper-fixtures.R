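# shared fixtures: small deterministic images and error metrics

rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))
rmse <- function(x, ref) sqrt(mean((x - ref)^2))

# smooth compactly supported test image (well-behaved under interpolation)
smooth_blob <- function(n, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    img <- matrix(0, n, n)
    gi <- matrix(seq_len(n), n, n)
    gj <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (k in 1:4) {
      cx <- runif(1, 0.3, 0.7) * n
      cy <- runif(1, 0.3, 0.7) * n
      s <- runif(1, 0.1, 0.16) * n
      img <- img + runif(1, 0.5, 1) * exp(-((gi - cx)^2 + (gj - cy)^2) / (2 * s^2))
    }
    img
  })
}

random_field <- function(n, seed = 1) {
  set.seed(seed)
  complex_field(matrix(rnorm(n * n), n), matrix(rnorm(n * n), n))
}

# adjoint dot-product check <Av, u> == <v, A^T u> through the tape
adjoint_gap <- function(op, dom_dim, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(prod(dom_dim)), dom_dim[1], dom_dim[2])
  Av <- ad_val(op(v))
  u <- array(rnorm(length(Av)), dim = dim_or_len_test(Av))
  lhs <- sum(Av * u)
  g <- ad_grad(function(p) ad_sum(ad_mul(op(p$v), u)), list(v = v))$grads$v
  rhs <- sum(v * g)
  abs(lhs - rhs) / max(abs(lhs), 1e-12)
}

dim_or_len_test <- function(x) if (is.null(dim(x))) length(x) else dim(x)
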
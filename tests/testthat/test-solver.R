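# optimizer harness and the independent gradient oracles

test_that("both methods find the minimum of a separable quadratic", {
  cc <- matrix(c(1, -2, 0.5, 3), 2)
  loss <- function(p) l2_fidelity(p$x, cc)
  for (m in c("lbfgs", "adam")) {
    res <- minimize(loss, list(x = matrix(0, 2, 2)), method = m,
                    max_iter = if (m == "adam") 3000 else 100, lr = 0.05)
    expect_lt(max(abs(res$par$x - cc)), 1e-5)
    expect_true(all(is.finite(res$trace)))
    expect_equal(res$iterations, length(res$trace))
  }
})

test_that("zero iteration budget returns the initial point with an empty trace", {
  res <- minimize(function(p) ad_sum(ad_mul(p$x, p$x)), list(x = c(1, 2)),
                  max_iter = 0)
  expect_equal(res$par$x, c(1, 2))
  expect_length(res$trace, 0)
  expect_false(res$converged)
})

test_that("identical inputs give bitwise-identical traces", {
  set.seed(40)
  y <- matrix(rnorm(16), 4)
  loss <- function(p) ad_add(l2_fidelity(idct2(p$x), y), ad_mul(l1_norm(p$x), 0.01))
  r1 <- minimize(loss, list(x = matrix(0, 4, 4)), method = "lbfgs", max_iter = 50, seed = 1)
  r2 <- minimize(loss, list(x = matrix(0, 4, 4)), method = "lbfgs", max_iter = 50, seed = 1)
  expect_identical(r1$trace, r2$trace)
  a1 <- minimize(loss, list(x = matrix(0, 4, 4)), method = "adam", max_iter = 50, seed = 1)
  a2 <- minimize(loss, list(x = matrix(0, 4, 4)), method = "adam", max_iter = 50, seed = 1)
  expect_identical(a1$trace, a2$trace)
})

test_that("best-so-far loss is non-increasing under the quasi-Newton method", {
  set.seed(41)
  y <- matrix(rnorm(36), 6)
  loss <- function(p) l2_fidelity(blur2d(p$x, gaussian_kernel(3, 1)), y)
  res <- minimize(loss, list(x = matrix(0, 6, 6)), method = "lbfgs", max_iter = 60)
  expect_true(all(diff(cummin(res$trace)) <= 0))
})

test_that("analytic gradient in x matches Eq-style closed form and finite differences", {
  expect_equal(analytic_grad_x(diag(2), c(1, -2), c(0, 0)), c(3, -5))
  expect_equal(analytic_grad_x(diag(3), c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  set.seed(42)
  A <- matrix(rnorm(48), 8, 6)
  x <- rnorm(6); y <- rnorm(8)
  # finite differences of the smooth part plus the L1 subgradient
  fd_smooth <- fd_gradient(function(v) sum((A %*% v - y)^2), x)
  expect_lt(max(abs(analytic_grad_x(A, x, y) - (fd_smooth + sign(x)))), 1e-5)
})

test_that("analytic gradient in A is the expected outer product", {
  set.seed(43)
  A <- matrix(rnorm(20), 5, 4)
  x <- rnorm(4)
  yc <- as.vector(A %*% x)
  expect_equal(analytic_grad_A(A, x, yc), matrix(0, 5, 4))
  # x = e1 concentrates the gradient in column 1
  e1 <- c(1, 0, 0, 0)
  gA <- analytic_grad_A(A, e1, rnorm(5))
  expect_true(all(gA[, 2:4] == 0))
  y2 <- rnorm(5)
  fdA <- matrix(0, 5, 4)
  for (i in 1:5) for (j in 1:4) {
    f <- function(a) { Am <- A; Am[i, j] <- a; sum((Am %*% x - y2)^2) }
    h <- 1e-6
    fdA[i, j] <- (f(A[i, j] + h) - f(A[i, j] - h)) / (2 * h)
  }
  expect_lt(max(abs(analytic_grad_A(A, x, y2) - fdA)), 1e-5)
})

test_that("fd_gradient recovers simple closed-form gradients", {
  x <- c(0.5, -1, 2)
  expect_equal(fd_gradient(function(v) sum(v^2), x), 2 * x, tolerance = 1e-7)
  expect_equal(fd_gradient(function(v) sum(3 * v), x), rep(3, 3), tolerance = 1e-9)
  expect_error(fd_gradient(function(v) sum(v), x, eps = 0), "positive")
})

test_that("verify_gradients flags nothing on the composite sparse-recovery closure", {
  set.seed(44)
  m <- mask_values(make_mask(c(8, 8), 0.5, "random", seed = 2))
  y <- apply_mask(matrix(rnorm(64), 8), m)
  loss <- function(p) cs_loss(p$x, m, y, loss_weights(lambda1 = 1e-3))
  rep <- verify_gradients(loss, list(x = matrix(rnorm(64, sd = 0.3), 8)))
  expect_lt(rep$max_rel, 1e-4)
  # a parameter the loss ignores reports zero discrepancy and gradient
  loss2 <- function(p) cs_loss(p$x, m, y, loss_weights(lambda1 = 1e-3))
  rep2 <- verify_gradients(loss2, list(x = matrix(0.1, 8, 8), unused = c(1, 2)))
  expect_lt(rep2$max_rel[rep2$parameter == "unused"], 1e-10)
  expect_equal(rep2$grad_norm[rep2$parameter == "unused"], 0)
})

test_that("a forward-consistent sparse instance is solved to machine data fit", {
  set.seed(45)
  coeffs <- matrix(0, 16, 16)
  coeffs[sample.int(256, 8)] <- rnorm(8)
  m <- mask_values(make_mask(c(16, 16), 0.5, "random", seed = 5))
  y <- apply_mask(idct2(coeffs), m)
  loss <- function(p) cs_loss(p$x, m, y, loss_weights(lambda1 = 1e-8))
  res <- minimize(loss, list(x = matrix(0, 16, 16)), method = "lbfgs",
                  max_iter = 200)
  data_term <- l2_fidelity(apply_mask(idct2(res$par$x), m), y)
  expect_lt(data_term, 1e-6)
})
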
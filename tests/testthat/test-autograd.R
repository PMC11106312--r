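# Every differentiable primitive is checked against central finite
# differences on small random tensors.

ag <- function(name) get(name, envir = asNamespace("cbctgan"))

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3)
  conv_val <- ag("conv2d_value")
  xn <- ag("ag_param")(x); wn <- ag("ag_param")(w); bn <- ag("ag_param")(b)
  loss <- ag("ag_sum")(ag("ag_tanh")(ag("ag_conv2d")(xn, wn, bn, 2L, 1L)))
  ag("ag_backward")(loss)
  f <- function(xx, ww, bb) sum(tanh(conv_val(xx, ww, bb, 2L, 1L)))
  expect_lt(rel_err(xn$grad, num_grad(function(v) f(v, w, b), x)), 1e-6)
  expect_lt(rel_err(wn$grad, num_grad(function(v) f(x, v, b), w)), 1e-6)
  expect_lt(rel_err(bn$grad, num_grad(function(v) f(x, w, v), b)), 1e-6)
})

test_that("transposed-convolution op gradients match finite differences", {
  set.seed(2)
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  g0 <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  gn <- ag("ag_param")(g0); wn <- ag("ag_param")(w)
  node <- ag("ag_conv2d_input_grad")(gn, wn, 5L, 5L, 2L, 1L)
  loss <- ag("ag_sum")(ag("ag_tanh")(node))
  ag("ag_backward")(loss)
  fval <- function(gg, ww) {
    gm <- matrix(aperm(gg, c(1, 2, 4, 3)), ncol = 3)
    yv <- ag(".col2im_cpp")(gm %*% t(matrix(ww, ncol = 3)),
                            5L, 5L, 2L, 2L, 3L, 2L, 1L)
    sum(tanh(yv))
  }
  expect_lt(rel_err(gn$grad, num_grad(function(v) fval(v, w), g0)), 1e-6)
  expect_lt(rel_err(wn$grad, num_grad(function(v) fval(g0, v), w)), 1e-6)
})

test_that("depth-wise convolution gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3) * 0.4, c(3, 3, 3))
  b <- rnorm(3)
  xn <- ag("ag_param")(x); wn <- ag("ag_param")(w); bn <- ag("ag_param")(b)
  loss <- ag("ag_sum")(ag("ag_tanh")(ag("ag_dwconv2d")(xn, wn, bn, 1L)))
  ag("ag_backward")(loss)
  f <- function(xx, ww, bb) {
    y <- ag(".dwconv_fwd_cpp")(xx, ww, 1L)
    sum(tanh(sweep(y, 3, bb, "+")))
  }
  expect_lt(rel_err(xn$grad, num_grad(function(v) f(v, w, b), x)), 1e-6)
  expect_lt(rel_err(wn$grad, num_grad(function(v) f(x, v, b), w)), 1e-6)
  expect_lt(rel_err(bn$grad, num_grad(function(v) f(x, w, v), b)), 1e-6)
})

test_that("resize, upsample, layernorm and attention gradients are exact", {
  set.seed(4)
  xr <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  xn <- ag("ag_param")(xr)
  ag("ag_backward")(ag("ag_sum")(ag("ag_tanh")(ag("ag_resize_bilinear")(xn, 3L, 3L))))
  expect_lt(rel_err(xn$grad, num_grad(function(v) {
    sum(tanh(ag(".resize_bilinear_cpp")(v, 3L, 3L)))
  }, xr)), 1e-5)

  xn <- ag("ag_param")(xr)
  ag("ag_backward")(ag("ag_sum")(ag("ag_tanh")(ag("ag_upsample2")(xn))))
  up <- function(v) v[rep(1:6, each = 2), rep(1:6, each = 2), , , drop = FALSE]
  expect_lt(rel_err(xn$grad, num_grad(function(v) sum(tanh(up(v))), xr)), 1e-5)

  xt <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  gn <- ag("ag_param")(rnorm(6)); bn <- ag("ag_param")(rnorm(6))
  xn <- ag("ag_param")(xt)
  ag("ag_backward")(ag("ag_sum")(ag("ag_tanh")(ag("ag_layernorm")(xn, gn, bn))))
  lnval <- function(xx, gg, bb, eps = 1e-5) {
    out <- xx
    for (n in 1:2) for (t in 1:4) {
      v <- xx[t, , n]
      out[t, , n] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps) * gg + bb
    }
    out
  }
  expect_lt(rel_err(xn$grad, num_grad(function(v) {
    sum(tanh(lnval(v, gn$value, bn$value)))
  }, xt)), 1e-4)

  set.seed(5)
  pw <- replicate(4, matrix(rnorm(36) * 0.4, 6, 6), simplify = FALSE)
  pb <- replicate(4, rnorm(6) * 0.1, simplify = FALSE)
  nodes <- lapply(c(pw, pb), ag("ag_param"))
  xn <- ag("ag_param")(xt)
  out <- ag("ag_attention")(xn, nodes[[1]], nodes[[5]], nodes[[2]], nodes[[6]],
                            nodes[[3]], nodes[[7]], nodes[[4]], nodes[[8]], 2)
  ag("ag_backward")(ag("ag_sum")(ag("ag_tanh")(out)))
  attval <- function(xx, wq, bq, wk, bk, wv, bv, wo, bo, nh = 2) {
    s <- 0
    for (n in 1:dim(xx)[3]) {
      xm <- xx[, , n]
      Q <- sweep(xm %*% wq, 2, bq, "+"); K <- sweep(xm %*% wk, 2, bk, "+")
      V <- sweep(xm %*% wv, 2, bv, "+")
      O <- matrix(0, nrow(xm), 6)
      for (h in 1:nh) {
        idx <- ((h - 1) * 3 + 1):(h * 3)
        S <- Q[, idx] %*% t(K[, idx]) / sqrt(3)
        P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
        O[, idx] <- P %*% V[, idx]
      }
      s <- s + sum(tanh(sweep(O %*% wo, 2, bo, "+")))
    }
    s
  }
  expect_lt(rel_err(xn$grad, num_grad(function(v) {
    attval(v, pw[[1]], pb[[1]], pw[[2]], pb[[2]], pw[[3]], pb[[3]], pw[[4]], pb[[4]])
  }, xt)), 1e-4)
})

test_that("fused losses and elementwise ops differentiate correctly", {
  set.seed(6)
  a <- array(rnorm(12), c(3, 4))
  b <- array(rnorm(12), c(3, 4))
  an <- ag("ag_param")(a)
  ag("ag_backward")(ag("ag_l1_loss")(an, ag("ag_const")(b)))
  expect_equal(an$grad, sign(a - b) / 12, tolerance = 1e-12)
  an <- ag("ag_param")(a)
  ag("ag_backward")(ag("ag_l2_loss")(an, ag("ag_const")(b)))
  expect_equal(an$grad, 2 * (a - b) / 12, tolerance = 1e-12)
  xn <- ag("ag_param")(rnorm(10))
  ag("ag_backward")(ag("ag_sum")(ag("ag_gelu")(xn)))
  expect_lt(rel_err(xn$grad, num_grad(function(v) {
    sum(ag("gelu_value")(v))
  }, xn$value)), 1e-5)
})

test_that("gradients accumulate across shared subexpressions", {
  xn <- ag("ag_param")(2)
  y <- ag("ag_add")(ag("ag_square")(xn), ag("ag_mul_const")(xn, 3)) # x^2 + 3x
  ag("ag_backward")(y)
  expect_equal(xn$grad, 2 * 2 + 3)
})
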
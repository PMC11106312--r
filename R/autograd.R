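# Minimal reverse-mode autodiff over dense arrays.
#
# Tensors are plain R arrays. Image batches use dim c(H, W, C, N); token
# batches use dim c(L, d, N). A node is an environment holding the forward
# value, its parents, and a backward closure mapping the upstream gradient to
# per-parent gradients. backward() runs the tape in reverse topological order.
#
# The engine is strictly first-order. The one place second-order information
# is needed (training through the gradient penalty) builds the input-gradient
# computation itself as a forward graph of these same primitives, so ordinary
# backprop over that graph yields the required weight gradients.

ag_env <- new.env(parent = emptyenv())
ag_env$counter <- 0L

ag_next_id <- function() {
  ag_env$counter <- ag_env$counter + 1L
  ag_env$counter
}

ag_node <- function(value, parents = list(), backward = NULL,
                    requires_grad = FALSE) {
  rg <- requires_grad
  if (!rg && length(parents)) {
    for (p in parents) if (p$requires_grad) { rg <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- if (rg) parents else list()
  e$backward_fn <- if (rg) backward else NULL
  e$requires_grad <- rg
  e$grad <- NULL
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

ag_const <- function(value) ag_node(value)
ag_param <- function(value) ag_node(value, requires_grad = TRUE)

is_ag_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag_node(x)) x$value else x

# Reverse topological order via iterative DFS on node ids.
ag_toposort <- function(root) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$expanded) {
      order[[length(order) + 1L]] <- top$node
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
    for (p in top$node$parents) {
      if (p$requires_grad && is.null(seen[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  rev(order)
}

# Accumulate gradients of a scalar root into every reachable parameter node.
# Interior nodes are dismantled as soon as their backward has run (their
# gradient, closure, and parent links are dropped) so that peak memory stays
# proportional to the live frontier of the graph rather than its full size.
ag_backward <- function(root) {
  stopifnot(is_ag_node(root), length(root$value) == 1L)
  if (!root$requires_grad) return(invisible(NULL))
  nodes <- ag_toposort(root)
  for (nd in nodes) nd$grad <- NULL
  root$grad <- 1
  for (nd in nodes) {
    if (is.null(nd$backward_fn)) next
    if (is.null(nd$grad)) {
      nd$backward_fn <- NULL
      nd$parents <- list()
      next
    }
    grads <- nd$backward_fn(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires_grad || is.null(grads[[i]])) next
      p$grad <- if (is.null(p$grad)) grads[[i]] else p$grad + grads[[i]]
    }
    nd$grad <- NULL
    nd$backward_fn <- NULL
    nd$parents <- list()
    if (!identical(nd, root)) nd$value <- NULL
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and reduction ops ----------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_add_const <- function(a, k) {
  ag_node(a$value + k, list(a), function(g) list(g))
}

ag_mul_const <- function(a, k) {
  ag_node(a$value * k, list(a), function(g) list(g * k))
}

# x * alpha where alpha is a scalar parameter (rezero gate).
ag_scale <- function(x, alpha) {
  xv <- x$value; av <- as.numeric(alpha$value)
  ag_node(xv * av, list(x, alpha),
          function(g) list(g * av, sum(g * xv)))
}

ag_sum <- function(x) {
  dm <- dim(x$value)
  ag_node(sum(x$value), list(x), function(g) {
    out <- array(g, dim = if (is.null(dm)) length(x$value) else dm)
    list(out)
  })
}

ag_mean <- function(x) {
  n <- length(x$value)
  dm <- dim(x$value)
  ag_node(mean(x$value), list(x), function(g) {
    list(array(g / n, dim = if (is.null(dm)) n else dm))
  })
}

ag_square <- function(x) {
  xv <- x$value
  ag_node(xv^2, list(x), function(g) list(2 * g * xv))
}

ag_sqrt <- function(x) {
  yv <- sqrt(x$value)
  ag_node(yv, list(x), function(g) list(g / (2 * pmax(yv, 1e-12))))
}

ag_abs <- function(x) {
  xv <- x$value
  ag_node(abs(xv), list(x), function(g) list(g * sign(xv)))
}

ag_tanh <- function(x) {
  yv <- tanh(x$value)
  ag_node(yv, list(x), function(g) list(g * (1 - yv^2)))
}

ag_sigmoid <- function(x) {
  yv <- 1 / (1 + exp(-x$value))
  ag_node(yv, list(x), function(g) list(g * yv * (1 - yv)))
}

ag_leaky_relu <- function(x, slope = 0.2) {
  xv <- x$value
  m <- 1 - (1 - slope) * (xv <= 0)
  ag_node(xv * m, list(x), function(g) list(g * m))
}

# tanh-based GELU approximation (standard in transformer implementations).
gelu_value <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

ag_gelu <- function(x) {
  xv <- x$value
  k <- sqrt(2 / pi)
  inner <- k * (xv + 0.044715 * xv^3)
  t <- tanh(inner)
  dinner <- k * (1 + 3 * 0.044715 * xv^2)
  deriv <- 0.5 * (1 + t) + 0.5 * xv * (1 - t^2) * dinner
  ag_node(0.5 * xv * (1 + t), list(x), function(g) list(g * deriv))
}

# ---- matrix / token ops ----------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

# Token-wise linear map: x dim (L, d_in, N), w (d_in, d_out), b (d_out).
ag_tokens_linear <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); L <- d[1]; din <- d[2]; N <- d[3]
  dout <- ncol(wv)
  xm <- matrix(aperm(xv, c(1, 3, 2)), nrow = L * N, ncol = din)
  ym <- xm %*% wv
  if (!is.null(b)) ym <- sweep(ym, 2, b$value, "+")
  yv <- aperm(array(ym, c(L, N, dout)), c(1, 3, 2))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(yv, parents, function(g) {
    gm <- matrix(aperm(g, c(1, 3, 2)), nrow = L * N, ncol = dout)
    gx <- aperm(array(gm %*% t(wv), c(L, N, din)), c(1, 3, 2))
    gw <- crossprod(xm, gm)
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(gm))
  })
}

# Layer normalization over the feature dimension of (L, d, N) tokens.
# Internally works in (d, L*N) layout where length-d vectors recycle down
# the columns, avoiding apply().
ag_layernorm <- function(x, gain, bias, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); dd <- d[2]
  xm <- matrix(aperm(xv, c(2, 1, 3)), nrow = dd)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  inv_sd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- (xm - rep(mu, each = dd)) * rep(inv_sd, each = dd)
  gv <- gain$value; bv <- bias$value
  ym <- xhat * gv + bv
  yv <- aperm(array(ym, c(dd, d[1], d[3])), c(2, 1, 3))
  ag_node(yv, list(x, gain, bias), function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3)), nrow = dd)
    gg <- rowSums(gm * xhat)
    gb <- rowSums(gm)
    gxhat <- gm * gv
    m1 <- rep(colMeans(gxhat), each = dd)
    m2 <- rep(colMeans(gxhat * xhat), each = dd)
    gxm <- (gxhat - m1 - xhat * m2) * rep(inv_sd, each = dd)
    gx <- aperm(array(gxm, c(dd, d[1], d[3])), c(2, 1, 3))
    list(gx, gg, gb)
  })
}

# Fused multi-head self-attention on (L, d, N) tokens.
# wq/wk/wv/wo are (d, d); bq/bk/bv/bo length d. n_heads must divide d.
ag_attention <- function(x, wq, bq, wk, bk, wv, bv, wo, bo, n_heads) {
  xv <- x$value
  d <- dim(xv); L <- d[1]; dd <- d[2]; N <- d[3]
  stopifnot(dd %% n_heads == 0L)
  dh <- dd %/% n_heads
  scale <- 1 / sqrt(dh)
  Q <- K <- V <- O <- array(0, c(L, dd, N))
  P_all <- vector("list", N)
  for (n in seq_len(N)) {
    xm <- xv[, , n, drop = TRUE]
    if (is.null(dim(xm))) xm <- matrix(xm, nrow = L)
    Q[, , n] <- sweep(xm %*% wq$value, 2, bq$value, "+")
    K[, , n] <- sweep(xm %*% wk$value, 2, bk$value, "+")
    V[, , n] <- sweep(xm %*% wv$value, 2, bv$value, "+")
    Pn <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[, idx, n, drop = TRUE] %*% t(K[, idx, n, drop = TRUE])) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      P <- E / rowSums(E)
      Pn[[h]] <- P
      O[, idx, n] <- P %*% V[, idx, n, drop = TRUE]
    }
    P_all[[n]] <- Pn
  }
  Y <- array(0, c(L, dd, N))
  for (n in seq_len(N)) {
    Y[, , n] <- sweep(O[, , n, drop = TRUE] %*% wo$value, 2, bo$value, "+")
  }
  ag_node(Y, list(x, wq, bq, wk, bk, wv, bv, wo, bo), function(g) {
    gx <- array(0, c(L, dd, N))
    gwq <- gwk <- gwv <- gwo <- matrix(0, dd, dd)
    gbq <- gbk <- gbv <- gbo <- numeric(dd)
    for (n in seq_len(N)) {
      gy <- g[, , n, drop = TRUE]
      if (is.null(dim(gy))) gy <- matrix(gy, nrow = L)
      On <- O[, , n, drop = TRUE]
      gwo <- gwo + crossprod(On, gy)
      gbo <- gbo + colSums(gy)
      gO <- gy %*% t(wo$value)
      gQ <- gK <- gV <- matrix(0, L, dd)
      for (h in seq_len(n_heads)) {
        idx <- ((h - 1) * dh + 1):(h * dh)
        P <- P_all[[n]][[h]]
        gOh <- gO[, idx, drop = FALSE]
        Vh <- V[, idx, n, drop = TRUE]
        gP <- gOh %*% t(Vh)
        gV[, idx] <- crossprod(P, gOh)
        gS <- P * (gP - rowSums(gP * P))
        gQ[, idx] <- (gS %*% K[, idx, n, drop = TRUE]) * scale
        gK[, idx] <- (crossprod(gS, Q[, idx, n, drop = TRUE])) * scale
      }
      xm <- xv[, , n, drop = TRUE]
      if (is.null(dim(xm))) xm <- matrix(xm, nrow = L)
      gwq <- gwq + crossprod(xm, gQ); gbq <- gbq + colSums(gQ)
      gwk <- gwk + crossprod(xm, gK); gbk <- gbk + colSums(gK)
      gwv <- gwv + crossprod(xm, gV); gbv <- gbv + colSums(gV)
      gx[, , n] <- gQ %*% t(wq$value) + gK %*% t(wk$value) + gV %*% t(wv$value)
    }
    list(gx, gwq, gbq, gwk, gbk, gwv, gbv, gwo, gbo)
  })
}

# ---- convolution ops --------------------------------------------------------

conv_out_size <- function(input, k, stride, pad) {
  (input + 2L * pad - k) %/% stride + 1L
}

# Value-level conv2d used by both the taped op and plain image filtering.
conv2d_value <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  .conv2d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad))
}

# conv2d: x (H,W,Cin,N), w (k,k,Cin,Cout), b length Cout (or NULL).
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- x$value; wv <- w$value
  dx <- dim(xv); dw <- dim(wv)
  k <- dw[1]; cout <- dw[4]
  yv <- conv2d_value(xv, wv, if (is.null(b)) NULL else b$value, stride, pad)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(yv, parents, function(g) {
    # the fused kernel recomputes im2col internally rather than caching it,
    # keeping peak memory proportional to the activations
    bw <- .conv2d_bwd_cpp(xv, wv, g, as.integer(stride), as.integer(pad), TRUE)
    if (is.null(b)) list(bw$gx, bw$gw) else list(bw$gx, bw$gw, bw$gb)
  })
}

# Forward op computing the conv2d input-gradient (a transposed convolution).
# Used to express nabla_x D(x) as a differentiable graph for the gradient
# penalty; its own backward needs only first-order kernels.
ag_conv2d_input_grad <- function(g, w, in_h, in_w, stride = 1L, pad = 0L) {
  gv <- g$value; wv <- w$value
  dg <- dim(gv); dw <- dim(wv)
  k <- dw[1]; cin <- dw[3]; cout <- dw[4]
  gm <- matrix(aperm(gv, c(1, 2, 4, 3)), ncol = cout)
  wmat <- matrix(wv, ncol = cout)
  yv <- .col2im_cpp(gm %*% t(wmat), in_h, in_w, cin, dg[4],
                    as.integer(k), as.integer(stride), as.integer(pad))
  ag_node(yv, list(g, w), function(u) {
    # d/dg: conv2d forward of u with w (no bias); d/dw: conv weight grad
    # with input u and output-grad g.
    gg <- conv2d_value(u, wv, NULL, stride, pad)
    gw <- .conv2d_bwd_cpp(u, wv, gv, as.integer(stride), as.integer(pad),
                          FALSE)$gw
    list(gg, gw)
  })
}

# Depth-wise conv: x (H,W,C,N), w (k,k,C), b length C (or NULL), stride 1.
ag_dwconv2d <- function(x, w, b = NULL, pad = 1L) {
  xv <- x$value; wv <- w$value
  dx <- dim(xv); k <- dim(wv)[1]
  yv <- .dwconv_fwd_cpp(xv, wv, as.integer(pad))
  if (!is.null(b)) {
    yv <- sweep(yv, 3, b$value, "+")
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(yv, parents, function(g) {
    gx <- .dwconv_bwd_input_cpp(g, wv, dx[1], dx[2], as.integer(pad))
    gw <- .dwconv_bwd_weight_cpp(xv, g, as.integer(k), as.integer(pad))
    if (is.null(b)) list(gx, gw) else list(gx, gw, apply(g, 3, sum))
  })
}

ag_resize_bilinear <- function(x, out_h, out_w) {
  xv <- x$value
  dx <- dim(xv)
  yv <- .resize_bilinear_cpp(xv, as.integer(out_h), as.integer(out_w))
  ag_node(yv, list(x), function(g) {
    list(.resize_bilinear_adj_cpp(g, dx[1], dx[2]))
  })
}

# Nearest-neighbour x2 upsampling (pure R; the adjoint sums 2x2 blocks).
ag_upsample2 <- function(x) {
  xv <- x$value
  d <- dim(xv)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  yv <- xv[ri, ci, , , drop = FALSE]
  ag_node(yv, list(x), function(g) {
    odd_r <- seq(1, 2 * d[1], by = 2)
    odd_c <- seq(1, 2 * d[2], by = 2)
    gh <- g[odd_r, , , , drop = FALSE] + g[odd_r + 1, , , , drop = FALSE]
    gx <- gh[, odd_c, , , drop = FALSE] + gh[, odd_c + 1, , , drop = FALSE]
    list(gx)
  })
}

ag_concat_ch <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  yv <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  yv[, , seq_len(da[3]), ] <- av
  yv[, , da[3] + seq_len(db[3]), ] <- bv
  ag_node(yv, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Row-major (row, col) flattening: token index t = row * W + col (0-based),
# i.e. the column index varies fastest. x (H,W,C,N) -> tokens (H*W, C, N).
ag_img2seq <- function(x) {
  xv <- x$value
  d <- dim(xv)
  yv <- array(aperm(xv, c(2, 1, 3, 4)), c(d[1] * d[2], d[3], d[4]))
  nd <- ag_node(yv, list(x), function(g) {
    list(aperm(array(g, c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4)))
  })
  attr(nd$value, "grid_shape") <- c(w = d[2], h = d[1])
  nd
}

# Inverse of ag_img2seq for a (w, h) grid carried alongside the sequence.
ag_seq2img <- function(x, grid_w, grid_h) {
  xv <- x$value
  d <- dim(xv)
  stopifnot(d[1] == grid_w * grid_h)
  yv <- aperm(array(xv, c(grid_w, grid_h, d[2], d[3])), c(2, 1, 3, 4))
  ag_node(yv, list(x), function(g) {
    list(array(aperm(g, c(2, 1, 3, 4)), c(grid_w * grid_h, d[2], d[3])))
  })
}

# Per-sample sum of squares over all non-batch dims: (H,W,C,N) -> length-N.
ag_sumsq_per_sample <- function(x) {
  xv <- x$value
  d <- dim(xv)
  yv <- apply(xv^2, 4, sum)
  ag_node(yv, list(x), function(g) {
    gb <- aperm(array(rep(g, each = d[1] * d[2] * d[3]), d), c(1, 2, 3, 4))
    list(2 * xv * gb)
  })
}

# Mean of |a - b| and mean of (a - b)^2 as single fused losses.
ag_l1_loss <- function(a, b) {
  diff <- a$value - b$value
  n <- length(diff)
  dm <- dim(diff)
  ag_node(mean(abs(diff)), list(a, b), function(g) {
    gd <- g * sign(diff) / n
    if (!is.null(dm)) gd <- array(gd, dm)
    list(gd, -gd)
  })
}

ag_l2_loss <- function(a, b) {
  diff <- a$value - b$value
  n <- length(diff)
  dm <- dim(diff)
  ag_node(mean(diff^2), list(a, b), function(g) {
    gd <- g * 2 * diff / n
    if (!is.null(dm)) gd <- array(gd, dm)
    list(gd, -gd)
  })
}
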
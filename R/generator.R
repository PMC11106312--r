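#' Generator architecture hyperparameters
#'
#' The generator is a U-net whose bottleneck is a stack of transformer
#' encoder blocks: a stem convolution produces a `(w0, h0, f0)` feature map,
#' each of `encoder_depth` downsampling blocks halves the spatial dimensions
#' and doubles the channels, the bottleneck map is flattened row-major into
#' `w * h` tokens that are concatenated with a 2-D Fourier positional
#' embedding of dimension `fourier_dim` and linearly mapped to `token_dim`,
#' `transformer_depth` rezero-gated blocks (pre-norm self-attention plus a
#' feed-forward network) transform the tokens, and the mirror decoder with
#' skip connections and nearest-neighbour upsampling reconstructs the image
#' through a final convolution and tanh squashing to `[-1, 1]`.
#'
#' @param input_size input side length in pixels; must be divisible by
#'   `2^encoder_depth`.
#' @param base_width `f0`, channels after the stem convolution.
#' @param encoder_depth number of downsampling blocks (0 allowed for testing).
#' @param transformer_depth number of transformer encoder blocks (>= 1).
#' @param fourier_dim `f_p`, positional embedding channels (multiple of 4).
#' @param token_dim `f_v`, token width inside the transformer (multiple of
#'   `n_heads`).
#' @param n_heads self-attention heads.
#' @param ffn_variant `"dwconv"` (two 1x1 convolutions around a depth-wise
#'   convolution on the re-gridded tokens) or `"mlp"` (plain two-layer
#'   feed-forward); the ablation axis for the depth-wise convolution network.
#' @param ffn_expansion hidden-width multiplier of the feed-forward network.
#' @param dw_kernel depth-wise convolution kernel size (odd).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(input_size = 256L,
                             base_width = 48L,
                             encoder_depth = 4L,
                             transformer_depth = 12L,
                             fourier_dim = 32L,
                             token_dim = 384L,
                             n_heads = 6L,
                             ffn_variant = c("dwconv", "mlp"),
                             ffn_expansion = 4,
                             dw_kernel = 3L) {
  ffn_variant <- match.arg(ffn_variant)
  input_size <- as.integer(input_size)
  encoder_depth <- as.integer(encoder_depth)
  if (encoder_depth < 0) stop("`encoder_depth` must be >= 0", call. = FALSE)
  if (input_size %% (2^encoder_depth) != 0) {
    stop("`input_size` must be divisible by 2^encoder_depth", call. = FALSE)
  }
  if (transformer_depth < 1) stop("`transformer_depth` must be >= 1", call. = FALSE)
  if (fourier_dim %% 4 != 0 || fourier_dim < 4) {
    stop("`fourier_dim` must be a positive multiple of 4", call. = FALSE)
  }
  if (token_dim %% n_heads != 0) {
    stop("`token_dim` must be divisible by `n_heads`", call. = FALSE)
  }
  if (dw_kernel %% 2 != 1) stop("`dw_kernel` must be odd", call. = FALSE)
  if (base_width < 1 || token_dim < 1 || ffn_expansion <= 0) {
    stop("all generator dimensions must be positive", call. = FALSE)
  }
  structure(list(input_size = input_size,
                 base_width = as.integer(base_width),
                 encoder_depth = encoder_depth,
                 transformer_depth = as.integer(transformer_depth),
                 fourier_dim = as.integer(fourier_dim),
                 token_dim = as.integer(token_dim),
                 n_heads = as.integer(n_heads),
                 ffn_variant = ffn_variant,
                 ffn_expansion = ffn_expansion,
                 dw_kernel = as.integer(dw_kernel)),
            class = "generator_config")
}

#' Expected feature-map shapes of a generator configuration
#'
#' @param cfg a [generator_config()].
#' @return List with the bottleneck grid `(w, h)`, bottleneck channels `f`,
#'   and token count `w * h`.
#' @export
generator_shapes <- function(cfg) {
  side <- cfg$input_size %/% (2^cfg$encoder_depth)
  channels <- cfg$base_width * 2^cfg$encoder_depth
  list(bottleneck_side = side, bottleneck_channels = channels,
       n_tokens = side * side)
}

# Weight init follows the CycleGAN-lineage convention of N(0, 0.02) for
# convolutions; linear token maps use Glorot scaling (their fan-in is large
# enough that a fixed 0.02 would starve the tokens).
init_conv <- function(k, cin, cout) {
  ag_param(array(rnorm(k * k * cin * cout, 0, 0.02), c(k, k, cin, cout)))
}

init_linear <- function(din, dout) {
  ag_param(matrix(rnorm(din * dout, 0, sqrt(1 / din)), din, dout))
}

init_bias <- function(n) ag_param(numeric(n))

#' Initialize generator parameters
#'
#' All rezero gates start at exactly 0, so every transformer block is the
#' identity map at initialization; convolution weights use He initialization
#' and linear maps Glorot-style scaling.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed for the weight draws.
#' @return An object of class `cbct_generator`.
#' @export
generator_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  local_seed(seed, {
    f0 <- cfg$base_width
    fv <- cfg$token_dim
    fp <- cfg$fourier_dim
    depth <- cfg$encoder_depth
    fb <- f0 * 2^depth
    params <- list(
      stem = list(w = init_conv(3, 1, f0), b = init_bias(f0)),
      down = lapply(seq_len(depth), function(i) {
        cin <- f0 * 2^(i - 1)
        list(w = init_conv(3, cin, 2 * cin), b = init_bias(2 * cin))
      }),
      tok = list(w_feat = init_linear(fb, fv),
                 w_pos = init_linear(fp, fv),
                 b = init_bias(fv)),
      blocks = lapply(seq_len(cfg$transformer_depth), function(j) {
        blk <- list(
          ln1_g = ag_param(rep(1, fv)), ln1_b = init_bias(fv),
          wq = init_linear(fv, fv), bq = init_bias(fv),
          wk = init_linear(fv, fv), bk = init_bias(fv),
          wv = init_linear(fv, fv), bv = init_bias(fv),
          wo = init_linear(fv, fv), bo = init_bias(fv),
          alpha1 = ag_param(0),
          ln2_g = ag_param(1 + numeric(fv)), ln2_b = init_bias(fv),
          alpha2 = ag_param(0))
        hidden <- as.integer(round(cfg$ffn_expansion * fv))
        if (cfg$ffn_variant == "dwconv") {
          blk$ffn <- list(
            w1 = init_conv(1, fv, hidden), b1 = init_bias(hidden),
            wd = ag_param(array(rnorm(cfg$dw_kernel^2 * hidden, 0,
                                      sqrt(2 / cfg$dw_kernel^2)),
                                c(cfg$dw_kernel, cfg$dw_kernel, hidden))),
            bd = init_bias(hidden),
            w2 = init_conv(1, hidden, fv), b2 = init_bias(fv))
        } else {
          blk$ffn <- list(
            w1 = init_linear(fv, hidden), b1 = init_bias(hidden),
            w2 = init_linear(hidden, fv), b2 = init_bias(fv))
        }
        blk
      }),
      detok = list(w = init_linear(fv, fb), b = init_bias(fb)),
      up = lapply(seq_len(depth), function(i) {
        # level i consumed in order depth..1; channels at that level:
        cin <- f0 * 2^i
        list(w1 = init_conv(3, cin, cin %/% 2), b1 = init_bias(cin %/% 2),
             w2 = init_conv(3, cin, cin %/% 2), b2 = init_bias(cin %/% 2))
      }),
      out = list(w = init_conv(3, f0, 1), b = init_bias(1))
    )
    structure(list(cfg = cfg, params = params), class = "cbct_generator")
  })
}

# Flat list of every trainable node in a parameter tree.
collect_params <- function(x) {
  if (is_ag_node(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

#' Number of trainable scalars in a model
#'
#' @param model a `cbct_generator`, `cbct_discriminator`, or any nested list
#'   of parameter nodes.
#' @export
n_parameters <- function(model) {
  ps <- collect_params(if (!is.null(model$params)) model$params else model)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

#' 2-D Fourier positional embedding
#'
#' Each grid position `(row, col)` (0-based, row-major token order
#' `t = row * w + col`) is encoded as sines and cosines of its normalized
#' coordinates at geometrically spaced frequencies: for `f_p` channels,
#' `f_p / 4` frequencies `2^k` are applied to `row / h` and `col / w`. The
#' base frequency alone makes the embedding injective on the grid.
#'
#' @param w,h grid width and height.
#' @param f_p embedding dimension (multiple of 4).
#' @return A `(w * h) x f_p` matrix in row-major token order.
#' @export
fourier_embedding <- function(w, h, f_p) {
  stopifnot(f_p %% 4 == 0)
  n_freq <- f_p %/% 4
  rows <- rep(0:(h - 1), each = w) / h
  cols <- rep(0:(w - 1), times = h) / w
  out <- matrix(0, w * h, f_p)
  for (k in seq_len(n_freq)) {
    fr <- 2^(k - 1) * 2 * pi
    out[, 4 * k - 3] <- sin(fr * rows)
    out[, 4 * k - 2] <- cos(fr * rows)
    out[, 4 * k - 1] <- sin(fr * cols)
    out[, 4 * k] <- cos(fr * cols)
  }
  out
}

# Token linear map with an additive positional projection:
# y[,,n] = x[,,n] %*% w_feat + pos %*% w_pos + b.
ag_tokens_linear_pos <- function(x, w_feat, w_pos, b, pos) {
  xv <- x$value
  d <- dim(xv); L <- d[1]; din <- d[2]; N <- d[3]
  dout <- ncol(w_feat$value)
  xm <- matrix(aperm(xv, c(1, 3, 2)), nrow = L * N, ncol = din)
  posterm <- pos %*% w_pos$value
  ym <- sweep(xm %*% w_feat$value, 2, b$value, "+")
  yv <- aperm(array(ym, c(L, N, dout)), c(1, 3, 2))
  yv <- yv + array(rep(posterm, times = N), c(L, dout, N))
  ag_node(yv, list(x, w_feat, w_pos, b), function(g) {
    gm <- matrix(aperm(g, c(1, 3, 2)), nrow = L * N, ncol = dout)
    gx <- aperm(array(gm %*% t(w_feat$value), c(L, N, din)), c(1, 3, 2))
    gwf <- crossprod(xm, gm)
    gsum <- apply(g, c(1, 2), sum)    # sum over batch
    gwp <- crossprod(pos, gsum)
    list(gx, gwf, gwp, colSums(gm))
  })
}

# ---- forward passes (node level) -------------------------------------------

g_encode <- function(gen, x) {
  p <- gen$params
  h <- ag_leaky_relu(ag_conv2d(x, p$stem$w, p$stem$b, 1L, 1L), 0.2)
  skips <- list()
  for (i in seq_len(gen$cfg$encoder_depth)) {
    skips[[i]] <- h
    h <- ag_leaky_relu(ag_conv2d(h, p$down[[i]]$w, p$down[[i]]$b, 2L, 1L), 0.2)
  }
  list(bottleneck = h, skips = skips)
}

g_tokenize <- function(gen, fmap) {
  d <- dim(fmap$value)
  seq <- ag_img2seq(fmap)
  pos <- fourier_embedding(d[2], d[1], gen$cfg$fourier_dim)
  tok <- ag_tokens_linear_pos(seq, gen$params$tok$w_feat, gen$params$tok$w_pos,
                              gen$params$tok$b, pos)
  attr(tok$value, "grid_shape") <- c(w = d[2], h = d[1])
  tok
}

g_ffn <- function(gen, blk, x, grid_w, grid_h) {
  if (gen$cfg$ffn_variant == "dwconv") {
    img <- ag_seq2img(x, grid_w, grid_h)
    h <- ag_conv2d(img, blk$ffn$w1, blk$ffn$b1, 1L, 0L)
    h <- ag_dwconv2d(h, blk$ffn$wd, blk$ffn$bd,
                     pad = (gen$cfg$dw_kernel - 1L) %/% 2L)
    h <- ag_gelu(h)
    h <- ag_conv2d(h, blk$ffn$w2, blk$ffn$b2, 1L, 0L)
    ag_img2seq(h)
  } else {
    h <- ag_gelu(ag_tokens_linear(x, blk$ffn$w1, blk$ffn$b1))
    ag_tokens_linear(h, blk$ffn$w2, blk$ffn$b2)
  }
}

g_transformer <- function(gen, tok, grid_w = NULL, grid_h = NULL) {
  if (is.null(grid_w)) {
    gs <- attr(tok$value, "grid_shape")
    if (is.null(gs)) stop("token sequence carries no grid_shape", call. = FALSE)
    grid_w <- gs[["w"]]; grid_h <- gs[["h"]]
  }
  for (blk in gen$params$blocks) {
    a <- ag_attention(ag_layernorm(tok, blk$ln1_g, blk$ln1_b),
                      blk$wq, blk$bq, blk$wk, blk$bk, blk$wv, blk$bv,
                      blk$wo, blk$bo, gen$cfg$n_heads)
    tok <- ag_add(tok, ag_scale(a, blk$alpha1))
    f <- g_ffn(gen, blk, ag_layernorm(tok, blk$ln2_g, blk$ln2_b),
               grid_w, grid_h)
    tok <- ag_add(tok, ag_scale(f, blk$alpha2))
  }
  attr(tok$value, "grid_shape") <- c(w = grid_w, h = grid_h)
  tok
}

g_detokenize <- function(gen, tok, grid_w = NULL, grid_h = NULL) {
  if (is.null(grid_w)) {
    gs <- attr(tok$value, "grid_shape")
    if (is.null(gs)) stop("token sequence carries no grid_shape", call. = FALSE)
    grid_w <- gs[["w"]]; grid_h <- gs[["h"]]
  }
  h <- ag_tokens_linear(tok, gen$params$detok$w, gen$params$detok$b)
  ag_seq2img(h, grid_w, grid_h)
}

g_decode <- function(gen, bottleneck, skips) {
  p <- gen$params
  h <- bottleneck
  for (i in rev(seq_len(gen$cfg$encoder_depth))) {
    h <- ag_upsample2(h)
    h <- ag_leaky_relu(ag_conv2d(h, p$up[[i]]$w1, p$up[[i]]$b1, 1L, 1L), 0.2)
    if (!all(dim(h$value)[1:2] == dim(skips[[i]]$value)[1:2])) {
      stop("skip shape mismatch in decoder", call. = FALSE)
    }
    h <- ag_concat_ch(h, skips[[i]])
    h <- ag_leaky_relu(ag_conv2d(h, p$up[[i]]$w2, p$up[[i]]$b2, 1L, 1L), 0.2)
  }
  ag_tanh(ag_conv2d(h, p$out$w, p$out$b, 1L, 1L))
}

g_forward <- function(gen, x) {
  enc <- g_encode(gen, x)
  d <- dim(enc$bottleneck$value)
  tok <- g_tokenize(gen, enc$bottleneck)
  tok <- g_transformer(gen, tok, d[2], d[1])
  bott <- g_detokenize(gen, tok, d[2], d[1])
  g_decode(gen, bott, enc$skips)
}

# ---- array-level module surface --------------------------------------------

as_batch <- function(x) {
  if (is_domain_image(x)) x <- x$pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Run the encoder path
#'
#' @param gen a `cbct_generator`.
#' @param x normalized image: `domain_image`, matrix, or `(H, W, 1, N)` array.
#' @return List with `bottleneck` and `skips` feature arrays `(H, W, C, N)`.
#' @export
gen_encode <- function(gen, x) {
  x <- as_batch(x)
  if (dim(x)[1] != gen$cfg$input_size && gen$cfg$encoder_depth > 0 &&
      dim(x)[1] %% 2^gen$cfg$encoder_depth != 0) {
    stop("input size not divisible by 2^encoder_depth", call. = FALSE)
  }
  enc <- g_encode(gen, ag_const(x))
  list(bottleneck = enc$bottleneck$value,
       skips = lapply(enc$skips, function(s) s$value))
}

#' Flatten a feature map into a positional token sequence
#'
#' @param gen a `cbct_generator`.
#' @param fmap feature array `(h, w, f, N)`.
#' @return Token array `(w * h, token_dim, N)` with attribute `grid_shape`.
#' @export
gen_tokenize <- function(gen, fmap) {
  g_tokenize(gen, ag_const(fmap))$value
}

#' Apply the transformer encoder stack to a token sequence
#'
#' @param gen a `cbct_generator`.
#' @param tokens token array from [gen_tokenize()] (attribute `grid_shape`
#'   required, or pass `grid_w`/`grid_h`).
#' @param grid_w,grid_h token grid dimensions.
#' @export
gen_transformer <- function(gen, tokens, grid_w = NULL, grid_h = NULL) {
  if (is.null(grid_w)) {
    gs <- attr(tokens, "grid_shape")
    if (is.null(gs)) stop("token sequence carries no grid_shape", call. = FALSE)
    grid_w <- gs[["w"]]; grid_h <- gs[["h"]]
  }
  g_transformer(gen, ag_const(tokens), grid_w, grid_h)$value
}

#' Project tokens back to a feature map
#'
#' @inheritParams gen_transformer
#' @export
gen_detokenize <- function(gen, tokens, grid_w = NULL, grid_h = NULL) {
  if (is.null(grid_w)) {
    gs <- attr(tokens, "grid_shape")
    if (is.null(gs)) stop("token sequence carries no grid_shape", call. = FALSE)
    grid_w <- gs[["w"]]; grid_h <- gs[["h"]]
  }
  g_detokenize(gen, ag_const(tokens), grid_w, grid_h)$value
}

#' Run the decoder path
#'
#' @param gen a `cbct_generator`.
#' @param bottleneck feature array at the bottleneck resolution.
#' @param skips list of skip feature arrays from [gen_encode()].
#' @return Image array in `[-1, 1]`, same spatial size as the encoder input.
#' @export
gen_decode <- function(gen, bottleneck, skips) {
  g_decode(gen, ag_const(bottleneck), lapply(skips, ag_const))$value
}

#' Translate an image to the other domain
#'
#' The full generator pass: encode, tokenize, transformer stack, detokenize,
#' decode. Input and output are normalized images of identical size; the
#' domain tag is flipped.
#'
#' @param image a normalized `domain_image` whose side equals the generator's
#'   `input_size` (any size divisible by `2^encoder_depth` is accepted).
#' @param gen a `cbct_generator`.
#' @return A normalized `domain_image` in the opposite domain.
#' @export
translate <- function(image, gen) {
  assert_normalized(image, "image")
  x <- as_batch(image)
  y <- g_forward(gen, ag_const(x))$value[, , 1, 1]
  domain_image(matrix(y, dim(x)[1], dim(x)[2]),
               domain = other_domain(image$domain), scale = "normalized")
}

# Batched forward used by training/evaluation: (H,W,1,N) array in and out.
translate_batch <- function(gen, x) {
  g_forward(gen, ag_const(x))$value
}
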
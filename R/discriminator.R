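#' Discriminator architecture hyperparameters
#'
#' A patch discriminator: `n_layers` stride-2 4x4 convolutions (channels
#' double each layer, LeakyReLU 0.2 between), one stride-1 4x4 convolution,
#' and a final stride-1 4x4 convolution to a single-channel realness map.
#' With `n_layers = 3` the receptive field is the classic 70x70 patch. No
#' normalization layers are used anywhere: the gradient penalty regularizes
#' the input gradient, and normalization layers would couple samples and
#' distort it.
#'
#' For an `s x s` input the score map side is `s / 2^n_layers - 2` (each
#' stride-1 4x4 layer with padding 1 removes one row/column).
#'
#' @param base_width channels of the first layer.
#' @param n_layers number of stride-2 layers (>= 1).
#' @param output `"patch_map"` (spatial realness map) or `"scalar"` (mean of
#'   the map).
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(base_width = 64L, n_layers = 3L,
                                 output = c("patch_map", "scalar")) {
  output <- match.arg(output)
  if (n_layers < 1) stop("`n_layers` must be >= 1", call. = FALSE)
  if (base_width < 1) stop("`base_width` must be positive", call. = FALSE)
  structure(list(base_width = as.integer(base_width),
                 n_layers = as.integer(n_layers), output = output),
            class = "discriminator_config")
}

#' Expected score-map side length for a square input
#'
#' @param cfg a [discriminator_config()].
#' @param input_size input side length in pixels.
#' @export
discriminator_score_shape <- function(cfg, input_size) {
  s <- input_size
  for (i in seq_len(cfg$n_layers)) s <- (s + 2 - 4) %/% 2 + 1
  s <- s + 2 - 4 + 1   # stride-1 4x4 pad 1
  s <- s + 2 - 4 + 1
  as.integer(s)
}

#' Initialize discriminator parameters
#'
#' @param cfg a [discriminator_config()].
#' @param seed integer seed for the weight draws.
#' @return An object of class `cbct_discriminator`.
#' @export
discriminator_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "discriminator_config"))
  local_seed(seed, {
    layers <- list()
    cin <- 1L
    cout <- cfg$base_width
    for (i in seq_len(cfg$n_layers)) {
      layers[[i]] <- list(w = init_conv(4, cin, cout), b = init_bias(cout),
                          stride = 2L)
      cin <- cout
      cout <- min(cout * 2L, cfg$base_width * 8L)
    }
    layers[[cfg$n_layers + 1L]] <- list(w = init_conv(4, cin, cout),
                                        b = init_bias(cout), stride = 1L)
    layers[[cfg$n_layers + 2L]] <- list(w = init_conv(4, cout, 1L),
                                        b = init_bias(1L), stride = 1L)
    structure(list(cfg = cfg, params = list(layers = layers)),
              class = "cbct_discriminator")
  })
}

# Node-level forward. When `keep_preacts` the LeakyReLU derivative masks and
# per-layer input sizes are returned so the input-gradient graph for the
# gradient penalty can be assembled.
d_forward <- function(disc, x, keep_preacts = FALSE) {
  layers <- disc$params$layers
  n <- length(layers)
  masks <- vector("list", n - 1L)
  sizes <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    sizes[[i]] <- dim(h$value)[1:2]
    pad <- if (is.null(layers[[i]]$pad)) 1L else layers[[i]]$pad
    h <- ag_conv2d(h, layers[[i]]$w, layers[[i]]$b, layers[[i]]$stride, pad)
    if (i < n) {
      if (keep_preacts) masks[[i]] <- 1 - 0.8 * (h$value <= 0)
      h <- ag_leaky_relu(h, 0.2)
    }
  }
  if (keep_preacts) list(score = h, masks = masks, sizes = sizes) else h
}

#' Score an image batch with the patch discriminator
#'
#' @param disc a `cbct_discriminator`.
#' @param x normalized image: `domain_image`, matrix, or `(H, W, 1, N)` array.
#' @return A score array `(h', w', 1, N)` (`output = "patch_map"`), or a
#'   length-`N` vector of mean scores (`output = "scalar"`).
#' @export
discriminator_score <- function(disc, x) {
  x <- as_batch(x)
  rf <- 2^disc$cfg$n_layers + 6L
  if (dim(x)[1] < rf || dim(x)[2] < rf) {
    stop("input smaller than the discriminator receptive field", call. = FALSE)
  }
  s <- d_forward(disc, ag_const(x))$value
  if (disc$cfg$output == "scalar") apply(s, 4, mean) else s
}

# Differentiable graph of nabla_x mean(D(x)) per sample. The LeakyReLU
# derivative masks are treated as constants (they are piecewise constant in
# the weights, so this matches the almost-everywhere exact gradient). The
# result is a node whose own backward pass yields d(penalty)/d(weights).
d_input_grad_graph <- function(disc, x_batch) {
  ff <- d_forward(disc, ag_const(x_batch), keep_preacts = TRUE)
  layers <- disc$params$layers
  n <- length(layers)
  ds <- dim(ff$score$value)
  seed <- array(1 / (ds[1] * ds[2]), ds)
  g <- ag_const(seed)
  for (i in rev(seq_len(n))) {
    sz <- ff$sizes[[i]]
    pad <- if (is.null(layers[[i]]$pad)) 1L else layers[[i]]$pad
    g <- ag_conv2d_input_grad(g, layers[[i]]$w, sz[1], sz[2],
                              layers[[i]]$stride, pad)
    if (i > 1L) g <- ag_mul(g, ag_const(ff$masks[[i - 1L]]))
  }
  g
}

# Node-level gamma-centred penalty: mean_n ((||grad_n||_2 - gamma)^2 / gamma^2).
gp_penalty_node <- function(disc, x_batch, gamma) {
  g <- d_input_grad_graph(disc, x_batch)
  norms <- ag_sqrt(ag_sumsq_per_sample(g))
  dev <- ag_add_const(norms, -gamma)
  ag_mul_const(ag_mean(ag_square(dev)), 1 / gamma^2)
}
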
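# Shared tiny fixtures: everything is built in code at test time.

tiny_gen_cfg <- function(...) {
  args <- list(input_size = 32L, base_width = 4L, encoder_depth = 2L,
               transformer_depth = 1L, fourier_dim = 8L, token_dim = 16L,
               n_heads = 2L, ffn_variant = "dwconv", ffn_expansion = 2)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

tiny_disc_cfg <- function(...) {
  args <- list(base_width = 4L, n_layers = 2L)
  args[names(list(...))] <- list(...)
  do.call(discriminator_config, args)
}

tiny_spec <- function(...) {
  args <- list(image_size = 32L, n_structures = 2L)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

rand_image <- function(n = 32L, seed = 1, lo = -1, hi = 1) {
  set.seed(seed)
  matrix(runif(n * n, lo, hi), n, n)
}

rand_batch <- function(n = 32L, N = 2L, seed = 1) {
  set.seed(seed)
  array(runif(n * n * N, -1, 1), c(n, n, 1L, N))
}

# central-difference gradient of a scalar function of an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(1e-8, max(abs(want)))
}

# single-layer 1x1-conv discriminator with weight c: D(x) = c * x pixelwise;
# the gradient of the mean score has norm c / sqrt(H*W)
linear_pixel_disc <- function(c_val) {
  w <- cbctgan:::ag_param(array(c_val, c(1, 1, 1, 1)))
  b <- cbctgan:::ag_param(0)
  structure(list(cfg = discriminator_config(base_width = 1L, n_layers = 1L),
                 params = list(layers = list(list(w = w, b = b, stride = 1L,
                                                  pad = 0L)))),
            class = "cbct_discriminator")
}
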
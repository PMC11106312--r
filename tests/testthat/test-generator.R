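test_that("encoder halves spatial dims and doubles channels per block", {
  # 256 input, f0 = 48, depth 4: bottleneck 16 x 16 x 768 by the rule
  cfg <- generator_config(input_size = 256L, base_width = 48L,
                          encoder_depth = 4L, transformer_depth = 1L,
                          fourier_dim = 32L, token_dim = 64L, n_heads = 4L)
  gen <- generator_init(cfg, seed = 1)
  enc <- gen_encode(gen, matrix(runif(256 * 256, -1, 1), 256))
  expect_equal(dim(enc$bottleneck), c(16, 16, 768, 1))
  expect_length(enc$skips, 4)
  expect_equal(dim(enc$skips[[1]])[1:3], c(256, 256, 48))

  cfg2 <- generator_config(input_size = 64L, base_width = 8L,
                           encoder_depth = 2L, transformer_depth = 1L,
                           fourier_dim = 8L, token_dim = 16L, n_heads = 2L)
  gen2 <- generator_init(cfg2, seed = 1)
  enc2 <- gen_encode(gen2, matrix(runif(64 * 64, -1, 1), 64))
  expect_equal(dim(enc2$bottleneck), c(16, 16, 32, 1))

  # degenerate depth 0: bottleneck is the preprocessed map, no skips
  cfg0 <- generator_config(input_size = 32L, base_width = 4L,
                           encoder_depth = 0L, transformer_depth = 1L,
                           fourier_dim = 8L, token_dim = 8L, n_heads = 2L)
  gen0 <- generator_init(cfg0, seed = 1)
  enc0 <- gen_encode(gen0, matrix(runif(32 * 32, -1, 1), 32))
  expect_equal(dim(enc0$bottleneck), c(32, 32, 4, 1))
  expect_length(enc0$skips, 0)
})

test_that("halving/doubling and token count hold across random legal configs", {
  set.seed(42)
  for (i in 1:4) {
    depth <- sample(1:3, 1)
    f0 <- sample(c(2L, 4L, 6L), 1)
    size <- 2^depth * sample(c(4L, 8L), 1)
    cfg <- generator_config(input_size = size, base_width = f0,
                            encoder_depth = depth, transformer_depth = 1L,
                            fourier_dim = 8L, token_dim = 8L, n_heads = 2L)
    gen <- generator_init(cfg, seed = i)
    enc <- gen_encode(gen, matrix(runif(size^2, -1, 1), size))
    sh <- generator_shapes(cfg)
    expect_equal(dim(enc$bottleneck)[1:2],
                 rep(size %/% 2^depth, 2))
    expect_equal(dim(enc$bottleneck)[3], f0 * 2^depth)
    tok <- gen_tokenize(gen, enc$bottleneck)
    expect_equal(dim(tok)[1], sh$n_tokens)
  }
})

test_that("tokenization flattens row-major with injective positional encoding", {
  cfg <- tiny_gen_cfg()
  gen <- generator_init(cfg, seed = 2)
  fmap <- array(runif(16 * 16 * 16, -1, 1), c(16, 16, 16, 1))
  tok <- gen_tokenize(gen, fmap)
  expect_equal(dim(tok), c(256, cfg$token_dim, 1))

  # identical features at different grid positions produce different tokens
  fmap_const <- array(0.7, c(4, 4, 16, 1))
  tok_c <- gen_tokenize(gen, fmap_const)
  expect_gt(min(dist(tok_c[, , 1])), 0)

  one <- gen_tokenize(gen, array(0.3, c(1, 1, 16, 1)))
  expect_equal(dim(one)[1], 1)

  # the raw embedding itself is injective on the grid
  emb <- fourier_embedding(8, 8, 16)
  expect_equal(nrow(unique(round(emb, 12))), 64)
})

test_that("transformer stack is the exact identity at rezero init", {
  gen <- generator_init(tiny_gen_cfg(transformer_depth = 3L), seed = 3)
  tok <- array(rnorm(64 * 16 * 2), c(64, 16, 2))
  out <- gen_transformer(gen, tok, grid_w = 8, grid_h = 8)
  expect_identical(as.vector(out), as.vector(tok))
})

test_that("deeper stacks and ffn variants change the parameter count", {
  n1 <- n_parameters(generator_init(tiny_gen_cfg(transformer_depth = 1L), 1))
  n12 <- n_parameters(generator_init(tiny_gen_cfg(transformer_depth = 12L), 1))
  expect_gt(n12, n1)
  n_dw <- n_parameters(generator_init(tiny_gen_cfg(ffn_variant = "dwconv"), 1))
  n_mlp <- n_parameters(generator_init(tiny_gen_cfg(ffn_variant = "mlp"), 1))
  expect_false(n_dw == n_mlp)
})

test_that("dwconv ffn makes the trained stack sensitive to token order", {
  gen <- generator_init(tiny_gen_cfg(transformer_depth = 1L), seed = 4)
  # emulate trained weights: set the rezero gates away from zero
  for (blk in gen$params$blocks) {
    blk$alpha1$value <- 0.5
    blk$alpha2$value <- 0.5
  }
  set.seed(9)
  tok <- array(rnorm(64 * 16), c(64, 16, 1))
  perm <- sample(64)
  out <- gen_transformer(gen, tok, grid_w = 8, grid_h = 8)
  out_perm <- gen_transformer(gen, tok[perm, , , drop = FALSE],
                              grid_w = 8, grid_h = 8)
  # position-sensitive: permuting inputs does not just permute outputs
  expect_gt(max(abs(out_perm - out[perm, , , drop = FALSE])), 1e-6)
})

test_that("dwconv ffn output depends only on the depth-wise kernel footprint", {
  gen <- generator_init(tiny_gen_cfg(transformer_depth = 1L), seed = 5)
  blk <- gen$params$blocks[[1]]
  tok <- array(rnorm(64 * 16), c(64, 16, 1))
  base <- cbctgan:::g_ffn(gen, blk, cbctgan:::ag_const(tok), 8, 8)$value
  # perturb the token at grid (row 7, col 7) -> token index 6*8+7 = 55 (1-based)
  tok2 <- tok
  tok2[55, , 1] <- tok2[55, , 1] + 10
  pert <- cbctgan:::g_ffn(gen, blk, cbctgan:::ag_const(tok2), 8, 8)$value
  # token (row 0, col 0) is far outside the 3x3 footprint: unchanged
  expect_equal(pert[1, , 1], base[1, , 1], tolerance = 1e-12)
  # a neighbour inside the footprint changes
  expect_gt(max(abs(pert[55, , 1] - base[55, , 1])), 0)

  # Seq2Img / Img2Seq round trip preserves every position
  x <- array(rnorm(4 * 3 * 2 * 2), c(3, 4, 2, 2))
  seq <- cbctgan:::ag_img2seq(cbctgan:::ag_const(x))
  back <- cbctgan:::ag_seq2img(cbctgan:::ag_node(seq$value), 4L, 3L)
  expect_identical(back$value, x)
})

test_that("detokenization restores the grid and inverts flattening", {
  gen <- generator_init(tiny_gen_cfg(), seed = 6)
  tok <- array(rnorm(12 * gen$cfg$token_dim), c(12, gen$cfg$token_dim, 1))
  fmap <- gen_detokenize(gen, tok, grid_w = 4, grid_h = 3)
  expect_equal(dim(fmap)[1:2], c(3, 4))
  one <- gen_detokenize(gen, tok[1, , , drop = FALSE], grid_w = 1, grid_h = 1)
  expect_equal(dim(one)[1:2], c(1, 1))
})

test_that("decoder mirrors the encoder and squashes into [-1, 1]", {
  gen <- generator_init(tiny_gen_cfg(), seed = 7)
  x <- rand_image(32, seed = 7)
  enc <- gen_encode(gen, x)
  out <- gen_decode(gen, enc$bottleneck, enc$skips)
  expect_equal(dim(out)[1:2], c(32, 32))
  expect_true(all(out >= -1 & out <= 1))
  # zero-weight final conv gives an exactly zero image
  gen$params$out$w$value[] <- 0
  gen$params$out$b$value[] <- 0
  out0 <- gen_decode(gen, enc$bottleneck, enc$skips)
  expect_true(all(out0 == 0))
})

test_that("translate preserves shape, flips domain, and respects rezero", {
  gen <- generator_init(tiny_gen_cfg(), seed = 8)
  img <- domain_image(rand_image(32, seed = 8), "A_cbct", "normalized")
  out <- translate(img, gen)
  expect_equal(dim(out$pixels), c(32, 32))
  expect_equal(out$domain, "B_ct")
  expect_true(all(out$pixels >= -1 & out$pixels <= 1))

  # with rezero gates at zero, perturbing transformer weights cannot change
  # the output; once the gates open it does
  base <- translate(img, gen)$pixels
  gen$params$blocks[[1]]$wq$value[] <- gen$params$blocks[[1]]$wq$value + 0.5
  expect_identical(translate(img, gen)$pixels, base)
  gen$params$blocks[[1]]$alpha1$value <- 0.3
  expect_gt(max(abs(translate(img, gen)$pixels - base)), 0)
})

test_that("gradient reaches every parameter group of the generator", {
  gen <- generator_init(tiny_gen_cfg(transformer_depth = 1L), seed = 9)
  for (blk in gen$params$blocks) {
    blk$alpha1$value <- 0.05
    blk$alpha2$value <- 0.05
  }
  x <- cbctgan:::ag_const(rand_batch(32, 2, seed = 9))
  y <- cbctgan:::g_forward(gen, x)
  loss <- cbctgan:::ag_mean(cbctgan:::ag_square(y))
  params <- cbctgan:::collect_params(gen$params)
  cbctgan:::ag_zero_grad(params)
  cbctgan:::ag_backward(loss)
  for (p in params) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
    expect_gt(sum(p$grad != 0), 0)
  }
})
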
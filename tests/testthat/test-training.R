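make_tiny_model <- function(seed = 1L) {
  cyclegan_init(tiny_gen_cfg(), tiny_disc_cfg(), loss_weights(), seed = seed)
}

tiny_batches <- function(n_batches, bs = 2L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_batches), function(i) {
    array(runif(32 * 32 * bs, -1, 1), c(32, 32, 1, bs))
  })
}

test_that("one training step runs five generator updates and one discriminator update", {
  model <- make_tiny_model()
  cfg <- train_config(epochs = 1L, batch_size = 2L, lr_gen = 1e-4,
                      lr_disc = 1e-4, seed = 1L)
  res <- train_step(model, tiny_batches(6, seed = 1), tiny_batches(6, seed = 2),
                    cfg)
  expect_equal(model$counters$gen_updates, 5L)
  expect_equal(model$counters$disc_updates, 1L)
  res <- train_step(model, tiny_batches(6, seed = 3), tiny_batches(6, seed = 4),
                    cfg, res$opt)
  expect_equal(model$counters$gen_updates, 10L)
  expect_equal(model$counters$disc_updates, 2L)
})

test_that("zero learning rates leave every parameter bit-identical", {
  model <- make_tiny_model()
  before <- cbctgan:::snapshot_params(model)
  cfg <- train_config(epochs = 1L, batch_size = 2L, lr_gen = 0, lr_disc = 0,
                      seed = 1L)
  train_step(model, tiny_batches(6, seed = 1), tiny_batches(6, seed = 2), cfg)
  after <- cbctgan:::snapshot_params(model)
  expect_identical(before, after)
})

test_that("loss breakdown totals equal the stated weighted sums", {
  model <- make_tiny_model()
  cfg <- train_config(epochs = 1L, batch_size = 2L, seed = 1L)
  bd <- train_step(model, tiny_batches(6, seed = 1), tiny_batches(6, seed = 2),
                   cfg)$breakdown
  w <- model$weights
  expect_lt(abs(bd$gen_total_ab -
                (bd$gan_ab + w$lambda_cyc * bd$cyc_a + w$lambda_idt * bd$idt_a +
                 w$lambda_consist * bd$consist_a)), 1e-6)
  expect_lt(abs(bd$gen_total_ba -
                (bd$gan_ba + w$lambda_cyc * bd$cyc_b + w$lambda_idt * bd$idt_b +
                 w$lambda_consist * bd$consist_b)), 1e-6)
  expect_lt(abs(bd$disc_total_a - (bd$disc_a + bd$gp_a)), 1e-6)
  expect_true(all(unlist(bd) >= 0 | is.na(unlist(bd))))
})

test_that("fixed seeds make training bit-reproducible", {
  spec <- tiny_spec()
  ds <- build_dataset(spec, 4, 1, seed = 3)
  cfg <- train_config(epochs = 1L, batch_size = 2L, seed = 11L,
                      lr_gen = 1e-3, lr_disc = 1e-3)
  f1 <- fit(ds, cfg, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  f2 <- fit(ds, cfg, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  expect_identical(f1$history[, setdiff(names(f1$history), "wall_s")],
                   f2$history[, setdiff(names(f2$history), "wall_s")])
  expect_identical(cbctgan:::snapshot_params(f1$model),
                   cbctgan:::snapshot_params(f2$model))
})

test_that("fit runs the contracted number of steps and validates", {
  ds <- build_dataset(tiny_spec(), 4, 1, seed = 3)
  cfg <- train_config(epochs = 1L, batch_size = 5L, seed = 1L)
  fr <- fit(ds, cfg, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  expect_equal(nrow(fr$history), 1L)   # 4 images, batch 5 -> one step
  expect_equal(nrow(fr$validation), 1L)
  expect_true(all(c("mae", "psnr", "ssim") %in% names(fr$validation)))
  expect_error(fit(structure(list(train_A = list(), train_B = list(),
                                  test_pairs = list(), seed = 1,
                                  spec = tiny_spec()),
                             class = "dataset_bundle"), cfg),
               "empty dataset")
})

test_that("ablation toggles act on the loss surface as contracted", {
  ds <- build_dataset(tiny_spec(), 4, 1, seed = 3)
  # pl off: consistency column identically zero
  cfg_nopl <- train_config(epochs = 1L, batch_size = 2L, seed = 1L, pl = FALSE)
  fr <- fit(ds, cfg_nopl, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  expect_true(all(fr$history$consist_a == 0))
  expect_true(all(fr$history$consist_b == 0))
  # gp off: penalty column zero and disc totals equal the classification loss
  cfg_nogp <- train_config(epochs = 1L, batch_size = 2L, seed = 1L, gp = FALSE)
  fr2 <- fit(ds, cfg_nogp, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  expect_true(all(fr2$history$gp_a == 0 & fr2$history$gp_b == 0))
  expect_equal(fr2$history$disc_total_a, fr2$history$disc_a)
  # with gp on the penalty contributes
  cfg_gp <- train_config(epochs = 1L, batch_size = 2L, seed = 1L, gp = TRUE)
  fr3 <- fit(ds, cfg_gp, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  expect_gt(max(fr3$history$gp_a), 0)
  # dcn off: generators use the mlp ffn and the parameter count changes
  m_dcn <- cyclegan_init(tiny_gen_cfg(), tiny_disc_cfg(), seed = 1, dcn = TRUE)
  m_mlp <- cyclegan_init(tiny_gen_cfg(), tiny_disc_cfg(), seed = 1, dcn = FALSE)
  expect_equal(m_mlp$gen_ab$cfg$ffn_variant, "mlp")
  expect_false(n_parameters(m_dcn$gen_ab) == n_parameters(m_mlp$gen_ab))
})

test_that("checkpoints round-trip and resumed models reproduce losses", {
  model <- make_tiny_model(seed = 5L)
  cfg <- train_config(epochs = 1L, batch_size = 2L, seed = 5L,
                      lr_gen = 1e-3, lr_disc = 1e-3)
  train_step(model, tiny_batches(6, seed = 1), tiny_batches(6, seed = 2), cfg)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  resumed <- load_checkpoint(ck)
  expect_identical(cbctgan:::snapshot_params(resumed),
                   cbctgan:::snapshot_params(model))
  expect_equal(resumed$counters$gen_updates, 5L)
  # identical continuation: same batches, fresh optimizer state on both sides
  bA <- tiny_batches(6, seed = 7)
  bB <- tiny_batches(6, seed = 8)
  bd1 <- train_step(model, bA, bB, cfg)$breakdown
  bd2 <- train_step(resumed, bA, bB, cfg)$breakdown
  expect_equal(bd1[, !(names(bd1) %in% c("gen_updates", "disc_updates"))],
               bd2[, !(names(bd2) %in% c("gen_updates", "disc_updates"))])
  # translation outputs agree exactly
  img <- domain_image(rand_image(32, seed = 10), "A_cbct", "normalized")
  expect_identical(translate(img, model$gen_ab)$pixels,
                   translate(img, resumed$gen_ab)$pixels)
})

test_that("checkpoints refuse to load into a mismatched architecture", {
  model <- make_tiny_model()
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  raw <- readRDS(ck)
  raw$cfgs$gen$base_width <- 8L    # tamper with the stored architecture
  saveRDS(raw, ck)
  expect_error(load_checkpoint(ck), "hash mismatch")
})

test_that("training histories survive CSV round trips", {
  ds <- build_dataset(tiny_spec(), 4, 1, seed = 3)
  cfg <- train_config(epochs = 2L, batch_size = 2L, seed = 1L)
  fr <- fit(ds, cfg, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg())
  f <- tempfile(fileext = ".csv")
  write_history(fr$history, f)
  back <- read_history(f)
  expect_equal(as.data.frame(back), as.data.frame(fr$history),
               tolerance = 1e-12)
  expect_true(all(diff(back$gen_updates) > 0))
})
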
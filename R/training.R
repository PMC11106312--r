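#' Training schedule and optimizer configuration
#'
#' The update schedule follows the 5:1 rule: each training step performs
#' `gen_steps_per_disc_step` generator updates, each on a freshly drawn
#' batch, followed by one discriminator update. Ablation toggles mirror the
#' method's three additions: `dcn` (depth-wise convolution feed-forward
#' network vs plain MLP), `gp` (gradient penalty on the discriminators),
#' `pl` (pixel-wise consistency loss in the generator objective).
#'
#' @param epochs training epochs (an epoch cycles once through the shuffled
#'   generator-batch schedule).
#' @param batch_size images per batch (default 5).
#' @param gen_steps_per_disc_step generator updates per discriminator update
#'   (default 5).
#' @param lr_gen,lr_disc Adam learning rates.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed integer seed governing weight init order, batch draws, and
#'   everything stochastic in [fit()].
#' @param dcn,gp,pl logical ablation toggles.
#' @param validate_every validate on the test pairs every this many epochs.
#' @param validate_per_step if `TRUE`, validate after every training step
#'   instead (finer-grained best-checkpoint selection for short schedules).
#' @param verbose print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 5L,
                         gen_steps_per_disc_step = 5L,
                         lr_gen = 1e-4, lr_disc = 1e-4,
                         beta1 = 0.5, beta2 = 0.99, adam_eps = 1e-8,
                         seed = 0L, dcn = TRUE, gp = TRUE, pl = TRUE,
                         validate_every = 1L, validate_per_step = FALSE,
                         verbose = FALSE) {
  for (nm in c("epochs", "batch_size", "gen_steps_per_disc_step")) {
    v <- get(nm)
    if (length(v) != 1 || !is.numeric(v) || v < 1 || v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 gen_steps_per_disc_step = as.integer(gen_steps_per_disc_step),
                 lr_gen = lr_gen, lr_disc = lr_disc,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed),
                 dcn = isTRUE(dcn), gp = isTRUE(gp), pl = isTRUE(pl),
                 validate_every = as.integer(validate_every),
                 validate_per_step = isTRUE(validate_per_step),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Initialize the full translation model
#'
#' Two generators (A->B and B->A) and two patch discriminators (one per
#' domain), plus update counters. The `dcn` toggle selects the generator's
#' feed-forward variant.
#'
#' @param gen_cfg a [generator_config()] shared by both generators.
#' @param disc_cfg a [discriminator_config()] shared by both discriminators.
#' @param weights a [loss_weights()].
#' @param seed integer seed for all weight draws.
#' @param dcn if `FALSE`, overrides `gen_cfg$ffn_variant` to `"mlp"`.
#' @return An object of class `cyclegan_model`.
#' @export
cyclegan_init <- function(gen_cfg = generator_config(),
                          disc_cfg = discriminator_config(),
                          weights = loss_weights(), seed = 1L, dcn = TRUE) {
  if (!dcn) gen_cfg$ffn_variant <- "mlp"
  counters <- new.env(parent = emptyenv())
  counters$gen_updates <- 0L
  counters$disc_updates <- 0L
  structure(list(gen_ab = generator_init(gen_cfg, seed),
                 gen_ba = generator_init(gen_cfg, seed + 1L),
                 disc_a = discriminator_init(disc_cfg, seed + 2L),
                 disc_b = discriminator_init(disc_cfg, seed + 3L),
                 weights = weights, counters = counters,
                 seed = as.integer(seed)),
            class = "cyclegan_model")
}

#' @export
print.cyclegan_model <- function(x, ...) {
  cat(sprintf("<cyclegan_model> generators %s params each (ffn=%s), discriminators %s params each\n",
              format(n_parameters(x$gen_ab), big.mark = ","),
              x$gen_ab$cfg$ffn_variant,
              format(n_parameters(x$disc_a), big.mark = ",")))
  cat(sprintf("  updates: generator %d, discriminator %d\n",
              x$counters$gen_updates, x$counters$disc_updates))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(params = params,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$params)) {
    p <- state$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

# ---- loss graph assembly ----------------------------------------------------

# One generator-direction loss (adversarial + weighted cycle/identity/
# consistency terms) assembled as graph nodes.
gen_direction_losses <- function(gen_fwd, gen_bwd, disc_target, src, w, pl_on) {
  fake <- g_forward(gen_fwd, src)
  rec <- g_forward(gen_bwd, fake)
  idt <- g_forward(gen_bwd, src)       # same-domain mapping of the source
  sc <- d_forward(disc_target, fake)
  gan <- gan_loss_node(sc, 1, w$gan_form)
  cyc <- reg_loss_node(rec, src, w$reg_form)
  idt_l <- reg_loss_node(idt, src, w$reg_form)
  consist <- if (pl_on) consist_loss_node(src, fake, w$consist_size) else NULL
  total <- ag_add(gan, ag_mul_const(cyc, w$lambda_cyc))
  total <- ag_add(total, ag_mul_const(idt_l, w$lambda_idt))
  if (!is.null(consist)) {
    total <- ag_add(total, ag_mul_const(consist, w$lambda_consist))
  }
  list(gan = gan$value, cyc = cyc$value, idt = idt_l$value,
       consist = if (is.null(consist)) 0 else consist$value,
       total_node = total, fake = fake$value)
}

disc_losses <- function(disc, real, fake_detached, w, gp_on) {
  sc_real <- d_forward(disc, real)
  sc_fake <- d_forward(disc, fake_detached)
  gan <- ag_add(gan_loss_node(sc_real, 1, w$gan_form),
                gan_loss_node(sc_fake, 0, w$gan_form))
  gp_node <- NULL
  if (gp_on && w$lambda_gp > 0) {
    # penalty averaged over the real and generated batches
    p_real <- gp_penalty_node(disc, real$value, w$gamma)
    p_fake <- gp_penalty_node(disc, fake_detached$value, w$gamma)
    gp_node <- ag_mul_const(ag_add(p_real, p_fake), w$lambda_gp / 2)
  }
  total <- if (is.null(gp_node)) gan else ag_add(gan, gp_node)
  list(gan = gan$value, gp = if (is.null(gp_node)) 0 else gp_node$value,
       total_node = total)
}

check_finite <- function(x, what, context = "") {
  if (!all(is.finite(unlist(x)))) {
    stop(sprintf("non-finite %s encountered%s; training aborted (reload the last saved checkpoint to resume)",
                 what, context), call. = FALSE)
  }
  invisible(x)
}

#' One training step: five generator updates, one discriminator update
#'
#' Performs `gen_steps_per_disc_step` generator updates — each on a freshly
#' drawn pair of batches — followed by a single discriminator update (with
#' gradient penalty when enabled), exactly the update ratio of the training
#' schedule. Both generators are updated jointly on the sum of the two
#' direction losses; both discriminators jointly on theirs.
#'
#' @param model a [cyclegan_init()] model (updated in place: parameter nodes
#'   and counters are mutable).
#' @param batches_A,batches_B lists of `gen_steps_per_disc_step + 1`
#'   normalized image batches `(H, W, 1, n)`; the final element feeds the
#'   discriminator update.
#' @param cfg a [train_config()].
#' @param opt optimizer state from a previous call (or `NULL` to create).
#' @return List with the final `breakdown` (a one-row data.frame of all loss
#'   components) and the optimizer state `opt`.
#' @export
train_step <- function(model, batches_A, batches_B, cfg = train_config(),
                       opt = NULL) {
  w <- model$weights
  stopifnot(is.list(batches_A), is.list(batches_B),
            length(batches_A) >= cfg$gen_steps_per_disc_step + 1L,
            length(batches_B) >= cfg$gen_steps_per_disc_step + 1L)
  if (is.null(opt)) {
    opt <- list(
      gen = adam_new(c(collect_params(model$gen_ab$params),
                       collect_params(model$gen_ba$params))),
      disc = adam_new(c(collect_params(model$disc_a$params),
                        collect_params(model$disc_b$params))))
  }
  breakdown <- NULL
  fake_b_last <- fake_a_last <- NULL
  for (s in seq_len(cfg$gen_steps_per_disc_step)) {
    a <- ag_const(batches_A[[s]])
    b <- ag_const(batches_B[[s]])
    dir_ab <- gen_direction_losses(model$gen_ab, model$gen_ba, model$disc_b,
                                   a, w, cfg$pl)
    dir_ba <- gen_direction_losses(model$gen_ba, model$gen_ab, model$disc_a,
                                   b, w, cfg$pl)
    total <- ag_add(dir_ab$total_node, dir_ba$total_node)
    check_finite(total$value, "generator loss")
    ag_zero_grad(opt$gen$params)
    ag_backward(total)
    opt$gen <- adam_step(opt$gen, cfg$lr_gen, cfg$beta1, cfg$beta2, cfg$adam_eps)
    model$counters$gen_updates <- model$counters$gen_updates + 1L
    fake_b_last <- dir_ab$fake
    fake_a_last <- dir_ba$fake
    breakdown <- data.frame(
      gan_ab = dir_ab$gan, cyc_a = dir_ab$cyc, idt_a = dir_ab$idt,
      consist_a = dir_ab$consist, gen_total_ab = gen_direction_total(dir_ab, w),
      gan_ba = dir_ba$gan, cyc_b = dir_ba$cyc, idt_b = dir_ba$idt,
      consist_b = dir_ba$consist, gen_total_ba = gen_direction_total(dir_ba, w))
  }
  # discriminator update on fresh real batches; fakes regenerated (detached)
  a_d <- batches_A[[cfg$gen_steps_per_disc_step + 1L]]
  b_d <- batches_B[[cfg$gen_steps_per_disc_step + 1L]]
  fake_b_d <- translate_batch(model$gen_ab, a_d)
  fake_a_d <- translate_batch(model$gen_ba, b_d)
  la <- disc_losses(model$disc_a, ag_const(a_d), ag_const(fake_a_d), w, cfg$gp)
  lb <- disc_losses(model$disc_b, ag_const(b_d), ag_const(fake_b_d), w, cfg$gp)
  dtotal <- ag_add(la$total_node, lb$total_node)
  check_finite(dtotal$value, "discriminator loss")
  ag_zero_grad(opt$disc$params)
  ag_backward(dtotal)
  opt$disc <- adam_step(opt$disc, cfg$lr_disc, cfg$beta1, cfg$beta2, cfg$adam_eps)
  model$counters$disc_updates <- model$counters$disc_updates + 1L
  breakdown <- cbind(breakdown,
                     data.frame(disc_a = la$gan, gp_a = la$gp,
                                disc_total_a = la$gan + la$gp,
                                disc_b = lb$gan, gp_b = lb$gp,
                                disc_total_b = lb$gan + lb$gp,
                                gen_updates = model$counters$gen_updates,
                                disc_updates = model$counters$disc_updates))
  list(breakdown = breakdown, opt = opt)
}

gen_direction_total <- function(dir, w) {
  dir$gan + w$lambda_cyc * dir$cyc + w$lambda_idt * dir$idt +
    w$lambda_consist * dir$consist
}

# Snapshot / restore raw parameter values of a model (deep copy).
snapshot_params <- function(model) {
  lapply(c(collect_params(model$gen_ab$params),
           collect_params(model$gen_ba$params),
           collect_params(model$disc_a$params),
           collect_params(model$disc_b$params)),
         function(p) p$value)
}

restore_params <- function(model, snapshot) {
  ps <- c(collect_params(model$gen_ab$params),
          collect_params(model$gen_ba$params),
          collect_params(model$disc_a$params),
          collect_params(model$disc_b$params))
  stopifnot(length(ps) == length(snapshot))
  for (i in seq_along(ps)) ps[[i]]$value <- snapshot[[i]]
  invisible(model)
}

#' Train the translation model on a dataset bundle
#'
#' Images are normalized to `[-1, 1]` with `window` (and resized to the
#' generator's `input_size` when needed). Each epoch shuffles the training
#' pools and runs `floor(n / (batch_size * gen_steps_per_disc_step))`
#' training steps (at least one), so every training image feeds roughly one
#' generator update per epoch. After every `validate_every` epochs the A
#' members of the test pairs are translated and masked MAE/PSNR/SSIM against
#' the B members recorded; the parameters with the best validation MAE are
#' kept and restored into the model at the end.
#'
#' @param dataset a [build_dataset()] bundle (hu_like images).
#' @param cfg a [train_config()].
#' @param model a [cyclegan_init()] model, or `NULL` to create one from
#'   `gen_cfg`/`disc_cfg`/`weights` with seed `cfg$seed`.
#' @param gen_cfg,disc_cfg,weights used only when `model` is `NULL`.
#' @param window a [norm_window()].
#' @param checkpoint_dir if non-`NULL`, the best model is saved here.
#' @return An object of class `cbct_fit`: the trained `model` (best
#'   validation weights restored), `history` (class `train_history`), and the
#'   validation table.
#' @export
fit <- function(dataset, cfg = train_config(), model = NULL,
                gen_cfg = generator_config(), disc_cfg = discriminator_config(),
                weights = loss_weights(), window = norm_window(),
                checkpoint_dir = NULL) {
  stopifnot(inherits(dataset, "dataset_bundle"))
  if (length(dataset$train_A) < 1 || length(dataset$train_B) < 1) {
    stop("empty dataset", call. = FALSE)
  }
  if (is.null(model)) {
    model <- cyclegan_init(gen_cfg, disc_cfg, weights, seed = cfg$seed,
                           dcn = cfg$dcn)
  }
  size <- model$gen_ab$cfg$input_size
  prep <- function(img) {
    if (nrow(img$pixels) != size) img <- resize_image(img, size)
    normalize_image(img, window)$pixels
  }
  pool_A <- lapply(dataset$train_A, prep)
  pool_B <- lapply(dataset$train_B, prep)
  n <- min(length(pool_A), length(pool_B))
  gspd <- cfg$gen_steps_per_disc_step
  bs <- cfg$batch_size
  steps_per_epoch <- max(1L, n %/% (bs * gspd))
  make_batch <- function(pool, idx) {
    array(unlist(pool[idx]), c(size, size, 1L, length(idx)))
  }
  history <- NULL
  validation <- NULL
  opt <- NULL
  best <- list(mae = Inf, snapshot = NULL, epoch = NA_integer_)
  t_start <- proc.time()[3]
  validate_now <- function(epoch, step) {
    rep_ <- evaluate_pairs(dataset$test_pairs, model$gen_ab,
                           window = window, scale = "hu")
    validation <<- rbind(validation,
                         data.frame(epoch = epoch, step = step,
                                    mae = rep_$mae, psnr = rep_$psnr,
                                    ssim = rep_$ssim))
    if (is.finite(rep_$mae) && rep_$mae < best$mae) {
      best <<- list(mae = rep_$mae, snapshot = snapshot_params(model),
                    epoch = epoch)
    }
    rep_
  }
  local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord_A <- sample.int(length(pool_A))
      ord_B <- sample.int(length(pool_B))
      for (step in seq_len(steps_per_epoch)) {
        draw <- function(ord, pool) {
          lapply(seq_len(gspd + 1L), function(s) {
            if (s <= gspd) {
              lo <- (step - 1L) * gspd * bs + (s - 1L) * bs
              idx <- ord[(lo + seq_len(bs) - 1L) %% length(pool) + 1L]
            } else {
              idx <- sample.int(length(pool), bs, replace = bs > length(pool))
            }
            make_batch(pool, idx)
          })
        }
        res <- train_step(model, draw(ord_A, pool_A), draw(ord_B, pool_B),
                          cfg, opt)
        opt <- res$opt
        row <- cbind(data.frame(epoch = epoch, step = step,
                                wall_s = unname(proc.time()[3] - t_start)),
                     res$breakdown)
        history <- if (is.null(history)) row else rbind(history, row)
        if (cfg$validate_per_step) validate_now(epoch, step)
      }
      if (!cfg$validate_per_step &&
          (epoch %% cfg$validate_every == 0L || epoch == cfg$epochs)) {
        validate_now(epoch, steps_per_epoch)
      }
      if (cfg$verbose && !is.null(validation)) {
        last <- validation[nrow(validation), ]
        message(sprintf("epoch %d: val MAE %.2f, PSNR %.2f, SSIM %.4f (best %.2f)",
                        epoch, last$mae, last$psnr, last$ssim, best$mae))
      }
    }
  })
  if (!is.null(best$snapshot)) restore_params(model, best$snapshot)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(checkpoint_dir, "best.rds"))
  }
  structure(list(model = model,
                 history = structure(history, class = c("train_history",
                                                        "data.frame")),
                 validation = validation,
                 best_epoch = best$epoch),
            class = "cbct_fit")
}

#' @export
print.cbct_fit <- function(x, ...) {
  cat(sprintf("<cbct_fit> %d training steps, best epoch %s (val MAE %.2f HU)\n",
              nrow(x$history), x$best_epoch,
              min(x$validation$mae, na.rm = TRUE)))
  invisible(x)
}

#' Save or load the training history as CSV
#'
#' @param history a `train_history` data.frame.
#' @param path CSV file path.
#' @export
write_history <- function(history, path) {
  write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  structure(read.csv(path), class = c("train_history", "data.frame"))
}

#' Save a model checkpoint
#'
#' The checkpoint stores the raw parameter arrays together with the full
#' architecture configurations and a hash of those configurations; loading
#' re-creates the model and verifies the hash, so a checkpoint can never be
#' silently loaded into a mismatched architecture.
#'
#' @param model a `cyclegan_model`.
#' @param path destination file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  cfgs <- list(gen = model$gen_ab$cfg, disc = model$disc_a$cfg,
               weights = model$weights)
  saveRDS(list(cfgs = cfgs, hash = config_hash(cfgs),
               params = snapshot_params(model),
               counters = list(gen = model$counters$gen_updates,
                               disc = model$counters$disc_updates),
               seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(config_hash(ck$cfgs), ck$hash)) {
    stop("checkpoint config hash mismatch: file corrupted or incompatible",
         call. = FALSE)
  }
  model <- cyclegan_init(ck$cfgs$gen, ck$cfgs$disc, ck$cfgs$weights,
                         seed = ck$seed)
  restore_params(model, ck$params)
  model$counters$gen_updates <- ck$counters$gen
  model$counters$disc_updates <- ck$counters$disc
  model
}
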
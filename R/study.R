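#' Reduced phantom translation study
#'
#' The package's self-contained reference experiment: simulate an unpaired
#' CBCT/CT phantom dataset, train a reduced translation model on CPU, and
#' measure whether the synthetic CT moves closer to the ground-truth CT than
#' the CBCT it was generated from. All quantities are computed inside the
#' body masks on the HU-like scale.
#'
#' The default problem size (64 x 64 phantoms, 200 unpaired images per
#' domain, 8 aligned test pairs, encoder depth 2, 2 transformer blocks,
#' base width 16, 4 epochs) is chosen so the whole study runs in minutes on
#' one CPU while still exercising every component of the method: both
#' generators, both discriminators, all five loss terms, and the 5:1 update
#' schedule. The learning rate is raised to 1e-3 (from the full-scale 1e-4
#' default) to match the much smaller model and step budget, and validation
#' runs after every training step so the best-by-validation-MAE checkpoint
#' tracks the oscillating adversarial dynamics closely.
#'
#' @param seed integer; controls the dataset, weight init, and batch order.
#' @param epochs training epochs.
#' @param n_train unpaired training images per domain.
#' @param n_test aligned test pairs held out for evaluation.
#' @param image_size phantom side length in pixels.
#' @param lr generator and discriminator learning rate.
#' @param verbose print per-epoch validation metrics.
#' @return List with `baseline` and `trained` metric reports (CBCT vs CT and
#'   sCT vs CT), the `fit` object, the `spec` used, and `improved`
#'   (`trained$mae < baseline$mae`).
#' @export
run_phantom_study <- function(seed = 1L, epochs = 4L, n_train = 200L,
                              n_test = 8L, image_size = 64L, lr = 1e-3,
                              verbose = FALSE) {
  spec <- phantom_spec(image_size = as.integer(image_size))
  dataset <- build_dataset(spec, n_train_per_domain = n_train,
                           n_test = n_test, seed = seed)
  window <- norm_window()
  baseline <- evaluate_pairs(dataset$test_pairs, function(img) img,
                             window = window, scale = "hu")
  gen_cfg <- generator_config(input_size = as.integer(image_size),
                              base_width = 16L, encoder_depth = 2L,
                              transformer_depth = 2L, fourier_dim = 16L,
                              token_dim = 48L, n_heads = 4L,
                              ffn_expansion = 2)
  disc_cfg <- discriminator_config(base_width = 16L, n_layers = 3L)
  cfg <- train_config(epochs = as.integer(epochs), batch_size = 5L,
                      lr_gen = lr, lr_disc = lr, seed = seed,
                      validate_per_step = TRUE, verbose = verbose)
  fit_res <- fit(dataset, cfg = cfg, gen_cfg = gen_cfg, disc_cfg = disc_cfg,
                 weights = loss_weights(), window = window)
  trained <- evaluate_pairs(dataset$test_pairs, fit_res$model,
                            window = window, scale = "hu")
  list(baseline = baseline, trained = trained, fit = fit_res, spec = spec,
       improved = trained$mae < baseline$mae)
}
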
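#' Default run configuration
#'
#' Nested configuration covering every tunable of the pipeline, grouped by
#' component. [read_run_config()] merges a YAML file over these defaults and
#' rejects unknown keys, so typos cannot silently fall back to defaults.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    phantom = list(image_size = 256L, n_structures = 6L,
                   cupping_amplitude = 120, n_streaks = 8L,
                   streak_amplitude = 80, noise_sigma = 50, blur_sigma = 0.8,
                   misalign_max_shift = 2, misalign_max_rot = 1),
    preprocess = list(hu_min = -1000, hu_max = 1000, size = 256L,
                      air_threshold = -500),
    generator = list(input_size = 256L, base_width = 48L, encoder_depth = 4L,
                     transformer_depth = 12L, fourier_dim = 32L,
                     token_dim = 384L, n_heads = 6L, ffn_variant = "dwconv",
                     ffn_expansion = 4, dw_kernel = 3L),
    discriminator = list(base_width = 64L, n_layers = 3L,
                         output = "patch_map"),
    losses = list(lambda_cyc = 10, lambda_idt = 0.5, lambda_gp = 10,
                  gamma = 1, lambda_consist = 1, gan_form = "least_squares",
                  reg_form = "l1", consist_size = 32L),
    training = list(epochs = 200L, batch_size = 5L,
                    gen_steps_per_disc_step = 5L, lr_gen = 1e-4,
                    lr_disc = 1e-4, beta1 = 0.5, beta2 = 0.99,
                    dcn = TRUE, gp = TRUE, pl = TRUE, validate_every = 1L),
    evaluation = list(masked = TRUE, scale = "hu",
                      psnr_convention = "standard",
                      hist_range = c(-500, 500), hist_bins = 50L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(sprintf("config section `%s` must be a mapping", path), call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, if (nzchar(path)) "." else "", unknown,
                        collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, if (nzchar(path)) "." else "", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; keys must be a subset of [default_run_config()].
#' @return The merged configuration with attribute `hash`.
#' @export
read_run_config <- function(path) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical (sorted-key) JSON serialization; used to verify that
#' checkpoints are loaded into the architecture that produced them.
#'
#' @param cfg any list of plain values.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(strip_attrs(cfg), auto_unbox = TRUE, digits = NA,
                         sort_keys = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

strip_attrs <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, strip_attrs)
    names(out) <- names(x)
    return(out)
  }
  attributes(x) <- if (!is.null(dim(x))) list(dim = dim(x)) else NULL
  x
}

# Write the resolved config + seed next to run outputs (reproducibility
# contract: every artifact-producing run is reconstructible from these).
write_resolved_config <- function(cfg, seed, out_dir) {
  jsonlite::write_json(list(config = strip_attrs(cfg), seed = seed,
                            hash = config_hash(cfg)),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

config_to_phantom_spec <- function(pc) {
  phantom_spec(image_size = pc$image_size, n_structures = pc$n_structures,
               cupping_amplitude = pc$cupping_amplitude,
               n_streaks = pc$n_streaks,
               streak_amplitude = pc$streak_amplitude,
               noise_sigma = pc$noise_sigma, blur_sigma = pc$blur_sigma,
               misalign_max_shift = pc$misalign_max_shift,
               misalign_max_rot = pc$misalign_max_rot)
}

config_to_generator <- function(gc) {
  generator_config(input_size = gc$input_size, base_width = gc$base_width,
                   encoder_depth = gc$encoder_depth,
                   transformer_depth = gc$transformer_depth,
                   fourier_dim = gc$fourier_dim, token_dim = gc$token_dim,
                   n_heads = gc$n_heads, ffn_variant = gc$ffn_variant,
                   ffn_expansion = gc$ffn_expansion, dw_kernel = gc$dw_kernel)
}

config_to_discriminator <- function(dc) {
  discriminator_config(base_width = dc$base_width, n_layers = dc$n_layers,
                       output = dc$output)
}

config_to_weights <- function(lc) {
  loss_weights(lambda_cyc = lc$lambda_cyc, lambda_idt = lc$lambda_idt,
               lambda_gp = lc$lambda_gp, gamma = lc$gamma,
               lambda_consist = lc$lambda_consist, gan_form = lc$gan_form,
               reg_form = lc$reg_form, consist_size = lc$consist_size)
}

config_to_train <- function(tc, seed = 0L) {
  train_config(epochs = tc$epochs, batch_size = tc$batch_size,
               gen_steps_per_disc_step = tc$gen_steps_per_disc_step,
               lr_gen = tc$lr_gen, lr_disc = tc$lr_disc, beta1 = tc$beta1,
               beta2 = tc$beta2, seed = seed, dcn = tc$dcn, gp = tc$gp,
               pl = tc$pl, validate_every = tc$validate_every)
}
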
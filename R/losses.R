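#' Loss weights and functional forms
#'
#' The weighted loss family of the cycle-consistent translation model. The
#' generator objective per direction is
#' `gan + lambda_cyc * cyc + lambda_idt * idt + lambda_consist * consist`;
#' each discriminator adds a gamma-centred gradient penalty
#' `lambda_gp * E[ (||grad_x D(x)||_2 - gamma)^2 / gamma^2 ]` to its
#' classification loss.
#'
#' @param lambda_cyc cycle-consistency weight (default 10).
#' @param lambda_idt identity weight (default 0.5).
#' @param lambda_gp gradient-penalty weight.
#' @param gamma target input-gradient norm (> 0).
#' @param lambda_consist pixel-wise consistency weight.
#' @param gan_form `"least_squares"` or `"cross_entropy"` adversarial loss.
#' @param reg_form `"l1"` or `"l2"` regression loss for cycle/identity terms.
#' @param consist_size side of the low-pass downsized images compared by the
#'   consistency loss (default 32).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_cyc = 10, lambda_idt = 0.5, lambda_gp = 10,
                         gamma = 1, lambda_consist = 1,
                         gan_form = c("least_squares", "cross_entropy"),
                         reg_form = c("l1", "l2"), consist_size = 32L) {
  gan_form <- match.arg(gan_form)
  reg_form <- match.arg(reg_form)
  if (any(c(lambda_cyc, lambda_idt, lambda_gp, lambda_consist) < 0)) {
    stop("all lambda weights must be >= 0", call. = FALSE)
  }
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (consist_size < 1) stop("`consist_size` must be >= 1", call. = FALSE)
  structure(list(lambda_cyc = lambda_cyc, lambda_idt = lambda_idt,
                 lambda_gp = lambda_gp, gamma = gamma,
                 lambda_consist = lambda_consist, gan_form = gan_form,
                 reg_form = reg_form, consist_size = as.integer(consist_size)),
            class = "loss_weights")
}

as_node <- function(x) {
  if (is_ag_node(x)) return(x)
  if (is_domain_image(x)) x <- x$pixels
  ag_const(x)
}

# ---- node-level losses (shared by the public API and the training loop) ----

gan_loss_node <- function(scores, target_label, form) {
  if (form == "least_squares") {
    ag_l2_loss(scores, ag_const(array(target_label, dim(scores$value))))
  } else {
    p <- ag_sigmoid(scores)
    eps <- 1e-7
    if (target_label == 1) {
      ag_mul_const(ag_mean(ag_log_node(ag_add_const(p, eps))), -1)
    } else {
      ag_mul_const(ag_mean(ag_log_node(ag_add_const(ag_mul_const(p, -1), 1 + eps))), -1)
    }
  }
}

ag_log_node <- function(x) {
  xv <- x$value
  ag_node(log(xv), list(x), function(g) list(g / xv))
}

reg_loss_node <- function(x, y, form) {
  if (form == "l1") ag_l1_loss(x, y) else ag_l2_loss(x, y)
}

consist_loss_node <- function(source, translated, consist_size) {
  f_src <- ag_resize_bilinear(source, consist_size, consist_size)
  f_tr <- ag_resize_bilinear(translated, consist_size, consist_size)
  ag_l1_loss(f_tr, f_src)
}

# ---- public (array-level) losses -------------------------------------------

#' Adversarial classification loss
#'
#' Least squares: mean of `(score - label)^2`. Cross entropy: mean binary
#' log-loss of `sigmoid(score)` against the label. Label 1 marks real images,
#' 0 generated ones.
#'
#' @param scores numeric vector/matrix/array of discriminator scores.
#' @param target_label 0 or 1.
#' @param form `"least_squares"` or `"cross_entropy"`.
#' @return Nonnegative scalar.
#' @export
gan_loss <- function(scores, target_label, form = c("least_squares", "cross_entropy")) {
  form <- match.arg(form)
  stopifnot(target_label %in% c(0, 1))
  s <- as_node(as.array(scores))
  gan_loss_node(s, target_label, form)$value
}

#' Cycle-consistency loss
#'
#' Regression loss between an image and its round-trip reconstruction
#' through both generators.
#'
#' @param x original image (matrix, array, or `domain_image`).
#' @param x_reconstructed round-trip reconstruction, same shape.
#' @param reg_form `"l1"` or `"l2"`.
#' @export
cycle_loss <- function(x, x_reconstructed, reg_form = c("l1", "l2")) {
  reg_form <- match.arg(reg_form)
  reg_loss_node(as_node(x_reconstructed), as_node(x), reg_form)$value
}

#' Identity loss
#'
#' Regression loss between an image and the output of the generator that
#' maps into that image's own domain.
#'
#' @param x original image.
#' @param g_x same-domain generator output for `x`.
#' @param reg_form `"l1"` or `"l2"`.
#' @export
identity_loss <- function(x, g_x, reg_form = c("l1", "l2")) {
  reg_form <- match.arg(reg_form)
  reg_loss_node(as_node(g_x), as_node(x), reg_form)$value
}

#' Pixel-wise consistency loss
#'
#' L1 difference between low-pass versions of the source and translated
#' images, obtained by bilinear downsizing to `consist_size x consist_size`.
#' High-frequency differences (noise, streaks) are removed by the low-pass
#' operator, so the term anchors only the coarse anatomy.
#'
#' @param source source-domain image.
#' @param translated generator output for `source`.
#' @param consist_size target side of the low-pass resize (default 32).
#' @export
pixel_consistency_loss <- function(source, translated, consist_size = 32L) {
  s <- as_batch(if (is_domain_image(source)) source$pixels else source)
  t_ <- as_batch(if (is_domain_image(translated)) translated$pixels else translated)
  consist_loss_node(ag_const(s), ag_const(t_), as.integer(consist_size))$value
}

#' Gamma-centred gradient penalty
#'
#' `lambda_gp * mean_n ((||grad_x D(x_n)||_2 - gamma)^2 / gamma^2)`, with the
#' gradient of each sample's mean patch score taken with respect to its input
#' pixels by backpropagation through the discriminator.
#'
#' @param disc a `cbct_discriminator`.
#' @param sample_batch images: matrix, `(H, W, 1, N)` array, or list of
#'   matrices/`domain_image`s.
#' @param lambda_gp penalty weight.
#' @param gamma target gradient norm.
#' @return Nonnegative scalar; errors if the gradient is not finite.
#' @export
gradient_penalty <- function(disc, sample_batch, lambda_gp = 10, gamma = 1) {
  if (is.list(sample_batch) && !is.array(sample_batch)) {
    mats <- lapply(sample_batch, function(m) if (is_domain_image(m)) m$pixels else m)
    sample_batch <- array(unlist(mats), c(dim(mats[[1]]), 1L, length(mats)))
  }
  x <- as_batch(sample_batch)
  pen <- gp_penalty_node(disc, x, gamma)
  out <- lambda_gp * pen$value
  if (!is.finite(out)) {
    stop("gradient penalty is not finite: discriminator gradients diverged",
         call. = FALSE)
  }
  out
}

#' Total generator loss for one direction
#'
#' `gan + lambda_cyc * cyc + lambda_idt * idt + lambda_consist * consist`.
#'
#' @param parts named list or vector with elements `gan`, `cyc`, `idt`,
#'   `consist`.
#' @param weights a [loss_weights()].
#' @export
generator_total <- function(parts, weights = loss_weights()) {
  parts <- as.list(parts)
  consist <- if (is.null(parts$consist)) 0 else parts$consist
  parts$gan + weights$lambda_cyc * parts$cyc + weights$lambda_idt * parts$idt +
    weights$lambda_consist * consist
}

#' Total discriminator loss
#'
#' Classification loss on real images labelled 1 plus on generated images
#' labelled 0, plus a precomputed gradient-penalty term added linearly.
#'
#' @param real_scores,fake_scores discriminator outputs.
#' @param gp_term nonnegative penalty value (0 disables).
#' @param form adversarial loss form.
#' @export
discriminator_total <- function(real_scores, fake_scores, gp_term = 0,
                                form = c("least_squares", "cross_entropy")) {
  form <- match.arg(form)
  gan_loss(real_scores, 1, form) + gan_loss(fake_scores, 0, form) + gp_term
}
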
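#' Least-squares adversarial loss
#'
#' The least-squares GAN objective drives discriminator outputs toward 1 on
#' real samples and 0 on generated ones:
#' `mean((d_real - 1)^2) + mean(d_fake^2)`. It replaces the saturating
#' log-likelihood objective for training stability.
#'
#' @param d_real Discriminator outputs on a real batch.
#' @param d_fake Discriminator outputs on a generated batch.
#' @return Nonnegative scalar loss.
#' @export
lsgan_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0 || length(d_fake) == 0)
    stop("empty batch passed to lsgan_loss")
  mean((d_real - 1)^2) + mean(d_fake^2)
}

#' Cycle-consistency loss (L1)
#'
#' Mean over samples of the feature-summed L1 distance between each sample
#' and its two-generator reconstruction, in both directions:
#' `mean ||G_BA(G_AB(a)) - a||_1 + mean ||G_AB(G_BA(b)) - b||_1`.
#'
#' @param a,b Real batches (samples x features).
#' @param a_rec,b_rec Their reconstructions, matching shapes.
#' @return Nonnegative scalar loss.
#' @export
cycle_loss <- function(a, a_rec, b, b_rec) {
  a <- rbind(a); a_rec <- rbind(a_rec); b <- rbind(b); b_rec <- rbind(b_rec)
  if (!all(dim(a) == dim(a_rec)) || !all(dim(b) == dim(b_rec)))
    stop("shape mismatch between batches and reconstructions")
  mean(rowSums(abs(a_rec - a))) + mean(rowSums(abs(b_rec - b)))
}

#' Identity loss (L1)
#'
#' Penalizes a generator for altering a sample that already belongs to its
#' output domain: `mean ||G_AB(b) - b||_1 + mean ||G_BA(a) - a||_1`.
#'
#' @param b,a Real batches from the generator's own output domain.
#' @param g_ab_of_b `G_AB(b)`; @param g_ba_of_a `G_BA(a)`.
#' @return Nonnegative scalar loss.
#' @export
identity_loss <- function(b, g_ab_of_b, a, g_ba_of_a) {
  b <- rbind(b); g_ab_of_b <- rbind(g_ab_of_b)
  a <- rbind(a); g_ba_of_a <- rbind(g_ba_of_a)
  if (!all(dim(b) == dim(g_ab_of_b)) || !all(dim(a) == dim(g_ba_of_a)))
    stop("shape mismatch between batches and generator outputs")
  mean(rowSums(abs(g_ab_of_b - b))) + mean(rowSums(abs(g_ba_of_a - a)))
}

#' Bundle the four scalar loss terms
#'
#' @param gan_ab,gan_ba Adversarial losses of the two directions.
#' @param cycle Cycle-consistency loss.
#' @param identity Identity loss.
#' @return A `loss_terms` object (named list).
#' @export
loss_terms <- function(gan_ab, gan_ba, cycle, identity) {
  for (v in c(gan_ab, gan_ba, cycle, identity))
    if (!is.na(v) && v < 0) stop("loss components must be nonnegative")
  structure(list(gan_ab = gan_ab, gan_ba = gan_ba, cycle = cycle,
                 identity = identity),
            class = "loss_terms")
}

#' Weighted total training objective
#'
#' `gan_ab + gan_ba + lambda_cycle * cycle + lambda_identity * identity`.
#' With both weights at 1 this is the plain sum of the four terms; setting
#' `lambda_identity = 0` removes the identity term (the identity-loss
#' ablation).
#'
#' @param terms A [loss_terms()] object.
#' @param lambda_cycle,lambda_identity Nonnegative weights (default 1).
#' @return Scalar total loss.
#' @export
total_loss <- function(terms, lambda_cycle = 1, lambda_identity = 1) {
  if (lambda_cycle < 0 || lambda_identity < 0)
    stop("loss weights must be nonnegative")
  terms$gan_ab + terms$gan_ba + lambda_cycle * terms$cycle +
    lambda_identity * terms$identity
}
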
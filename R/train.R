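#' Training configuration
#'
#' Captures the stabilization schedule used for adversarial training: the
#' generators take `g_steps_per_d_step` updates for every discriminator
#' update (so the generator trains three times as much by default, keeping
#' the discriminator from converging first), and the whole epoch schedule is
#' executed `n_repeats` times consecutively on the same data without
#' re-initialization. Optimization is Adam with the usual adversarial
#' settings (lr 2e-4, beta1 0.5, beta2 0.999).
#'
#' @param epochs Epochs per repeat (default 200).
#' @param batch_size Minibatch size (default 64).
#' @param g_steps_per_d_step Generator updates per discriminator update
#'   (default 3).
#' @param n_repeats Consecutive passes over the schedule (default 3).
#' @param lambda_cycle,lambda_identity Weights of the cycle and identity
#'   losses (default 1; set `lambda_identity = 0` for the ablation).
#' @param learning_rate,beta1,beta2 Adam hyper-parameters.
#' @param d_learning_rate Discriminator learning rate (default: equal to
#'   the generator rate); a separate rate is the standard lever for
#'   rebalancing adversarial training when the loss history shows one side
#'   outpacing the other.
#' @param seed Integer seed controlling initialization-independent training
#'   randomness (shuffling).
#' @param freeze_generators Skip generator updates (diagnostic use).
#' @param restart_each_repeat Re-initialize the networks at the start of
#'   every repeat instead of continuing training.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 200, batch_size = 64, g_steps_per_d_step = 3,
                         n_repeats = 3, lambda_cycle = 1, lambda_identity = 1,
                         learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         d_learning_rate = learning_rate,
                         seed = 1, freeze_generators = FALSE,
                         restart_each_repeat = FALSE) {
  if (epochs < 0 || batch_size < 1 || g_steps_per_d_step < 0 || n_repeats < 1)
    stop("epochs/batch_size/g_steps_per_d_step/n_repeats out of range")
  if (lambda_cycle < 0 || lambda_identity < 0)
    stop("loss weights must be nonnegative")
  if (learning_rate <= 0 || d_learning_rate <= 0)
    stop("learning rates must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 g_steps_per_d_step = as.integer(g_steps_per_d_step),
                 n_repeats = as.integer(n_repeats),
                 lambda_cycle = lambda_cycle, lambda_identity = lambda_identity,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 d_learning_rate = d_learning_rate,
                 seed = as.integer(seed),
                 freeze_generators = isTRUE(freeze_generators),
                 restart_each_repeat = isTRUE(restart_each_repeat)),
            class = "train_config")
}

#' Train the cycle-transfer model on two domains
#'
#' Runs the adversarial loop: per minibatch, `g_steps_per_d_step` generator
#' updates (discriminators frozen) followed by one update of each
#' discriminator (generators frozen), repeated over
#' `epochs x n_repeats` passes. Unequal domain sizes are handled by
#' partitioning the larger domain into batches and cycling a reshuffled
#' stream of the smaller one. Deterministic given the config seed.
#'
#' @param model An untrained (or previously trained) `surv_gan` model.
#' @param domain_a,domain_b Preprocessed `domain_dataset`s restricted (or
#'   restrictable) to the model's gene list.
#' @param config A [train_config()].
#' @return The trained model; `$history` holds one row per pass with the
#'   adversarial, cycle, identity and total losses, and
#'   `$d_update_trace` the per-update discriminator loss.
#' @export
train_survgan <- function(model, domain_a, domain_b, config = train_config()) {
  stopifnot(inherits(model, "surv_gan"), inherits(config, "train_config"))
  xa <- model_matrix(domain_a, model$genes)
  xb <- model_matrix(domain_b, model$genes)
  if (ncol(xa) != model$generator_spec$input_dim)
    stop("feature dimension mismatch between data and model")
  if (config$epochs == 0) {
    model$history <- empty_history()
    model$d_update_trace <- numeric(0)
    model$config <- config
    return(model)
  }
  res <- cpp_train(model$gen_ab, model$gen_ba, model$disc_a, model$disc_b,
                   t(xa), t(xb), unclass(config))
  model$gen_ab <- structure(res$gen_ab, class = "generator_params")
  model$gen_ba <- structure(res$gen_ba, class = "generator_params")
  model$disc_a <- structure(res$disc_a, class = "discriminator_params")
  model$disc_b <- structure(res$disc_b, class = "discriminator_params")
  h <- as.data.frame(res$history)
  names(h) <- c("gan_ab", "gan_ba", "cycle", "identity", "total", "d_loss")
  h$pass <- seq_len(nrow(h))
  model$history <- h[, c("pass", "gan_ab", "gan_ba", "cycle", "identity",
                         "total", "d_loss")]
  model$d_update_trace <- as.numeric(res$d_update_trace)
  model$batches_per_epoch <- res$batches_per_epoch
  model$trained <- !config$freeze_generators
  model$config <- config
  model
}

empty_history <- function() {
  data.frame(pass = integer(0), gan_ab = numeric(0), gan_ba = numeric(0),
             cycle = numeric(0), identity = numeric(0), total = numeric(0),
             d_loss = numeric(0))
}

#' Write a training history as TSV
#' @param model A trained `surv_gan` model.
#' @param path Output path.
#' @return Invisibly, the history data frame.
#' @export
write_history <- function(model, path) {
  utils::write.table(model$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model$history)
}
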
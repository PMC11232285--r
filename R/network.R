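#' Generator architecture specification
#'
#' The generator is a residual multilayer perceptron mapping one domain's
#' feature space onto the other's. Input and output dimension are equal
#' (`n_genes + 1`: selected genes plus the log-scale survival-time feature).
#' Architecture: two hidden layers (dense + batch norm + ReLU), three
#' residual blocks, two further hidden layers, and a final linear dense
#' layer. Each residual block is `y = x + BN(dense(ReLU(BN(dense(x)))))`;
#' no activation follows the skip addition, and the final dense layer is
#' linear so log-scale outputs stay unbounded above.
#'
#' @param input_dim Feature dimension (genes + 1).
#' @param hidden_width Width of every hidden layer (default 256).
#' @param n_residual_blocks Number of residual blocks (default 3).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(input_dim, hidden_width = 256, n_residual_blocks = 3) {
  if (input_dim < 1 || hidden_width < 1 || n_residual_blocks < 0)
    stop("invalid generator spec: dimensions must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_width = as.integer(hidden_width),
                 n_residual_blocks = as.integer(n_residual_blocks)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Three hidden layers of dense + leaky-ReLU, then a final linear dense
#' layer producing one unbounded scalar per sample (least-squares GAN:
#' no terminal squashing).
#'
#' @param input_dim Feature dimension.
#' @param hidden_widths Integer vector of the three hidden widths
#'   (default `c(256, 128, 64)`).
#' @param leaky_slope Negative-part slope of the leaky ReLU (default 0.2).
#' @return A `discriminator_spec` object.
#' @export
discriminator_spec <- function(input_dim, hidden_widths = c(256, 128, 64),
                               leaky_slope = 0.2) {
  if (length(hidden_widths) != 3 || any(hidden_widths < 1))
    stop("`hidden_widths` must be three positive integers")
  if (leaky_slope < 0 || leaky_slope >= 1)
    stop("`leaky_slope` must lie in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(hidden_widths),
                 leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

#' Build a generator / discriminator with deterministic initialization
#'
#' Weights are He-initialized from a counter-based RNG seeded with `seed`,
#' so the same seed always yields the same network. Batch-norm scale/shift
#' start at 1/0 with unit running variance (pass-through at initialization).
#'
#' @param spec A [generator_spec()] or [discriminator_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return A parameter list (class `generator_params` / `discriminator_params`).
#' @export
build_generator <- function(spec, seed) {
  stopifnot(inherits(spec, "generator_spec"))
  p <- cpp_init_generator(spec$input_dim, spec$hidden_width,
                          spec$n_residual_blocks, as.double(seed))
  structure(p, class = "generator_params")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(spec, seed) {
  stopifnot(inherits(spec, "discriminator_spec"))
  p <- cpp_init_discriminator(spec$input_dim, spec$hidden_widths[1],
                              spec$hidden_widths[2], spec$hidden_widths[3],
                              spec$leaky_slope, as.double(seed))
  structure(p, class = "discriminator_params")
}

#' Apply a generator or discriminator to a batch
#'
#' Rows of `x` are samples. `training = TRUE` normalizes with batch
#' statistics (as during training); the default uses the stored running
#' statistics, so generation is independent of batch composition.
#'
#' @param params Network parameters from [build_generator()] /
#'   [build_discriminator()] or a trained model.
#' @param x Numeric matrix, samples x features.
#' @param training Use batch statistics instead of running statistics.
#' @return Generator: matrix of the same shape. Discriminator: one scalar
#'   per row of `x`.
#' @export
generator_forward <- function(params, x, training = FALSE) {
  x <- rbind(x)
  out <- t(cpp_generator_forward(params, t(x), training))
  dimnames(out) <- dimnames(x)
  out
}

#' @rdname generator_forward
#' @export
discriminator_forward <- function(params, x) {
  x <- rbind(x)
  as.numeric(cpp_discriminator_forward(params, t(x)))
}

#' Assemble the four-network cycle-transfer model
#'
#' Holds the two generators (A to B and B to A), the two least-squares
#' discriminators, the specs they were built from, and the gene list that
#' fixes the feature space.
#'
#' @param genes Character vector of selected gene IDs; the networks operate
#'   on `length(genes) + 1` features (genes plus the survival-time feature).
#' @param hidden_width Generator hidden width.
#' @param disc_widths Discriminator hidden widths.
#' @param n_residual_blocks Residual blocks in each generator.
#' @param leaky_slope Discriminator leaky-ReLU slope.
#' @param seed Integer seed; the four networks use offset sub-seeds.
#' @param domain_a,domain_b Optional cohort names, recorded for bookkeeping.
#' @return A `surv_gan` model object (untrained).
#' @export
surv_gan <- function(genes, hidden_width = 256, disc_widths = c(256, 128, 64),
                     n_residual_blocks = 3, leaky_slope = 0.2, seed = 1,
                     domain_a = "A", domain_b = "B") {
  d <- length(genes) + 1L
  gspec <- generator_spec(d, hidden_width, n_residual_blocks)
  dspec <- discriminator_spec(d, disc_widths, leaky_slope)
  structure(list(
    genes = genes,
    generator_spec = gspec,
    discriminator_spec = dspec,
    gen_ab = build_generator(gspec, seed),
    gen_ba = build_generator(gspec, seed + 1),
    disc_a = build_discriminator(dspec, seed + 2),
    disc_b = build_discriminator(dspec, seed + 3),
    domain_a = domain_a, domain_b = domain_b,
    trained = FALSE, history = NULL, config = NULL, seed = seed),
    class = "surv_gan")
}

#' @export
print.surv_gan <- function(x, ...) {
  cat(sprintf(paste0("<surv_gan> %s <-> %s: %d features (%d genes + time), ",
                     "generator width %d x %d residual blocks, %s\n"),
              x$domain_a, x$domain_b, length(x$genes) + 1, length(x$genes),
              x$generator_spec$hidden_width,
              x$generator_spec$n_residual_blocks,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all four networks, their
#' specs, the gene list and the training configuration.
#'
#' @param model A `surv_gan` model.
#' @param path Checkpoint path.
#' @return `read_model()` returns the model; `write_model()` returns it
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "surv_gan"))
  saveRDS(model, path)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "surv_gan")) stop("not a surv_gan checkpoint: ", path)
  model
}
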
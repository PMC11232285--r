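#' Generate target-style samples from a source domain
#'
#' Applies the direction's generator (in inference mode, using running
#' batch-norm statistics) to every source sample's feature vector
#' (selected-gene expression + log2-scale time). The output is split back
#' into expression (clipped at 0: the log2(x+1) scale is nonnegative) and a
#' survival-time feature back-transformed to days as
#' `max(2^y - 1, 1)` (floored at one day, mirroring the removal of zero-day
#' samples). In `"joint"` mode the generated time is kept; in
#' `"expression_only"` mode it is discarded and the source sample's real
#' time is retained. Event indicators are always carried over from the
#' source, so event counts are conserved.
#'
#' @param model A trained `surv_gan` model.
#' @param source A preprocessed `domain_dataset` containing the model's
#'   gene list.
#' @param direction `"ab"` (apply G_AB) or `"ba"` (apply G_BA).
#' @param mode `"joint"` or `"expression_only"`.
#' @return A `transfer_result`: generated expression, generated times in
#'   days, source events and IDs, plus a count of negative expression
#'   entries that were clipped.
#' @export
style_transfer <- function(model, source, direction = c("ab", "ba"),
                           mode = c("joint", "expression_only")) {
  stopifnot(inherits(model, "surv_gan"))
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  x <- model_matrix(source, model$genes)  # errors on gene-list mismatch
  gen <- if (direction == "ab") model$gen_ab else model$gen_ba
  y <- generator_forward(gen, x, training = FALSE)
  g <- length(model$genes)
  expr <- y[, seq_len(g), drop = FALSE]
  n_clipped <- sum(expr < 0)
  expr[expr < 0] <- 0
  colnames(expr) <- model$genes
  rownames(expr) <- rownames(x)
  time_days <- pmax(2^y[, g + 1] - 1, 1)
  if (mode == "expression_only") time_days <- source$survival$time
  structure(list(
    expression = expr,
    time_days = as.numeric(time_days),
    events = source$survival$event,
    source_sample_ids = source$survival$sample_id,
    source_name = source$name,
    target_name = if (direction == "ab") model$domain_b else model$domain_a,
    direction = direction, mode = mode, n_clipped = n_clipped),
    class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s -> %s style: %d samples, mode %s, %d clipped entries\n",
              x$source_name, x$target_name, nrow(x$expression), x$mode,
              x$n_clipped))
  invisible(x)
}

#' Round-trip a domain through both generators
#'
#' Maps every source sample to the other domain and back
#' (`source -> G -> G^-1-direction`), returning the reconstructed
#' expression and times with the same splitting and back-transform rules as
#' [style_transfer()]. Reconstruction error against the source measures
#' cycle fidelity.
#'
#' @param model A trained `surv_gan` model.
#' @param source A preprocessed `domain_dataset`.
#' @param direction `"aba"` (A to B to A) or `"bab"`.
#' @return List with `expression` (clipped at 0), `time_days`, and the raw
#'   network output `features` (uncut, for error metrics that include the
#'   time feature).
#' @export
reconstruct_domain <- function(model, source, direction = c("aba", "bab")) {
  stopifnot(inherits(model, "surv_gan"))
  direction <- match.arg(direction)
  x <- model_matrix(source, model$genes)
  first <- if (direction == "aba") model$gen_ab else model$gen_ba
  second <- if (direction == "aba") model$gen_ba else model$gen_ab
  y <- generator_forward(second, generator_forward(first, x, training = FALSE),
                         training = FALSE)
  g <- length(model$genes)
  expr <- y[, seq_len(g), drop = FALSE]
  expr[expr < 0] <- 0
  colnames(expr) <- model$genes
  rownames(expr) <- rownames(x)
  list(expression = expr,
       time_days = pmax(2^y[, g + 1] - 1, 1),
       features = y)
}

#' Augment a real dataset with generated samples
#'
#' Row-concatenates the real target-domain data with a transfer result's
#' generated samples. Generated sample IDs get the prefix `"gen:"` so that
#' benchmark code can audit that they never leak into test folds; their
#' survival records combine generated times with the source domain's event
#' indicators.
#'
#' @param real_target A preprocessed `domain_dataset` (the target domain).
#' @param transfer A `transfer_result` in the same gene space.
#' @return A `domain_dataset` with real rows first, generated rows after.
#' @export
augment_domain <- function(real_target, transfer) {
  stopifnot(inherits(real_target, "domain_dataset"),
            inherits(transfer, "transfer_result"))
  genes <- colnames(transfer$expression)
  if (!all(genes %in% colnames(real_target$expression)))
    stop("gene lists of real data and transfer result do not match")
  real <- subset_genes(real_target, genes)
  if (nrow(transfer$expression) == 0) return(real)
  gen_ids <- paste0("gen:", transfer$source_sample_ids)
  expr <- rbind(real$expression, transfer$expression)
  rownames(expr) <- c(rownames(real$expression), gen_ids)
  surv <- rbind(real$survival,
                data.frame(sample_id = gen_ids,
                           time = transfer$time_days,
                           event = transfer$events,
                           stringsAsFactors = FALSE))
  domain_dataset(real$name, expr, surv, normalized = real$normalized)
}

#' Write a transfer result using the standard TSV dialects
#' @param transfer A `transfer_result`.
#' @param expression_path,survival_path Output paths.
#' @return Invisibly, the transfer result.
#' @export
write_transfer <- function(transfer, expression_path, survival_path) {
  ids <- paste0("gen:", transfer$source_sample_ids)
  df <- data.frame(sample_id = ids, transfer$expression, check.names = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = ids, time = transfer$time_days,
               event = transfer$events),
    survival_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(transfer)
}
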
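#' Score every gene by univariate Cox proportional-hazards concordance
#'
#' For each gene a univariate Cox model is fitted against the domain's
#' survival (Breslow tie handling, unpenalized, at most 100 Newton
#' iterations) and Harrell's C-index of the fitted risk score on the same
#' data is reported. Higher values mark genes whose expression ranks
#' survival better; a constant gene or a failed fit scores 0.5.
#'
#' @param dataset A preprocessed `domain_dataset` with at least two observed
#'   events.
#' @return Data frame with columns `gene_id`, `c_index`, `rank` (rank 1 =
#'   highest C-index; ties broken by gene ID).
#' @export
score_genes <- function(dataset) {
  stopifnot(inherits(dataset, "domain_dataset"))
  if (sum(dataset$survival$event) < 2)
    stop("need at least 2 observed events to score genes")
  tt <- dataset$survival$time
  ev <- dataset$survival$event
  y <- survival::Surv(tt, ev)
  ctrl <- survival::coxph.control(iter.max = 100)
  cvals <- vapply(seq_len(ncol(dataset$expression)), function(j) {
    x <- dataset$expression[, j]
    if (stats::sd(x) == 0) {
      warning("constant gene '", colnames(dataset$expression)[j],
              "' assigned C-index 0.5", call. = FALSE)
      return(0.5)
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x, ties = "breslow", control = ctrl)),
      error = function(e) NULL)
    # a monotone (perfectly separating) likelihood drives the coefficient to
    # infinity and coxph reports NA, but the linear predictor still ranks
    # risk validly; only a failed or degenerate fit falls back to 0.5
    lp <- if (is.null(fit)) NULL else as.numeric(fit$linear.predictors)
    if (is.null(lp) || !all(is.finite(lp)) || stats::sd(lp) == 0) {
      warning("Cox fit failed for gene '", colnames(dataset$expression)[j],
              "'; assigned C-index 0.5", call. = FALSE)
      return(0.5)
    }
    concordance_index(tt, ev, lp)
  }, numeric(1))
  gene_id <- colnames(dataset$expression)
  ord <- order(-cvals, gene_id)
  rank <- integer(length(cvals))
  rank[ord] <- seq_along(cvals)
  data.frame(gene_id = gene_id, c_index = cvals, rank = rank,
             stringsAsFactors = FALSE)
}

#' Select the top-ranked genes
#'
#' Returns the `k` gene IDs with the highest Cox C-index, in descending
#' score order, ties broken lexicographically by gene ID. The same list is
#' meant to be applied to both the source and the target domain, so the two
#' sides of a style transfer share one feature space.
#'
#' @param scores Data frame from [score_genes()].
#' @param k Number of genes to keep (default 300).
#' @return Character vector of `k` gene IDs.
#' @export
select_top_genes <- function(scores, k = 300) {
  if (k > nrow(scores))
    stop("k (", k, ") exceeds the number of scored genes (", nrow(scores), ")")
  ord <- order(-scores$c_index, scores$gene_id)
  scores$gene_id[ord][seq_len(k)]
}

#' Write gene scores / read a ranked gene list
#'
#' `write_gene_scores()` emits a two-column TSV (`gene_id`, `c_index`);
#' `write_gene_list()` / `read_gene_list()` handle the plain-text ranked
#' list consumed by the transfer and survival modules.
#'
#' @param scores Data frame from [score_genes()].
#' @param path Output path.
#' @return Invisibly, the input (writers) or a character vector (reader).
#' @export
write_gene_scores <- function(scores, path) {
  utils::write.table(scores[, c("gene_id", "c_index")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(scores)
}

#' @rdname write_gene_scores
#' @param genes Character vector of gene IDs.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(genes)
}

#' @rdname write_gene_scores
#' @export
read_gene_list <- function(path) readLines(path)
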
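#' Construct a domain dataset
#'
#' A domain dataset bundles one cancer cohort: an expression matrix
#' (samples x genes) and a survival table aligned 1:1 with its rows.
#' It is the unit of data every other function in the package consumes.
#'
#' @param name Cohort name (e.g. a cancer-type abbreviation).
#' @param expression Numeric matrix, samples in rows (rownames = sample IDs),
#'   genes in columns (colnames = gene IDs). No missing values allowed.
#' @param survival Data frame with columns `sample_id`, `time` (days, > 0
#'   after preprocessing) and `event` (1 = event observed, 0 = censored).
#' @param normalized Logical; `TRUE` once values are on the log2(x+1) scale.
#'   Guards against double normalization.
#' @return An object of class `domain_dataset`.
#' @export
domain_dataset <- function(name, expression, survival, normalized = FALSE) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("`expression` needs sample IDs as rownames and gene IDs as colnames")
  if (anyNA(expression))
    stop("`expression` contains missing values")
  survival <- as.data.frame(survival, stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(survival)))
    stop("`survival` must have columns sample_id, time, event")
  survival <- survival[, req]
  survival$sample_id <- as.character(survival$sample_id)
  if (!identical(rownames(expression), survival$sample_id))
    stop("expression rows and survival records must list identical sample IDs in identical order")
  if (anyNA(survival$time) || anyNA(survival$event))
    stop("survival table contains missing values")
  if (!all(survival$event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (observed)")
  if (any(survival$time < 0))
    stop("survival times must be nonnegative")
  if (any(expression < 0))
    stop("expression values must be nonnegative")
  structure(
    list(name = as.character(name)[1], expression = expression,
         survival = survival, normalized = isTRUE(normalized)),
    class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> %s: %d samples x %d genes, %d events, %s\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$survival$event),
              if (x$normalized) "log2(x+1) scale" else "raw scale"))
  invisible(x)
}

#' @export
dim.domain_dataset <- function(x) dim(x$expression)

#' Number of samples in a domain dataset
#' @param dataset A `domain_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) nrow(dataset$expression)

#' Read one cancer domain from expression and survival tables
#'
#' Both files are tab-separated. The expression file is a matrix with the
#' first column holding sample IDs and genes as the remaining columns
#' (set `genes_as_rows = TRUE` for the transposed dialect). The survival
#' file has the header `sample_id<TAB>time<TAB>event`. Only sample IDs
#' present in both files are retained, ordered lexicographically so that
#' downstream deterministic splits are well defined.
#'
#' @param expression_path,survival_path Paths to the two TSV files.
#' @param name Cohort name; defaults to the expression file stem.
#' @param genes_as_rows Set `TRUE` if the expression matrix stores genes as
#'   rows and samples as columns.
#' @param sample_whitelist Optional character vector; when given, only these
#'   sample IDs are kept (e.g. tumor-only barcodes selected upstream).
#' @param normalized Whether the values on disk are already log2(x+1) scaled.
#' @return A `domain_dataset` with raw values as read.
#' @export
read_domain <- function(expression_path, survival_path, name = NULL,
                        genes_as_rows = FALSE, sample_whitelist = NULL,
                        normalized = FALSE) {
  if (!file.exists(expression_path)) stop("expression file not found: ", expression_path)
  if (!file.exists(survival_path)) stop("survival file not found: ", survival_path)
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2) stop("malformed expression file (need ID column plus genes): ",
                           expression_path)
  ids <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(expr[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))[1]
    stop(sprintf("malformed expression file %s: non-numeric value at data line %d",
                 expression_path, bad))
  }
  rownames(m) <- ids
  if (genes_as_rows) m <- t(m)

  surv <- utils::read.delim(survival_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(surv)))
    stop("malformed survival file (header must name sample_id, time, event): ",
         survival_path)
  if (!is.numeric(surv$time) || !is.numeric(surv$event)) {
    bad <- which(is.na(suppressWarnings(as.numeric(surv$time))) |
                 is.na(suppressWarnings(as.numeric(surv$event))))[1]
    stop(sprintf("malformed survival file %s: non-numeric value at data line %d",
                 survival_path, bad))
  }
  surv$sample_id <- as.character(surv$sample_id)
  if (anyDuplicated(surv$sample_id))
    stop("duplicate sample IDs in survival file: ", survival_path)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample IDs in expression file: ", expression_path)

  keep <- sort(intersect(rownames(m), surv$sample_id))
  if (!is.null(sample_whitelist)) keep <- intersect(keep, sample_whitelist)
  if (length(keep) == 0)
    stop("no overlapping sample IDs between expression and survival tables")
  m <- m[keep, , drop = FALSE]
  surv <- surv[match(keep, surv$sample_id), , drop = FALSE]
  rownames(surv) <- NULL
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(expression_path))
  domain_dataset(name, m, surv, normalized = normalized)
}

#' Write a domain dataset to the TSV dialects `read_domain()` accepts
#'
#' @param dataset A `domain_dataset`.
#' @param expression_path,survival_path Output file paths.
#' @return Invisibly, the dataset.
#' @export
write_domain <- function(dataset, expression_path, survival_path) {
  stopifnot(inherits(dataset, "domain_dataset"))
  df <- data.frame(sample_id = rownames(dataset$expression),
                   dataset$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$survival, survival_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Preprocess a raw domain dataset
#'
#' Applies the standard preparation for model input: samples with a recorded
#' survival time of 0 days are removed, and expression values move to the
#' log2(x+1) scale. Survival times stay in days inside the survival table
#' (all survival statistics operate on days); the model-facing log2(t+1)
#' time feature is derived later, when network input is assembled.
#'
#' @param dataset A raw `domain_dataset` (FPKM-like nonnegative values).
#' @return The preprocessed `domain_dataset` with `normalized = TRUE`.
#' @export
preprocess_domain <- function(dataset) {
  stopifnot(inherits(dataset, "domain_dataset"))
  if (dataset$normalized)
    stop("dataset is already normalized; preprocess_domain() must not be applied twice")
  keep <- dataset$survival$time > 0
  expr <- log2(dataset$expression[keep, , drop = FALSE] + 1)
  surv <- dataset$survival[keep, , drop = FALSE]
  rownames(surv) <- NULL
  domain_dataset(dataset$name, expr, surv, normalized = TRUE)
}

#' Keep only samples whose time is positive (idempotent filter step)
#' @noRd
drop_zero_day_samples <- function(dataset) {
  keep <- dataset$survival$time > 0
  subset_samples(dataset, which(keep))
}

#' Subset a domain dataset by sample index or ID
#' @param dataset A `domain_dataset`.
#' @param i Integer indices or character sample IDs.
#' @return The subset `domain_dataset`.
#' @export
subset_samples <- function(dataset, i) {
  if (is.character(i)) i <- match(i, rownames(dataset$expression))
  expr <- dataset$expression[i, , drop = FALSE]
  surv <- dataset$survival[i, , drop = FALSE]
  rownames(surv) <- NULL
  domain_dataset(dataset$name, expr, surv, normalized = dataset$normalized)
}

#' Restrict a domain dataset to a gene list (in the given order)
#' @param dataset A `domain_dataset`.
#' @param genes Character vector of gene IDs; all must be present.
#' @return The gene-subset `domain_dataset`.
#' @export
subset_genes <- function(dataset, genes) {
  missing <- setdiff(genes, colnames(dataset$expression))
  if (length(missing))
    stop("genes absent from dataset: ", paste(utils::head(missing, 5), collapse = ", "))
  expr <- dataset$expression[, genes, drop = FALSE]
  domain_dataset(dataset$name, expr, dataset$survival,
                 normalized = dataset$normalized)
}

#' Summarize a cohort for filtering
#' @param name Cohort name.
#' @param n_samples Total sample count.
#' @param n_events Observed-event count.
#' @return A one-row data frame of class `cohort_summary`.
#' @export
cohort_summary <- function(name, n_samples, n_events) {
  if (n_events < 0 || n_events > n_samples)
    stop("need 0 <= n_events <= n_samples")
  structure(data.frame(name = name, n_samples = as.integer(n_samples),
                       n_events = as.integer(n_events),
                       stringsAsFactors = FALSE),
            class = c("cohort_summary", "data.frame"))
}

#' @rdname cohort_summary
#' @param dataset A `domain_dataset` to summarize.
#' @export
summarize_cohort <- function(dataset) {
  cohort_summary(dataset$name, n_samples(dataset), sum(dataset$survival$event))
}

#' Filter cohorts by sample- and event-count thresholds
#'
#' A cohort enters the study only when it has at least `min_samples` samples
#' and at least `min_events` observed events; cohorts below either bar are
#' too small for a stable survival benchmark.
#'
#' @param summaries Data frame of cohort summaries (columns `name`,
#'   `n_samples`, `n_events`), e.g. from rbinding [cohort_summary()] rows.
#' @param min_samples Minimum sample count (default 300).
#' @param min_events Minimum observed-event count (default 50).
#' @return The retained rows, original order preserved.
#' @export
filter_cohorts <- function(summaries, min_samples = 300, min_events = 50) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0) stop("`summaries` is empty")
  keep <- summaries$n_samples >= min_samples & summaries$n_events >= min_events
  summaries[keep, , drop = FALSE]
}

#' Assemble the network input matrix for a domain
#'
#' The model sees each sample as its selected-gene expression vector plus the
#' survival time as one extra feature on the log2(t+1) scale (column
#' `.time`). Expression must already be normalized.
#'
#' @param dataset A preprocessed `domain_dataset`.
#' @param genes Gene IDs defining the feature order (the selected gene list).
#' @return Numeric matrix, samples x (length(genes) + 1).
#' @export
model_matrix <- function(dataset, genes = colnames(dataset$expression)) {
  if (!dataset$normalized)
    stop("dataset must be preprocessed (log2 scale) before model input is assembled")
  ds <- subset_genes(dataset, genes)
  cbind(ds$expression, .time = log2(ds$survival$time + 1))
}
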
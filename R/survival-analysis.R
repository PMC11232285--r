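#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose predicted risk ordering
#' matches their survival-time ordering.
#' A pair is comparable when the shorter observed time belongs to a subject
#' with an observed event (pairs tied on time are never comparable); risk
#' ties count one half.
#'
#' @param times Observed times (days).
#' @param events Event indicators (1 = observed, 0 = censored).
#' @param risks Predicted risk scores (higher = shorter expected survival).
#' @return Concordance in \[0, 1\]; 0.5 with a warning when no pair is
#'   comparable.
#' @export
concordance_index <- function(times, events, risks) {
  n <- length(times)
  if (length(events) != n || length(risks) != n)
    stop("times, events and risks must have equal length")
  if (n < 2) stop("need at least 2 subjects")
  # ordered pairs (i, j) with t_i < t_j and subject i's event observed
  cmp <- outer(times, times, "<") & (events == 1)
  n_comp <- sum(cmp)
  if (n_comp == 0) {
    warning("no comparable pairs; returning concordance 0.5", call. = FALSE)
    return(0.5)
  }
  conc <- sum(cmp & outer(risks, risks, ">")) +
    0.5 * sum(cmp & outer(risks, risks, "=="))
  conc / n_comp
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function. Censored subjects
#' leave the risk set without producing a drop.
#'
#' @param times Observed times.
#' @param events Event indicators.
#' @return Data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  if (length(times) < 1) stop("need at least one subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed minus expected events in group 1
#' are accumulated with their hypergeometric variance; the statistic
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-square with 1 df.
#'
#' @param times_1,events_1 First group.
#' @param times_2,events_2 Second group.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(times_1, events_1, times_2, events_2) {
  if (length(times_1) == 0 || length(times_2) == 0)
    stop("both groups must be nonempty")
  if (sum(events_1) + sum(events_2) == 0) {
    warning("no events in either group; log-rank statistic is 0", call. = FALSE)
    return(list(statistic = 0, p_value = 1))
  }
  grp <- c(rep(1L, length(times_1)), rep(2L, length(times_2)))
  fit <- survival::survdiff(
    survival::Surv(c(times_1, times_2), c(events_1, events_2)) ~ grp)
  stat <- as.numeric(fit$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Univariate Cox fit via the low-level fitter (fast path for per-gene scans).
# Returns c(coef, z); c(NA, NA) when the fit degenerates.
cox_uni <- function(x, y, control) {
  fit <- tryCatch(
    survival::coxph.fit(matrix(x, ncol = 1), y, strata = NULL, offset = NULL,
                        init = 0, control = control, weights = NULL,
                        method = "breslow", rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_))
  b <- as.numeric(fit$coefficients)
  v <- as.numeric(fit$var)
  if (!is.finite(b) || !is.finite(v) || v <= 0) return(c(NA_real_, NA_real_))
  c(b, b / sqrt(v))
}

#' Fit a supervised principal components survival model
#'
#' Genes are standardized with training means and SDs, screened by the
#' absolute Wald z of a per-gene univariate Cox fit, and the first principal
#' component of the retained standardized submatrix is regressed on survival
#' with a univariate Cox model. The screening threshold is chosen from a
#' quantile grid of |z| by internal K-fold cross-validation maximizing the
#' validation concordance. Prediction uses only training-derived parameters.
#'
#' @param train A preprocessed `domain_dataset`.
#' @param n_folds Internal CV folds for the threshold search (default 3).
#' @param threshold_probs Quantile probabilities of |z| forming the
#'   threshold grid (default `seq(0, 0.9, 0.1)`; 0 keeps every gene).
#' @param seed Seed for the internal fold assignment.
#' @return A `superpc_model` with the standardization parameters, retained
#'   gene set, screening threshold, unit-norm PC loadings and Cox
#'   coefficient.
#' @export
fit_superpc <- function(train, n_folds = 3, threshold_probs = seq(0, 0.9, 0.1),
                        seed = 1) {
  stopifnot(inherits(train, "domain_dataset"))
  X <- train$expression
  if (ncol(X) < 2) stop("need at least 2 genes")
  tt <- train$survival$time
  ev <- train$survival$event
  if (sum(ev) < 2) stop("need at least 2 observed events")
  ctrl <- survival::coxph.control(iter.max = 50)

  # internal CV over the threshold grid
  n <- nrow(X)
  folds <- NULL
  rng <- make_rng(seed)
  for (attempt in 1:3) {
    f <- sample_with_rng(rng, rep_len(seq_len(n_folds), n))
    ok <- all(vapply(seq_len(n_folds), function(k) {
      sum(ev[f != k]) >= 2 && sum(f == k) >= 2
    }, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build CV folds with events in every training part")

  cv_c <- matrix(NA_real_, n_folds, length(threshold_probs))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit_k <- superpc_core(X[tr, , drop = FALSE], tt[tr], ev[tr],
                          threshold_probs, ctrl)
    for (j in seq_along(threshold_probs)) {
      m <- fit_k[[j]]
      if (is.null(m)) next
      hz <- superpc_hazard(m, X[!tr, , drop = FALSE])
      cv_c[k, j] <- tryCatch(
        suppressWarnings(concordance_index(tt[!tr], ev[!tr], hz)),
        error = function(e) NA_real_)
    }
  }
  mean_c <- colMeans(cv_c, na.rm = TRUE)
  best <- which.max(mean_c)

  final <- superpc_core(X, tt, ev, threshold_probs[best], ctrl)[[1]]
  if (is.null(final)) stop("supervised PC fit degenerated on the full training set")
  final$cv_concordance <- data.frame(threshold_prob = threshold_probs,
                                     mean_c_index = mean_c)
  final$threshold_prob <- threshold_probs[best]
  class(final) <- "superpc_model"
  final
}

# Fits one supervised-PC model per screening threshold (quantile prob of the
# shared |z| scores). Returns a list parallel to `probs`.
superpc_core <- function(X, tt, ev, probs, ctrl) {
  mu <- colMeans(X)
  sd0 <- apply(X, 2, stats::sd)
  sd0[sd0 == 0] <- 1
  Xs <- scale(X, center = mu, scale = sd0)
  y <- survival::Surv(tt, ev)
  z <- apply(Xs, 2, function(x) cox_uni(x, y, ctrl)[2])
  z[!is.finite(z)] <- 0
  az <- abs(z)
  lapply(probs, function(p) {
    thr <- stats::quantile(az, p, names = FALSE)
    keep <- az >= thr
    if (!any(keep)) keep[which.max(az)] <- TRUE  # force at least one gene
    Xk <- Xs[, keep, drop = FALSE]
    sv <- tryCatch(svd(Xk, nu = 0, nv = 1), error = function(e) NULL)
    if (is.null(sv)) return(NULL)
    v <- sv$v[, 1]
    score <- as.numeric(Xk %*% v)
    cf <- cox_uni(score, y, ctrl)[1]
    if (!is.finite(cf)) return(NULL)
    list(gene_means = mu, gene_sds = sd0,
         retained_genes = colnames(X)[keep],
         screening_threshold = thr,
         pc_loadings = stats::setNames(v, colnames(X)[keep]),
         cox_coefficient = cf)
  })
}

superpc_hazard <- function(model, X) {
  g <- model$retained_genes
  missing <- setdiff(g, colnames(X))
  if (length(missing))
    stop("data lack retained genes: ", paste(utils::head(missing, 5), collapse = ", "))
  Xk <- scale(X[, g, drop = FALSE], center = model$gene_means[g],
              scale = model$gene_sds[g])
  exp(model$cox_coefficient * as.numeric(Xk %*% model$pc_loadings))
}

#' Predict partial hazards from a supervised PC model
#'
#' Standardizes with the training parameters, projects onto the stored PC
#' loadings, multiplies by the Cox coefficient and exponentiates.
#'
#' @param model A `superpc_model`.
#' @param data A `domain_dataset` or an expression matrix containing all
#'   retained genes.
#' @return Numeric vector of partial hazards (`exp` of the linear
#'   predictor), one per sample.
#' @export
predict_partial_hazard <- function(model, data) {
  stopifnot(inherits(model, "superpc_model"))
  X <- if (inherits(data, "domain_dataset")) data$expression else data
  superpc_hazard(model, X)
}

#' @export
print.superpc_model <- function(x, ...) {
  cat(sprintf("<superpc_model> %d retained genes (|z| >= %.3f), Cox coefficient %.4f\n",
              length(x$retained_genes), x$screening_threshold,
              x$cox_coefficient))
  invisible(x)
}

#' Split a dataset into train/test in stored ("chronological") order
#'
#' The sorted-sample-ID order established at read time serves as the
#' deterministic stand-in for accrual order: the first fraction of samples
#' trains, the rest tests.
#'
#' @param dataset A `domain_dataset`.
#' @param train_fraction Fraction of samples in the training part
#'   (default 0.7).
#' @return List with `train` and `test` datasets.
#' @export
chronological_split <- function(dataset, train_fraction = 0.7) {
  n <- n_samples(dataset)
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) stop("split leaves an empty part")
  list(train = subset_samples(dataset, seq_len(n_train)),
       test = subset_samples(dataset, (n_train + 1):n))
}

#' Stratify a test set into risk groups and test their separation
#'
#' The risk threshold is the median partial hazard of the *training* set;
#' test samples with hazard strictly above it form the high-risk group.
#' Returns both Kaplan-Meier curves and the log-rank p-value between them.
#'
#' @param model A fitted `superpc_model`.
#' @param train,test Preprocessed `domain_dataset`s.
#' @return List with `km_high`, `km_low`, `p_value`, `statistic` and the
#'   test `groups` (`"high"`/`"low"`).
#' @export
stratify_and_test <- function(model, train, test) {
  thr <- stats::median(predict_partial_hazard(model, train))
  hz <- predict_partial_hazard(model, test)
  high <- hz > thr
  groups <- ifelse(high, "high", "low")
  tt <- test$survival$time
  ev <- test$survival$event
  if (all(high) || !any(high)) {
    warning("one risk group is empty; log-rank p-value set to 1", call. = FALSE)
    return(list(km_high = if (any(high)) km_curve(tt[high], ev[high]) else NULL,
                km_low = if (any(!high)) km_curve(tt[!high], ev[!high]) else NULL,
                p_value = 1, statistic = 0, groups = groups))
  }
  lr <- logrank_test(tt[high], ev[high], tt[!high], ev[!high])
  list(km_high = km_curve(tt[high], ev[high]),
       km_low = km_curve(tt[!high], ev[!high]),
       p_value = lr$p_value, statistic = lr$statistic, groups = groups)
}

#' Repeated cross-validation benchmark of augmented vs real-only training
#'
#' For each round the *real* target data are split at random into train and
#' test parts. Every condition fits a supervised PC model on the real
#' training part -- plus, for augmented conditions, that condition's
#' generated samples -- and is scored by the concordance index on the
#' untouched real test part. Generated samples never enter a test fold
#' (audited via their `gen:` ID prefix). Conditions share the identical
#' split within a round, so per-round C-indices are paired; condition
#' medians and paired two-sided Wilcoxon signed-rank p-values against the
#' real-only condition summarize the benchmark.
#'
#' @param real_target The real target-domain `domain_dataset`.
#' @param augmentations Named list of `transfer_result`s (may be empty).
#' @param n_rounds Number of CV rounds (default 100).
#' @param test_fraction Fraction of real samples held out per round.
#' @param seed Base seed; round r uses seed + r.
#' @param n_folds,threshold_probs Passed to [fit_superpc()].
#' @return A `benchmark_result`: per-round C-index matrix (`rounds`),
#'   condition `medians`, `p_vs_real`, and the per-round seeds.
#' @export
run_cv_benchmark <- function(real_target, augmentations = list(),
                             n_rounds = 100, test_fraction = 0.3, seed = 1,
                             n_folds = 3, threshold_probs = seq(0, 0.9, 0.1)) {
  stopifnot(inherits(real_target, "domain_dataset"))
  if (n_rounds < 2) stop("need at least 2 rounds")
  if (length(augmentations) && is.null(names(augmentations)))
    stop("`augmentations` must be a named list")
  conditions <- c("real", names(augmentations))
  n <- n_samples(real_target)
  n_test <- max(1, round(test_fraction * n))
  if (n_test >= n) stop("test fraction leaves no training samples")

  res <- matrix(NA_real_, n_rounds, length(conditions),
                dimnames = list(NULL, conditions))
  round_seeds <- seed + seq_len(n_rounds)
  for (r in seq_len(n_rounds)) {
    rng <- make_rng(round_seeds[r])
    test_idx <- sample_with_rng(rng, seq_len(n), n_test)
    test_ds <- subset_samples(real_target, test_idx)
    train_ds <- subset_samples(real_target, setdiff(seq_len(n), test_idx))
    if (any(startsWith(test_ds$survival$sample_id, "gen:")))
      stop("generated samples leaked into a test fold")
    for (cond in conditions) {
      fit_data <- if (cond == "real") train_ds else
        augment_domain(train_ds, augmentations[[cond]])
      fit <- tryCatch(
        suppressWarnings(fit_superpc(fit_data, n_folds = n_folds,
                                     threshold_probs = threshold_probs,
                                     seed = round_seeds[r])),
        error = function(e) NULL)
      if (is.null(fit)) next
      hz <- predict_partial_hazard(fit, test_ds)
      res[r, cond] <- tryCatch(
        suppressWarnings(concordance_index(test_ds$survival$time,
                                           test_ds$survival$event, hz)),
        error = function(e) NA_real_)
    }
  }

  medians <- apply(res, 2, stats::median, na.rm = TRUE)
  p_vs_real <- vapply(conditions[-1], function(cond) {
    d <- res[, cond] - res[, "real"]
    d <- d[is.finite(d)]
    if (length(d) == 0 || all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                        exact = FALSE)$p.value)
  }, numeric(1))
  structure(list(rounds = res, medians = medians, p_vs_real = p_vs_real,
                 round_seeds = round_seeds, test_fraction = test_fraction),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", nrow(x$rounds), "rounds\n")
  for (cond in colnames(x$rounds)) {
    p <- if (cond == "real") "" else
      sprintf(" (p vs real = %.3g)", x$p_vs_real[[cond]])
    cat(sprintf("  %-12s median C-index %.3f%s\n", cond,
                x$medians[[cond]], p))
  }
  invisible(x)
}

#' Write a benchmark report as TSV
#' @param result A `benchmark_result`.
#' @param rounds_path Per-round TSV (round, condition, c_index).
#' @param summary_path Summary TSV (condition, median, p_vs_real).
#' @return Invisibly, the result.
#' @export
write_benchmark <- function(result, rounds_path, summary_path) {
  long <- data.frame(
    round = rep(seq_len(nrow(result$rounds)), ncol(result$rounds)),
    condition = rep(colnames(result$rounds), each = nrow(result$rounds)),
    c_index = as.vector(result$rounds))
  utils::write.table(long, rounds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- data.frame(
    condition = colnames(result$rounds),
    median = unname(result$medians),
    p_vs_real = c(NA, unname(result$p_vs_real))[
      seq_along(result$medians)])
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}

# Local RNG helpers: keep package randomness insulated from the caller's
# global RNG state and reproducible from integer seeds.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

sample_with_rng <- function(rng, x, size = length(x)) {
  with_rng(rng, sample(x, size))
}
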
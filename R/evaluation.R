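#' k-nearest-neighbour purity
#'
#' For every point, the fraction of its `k` nearest Euclidean neighbours
#' (excluding itself) that share its label, averaged over points. Distance
#' ties are broken by point index. A purity near the label frequency means
#' the groups are mixed; 1 means perfect local separation.
#'
#' @param points Numeric matrix, points in rows.
#' @param labels Label per point.
#' @param k Neighbourhood size (default 10).
#' @return Purity in \[0, 1\].
#' @export
knn_purity <- function(points, labels, k = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) != n) stop("labels must match the number of points")
  if (k >= n) stop("k must be smaller than the number of points")
  d <- as.matrix(stats::dist(points))
  mean(vapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])          # stable: index order breaks ties
    nb <- (seq_len(n)[-i])[ord][seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}

#' Gaussian-mixture clustering with hard assignments
#'
#' Fits a full-covariance Gaussian mixture and returns the
#' argmax-responsibility assignment per point. Model-based hierarchical
#' initialization makes the fit deterministic; points are pre-sorted into a
#' canonical order before fitting so the result is invariant to input
#' permutation. If the full-covariance fit degenerates (singular
#' covariance), progressively more constrained covariance models are tried.
#'
#' @param points Numeric matrix, points in rows.
#' @param n_components Number of mixture components (default 2).
#' @param seed Seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @return Integer vector of cluster assignments in `1..n_components`.
#' @export
cluster_gmm <- function(points, n_components = 2, seed = 1) {
  points <- as.matrix(points)
  if (nrow(points) <= n_components)
    stop("need more points than mixture components")
  ord <- do.call(order, as.data.frame(points))
  sorted <- points[ord, , drop = FALSE]
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the calling frame
  cls <- NULL
  for (mn in c("VVV", "EEE", "EII")) {
    fit <- tryCatch(
      withCallingHandlers(
        mclust::Mclust(sorted, G = n_components, modelNames = mn,
                       verbose = FALSE),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$classification)) {
      if (mn != "VVV")
        message("full-covariance mixture degenerated; used model ", mn)
      cls <- fit$classification
      break
    }
  }
  if (is.null(cls)) stop("Gaussian-mixture clustering failed")
  out <- integer(nrow(points))
  out[ord] <- as.integer(cls)
  out
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; invariant to permutations of either labeling.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("labelings must have equal length")
  tab <- table(labels_true, labels_pred)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  hr <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (hr == 0 && hc == 0) {
    warning("both labelings have a single class; NMI set to 1", call. = FALSE)
    return(1)
  }
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pr[row(p)][nz] * pc[col(p)][nz])))
  max(0, min(1, mi / ((hr + hc) / 2)))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance
#' (Hubert-Arabie). 1 for identical labelings, about 0 for independent
#' ones; can be negative.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return ARI, at most 1.
#' @export
ari <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("labelings must have equal length")
  mclust::adjustedRandIndex(labels_true, labels_pred)
}

#' Mean silhouette width
#'
#' Per point, `(b - a) / max(a, b)` where `a` is its mean distance to its
#' own cluster's other members and `b` the smallest mean distance to
#' another cluster; the mean over points is returned. Points in singleton
#' clusters, and points with `a = b = 0`, contribute 0.
#'
#' @param points Numeric matrix, points in rows.
#' @param assignments Cluster assignment per point.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_index <- function(points, assignments) {
  points <- as.matrix(points)
  cl <- as.character(assignments)
  ids <- unique(cl)
  if (length(ids) < 2) stop("need at least 2 clusters")
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ids, cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Dunn index
#'
#' Minimum single-linkage distance between any two clusters divided by the
#' maximum intra-cluster diameter. Larger values mean tighter, better
#' separated clusters; the index is invariant to uniform scaling.
#'
#' @param points Numeric matrix, points in rows.
#' @param assignments Cluster assignment per point (at least 2 clusters
#'   with at least 2 points each).
#' @return Dunn index, nonnegative.
#' @export
dunn_index <- function(points, assignments) {
  points <- as.matrix(points)
  cl <- as.character(assignments)
  ids <- unique(cl)
  if (length(ids) < 2) stop("need at least 2 clusters")
  if (any(table(cl) < 2)) stop("every cluster needs at least 2 points")
  d <- as.matrix(stats::dist(points))
  diam <- max(vapply(ids, function(g) {
    m <- d[cl == g, cl == g, drop = FALSE]
    max(m)
  }, numeric(1)))
  if (diam == 0) stop("degenerate clustering: all intra-cluster distances are 0")
  sep <- min(vapply(utils::combn(ids, 2, simplify = FALSE), function(pr) {
    min(d[cl == pr[1], cl == pr[2], drop = FALSE])
  }, numeric(1)))
  sep / diam
}

#' Reconstruction error between paired real and reconstructed samples
#'
#' `mse` is the mean squared error over all sample-by-feature entries;
#' `r2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' pooled mean of the real entries.
#'
#' @param real,reconstructed Matrices of identical shape (samples x
#'   features, expression plus the time feature), same sample order.
#' @return List with `mse` and `r2`.
#' @export
reconstruction_error <- function(real, reconstructed) {
  real <- as.matrix(real); reconstructed <- as.matrix(reconstructed)
  if (!all(dim(real) == dim(reconstructed)))
    stop("real and reconstructed matrices must have identical shape")
  err <- real - reconstructed
  ss_res <- sum(err^2)
  ss_tot <- sum((real - mean(real))^2)
  list(mse = mean(err^2),
       r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}

#' Distribution-level evaluation of a style-transfer condition
#'
#' Pools real (and, for the model condition, generated) selected-gene
#' expression vectors, labels each point by its domain style, clusters the
#' pool with a two-component Gaussian mixture and reports kNN purity (on
#' the style labels), NMI and ARI (mixture assignments vs style labels),
#' and silhouette and Dunn (on the mixture assignments). With
#' reconstructions supplied, MSE and R-squared between real and
#' reconstructed feature matrices (expression + time feature) are added;
#' the `"none"` condition reports them as `NA` since there is nothing to
#' reconstruct.
#'
#' @param real_a,real_b Real `domain_dataset`s on a shared gene list.
#' @param generated Optional list with elements `ab` and/or `ba`
#'   (`transfer_result`s): generated points enter the pool under their
#'   target style's label.
#' @param reconstructed Optional list with elements `a` and/or `b` from
#'   [reconstruct_domain()] paired with `real_a` / `real_b`.
#' @param k Neighbourhood size for kNN purity.
#' @param seed Seed forwarded to [cluster_gmm()].
#' @return An `eval_report` row: condition, knn_purity, nmi, ari,
#'   silhouette, dunn, mse, r2.
#' @export
evaluate_condition <- function(real_a, real_b, generated = NULL,
                               reconstructed = NULL, k = 10, seed = 1) {
  genes <- colnames(real_a$expression)
  if (!identical(genes, colnames(real_b$expression)))
    stop("real domains must share one gene list")
  pts <- rbind(real_a$expression, real_b$expression)
  labels <- c(rep(real_a$name, n_samples(real_a)),
              rep(real_b$name, n_samples(real_b)))
  condition <- "none"
  if (!is.null(generated)) {
    condition <- "model"
    for (tr in generated) {
      if (!identical(colnames(tr$expression), genes))
        stop("generated data are not in the shared gene space")
      pts <- rbind(pts, tr$expression)
      labels <- c(labels, rep(tr$target_name, nrow(tr$expression)))
    }
  }
  asg <- cluster_gmm(pts, n_components = 2, seed = seed)
  mse <- NA_real_; r2 <- NA_real_
  if (!is.null(reconstructed)) {
    pairs <- list(list(real_a, reconstructed$a), list(real_b, reconstructed$b))
    real_stack <- NULL; rec_stack <- NULL
    for (pr in pairs) {
      if (is.null(pr[[2]])) next
      real_stack <- rbind(real_stack, model_matrix(pr[[1]], genes))
      rec_stack <- rbind(rec_stack, pr[[2]]$features)
    }
    if (!is.null(real_stack)) {
      re <- reconstruction_error(real_stack, rec_stack)
      mse <- re$mse; r2 <- re$r2
    }
  }
  structure(data.frame(
    condition = condition,
    knn_purity = knn_purity(pts, labels, k = k),
    nmi = nmi(labels, asg),
    ari = ari(labels, asg),
    silhouette = silhouette_index(pts, asg),
    dunn = dunn_index(pts, asg),
    mse = mse, r2 = r2), class = c("eval_report", "data.frame"))
}
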
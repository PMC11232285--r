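test_that("concordance index matches hand-built rankings", {
  expect_equal(concordance_index(c(3, 5, 10), c(1, 1, 1), c(1.2, 0.9, 0.1)), 1)
  expect_equal(concordance_index(c(3, 5, 10), c(1, 1, 1), c(0.1, 0.9, 1.2)), 0)
  # censoring the shortest time leaves exactly one comparable pair (5 vs 10)
  expect_equal(concordance_index(c(3, 5, 10), c(0, 1, 1), c(0, 1, 0)), 1)
  expect_equal(concordance_index(c(3, 5, 10), c(0, 1, 1), c(0, 0, 1)), 0)
  expect_equal(concordance_index(c(3, 5, 10), c(0, 1, 1), c(0, 1, 1)), 0.5)
  expect_warning(v <- concordance_index(c(3, 5), c(0, 0), c(1, 2)),
                 "no comparable")
  expect_equal(v, 0.5)
  expect_error(concordance_index(1:3, c(1, 1), 1:3), "equal length")
})

test_that("concordance index equals the brute-force pair enumeration on random tables", {
  for (s in 1:60) {
    tab <- random_survival_table(n = sample(5:30, 1), seed = 1000 + s)
    if (sum(tab$event) == 0) next
    expect_equal(
      suppressWarnings(concordance_index(tab$time, tab$event, tab$risk)),
      oracle_concordance(tab$time, tab$event, tab$risk),
      info = paste("seed", s))
  }
})

test_that("Kaplan-Meier curve equals the product-limit hand computation", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_curve(c(4, 8), c(0, 0))
  expect_equal(km2$surv, c(1, 1))
  # censoring removes from the risk set without a drop
  km3 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km3$surv, c(2 / 3, 2 / 3, 0))
  # no censoring: equals the empirical survival function
  set.seed(2)
  tt <- sample(1:40, 25, replace = TRUE)
  km4 <- km_curve(tt, rep(1, 25))
  emp <- sapply(km4$time, function(u) mean(tt > u))
  expect_equal(km4$surv, emp)
  expect_equal(km4$surv, oracle_km(tt, rep(1, 25))$surv)
})

test_that("log-rank test matches the hypergeometric summation oracle", {
  for (s in 1:40) {
    set.seed(2000 + s)
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    t1 <- sample(1:15, n1, replace = TRUE); e1 <- rbinom(n1, 1, 0.7)
    t2 <- sample(1:15, n2, replace = TRUE); e2 <- rbinom(n2, 1, 0.5)
    if (sum(e1) + sum(e2) == 0) next
    got <- logrank_test(t1, e1, t2, e2)
    want <- oracle_logrank(t1, e1, t2, e2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(t2, e2, t1, e1)$statistic, got$statistic,
                 tolerance = 1e-10)
  }
})

test_that("log-rank of identical groups is null; no events warns", {
  t1 <- c(2, 5, 9, 12); e1 <- c(1, 0, 1, 1)
  got <- logrank_test(t1, e1, t1, e1)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)
  expect_warning(res <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
  expect_equal(res$p_value, 1)
})

make_pc_domain <- function(n, g, seed, signal = TRUE) {
  set.seed(seed)
  z <- rnorm(n)
  expr <- sapply(seq_len(g), function(j) {
    if (signal && j <= ceiling(g / 2)) z + rnorm(n, 0, 0.7) + 3
    else rnorm(n, 3, 1)
  })
  expr <- pmax(expr, 0)
  dimnames(expr) <- list(sprintf("s%04d", seq_len(n)),
                         sprintf("g%03d", seq_len(g)))
  lam <- 0.002 * exp(1.3 * z)
  te <- rexp(n) / lam
  tc <- rexp(n) / 0.002
  domain_dataset("P", expr,
                 data.frame(sample_id = rownames(expr),
                            time = pmax(pmin(te, tc), 1),
                            event = as.integer(te <= tc)),
                 normalized = TRUE)
}

test_that("supervised PC model recovers a strong latent risk signal", {
  train <- make_pc_domain(300, 20, seed = 31)
  test <- make_pc_domain(150, 20, seed = 32)
  fit <- fit_superpc(train, seed = 1)
  expect_true(length(fit$retained_genes) >= 1)
  expect_equal(sum(fit$pc_loadings^2), 1, tolerance = 1e-8)  # unit norm
  hz <- predict_partial_hazard(fit, test)
  cc <- concordance_index(test$survival$time, test$survival$event, hz)
  expect_gt(cc, 0.65)
})

test_that("a single screened gene reduces to that gene's own concordance", {
  set.seed(40)
  n <- 120
  z <- rnorm(n)
  expr <- cbind(gsig = z + 3, gn1 = rnorm(n, 3), gn2 = rnorm(n, 3))
  expr <- pmax(expr, 0)
  rownames(expr) <- sprintf("s%03d", 1:n)
  lam <- 0.002 * exp(1.5 * z)
  te <- rexp(n) / lam
  ds <- domain_dataset("S", expr,
                       data.frame(sample_id = rownames(expr),
                                  time = pmax(te, 1), event = rep(1, n)),
                       normalized = TRUE)
  # force a screen that keeps only the top gene
  fit <- fit_superpc(ds, threshold_probs = c((ncol(expr) - 1) / ncol(expr)),
                     seed = 1)
  expect_identical(fit$retained_genes, "gsig")
  hz <- predict_partial_hazard(fit, ds)
  c_model <- concordance_index(ds$survival$time, ds$survival$event, hz)
  c_gene <- concordance_index(ds$survival$time, ds$survival$event,
                              ds$expression[, "gsig"])
  expect_equal(c_model, max(c_gene, 1 - c_gene), tolerance = 1e-10)
})

test_that("partial hazards are monotone in the PC score and 1 at zero coefficient", {
  train <- make_pc_domain(200, 10, seed = 33)
  fit <- fit_superpc(train, seed = 2)
  fit0 <- fit
  fit0$cox_coefficient <- 0
  expect_equal(predict_partial_hazard(fit0, train),
               rep(1, n_samples(train)))
  Xs <- scale(train$expression[, fit$retained_genes, drop = FALSE],
              fit$gene_means[fit$retained_genes],
              fit$gene_sds[fit$retained_genes])
  score <- as.numeric(Xs %*% fit$pc_loadings) * sign(fit$cox_coefficient)
  hz <- predict_partial_hazard(fit, train)
  expect_equal(order(score), order(hz))
  expect_error(predict_partial_hazard(fit, train$expression[, -1]),
               "retained genes")
})

test_that("pure-noise genes yield chance-level test concordance", {
  cs <- sapply(1:6, function(s) {
    train <- make_pc_domain(300, 15, seed = 50 + s, signal = FALSE)
    test <- make_pc_domain(120, 15, seed = 80 + s, signal = FALSE)
    fit <- suppressWarnings(fit_superpc(train, seed = s))
    hz <- predict_partial_hazard(fit, test)
    suppressWarnings(concordance_index(test$survival$time,
                                       test$survival$event, hz))
  })
  expect_lt(abs(median(cs) - 0.5), 0.08)
})

test_that("risk stratification thresholds on the training median only", {
  train <- make_pc_domain(300, 20, seed = 35)
  test <- make_pc_domain(150, 20, seed = 36)
  fit <- fit_superpc(train, seed = 1)
  res <- stratify_and_test(fit, train, test)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # permuting test order permutes groups identically
  perm <- sample(n_samples(test))
  res2 <- stratify_and_test(fit, train, subset_samples(test, perm))
  expect_identical(res2$groups, res$groups[perm])
  # all-equal hazards put every sample in the low-risk group (strict >)
  fit0 <- fit; fit0$cox_coefficient <- 0
  expect_warning(res0 <- stratify_and_test(fit0, train, test), "empty")
  expect_true(all(res0$groups == "low"))
  expect_equal(res0$p_value, 1)
})

test_that("chronological split follows stored order", {
  ds <- tiny_domain(n = 10, g = 3, seed = 9)
  sp <- chronological_split(ds, 0.7)
  expect_equal(n_samples(sp$train), 7)
  expect_identical(sp$train$survival$sample_id, ds$survival$sample_id[1:7])
  expect_identical(sp$test$survival$sample_id, ds$survival$sample_id[8:10])
})

make_empty_transfer <- function(tr) {
  tr$expression <- tr$expression[0, , drop = FALSE]
  tr$time_days <- numeric(0); tr$events <- integer(0)
  tr$source_sample_ids <- character(0)
  tr
}

test_that("CV benchmark pairs conditions within rounds and audits leakage", {
  sim <- small_sim(seed = 21, n = 80, g = 12, informative = 5)
  m <- make_identity_model(colnames(sim$a$expression))
  tr <- style_transfer(m, sim$a, "ab")
  bench <- suppressWarnings(
    run_cv_benchmark(sim$b, list(augmented = tr), n_rounds = 4,
                     test_fraction = 0.3, seed = 5))
  expect_equal(dim(bench$rounds), c(4L, 2L))
  expect_named(bench$medians, c("real", "augmented"))
  expect_true(bench$p_vs_real[["augmented"]] >= 0)
  # identical conditions give equal medians and p = 1
  bench2 <- suppressWarnings(
    run_cv_benchmark(sim$b, list(same = make_empty_transfer(tr)),
                     n_rounds = 3, test_fraction = 0.3, seed = 6))
  expect_equal(bench2$medians[["same"]], bench2$medians[["real"]])
  expect_equal(bench2$p_vs_real[["same"]], 1)
})

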
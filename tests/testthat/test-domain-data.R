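test_that("read_domain keeps the sorted intersection of sample IDs", {
  tmp <- withr::local_tempdir()
  expr <- data.frame(sample_id = c("s3", "s1", "s2"),
                     gA = c(1, 2, 3), gB = c(4, 5, 6))
  surv <- data.frame(sample_id = c("s2", "s3", "s4"),
                     time = c(10, 20, 30), event = c(1, 0, 1))
  write.table(expr, file.path(tmp, "e.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(surv, file.path(tmp, "s.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  ds <- read_domain(file.path(tmp, "e.tsv"), file.path(tmp, "s.tsv"))
  expect_identical(rownames(ds$expression), c("s2", "s3"))
  expect_identical(ds$survival$sample_id, c("s2", "s3"))
  expect_equal(ds$expression["s2", "gA"], 3)
  expect_equal(ds$survival$time, c(10, 20))

  # zero overlap is an error
  surv2 <- data.frame(sample_id = c("x1", "x2"), time = c(1, 2), event = c(1, 1))
  write.table(surv2, file.path(tmp, "s2.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_domain(file.path(tmp, "e.tsv"), file.path(tmp, "s2.tsv")),
               "no overlapping")
})

test_that("domain validation rejects malformed survival records", {
  expr <- matrix(1:6, 3, 2,
                 dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  surv <- data.frame(sample_id = c("a", "b", "c"), time = c(1, 2, 3),
                     event = c(0, 1, 2))
  expect_error(domain_dataset("X", expr, surv), "event")
  surv$event <- c(0, 1, 1)
  surv$time[2] <- -5
  expect_error(domain_dataset("X", expr, surv), "nonnegative")
  surv$time[2] <- 2
  surv$sample_id <- c("a", "c", "b")
  expect_error(domain_dataset("X", expr, surv), "identical order")
})

test_that("read/write round-trips a domain bit-identically on retained fields", {
  tmp <- withr::local_tempdir()
  ds <- tiny_domain(n = 10, g = 5, seed = 7)
  write_domain(ds, file.path(tmp, "e.tsv"), file.path(tmp, "s.tsv"))
  back <- read_domain(file.path(tmp, "e.tsv"), file.path(tmp, "s.tsv"),
                      name = ds$name, normalized = TRUE)
  expect_equal(back$expression, ds$expression)
  expect_equal(back$survival, ds$survival)
})

test_that("preprocess removes zero-day samples and log-transforms once", {
  expr <- matrix(c(0, 1, 3, 1023, 7, 0, 15, 31, 63, 127), 5, 2,
                 dimnames = list(paste0("s", 1:5), c("g1", "g2")))
  surv <- data.frame(sample_id = paste0("s", 1:5),
                     time = c(100, 0, 50, 1023, 20),
                     event = c(1, 1, 0, 1, 0))
  ds <- domain_dataset("X", expr, surv)
  pp <- preprocess_domain(ds)
  expect_equal(n_samples(pp), 4)              # one zero-day sample dropped
  expect_true(pp$normalized)
  expect_equal(unname(pp$expression[, "g1"]), c(0, 2, 10, 3))  # log2(x+1)
  # model-facing time feature is log2(t+1): 1023 days -> 10
  mm <- model_matrix(pp)
  expect_equal(unname(mm["s4", ".time"]), 10)
  # days are retained for survival statistics
  expect_equal(pp$survival$time, c(100, 50, 1023, 20))
  # the normalized flag guards against double transformation
  expect_error(preprocess_domain(pp), "already normalized")
  # re-applying the time filter removes nothing further
  expect_equal(n_samples(survgan:::drop_zero_day_samples(pp)), 4)
})

test_that("cohort filtering applies both thresholds with order preserved", {
  s <- rbind(cohort_summary("BLCA", 395, 110),
             cohort_summary("small", 299, 60),
             cohort_summary("few_events", 400, 49),
             cohort_summary("edge", 300, 50))
  kept <- filter_cohorts(s)
  expect_identical(kept$name, c("BLCA", "edge"))
  expect_error(cohort_summary("bad", 10, 11), "n_events")
  expect_error(filter_cohorts(s[0, ]), "empty")
})
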
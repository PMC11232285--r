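test_that("simulation is deterministic in its seed and leaves global RNG alone", {
  cfg <- synthetic_config(n_a = 50, n_b = 40, n_genes = 12, seed = 77)
  set.seed(123); before <- rnorm(1)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$a$expression, s2$a$expression)
  expect_identical(s1$b$survival, s2$b$survival)
  set.seed(123)
  expect_identical(rnorm(1), before)  # package did not consume caller RNG
  s3 <- simulate_pair(synthetic_config(n_a = 50, n_b = 40, n_genes = 12,
                                       seed = 78))
  expect_false(identical(s1$a$expression, s3$a$expression))
})

test_that("simulated domains satisfy the dataset invariants", {
  sim <- small_sim(seed = 14, n = 80, g = 15)
  for (ds in list(sim$a, sim$b)) {
    expect_s3_class(ds, "domain_dataset")
    expect_true(ds$normalized)
    expect_true(all(ds$expression >= 0))
    expect_true(all(ds$survival$time >= 1))
    expect_true(all(ds$survival$event %in% 0:1))
  }
  expect_length(sim$ground_truth$informative, 6)
})

test_that("the censoring rate calibration hits its target", {
  sim <- simulate_pair(synthetic_config(n_a = 1000, n_b = 1000, n_genes = 10,
                                        censor_rate = 0.3, seed = 5))
  for (ds in list(sim$a, sim$b))
    expect_lt(abs(mean(1 - ds$survival$event) - 0.3), 0.04)
})

test_that("zero effect size yields chance-level per-gene concordance", {
  sim <- simulate_pair(synthetic_config(n_a = 500, n_b = 100, n_genes = 30,
                                        n_informative = 10, effect_size = 0,
                                        seed = 6))
  scores <- suppressWarnings(score_genes(sim$a))
  expect_lt(max(abs(scores$c_index - 0.5)), 0.1)
})

test_that("informative genes out-rank noise genes when the effect is real", {
  hits <- sapply(1:5, function(s) {
    sim <- simulate_pair(synthetic_config(n_a = 300, n_b = 50, n_genes = 40,
                                          n_informative = 8, effect_size = 1.2,
                                          seed = 400 + s))
    scores <- suppressWarnings(score_genes(sim$a))
    top <- select_top_genes(scores, 8)
    mean(top %in% sim$ground_truth$gene_ids[sim$ground_truth$informative])
  })
  expect_gte(median(hits), 0.75)
})

test_that("domains separate under Gaussian-mixture clustering at shift 2", {
  aris <- sapply(1:3, function(s) {
    sim <- simulate_pair(synthetic_config(n_a = 80, n_b = 80, n_genes = 15,
                                          domain_shift = 2, seed = 500 + s))
    pts <- rbind(sim$a$expression, sim$b$expression)
    labs <- rep(c("A", "B"), each = 80)
    ari(labs, cluster_gmm(pts, 2, seed = s))
  })
  expect_gte(median(aris), 0.9)
})

test_that("the oracle map transfers one domain onto the other", {
  sim <- small_sim(seed = 15, n = 100, g = 12, informative = 4, shift = 3)
  tr <- known_map_transfer(sim$ground_truth, sim$a, "ab")
  # transferred A means land near real-B means, far from real-A means
  db <- sqrt(sum((colMeans(tr$expression) - colMeans(sim$b$expression))^2))
  da <- sqrt(sum((colMeans(tr$expression) - colMeans(sim$a$expression))^2))
  expect_lt(db, da / 3)
  # map then inverse map recovers the source up to noise terms
  back <- known_map_transfer(
    sim$ground_truth,
    domain_dataset("B", tr$expression,
                   data.frame(sample_id = tr$source_sample_ids,
                              time = tr$time_days, event = tr$events),
                   normalized = TRUE),
    "ba")
  resid <- back$expression - sim$a$expression
  expect_lt(mean(abs(resid)), 3 * sim$ground_truth$noise_sd)
  # events ride along unchanged
  expect_identical(tr$events, sim$a$survival$event)
})

test_that("zero domain shift makes the oracle map mean-preserving", {
  sim <- simulate_pair(synthetic_config(n_a = 200, n_b = 200, n_genes = 10,
                                        domain_shift = 0, seed = 16))
  tr <- known_map_transfer(sim$ground_truth, sim$a, "ab")
  expect_lt(max(abs(colMeans(tr$expression) - colMeans(sim$a$expression))),
            0.2)
})
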
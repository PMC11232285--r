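sim2 <- small_sim(seed = 4, n = 90, g = 10, informative = 4)

test_that("zero epochs return the model unchanged with empty history", {
  m <- surv_gan(colnames(sim2$a$expression), hidden_width = 16,
                disc_widths = c(16, 8, 4), seed = 1)
  x <- matrix(abs(rnorm(3 * 11)), 3, 11)
  before <- generator_forward(m$gen_ab, x)
  m2 <- train_survgan(m, sim2$a, sim2$b, train_config(epochs = 0, seed = 1))
  expect_equal(nrow(m2$history), 0)
  expect_identical(generator_forward(m2$gen_ab, x), before)
})

test_that("history length is epochs x n_repeats and batching follows the larger domain", {
  sim_uneq <- simulate_pair(synthetic_config(n_a = 130, n_b = 40, n_genes = 8,
                                             n_informative = 3, seed = 7))
  m <- surv_gan(colnames(sim_uneq$a$expression), hidden_width = 16,
                disc_widths = c(16, 8, 4), seed = 1)
  cfg <- train_config(epochs = 4, n_repeats = 3, batch_size = 32, seed = 2)
  m <- train_survgan(m, sim_uneq$a, sim_uneq$b, cfg)
  expect_equal(nrow(m$history), 12)
  expect_equal(m$batches_per_epoch, ceiling(130 / 32))  # larger domain rules
  # one discriminator update per batch was recorded
  expect_length(m$d_update_trace, 12 * ceiling(130 / 32))
  expect_true(all(is.finite(m$history$total)))
})

test_that("training is reproducible from its seed", {
  run <- function() {
    m <- surv_gan(colnames(sim2$a$expression), hidden_width = 16,
                  disc_widths = c(16, 8, 4), seed = 3)
    m <- train_survgan(m, sim2$a, sim2$b,
                       train_config(epochs = 3, n_repeats = 1, seed = 3))
    m
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  x <- model_matrix(sim2$a, m1$genes)[1:5, ]
  expect_identical(generator_forward(m1$gen_ab, x),
                   generator_forward(m2$gen_ab, x))
})

test_that("frozen generators let the discriminators improve monotonically in trend", {
  # with generators frozen and cycle/identity off, the discriminator loss
  # averaged over repeats should not increase over the first updates
  losses <- sapply(1:3, function(s) {
    m <- surv_gan(colnames(sim2$a$expression), hidden_width = 16,
                  disc_widths = c(16, 8, 4), seed = s)
    m <- train_survgan(m, sim2$a, sim2$b,
                       train_config(epochs = 10, n_repeats = 1, batch_size = 32,
                                    lambda_cycle = 0, lambda_identity = 0,
                                    freeze_generators = TRUE, seed = s))
    m$d_update_trace[1:20]
  })
  avg <- rowMeans(losses)
  # declining in expectation: negative trend and a lower closing level
  slope <- unname(coef(lm(avg ~ seq_along(avg)))[2])
  expect_lt(slope, 0)
  expect_lt(mean(avg[17:20]), mean(avg[1:4]))
})

test_that("training aborts with a diagnostic when losses turn non-finite", {
  m <- surv_gan(colnames(sim2$a$expression), hidden_width = 16,
                disc_widths = c(16, 8, 4), seed = 1)
  m$gen_ab$dense$d0$W[] <- NaN
  expect_error(
    train_survgan(m, sim2$a, sim2$b,
                  train_config(epochs = 1, n_repeats = 1, seed = 1)),
    "non-finite")
})

test_that("domain feature mismatch is rejected", {
  m <- surv_gan(colnames(sim2$a$expression)[1:5], hidden_width = 16,
                disc_widths = c(16, 8, 4), seed = 1)
  bad <- small_sim(seed = 5, n = 30, g = 3, informative = 2)
  expect_error(train_survgan(m, bad$a, bad$b, train_config(epochs = 1)),
               "absent|mismatch")
})
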
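# Fixture builders shared across test files. All data are generated in code
# at test time.

tiny_domain <- function(n = 20, g = 5, seed = 1, name = "T",
                        normalized = TRUE) {
  set.seed(seed)
  expr <- matrix(abs(rnorm(n * g)), n, g,
                 dimnames = list(sprintf("%s%03d", name, seq_len(n)),
                                 sprintf("g%02d", seq_len(g))))
  domain_dataset(name, expr,
                 data.frame(sample_id = rownames(expr),
                            time = round(rexp(n, 1 / 500)) + 1,
                            event = rbinom(n, 1, 0.7)),
                 normalized = normalized)
}

# Hand-built generator parameters realizing the exact identity map on
# nonnegative inputs (in inference mode): batch-norm layers are set to
# pass-through (run_var = 1 - 1e-5 so the eps-inflated scale is exactly 1)
# and the residual branch second dense layer is zeroed, so each block adds 0.
identity_bn <- function(h) {
  list(gamma = rep(1, h), beta = rep(0, h),
       run_mean = rep(0, h), run_var = rep(1 - 1e-5, h))
}

make_identity_generator <- function(d, h = max(d, 8), n_res = 3) {
  stopifnot(h >= d)
  pad_in <- rbind(diag(d), matrix(0, h - d, d))
  pad_out <- cbind(diag(d), matrix(0, d, h - d))
  dz <- function(W) list(W = W, b = rep(0, nrow(W)))
  res <- lapply(seq_len(n_res), function(i)
    list(da = dz(diag(h)), bna = identity_bn(h),
         db = dz(matrix(0, h, h)), bnb = identity_bn(h)))
  structure(list(
    input_dim = as.integer(d), hidden_width = as.integer(h),
    n_residual_blocks = as.integer(n_res),
    dense = list(d0 = dz(pad_in), d1 = dz(diag(h)), d2 = dz(diag(h)),
                 d3 = dz(diag(h)), dout = dz(pad_out)),
    bn = list(b0 = identity_bn(h), b1 = identity_bn(h),
              b2 = identity_bn(h), b3 = identity_bn(h)),
    residual = res), class = "generator_params")
}

make_identity_model <- function(genes, domain_a = "A", domain_b = "B") {
  m <- surv_gan(genes, hidden_width = max(length(genes) + 1, 8),
                disc_widths = c(8, 8, 8), seed = 1,
                domain_a = domain_a, domain_b = domain_b)
  d <- length(genes) + 1
  m$gen_ab <- make_identity_generator(d, m$generator_spec$hidden_width)
  m$gen_ba <- make_identity_generator(d, m$generator_spec$hidden_width)
  m$trained <- TRUE
  m
}

small_sim <- function(seed = 1, n = 120, g = 20, informative = 6,
                      effect = 1.2, shift = 2) {
  simulate_pair(synthetic_config(n_a = n, n_b = n, n_genes = g,
                                 n_informative = informative,
                                 effect_size = effect, domain_shift = shift,
                                 seed = seed))
}
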
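#' Configure a full style-transfer pipeline run
#'
#' Bundles the per-stage settings of an end-to-end run: simulate (or read)
#' two domains, select genes on the target domain's survival signal, train
#' the cycle-transfer model, generate both directions, benchmark augmented
#' against real-only training and evaluate generation quality. Every
#' stochastic stage receives an explicit seed derived from the global seed.
#'
#' @param seed Global integer seed.
#' @param simulate A [synthetic_config()], or `NULL` to read real data from
#'   `paths` (a list with `expr_a`, `surv_a`, `expr_b`, `surv_b`).
#' @param paths Input file paths when `simulate` is `NULL`.
#' @param preprocess Whether inputs need [preprocess_domain()] (simulated
#'   data are already on the log scale).
#' @param n_top_genes Genes retained by the survival screen.
#' @param hidden_width,disc_widths Network widths.
#' @param train Named list of [train_config()] overrides.
#' @param transfer_mode `"joint"` or `"expression_only"`.
#' @param n_rounds,test_fraction Benchmark settings.
#' @param knn_k Neighbourhood size for the evaluation metrics.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, simulate = synthetic_config(seed = seed),
                            paths = NULL, preprocess = is.null(simulate),
                            n_top_genes = 50, hidden_width = 64,
                            disc_widths = c(128, 64, 32), train = list(),
                            transfer_mode = "joint", n_rounds = 20,
                            test_fraction = 0.3, knn_k = 10) {
  structure(list(seed = as.integer(seed), simulate = simulate, paths = paths,
                 preprocess = preprocess, n_top_genes = n_top_genes,
                 hidden_width = hidden_width, disc_widths = disc_widths,
                 train = train, transfer_mode = transfer_mode,
                 n_rounds = n_rounds, test_fraction = test_fraction,
                 knn_k = knn_k),
            class = "pipeline_config")
}

stage_paths <- function(out_dir) {
  files <- c(
    expr_a = "domain_a_expression.tsv", surv_a = "domain_a_survival.tsv",
    expr_b = "domain_b_expression.tsv", surv_b = "domain_b_survival.tsv",
    gene_scores = "gene_scores.tsv", genes = "genes.txt",
    model = "model.rds", history = "history.tsv",
    gen_ab_expr = "generated_b_expression.tsv",
    gen_ab_surv = "generated_b_survival.tsv",
    gen_ba_expr = "generated_a_expression.tsv",
    gen_ba_surv = "generated_a_survival.tsv",
    bench_rounds = "benchmark_rounds.tsv",
    bench_summary = "benchmark_summary.tsv",
    eval = "evaluation.tsv", manifest = "manifest.json")
  stats::setNames(file.path(out_dir, files), names(files))
}

#' Run the full pipeline
#'
#' Executes preprocess, gene selection, training, transfer, augmentation,
#' benchmark and evaluation in order, writing every stage's artifact (TSV /
#' checkpoint) under `out_dir` and a JSON manifest of all parameters and
#' seeds. A rerun with the same config reproduces all deterministic
#' artifacts byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the benchmark result, evaluation table
#'   and artifact paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(out_dir)
  say <- function(...) if (!quiet) message(...)

  # -- data stage ------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("simulate: two synthetic domains")
    sim <- simulate_pair(config$simulate)
    a <- sim$a; b <- sim$b
  } else {
    say("read: real domains")
    if (is.null(config$paths)) stop("config needs `paths` when simulate is NULL")
    a <- read_domain(config$paths$expr_a, config$paths$surv_a, name = "A")
    b <- read_domain(config$paths$expr_b, config$paths$surv_b, name = "B")
  }
  if (config$preprocess) {
    a <- preprocess_domain(a)
    b <- preprocess_domain(b)
  }
  write_domain(a, p["expr_a"], p["surv_a"])
  write_domain(b, p["expr_b"], p["surv_b"])

  # -- gene selection on the target domain (B) -------------------------
  say("select-genes: per-gene Cox concordance on the target domain")
  scores <- suppressWarnings(score_genes(b))
  genes <- select_top_genes(scores, k = min(config$n_top_genes, nrow(scores)))
  write_gene_scores(scores, p["gene_scores"])
  write_gene_list(genes, p["genes"])

  # -- training --------------------------------------------------------
  say("train: adversarial loop")
  tcfg <- do.call(train_config,
                  utils::modifyList(list(seed = config$seed), config$train))
  model <- surv_gan(genes, hidden_width = config$hidden_width,
                    disc_widths = config$disc_widths, seed = config$seed,
                    domain_a = a$name, domain_b = b$name)
  model <- train_survgan(model, subset_genes(a, genes), subset_genes(b, genes),
                         tcfg)
  write_model(model, p["model"])
  write_history(model, p["history"])

  # -- transfer + augmentation ----------------------------------------
  say("transfer: generate both directions")
  tr_ab <- style_transfer(model, a, "ab", mode = config$transfer_mode)
  tr_ba <- style_transfer(model, b, "ba", mode = config$transfer_mode)
  write_transfer(tr_ab, p["gen_ab_expr"], p["gen_ab_surv"])
  write_transfer(tr_ba, p["gen_ba_expr"], p["gen_ba_surv"])

  # -- benchmark on the target domain ---------------------------------
  say("benchmark: ", config$n_rounds, " CV rounds")
  bench <- run_cv_benchmark(subset_genes(b, genes),
                            augmentations = list(augmented = tr_ab),
                            n_rounds = config$n_rounds,
                            test_fraction = config$test_fraction,
                            seed = config$seed)
  write_benchmark(bench, p["bench_rounds"], p["bench_summary"])

  # -- evaluation ------------------------------------------------------
  say("evaluate: clustering and reconstruction metrics")
  asub <- subset_genes(a, genes); bsub <- subset_genes(b, genes)
  rec <- list(a = reconstruct_domain(model, a, "aba"),
              b = reconstruct_domain(model, b, "bab"))
  ev <- rbind(
    evaluate_condition(asub, bsub, k = config$knn_k, seed = config$seed),
    evaluate_condition(asub, bsub, generated = list(ab = tr_ab, ba = tr_ba),
                       reconstructed = rec, k = config$knn_k,
                       seed = config$seed))
  utils::write.table(ev, p["eval"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    config = unclass_rec(config),
    train_config = unclass(tcfg),
    genes = genes,
    artifacts = as.list(stats::setNames(basename(p), names(p))))
  jsonlite::write_json(manifest, p["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(benchmark = bench, evaluation = ev, paths = p,
                 model = model))
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_rec) else x
}
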
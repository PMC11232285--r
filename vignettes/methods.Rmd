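---
title: "Joint style transfer of expression and survival data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint style transfer of expression and survival data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Survival modelling from bulk RNA-seq is chronically under-powered: a cancer
cohort rarely exceeds a thousand samples while the feature space has tens of
thousands of genes. One way out is to borrow strength from a larger cohort of
a *different* cancer type by translating its samples into the style of the
small cohort and adding them to the training set. For the translated samples
to be useful in survival analysis they must carry survival times, not just
expression: this package therefore transfers expression and survival time
*jointly*, treating the (log-scale) survival time as one extra feature of
each sample.

## The model

Two cohorts (domains) $A$ and $B$ are linked by two generators
$G_{AB}: A \to B$ and $G_{BA}: B \to A$ and judged by two discriminators
$D_A$, $D_B$. Each sample is a vector of $p$ selected genes on the
$\log_2(x+1)$ scale plus $\log_2(t+1)$ survival time, so the networks map
$\mathbb{R}^{p+1} \to \mathbb{R}^{p+1}$.

Training minimizes four terms:

* **Adversarial (least squares).** For the $A \to B$ direction,
  $L_{GAN}(G_{AB}, D_B) = \mathbb{E}_b[(D_B(b)-1)^2] +
  \mathbb{E}_a[D_B(G_{AB}(a))^2]$, and symmetrically for $B \to A$. The
  least-squares form avoids the saturation of the log-likelihood objective.
* **Cycle consistency (L1).**
  $\mathbb{E}_a\lVert G_{BA}(G_{AB}(a)) - a\rVert_1 +
  \mathbb{E}_b\lVert G_{AB}(G_{BA}(b)) - b\rVert_1$: a sample translated to
  the other domain and back must return to itself, which pins the
  translation to sample-level content instead of an arbitrary
  distribution map.
* **Identity (L1).** $\mathbb{E}_b\lVert G_{AB}(b) - b\rVert_1 +
  \mathbb{E}_a\lVert G_{BA}(a) - a\rVert_1$: a generator applied to a sample
  already in its output domain should not change it. Setting
  `lambda_identity = 0` in `train_config()` reproduces the identity-loss
  ablation.

The total objective is the plain sum of the four terms, with configurable
weights on cycle and identity (`total_loss()`); L1 norms are summed over
features and averaged over the minibatch, which is the empirical version of
the per-sample expectations above.

**Architecture.** Generators are residual MLPs: two hidden layers
(dense + batch norm + ReLU), three residual blocks
($y = x + \mathrm{BN}(\mathrm{dense}(\mathrm{ReLU}(\mathrm{BN}(\mathrm{dense}(x)))))$,
no activation after the skip addition), two further hidden layers, and a
linear output layer (log-scale features are unbounded above, and a linear
head avoids gradient saturation). Discriminators are three
dense + leaky-ReLU layers (slope 0.2) and a linear scalar output — no
terminal squashing, as the least-squares objective requires. All hidden
widths are configuration; the defaults are 256 for the generator and
(256, 128, 64) for the discriminator.

**Schedule.** Discriminators that converge early starve the generators, so
each minibatch applies `g_steps_per_d_step = 3` generator updates per single
update of each discriminator, and the whole epoch schedule runs
`n_repeats = 3` times consecutively on the same data without
re-initialization (continued training; `restart_each_repeat` selects the
re-initializing reading). Optimization is Adam at learning rate 2e-4,
$\beta_1 = 0.5$, $\beta_2 = 0.999$ — the conventional settings for
cycle-consistent adversarial training — with batch size 64 and 200 epochs
per repeat. A separate discriminator learning rate (`d_learning_rate`,
default equal to the generator's) is exposed as the usual lever for
rebalancing adversarial training when the loss history shows one side
outpacing the other.

One diagnostic deserves emphasis for joint time generation. The quantity
that makes it worthwhile is the *dependence* between the time feature and
the informative genes, which is statistically subtle — a generator can
match the time marginal while leaving the generated time weakly coupled to
the generated expression. Before trusting jointly generated times, compare
the per-gene expression–time association pattern of the generated data
with that of the real target domain (the correlation of the two pattern
vectors should be high), and check that generated times correlate with the
source samples' times, since the cross-domain map preserves sample-level
risk. Unequal domains are handled by partitioning the larger domain
into batches and cycling a reshuffled stream of the smaller one, so an epoch
is one pass over the larger domain. Batch normalization uses batch
statistics during training (momentum 0.1, $\varepsilon = 10^{-5}$) and
running statistics at generation time, making generated output independent
of batch composition.

**Generation.** `style_transfer()` splits the network output back into
expression — clipped at 0, since the $\log_2(x+1)$ scale is nonnegative;
clip counts are reported as a quality diagnostic — and a time feature
back-transformed as $\max(2^y - 1, 1)$ days. The one-day floor mirrors the
removal of zero-day samples at preprocessing. In `expression_only` mode the
generated time is discarded and the source sample's real time retained,
which is the comparison arm for asking whether joint time generation helps.
Event indicators are always copied from the source sample, so event counts
are conserved through transfer. Generated times are kept real-valued
($\geq 1$); nothing downstream needs integer days.

## Preprocessing and cohort rules

`preprocess_domain()` removes samples with a recorded survival time of 0
days and moves expression to $\log_2(x+1)$. Survival times stay in days for
every survival statistic; only the model input uses $\log_2(t+1)$, assembled
on the fly by `model_matrix()`. The survival time enters the network raw on
that scale, without further rescaling against the expression features — the
two are already commensurate after the log transforms, and an extra
normalization would have to be inverted at generation time. A `normalized`
flag guards against double transformation. Cohorts enter a study only with
at least 300 samples and 50 observed events (`filter_cohorts()`); readers
align expression and survival tables on the sorted intersection of sample
IDs, which also fixes the deterministic order that the "chronological"
70/30 split (`chronological_split()`) keys on — with synthetic data there
is no accrual date, so stored order is the stand-in.

## Gene selection

`score_genes()` fits a univariate Cox proportional-hazards model per gene
(Breslow ties, unpenalized, at most 100 Newton iterations) and scores it by
Harrell's C-index of the fitted risk score on the same data; `select_top_genes()`
keeps the top `k = 300` by raw C-index, descending, with lexicographic
tie-breaks. Two consequences of ranking by raw C rather than $|C - 0.5|$:
strongly *protective* genes rank low, and the selection targets genes whose
higher expression predicts shorter survival. We follow the raw-C reading
deliberately and expose `k`. Selection uses only the target domain's
survival signal, and the same gene list is applied to both domains so the
transfer operates in one shared feature space. Scores are computed on the
full target dataset before any train/test split, mirroring the workflow
this package reproduces; note this leaks selection information across CV
folds of the downstream benchmark, which is acceptable for comparing
conditions that all share the same gene list but would bias an absolute
performance claim. When a Cox likelihood is monotone (a perfectly separating
gene) the coefficient estimate diverges and is reported as NA, but the
linear predictor still orders risk validly, so the C-index is computed from
it; constant genes and genuinely failed fits score 0.5.

## Survival evaluation

* `concordance_index()` implements Harrell's C directly: ordered pairs are
  comparable when the shorter observed time has an observed event (pairs
  tied on time are never comparable), risk ties count 1/2, and an
  instance with no comparable pairs returns 0.5 with a warning.
* `km_curve()` and `logrank_test()` wrap the survival package's
  product-limit estimator and two-group log-rank test.
* `fit_superpc()` is supervised principal components: standardize genes,
  screen by absolute univariate Cox Wald $z$, keep the first principal
  component of the survivors, and regress survival on it with a univariate
  Cox model. The screening threshold is chosen from a quantile grid of
  $|z|$ (default probabilities 0, 0.1, ..., 0.9) by internal 3-fold CV
  maximizing validation concordance; at least one gene is always retained,
  and prediction (`predict_partial_hazard()`) uses training-derived
  standardization, loadings and coefficient only.
* `stratify_and_test()` thresholds test-set partial hazards at the *training*
  median (strictly above = high risk, so all-tied hazards give one empty
  group and p = 1 by convention) and reports both Kaplan–Meier curves with
  the log-rank p-value.
* `run_cv_benchmark()` repeats, per round: split the real target data,
  fit SuperPC per condition on real training data plus that condition's
  generated samples, and score on the untouched real test fold. Generated
  samples carry a `gen:` ID prefix and never enter test folds. Conditions
  share splits within a round, so the summary uses condition medians and a
  paired two-sided Wilcoxon signed-rank test against the real-only
  condition (the round-wise differences are paired but far from normal,
  and all-zero difference vectors return p = 1).

## Generation-quality metrics

`evaluate_condition()` pools selected-gene expression vectors (the time
feature is excluded from the clustering space but included in MSE/R²),
labels each point with its domain style, clusters with a two-component
full-covariance Gaussian mixture and reports: kNN purity (k = 10 by
default, distance ties broken by index), NMI (arithmetic-mean entropy
normalization), ARI, mean silhouette (singletons and 0/0 cases contribute
0) and the Dunn index (single-linkage separation over maximum diameter).
MSE and R² compare real samples with their two-generator reconstructions
(R² about the pooled mean of the real entries) and are reported `NA` for
the real-only condition, which has nothing to reconstruct. The mixture fit
uses mclust's deterministic model-based hierarchical initialization rather
than random restarts; points are pre-sorted into a canonical order so
results are invariant to input permutation, and degenerate full-covariance
fits fall back to progressively constrained covariance models (EEE, then
EII) with a message.

## The synthetic testbed

`simulate_pair()` draws per-sample latents $z \sim N(0, I_L)$ (default
$L = 4$) and emits expression $\mathrm{softplus}(W_d z + \mu_d + \epsilon)$,
$\epsilon \sim N(0, 0.3^2)$. Softplus keeps values smooth and nonnegative on
the log-expression scale — a differentiable target for the GAN, unlike
clipping. A seeded random subset of `n_informative` genes loads on latent
coordinate 1 with unit magnitude and random sign; all other genes have
exactly zero loading on it, so "informative" is unambiguous in recovery
tests. The same coordinate drives the log hazard
($\mathrm{risk} = \beta z_1$, default $\beta = 1$), event times are
exponential with baseline median 730 days, and an independent exponential
censoring time is calibrated by root-finding so the expected censoring
fraction equals `censor_rate` (default 0.3, a typical cohort ballpark).
Domains share the risk-coordinate loadings, differ moderately in the
remaining loadings, and are separated by a per-gene mean shift of scale
`domain_shift` (default 2, at which the two domains are cleanly separable
by clustering). Because the construction is affine in $z$ up to the
softplus link, the true cross-domain map is known; `known_map_transfer()`
applies it as an oracle generator, upper-bounding achievable transfer
quality and letting augmentation/evaluation plumbing be tested without any
training.

What the generator does *not* emulate: TCGA-like marginal distributions
(zero inflation, heavy tails), gene-gene correlation beyond the low-rank
latent structure, batch effects, or non-proportional hazards. Passing tests
on this testbed therefore demonstrates that the machinery is correct and
that training converges on well-posed low-dimensional structure — not that
the model reaches any particular accuracy on real tumor cohorts.

## Problem sizes and numerical choices

The test-suite and reproduction-script runs use a deliberately desk-scale
configuration: 50 genes, a few hundred samples per domain, generator width
64 with discriminator widths (128, 64, 32), 200 epochs x 3 repeats, batch
64. These sizes keep a full adversarial training run in the one-to-two
minute range on a single CPU while leaving the network comfortably
over-parameterized for the synthetic testbed's 4-dimensional latent
structure; the 256-wide defaults remain appropriate for real 300-gene
cohorts. Other fixed numerical choices: He initialization from a
counter-based RNG (runs are bit-reproducible from their integer seed,
independent of R's global RNG state); batch-norm $\varepsilon = 10^{-5}$;
Adam $\varepsilon = 10^{-8}$; non-finite losses abort training with a
diagnostic rather than propagating NaN into checkpoints; standardization
SDs of constant genes are set to 1; SuperPC refolds up to three times if a
CV fold lands without events.

## Known limitations

* Adversarial training on tabular data remains sensitive to
  hyper-parameters; the loss history (`$history`, `$d_update_trace`) is the
  first diagnostic to inspect.
* Gene selection and the benchmark reuse the full target dataset for
  screening (see above); the CV benchmark measures *relative* benefit of
  augmentation, not absolute generalization.
* The joint time feature is a single scalar; competing risks,
  time-dependent covariates and clinical covariates are out of scope.
* Generated samples inherit their event indicator from the source domain
  sample; the model never generates censoring status.
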
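test_that("rank AUC matches the pairwise Mann-Whitney count", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)

  probs <- c(0.9, 0.8, 0.4, 0.2); labels <- c(1, 0, 1, 0)
  # enumeration oracle over all positive-negative pairs (ties count half)
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  cnt <- 0
  for (p in pos) for (q in neg) cnt <- cnt + (p > q) + 0.5 * (p == q)
  expect_equal(auc_rank(probs, labels), cnt / (length(pos) * length(neg)))

  # cross-check against an independent ROC implementation on a random case
  skip_if_not_installed("pROC")
  set.seed(14)
  pr <- runif(40); lb <- rbinom(40, 1, 0.5)
  expect_equal(auc_rank(pr, lb),
               as.numeric(pROC::auc(pROC::roc(lb, pr, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))))

  expect_error(auc_rank(c(0.1, 0.9), c(1, 1)), class = "fedsimhash_metric_error")
})

test_that("threshold metrics follow their definitions", {
  probs <- c(0.9, 0.6, 0.4, 0.1)
  labels <- c(1, 0, 1, 0)
  m <- compute_metrics(probs, labels, threshold = 0.5)
  # predictions: 1, 1, 0, 0 -> TP 1, FP 1, FN 1, TN 1
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$f1, 0.5)  # precision 0.5, recall 0.5
  expect_equal(m$n, 4L)
  expect_equal(m$n_pos, 2L)
})

test_that("folds are stratified within one patient of the global rate", {
  set.seed(15)
  labels <- rbinom(83, 1, 0.37)
  fold <- fedsimhash:::make_folds(labels, 5, seed = 4)
  expect_equal(sort(unique(fold)), 1:5)
  global_rate <- mean(labels)
  for (f in 1:5) {
    nf <- sum(fold == f)
    expect_lte(abs(sum(labels[fold == f]) - global_rate * nf), 1)
  }
  # identical seed, identical folds (the paired design)
  expect_identical(fold, fedsimhash:::make_folds(labels, 5, seed = 4))
})

test_that("raw cosine baseline separates orthogonal feature blocks perfectly", {
  # positives live on features 1-3, negatives on features 4-6
  n <- 12
  P <- matrix(0, 6, n)
  labels <- rep(c(1L, 0L), each = n / 2)
  set.seed(16)
  P[1:3, labels == 1L] <- abs(rnorm(3 * n / 2)) + 0.5
  P[4:6, labels == 0L] <- abs(rnorm(3 * n / 2)) + 0.5
  site <- new_site_data(list(l = P), labels)
  rep <- run_experiment(list(site), eval_cfg = eval_config(folds = 3, repeats = 2,
                                                           kappa = 3L, seed = 5),
                        system = "open", code_mode = "raw",
                        baseline_metric = "cosine")
  expect_true(all(rep$auc == 1))
})

test_that("distance matrices agree with stats::dist on small inputs", {
  set.seed(17)
  Q <- matrix(rnorm(12), 3, 4)
  R <- matrix(rnorm(15), 3, 5)
  X <- t(cbind(Q, R))
  D_all <- as.matrix(stats::dist(X, method = "euclidean"))
  expect_equal(unname(fedsimhash:::raw_distance_matrix(Q, R, "euclidean")),
               unname(D_all[1:4, 5:9]), tolerance = 1e-12)
  D_man <- as.matrix(stats::dist(X, method = "manhattan"))
  expect_equal(unname(fedsimhash:::raw_distance_matrix(Q, R, "cityblock")),
               unname(D_man[1:4, 5:9]), tolerance = 1e-12)
  # correlation distance vs cor()
  Dc <- fedsimhash:::raw_distance_matrix(Q, R, "correlation")
  expect_equal(unname(Dc), unname(1 - stats::cor(Q, R)), tolerance = 1e-12)
})

test_that("open and closed systems coincide for a single site", {
  co <- toy_cohort(n = 30L, seed = 71)
  sites <- toy_sites_from_cohort(co, M = 1L)
  cfg <- hash_config(max_iter = 3)
  ecfg <- eval_config(folds = 3, repeats = 1, kappa = c(1L, 3L), seed = 6)
  r_open <- suppressWarnings(run_experiment(sites, cfg, ecfg, system = "open"))
  r_closed <- suppressWarnings(run_experiment(sites, cfg, ecfg, system = "closed"))
  r_fed <- suppressWarnings(run_experiment(sites, cfg, ecfg, system = "federated"))
  for (col in c("auc", "f1", "sensitivity", "specificity")) {
    expect_equal(r_open[[col]], r_closed[[col]], tolerance = 1e-12)
    expect_equal(r_open[[col]], r_fed[[col]], tolerance = 1e-9)
  }
})

test_that("uni-hash mode concatenates features into a single 52-bit function", {
  co <- toy_cohort(n = 24L, seed = 81)
  sites <- toy_sites_from_cohort(co, M = 1L)
  expect_equal(sum(default_bits(names(sites[[1]]$P))), 52L)
  cfg <- hash_config(max_iter = 2)
  ecfg <- eval_config(folds = 2, repeats = 1, kappa = 3L, seed = 7)
  r <- suppressWarnings(run_experiment(sites, cfg, ecfg, system = "open",
                                       code_mode = "uni"))
  expect_equal(nrow(r), 1L)
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("per-site breakdown is reported for the closed system", {
  co <- toy_cohort(n = 40L, seed = 91)
  sites <- toy_sites_from_cohort(co, M = 2L)
  cfg <- hash_config(max_iter = 2)
  ecfg <- eval_config(folds = 2, repeats = 1, kappa = 3L, seed = 8)
  r <- suppressWarnings(run_experiment(sites, cfg, ecfg, system = "closed"))
  ps <- attr(r, "per_site")
  expect_equal(sort(unique(ps$site)), 1:2)
  # closed-system row is the unweighted mean across sites
  expect_equal(r$auc, mean(ps$auc))
})

test_that("single-class sites yield undefined closed-system metrics, not crashes", {
  co <- generate_cohort(cohort_config(40, positive_fraction = 0.5, seed = 17))
  plan <- site_partition_plan(2, c(16L, 16L), c(0, 0.5))
  parts <- partition_sites(co, plan, seed = 2)
  spec <- build_domain_vocabulary(co, exclude = "d_000")
  sites <- lapply(1:2, function(i) {
    assemble_site(parts[[i]], spec, target_code = "d_000", site = i)
  })
  ecfg <- eval_config(folds = 2, repeats = 1, kappa = 3L, seed = 9)
  r <- suppressWarnings(run_experiment(sites, hash_config(max_iter = 2), ecfg,
                                       system = "closed"))
  ps <- attr(r, "per_site")
  expect_true(is.na(ps$auc[ps$site == 1]))
  expect_false(is.na(ps$auc[ps$site == 2]))
})

test_that("the imbalance experiment pairs balanced and skewed arms", {
  co <- generate_cohort(cohort_config(
    72, domains = c(l = 10L, p = 10L, d = 8L, c = 6L, s = 6L),
    positive_fraction = 0.4, signal_strength = 2.5,
    events_per_patient = c(12L, 30L), seed = 19
  ))
  r <- suppressWarnings(imbalance_experiment(
    co, sizes = rep(20L, 3), ratios = c(0.1, 0.3, 0.5),
    cfg = hash_config(max_iter = 2),
    eval_cfg = eval_config(folds = 2, repeats = 1, kappa = 3L, seed = 10),
    seed = 3
  ))
  expect_setequal(unique(r$arm), c("balanced", "imbalanced"))
  expect_true(all(r$auc >= 0 & r$auc <= 1))
  expect_s3_class(autoplot(r), "ggplot")
})
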
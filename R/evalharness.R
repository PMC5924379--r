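#' Configure the evaluation harness
#'
#' Repeated stratified cross-validation settings for the k-NN
#' disease-incidence experiments: 5 folds repeated 10 times by default, with
#' neighbourhood sizes kappa in {1, 3, 9} and a 0.5 voting threshold for the
#' binary metrics.
#'
#' @param folds Number of CV folds (>= 2).
#' @param repeats Number of CV repetitions.
#' @param kappa Integer vector of neighbourhood sizes.
#' @param threshold Voting-probability threshold for F1 / sensitivity /
#'   specificity.
#' @param seed Seed governing fold assignment and fit initialization; a
#'   given seed yields byte-identical folds across systems and code modes
#'   (the paired design).
#' @return An `eval_config`.
#' @export
eval_config <- function(folds = 5L, repeats = 10L, kappa = c(1L, 3L, 9L),
                        threshold = 0.5, seed = 1L) {
  if (!is_count(folds) || folds < 2) abort_config("`folds` must be an integer >= 2.")
  if (!is_count(repeats)) abort_config("`repeats` must be a positive integer.")
  if (!all(vapply(kappa, is_count, logical(1)))) {
    abort_config("all `kappa` values must be positive integers.")
  }
  structure(
    list(folds = as.integer(folds), repeats = as.integer(repeats),
         kappa = as.integer(kappa), threshold = threshold, seed = as.integer(seed)),
    class = "eval_config"
  )
}

#' Area under the ROC curve by rank statistic
#'
#' Mann–Whitney formulation: the probability that a randomly chosen positive
#' receives a higher score than a randomly chosen negative, with ties
#' counted half.
#'
#' @param probs Numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC undefined: both classes must be present.",
                 class = "fedsimhash_metric_error")
  }
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from voting probabilities
#'
#' AUC (rank statistic over all thresholds), plus threshold-based F1
#' (harmonic mean of precision and recall), sensitivity (TPR) and
#' specificity (TN / (TN + FP)).
#'
#' @param probs k-NN voting probabilities.
#' @param labels 0/1 outcome labels.
#' @param threshold Decision threshold (default 0.5; predictions are
#'   positive when `prob >= threshold`).
#' @return One-row tibble: `auc`, `f1`, `sensitivity`, `specificity`, `n`,
#'   `n_pos`.
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels)) abort_dim("probs and labels must align.")
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble::tibble(
    auc = auc_rank(probs, labels),
    f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0,
    sensitivity = recall,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n = length(labels),
    n_pos = sum(labels == 1L)
  )
}

# Stratified fold assignment: within each class, patients are shuffled and
# dealt round-robin, so each fold's positive fraction is within one patient
# of the overall rate.
make_folds <- function(labels, folds, seed) {
  with_seed_(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- resample(which(labels == cls), sum(labels == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

# ---- raw-feature baseline distances ---------------------------------------

raw_distance_matrix <- function(Q, R, metric) {
  # Q, R: features x patients; returns n_query x n_ref distances
  switch(metric,
    euclidean = {
      qq <- colSums(Q * Q); rr <- colSums(R * R)
      d2 <- outer(qq, rr, "+") - 2 * crossprod(Q, R)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      t(apply(Q, 2, function(q) colSums(abs(R - q))))
    },
    cosine = {
      qn <- sqrt(pmax(colSums(Q * Q), .Machine$double.eps))
      rn <- sqrt(pmax(colSums(R * R), .Machine$double.eps))
      1 - crossprod(Q, R) / outer(qn, rn)
    },
    correlation = {
      Qc <- sweep(Q, 2, colMeans(Q))
      Rc <- sweep(R, 2, colMeans(R))
      qn <- sqrt(pmax(colSums(Qc * Qc), .Machine$double.eps))
      rn <- sqrt(pmax(colSums(Rc * Rc), .Machine$double.eps))
      1 - crossprod(Qc, Rc) / outer(qn, rn)
    },
    abort_config(sprintf("unknown baseline metric '%s'.", metric))
  )
}

# kappa-NN voting probabilities from a distance matrix (ties by reference id).
knn_probs_from_dist <- function(D, ref_ids, ref_labels, kappa) {
  vapply(seq_len(nrow(D)), function(qi) {
    ord <- order(D[qi, ], ref_ids)
    mean(ref_labels[ord[seq_len(kappa)]] == 1L)
  }, numeric(1))
}

# ---- the experiment engine -------------------------------------------------

# One CV fold of one system: returns per-kappa probabilities for the test
# patients (rows: pooled patient index within the fold's test set).
fold_probs <- function(sites, test_masks, cfg, eval_cfg, system, code_mode,
                       baseline_metric, fit_seed) {
  train_sites <- lapply(seq_along(sites), function(i) {
    site_subset(sites[[i]], which(!test_masks[[i]]))
  })
  test_sites <- lapply(seq_along(sites), function(i) {
    site_subset(sites[[i]], which(test_masks[[i]]))
  })
  if (code_mode == "uni") {
    train_sites <- lapply(train_sites, concat_site)
    test_sites <- lapply(test_sites, concat_site)
  }
  cfg_fold <- cfg
  cfg_fold$seed <- fit_seed
  if (code_mode == "uni" && is.null(cfg$bits)) {
    # uni-hash: one function over the concatenated features, b = sum(b_k)
    b_total <- sum(default_bits(names(sites[[1]]$P)))
    cfg_fold$bits <- c(all = b_total)
  }

  per_site_probs <- function(D_list, ref_labels_list, ref_ids_list, kappa) {
    lapply(seq_along(D_list), function(i) {
      knn_probs_from_dist(D_list[[i]], ref_ids_list[[i]], ref_labels_list[[i]], kappa)
    })
  }

  if (code_mode == "raw") {
    # no hashing: distances on concatenated unscaled feature vectors
    feat <- function(s) do.call(rbind, unname(s$P))
    if (system == "closed") {
      D_list <- lapply(seq_along(sites), function(i) {
        raw_distance_matrix(feat(test_sites[[i]]), feat(train_sites[[i]]), baseline_metric)
      })
      ref_labels <- lapply(train_sites, `[[`, "labels")
      ref_ids <- lapply(train_sites, `[[`, "pids")
    } else {
      pooled_train <- pool_sites(train_sites)
      pooled_test <- pool_sites(test_sites)
      D_list <- list(raw_distance_matrix(feat(pooled_test), feat(pooled_train),
                                         baseline_metric))
      ref_labels <- list(pooled_train$labels)
      ref_ids <- list(pooled_train$pids)
    }
  } else {
    # fit hash functions on the training patients only
    if (system == "open") {
      fit <- fit_hash_model(pool_sites(train_sites, cross_site_relations = TRUE),
                            cfg_fold)
    } else if (system == "federated") {
      fit <- federated_fit(train_sites, cfg_fold)
    } else if (system == "closed") {
      fits <- lapply(train_sites, function(s) fit_hash_model(list(s), cfg_fold))
    } else {
      abort_config(sprintf("unknown system '%s'.", system))
    }
    if (system == "closed") {
      D_list <- lapply(seq_along(sites), function(i) {
        Cr <- concat_codes(encode(fits[[i]], train_sites[[i]]))
        Cq <- concat_codes(encode(fits[[i]], test_sites[[i]]))
        hamming_matrix(Cq, Cr)
      })
      ref_labels <- lapply(train_sites, `[[`, "labels")
      ref_ids <- lapply(train_sites, `[[`, "pids")
    } else {
      pooled_train <- pool_sites(train_sites)
      pooled_test <- pool_sites(test_sites)
      Cr <- concat_codes(encode(fit, pooled_train))
      Cq <- concat_codes(encode(fit, pooled_test))
      D_list <- list(hamming_matrix(Cq, Cr))
      ref_labels <- list(pooled_train$labels)
      ref_ids <- list(pooled_train$pids)
    }
  }

  lapply(eval_cfg$kappa, function(kp) {
    kp_eff <- min(kp, min(vapply(ref_labels, length, integer(1))))
    per_site_probs(D_list, ref_labels, ref_ids, kp_eff)
  })
}

#' Run a cross-validated k-NN similarity experiment
#'
#' Reproduces the open / closed / federated system comparison at desk scale:
#' for each CV repeat, patients are stratified into folds (byte-identical
#' fold assignments across systems for a given seed, so comparisons are
#' paired); per fold the hash model is fitted on the training patients under
#' the requested system — `open` pools all sites' data and supervision,
#' `closed` fits and evaluates each site in isolation (metrics averaged
#' across sites), `federated` fits across the message boundary and searches
#' across all sites' codes — and the held-out patients are scored by
#' Hamming-distance k-NN voting. `code_mode = "uni"` concatenates all
#' features into a single hash function with `b = sum(b_k)` bits;
#' `code_mode = "raw"` skips hashing and ranks by a raw-feature distance.
#'
#' @param sites List of `site_data` objects.
#' @param cfg A [hash_config()] for the hash-based modes.
#' @param eval_cfg An [eval_config()].
#' @param system `"federated"`, `"open"` or `"closed"`.
#' @param code_mode `"multi"`, `"uni"` or `"raw"`.
#' @param baseline_metric For `code_mode = "raw"`: `"euclidean"`,
#'   `"cityblock"`, `"cosine"` or `"correlation"`.
#' @return A `fedsim_metrics` tibble: one row per (repeat, kappa) — for the
#'   closed system the unweighted mean across sites, with the per-site
#'   breakdown in `attr(, "per_site")`.
#' @export
run_experiment <- function(sites, cfg = hash_config(), eval_cfg = eval_config(),
                           system = c("federated", "open", "closed"),
                           code_mode = c("multi", "uni", "raw"),
                           baseline_metric = "cosine") {
  system <- match.arg(system)
  code_mode <- match.arg(code_mode)
  if (inherits(sites, "site_data")) sites <- list(sites)

  site_sizes <- vapply(sites, `[[`, integer(1), "n")
  all_labels <- unlist(lapply(sites, `[[`, "labels"), use.names = FALSE)
  site_of <- rep(seq_along(sites), site_sizes)

  rows <- list()
  per_site_rows <- list()
  for (rep_i in seq_len(eval_cfg$repeats)) {
    fold_of <- make_folds(all_labels, eval_cfg$folds,
                          seed = eval_cfg$seed + 7919L * rep_i)
    # collect per-kappa probabilities over all folds (each patient scored
    # exactly once, in the fold where it is held out)
    probs <- lapply(eval_cfg$kappa, function(kp) rep(NA_real_, length(all_labels)))
    for (f in seq_len(eval_cfg$folds)) {
      test_masks <- lapply(seq_along(sites), function(i) {
        fold_of[site_of == i] == f
      })
      if (!any(unlist(test_masks))) next
      fp <- fold_probs(sites, test_masks, cfg, eval_cfg, system, code_mode,
                       baseline_metric,
                       fit_seed = (eval_cfg$seed + 104729L * rep_i + 1299709L * f) %% .Machine$integer.max)
      test_idx_by_site <- lapply(seq_along(sites), function(i) {
        which(site_of == i)[test_masks[[i]]]
      })
      for (ki in seq_along(eval_cfg$kappa)) {
        if (system == "closed") {
          for (i in seq_along(sites)) {
            probs[[ki]][test_idx_by_site[[i]]] <- fp[[ki]][[i]]
          }
        } else {
          pooled_idx <- unlist(test_idx_by_site, use.names = FALSE)
          probs[[ki]][pooled_idx] <- unlist(fp[[ki]], use.names = FALSE)
        }
      }
    }
    for (ki in seq_along(eval_cfg$kappa)) {
      kp <- eval_cfg$kappa[ki]
      if (system == "closed") {
        per_site <- lapply(seq_along(sites), function(i) {
          idx <- which(site_of == i)
          m <- tryCatch(
            compute_metrics(probs[[ki]][idx], all_labels[idx], eval_cfg$threshold),
            error = function(e) {
              tibble::tibble(auc = NA_real_, f1 = NA_real_, sensitivity = NA_real_,
                             specificity = NA_real_, n = length(idx),
                             n_pos = sum(all_labels[idx] == 1L))
            })
          dplyr::mutate(m, site = i, repeat_ = rep_i, kappa = kp)
        })
        per_site_rows <- c(per_site_rows, per_site)
        avg <- dplyr::summarise(
          dplyr::bind_rows(per_site),
          auc = mean(auc, na.rm = TRUE), f1 = mean(f1, na.rm = TRUE),
          sensitivity = mean(sensitivity, na.rm = TRUE),
          specificity = mean(specificity, na.rm = TRUE),
          n = sum(n), n_pos = sum(n_pos)
        )
        rows[[length(rows) + 1L]] <- dplyr::mutate(avg, repeat_ = rep_i, kappa = kp)
      } else {
        m <- compute_metrics(probs[[ki]], all_labels, eval_cfg$threshold)
        rows[[length(rows) + 1L]] <- dplyr::mutate(m, repeat_ = rep_i, kappa = kp)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, system = system, code_mode = code_mode,
                       .before = 1)
  out <- dplyr::relocate(out, system, code_mode, repeat_, kappa)
  class(out) <- c("fedsim_metrics", class(out))
  if (length(per_site_rows)) attr(out, "per_site") <- dplyr::bind_rows(per_site_rows)
  out
}

#' Summarise a metric report
#'
#' Mean and SD of each metric across CV repeats, per kappa.
#'
#' @param report A [run_experiment()] result (rows may span several systems).
#' @return A tibble with one row per (system, code_mode, kappa).
#' @export
summarise_metrics <- function(report) {
  dplyr::summarise(
    dplyr::group_by(report, .data$system, .data$code_mode, .data$kappa),
    auc_mean = mean(.data$auc, na.rm = TRUE),
    auc_sd = stats::sd(.data$auc),
    f1_mean = mean(.data$f1, na.rm = TRUE),
    sensitivity_mean = mean(.data$sensitivity, na.rm = TRUE),
    specificity_mean = mean(.data$specificity, na.rm = TRUE),
    repeats = dplyr::n(),
    .groups = "drop"
  )
}

#' Balanced versus imbalanced site composition
#'
#' Partitions one cohort twice with shared seeds — once with every site at
#' the cohort's own positive rate, once with skewed per-site rates (default
#' 10% / 30% / 50%) — assembles features identically, and runs the same
#' cross-validated experiment on both arms, so any metric difference is
#' attributable to the site composition alone.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param sizes Patients per site (length gives the number of sites).
#' @param ratios Per-site positive fractions of the imbalanced arm.
#' @param cfg A [hash_config()].
#' @param eval_cfg An [eval_config()].
#' @param gamma Feature decay constant.
#' @param target_code Target diagnosis code.
#' @param system Which system to evaluate (default federated).
#' @param seed Partition seed.
#' @return A `fedsim_metrics` tibble with an `arm` column
#'   (`"balanced"` / `"imbalanced"`).
#' @export
imbalance_experiment <- function(cohort, sizes = rep(100L, 3L),
                                 ratios = c(0.1, 0.3, 0.5),
                                 cfg = hash_config(), eval_cfg = eval_config(),
                                 gamma = 0.01, target_code = "d_000",
                                 system = "federated", seed = 1L) {
  if (length(ratios) != length(sizes)) abort_config("`ratios` must match `sizes`.")
  spec <- build_domain_vocabulary(cohort, exclude = target_code)
  arms <- list(
    balanced = site_partition_plan(length(sizes), sizes, "inherit"),
    imbalanced = site_partition_plan(length(sizes), sizes, ratios)
  )
  out <- lapply(names(arms), function(arm) {
    parts <- partition_sites(cohort, arms[[arm]], seed = seed)
    sites <- lapply(seq_along(parts), function(i) {
      assemble_site(parts[[i]], spec, gamma = gamma, target_code = target_code, site = i)
    })
    rep <- run_experiment(sites, cfg, eval_cfg, system = system)
    dplyr::mutate(rep, arm = arm, .before = 1)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("fedsim_metrics", class(res))
  res
}
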
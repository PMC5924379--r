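#' Configure a synthetic patient cohort
#'
#' Defines the generating conditions for an in-silico cohort of coded event
#' sequences: per-domain vocabularies, disease prevalence, and the strength of
#' the label signal planted into the coded events. The generator emulates the
#' structure of multi-admission EHR extracts — six feature domains
#' (demographics plus lab results `l`, prescriptions `p`, diagnoses `d`,
#' conditions `c`, symptoms `s`) — without attempting to match any real
#' database's marginal code frequencies.
#'
#' Positive patients carry the target diagnosis code in exactly one admission
#' (never the first, so that a pre-incidence history always exists) and draw
#' their coded events with probability multiplied by `exp(signal_strength)`
#' on a designated "signal" subset comprising the first 20% of each coded
#' domain's vocabulary. `signal_strength = 0` makes positives and negatives
#' exchangeable apart from the target code itself.
#'
#' @param n_patients Number of patients to generate.
#' @param domains Named integer vector of vocabulary sizes for the coded
#'   domains (names among `l`, `p`, `d`, `c`, `s`). Demographics are always
#'   included and need no vocabulary.
#' @param positive_fraction Fraction of patients labelled positive.
#' @param signal_strength Log-odds enrichment of signal codes in positives
#'   (>= 0; 0 disables the planted signal).
#' @param events_per_patient Integer range `c(lo, hi)`: total coded events per
#'   patient, distributed over admissions (each admission receives at least
#'   one event).
#' @param admissions_range Integer range for the number of admissions per
#'   patient (positives draw from `max(2, lo):hi` so the incident admission
#'   is never the first).
#' @param target_code Diagnosis code marking disease incidence; inserted into
#'   exactly one admission of each positive, never present for negatives.
#' @param seed Integer seed; fully determines the output.
#' @return A `cohort_config` object.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients,
                          domains = c(l = 30L, p = 40L, d = 30L, c = 15L, s = 15L),
                          positive_fraction = 0.5,
                          signal_strength = 2,
                          events_per_patient = c(20L, 60L),
                          admissions_range = c(1L, 5L),
                          target_code = "d_000",
                          seed = 1L) {
  if (!is_count(n_patients)) abort_config("`n_patients` must be a positive integer.")
  if (length(domains) == 0) abort_config("`domains` must name at least one coded domain.")
  tags <- names(domains)
  if (is.null(tags) || anyDuplicated(tags) || !all(tags %in% setdiff(DOMAIN_TAGS, "demo"))) {
    abort_config("`domains` names must be unique tags among 'l', 'p', 'd', 'c', 's'.")
  }
  if (!all(vapply(domains, is_count, logical(1)))) {
    abort_config("every domain vocabulary size must be a positive integer.")
  }
  if (!is_fraction(positive_fraction)) abort_config("`positive_fraction` must lie in [0, 1].")
  if (!is.numeric(signal_strength) || signal_strength < 0) {
    abort_config("`signal_strength` must be a non-negative real.")
  }
  if (length(events_per_patient) != 2 || events_per_patient[1] < 1 ||
      events_per_patient[2] < events_per_patient[1]) {
    abort_config("`events_per_patient` must be an increasing positive integer range.")
  }
  if (length(admissions_range) != 2 || admissions_range[1] < 1 ||
      admissions_range[2] < admissions_range[1]) {
    abort_config("`admissions_range` must be an increasing positive integer range.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      domains = vapply(domains, as.integer, integer(1)),
      positive_fraction = positive_fraction,
      signal_strength = signal_strength,
      events_per_patient = as.integer(events_per_patient),
      admissions_range = as.integer(admissions_range),
      target_code = target_code,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Code labels for one coded domain, e.g. "d_001".."d_030".
domain_codes <- function(tag, vocab_size) {
  sprintf("%s_%03d", tag, seq_len(vocab_size))
}

# The planted-signal subset: first 20% (at least one) of each coded vocabulary.
signal_codes <- function(tag, vocab_size) {
  domain_codes(tag, vocab_size)[seq_len(max(1L, ceiling(0.2 * vocab_size)))]
}

#' Generate a synthetic event-sequence cohort
#'
#' Draws `n_patients` multi-admission event sequences under a
#' [cohort_config()]. Each patient is a row of the returned tibble with a
#' stable id, a binary disease label, static demographics, and a list of
#' admissions (character vectors of prefixed codes, in temporal order).
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `pid`, `label` (0/1), `gender` ("M"/"F"),
#'   `age`, and list-column `admissions`.
#' @examples
#' cohort <- generate_cohort(cohort_config(20, seed = 7))
#' table(cohort$label)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort_config("`config` must be a cohort_config.")
  n <- config$n_patients
  n_pos <- as.integer(round(n * config$positive_fraction))
  tags <- names(config$domains)

  with_seed_(config$seed, {
    labels <- integer(n)
    labels[resample(seq_len(n), n_pos)] <- 1L

    # Per-domain sampling weights: positives up-weight the signal subset.
    weights <- lapply(tags, function(tag) {
      v <- config$domains[[tag]]
      w_neg <- rep(1, v)
      w_pos <- w_neg
      w_pos[seq_len(max(1L, ceiling(0.2 * v)))] <- exp(config$signal_strength)
      list(codes = domain_codes(tag, v), neg = w_neg / sum(w_neg), pos = w_pos / sum(w_pos))
    })
    names(weights) <- tags

    patients <- lapply(seq_len(n), function(j) {
      pos <- labels[j] == 1L
      adm_lo <- if (pos) max(2L, config$admissions_range[1]) else config$admissions_range[1]
      adm_hi <- max(adm_lo, config$admissions_range[2])
      n_adm <- resample(adm_lo:adm_hi)
      n_ev <- max(n_adm, resample(config$events_per_patient[1]:config$events_per_patient[2]))
      # every admission gets at least one event, remainder spread uniformly
      adm_of_event <- c(seq_len(n_adm),
                        resample(seq_len(n_adm), n_ev - n_adm, replace = TRUE))
      ev_tags <- resample(tags, n_ev, replace = TRUE)
      codes <- vapply(ev_tags, function(tag) {
        w <- weights[[tag]]
        resample(w$codes, prob = if (pos) w$pos else w$neg)
      }, character(1))
      admissions <- split(codes, factor(adm_of_event, levels = seq_len(n_adm)))
      admissions <- lapply(admissions, unname)
      if (pos) {
        incident <- resample(2:n_adm)
        admissions[[incident]] <- c(admissions[[incident]], config$target_code)
      }
      list(
        gender = resample(c("M", "F")),
        age = round(stats::runif(1, 18, 90)),
        admissions = unname(admissions)
      )
    })

    tibble::tibble(
      pid = sprintf("pt%05d", seq_len(n)),
      label = labels,
      gender = vapply(patients, `[[`, character(1), "gender"),
      age = vapply(patients, `[[`, numeric(1), "age"),
      admissions = lapply(patients, `[[`, "admissions")
    )
  })
}

#' Plan a horizontal multi-site partition
#'
#' @param M Number of sites.
#' @param per_site_sizes Integer vector of length `M`: patients per site.
#' @param per_site_positive_fraction Either `"inherit"` (each site reproduces
#'   the cohort's overall positive rate) or a numeric vector of length `M`
#'   of per-site positive fractions.
#' @return A `site_partition_plan` object.
#' @seealso [partition_sites()]
#' @export
site_partition_plan <- function(M = 3L,
                                per_site_sizes = rep(125L, M),
                                per_site_positive_fraction = "inherit") {
  if (!is_count(M)) abort_config("`M` must be a positive integer.")
  if (length(per_site_sizes) != M) abort_config("`per_site_sizes` must have length M.")
  if (!all(vapply(per_site_sizes, is_count, logical(1)))) {
    abort_config("site sizes must be positive integers.")
  }
  inherit <- identical(per_site_positive_fraction, "inherit")
  if (!inherit) {
    if (length(per_site_positive_fraction) != M ||
        !all(vapply(per_site_positive_fraction, is_fraction, logical(1)))) {
      abort_config("`per_site_positive_fraction` must be 'inherit' or M fractions in [0, 1].")
    }
  }
  structure(
    list(M = as.integer(M),
         per_site_sizes = as.integer(per_site_sizes),
         per_site_positive_fraction = if (inherit) "inherit" else per_site_positive_fraction),
    class = "site_partition_plan"
  )
}

#' Partition a cohort across sites
#'
#' Assigns disjoint patients to `M` sites, honouring each site's requested
#' size exactly and its positive count as `floor(size * fraction)` (the
#' remainder of each site is filled with negatives; if the negative pool is
#' exhausted the shortfall is topped up from leftover positives, so only an
#' infeasible positive count is an error). With
#' `per_site_positive_fraction = "inherit"` every site reproduces the
#' cohort's overall positive rate.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param plan A [site_partition_plan()].
#' @param seed Integer seed controlling the random assignment.
#' @return A list of `M` cohort tibbles.
#' @export
partition_sites <- function(cohort, plan, seed = 1L) {
  if (!inherits(plan, "site_partition_plan")) abort_config("`plan` must be a site_partition_plan.")
  if (sum(plan$per_site_sizes) > nrow(cohort)) {
    abort_config("requested site sizes exceed the cohort size.")
  }
  overall <- mean(cohort$label == 1L)
  fracs <- if (identical(plan$per_site_positive_fraction, "inherit")) {
    rep(overall, plan$M)
  } else {
    plan$per_site_positive_fraction
  }
  n_pos_site <- as.integer(floor(plan$per_site_sizes * fracs))
  n_neg_site <- plan$per_site_sizes - n_pos_site

  with_seed_(seed, {
    pos_pool <- resample(which(cohort$label == 1L), sum(cohort$label == 1L))
    neg_pool <- resample(which(cohort$label == 0L), sum(cohort$label == 0L))
    sites <- vector("list", plan$M)
    for (i in seq_len(plan$M)) {
      if (n_pos_site[i] > length(pos_pool)) {
        rlang::abort(
          sprintf("site %d needs %d positives but only %d remain.",
                  i, n_pos_site[i], length(pos_pool)),
          class = "fedsimhash_partition_error"
        )
      }
      take_pos <- utils::head(pos_pool, n_pos_site[i])
      pos_pool <- utils::tail(pos_pool, length(pos_pool) - n_pos_site[i])
      n_neg_avail <- min(n_neg_site[i], length(neg_pool))
      take_neg <- utils::head(neg_pool, n_neg_avail)
      neg_pool <- utils::tail(neg_pool, length(neg_pool) - n_neg_avail)
      # floor rounding can exhaust the negative pool before the last site;
      # the shortfall is topped up from the leftover positives
      short <- n_neg_site[i] - n_neg_avail
      if (short > 0) {
        if (short > length(pos_pool)) {
          rlang::abort(
            sprintf("site %d needs %d more patients but the cohort is exhausted.",
                    i, short - length(pos_pool)),
            class = "fedsimhash_partition_error"
          )
        }
        take_pos <- c(take_pos, utils::head(pos_pool, short))
        pos_pool <- utils::tail(pos_pool, length(pos_pool) - short)
      }
      idx <- sort(c(take_pos, take_neg))
      sites[[i]] <- cohort[idx, , drop = FALSE]
    }
    names(sites) <- paste0("site", seq_len(plan$M))
    sites
  })
}

#' Read and write cohorts as JSON-lines
#'
#' One JSON object per patient:
#' `{"pid": ..., "label": 0|1, "demographics": {"gender": "M"|"F", "age": n},
#'  "admissions": [[code, ...], ...]}`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_jsonl()` returns `path` invisibly;
#'   `read_cohort_jsonl()` returns a cohort tibble.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(seq_len(nrow(cohort)), function(j) {
    jsonlite::toJSON(
      list(
        pid = cohort$pid[j],
        label = cohort$label[j],
        demographics = list(gender = cohort$gender[j], age = cohort$age[j]),
        admissions = cohort$admissions[[j]]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  tibble::tibble(
    pid = vapply(recs, function(r) as.character(r$pid), character(1)),
    label = vapply(recs, function(r) as.integer(r$label), integer(1)),
    gender = vapply(recs, function(r) as.character(r$demographics$gender), character(1)),
    age = vapply(recs, function(r) as.numeric(r$demographics$age), numeric(1)),
    admissions = lapply(recs, function(r) {
      lapply(r$admissions, function(a) vapply(a, as.character, character(1), USE.NAMES = FALSE))
    })
  )
}
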
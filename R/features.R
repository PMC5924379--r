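#' Build per-domain code vocabularies from a cohort
#'
#' Scans every admission of every patient and collects, per feature domain,
#' the sorted set of observed codes. Codes are assigned to domains by their
#' prefix (`l_`, `p_`, `d_`, `c_`, `s_`); the demographics domain is always
#' present with the fixed dictionary `gender_M`, `gender_F`, `age`.
#' Lexicographic sorting makes the column order of downstream feature
#' matrices canonical and reproducible.
#'
#' @param cohorts A cohort tibble (or a list of cohort tibbles, e.g. one per
#'   site, whose vocabularies are unioned).
#' @param exclude Codes to leave out of the vocabulary — typically the target
#'   diagnosis, so the feature space never contains the outcome of interest.
#' @return A `feature_domain_spec`: list with `tags` (domain ordering,
#'   demographics first), `vocab` (named list of code vectors) and `dims`
#'   (named integer vector `d_k`).
#' @export
build_domain_vocabulary <- function(cohorts, exclude = character(0)) {
  if (inherits(cohorts, "data.frame")) cohorts <- list(cohorts)
  all_codes <- unlist(lapply(cohorts, function(co) unlist(co$admissions)), use.names = FALSE)
  if (length(cohorts) == 0 || sum(vapply(cohorts, nrow, integer(1))) == 0) {
    abort_config("cannot build a vocabulary from an empty cohort.")
  }
  prefix <- sub("_.*$", "", all_codes)
  bad <- !(prefix %in% setdiff(DOMAIN_TAGS, "demo"))
  if (any(bad)) {
    rlang::abort(
      sprintf("unknown code prefix in '%s' (expected l_, p_, d_, c_ or s_).",
              all_codes[which(bad)[1]]),
      class = "fedsimhash_format_error"
    )
  }
  vocab <- list(demo = c("gender_M", "gender_F", "age"))
  for (tag in setdiff(DOMAIN_TAGS, "demo")) {
    codes <- setdiff(sort(unique(all_codes[prefix == tag])), exclude)
    if (length(codes)) vocab[[tag]] <- codes
  }
  structure(
    list(
      tags = names(vocab),
      vocab = vocab,
      dims = vapply(vocab, length, integer(1))
    ),
    class = "feature_domain_spec"
  )
}

#' Slice a patient history at first disease incidence
#'
#' Implements the incidence-prediction slicing rule: if the target diagnosis
#' code occurs, the admission containing its first occurrence is cut out and
#' only admissions strictly before it are kept, with label 1; the retained
#' feature stream therefore never contains the outcome code. Patients whose
#' target occurs in the very first admission have no usable history and are
#' flagged for the caller to exclude. Patients without the target keep all
#' admissions, label 0.
#'
#' @param admissions List of character vectors (admissions in temporal order).
#' @param target_code The target diagnosis code.
#' @return List with `admissions` (retained), `label` (0/1) and `no_history`
#'   (TRUE when the target appeared in the first admission).
#' @export
slice_at_first_target <- function(admissions, target_code) {
  hit <- which(vapply(admissions, function(a) target_code %in% a, logical(1)))
  if (length(hit) == 0) {
    return(list(admissions = admissions, label = 0L, no_history = FALSE))
  }
  first <- hit[1]
  if (first == 1L) {
    return(list(admissions = list(), label = 1L, no_history = TRUE))
  }
  list(admissions = admissions[seq_len(first - 1L)], label = 1L, no_history = FALSE)
}

#' Time-decayed one-hot feature vectors for one patient
#'
#' Flattens the retained admissions into a single event stream (events are
#' assumed equally spaced) and accumulates, per domain, one-hot indicators
#' weighted by `exp(-gamma * t)`, where `t` counts event steps backwards from
#' the most recent event (`t = 0` at the end of the stream, so recent events
#' weigh most). Demographics (`gender` one-hot plus raw `age`) are copied
#' without decay. Codes absent from the vocabulary are dropped with a
#' warning, so a fixed spec can be applied to new cohorts.
#'
#' @param admissions List of character vectors (already sliced).
#' @param gender `"M"` or `"F"`.
#' @param age Numeric age, used as-is.
#' @param spec A [build_domain_vocabulary()] spec.
#' @param gamma Non-negative decay constant (default 0.01); `gamma = 0`
#'   reduces to raw event counts.
#' @return Named list of numeric vectors, one per domain in `spec$tags`.
#' @export
vectorize_patient <- function(admissions, gender, age, spec, gamma = 0.01) {
  if (!is.numeric(gamma) || gamma < 0) abort_config("`gamma` must be non-negative.")
  out <- lapply(spec$dims, function(d) numeric(d))
  for (tag in spec$tags) names(out[[tag]]) <- spec$vocab[[tag]]

  events <- unlist(admissions, use.names = FALSE)
  n <- length(events)
  if (n > 0) {
    w <- exp(-gamma * (n - seq_len(n)))  # t = 0 at the most recent event
    prefix <- sub("_.*$", "", events)
    dropped <- 0L
    for (j in seq_len(n)) {
      tag <- prefix[j]
      pos <- match(events[j], spec$vocab[[tag]])
      if (is.null(spec$vocab[[tag]]) || is.na(pos)) {
        dropped <- dropped + 1L
        next
      }
      out[[tag]][pos] <- out[[tag]][pos] + w[j]
    }
    if (dropped > 0) {
      rlang::warn(sprintf("dropped %d event(s) with codes outside the vocabulary.", dropped))
    }
  }
  out$demo <- c(gender_M = as.numeric(gender == "M"),
                gender_F = as.numeric(gender == "F"),
                age = as.numeric(age))
  out[spec$tags]
}

# Pairwise label-relationship matrix: +1 same label, -1 different, 0 on the
# diagonal (self-pairs carry no supervision).
relationship_matrix <- function(labels) {
  R <- outer(labels, labels, function(a, b) ifelse(a == b, 1, -1))
  diag(R) <- 0
  R
}

#' Assemble one site's feature matrices
#'
#' Applies [slice_at_first_target()] then [vectorize_patient()] to every
#' patient of a cohort, drops patients without pre-incidence history (with a
#' warning), and packs the result into per-domain matrices `P_k` of shape
#' `d_k x N` (patients as columns, identical column order across domains)
#' together with the labels and their pairwise relationship matrix.
#'
#' @param cohort A cohort tibble.
#' @param spec A [build_domain_vocabulary()] spec.
#' @param gamma Time-decay constant (default 0.01).
#' @param target_code Target diagnosis code.
#' @param site Integer site index carried along for bookkeeping.
#' @return A `site_data` object: list with `site`, `P` (named list of
#'   matrices), `labels`, `pids`, `R` and `n`.
#' @export
assemble_site <- function(cohort, spec, gamma = 0.01, target_code = "d_000", site = 1L) {
  sliced <- lapply(cohort$admissions, slice_at_first_target, target_code = target_code)
  keep <- !vapply(sliced, `[[`, logical(1), "no_history")
  if (sum(!keep) > 0) {
    rlang::warn(sprintf("site %d: dropped %d patient(s) with no pre-incidence history.",
                        site, sum(!keep)))
  }
  if (!any(keep)) {
    rlang::abort(sprintf("site %d: no usable patients after slicing.", site),
                 class = "fedsimhash_assembly_error")
  }
  idx <- which(keep)
  labels <- vapply(sliced[idx], `[[`, integer(1), "label")
  vecs <- lapply(idx, function(j) {
    vectorize_patient(sliced[[j]]$admissions, cohort$gender[j], cohort$age[j],
                      spec, gamma = gamma)
  })
  P <- lapply(spec$tags, function(tag) {
    m <- vapply(vecs, function(v) v[[tag]], numeric(spec$dims[[tag]]))
    m <- matrix(m, nrow = spec$dims[[tag]],
                dimnames = list(spec$vocab[[tag]], cohort$pid[idx]))
    m
  })
  names(P) <- spec$tags
  new_site_data(P = P, labels = labels, pids = cohort$pid[idx], site = site)
}

#' Construct a site dataset from matrices
#'
#' Low-level constructor used by [assemble_site()] and by tests/toy examples:
#' wraps per-domain feature matrices, labels and patient ids into a validated
#' `site_data` object, rebuilding the relationship matrix from the labels.
#'
#' @param P Named list of `d_k x N` numeric matrices sharing column count.
#' @param labels Integer 0/1 vector of length `N`.
#' @param pids Optional patient ids (default `"p1"..."pN"`).
#' @param site Site index.
#' @return A `site_data` object.
#' @export
new_site_data <- function(P, labels, pids = NULL, site = 1L) {
  ns <- unique(vapply(P, ncol, integer(1)))
  if (length(ns) != 1) abort_dim("all domain matrices must share the same column count.")
  n <- ns
  if (length(labels) != n) abort_dim("`labels` length must match the number of patients.")
  pids <- pids %||% paste0("p", seq_len(n))
  structure(
    list(site = as.integer(site), P = P, labels = as.integer(labels),
         pids = as.character(pids), R = relationship_matrix(as.integer(labels)), n = n),
    class = "site_data"
  )
}

# Restrict a site to a subset of its patients (R rebuilt from the subset).
site_subset <- function(site, idx) {
  new_site_data(
    P = lapply(site$P, function(m) m[, idx, drop = FALSE]),
    labels = site$labels[idx],
    pids = site$pids[idx],
    site = site$site
  )
}

# Pool several sites into one. `cross_site_relations` controls the pooled
# relationship matrix: TRUE rebuilds it from the pooled labels (open-system
# reading, cross-site pairs supervised); FALSE keeps the block-diagonal union
# of the per-site matrices (cross-site relations unknown, entries 0), which
# is the objective the federated fit actually optimizes.
pool_sites <- function(sites, cross_site_relations = TRUE) {
  tags <- names(sites[[1]]$P)
  P <- lapply(tags, function(tag) do.call(cbind, lapply(sites, function(s) s$P[[tag]])))
  names(P) <- tags
  labels <- unlist(lapply(sites, `[[`, "labels"), use.names = FALSE)
  pids <- unlist(lapply(sites, `[[`, "pids"), use.names = FALSE)
  pooled <- new_site_data(P = P, labels = labels, pids = pids, site = 1L)
  if (!cross_site_relations) {
    R <- matrix(0, pooled$n, pooled$n)
    at <- 0L
    for (s in sites) {
      idx <- at + seq_len(s$n)
      R[idx, idx] <- s$R
      at <- at + s$n
    }
    pooled$R <- R
  }
  pooled
}

# Collapse the K domains of a site into one concatenated "all" domain
# (uni-hash representation).
concat_site <- function(site) {
  new_site_data(
    P = list(all = do.call(rbind, unname(site$P))),
    labels = site$labels, pids = site$pids, site = site$site
  )
}

#' Serialize a site dataset as plain text
#'
#' Writes one TSV per domain (rows = feature codes, columns = patient ids),
#' a labels TSV and a JSON sidecar with the domain ordering.
#'
#' @param site A `site_data` object.
#' @param dir Output directory (created if missing).
#' @return `write_site_data()` returns `dir` invisibly; `read_site_data()`
#'   returns a `site_data`.
#' @export
write_site_data <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tag in names(site$P)) {
    utils::write.table(site$P[[tag]], file.path(dir, paste0("P_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  utils::write.table(
    data.frame(pid = site$pids, label = site$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(list(site = site$site, domains = names(site$P)),
                       file.path(dir, "site.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_site_data
#' @export
read_site_data <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "site.json"), simplifyVector = TRUE)
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t", header = TRUE,
                           colClasses = c("character", "integer"))
  P <- lapply(meta$domains, function(tag) {
    m <- utils::read.table(file.path(dir, paste0("P_", tag, ".tsv")), sep = "\t",
                           header = TRUE, row.names = 1, check.names = FALSE)
    as.matrix(m)
  })
  names(P) <- meta$domains
  new_site_data(P = P, labels = lab$label, pids = lab$pid, site = meta$site)
}
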
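#' Per-domain hash-code similarity
#'
#' Normalized inner product of two `b_k`-bit codes,
#' `s = (1/b_k) * h_u' h_v`, which lies in \[-1, 1\] and relates to the
#' Hamming distance by `s = 1 - 2 d_H / b_k`.
#'
#' @param h_u,h_v Numeric vectors of equal length with entries in -1/+1.
#' @return Scalar similarity in \[-1, 1\].
#' @export
domain_similarity <- function(h_u, h_v) {
  check_code(h_u)
  check_code(h_v)
  if (length(h_u) != length(h_v)) abort_dim("codes must have equal length.")
  sum(h_u * h_v) / length(h_u)
}

check_code <- function(h) {
  if (!is.numeric(h) || !all(h %in% c(-1, 1))) {
    rlang::abort("hash codes must have entries in {-1, +1}.",
                 class = "fedsimhash_code_error")
  }
  invisible(TRUE)
}

#' Overall similarity across feature domains
#'
#' Mean of the `K` per-domain normalized similarities, so the overall score
#' is bounded in \[-1, 1\] and the per-domain breakdown explains *why* two
#' patients are similar (their demographics, their diagnoses, ...), not just
#' how much.
#'
#' @param codes_u,codes_v Named lists of `K` per-domain -1/+1 vectors with
#'   matching lengths (or `hash_codes` columns; see [knn_predict()] for bulk
#'   search).
#' @return List with `value` (the overall mean similarity) and `by_domain`
#'   (tibble of per-domain similarities).
#' @export
overall_similarity <- function(codes_u, codes_v) {
  if (length(codes_u) != length(codes_v)) {
    abort_dim("both patients must have codes for the same K domains.")
  }
  sims <- vapply(seq_along(codes_u), function(k) {
    domain_similarity(codes_u[[k]], codes_v[[k]])
  }, numeric(1))
  names(sims) <- names(codes_u) %||% paste0("domain", seq_along(sims))
  list(value = mean(sims),
       by_domain = tibble::tibble(domain = names(sims), similarity = unname(sims)))
}

#' Hamming distance between binary codes
#'
#' Number of positions at which two equal-length -1/+1 codes differ.
#' `concatenated_hamming()` sums the per-domain distances, i.e. the Hamming
#' distance over the concatenated `b = sum(b_k)` bits, which is the ranking
#' measure of the similarity search.
#'
#' @param h_u,h_v -1/+1 vectors of equal length.
#' @return Integer in `[0, b]`.
#' @export
hamming_distance <- function(h_u, h_v) {
  check_code(h_u)
  check_code(h_v)
  if (length(h_u) != length(h_v)) abort_dim("codes must have equal length.")
  sum(h_u != h_v)
}

#' @rdname hamming_distance
#' @param codes_u,codes_v Lists of per-domain -1/+1 vectors.
#' @export
concatenated_hamming <- function(codes_u, codes_v) {
  sum(vapply(seq_along(codes_u), function(k) {
    hamming_distance(codes_u[[k]], codes_v[[k]])
  }, numeric(1)))
}

# Pairwise Hamming distances between the columns of two concatenated +-1
# code matrices: d_H = (b - u'v) / 2.
hamming_matrix <- function(Cq, Cr) {
  b <- nrow(Cq)
  (b - crossprod(Cq, Cr)) / 2   # n_query x n_ref
}

#' Hamming-distance k-nearest-neighbour prediction
#'
#' For each query patient, ranks the reference patients by Hamming distance
#' over the concatenated multi-domain code (distance ties broken by
#' reference id, ascending, so results are deterministic) and votes: the
#' predicted probability is the fraction of the `kappa` nearest references
#' carrying the positive label.
#'
#' @param query A `hash_codes` object (or bare -1/+1 matrix, bits x patients).
#' @param reference A `hash_codes` object (or matrix) for the reference set.
#' @param labels Integer 0/1 labels aligned with the reference columns.
#' @param kappa Number of neighbours (>= 1, at most the reference count).
#' @param neighbors Keep the per-query neighbour table? (default TRUE; turn
#'   off for bulk evaluation).
#' @return A tibble with one row per query: `query_id`, `kappa`, `prob`, and
#'   (if requested) a `neighbors` list-column of tibbles
#'   (`ref_id`, `distance`, `similarity`) sorted by distance.
#' @export
knn_predict <- function(query, reference, labels, kappa = 3L, neighbors = TRUE) {
  if (!is_count(kappa)) abort_config("`kappa` must be a positive integer.")
  Cq <- if (inherits(query, "hash_codes")) concat_codes(query) else as.matrix(query)
  Cr <- if (inherits(reference, "hash_codes")) concat_codes(reference) else as.matrix(reference)
  qids <- if (inherits(query, "hash_codes")) query$pids else
    colnames(Cq) %||% paste0("q", seq_len(ncol(Cq)))
  rids <- if (inherits(reference, "hash_codes")) reference$pids else
    colnames(Cr) %||% paste0("r", seq_len(ncol(Cr)))
  if (kappa > ncol(Cr)) abort_config("`kappa` exceeds the number of references.")
  if (length(labels) != ncol(Cr)) abort_dim("`labels` must match the reference count.")
  check_code(Cq)
  check_code(Cr)
  if (nrow(Cq) != nrow(Cr)) abort_dim("query and reference codes must share bit length.")

  b <- nrow(Cq)
  D <- hamming_matrix(Cq, Cr)
  rows <- lapply(seq_len(ncol(Cq)), function(qi) {
    ord <- order(D[qi, ], rids)
    top <- ord[seq_len(kappa)]
    out <- tibble::tibble(
      query_id = qids[qi],
      kappa = as.integer(kappa),
      prob = mean(labels[top] == 1L)
    )
    if (neighbors) {
      out$neighbors <- list(tibble::tibble(
        ref_id = rids[top],
        distance = as.integer(D[qi, top]),
        similarity = 1 - 2 * D[qi, top] / b
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Read and write hash codes as TSV
#'
#' Codes are stored as a tab-separated table of -1/+1 integers with one row
#' per bit (row names `domain.bit`) and one column per patient.
#'
#' @param hc A `hash_codes` object.
#' @param path File path.
#' @return `write_codes_tsv()` returns `path` invisibly; `read_codes_tsv()`
#'   returns a `hash_codes`.
#' @export
write_codes_tsv <- function(hc, path) {
  C <- concat_codes(hc)
  rownames(C) <- unlist(lapply(names(hc$codes), function(k) {
    paste0(k, ".", seq_len(nrow(hc$codes[[k]])))
  }), use.names = FALSE)
  colnames(C) <- hc$pids
  utils::write.table(C, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_codes_tsv
#' @export
read_codes_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                                   check.names = FALSE))
  doms <- sub("\\.[0-9]+$", "", rownames(m))
  codes <- lapply(unique(doms), function(k) {
    block <- m[doms == k, , drop = FALSE]
    storage.mode(block) <- "double"
    block
  })
  names(codes) <- unique(doms)
  structure(list(codes = codes, pids = colnames(m),
                 bits = vapply(codes, nrow, integer(1))),
            class = "hash_codes")
}
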
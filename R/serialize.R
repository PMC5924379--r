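#' Read and write fitted hash models
#'
#' A model directory holds a JSON header (code lengths, regularizers,
#' surrogate smoothing, seed, convergence summary) plus one TSV of
#' coefficients per domain (rows = feature codes, columns = hash directions).
#'
#' @param fit A `fed_hash_fit` (or bare named list of `W_k` for
#'   `write_hash_model()` with `header = NULL` fields filled as `NA`).
#' @param dir Directory path.
#' @return `write_hash_model()` returns `dir` invisibly; `read_hash_model()`
#'   returns a list with `W` (named list of matrices) and `header`, usable
#'   wherever a model is accepted (e.g. [encode()]).
#' @export
write_hash_model <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- if (inherits(fit, "fed_hash_fit")) fit$W else fit
  header <- if (inherits(fit, "fed_hash_fit")) {
    cfg <- fit$config
    list(domains = names(W), bits = as.list(fit$bits),
         lambda = cfg$lambda, eta = cfg$eta, xi = cfg$xi, seed = cfg$seed,
         method = fit$method, iterations = fit$iterations,
         converged = fit$converged,
         objective_final = fit$trace[length(fit$trace)])
  } else {
    list(domains = names(W),
         bits = as.list(vapply(W, ncol, integer(1))))
  }
  jsonlite::write_json(header, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in names(W)) {
    utils::write.table(W[[k]], file.path(dir, paste0("W_", k, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

#' @rdname write_hash_model
#' @export
read_hash_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  W <- lapply(header$domains, function(k) {
    as.matrix(utils::read.table(file.path(dir, paste0("W_", k, ".tsv")),
                                sep = "\t", header = TRUE, row.names = 1,
                                check.names = FALSE))
  })
  names(W) <- header$domains
  list(W = W, header = header)
}
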
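#' Configure a simulated federation
#'
#' Sites are simulated in-process behind a strict message boundary: the
#' coordinating server sees only aggregate derivative statistics
#' (`d_k x b_k` gradients, `d_k x d_k` Hessian blocks) and scalar objective
#' values; patient-level matrices (`P`, `Q`, `H`, `R`) never cross the
#' boundary, and every exchanged message is recorded in an audit log. Only
#' the synchronous schedule is supported — it is what makes the federated
#' run provably identical to the centralized one. `async_update()` is an
#' interface stub for streaming updates.
#'
#' @param M Number of sites (>= 1).
#' @param schedule Only `"synchronous"`.
#' @param max_rounds Cap on communication rounds (defaults to the optimizer's
#'   `max_iter`).
#' @return A `federation_config`.
#' @export
federation_config <- function(M = 3L, schedule = "synchronous", max_rounds = NULL) {
  if (!is_count(M)) abort_config("`M` must be a positive integer.")
  schedule <- match.arg(schedule, "synchronous")
  structure(list(M = as.integer(M), schedule = schedule, max_rounds = max_rounds),
            class = "federation_config")
}

# ---- message schema --------------------------------------------------------

# Allowed payload shapes for a W-update bundle from site i, domain k:
#   gradient d_k x b_k, hessian_block d_k x d_k, n / objective scalars.
# Anything with a patient-indexed dimension is rejected.
validate_bundle <- function(bundle, d_k, b_k) {
  allowed <- c("type", "site", "k", "version", "gradient", "hessian_block", "n")
  extra <- setdiff(names(bundle), allowed)
  if (length(extra)) {
    rlang::abort(sprintf("bundle carries disallowed field(s): %s",
                         paste(extra, collapse = ", ")),
                 class = "fedsimhash_schema_error")
  }
  if (!identical(dim(bundle$gradient), c(d_k, b_k))) {
    rlang::abort("bundle gradient is not a d_k x b_k aggregate.",
                 class = "fedsimhash_schema_error")
  }
  if (!identical(dim(bundle$hessian_block), c(d_k, d_k))) {
    rlang::abort("bundle Hessian is not a d_k x d_k aggregate.",
                 class = "fedsimhash_schema_error")
  }
  if (!(is.numeric(bundle$n) && length(bundle$n) == 1)) {
    rlang::abort("bundle patient count must be a scalar.",
                 class = "fedsimhash_schema_error")
  }
  invisible(TRUE)
}

new_message_log <- function() {
  env <- new.env(parent = emptyenv())
  env$messages <- list()
  env
}

log_message <- function(log, type, site, k, payload_dims) {
  log$messages[[length(log$messages) + 1L]] <-
    list(type = type, site = site, k = k, payload_dims = payload_dims)
  invisible(NULL)
}

#' Audit a federation message log
#'
#' Structural privacy check: verifies that every recorded message carried
#' only aggregate payloads — `d_k x b_k` gradients, `d_k x d_k` Hessian
#' blocks, broadcast model blocks of the same shapes, and scalars — and
#' nothing patient-indexed (no dimension equal to any site's patient count,
#' beyond coincidence with the allowed aggregate shapes).
#'
#' @param fit A [federated_fit()] result (or its `message_log`).
#' @return A tibble with one row per message (`type`, `site`, `k`, `dims`)
#'   invisibly classed as passing; aborts if any message violates the schema.
#' @export
audit_message_log <- function(fit) {
  log <- if (inherits(fit, "fed_hash_fit")) attr(fit, "message_log") else fit
  if (is.null(log)) abort_config("no message log found; was this a federated fit?")
  dims_allowed <- attr(log, "allowed_dims")
  rows <- lapply(log$messages, function(m) {
    for (d in m$payload_dims) {
      key <- paste(d, collapse = "x")
      if (!(key %in% c("1x1", dims_allowed))) {
        rlang::abort(sprintf("message of type '%s' carried a %s payload.", m$type, key),
                     class = "fedsimhash_schema_error")
      }
    }
    tibble::tibble(type = m$type, site = m$site %||% NA_integer_,
                   k = m$k %||% NA_character_,
                   dims = paste(vapply(m$payload_dims, paste, character(1), collapse = "x"),
                                collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

# ---- site node -------------------------------------------------------------

# A data custodian: owns its site_data and Q blocks; answers only statistics
# and scalar objective queries. Wraps the hashcore site handle and logs every
# exchange.
fed_site_node <- function(site, cfg, log) {
  handle <- local_site_handle(site, cfg)
  version <- new.env(parent = emptyenv())
  version$v <- 0L
  list(
    site = site$site,
    n = site$n,
    init_Q = function(W) {
      handle$init_Q(W)
      handle$set_W(W)
      version$v <- 1L
      log_message(log, "model", site$site, NA_character_,
                  lapply(W, dim))
      invisible(NULL)
    },
    version = function() version$v,
    w_stats = function(k, Wk, model_version) {
      if (model_version != version$v) {
        rlang::abort(sprintf("site %d holds model version %d, coordinator sent %d.",
                             site$site, version$v, model_version),
                     class = "fedsimhash_protocol_error")
      }
      st <- handle$w_stats(k, Wk)
      bundle <- list(type = "bundle", site = site$site, k = k, version = version$v,
                     gradient = st$gradient, hessian_block = st$hessian_block,
                     n = site$n)
      validate_bundle(bundle, nrow(st$gradient), ncol(st$gradient))
      log_message(log, "bundle", site$site, k,
                  list(dim(st$gradient), dim(st$hessian_block), c(1L, 1L)))
      bundle
    },
    objective = function(k = NULL, Wk = NULL) {
      f <- handle$objective(k = k, Wk = Wk)
      log_message(log, "objective", site$site, k %||% NA_character_, list(c(1L, 1L)))
      f
    },
    commit_W = function(W) {
      handle$set_W(W)
      version$v <- version$v + 1L
      log_message(log, "model", site$site, NA_character_, lapply(W, dim))
      invisible(NULL)
    },
    q_update = function(k, Wk) {
      f <- handle$q_update(k, Wk)
      log_message(log, "ack", site$site, k, list(c(1L, 1L)))
      f
    },
    handle = handle
  )
}

#' Per-site derivative statistics for a W update
#'
#' The aggregate statistics one data custodian contributes to the update of
#' `W_k`: its gradient block, its shared per-column Hessian block and its
#' patient count. Equals [derivatives_W()] restricted to that site, and is
#' schema-validated to contain no patient-level payload.
#'
#' @param site A `site_data`.
#' @param model Named list of current `W_k` (the broadcast model).
#' @param aux That site's named list of `Q_k` blocks.
#' @param k Domain tag.
#' @param cfg A [hash_config()].
#' @return A bundle: list with `type`, `site`, `k`, `version`, `gradient`
#'   (`d_k x b_k`), `hessian_block` (`d_k x d_k`), `n`.
#' @export
local_W_statistics <- function(site, model, aux, k, cfg) {
  W <- if (inherits(model, "fed_hash_fit")) model$W else model
  S <- surrogate_sign(aux[[k]], cfg$xi)
  E <- crossprod(W[[k]], site$P[[k]]) - S
  bundle <- list(type = "bundle", site = site$site, k = k, version = 1L,
                 gradient = 2 * (site$P[[k]] %*% t(E)),
                 hessian_block = 2 * tcrossprod(site$P[[k]]),
                 n = site$n)
  validate_bundle(bundle, nrow(W[[k]]), ncol(W[[k]]))
  bundle
}

#' Aggregate site bundles and take a damped Newton step on W_k
#'
#' Sums the per-site gradients and Hessian blocks (summation happens before
#' inversion, the mathematically exact reading of the aggregated Newton
#' update), then applies the same ridged, step-halved Newton step as the
#' centralized optimizer. The objective needed by the line search is supplied
#' as a callback so the caller can route it through the message boundary.
#'
#' @param bundles List of bundles, one per site, all for domain `k`.
#' @param model Named list of current `W_k`.
#' @param k Domain tag.
#' @param cfg A [hash_config()].
#' @param objective_fn Function of a candidate `W_k` returning the total
#'   objective (sum of the sites' scalar replies).
#' @param f_current Current total objective.
#' @return The updated `W_k` matrix.
#' @export
aggregate_and_update_W <- function(bundles, model, k, cfg, objective_fn, f_current) {
  W <- if (inherits(model, "fed_hash_fit")) model$W else model
  ks <- unique(vapply(bundles, `[[`, character(1), "k"))
  if (!identical(ks, k)) {
    rlang::abort("bundles do not all refer to the requested domain.",
                 class = "fedsimhash_protocol_error")
  }
  vs <- unique(vapply(bundles, function(b) as.integer(b$version), integer(1)))
  if (length(vs) != 1) {
    rlang::abort("bundles refer to different model versions.",
                 class = "fedsimhash_protocol_error")
  }
  grad_sum <- Reduce(`+`, lapply(bundles, `[[`, "gradient"))
  hess_sum <- Reduce(`+`, lapply(bundles, `[[`, "hessian_block"))
  res <- newton_W_step(W[[k]], grad_sum, hess_sum, cfg, objective_fn, f_current, k)
  res$W
}

#' Fit the hash model across a simulated federation
#'
#' Runs the same damped block-coordinate Newton schedule as
#' [fit_hash_model()], but with every site behind a message boundary: for
#' each `W_k` update the coordinator collects one derivative bundle per site
#' (synchronous schedule — a missing site is a protocol error), sums them,
#' line-searches using the sites' scalar objective replies, and broadcasts
#' the committed block; `Q` updates and the hash codes themselves never
#' leave their site. Because both paths share the same numeric kernels in
#' the same order, the federated objective trace equals the centralized one
#' on the same sites.
#'
#' @param sites List of `site_data` objects (the data custodians).
#' @param cfg A [hash_config()]; the broadcast seed fixes the shared
#'   initialization.
#' @param fed A [federation_config()] (defaults to `length(sites)` sites).
#' @return A `fed_hash_fit` with `method = "federated"` and the message
#'   audit log attached (see [audit_message_log()]).
#' @export
federated_fit <- function(sites, cfg = hash_config(), fed = NULL) {
  if (inherits(sites, "site_data")) sites <- list(sites)
  fed <- fed %||% federation_config(M = length(sites))
  if (fed$M != length(sites)) abort_config("`fed$M` must match the number of sites.")
  bits <- resolve_bits(cfg, sites[[1]])
  W <- init_W(sites[[1]], bits, cfg$seed)

  log <- new_message_log()
  attr(log, "allowed_dims") <- unique(c(
    vapply(names(W), function(k) paste(dim(W[[k]]), collapse = "x"), character(1)),
    vapply(names(W), function(k) paste(c(nrow(W[[k]]), nrow(W[[k]])), collapse = "x"),
           character(1))
  ))
  nodes <- lapply(sites, fed_site_node, cfg = cfg, log = log)
  for (nd in nodes) nd$init_Q(W)

  # Adapter: present the nodes to the shared driver as site handles, with the
  # version checks and logging of the message layer in between.
  handles <- lapply(nodes, function(nd) {
    list(
      set_W = function(W) nd$commit_W(W),
      w_stats = function(k, Wk) {
        b <- nd$w_stats(k, Wk, nd$version())
        list(gradient = b$gradient, hessian_block = b$hessian_block)
      },
      objective = function(k = NULL, Wk = NULL) nd$objective(k = k, Wk = Wk),
      q_update = function(k, Wk) nd$q_update(k, Wk)
    )
  })
  res <- bcd_drive(handles, W, cfg)
  res$handles <- lapply(nodes, `[[`, "handle")
  fit <- new_hash_fit(res, sites, bits, cfg, method = "federated")
  attr(fit, "message_log") <- log
  fit
}

#' Asynchronous update stub
#'
#' Streaming (asynchronous) model updates as new patients arrive are part of
#' the framework's design space but are deliberately not implemented: the
#' synchronous schedule is what makes the federated run exactly equal to the
#' centralized one, which anchors the correctness guarantees of this
#' package. Calling this stub is an explicit error.
#'
#' @param ... Ignored.
#' @export
async_update <- function(...) {
  rlang::abort("asynchronous updates are an interface stub; use federated_fit().",
               class = "fedsimhash_not_implemented")
}
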
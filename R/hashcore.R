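#' Configure the hash-learning optimizer
#'
#' Holds the hyper-parameters of the supervised hashing objective
#' \deqn{f(W,Q) = \sum_{i,k} \|W_k^\top P_k^i - S_L(Q_k^i)\|_F^2
#'   + \lambda \sum_{i,k} \mathrm{tr}(-S_L(Q_k^i)\, R^i\, S_L(Q_k^i)^\top)
#'   + \eta \sum_{i,k} \|Q_k^i\|_F^2}
#' and of the damped block-coordinate Newton solver. Defaults follow the
#' reference configuration: \eqn{\lambda = 0.5}, \eqn{\eta = 10^{-3}}, 2 bits
#' for demographics and 10 bits for every coded domain (52 bits total for the
#' six-domain setting).
#'
#' @param bits Named integer vector of code lengths `b_k` per domain, or
#'   `NULL` to derive the default from the site's domains (demographics 2,
#'   coded domains 10).
#' @param lambda Weight of the supervised pairwise loss (>= 0).
#' @param eta Weight of the Frobenius regularizer on `Q` (>= 0).
#' @param xi Smoothing constant of the surrogate sign function (> 0).
#'   Smaller values sharpen the sign approximation at the cost of steeper
#'   curvature.
#' @param max_iter Maximum number of block-coordinate sweeps.
#' @param rel_tol Relative objective-change tolerance for convergence; an
#'   infinite value returns the initialization unchanged.
#' @param hessian_ridge Ridge added to each Newton system, or `NULL` for the
#'   adaptive default `1e-6 * trace(H)/dim(H)` per block.
#' @param seed Seed for the Gaussian initialization of the `W_k`.
#' @return A `hash_config` object.
#' @export
hash_config <- function(bits = NULL, lambda = 0.5, eta = 1e-3, xi = 0.5,
                        max_iter = 100L, rel_tol = 1e-6,
                        hessian_ridge = NULL, seed = 1L) {
  if (!is.null(bits) && (is.null(names(bits)) || any(bits < 1))) {
    abort_config("`bits` must be a named vector of positive code lengths.")
  }
  if (lambda < 0) abort_config("`lambda` must be non-negative.")
  if (eta < 0) abort_config("`eta` must be non-negative.")
  if (!is.numeric(xi) || xi <= 0) abort_config("`xi` must be strictly positive.")
  structure(
    list(bits = if (is.null(bits)) NULL else vapply(bits, as.integer, integer(1)),
         lambda = lambda, eta = eta, xi = xi,
         max_iter = as.integer(max_iter), rel_tol = rel_tol,
         hessian_ridge = hessian_ridge, seed = as.integer(seed)),
    class = "hash_config"
  )
}

#' Default per-domain code lengths
#'
#' Demographics get 2 bits, every coded domain 10, mirroring the reference
#' configuration (2 + 5 x 10 = 52 bits for the six-domain setting).
#'
#' @param domains Character vector of domain tags (e.g. `names(site$P)`).
#' @return Named integer vector of bits per domain.
#' @export
default_bits <- function(domains) {
  b <- ifelse(domains == "demo", 2L, 10L)
  names(b) <- domains
  b
}

resolve_bits <- function(cfg, site) {
  if (!is.null(cfg$bits)) {
    missing <- setdiff(names(site$P), names(cfg$bits))
    if (length(missing)) abort_config(paste0("`bits` missing domain(s): ",
                                             paste(missing, collapse = ", ")))
    return(cfg$bits[names(site$P)])
  }
  default_bits(names(site$P))
}

#' Smooth surrogate of the sign function
#'
#' Elementwise map \eqn{q \mapsto q/\sqrt{q^2 + \xi}}: a differentiable
#' approximation of `sign(q)` with values in (-1, 1), exact sign agreement
#' wherever `q != 0`, and `S_L(0) = 0`. Shrinking `xi` toward 0 sharpens the
#' approximation toward the hard sign.
#'
#' @param Q Numeric vector or matrix.
#' @param xi Strictly positive smoothing constant.
#' @return Object of the same shape as `Q`.
#' @export
surrogate_sign <- function(Q, xi) {
  if (!is.numeric(xi) || length(xi) != 1 || xi <= 0) {
    abort_config("`xi` must be a strictly positive scalar.")
  }
  Q / sqrt(Q * Q + xi)
}

# First and second elementwise derivatives of the surrogate sign.
surrogate_d1 <- function(Q, xi) xi * (Q * Q + xi)^(-1.5)
surrogate_d2 <- function(Q, xi) -3 * xi * Q * (Q * Q + xi)^(-2.5)

# Objective contribution of one site (all domains).
site_objective <- function(W, Qs, site, cfg) {
  total <- 0
  for (k in names(W)) {
    S <- surrogate_sign(Qs[[k]], cfg$xi)
    E <- crossprod(W[[k]], site$P[[k]]) - S
    total <- total + sum(E * E) +
      cfg$lambda * (-sum((S %*% site$R) * S)) +
      cfg$eta * sum(Qs[[k]] * Qs[[k]])
  }
  total
}

#' Objective value of the hashing problem
#'
#' Evaluates the full objective (reconfiguration error + supervised pairwise
#' loss + Frobenius regularizer on `Q`) summed over sites and domains. The
#' value is additive over sites, which is what makes the federated
#' optimization possible.
#'
#' @param model A list of per-domain coefficient matrices `W_k`
#'   (`d_k x b_k`), or a fitted [fit_hash_model()] object.
#' @param aux List (one element per site) of named lists of `Q_k` matrices
#'   (`b_k x N_i`).
#' @param sites List of `site_data` objects.
#' @param cfg A [hash_config()].
#' @return Finite numeric scalar.
#' @export
objective_value <- function(model, aux, sites, cfg) {
  W <- if (inherits(model, "fed_hash_fit")) model$W else model
  check_problem_shapes(W, aux, sites)
  total <- 0
  for (i in seq_along(sites)) {
    total <- total + site_objective(W, aux[[i]], sites[[i]], cfg)
  }
  total
}

check_problem_shapes <- function(W, aux, sites) {
  for (i in seq_along(sites)) {
    for (k in names(W)) {
      P <- sites[[i]]$P[[k]]
      Q <- aux[[i]][[k]]
      if (is.null(P) || is.null(Q)) {
        abort_dim(sprintf("missing domain '%s' at site %d.", k, i))
      }
      if (nrow(P) != nrow(W[[k]]) || ncol(Q) != ncol(P) || nrow(Q) != ncol(W[[k]])) {
        abort_dim(sprintf("shape mismatch at site %d, domain '%s'.", i, k))
      }
    }
  }
  invisible(TRUE)
}

#' Analytic derivatives with respect to a hash-coefficient block
#'
#' Gradient and Hessian of the objective with respect to `W_k`, restricted to
#' one site's contribution (contributions are additive over sites). Only the
#' reconfiguration term depends on `W`, so the gradient is
#' `2 P (W_k' P - S_L(Q))'` and the Hessian is exactly block-diagonal across
#' the `b_k` columns of `W_k` with identical `d_k x d_k` blocks `2 P P'`.
#'
#' @param k Domain tag.
#' @param model Named list of `W_k` matrices.
#' @param aux Named list of that site's `Q_k` matrices.
#' @param site A `site_data`.
#' @param cfg A [hash_config()].
#' @return List with `gradient` (`d_k x b_k`), `hessian` (the full
#'   `(d_k b_k) x (d_k b_k)` matrix, column-major layout) and
#'   `hessian_block` (the shared `d_k x d_k` block).
#' @export
derivatives_W <- function(k, model, aux, site, cfg) {
  W <- if (inherits(model, "fed_hash_fit")) model$W else model
  d <- nrow(W[[k]]); b <- ncol(W[[k]])
  if (is.null(site$P[[k]]) || site$n == 0) {
    return(list(gradient = matrix(0, d, b),
                hessian = matrix(0, d * b, d * b),
                hessian_block = matrix(0, d, d)))
  }
  P <- site$P[[k]]
  S <- surrogate_sign(aux[[k]], cfg$xi)
  E <- crossprod(W[[k]], P) - S          # b x N residual
  grad <- 2 * (P %*% t(E))               # d x b
  block <- 2 * tcrossprod(P)             # d x d, same for every column
  if (any(!is.finite(grad)) || any(!is.finite(block))) {
    rlang::abort(sprintf("non-finite derivatives for W block '%s'.", k),
                 class = "fedsimhash_numeric_error")
  }
  list(gradient = grad,
       hessian = diag(b) %x% block,
       hessian_block = block)
}

# Gradient of the objective wrt one site's Q_k plus the exact per-row Hessian
# blocks. The Hessian of f in Q is block-diagonal across the b_k rows of Q:
# within row l it couples patients only through the relationship matrix R.
q_gradient_blocks <- function(Wk, Qk, site, k, cfg) {
  P <- site$P[[k]]
  A <- crossprod(Wk, P)
  S <- surrogate_sign(Qk, cfg$xi)
  S1 <- surrogate_d1(Qk, cfg$xi)
  S2 <- surrogate_d2(Qk, cfg$xi)
  SR <- S %*% site$R
  G <- 2 * (S - A) * S1 - 2 * cfg$lambda * SR * S1 + 2 * cfg$eta * Qk
  Dmat <- 2 * S1 * S1 + 2 * (S - A) * S2 - 2 * cfg$lambda * SR * S2 + 2 * cfg$eta
  blocks <- lapply(seq_len(nrow(Qk)), function(l) {
    H <- -2 * cfg$lambda * (tcrossprod(S1[l, ]) * site$R)
    diag(H) <- Dmat[l, ]   # R has zero diagonal, so no term is double counted
    H
  })
  list(gradient = G, blocks = blocks)
}

#' Analytic derivatives with respect to a site's relaxation block
#'
#' Gradient and Hessian of the objective with respect to `Q_k^i`. The
#' gradient chains through the surrogate sign; the Hessian is exactly
#' block-diagonal across the `b_k` rows of `Q` (patients within a row couple
#' through the relationship matrix `R^i`), and is returned both as those
#' row blocks and assembled into the full `(b_k N_i) x (b_k N_i)` matrix in
#' column-major (`vec(Q)`) layout.
#'
#' @param i Site index (bookkeeping only; pass that site's data in `site`).
#' @param k Domain tag.
#' @param model Named list of `W_k` matrices.
#' @param aux Named list of that site's `Q_k` matrices.
#' @param site A `site_data`.
#' @param cfg A [hash_config()].
#' @return List with `gradient` (`b_k x N_i`), `hessian`
#'   (`(b_k N_i) x (b_k N_i)`) and `row_blocks` (list of `N_i x N_i`
#'   matrices, one per code bit).
#' @export
derivatives_Q <- function(i, k, model, aux, site, cfg) {
  W <- if (inherits(model, "fed_hash_fit")) model$W else model
  gb <- q_gradient_blocks(W[[k]], aux[[k]], site, k, cfg)
  b <- nrow(aux[[k]]); n <- ncol(aux[[k]])
  H <- matrix(0, b * n, b * n)
  for (l in seq_len(b)) {
    idx <- (seq_len(n) - 1L) * b + l    # positions of row l in vec(Q)
    H[idx, idx] <- gb$blocks[[l]]
  }
  if (any(!is.finite(gb$gradient)) || any(!is.finite(H))) {
    rlang::abort(sprintf("non-finite derivatives for Q block site %d, domain '%s'.", i, k),
                 class = "fedsimhash_numeric_error")
  }
  list(gradient = gb$gradient, hessian = H, row_blocks = gb$blocks)
}

ridge_for <- function(H, cfg) {
  cfg$hessian_ridge %||% (1e-6 * sum(diag(H)) / nrow(H))
}

solve_ridged <- function(H, B, cfg, what) {
  r <- ridge_for(H, cfg)
  out <- tryCatch(solve(H + diag(r, nrow(H)), B),
                  error = function(e) NULL)
  if (is.null(out)) {
    rlang::abort(sprintf("singular Hessian (even after ridge) in %s.", what),
                 class = "fedsimhash_numeric_error")
  }
  out
}

MAX_HALVINGS <- 20L

# One damped Newton update of W_k given aggregated per-site statistics.
# `objective_fn(Wk)` must return the total objective with W_k replaced.
newton_W_step <- function(Wk, grad_sum, hess_block_sum, cfg, objective_fn, f_cur, k) {
  delta <- solve_ridged(hess_block_sum, grad_sum, cfg, sprintf("W block '%s'", k))
  step <- 1
  for (h in seq_len(MAX_HALVINGS)) {
    cand <- Wk - step * delta
    f_new <- objective_fn(cand)
    if (f_new <= f_cur + 1e-12 * max(1, abs(f_cur))) {
      return(list(W = cand, f = f_new, accepted = TRUE))
    }
    step <- step / 2
  }
  list(W = Wk, f = f_cur, accepted = FALSE)
}

# One damped Newton update of a site's Q_k. Only this site's objective moves,
# so the line search is local to the site. The trace term makes the row
# Hessians indefinite away from the optimum, so each block is lifted to its
# diagonally dominant (Gershgorin) majorant before solving: the step is then
# always a descent direction, and — because the modification acts row-wise on
# a block-diagonal structure — it is exactly decomposable across sites.
newton_Q_step <- function(Wk, Qk, site, k, cfg, f_site_fn, f_site_cur) {
  gb <- q_gradient_blocks(Wk, Qk, site, k, cfg)
  S1 <- surrogate_d1(Qk, cfg$xi)
  delta <- matrix(0, nrow(Qk), ncol(Qk))
  for (l in seq_len(nrow(Qk))) {
    H <- gb$blocks[[l]]
    r <- ridge_for(H, cfg)
    if (r <= 0) r <- .Machine$double.eps
    off_rho <- rowSums(abs(H)) - abs(diag(H))
    # Gauss-Newton floor: the always-positive curvature of the
    # reconfiguration and eta terms, so saturated entries (s' ~ 0) cannot
    # produce unbounded steps when the s'' terms cancel the diagonal
    gn_floor <- 2 * S1[l, ]^2 + 2 * cfg$eta
    diag(H) <- pmax(diag(H), gn_floor) + off_rho + r
    delta[l, ] <- tryCatch(solve(H, gb$gradient[l, ]), error = function(e) {
      rlang::abort(sprintf("singular Hessian (even after ridge) in Q block site %d, domain '%s', bit %d.",
                           site$site, k, l),
                   class = "fedsimhash_numeric_error")
    })
  }
  step <- 1
  for (h in seq_len(MAX_HALVINGS)) {
    cand <- Qk - step * delta
    f_new <- f_site_fn(cand)
    if (f_new <= f_site_cur + 1e-12 * max(1, abs(f_site_cur))) {
      return(list(Q = cand, f = f_new, accepted = TRUE))
    }
    step <- step / 2
  }
  list(Q = Qk, f = f_site_cur, accepted = FALSE)
}

# Direct (in-memory) site handle used by the centralized fit. A handle
# exposes closures over one site's private state:
#   $init_Q(W)        -- set Q_k = W_k' P_k
#   $set_W(W)         -- cache the committed broadcast model
#   $w_stats(k, Wk)   -- list(gradient d_k x b_k, hessian_block d_k x d_k)
#   $objective(k, Wk) -- local objective, optionally with W_k overridden
#   $q_update(k, Wk)  -- damped local Newton step on Q_k; returns the new
#                        local objective (a scalar)
# fit_hash_model wires handles directly to site_data; federated_fit wires
# the same handles through the message layer, so both execute identical
# arithmetic in identical order.
local_site_handle <- function(site, cfg) {
  env <- new.env(parent = emptyenv())
  env$Q <- NULL
  env$W_cache <- NULL
  obj_with <- function(k = NULL, Wk = NULL) {
    W <- env$W_cache
    if (!is.null(k)) W[[k]] <- Wk
    site_objective(W, env$Q, site, cfg)
  }
  list(
    init_Q = function(W) {
      env$Q <- lapply(names(W), function(k) crossprod(W[[k]], site$P[[k]]))
      names(env$Q) <- names(W)
      invisible(NULL)
    },
    set_W = function(W) { env$W_cache <- W; invisible(NULL) },
    w_stats = function(k, Wk) {
      S <- surrogate_sign(env$Q[[k]], cfg$xi)
      E <- crossprod(Wk, site$P[[k]]) - S
      list(gradient = 2 * (site$P[[k]] %*% t(E)),
           hessian_block = 2 * tcrossprod(site$P[[k]]))
    },
    objective = obj_with,
    q_update = function(k, Wk) {
      env$W_cache[[k]] <- Wk
      f_site_fn <- function(Qcand) {
        Qs <- env$Q
        Qs[[k]] <- Qcand
        site_objective(env$W_cache, Qs, site, cfg)
      }
      res <- newton_Q_step(Wk, env$Q[[k]], site, k, cfg, f_site_fn, obj_with())
      env$Q[[k]] <- res$Q
      res$f
    },
    state = env
  )
}

#' Fit the multi-domain hash model
#'
#' Damped block-coordinate Newton descent on the hashing objective: each
#' sweep updates every `W_k` (aggregating per-site gradient and Hessian
#' statistics, one `d_k x d_k` solve per domain) and then every site's
#' `Q_k^i` (per-bit `N_i x N_i` solves, local to the site). Every block step
#' is safeguarded by a step-halving line search so the objective trace is
#' non-increasing; iteration stops when the relative objective change drops
#' below `rel_tol` or after `max_iter` sweeps. With an infinite `rel_tol`
#' the seeded initialization (`W_k` small Gaussian, `Q_k^i = W_k' P_k^i`) is
#' returned unchanged.
#'
#' @param sites List of `site_data` objects (at least one, each ideally with
#'   both labels present — a warning is issued otherwise).
#' @param cfg A [hash_config()].
#' @return A `fed_hash_fit` object: fields `W` (per-domain coefficients),
#'   `aux` (per-site `Q` blocks), `trace` (objective per sweep, starting at
#'   the initialization), `iterations`, `converged`, `bits`, `config`.
#' @seealso [encode()], [objective_value()], [federated_fit()]
#' @export
fit_hash_model <- function(sites, cfg = hash_config()) {
  if (inherits(sites, "site_data")) sites <- list(sites)
  if (length(sites) < 1) abort_config("need at least one site.")
  for (s in sites) {
    if (s$n < 2 || length(unique(s$labels)) < 2) {
      rlang::warn(sprintf("site %d has fewer than 2 patients or a single class.", s$site))
    }
  }
  bits <- resolve_bits(cfg, sites[[1]])
  W <- init_W(sites[[1]], bits, cfg$seed)

  handles <- lapply(sites, local_site_handle, cfg = cfg)
  for (h in handles) h$init_Q(W)
  res <- bcd_drive(handles, W, cfg)
  new_hash_fit(res, sites, bits, cfg, method = "centralized")
}

# Block-coordinate descent schedule shared by the centralized and federated
# fits: per sweep, every W_k (aggregated damped Newton) then every site's
# Q_k (local damped Newton). Keeps each handle's committed-W cache current
# after every accepted W block.
bcd_drive <- function(handles, W, cfg) {
  domains <- names(W)
  for (h in handles) h$set_W(W)
  f_sites <- vapply(handles, function(h) h$objective(), numeric(1))
  f_cur <- sum(f_sites)
  trace <- f_cur
  iterations <- 0L
  converged <- FALSE

  if (is.finite(cfg$rel_tol)) {
    for (it in seq_len(cfg$max_iter)) {
      for (k in domains) {
        stats <- lapply(handles, function(h) h$w_stats(k, W[[k]]))
        grad_sum <- Reduce(`+`, lapply(stats, `[[`, "gradient"))
        hess_sum <- Reduce(`+`, lapply(stats, `[[`, "hessian_block"))
        obj_fn <- function(cand) {
          sum(vapply(handles, function(h) h$objective(k = k, Wk = cand), numeric(1)))
        }
        res <- newton_W_step(W[[k]], grad_sum, hess_sum, cfg, obj_fn, f_cur, k)
        W[[k]] <- res$W
        f_cur <- res$f
        for (h in handles) h$set_W(W)
      }
      for (i in seq_along(handles)) {
        for (k in domains) {
          f_sites[i] <- handles[[i]]$q_update(k, W[[k]])
        }
      }
      f_new <- sum(f_sites)
      iterations <- it
      rel <- abs(trace[length(trace)] - f_new) /
        max(abs(trace[length(trace)]), .Machine$double.eps)
      trace <- c(trace, f_new)
      f_cur <- f_new
      if (rel < cfg$rel_tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(W = W, trace = trace, iterations = iterations, converged = converged,
       handles = handles)
}

init_W <- function(site, bits, seed) {
  with_seed_(seed, {
    W <- lapply(names(site$P), function(k) {
      d <- nrow(site$P[[k]])
      matrix(stats::rnorm(d * bits[[k]], sd = 0.1), d, bits[[k]],
             dimnames = list(rownames(site$P[[k]]), NULL))
    })
    names(W) <- names(site$P)
    W
  })
}

new_hash_fit <- function(res, sites, bits, cfg, method) {
  aux <- lapply(res$handles, function(h) h$state$Q)
  structure(
    list(W = res$W, aux = aux, trace = res$trace,
         iterations = res$iterations, converged = res$converged,
         bits = bits, config = cfg, method = method,
         n_sites = length(sites),
         n_patients = sum(vapply(sites, `[[`, integer(1), "n")),
         domains = names(res$W)),
    class = "fed_hash_fit"
  )
}

#' @export
print.fed_hash_fit <- function(x, ...) {
  cat(sprintf("<fed_hash_fit> %s fit: %d site(s), %d patients, %d domains (%d bits)\n",
              x$method, x$n_sites, x$n_patients, length(x$domains), sum(x$bits)))
  cat(sprintf("  objective %.6g -> %.6g in %d sweep(s)%s\n",
              x$trace[1], x$trace[length(x$trace)], x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Hash-encode patients with a fitted model
#'
#' Applies the learned hash functions `f_k(P) = sign(W_k' P_k)` elementwise;
#' by convention `sign(0) = +1`. Accepts a fitted model and either a
#' `site_data` or a named list of per-domain feature matrices.
#'
#' @param model A `fed_hash_fit` (or bare named list of `W_k`).
#' @param data A `site_data` or named list of `d_k x N` matrices.
#' @return A `hash_codes` object: named list `codes` of `b_k x N` matrices
#'   with entries in -1/+1, plus `pids` and `bits`.
#' @export
encode <- function(model, data) {
  W <- if (inherits(model, "fed_hash_fit")) model$W
       else if (is.list(model$W %||% NULL) && !is.null(model$header)) model$W
       else model
  P <- if (inherits(data, "site_data")) data$P else data
  pids <- if (inherits(data, "site_data")) data$pids else colnames(P[[1]])
  codes <- lapply(names(W), function(k) {
    if (is.null(P[[k]]) || nrow(P[[k]]) != nrow(W[[k]])) {
      abort_dim(sprintf("feature matrix for domain '%s' missing or misshaped.", k))
    }
    proj <- crossprod(W[[k]], P[[k]])
    H <- ifelse(proj >= 0, 1, -1)  # sign(0) = +1
    storage.mode(H) <- "double"
    H
  })
  names(codes) <- names(W)
  structure(
    list(codes = codes,
         pids = pids %||% paste0("p", seq_len(ncol(codes[[1]]))),
         bits = vapply(codes, nrow, integer(1))),
    class = "hash_codes"
  )
}

#' Hard-threshold a fitted model's relaxation blocks into hash codes
#'
#' Returns `H_k^i = sign(Q_k^i)` for one site of a fitted model (the codes
#' the optimization itself relaxed), as opposed to [encode()], which applies
#' the learned projection to (possibly new) feature matrices.
#'
#' @param fit A `fed_hash_fit`.
#' @param site_index Which site's `Q` blocks to threshold.
#' @param pids Optional patient ids.
#' @return A `hash_codes` object.
#' @export
codes_from_aux <- function(fit, site_index = 1L, pids = NULL) {
  Qs <- fit$aux[[site_index]]
  codes <- lapply(Qs, function(Q) {
    H <- ifelse(Q >= 0, 1, -1)
    storage.mode(H) <- "double"
    H
  })
  structure(
    list(codes = codes,
         pids = pids %||% paste0("p", seq_len(ncol(codes[[1]]))),
         bits = vapply(codes, nrow, integer(1))),
    class = "hash_codes"
  )
}

# Stack the per-domain code blocks into one (sum b_k) x N matrix.
concat_codes <- function(hc) {
  do.call(rbind, unname(hc$codes))
}

#' @export
print.hash_codes <- function(x, ...) {
  cat(sprintf("<hash_codes> %d patients, %d domains, %d bits total\n",
              length(x$pids), length(x$codes), sum(x$bits)))
  invisible(x)
}
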
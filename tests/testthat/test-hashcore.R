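test_that("surrogate sign matches its closed form and limits", {
  expect_equal(surrogate_sign(0, 1), 0)
  expect_equal(surrogate_sign(3, 16), 0.6)  # 3/sqrt(25)
  # monotone approach to sign(q) as xi shrinks
  vals <- vapply(c(1, 1e-1, 1e-2, 1e-4), function(xi) surrogate_sign(1, xi), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(abs(vals[4] - 1), 1e-4)
  # range and odd symmetry
  q <- seq(-5, 5, by = 0.25)
  s <- surrogate_sign(q, 0.5)
  expect_true(all(s > -1 & s < 1))
  expect_equal(s, -rev(s))
  expect_equal(sign(s[q != 0]), sign(q[q != 0]))
  expect_error(surrogate_sign(1, 0), class = "fedsimhash_config_error")
  expect_error(surrogate_sign(1, -2), class = "fedsimhash_config_error")
})

test_that("objective matches an independent scalar expansion on a toy instance", {
  # d = 1, b = 1, N = 2: every matrix is a scalar or a 2-vector
  P <- matrix(c(2, -1), 1, 2)
  site <- new_site_data(list(dom = P), c(1L, 0L))
  cfg <- hash_config(bits = c(dom = 1L), lambda = 0.5, eta = 1e-3, xi = 0.5)
  W <- list(dom = matrix(0.7, 1, 1))
  Q <- list(dom = matrix(c(0.3, -0.2), 1, 2))

  s <- function(q) q / sqrt(q^2 + 0.5)
  # reconfiguration: sum over patients of (w*p - s(q))^2
  t1 <- (0.7 * 2 - s(0.3))^2 + (0.7 * -1 - s(-0.2))^2
  # supervised: -lambda * sum_{u,v} s(q_u) r_uv s(q_v), r offdiag = -1 here
  t2 <- 0.5 * -(s(0.3) * -1 * s(-0.2) + s(-0.2) * -1 * s(0.3))
  t3 <- 1e-3 * (0.3^2 + 0.2^2)
  expect_equal(objective_value(W, list(Q), list(site), cfg), t1 + t2 + t3,
               tolerance = 1e-12)

  # zero case: all three terms vanish
  W0 <- list(dom = matrix(0, 1, 1)); Q0 <- list(dom = matrix(0, 1, 2))
  expect_equal(objective_value(W0, list(Q0), list(site), cfg), 0)
})

test_that("objective is additive over sites", {
  s1 <- toy_site(101, d = 3, n = 4, site = 1)
  s2 <- toy_site(102, d = 3, n = 6, site = 2)
  cfg <- hash_config(bits = c(dom = 2L))
  set.seed(1)
  W <- list(dom = matrix(rnorm(6), 3, 2))
  Q1 <- list(dom = matrix(rnorm(8), 2, 4))
  Q2 <- list(dom = matrix(rnorm(12), 2, 6))
  f_both <- objective_value(W, list(Q1, Q2), list(s1, s2), cfg)
  f_1 <- objective_value(W, list(Q1), list(s1), cfg)
  f_2 <- objective_value(W, list(Q2), list(s2), cfg)
  expect_equal(f_both, f_1 + f_2, tolerance = 1e-12)

  expect_error(objective_value(W, list(Q1), list(s2), cfg),
               class = "fedsimhash_dim_error")
})

test_that("analytic W and Q derivatives match finite differences", {
  for (seed in 1:20) {
    set.seed(seed)
    d <- sample(2:5, 1); b <- sample(1:3, 1); n <- sample(3:6, 1)
    site <- toy_site(seed + 1000, d = d, n = n)
    cfg <- hash_config(bits = c(dom = b), lambda = 0.5, eta = 1e-3,
                       xi = if (seed %% 2) 0.5 else 1e-2)
    W <- list(dom = matrix(rnorm(d * b), d, b))
    Q <- list(dom = matrix(rnorm(b * n), b, n))

    fW <- function(wv) {
      objective_value(list(dom = matrix(wv, d, b)), list(Q), list(site), cfg)
    }
    fQ <- function(qv) {
      objective_value(W, list(list(dom = matrix(qv, b, n))), list(site), cfg)
    }
    rel_err <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))

    dW <- derivatives_W("dom", W, Q, site, cfg)
    gW_fd <- fd_gradient(fW, as.vector(W$dom))
    expect_lt(rel_err(as.vector(dW$gradient), gW_fd), 1e-5)
    gWfun <- function(wv) {
      as.vector(derivatives_W("dom", list(dom = matrix(wv, d, b)), Q, site, cfg)$gradient)
    }
    HW_fd <- fd_jacobian(gWfun, as.vector(W$dom))
    expect_lt(rel_err(dW$hessian, HW_fd), 1e-5)
    expect_true(isSymmetric(dW$hessian, tol = 1e-10))
    expect_true(min(eigen(dW$hessian, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)

    dQ <- derivatives_Q(1, "dom", W, Q, site, cfg)
    gQ_fd <- fd_gradient(fQ, as.vector(Q$dom))
    expect_lt(rel_err(as.vector(dQ$gradient), gQ_fd), 1e-5)
    gQfun <- function(qv) {
      as.vector(derivatives_Q(1, "dom", W, list(dom = matrix(qv, b, n)), site, cfg)$gradient)
    }
    HQ_fd <- fd_jacobian(gQfun, as.vector(Q$dom))
    expect_lt(rel_err(dQ$hessian, HQ_fd), 1e-5)
    expect_true(isSymmetric(dQ$hessian, tol = 1e-8))
  }
})

test_that("W gradient vanishes at the least-squares solution when lambda = 0", {
  set.seed(3)
  d <- 4; b <- 2; n <- 6
  site <- toy_site(33, d = d, n = n)
  cfg <- hash_config(bits = c(dom = b), lambda = 0, eta = 0)
  Q <- list(dom = matrix(rnorm(b * n), b, n))
  S <- surrogate_sign(Q$dom, cfg$xi)
  # normal equations solved independently: W* = (P P')^{-1} P S'
  P <- site$P$dom
  Wstar <- solve(tcrossprod(P), P %*% t(S))
  dW <- derivatives_W("dom", list(dom = Wstar), Q, site, cfg)
  expect_lt(max(abs(dW$gradient)), 1e-9)
})

test_that("Q gradient is stationary at zero and linear in lambda", {
  set.seed(4)
  d <- 3; b <- 2; n <- 5
  site <- toy_site(44, d = d, n = n)
  W0 <- list(dom = matrix(0, d, b))
  Q0 <- list(dom = matrix(0, b, n))
  cfg0 <- hash_config(bits = c(dom = b), lambda = 0)
  expect_equal(derivatives_Q(1, "dom", W0, Q0, site, cfg0)$gradient,
               matrix(0, b, n))

  W <- list(dom = matrix(rnorm(d * b), d, b))
  Q <- list(dom = matrix(rnorm(b * n), b, n))
  g_at <- function(lam) {
    cfg <- hash_config(bits = c(dom = b), lambda = lam)
    derivatives_Q(1, "dom", W, Q, site, cfg)$gradient
  }
  sup1 <- g_at(1) - g_at(0)
  sup2 <- g_at(2) - g_at(0)
  expect_equal(sup2, 2 * sup1, tolerance = 1e-10)
})

test_that("empty sites contribute zero derivatives", {
  site <- toy_site(55, d = 3, n = 4)
  empty <- fedsimhash:::site_subset(site, integer(0))
  cfg <- hash_config(bits = c(dom = 2L))
  W <- list(dom = matrix(1, 3, 2))
  dW <- derivatives_W("dom", W, list(dom = matrix(0, 2, 0)), empty, cfg)
  expect_equal(dW$gradient, matrix(0, 3, 2))
  expect_equal(dW$hessian_block, matrix(0, 3, 3))
})

test_that("fitting monotonically decreases the objective and is reproducible", {
  co <- toy_cohort(n = 40L, seed = 31)
  sites <- toy_sites_from_cohort(co, M = 2L)
  cfg <- hash_config(max_iter = 6, seed = 17)
  fit <- suppressWarnings(fit_hash_model(sites, cfg))
  expect_true(all(diff(fit$trace) <= 1e-8 * pmax(1, abs(fit$trace[-length(fit$trace)]))))
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])

  fit2 <- suppressWarnings(fit_hash_model(sites, cfg))
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$trace, fit2$trace)
})

test_that("infinite rel_tol returns the initialization after zero sweeps", {
  sites <- list(toy_site(61, d = 3, n = 5))
  cfg <- hash_config(bits = c(dom = 2L), rel_tol = Inf, seed = 9)
  fit <- suppressWarnings(fit_hash_model(sites, cfg))
  expect_equal(fit$iterations, 0L)
  expect_length(fit$trace, 1L)
  W0 <- fedsimhash:::init_W(sites[[1]], c(dom = 2L), 9L)
  expect_equal(fit$W, W0)
  expect_equal(fit$aux[[1]]$dom, crossprod(W0$dom, sites[[1]]$P$dom))
})

test_that("multi-site fit equals the pooled fit when cross-site relations are masked", {
  s1 <- toy_site2(301, d = c(3L, 2L), n = 8, site = 1)
  s2 <- toy_site2(302, d = c(3L, 2L), n = 10, site = 2)
  cfg <- hash_config(bits = c(a = 2L, b = 2L), max_iter = 8, seed = 23,
                     hessian_ridge = 1e-8)
  fit_split <- suppressWarnings(fit_hash_model(list(s1, s2), cfg))
  pooled <- fedsimhash:::pool_sites(list(s1, s2), cross_site_relations = FALSE)
  fit_pool <- suppressWarnings(fit_hash_model(list(pooled), cfg))
  expect_length(fit_split$trace, length(fit_pool$trace))
  rel <- abs(fit_split$trace - fit_pool$trace) / pmax(abs(fit_pool$trace), 1e-12)
  expect_true(all(rel <= 1e-8))
})

test_that("encoding thresholds projections with sign(0) = +1", {
  set.seed(6)
  site <- toy_site2(66, n = 4)
  W <- list(a = matrix(rnorm(6), 3, 2), b = matrix(rnorm(4), 2, 2))
  hc <- encode(W, site)
  # brute-force oracle: compare every projection entry against zero
  for (k in names(W)) {
    proj <- t(W[[k]]) %*% site$P[[k]]
    expect_equal(hc$codes[[k]], ifelse(proj >= 0, 1, -1))
    expect_true(all(hc$codes[[k]] %in% c(-1, 1)))
  }
  # negating W negates all nonzero codes
  Wn <- lapply(W, function(w) -w)
  hcn <- encode(Wn, site)
  for (k in names(W)) {
    nz <- abs(t(W[[k]]) %*% site$P[[k]]) > 1e-12
    expect_equal(hcn$codes[[k]][nz], -hc$codes[[k]][nz])
  }
  # exact zero maps to +1
  Wz <- list(a = matrix(0, 3, 1), b = matrix(0, 2, 1))
  hz <- encode(Wz, site)
  expect_true(all(hz$codes$a == 1))
  # sign(S_L(q)) == sign(q) wherever q != 0
  q <- matrix(c(-2, -0.1, 0.3, 5), 2, 2)
  expect_equal(sign(surrogate_sign(q, 0.5)), sign(q))
})

test_that("codes from the relaxation blocks agree with hard thresholding", {
  sites <- list(toy_site(71, d = 4, n = 6))
  cfg <- hash_config(bits = c(dom = 3L), max_iter = 3, seed = 2)
  fit <- suppressWarnings(fit_hash_model(sites, cfg))
  hc <- codes_from_aux(fit, 1)
  expect_equal(hc$codes$dom, ifelse(fit$aux[[1]]$dom >= 0, 1, -1))
})

test_that("tidy, glance and autoplot summarise a fit", {
  sites <- list(toy_site(81, d = 4, n = 6))
  cfg <- hash_config(bits = c(dom = 2L), max_iter = 2, seed = 5)
  fit <- suppressWarnings(fit_hash_model(sites, cfg))
  td <- tidy(fit)
  expect_equal(td$domain, "dom")
  expect_equal(unname(td$d), 4L)
  expect_equal(unname(td$bits), 2L)
  gl <- glance(fit)
  expect_equal(gl$iterations, fit$iterations)
  expect_equal(gl$objective_final, fit$trace[length(fit$trace)])
  expect_s3_class(autoplot(fit), "ggplot")
})
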
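test_that("a single-site bundle equals the centralized derivative", {
  site <- toy_site(201, d = 4, n = 5)
  cfg <- hash_config(bits = c(dom = 2L), seed = 3)
  set.seed(3)
  W <- list(dom = matrix(rnorm(8), 4, 2))
  Q <- list(dom = crossprod(W$dom, site$P$dom))
  bundle <- local_W_statistics(site, W, Q, "dom", cfg)
  dW <- derivatives_W("dom", W, Q, site, cfg)
  expect_equal(bundle$gradient, dW$gradient, tolerance = 1e-12)
  expect_equal(bundle$hessian_block, dW$hessian_block, tolerance = 1e-12)
})

test_that("site bundles sum to the pooled-data derivative", {
  s1 <- toy_site(202, d = 3, n = 4, site = 1)
  s2 <- toy_site(203, d = 3, n = 7, site = 2)
  cfg <- hash_config(bits = c(dom = 2L))
  set.seed(5)
  W <- list(dom = matrix(rnorm(6), 3, 2))
  Q1 <- list(dom = matrix(rnorm(8), 2, 4))
  Q2 <- list(dom = matrix(rnorm(14), 2, 7))
  b1 <- local_W_statistics(s1, W, Q1, "dom", cfg)
  b2 <- local_W_statistics(s2, W, Q2, "dom", cfg)

  pooled <- fedsimhash:::pool_sites(list(s1, s2), cross_site_relations = FALSE)
  Qp <- list(dom = cbind(Q1$dom, Q2$dom))
  dW <- derivatives_W("dom", W, Qp, pooled, cfg)
  rel <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))
  expect_lt(rel(b1$gradient + b2$gradient, dW$gradient), 1e-10)
  expect_lt(rel(b1$hessian_block + b2$hessian_block, dW$hessian_block), 1e-10)
})

test_that("the bundle schema rejects patient-level payloads", {
  site <- toy_site(204, d = 3, n = 6)
  bundle <- list(type = "bundle", site = 1L, k = "dom", version = 1L,
                 gradient = matrix(0, 3, 2), hessian_block = matrix(0, 3, 3),
                 n = 6)
  expect_silent(fedsimhash:::validate_bundle(bundle, 3L, 2L))

  leaky <- bundle
  leaky$P <- site$P$dom   # an N_i-column matrix must never ride along
  expect_error(fedsimhash:::validate_bundle(leaky, 3L, 2L),
               class = "fedsimhash_schema_error")

  wide <- bundle
  wide$gradient <- matrix(0, 3, 6)
  expect_error(fedsimhash:::validate_bundle(wide, 3L, 2L),
               class = "fedsimhash_schema_error")
})

test_that("aggregation sums before inversion and leaves stationary points fixed", {
  site <- toy_site(205, d = 3, n = 5)
  cfg <- hash_config(bits = c(dom = 2L))
  W <- list(dom = matrix(0.5, 3, 2))
  # all-zero gradients: W must not move
  bundles <- list(list(type = "bundle", site = 1L, k = "dom", version = 1L,
                       gradient = matrix(0, 3, 2),
                       hessian_block = diag(3), n = 5))
  Wnew <- aggregate_and_update_W(bundles, W, "dom", cfg,
                                 objective_fn = function(cand) 0, f_current = 0)
  expect_equal(Wnew, W$dom)

  # three identical sites == one site with tripled data weight
  set.seed(7)
  Wr <- list(dom = matrix(rnorm(6), 3, 2))
  Q <- list(dom = crossprod(Wr$dom, site$P$dom) + 0.1)
  b <- local_W_statistics(site, Wr, Q, "dom", cfg)
  obj3 <- function(cand) {
    3 * fedsimhash:::site_objective(list(dom = cand), Q, site, cfg)
  }
  f3 <- obj3(Wr$dom)
  W3 <- aggregate_and_update_W(list(b, b, b), Wr, "dom", cfg, obj3, f3)
  trip <- list(type = "bundle", site = 1L, k = "dom", version = 1L,
               gradient = 3 * b$gradient, hessian_block = 3 * b$hessian_block,
               n = 15)
  W1 <- aggregate_and_update_W(list(trip), Wr, "dom", cfg, obj3, f3)
  expect_equal(W3, W1, tolerance = 1e-12)
})

test_that("mismatched bundles raise protocol errors", {
  cfg <- hash_config(bits = c(dom = 2L))
  W <- list(dom = matrix(0, 3, 2))
  mk <- function(k, v) list(type = "bundle", site = 1L, k = k, version = v,
                            gradient = matrix(0, 3, 2),
                            hessian_block = diag(3), n = 2)
  expect_error(
    aggregate_and_update_W(list(mk("dom", 1L), mk("other", 1L)), W, "dom", cfg,
                           function(cand) 0, 0),
    class = "fedsimhash_protocol_error"
  )
  expect_error(
    aggregate_and_update_W(list(mk("dom", 1L), mk("dom", 2L)), W, "dom", cfg,
                           function(cand) 0, 0),
    class = "fedsimhash_protocol_error"
  )
})

test_that("a stale model version at a site is a protocol error", {
  site <- toy_site(206, d = 3, n = 5)
  cfg <- hash_config(bits = c(dom = 2L), seed = 1)
  log <- fedsimhash:::new_message_log()
  node <- fedsimhash:::fed_site_node(site, cfg, log)
  W <- fedsimhash:::init_W(site, c(dom = 2L), 1L)
  node$init_Q(W)
  expect_error(node$w_stats("dom", W$dom, model_version = 99L),
               class = "fedsimhash_protocol_error")
})

test_that("federated fit with one site is identical to the centralized fit", {
  sites <- list(toy_site(207, d = 4, n = 8))
  cfg <- hash_config(bits = c(dom = 3L), max_iter = 4, seed = 13)
  f_cen <- suppressWarnings(fit_hash_model(sites, cfg))
  f_fed <- suppressWarnings(federated_fit(sites, cfg))
  expect_identical(f_cen$trace, f_fed$trace)
  expect_identical(f_cen$W, f_fed$W)
  expect_identical(f_cen$aux, f_fed$aux)
})

test_that("federated fit equals the centralized fit on the same multi-site data", {
  co <- toy_cohort(n = 36L, seed = 51)
  for (M in c(2L, 3L)) {
    sites <- toy_sites_from_cohort(co, M = M)
    cfg <- hash_config(max_iter = 3, seed = 29)
    f_cen <- suppressWarnings(fit_hash_model(sites, cfg))
    f_fed <- suppressWarnings(federated_fit(sites, cfg))
    rel <- abs(f_cen$trace - f_fed$trace) / pmax(abs(f_cen$trace), 1e-12)
    expect_true(all(rel <= 1e-6))
    expect_equal(f_cen$W, f_fed$W, tolerance = 1e-10)
  }
})

test_that("the message audit finds only aggregate payloads", {
  co <- toy_cohort(n = 24L, seed = 61)
  sites <- toy_sites_from_cohort(co, M = 2L)
  cfg <- hash_config(max_iter = 2, seed = 31)
  fit <- suppressWarnings(federated_fit(sites, cfg))
  audit <- audit_message_log(fit)
  expect_gt(nrow(audit), 0)
  expect_true(all(audit$type %in% c("model", "bundle", "objective", "ack")))
  # no payload dimension matches a site's patient count
  ns <- vapply(sites, `[[`, integer(1), "n")
  d_bk <- unlist(lapply(fit$W, dim))
  forbidden <- setdiff(ns, d_bk)  # any N_i that is not also a d_k or b_k
  for (dims in strsplit(audit$dims, ";")) {
    for (dd in dims) {
      sizes <- as.integer(strsplit(dd, "x")[[1]])
      expect_true(all(!(sizes %in% forbidden)))
    }
  }
})

test_that("asynchronous updates are an explicit stub", {
  expect_error(async_update(), class = "fedsimhash_not_implemented")
})
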
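# Small in-code fixtures shared across test files.

# Random single-domain toy site (Gaussian features, both labels present).
toy_site <- function(seed, d = 3L, n = 4L, site = 1L) {
  set.seed(seed)
  P <- matrix(rnorm(d * n), d, n)
  labels <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  new_site_data(list(dom = P), labels, site = site)
}

# Random two-domain toy site.
toy_site2 <- function(seed, d = c(3L, 2L), n = 5L, site = 1L) {
  set.seed(seed)
  P <- list(a = matrix(rnorm(d[1] * n), d[1], n),
            b = matrix(rnorm(d[2] * n), d[2], n))
  labels <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  new_site_data(P, labels, site = site)
}

# Central finite-difference gradient of the objective wrt one W or Q block.
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# Central finite-difference Jacobian of a vector-valued gradient function,
# used to validate analytic Hessians.
fd_jacobian <- function(g, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (g(x + e) - g(x - e)) / (2 * eps)
  }, numeric(length(g(x))))
}

# A separable-signal cohort small enough for per-test fitting.
toy_cohort <- function(n = 60L, seed = 5L, signal = 2.5) {
  generate_cohort(cohort_config(
    n, domains = c(l = 12L, p = 12L, d = 10L, c = 8L, s = 8L),
    positive_fraction = 0.5, signal_strength = signal,
    events_per_patient = c(15L, 40L), seed = seed
  ))
}

# Assemble a cohort into M equal sites.
toy_sites_from_cohort <- function(cohort, M = 2L, seed = 9L,
                                  target_code = "d_000") {
  n_site <- nrow(cohort) %/% M
  parts <- partition_sites(cohort, site_partition_plan(M, rep(n_site, M)), seed = seed)
  spec <- build_domain_vocabulary(cohort, exclude = target_code)
  lapply(seq_len(M), function(i) {
    assemble_site(parts[[i]], spec, target_code = target_code, site = i)
  })
}

# All +-1 codes of a given length, as columns.
all_codes <- function(bits) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), bits)))
  t(g)
}
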
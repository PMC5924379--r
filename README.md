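# fedsimhash

Federated patient similarity learning with multi-domain binary hash codes.

Hospitals that cannot share patient records still want to answer the
question *"who, across all of our institutions, looks like this patient?"*.
`fedsimhash` implements a privacy-preserving answer in three layers:

1. **Representation.** Each patient is described by K heterogeneous feature
   domains (demographics, lab results `l`, prescriptions `p`, diagnoses `d`,
   conditions `c`, symptoms `s`). Coded events are embedded as time-decayed
   one-hot vectors — an event `t` steps before the end of the history
   contributes `exp(-γt)` to its code's entry — giving per-domain matrices
   `P_k ∈ R^{d_k×N}` per site.

2. **Learning to hash, federatedly.** One linear hash function per domain,
   `f_k(p) = sign(W_k' p) ∈ {−1,+1}^{b_k}`, is learned jointly across M
   sites by minimising

   ```
   f(W,Q) = Σ_{i,k} ‖W_k' P_k^i − S_L(Q_k^i)‖_F²
          + λ Σ_{i,k} tr(−S_L(Q_k^i) R^i S_L(Q_k^i)')
          + η Σ_{i,k} ‖Q_k^i‖_F²,     S_L(q) = q/√(q²+ξ),
   ```

   where `R^i` encodes which patient pairs share a label (+1) or not (−1),
   and the smooth surrogate `S_L` stands in for the non-differentiable sign.
   The solver is block-coordinate descent with damped Newton steps: each
   `W_k` update needs only per-site *aggregates* (a `d_k×b_k` gradient and a
   `d_k×d_k` Hessian block per site), so sites never transmit patient-level
   data; each `Q_k^i` update stays entirely inside its site. The federated
   run is provably identical to running the same optimizer with all data in
   one place.

3. **Search, optionally encrypted.** Similarity between two patients is the
   mean of per-domain normalized code inner products
   (`s_k = h_u'h_v / b_k ∈ [−1,1]`, overall `s = mean_k s_k`), equivalent to
   Hamming distance on the concatenated code (`s = 1 − 2d_H/b`). κ-NN voting
   over Hamming distances predicts disease incidence. When even codes must
   not leave a site, a Paillier (additively homomorphic) protocol lets a
   responder compute one encrypted inner product from an encrypted query;
   the querier decrypts exactly the Hamming distance and nothing else.

Default configuration mirrors the reference setting: λ = 0.5, η = 10⁻³,
γ = 0.01, b = 2 bits for demographics and 10 per coded domain (52 total),
M = 3 sites of 125 patients, κ ∈ {1, 3, 9}, 5-fold cross-validation.

Since real multi-site EHR extracts are access-restricted, the package ships
a synthetic cohort generator (`generate_cohort()`) that plants a tunable
label signal into multi-admission event sequences, so every claim above is
testable end to end.

## Worked example

```r
library(fedsimhash)

# a 3-site synthetic cohort with strong planted signal
cohort <- generate_cohort(cohort_config(150, signal_strength = 3, seed = 1))
parts  <- partition_sites(cohort, site_partition_plan(3, rep(50L, 3)), seed = 2)
spec   <- build_domain_vocabulary(cohort, exclude = "d_000")
sites  <- lapply(1:3, function(i)
  assemble_site(parts[[i]], spec, target_code = "d_000", site = i))

# federated fit: sites exchange only d_k x b_k / d_k x d_k aggregates
fit <- federated_fit(sites, hash_config(max_iter = 20, rel_tol = 1e-5, seed = 3))
fit
#> <fed_hash_fit> federated fit: 3 site(s), 150 patients, 6 domains (52 bits)
#>   objective -645.346 -> -186025 in 12 sweep(s) (converged)

glance(fit)[, c("total_bits", "iterations", "objective_final")]
#> # A tibble: 1 × 3
#>   total_bits iterations objective_final
#>        <int>      <int>           <dbl>
#> 1         52         12        -186025.

# encode one site and search another site's codes
codes2 <- encode(fit, sites[[2]])
res <- knn_predict(encode(fit, sites[[1]]), codes2, sites[[2]]$labels, kappa = 3)
res[1, ]
#> # A tibble: 1 × 4
#>   query_id kappa  prob neighbors
#>   <chr>    <int> <dbl> <list>
#> 1 pt00001      3     0 <tibble [3 × 3]>

# the same distance, computed without revealing either code
key <- paillier_keygen(512)
u <- fedsimhash:::concat_codes(encode(fit, sites[[1]]))[, 1]
v <- fedsimhash:::concat_codes(codes2)[, 1]
recover_hamming(respond_distance(encrypt_code(u, key$pub), v, key$pub), key, 52)
#> [1] 44
hamming_distance(u, v)
#> [1] 44
```

The `prob` column is the fraction of the κ nearest references carrying the
positive label — here all three neighbours of the first query patient are
negative, so its predicted incidence probability is 0 (this patient is
indeed a negative). The encrypted and plaintext Hamming distances agree
exactly.

The cross-validated system comparison (open = pooled data, closed =
per-site, federated = this package) runs through `run_experiment()` /
`imbalance_experiment()`; `summarise_metrics()` and `autoplot()` tabulate
and plot the per-repeat AUC / F1 / sensitivity / specificity.

A thin command-line interface wrapping these functions ships at
`inst/cli/fedsimhash` (subcommands `generate`, `assemble`, `fit`, `encode`,
`search`, `secure-search`, `evaluate`).

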
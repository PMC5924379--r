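---
title: "Methods: federated multi-domain patient hashing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated multi-domain patient hashing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedsimhash)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
establish.

## The model

Each patient is characterised by $K$ feature domains. Domain $k$ of site
$i$ is a matrix $P_k^i \in \mathbb{R}^{d_k \times N_i}$ of time-decayed
one-hot features; site $i$ also holds a pairwise relationship matrix $R^i$
with $r^i_{uv} = +1$ when patients $u,v$ share the outcome label, $-1$ when
they differ, and $0$ on the diagonal. The goal is one linear hash function
per domain, $f_k(p) = \mathrm{sign}(W_k^\top p) \in \{-1,+1\}^{b_k}$, shared
by all sites, such that Hamming distances between codes reflect
label-driven similarity.

Because the sign function blocks gradient methods, each site carries
relaxation blocks $Q_k^i \in \mathbb{R}^{b_k \times N_i}$ whose signs become
the site's codes, and the smooth surrogate
$S_L(q) = q/\sqrt{q^2 + \xi}$ replaces the sign inside the objective

$$
f(W, Q) \;=\; \sum_{i,k} \bigl\lVert W_k^\top P_k^i - S_L(Q_k^i)
\bigr\rVert_F^2
\;+\; \lambda \sum_{i,k} \operatorname{tr}\!\bigl(-S_L(Q_k^i)\, R^i\,
S_L(Q_k^i)^\top\bigr)
\;+\; \eta \sum_{i,k} \lVert Q_k^i \rVert_F^2 .
$$

The first term ties the relaxation to a *linear* projection of the
features, which is what lets new patients be encoded; the second pulls
same-label pairs toward identical code directions and different-label
pairs apart; the third makes the $Q$ blocks well-posed. Everything is
additive over sites, which is the entire basis of the federated
computation.

### Assumptions

* Sites share a common feature dictionary per domain (the package builds it
  with `build_domain_vocabulary()` and applies it everywhere; codes outside
  the dictionary are dropped with a warning at transform time).
* Supervision is a binary label; the relationship matrix is its complete
  pairwise encoding within a site. Cross-site pairs are *never* observed by
  the optimizer — that is a structural property of the federation, not an
  approximation.
* Events are equally spaced in time; the decay index $t$ counts event steps
  backwards from the most recent retained event ($t=0$ at the end, weight
  1). The printed form $e^{-\gamma t}$ fixes only the shape; the origin and
  orientation follow from the requirement that recent events weigh most.
  Decay is applied over the flattened admission-ordered event stream.

## Feature construction

`slice_at_first_target()` implements incidence prediction: for a patient in
whom the target diagnosis occurs, the admission containing its first
occurrence is cut out and only strictly earlier admissions are kept (label
1); others keep their whole history (label 0). A positive whose target
appears in the very first admission has no usable history and is excluded
(with a warning) by `assemble_site()`. The target code itself is excluded
from the vocabulary, so the feature space never contains the outcome.
Demographics (gender one-hot, age as-is) are static and undecayed. Lab
values are not quantized into critical-low…critical-high bins and no
temporal-pattern dictionary is built; those are documented options of the
representation, not implemented here.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `lambda` | 0.5 | ≥ 0 | weight of the supervised pairwise term |
| `eta` | 1e-3 | ≥ 0 | Frobenius regularizer on `Q` |
| `xi` | 0.5 | > 0 | surrogate smoothing; smaller = sharper sign |
| `gamma` | 0.01 | per event step | feature time decay |
| `bits` | demo 2, coded 10 | ≥ 1 | code length per domain (52 total at K = 6) |
| `max_iter`, `rel_tol` | 100, 1e-6 | — | block-sweep budget and stopping rule |
| `hessian_ridge` | 1e-6·trace/dim | ≥ 0 | Newton system regularization |

`lambda`, `eta` and the bit allocation follow the reference configuration.
`xi` is not stated anywhere authoritative; 0.5 keeps surrogate gradients
informative over the data scales produced by the feature pipeline, the
tests also exercise 0.01, and the value is exposed. Convergence constants
are ours; the stopping rule is relative objective change.

## The optimizer, and its numerics

Blocks are visited in a fixed order per sweep: $W_1 \dots W_K$, then every
site's $Q_k^i$. All updates are damped Newton steps with a step-halving
line search (at most 20 halvings) that enforces a non-increasing objective.

* **$W_k$ updates.** Only the reconfiguration term involves $W$, so the
  objective is exactly quadratic in $W_k$ and separable over its columns:
  the gradient is $2\sum_i P_k^i (W_k^\top P_k^i - S_L(Q_k^i))^\top$ and the
  Hessian is block-diagonal with the identical $d_k \times d_k$ block
  $2\sum_i P_k^i P_k^{i\top}$ per column. The per-column treatment is an
  exactness-preserving structure choice, not an approximation, and the
  update touches nothing larger than $d_k \times d_k$ aggregates.
* **$Q_k^i$ updates.** The Hessian in $Q$ is exactly block-diagonal across
  the $b_k$ rows of $Q$ (bits do not interact); within a row, patients
  couple through $R^i$. The exact row Hessian is indefinite away from the
  optimum (the trace term is nonconvex), and a raw Newton direction is then
  frequently an *ascent* direction. Each row block is therefore lifted to a
  strengthened diagonally dominant modification before solving: the
  diagonal becomes $\max(\text{diag}, 2 s'(q)^2 + 2\eta)$ plus the
  off-diagonal absolute row sum plus the ridge. This guarantees a positive
  definite system (Gershgorin), hence a descent direction with bounded
  steps — the Gauss–Newton floor $2s'^2 + 2\eta$ prevents the near-null
  systems that otherwise appear where the surrogate saturates. Because the
  modification is row-local and $R$ is block-diagonal across sites, it
  preserves exact site-decomposability of the step.
* **Degenerate inputs.** `rel_tol = Inf` returns the seeded initialization
  unchanged after zero sweeps. Empty sites contribute zero statistics.
  Singular systems that survive the ridge abort with the offending block
  named. `sign(0) = +1` everywhere, by documented convention.
* **Initialization.** $W_k$ entries are i.i.d. Gaussian (sd 0.1) from the
  configuration seed; $Q_k^i = W_k^\top P_k^i$, consistent with the
  reconfiguration term. Identical seeds give identical fits.

## Federation

`federated_fit()` runs the same schedule as `fit_hash_model()` with every
site behind an in-process message boundary. For a $W_k$ update each site
emits one bundle — a $d_k \times b_k$ gradient, one $d_k \times d_k$
Hessian block, a patient count — which the coordinator sums *before*
inversion (the mathematically exact reading of the aggregated Newton step);
line-search queries are answered by scalar objective contributions; $Q$
updates never leave their site. The message schema rejects any
patient-indexed payload, and `audit_message_log()` re-checks the recorded
traffic after the fact. Because both paths share the same numeric kernels
in the same order, the federated objective trace is *identical* to the
centralized fit of the same sites — this is asserted in the tests rather
than assumed.

Two distinct comparators deserve care. Fitting the M sites centrally (the
coordinator holds all data but the objective keeps per-site $R^i$) is
exactly equivalent to the federation. *Concatenating* the sites into one
and rebuilding $R$ from pooled labels is a different problem — it adds
cross-site supervised pairs the federation never sees; that stronger
comparator is precisely the **open system** of the evaluation harness. The
algebraic decomposability identity (split vs concatenated with cross-site
relations masked to 0) holds exactly for well-conditioned instances and is
tested on Gaussian toys with a fixed ridge; with the adaptive trace-scaled
ridge, or on badly scaled features (raw age), pooled and split line
searches can take different partial steps, so the identity is a property
of the mathematics, not of every floating-point trajectory.

Only the synchronous schedule exists; asynchronous streaming updates are a
stub (`async_update()`) because asynchrony would break the
federated-equals-centralized equivalence that anchors the tests. The
derivative bundles themselves are exchanged in the clear, as in the
framework this implements: its security argument is that they are
non-invertible aggregates, and no differential privacy or secure
aggregation is layered on top. Transport is an in-process queue; real
networking, retries and a PKI are out of scope.

## Similarity search and the encrypted protocol

Per-domain similarity is the normalized inner product
$s_k = h_u^\top h_v / b_k \in [-1,1]$; the overall score is the mean over
domains. The per-domain normalization is required for the advertised
$(-1,1)$ bound of the overall score — an unnormalized domain sum would be
bounded by $\sum b_k$ instead — and the package implements the normalized
reading; the acceptance enumeration (all $2^6 \times 2^6$ pairs at $K=2$,
$b_k=3$) confirms the bounds are attained. Ranking for κ-NN uses Hamming
distance over the concatenated code, equivalent to a $b_k$-weighted
similarity; the per-domain breakdown is reported alongside so a match can
be *explained* (similar demographics vs similar diagnoses). Distance ties
are broken by reference id, ascending, making results order-invariant.
The κ-NN vote probability is thresholded at 0.5 for F1 / sensitivity /
specificity; the threshold is exposed because no authoritative value
exists.

The encrypted path realises the per-pair protocol: the querier encrypts
its $\pm 1$ code bitwise under its Paillier public key; the responder —
holding only the public key, enforced by the interface — multiplies
ciphertexts (or their modular inverses at its $-1$ positions), obtaining
one re-randomized encryption of the inner product $u^\top v$, and returns
exactly that single ciphertext, never per-bit results; the querier
decrypts and converts $d_H = (b - u^\top v)/2$, with a parity and range
check guarding corrupted responses. Key generation uses OpenSSL's RSA
prime search for moduli ≥ 512 bits and an internal Miller–Rabin search
below that; the 2048-bit default reflects modern practice, while the
128-bit floor is supported for protocol testing only and is far below a
defensible deployment size. Big-integer arithmetic is unsigned, so
plaintexts are residues mod $n$ with a centered lift at decryption.
Halving happens after decryption, at the querier. The querier ranks
decrypted distances; encrypted *ranking* is deliberately not attempted.

## The synthetic cohort

The generator emulates the structure of a multi-admission EHR extract:
1–5 admissions per patient, 20–60 coded events spread over them (each
admission non-empty), six domains with desk-scale vocabularies, static
demographics. Disease is planted by inserting the target diagnosis into
exactly one admission of each positive — never the first, so a
pre-incidence history always exists — and by re-weighting a designated
signal subset (the first 20% of each coded vocabulary) by
$e^{\text{signal\_strength}}$ in positives. `signal_strength = 0` makes
positives and negatives exchangeable up to the target code itself, which
the tests verify by a two-proportion comparison.

What the generator does **not** emulate: realistic marginal code
frequencies or co-occurrence, inter-event time irregularity, site-specific
coding practice, label noise, or any real dimensionality (true extracts
have $d_k$ in the hundreds to thousands). Passing tests therefore
establish the *mechanics* — derivatives, decomposability, protocol
exactness, metric plumbing — and show signal recovery under favourable,
known-signal conditions; they do not predict performance on real clinical
data, and no real-data figure is reproduced here.

## Evaluation design and problem sizes

The harness reproduces the experimental design at desk scale: stratified
5-fold cross-validation (stratification keeps both classes in every fold
at these sizes; fold assignment is byte-identical across systems for a
given seed, so comparisons are paired), repeated CV, κ ∈ {1, 3, 9}, AUC by
rank statistic plus thresholded F1 / sensitivity / specificity. The open
system pools everything including cross-site supervision; the closed
system fits and evaluates each site alone, averaging metrics across sites
unweighted; the federated system fits across the boundary and searches all
sites' codes. Uni-hash concatenates features into one function with
$b = \sum_k b_k = 52$ bits. Raw baselines rank unscaled concatenated
features by Euclidean, cityblock, cosine or correlation distance —
deliberately unscaled, because the failure of naive concatenation under
heterogeneous value ranges (age vs decayed counts) is part of what the
comparison illustrates.

The signal-recovery study in the acceptance tests runs 3 sites × 50
patients, 5 folds, one repetition per seed, 10 seeds, 20 optimization
sweeps at `rel_tol = 1e-5`, with `signal_strength = 3`: the point where
the *best* raw baseline (cosine, κ = 9) itself reaches mean AUC ≥ 0.95,
i.e. the planted signal is unambiguously recoverable from raw features. At
that separability the federated multi-hash clears mean AUC 0.9 with a
clear margin over the closed system, while open and federated saturate and
coincide to within per-seed noise; the open-versus-federated leg of the
expected open ≥ federated ≥ closed ordering is therefore asserted with a
0.01 noise tolerance, and the federated-versus-closed leg strictly. The
imbalance experiment re-partitions one cohort at 10%/30%/50% per-site
positive rates against a balanced partition with shared seeds, so
composition is the only difference between arms.

## Known limitations

* Hash quality on real EHR data is unvalidated here (restricted data); all
  empirical statements are about the synthetic conditions above.
* The supervised term's weight effectively grows with $N^2$ while the
  reconfiguration term grows with $N$, so pooling sites shifts the balance
  between the two; λ may warrant rescaling for very different cohort
  sizes.
* Newton solves cost $O(d_k^3)$ per domain and $O(N_i^3)$ per code bit per
  site and sweep; desk-scale cohorts fit in seconds, but thousands of
  patients per site would require the structure-exploiting or first-order
  variants discussed in the field.
* The encrypted protocol reveals the exact Hamming distance to the
  querier (by design) and the code length to the responder; collusion
  resistance beyond the stated trust model is not attempted.
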
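# Additively homomorphic (Paillier) encrypted Hamming-distance protocol.
#
# The querying site encrypts its +-1 code bitwise under its public key; the
# responding site — holding only the public key — multiplies the ciphertexts
# (or their modular inverses, for its -1 bits) to obtain a single encryption
# of the inner product u'v, re-randomized, and returns that one ciphertext.
# The querier decrypts and converts: d_H = (b - u'v)/2. The responder never
# sees the query code, the querier never sees the responder's code, and only
# the Hamming distance is revealed.
#
# Arithmetic is on openssl's unsigned big integers; plaintexts live in Z_n
# with a centered lift at decryption (values above n/2 are negative).

bn <- function(x) openssl::bignum(x)

bn_num <- function(x) as.numeric(as.character(x))

# Uniform bignum in [0, n): rejection-free modular reduction of an oversized
# random value (bias is negligible at 8 surplus bytes).
bn_rand_mod <- function(n, bytes) {
  bn(openssl::rand_bytes(bytes + 8L)) %% n
}

# Miller-Rabin primality test on bignums (error prob <= 4^-rounds).
bn_is_prime <- function(n, rounds = 30L) {
  two <- bn(2L)
  if (n < bn(4L)) return(n >= two)
  if ((n %% two) == bn(0L)) return(FALSE)
  nm1 <- n - bn(1L)
  d <- nm1
  s <- 0L
  while ((d %% two) == bn(0L)) {
    d <- d %/% two
    s <- s + 1L
  }
  for (r in seq_len(rounds)) {
    a <- (bn_rand_mod(n - bn(3L), 32L)) + two   # a in [2, n-2]
    x <- openssl::bignum_mod_exp(a, d, n)
    if (x == bn(1L) || x == nm1) next
    ok <- FALSE
    for (j in seq_len(s - 1L)) {
      x <- openssl::bignum_mod_exp(x, two, n)
      if (x == nm1) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

SMALL_PRIMES <- c(3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59,
                  61, 67, 71, 73, 79, 83, 89, 97)

# Random prime of exactly `bits` bits (top two bits and low bit forced so the
# product of two such primes has full modulus length).
bn_gen_prime <- function(bits) {
  nbytes <- as.integer(ceiling(bits / 8))
  repeat {
    raw <- openssl::rand_bytes(nbytes)
    raw[1] <- as.raw(bitwOr(as.integer(raw[1]), 0xC0L))
    raw[nbytes] <- as.raw(bitwOr(as.integer(raw[nbytes]), 0x01L))
    cand <- bn(raw)
    divisible <- any(vapply(SMALL_PRIMES, function(p) {
      (cand %% bn(p)) == bn(0L)
    }, logical(1)))
    if (divisible) next
    if (bn_is_prime(cand)) return(cand)
  }
}

#' Generate a Paillier key pair
#'
#' Additively homomorphic encryption over `Z_n`:
#' `Dec(Enc(a) (*) Enc(b)) = a + b` (ciphertext multiplication) and
#' `Dec(Enc(a)^c) = a * c` for a plaintext scalar `c`. Moduli of at least
#' 512 bits are generated through OpenSSL's RSA prime search; smaller
#' test-scale moduli (down to the configurable 128-bit floor, which is far
#' below modern Paillier practice and supported for protocol testing only)
#' use an internal Miller–Rabin search. Encryption is randomized, so equal
#' plaintexts yield distinct ciphertexts.
#'
#' @param bits Modulus length in bits (>= 128; default 2048 for real use).
#' @return A `paillier_keypair` with fields `pub` (a `paillier_pubkey`:
#'   modulus `n`, `n2`, `bits`, `fingerprint`) and the private decryption
#'   parameters. Pass only `$pub` to responder code.
#' @export
paillier_keygen <- function(bits = 2048L) {
  if (!is.numeric(bits) || bits < 128) {
    abort_config("`bits` must be at least 128.")
  }
  bits <- as.integer(bits)
  if (bits >= 512) {
    key <- openssl::rsa_keygen(bits)
    dat <- as.list(key)$data
    p <- dat$p
    q <- dat$q
  } else {
    p <- bn_gen_prime(bits %/% 2L)
    repeat {
      q <- bn_gen_prime(bits %/% 2L)
      if (!(p == q)) break
    }
  }
  n <- p * q
  n2 <- n * n
  phi <- (p - bn(1L)) * (q - bn(1L))
  mu <- openssl::bignum_mod_inv(phi %% n, n)
  pub <- structure(
    list(n = n, n2 = n2, bits = bits,
         fingerprint = paste(as.character(openssl::sha256(charToRaw(as.character(n)))),
                             collapse = "")),
    class = "paillier_pubkey"
  )
  structure(list(pub = pub, phi = phi, mu = mu), class = "paillier_keypair")
}

#' Paillier primitives
#'
#' `paillier_encrypt()` encrypts a small signed integer (`|m|` up to `n/2`)
#' under the public key with fresh randomness; `paillier_decrypt()` inverts
#' it with the private key, applying a centered lift so small negative sums
#' decode correctly. `ct_add()` adds two ciphertexts homomorphically and
#' `ct_scalar_mult()` multiplies a ciphertext's plaintext by a signed
#' integer scalar.
#'
#' @param m Integer plaintext.
#' @param pub A `paillier_pubkey`.
#' @param key A `paillier_keypair`.
#' @param ct,ct1,ct2 Ciphertexts (bignums).
#' @param s Signed integer scalar.
#' @return Ciphertext (bignum) or decrypted numeric.
#' @keywords internal
#' @export
paillier_encrypt <- function(m, pub) {
  n <- pub$n
  mm <- if (m >= 0) bn(m) %% n else n - (bn(-m) %% n)
  r <- bn_rand_mod(n, pub$bits %/% 8L)
  if (r == bn(0L)) r <- bn(1L)
  gm <- (bn(1L) + mm * n) %% pub$n2          # (n+1)^m mod n^2
  (gm * openssl::bignum_mod_exp(r, n, pub$n2)) %% pub$n2
}

#' @rdname paillier_encrypt
#' @export
paillier_decrypt <- function(ct, key) {
  pub <- key$pub
  u <- openssl::bignum_mod_exp(ct, key$phi, pub$n2)
  L <- (u - bn(1L)) %/% pub$n
  m <- (L * key$mu) %% pub$n
  half <- pub$n %/% bn(2L)
  if (m > half) -bn_num(pub$n - m) else bn_num(m)
}

#' @rdname paillier_encrypt
#' @export
ct_add <- function(ct1, ct2, pub) (ct1 * ct2) %% pub$n2

#' @rdname paillier_encrypt
#' @export
ct_scalar_mult <- function(ct, s, pub) {
  if (s >= 0) {
    openssl::bignum_mod_exp(ct, bn(s), pub$n2)
  } else {
    openssl::bignum_mod_inv(openssl::bignum_mod_exp(ct, bn(-s), pub$n2), pub$n2)
  }
}

#' Encrypt a hash code for a similarity query
#'
#' One ciphertext per bit of the concatenated -1/+1 code; the message object
#' retains no plaintext bits. Encryption is randomized, so re-encrypting the
#' same code yields different ciphertexts.
#'
#' @param code -1/+1 vector (a patient's concatenated hash code).
#' @param pub A `paillier_pubkey`.
#' @return An `encrypted_code`: list with `cts` (ciphertext list), `b`,
#'   `fingerprint`.
#' @export
encrypt_code <- function(code, pub) {
  check_code(code)
  structure(
    list(cts = lapply(code, paillier_encrypt, pub = pub),
         b = length(code),
         fingerprint = pub$fingerprint),
    class = "encrypted_code"
  )
}

#' Respond to an encrypted similarity query
#'
#' The responding site combines the encrypted query bits with its own
#' plaintext code using only the public key: multiplying the ciphertexts of
#' its +1 positions and the modular inverses of those at its -1 positions
#' yields a single encryption of the inner product `u'v`, which is
#' re-randomized before transmission. Exactly one ciphertext is returned —
#' never per-bit results — so the querier can recover the Hamming distance
#' and nothing else.
#'
#' @param enc_query An [encrypt_code()] message.
#' @param local_code The responder's own -1/+1 code.
#' @param pub The shared `paillier_pubkey` (the responder never holds the
#'   private key).
#' @return A single ciphertext (bignum) encrypting `u'v`.
#' @export
respond_distance <- function(enc_query, local_code, pub) {
  check_code(local_code)
  if (!identical(enc_query$fingerprint, pub$fingerprint)) {
    rlang::abort("query encrypted under a different public key.",
                 class = "fedsimhash_protocol_error")
  }
  if (length(local_code) != enc_query$b) abort_dim("code lengths differ.")
  # start from a fresh encryption of zero: re-randomizes the response
  acc <- paillier_encrypt(0L, pub)
  for (t in seq_along(local_code)) {
    term <- if (local_code[t] > 0) enc_query$cts[[t]] else
      openssl::bignum_mod_inv(enc_query$cts[[t]], pub$n2)
    acc <- (acc * term) %% pub$n2
  }
  acc
}

#' Recover the Hamming distance from an encrypted response
#'
#' Decrypts the inner product `u'v` and converts it:
#' `d_H = (b - u'v) / 2`. Responses whose decryption falls outside
#' `[-b, b]` or has the wrong parity are rejected as corrupted.
#'
#' @param response Ciphertext from [respond_distance()].
#' @param key The querier's `paillier_keypair`.
#' @param b Code length in bits.
#' @return Integer Hamming distance in `[0, b]`.
#' @export
recover_hamming <- function(response, key, b) {
  ip <- paillier_decrypt(response, key)
  if (abs(ip) > b || ((b - ip) %% 2) != 0) {
    rlang::abort("decrypted value is not a valid inner product for this code length.",
                 class = "fedsimhash_integrity_error")
  }
  as.integer((b - ip) / 2)
}

#' @export
print.paillier_keypair <- function(x, ...) {
  cat(sprintf("<paillier_keypair> %d-bit modulus (fingerprint %s...)\n",
              x$pub$bits, substr(x$pub$fingerprint, 1, 12)))
  invisible(x)
}

#' @export
print.paillier_pubkey <- function(x, ...) {
  cat(sprintf("<paillier_pubkey> %d-bit modulus (fingerprint %s...)\n",
              x$bits, substr(x$fingerprint, 1, 12)))
  invisible(x)
}
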
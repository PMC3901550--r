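# Independent oracles for the two-sex recursion, kept deliberately separate
# from the package internals: genotype-frequency bookkeeping for one
# generation, long fixed-point iteration, and Brent root-finding on the naive
# per-sex expression.

# One generation by explicit genotype bookkeeping (scalar q).
oracle_step <- function(q, s, t, u) {
  geno <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  w1 <- geno * c(1, 1 - s, 1 - 2 * s)
  w2 <- geno * c(1, 1 - t, 1 - 2 * t)
  q1 <- (w1[2] / 2 + w1[3]) / sum(w1)
  q2 <- (w2[2] / 2 + w2[3]) / sum(w2)
  qbar <- (q1 + q2) / 2
  qbar + u * (1 - qbar)
}

# Naive per-sex post-selection frequencies, vectorised; used for brute-force
# iteration and as the function handed to uniroot.
oracle_delta <- function(q, s, t, u) {
  q1 <- q * (1 - s * (1 + q)) / (1 - 2 * s * q)
  q2 <- q * (1 - t * (1 + q)) / (1 - 2 * t * q)
  qbar <- (q1 + q2) / 2
  qbar + u * (1 - qbar) - q
}

# Brute-force fixed-point iteration from the fate of a new recurrent
# mutation (q0 = u), vectorised across loci.
oracle_iterate <- function(s, t, u, n_iter = 1e6, q0 = u) {
  q <- rep_len(q0, length(s))
  for (i in seq_len(n_iter)) {
    q <- pmin(pmax(q + oracle_delta(q, s, t, u), 0), 1)
  }
  q
}

# Brent root of the naive delta-q on (0, 1), with boundary handling mirroring
# the deterministic dynamics: no interior sign change means the attractor
# from q0 = u is a boundary.
oracle_root <- function(s, t, u, lo = 1e-14, hi = 1 - 1e-9) {
  f_lo <- oracle_delta(lo, s, t, u)
  f_hi <- oracle_delta(hi, s, t, u)
  if (sign(f_lo) * sign(f_hi) < 0) {
    uniroot(function(q) oracle_delta(q, s, t, u), c(lo, hi),
            tol = 1e-14)$root
  } else if (f_lo > 0) 1 else 0
}

# The 35-point (s, t) grid used for solver-vs-oracle agreement checks.
oracle_grid <- function() {
  expand.grid(
    s = c(0.001, 0.005, 0.01, 0.02, 0.05),
    t = c(-0.01, -0.005, -0.001, 0.001, 0.005, 0.01, 0.02)
  )
}
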
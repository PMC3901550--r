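#' Expected per-generation change in disease-allele frequency
#'
#' One generation of the deterministic two-sex life cycle: Hardy-Weinberg
#' genotypes, sex-specific viability selection with additive fitnesses
#' (`1, 1 - s, 1 - 2s` in sex 1; `1, 1 - t, 1 - 2t` in sex 2), equal-weight
#' averaging of post-selection allele frequencies across the sexes (allele
#' frequencies are assumed equal between sexes), then one-way mutation
#' wild-type to disease at rate `u`.
#'
#' Post-selection frequency within a sex is `q(1 - s(1 + q))/(1 - 2sq)`;
#' `delta_q()` evaluates the algebraically identical cancellation-free form
#' `(1 - u)(-q(1 - q)/2)(s/(1 - 2sq) + t/(1 - 2tq)) + u(1 - q)`, which keeps
#' full relative precision at both boundaries.
#'
#' @param q Current disease-allele frequency in `[0, 1]`.
#' @param s,t,u Locus parameters (see [loci_tbl()]). All arguments recycle.
#' @return `delta_q()` returns the expected change `q' - q`;
#'   `step_recursion()` returns the next-generation frequency `q'`, clamped
#'   to `[0, 1]`.
#' @examples
#' step_recursion(0, s = 0.01, t = 0.01, u = 1e-6) # just the mutational input
#' delta_q(1e-4, s = 0.01, t = 0.01, u = 1e-6)     # ~0 at equilibrium
#' @export
delta_q <- function(q, s, t, u) {
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  wbar1 <- 1 - 2 * s * q
  wbar2 <- 1 - 2 * t * q
  if (any(wbar1 <= 0) || any(wbar2 <= 0)) {
    abort("mean fitness <= 0 in one sex: locus invariants 2|s|, 2|t| < 1 violated")
  }
  (1 - u) * (-q * (1 - q) / 2) * (s / wbar1 + t / wbar2) + u * (1 - q)
}

#' @rdname delta_q
#' @export
step_recursion <- function(q, s, t, u) {
  pmin(pmax(q + delta_q(q, s, t, u), 0), 1)
}

#' Weak-selection closed form for the equilibrium frequency
#'
#' To second order in the selection coefficients the equilibrium condition
#' `delta_q = 0` reads `u = q[(s + t)/2 + q(s^2 + t^2)]`, a quadratic in `q`
#' whose admissible root is returned (clamped to `[0, 1]`). It reduces to
#' `2u/(s + t)` at mutation-selection balance and to
#' `-(s + t)/(2(s^2 + t^2))` under balancing selection with `u` negligible,
#' and it is the fast path used on large mutation samples.
#'
#' @inheritParams delta_q
#' @return Approximate equilibrium frequencies in `[0, 1]`.
#' @examples
#' q_eq_weak(0.01, 0.01, 1e-6)
#' @export
q_eq_weak <- function(s, t, u) {
  a <- s + t
  b <- s^2 + t^2
  q <- ifelse(b > 0,
    (-a / 2 + sqrt(a^2 / 4 + 4 * u * b)) / (2 * b),
    ifelse(a > 0, 2 * u / a, 1)
  )
  pmin(pmax(q, 0), 1)
}

## Vectorised bracketed bisection for the stable root of delta_q on
## [lo, 1 - lo]. Loci whose delta_q does not change sign on the bracket sit at
## a boundary: q = 1 when mutation/selection pushes up everywhere (one-way
## mutation with s + t <~ 2u, or net selection favouring the disease allele),
## q = 0 when u = 0 and selection is purifying.
solve_q_bisect <- function(s, t, u, maxit = 100L) {
  n <- length(s)
  lo <- rep(1e-15, n)
  ## keep mean fitness 1 - 2sq (and 1 - 2tq) positive: coefficients above
  ## 1/2 -- possible in unbounded gamma tails -- cap the admissible q range,
  ## and their equilibria sit far below the singularity
  hi <- pmin(1 - 1e-15,
             ifelse(s >= 0.5, 0.4999 / s, 1),
             ifelse(t >= 0.5, 0.4999 / t, 1))
  flo <- delta_q(lo, s, t, u)
  fhi <- delta_q(hi, s, t, u)
  interior <- sign(flo) * sign(fhi) < 0
  q <- ifelse(flo > 0 | (flo == 0 & fhi > 0), 1, 0)
  if (any(interior)) {
    li <- lo[interior]; hi2 <- hi[interior]
    si <- s[interior]; ti <- t[interior]; ui <- u[interior]
    sl <- sign(flo[interior])
    for (it in seq_len(maxit)) {
      mid <- (li + hi2) / 2
      fm <- delta_q(mid, si, ti, ui)
      up <- sign(fm) == sl & fm != 0
      li <- ifelse(up, mid, li)
      hi2 <- ifelse(up, hi2, mid)
      if (max(hi2 - li) < 4 * .Machine$double.eps) break
    }
    q[interior] <- (li + hi2) / 2
  }
  q
}

#' Solve per-locus equilibrium allele frequencies
#'
#' For each locus, locates the stable root of `delta_q = 0` on `[0, 1]` that
#' the deterministic recursion reaches from the fate of a recurrent new
#' mutation (`q0 = u`), and annotates the locus with its selection regime,
#' heterozygosity and per-sex variance contributions.
#'
#' Two methods are provided. `"exact"` (default) brackets and bisects the
#' full recursion's `delta_q` to machine precision; `"weak"` uses the
#' second-order closed form [q_eq_weak()], which agrees with the exact root
#' to about one part in 1e6 across the weak-selection regime and is the fast
#' path for million-locus samples.
#'
#' Near-neutral loci (`s + t` of order `u` or below) have no interior root
#' under deterministic one-way mutation: recurrent mutation fixes the disease
#' allele, and they are reported with `q_eq` at (or near) 1 and flagged
#' `near_neutral`. Such loci carry essentially no variance weight because
#' `q(1 - q) -> 0`.
#'
#' @param loci A data frame with columns `s`, `t` and (optionally) `u`, e.g.
#'   from [loci_tbl()] or [sample_dfe()].
#' @param u Mutation rate used when `loci` has no `u` column.
#' @param tol Maximum accepted `|delta_q|` at the reported root
#'   (default `1e-12`).
#' @param method `"exact"` or `"weak"`.
#' @return The input tibble with columns `q_eq`, `regime`, `H`, `v1`, `v2`,
#'   `residual` and `near_neutral` appended.
#' @examples
#' loci_tbl(s = 0.01, t = c(0.01, -0.0102), u = 1e-6) |> solve_equilibrium()
#' @export
solve_equilibrium <- function(loci, u = NULL, tol = 1e-12,
                              method = c("exact", "weak")) {
  method <- match.arg(method)
  loci <- tibble::as_tibble(loci)
  if (!"u" %in% names(loci)) {
    if (is.null(u)) abort("supply a mutation rate: `u` column or argument")
    loci$u <- u
  }
  validate_loci(loci)
  if (!is.numeric(tol) || tol <= 0) abort("tol must be positive")

  q <- switch(method,
    exact = solve_q_bisect(loci$s, loci$t, loci$u),
    weak = q_eq_weak(loci$s, loci$t, loci$u)
  )
  res <- abs(delta_q(q, loci$s, loci$t, loci$u))
  if (method == "exact" && any(res > tol)) {
    abort(paste0("equilibrium residual above tolerance at ",
                 sum(res > tol), " loci; max |delta_q| = ",
                 format(max(res))))
  }
  vc <- variance_contribution(loci$s, loci$t, q)
  loci$q_eq <- q
  loci$regime <- classify_regime(loci$s, loci$t)
  loci$H <- heterozygosity(q)
  loci$v1 <- vc$v1
  loci$v2 <- vc$v2
  loci$residual <- res
  ## flagged when one-way mutation overwhelms net purifying selection
  loci$near_neutral <- loci$s + loci$t > 0 & q > 0.99 &
    loci$regime == "mutation_selection_balance"
  loci
}

#' Equilibrium diversity across a grid of selection asymmetries
#'
#' Sweeps the asymmetry ratio `t/s` at fixed `s` values and solves each locus
#' exactly, tabulating equilibrium frequency and heterozygosity: the standard
#' picture of how sex-differential and sexually antagonistic selection
#' inflate diversity as `t/s` decreases.
#'
#' @param s Vector of sex-1 selection coefficients.
#' @param t_over_s Grid of asymmetry ratios.
#' @param u Mutation rate.
#' @param method Passed to [solve_equilibrium()].
#' @return A tibble with one row per `(s, t_over_s)` and columns `t`, `q_eq`,
#'   `regime`, `H`.
#' @examples
#' equilibrium_sweep(s = 0.01, t_over_s = seq(-0.5, 2, 0.5))
#' @export
equilibrium_sweep <- function(s = c(0.005, 0.01, 0.02),
                              t_over_s = seq(-0.5, 2, by = 0.01),
                              u = 1e-6, method = "exact") {
  if (length(s) == 0 || length(t_over_s) == 0) abort("empty sweep grid")
  grid <- tidyr::expand_grid(s = s, t_over_s = t_over_s)
  grid$t <- grid$s * grid$t_over_s
  solved <- solve_equilibrium(
    tibble::tibble(s = grid$s, t = grid$t, u = u),
    method = method
  )
  dplyr::bind_cols(
    grid[c("s", "t_over_s", "t")],
    solved[c("q_eq", "regime", "H")]
  )
}
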
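#' Partition sex-1 genetic variance by between-sex asymmetry class
#'
#' Solves every sampled locus to equilibrium, weights it by its contribution
#' to additive genetic variance in sex 1, `w = q_eq (1 - q_eq) s^2` (constant
#' factors cancel in the reported fractions), and partitions total variance
#' across classes of the asymmetry ratio `t/s`. Bins are half-open intervals
#' `(a, b]`: a ratio exactly on an edge belongs to the lower bin.
#'
#' The default path solves equilibria with the weak-selection closed form
#' ([q_eq_weak()]); set `verify_n > 0` to re-solve a random subsample with
#' the exact bisection solver and record the largest resulting shift in any
#' reported fraction (`consistency`, in percentage points).
#'
#' @param sample A tibble with columns `s`, `t` (e.g. from [sample_dfe()]).
#' @param u Mutation rate shared by all loci.
#' @param edges Increasing `t/s` breakpoints tiling the support; the first
#'   and last may be 0 and `Inf`.
#' @param thresholds Upper bounds for cumulative variance summaries.
#' @param method Equilibrium solver for the full sample, `"weak"` or
#'   `"exact"`.
#' @param verify_n Size of the exact-solver verification subsample (0 to
#'   skip; ignored when `method = "exact"`).
#' @param seed Seed for the verification subsample draw.
#' @return A `sexvar_partition` object with elements `bins` (tibble:
#'   `bin_lo`, `bin_hi`, `n_loci`, `locus_fraction`, `variance_fraction`),
#'   `cumulative` (tibble: `threshold`, `variance_fraction`,
#'   `locus_fraction`), `covariance_stat` (`cov[q(1-q)s^2, t/s]` across
#'   loci), `n_effective`, `consistency`, and the call parameters.
#' @examples
#' sample_dfe(dfe_params(0.2, 0.1, 0.75, n = 5000, seed = 1)) |>
#'   partition_variance(u = 1e-6)
#' @export
partition_variance <- function(sample, u = 1e-6,
                               edges = c(0, 1 / 4, 1 / 2, 1, 2, 4, Inf),
                               thresholds = c(1 / 4, 1 / 2, 1),
                               method = c("weak", "exact"),
                               verify_n = 0, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(u) || length(u) != 1 || u <= 0) abort("u must be positive")
  if (is.unsorted(edges, strictly = TRUE)) {
    abort("bin edges must be strictly increasing")
  }
  s <- sample$s
  t <- sample$t
  if (any(s <= 0) || any(t <= 0)) {
    abort("partitioning expects deleterious-both-sexes samples: s, t > 0")
  }
  solver <- function(idx) {
    q <- switch(method,
      weak = q_eq_weak(s[idx], t[idx], u),
      exact = solve_q_bisect(s[idx], t[idx], rep(u, length(idx)))
    )
    if (any(!is.finite(q))) abort("equilibrium solver failed on the sample")
    q
  }
  all_idx <- seq_along(s)
  q <- solver(all_idx)
  ratio <- t / s
  w <- q * (1 - q) * s^2
  total_w <- sum(w)
  if (total_w <= 0) abort("sample carries no variance weight")

  nb <- length(edges) - 1
  bin_idx <- as.integer(cut(ratio, breaks = edges, right = TRUE,
                            include.lowest = FALSE))
  if (anyNA(bin_idx)) {
    abort("some t/s ratios fall outside the bin edges; extend `edges`")
  }
  bins <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    n_loci = tabulate(bin_idx, nbins = nb),
    locus_fraction = tabulate(bin_idx, nbins = nb) / length(s),
    variance_fraction = vapply(
      seq_len(nb), function(i) sum(w[bin_idx == i]), numeric(1)
    ) / total_w
  )

  cumulative <- tibble::tibble(
    threshold = thresholds,
    variance_fraction = purrr::map_dbl(thresholds, ~ sum(w[ratio < .x]) / total_w),
    locus_fraction = purrr::map_dbl(thresholds, ~ mean(ratio < .x))
  )

  consistency <- NA_real_
  if (method == "weak" && verify_n > 0) {
    m <- min(verify_n, length(s))
    idx <- with_seed(derive_seed(seed, 1L),
                     function() sample.int(length(s), m))
    q_ex <- solve_q_bisect(s[idx], t[idx], rep(u, m))
    w_weak <- w[idx]
    w_ex <- q_ex * (1 - q_ex) * s[idx]^2
    f_weak <- purrr::map_dbl(thresholds,
                             ~ sum(w_weak[ratio[idx] < .x]) / sum(w_weak))
    f_ex <- purrr::map_dbl(thresholds,
                           ~ sum(w_ex[ratio[idx] < .x]) / sum(w_ex))
    consistency <- 100 * max(abs(f_weak - f_ex))
  }

  structure(
    list(
      bins = bins, cumulative = cumulative,
      covariance_stat = if (length(s) >= 2) cov(w, ratio) else NA_real_,
      n_effective = length(s), u = u, method = method,
      consistency = consistency,
      dfe_params = attr(sample, "dfe_params")
    ),
    class = "sexvar_partition"
  )
}

#' @export
print.sexvar_partition <- function(x, ...) {
  cat("Partition of sex-1 additive variance by t/s class\n")
  cat("  loci:", x$n_effective, "  u:", format(x$u),
      "  solver:", x$method, "\n")
  cat("  cov[q(1-q)s^2, t/s] =", format(x$covariance_stat), "\n")
  if (!is.na(x$consistency)) {
    cat("  weak vs exact solver shift:", format(x$consistency), "pp\n")
  }
  print(x$bins)
  cat("Cumulative variance fractions:\n")
  print(x$cumulative)
  invisible(x)
}

#' Covariance between variance weight and asymmetry ratio
#'
#' The hypothesis that asymmetrically selected loci dominate sex-1 variance
#' is `cov[q_eq(1 - q_eq) s^2, t/s] < 0` across loci: loci under weaker
#' selection in sex 2 reach higher frequencies for a given `s` and so carry
#' disproportionate weight.
#'
#' @inheritParams partition_variance
#' @param method Equilibrium solver (`"weak"` or `"exact"`).
#' @return The sample covariance (a length-1 numeric).
#' @examples
#' covariance_statistic(tibble::tibble(s = c(0.02, 0.002), t = c(0.002, 0.02)))
#' @export
covariance_statistic <- function(sample, u = 1e-6,
                                 method = c("weak", "exact")) {
  method <- match.arg(method)
  if (nrow(sample) < 2) abort("need at least 2 loci for a covariance")
  q <- switch(method,
    weak = q_eq_weak(sample$s, sample$t, u),
    exact = solve_q_bisect(sample$s, sample$t, rep(u, nrow(sample)))
  )
  cov(q * (1 - q) * sample$s^2, sample$t / sample$s)
}

#' Predicted sign of the covariance criterion under equal marginals
#'
#' In the small-variance Taylor limit, with identical marginal distributions
#' of `s` and `t` in the two sexes (mean ratio and variance ratio both 1),
#' the criterion for a negative covariance between variance weight and `t/s`
#' reduces to `r_st < 1`: any imperfect between-sex correlation suffices.
#'
#' @param r_st Between-sex correlation in `[0, 1]`.
#' @return `"negative"` for `r_st < 1`, `"zero"` at `r_st = 1`.
#' @examples
#' taylor_criterion_equal_marginals(c(0.75, 1))
#' @export
taylor_criterion_equal_marginals <- function(r_st) {
  if (any(r_st < 0 | r_st > 1)) abort("r_st must lie in [0, 1]")
  ifelse(r_st < 1, "negative", "zero")
}

#' Monte-Carlo estimate of the critical between-sex correlation
#'
#' Bisects the sign of the Monte-Carlo covariance `cov[q(1-q)s^2, t/s]` over
#' a bracket of `r_st` values, under equal gamma marginals. In the
#' small-variance limit the sign change sits at `r_st = 1`; this routine
#' checks that prediction numerically. Each evaluation draws a fresh seeded
#' sample, so the search is deterministic given `seed`.
#'
#' @param shape,scale Gamma marginal hyper-parameters.
#' @param bracket Lower and upper `r_st` bounds for the search.
#' @param n Mutations per covariance evaluation.
#' @param u Mutation rate.
#' @param seed Integer seed.
#' @param tol Bracket width at which to stop.
#' @param construction Passed to [sample_dfe()].
#' @return A `sexvar_critcorr` list: `estimate` (NA when the covariance does
#'   not change sign on the bracket), `bracket`, `evaluations` (tibble of
#'   `r_st`, `covariance`), `mc_halfwidth` (final bracket half-width).
#' @examples
#' critical_correlation(shape = 50, scale = 4e-4, n = 2e4, seed = 1)
#' @export
critical_correlation <- function(shape, scale, bracket = c(0.5, 1),
                                 n = 1e5, u = 1e-6, seed = NULL,
                                 tol = 0.005,
                                 construction = c("kibble", "trivariate",
                                                  "copula")) {
  construction <- match.arg(construction)
  if (length(bracket) != 2 || bracket[1] >= bracket[2] ||
      bracket[1] < 0 || bracket[2] > 1) {
    abort("bracket must be an increasing pair within [0, 1]")
  }
  evals <- list()
  eval_cov <- function(r, stream) {
    smp <- sample_dfe(dfe_params(shape, scale, r_st = r, n = n,
                                 seed = derive_seed(seed, stream),
                                 construction = construction))
    cv <- covariance_statistic(smp, u = u)
    evals[[length(evals) + 1]] <<- tibble::tibble(r_st = r, covariance = cv)
    cv
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- eval_cov(lo, 1L)
  f_hi <- eval_cov(hi, 2L)
  ## sign convention: the covariance is "negative" strictly below 0; a
  ## degenerate r_st = 1 sample has constant t/s and covariance exactly 0.
  if (!(f_lo < 0) || f_hi < 0) {
    return(structure(
      list(estimate = NA_real_, bracket = bracket,
           evaluations = dplyr::bind_rows(evals), mc_halfwidth = NA_real_,
           message = "covariance does not change sign on the bracket"),
      class = "sexvar_critcorr"
    ))
  }
  stream <- 3L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_cov(mid, stream) < 0) lo <- mid else hi <- mid
    stream <- stream + 1L
  }
  structure(
    list(estimate = (lo + hi) / 2, bracket = bracket,
         evaluations = dplyr::bind_rows(evals),
         mc_halfwidth = (hi - lo) / 2, message = NULL),
    class = "sexvar_critcorr"
  )
}

#' @export
print.sexvar_critcorr <- function(x, ...) {
  cat("Critical between-sex correlation (Monte-Carlo bisection)\n")
  if (is.na(x$estimate)) {
    cat("  ", x$message, "\n", sep = "")
  } else {
    cat("  r* =", format(x$estimate), "+/-", format(x$mc_halfwidth),
        "(bracket half-width)\n")
  }
  cat("  evaluations:\n")
  print(x$evaluations)
  invisible(x)
}
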
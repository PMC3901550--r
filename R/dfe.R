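#' Hyper-parameters of the bivariate gamma distribution of fitness effects
#'
#' The sex-specific selection coefficients `(s, t)` of new mutations are
#' modelled as a bivariate gamma distribution with equal `Gamma(shape, scale)`
#' marginals and between-sex Pearson correlation `r_st` in `[0, 1]`. The
#' marginal mean is `shape * scale`; shapes below 1 give the leptokurtic
#' (heavy-tailed, mass near zero) distributions inferred for deleterious
#' mutations.
#'
#' @param shape Gamma shape `k > 0`.
#' @param scale Gamma scale `theta > 0`.
#' @param r_st Between-sex correlation in `[0, 1]`. Negative correlations are
#'   not representable by the gamma constructions used here.
#' @param n Number of mutations (loci) to sample.
#' @param seed Optional integer seed; sampling is deterministic given the
#'   seed.
#' @param construction Bivariate-gamma coupling: `"kibble"` (default; the
#'   classical Kibble bivariate gamma via a Poisson mixture, exact marginals
#'   and exact Pearson correlation), `"trivariate"` (Cherian trivariate
#'   reduction `s = G0 + G1`, `t = G0 + G2`; exact marginals and correlation
#'   but a strongly atom-like symmetric coupling for small shapes), or
#'   `"copula"` (Gaussian copula with normal-score correlation `r_st`; exact
#'   marginals, Pearson correlation matched only approximately).
#' @return A `dfe_params` object (a validated list).
#' @examples
#' dfe_params(shape = 0.2, scale = 0.1, r_st = 0.75, n = 1000, seed = 1)
#' @export
dfe_params <- function(shape, scale, r_st, n, seed = NULL,
                       construction = c("kibble", "trivariate", "copula")) {
  construction <- match.arg(construction)
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0) {
    abort("shape must be a single positive number")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("scale must be a single positive number")
  }
  if (!is.numeric(r_st) || length(r_st) != 1 || r_st < 0 || r_st > 1) {
    abort("r_st must lie in [0, 1]: the gamma constructions cannot produce negative correlation")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("n must be a positive integer")
  }
  structure(
    list(shape = shape, scale = scale, r_st = r_st, mean = shape * scale,
         n = as.integer(n), seed = if (is.null(seed)) NULL else as.integer(seed),
         construction = construction),
    class = "dfe_params"
  )
}

#' @export
print.dfe_params <- function(x, ...) {
  cat("Bivariate gamma DFE (", x$construction, ")\n", sep = "")
  cat("  shape k =", x$shape, " scale theta =", x$scale,
      " mean k*theta =", x$mean, "\n")
  cat("  between-sex correlation r_st =", x$r_st, "\n")
  cat("  n =", x$n, " seed =", x$seed %||% NA, "\n")
  invisible(x)
}

## Strictly positive gamma draws (vectorised over shape): a component with
## shape 0 is identically zero; a positive-shape draw of exactly 0 (possible
## in floating point for tiny shapes) is resampled, because t/s and the locus
## invariants require positivity.
rgamma_pos <- function(n, shape, scale) {
  shape <- rep_len(shape, n)
  out <- numeric(n)
  pos <- shape > 0
  if (!any(pos)) return(out)
  x <- rgamma(sum(pos), shape = shape[pos], scale = scale)
  for (i in 1:100) {
    zero <- x == 0
    if (!any(zero)) {
      out[pos] <- x
      return(out)
    }
    x[zero] <- rgamma(sum(zero), shape = shape[pos][zero], scale = scale)
  }
  abort("could not draw strictly positive gamma variates")
}

## Kibble's bivariate gamma via the classical Poisson mixture: given
## s ~ Gamma(k, theta), draw N ~ Poisson(r s / ((1-r) theta)) and
## t = (1-r) theta Gamma(k + N). Marginals are exactly Gamma(k, theta) and
## the Pearson correlation is exactly r; the distribution is exchangeable.
sample_kibble <- function(n, shape, scale, r) {
  s <- rgamma_pos(n, shape, scale)
  if (r >= 1) return(list(s = s, t = s))
  if (r <= 0) return(list(s = s, t = rgamma_pos(n, shape, scale)))
  nn <- rpois(n, r * s / ((1 - r) * scale))
  t <- (1 - r) * scale * rgamma_pos(n, shape + nn, 1)
  list(s = s, t = t)
}

## Cherian trivariate reduction: s = G0 + G1, t = G0 + G2 with
## G0 ~ Gamma(k r, theta) shared and G1, G2 ~ Gamma(k (1-r), theta)
## independent. Exact marginals and exact Pearson correlation r.
sample_trivariate <- function(n, shape, scale, r) {
  g0 <- rgamma_pos(n, shape * r, scale)
  g1 <- rgamma_pos(n, shape * (1 - r), scale)
  g2 <- rgamma_pos(n, shape * (1 - r), scale)
  s <- g0 + g1
  t <- g0 + g2
  list(s = s, t = t)
}

## Gaussian copula with normal-scale correlation r; gamma marginals are exact
## but the Pearson correlation of (s, t) is attenuated relative to r.
sample_copula <- function(n, shape, scale, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  s <- qgamma(pnorm(z1), shape = shape, scale = scale)
  t <- qgamma(pnorm(z2), shape = shape, scale = scale)
  ## qgamma can underflow to 0 for tiny shapes; nudge into the open interval
  repeat {
    zero <- s == 0 | t == 0
    if (!any(zero)) break
    z <- rnorm(sum(zero))
    s[zero] <- qgamma(pnorm(z), shape = shape, scale = scale)
    t[zero] <- qgamma(pnorm(r * z + sqrt(1 - r^2) * rnorm(sum(zero))),
                      shape = shape, scale = scale)
  }
  list(s = s, t = t)
}

#' Sample correlated sex-specific selection coefficients
#'
#' Draws `n` mutations with sex-1 and sex-2 selection coefficients `(s, t)`
#' from a bivariate gamma distribution with equal marginals (all mutations
#' deleterious in both sexes). See [dfe_params()] for the available
#' couplings.
#'
#' @param params A [dfe_params()] object, or a shape if the remaining
#'   hyper-parameters are given individually.
#' @param scale,r_st,n,seed,construction Used only when `params` is the
#'   numeric shape.
#' @return A tibble with columns `locus_id`, `s`, `t`; the generating
#'   `dfe_params` object is attached as attribute `"dfe_params"`.
#' @examples
#' sample_dfe(dfe_params(0.2, 0.1, r_st = 0.75, n = 100, seed = 1))
#' @export
sample_dfe <- function(params, scale = NULL, r_st = NULL, n = NULL,
                       seed = NULL,
                       construction = c("kibble", "trivariate", "copula")) {
  if (!inherits(params, "dfe_params")) {
    params <- dfe_params(shape = params, scale = scale, r_st = r_st, n = n,
                         seed = seed, construction = match.arg(construction))
  }
  draw <- with_seed(params$seed, function() {
    switch(params$construction,
      kibble = sample_kibble(params$n, params$shape, params$scale, params$r_st),
      trivariate = sample_trivariate(params$n, params$shape, params$scale,
                                     params$r_st),
      copula = sample_copula(params$n, params$shape, params$scale,
                             params$r_st)
    )
  })
  out <- tibble::tibble(
    locus_id = paste0("L", seq_len(params$n)),
    s = draw$s, t = draw$t
  )
  attr(out, "dfe_params") <- params
  out
}

#' Moment diagnostics for a sampled mutation set
#'
#' Compares sample moments against their targets under the generating
#' distribution: means and variances of `s` and `t` against `k*theta` and
#' `k*theta^2`, and the Pearson correlation against `r_st`. Discrepancies
#' beyond 3 Monte-Carlo standard errors are flagged. Samples below 1e4
#' mutations are flagged as underpowered for moment checks.
#'
#' @param sample A tibble from [sample_dfe()] (must carry its `dfe_params`
#'   attribute, or pass `params`).
#' @param params Optional [dfe_params()] override.
#' @return A tibble with one row per moment: `estimate`, `target`, `error`,
#'   `mc_se`, `flagged`; attribute `"underpowered"` signals small samples.
#' @examples
#' marginal_check(sample_dfe(dfe_params(0.2, 0.1, 0.75, n = 2e4, seed = 1)))
#' @export
marginal_check <- function(sample, params = NULL) {
  params <- params %||% attr(sample, "dfe_params")
  if (is.null(params)) abort("no dfe_params available for the sample")
  n <- nrow(sample)
  underpowered <- n < 1e4
  if (underpowered) {
    warn("fewer than 1e4 mutations: moment checks are underpowered")
  }
  k <- params$shape; th <- params$scale
  ## gamma moments: sd(mean) = theta sqrt(k/n); var of the sample variance
  ## uses the gamma's fourth central moment 3 k theta^4 (k + 2)
  se_mean <- th * sqrt(k / n)
  se_var <- sqrt((3 * k * (k + 2) - k^2 * (n - 3) / (n - 1)) / n) * th^2
  ## correlation SE from the empirical influence function: heavy-tailed
  ## marginals inflate it far beyond the normal-theory (1 - r^2)/sqrt(n)
  zs <- as.numeric(scale(sample$s))
  zt <- as.numeric(scale(sample$t))
  r_hat <- mean(zs * zt) * n / (n - 1)
  infl <- zs * zt - r_hat / 2 * (zs^2 + zt^2)
  se_cor <- stats::sd(infl) / sqrt(n)
  out <- tibble::tibble(
    moment = c("mean_s", "mean_t", "var_s", "var_t", "corr_st"),
    estimate = c(mean(sample$s), mean(sample$t),
                 var(sample$s), var(sample$t),
                 if (var(sample$s) > 0 && var(sample$t) > 0)
                   cor(sample$s, sample$t) else NA_real_),
    target = c(k * th, k * th, k * th^2, k * th^2, params$r_st),
    mc_se = c(se_mean, se_mean, se_var, se_var, se_cor)
  )
  out$error <- out$estimate - out$target
  out$flagged <- !is.na(out$error) & abs(out$error) > 3 * out$mc_se
  attr(out, "underpowered") <- underpowered
  out[c("moment", "estimate", "target", "error", "mc_se", "flagged")]
}

#' Fraction of mutations with a smaller effect in sex 2
#'
#' Under any exchangeable equal-marginal coupling, half of the loci are
#' expected to fall in `t < s` (ties, probability zero in the continuous
#' case, are never counted as strictly smaller).
#'
#' @param sample A tibble with columns `s` and `t`.
#' @return The fraction of loci with `t < s`.
#' @examples
#' fraction_with_smaller_t(sample_dfe(dfe_params(0.2, 0.1, 0.75, 1e4, seed = 1)))
#' @export
fraction_with_smaller_t <- function(sample) {
  mean(sample$t < sample$s)
}
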
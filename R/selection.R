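#' Build a validated table of loci under sex-specific selection
#'
#' A locus carries a wild-type and a disease-predisposing allele. Genotype
#' fitnesses are additive within each sex: `1, 1 - s, 1 - 2s` in sex 1 and
#' `1, 1 - t, 1 - 2t` in sex 2, where `s > 0` is the per-copy cost in the
#' focal sex and `t` may be positive (costly to sex 2), zero (sex-limited), or
#' negative (sexually antagonistic: beneficial to sex 2). Disease
#' susceptibility rises by `gamma_effect` per disease-allele copy, with
#' `s = c * gamma_effect` linking disease severity to fitness cost.
#'
#' @param s Numeric vector of sex-1 selection coefficients, `0 < 2*s < 1`.
#' @param t Numeric vector of sex-2 selection coefficients, `2*|t| < 1`.
#'   Recycled against `s`.
#' @param u Mutation rate, wild-type to disease allele, per gamete per
#'   generation; `0 <= u < 1`. Recycled.
#' @param gamma_effect Optional per-copy disease effect size; if supplied it
#'   must satisfy `s = c * gamma_effect` within tolerance.
#' @param c Positive constant relating disease effect to fitness cost
#'   (default 1).
#' @param locus_id Optional identifiers; defaults to `L1, L2, ...`.
#'
#' @return A tibble with columns `locus_id`, `s`, `t`, `u` (and
#'   `gamma_effect`, `c` when given), one row per locus.
#' @examples
#' loci_tbl(s = c(0.01, 0.01), t = c(0.01, -0.0102), u = 1e-6)
#' @export
loci_tbl <- function(s, t, u = 1e-6, gamma_effect = NULL, c = 1,
                     locus_id = NULL) {
  n <- max(length(s), length(t), length(u))
  loci <- tibble::tibble(
    locus_id = locus_id %||% paste0("L", seq_len(n)),
    s = rep_len(s, n), t = rep_len(t, n), u = rep_len(u, n)
  )
  if (!is.null(gamma_effect)) {
    loci$gamma_effect <- rep_len(gamma_effect, n)
    loci$c <- rep_len(c, n)
  }
  validate_loci(loci)
  loci
}

## Locus invariants: all genotype fitnesses strictly positive in both sexes,
## the disease allele deleterious in the focal sex, a proper mutation rate,
## and s = c * gamma when the disease-effect parameterization is present.
validate_loci <- function(loci) {
  stopifnot(is.data.frame(loci))
  miss <- setdiff(c("s", "t", "u"), names(loci))
  if (length(miss) > 0) {
    abort(paste0("loci table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(loci$s)) || any(!is.finite(loci$t)) ||
      any(!is.finite(loci$u))) {
    abort("loci table contains non-finite s, t or u")
  }
  if (any(loci$s <= 0)) {
    abort("s must be > 0: the disease allele is deleterious in the focal sex")
  }
  if (any(2 * abs(loci$s) >= 1) || any(2 * abs(loci$t) >= 1)) {
    abort("need 2|s| < 1 and 2|t| < 1 so all genotype fitnesses stay positive")
  }
  if (any(loci$u < 0) || any(loci$u >= 1)) {
    abort("mutation rate u must satisfy 0 <= u < 1")
  }
  if ("gamma_effect" %in% names(loci)) {
    cc <- if ("c" %in% names(loci)) loci$c else 1
    bad <- abs(loci$s - cc * loci$gamma_effect) >
      1e-8 * pmax(abs(loci$s), 1e-12)
    if (any(bad)) abort("s and c * gamma_effect disagree beyond tolerance")
  }
  invisible(loci)
}

#' Per-locus contribution to population variance in disease susceptibility
#'
#' With susceptibility scores `0, gamma, 2*gamma` for the three genotypes and
#' allele frequencies `p` (wild-type) and `q` (disease), the locus contributes
#' `2 p q gamma^2` to population variance in disease predisposition.
#'
#' @param p Wild-type allele frequency.
#' @param q Disease allele frequency; `p + q` must equal 1.
#' @param gamma_effect Per-copy effect size on disease susceptibility.
#' @return Numeric vector of non-negative variance contributions.
#' @examples
#' susceptibility_variance(0.9, 0.1, 2) # 0.72
#' @export
susceptibility_variance <- function(p, q, gamma_effect) {
  if (any(abs(p + q - 1) > 1e-8)) {
    abort("inconsistent allele frequencies: p + q must equal 1")
  }
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  2 * p * q * gamma_effect^2
}

#' Heterozygosity at a biallelic locus
#'
#' @param q Allele frequency in `[0, 1]`.
#' @return `2 q (1 - q)`, in `[0, 0.5]`.
#' @examples
#' heterozygosity(1e-4)
#' @export
heterozygosity <- function(q) {
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  2 * q * (1 - q)
}

#' Classify the selection regime of a locus
#'
#' Sex-averaged selection maintains the disease allele as a balanced
#' polymorphism when `4st < s + t < 0`. When `s + t < 0` without balancing,
#' net selection favours the disease allele and drives it to fixation.
#' Otherwise variation persists only through recurrent mutation
#' (mutation-selection balance).
#'
#' @param s,t Sex-1 and sex-2 selection coefficients (`s > 0`).
#' @return Character vector: `"balancing_selection"`,
#'   `"disease_fixation"` or `"mutation_selection_balance"`.
#' @examples
#' classify_regime(0.01, c(0.01, -0.0102, -0.02))
#' @export
classify_regime <- function(s, t) {
  if (any(s <= 0)) abort("regime classification requires s > 0")
  sum_st <- s + t
  balancing <- 4 * s * t < sum_st & sum_st < 0
  dplyr::case_when(
    balancing ~ "balancing_selection",
    sum_st < 0 ~ "disease_fixation",
    TRUE ~ "mutation_selection_balance"
  )
}

#' Mutation-selection-balance approximation to the equilibrium frequency
#'
#' The classical two-sex heuristic `q_eq ~ 2u / (s + t)`: the equilibrium
#' frequency of a deleterious allele is set by mutational input against its
#' sex-averaged cost. Capped at 1. Only defined for net purifying selection
#' (`s + t > 0`).
#'
#' @param s,t Selection coefficients; `s + t > 0` required.
#' @param u Mutation rate.
#' @return Approximate equilibrium frequencies, `min(1, 2u/(s + t))`.
#' @examples
#' msb_approx(0.01, 0.01, 1e-6) # 1e-4
#' @export
msb_approx <- function(s, t, u) {
  if (any(s + t <= 0)) {
    abort("msb_approx requires s + t > 0 (mutation-selection balance)")
  }
  if (any(u < 0)) abort("u must be non-negative")
  pmin(1, 2 * u / (s + t))
}

#' Per-sex variance contributions of a locus at a given frequency
#'
#' A locus at frequency `q` contributes `2 q (1 - q) s^2` to additive fitness
#' variance in sex 1 and `2 q (1 - q) t^2` in sex 2. At mutation-selection
#' balance (small `q`) these reduce to the classical `~2 q s^2` forms, giving
#' `~2us` for a fully symmetric locus and `~4us` for a sex-limited one: the
#' asymmetry doubling.
#'
#' @param s,t Selection coefficients.
#' @param q_eq Allele frequency in `[0, 1]`.
#' @return A tibble with columns `v1` and `v2`.
#' @examples
#' variance_contribution(0.02, 0, msb_approx(0.02, 0, 1e-6))
#' @export
variance_contribution <- function(s, t, q_eq) {
  if (any(q_eq < 0 | q_eq > 1)) abort("q_eq must lie in [0, 1]")
  h <- q_eq * (1 - q_eq)
  tibble::tibble(v1 = 2 * h * s^2, v2 = 2 * h * t^2)
}
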
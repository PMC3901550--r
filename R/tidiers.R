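#' Tidy a variance partition
#'
#' @param x A `sexvar_partition` object.
#' @param ... Unused.
#' @return One row per `t/s` bin with `bin_lo`, `bin_hi`, `n_loci`,
#'   `locus_fraction`, `variance_fraction`.
#' @export
tidy.sexvar_partition <- function(x, ...) {
  x$bins
}

#' One-row summary of a variance partition
#'
#' @param x A `sexvar_partition` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_effective`, `u`, `method`,
#'   `covariance_stat`, `consistency`, and one `var_frac_lt_*` column per
#'   cumulative threshold.
#' @export
glance.sexvar_partition <- function(x, ...) {
  cum <- stats::setNames(
    as.list(x$cumulative$variance_fraction),
    paste0("var_frac_lt_", x$cumulative$threshold)
  )
  dplyr::bind_cols(
    tibble::tibble(
      n_effective = x$n_effective, u = x$u, method = x$method,
      covariance_stat = x$covariance_stat, consistency = x$consistency
    ),
    tibble::as_tibble(cum)
  )
}

#' Tidy a critical-correlation search
#'
#' @param x A `sexvar_critcorr` object.
#' @param ... Unused.
#' @return The evaluation tibble (`r_st`, `covariance`).
#' @export
tidy.sexvar_critcorr <- function(x, ...) {
  x$evaluations
}

#' One-row summary of a critical-correlation search
#'
#' @param x A `sexvar_critcorr` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `mc_halfwidth`, bracket bounds
#'   and the number of covariance evaluations.
#' @export
glance.sexvar_critcorr <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, mc_halfwidth = x$mc_halfwidth,
    bracket_lo = x$bracket[1], bracket_hi = x$bracket[2],
    n_evaluations = nrow(x$evaluations)
  )
}
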
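#' Plot a variance partition as class-wise columns
#'
#' Columns show, for each `t/s` class, its share of sex-1 additive variance
#' alongside its share of loci; asymmetric classes (`t/s < 1`) carrying more
#' variance than loci is the signature of sex-differential selection.
#'
#' @param object A `sexvar_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sexvar_partition <- function(object, ...) {
  dat <- object$bins |>
    dplyr::mutate(
      class = factor(
        sprintf("(%s, %s]", format(.data$bin_lo, trim = TRUE),
                format(.data$bin_hi, trim = TRUE)),
        levels = sprintf("(%s, %s]", format(object$bins$bin_lo, trim = TRUE),
                         format(object$bins$bin_hi, trim = TRUE))
      )
    ) |>
    tidyr::pivot_longer(c("locus_fraction", "variance_fraction"),
                        names_to = "share", values_to = "fraction")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$fraction,
                                    fill = .data$share)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "t/s class", y = "fraction of total",
                  fill = NULL,
                  title = "Sex-1 additive variance by between-sex asymmetry") +
    ggplot2::theme_minimal()
}

#' Plot an equilibrium sweep
#'
#' Equilibrium disease-allele frequency and heterozygosity against the
#' asymmetry ratio `t/s`, one curve per `s`; diversity inflates as selection
#' in sex 2 weakens and explodes in the sexually antagonistic range
#' (`t/s < 0`) once balancing selection takes over.
#'
#' @param sweep A tibble from [equilibrium_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  dat <- sweep |>
    tidyr::pivot_longer(c("q_eq", "H"), names_to = "measure",
                        values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_over_s, y = .data$value,
                                    colour = factor(.data$s),
                                    linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t/s", y = "equilibrium value (log scale)",
                  colour = "s", linetype = NULL) +
    ggplot2::theme_minimal()
}
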
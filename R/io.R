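loci_cols <- readr::cols(
  locus_id = readr::col_character(),
  s = readr::col_double(), t = readr::col_double(), u = readr::col_double(),
  q_eq = readr::col_double(), regime = readr::col_character(),
  H = readr::col_double(), v1 = readr::col_double(), v2 = readr::col_double(),
  near_neutral = readr::col_logical(),
  .default = readr::col_double()
)

#' Read and write locus tables
#'
#' Locus tables are tab-separated with a header row and `.` decimals;
#' canonical columns are `locus_id, s, t, u` plus, for solved tables,
#' `q_eq, regime, H, v1, v2`.
#'
#' @param path File path.
#' @return `read_loci()` returns a validated tibble.
#' @export
read_loci <- function(path) {
  loci <- readr::read_tsv(path, col_types = loci_cols, progress = FALSE)
  validate_loci(loci)
  loci
}

#' @rdname read_loci
#' @param loci A locus tibble.
#' @export
write_loci <- function(loci, path) {
  readr::write_tsv(loci, path)
  invisible(path)
}

#' Write a sampled mutation set with a reproducibility sidecar
#'
#' The `(s, t)` table goes to `path` as TSV; the generating hyper-parameters
#' and seed go to `<path>.json`, from which the sample can be regenerated
#' exactly.
#'
#' @param sample A tibble from [sample_dfe()].
#' @param path Output TSV path.
#' @return The TSV path, invisibly.
#' @export
write_dfe_sample <- function(sample, path) {
  readr::write_tsv(sample, path)
  params <- attr(sample, "dfe_params")
  if (!is.null(params)) {
    jsonlite::write_json(
      c(unclass(params), list(package_version = as.character(
        utils::packageVersion("sexvar")))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' @rdname write_dfe_sample
#' @return `read_dfe_sample()` returns the sample tibble with its
#'   `dfe_params` attribute restored from the sidecar when present.
#' @export
read_dfe_sample <- function(path) {
  smp <- readr::read_tsv(
    path,
    col_types = readr::cols(locus_id = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    p <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(smp, "dfe_params") <- dfe_params(
      shape = p$shape, scale = p$scale, r_st = p$r_st, n = p$n,
      seed = p$seed, construction = p$construction
    )
  }
  smp
}

#' Write a partition report
#'
#' Writes the per-bin table as TSV (`bin_lo, bin_hi, n_loci, locus_fraction,
#' variance_fraction`) and a JSON summary (cumulative fractions, covariance
#' statistic, solver, parameters) alongside it.
#'
#' @param partition A `sexvar_partition` object.
#' @param path Output TSV path; the JSON summary goes to `<path>.json`.
#' @return The TSV path, invisibly.
#' @export
write_partition_report <- function(partition, path) {
  readr::write_tsv(partition$bins, path)
  summary <- list(
    cumulative = partition$cumulative,
    covariance_stat = partition$covariance_stat,
    n_effective = partition$n_effective,
    u = partition$u,
    method = partition$method,
    consistency_pp = partition$consistency,
    dfe_params = if (!is.null(partition$dfe_params)) {
      unclass(partition$dfe_params)
    },
    package_version = as.character(utils::packageVersion("sexvar"))
  )
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
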
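#' Generate small deterministic locus fixtures
#'
#' Emits (a) a 10-locus hand-specified table spanning all three selection
#' regimes with its exact-solver companion, and (b) a seeded 1000-locus
#' bivariate-gamma sample (with JSON sidecar) plus its solved companion.
#' Output is byte-identical across runs with the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the sampled table.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create fixture directory: ", dir))

  hand <- loci_tbl(
    s = c(0.01, 0.02, 0.005, 0.01, 0.01, 0.02, 0.001, 0.3, 0.005, 0.01),
    t = c(0.01, 0.002, 0.005, -0.0102, -0.02, 0, 0.0005, 0.1, -0.005, 0.02),
    u = 1e-6
  )
  f_hand <- file.path(dir, "loci_regimes.tsv")
  f_hand_solved <- file.path(dir, "loci_regimes_solved.tsv")
  write_loci(hand, f_hand)
  write_loci(solve_equilibrium(hand), f_hand_solved)

  params <- dfe_params(shape = 0.2, scale = 0.1, r_st = 0.75, n = 1000,
                       seed = seed)
  smp <- sample_dfe(params)
  ## unbounded gamma tails occasionally exceed the fitness-positivity bound
  ## 2s < 1; such loci are outside the locus invariants and dropped here
  smp <- smp[2 * smp$s < 1 & 2 * smp$t < 1, ]
  f_smp <- file.path(dir, "dfe_sample_1k.tsv")
  f_smp_solved <- file.path(dir, "dfe_sample_1k_solved.tsv")
  write_dfe_sample(smp, f_smp)
  solved <- solve_equilibrium(dplyr::mutate(smp, u = 1e-6))
  readr::write_tsv(solved, f_smp_solved)

  invisible(c(
    loci = f_hand, loci_solved = f_hand_solved,
    dfe_sample = f_smp, dfe_sidecar = paste0(f_smp, ".json"),
    dfe_solved = f_smp_solved
  ))
}
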
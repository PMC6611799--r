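#' Generate small seeded fixture data sets
#'
#' Writes a compact simulated experiment (VCF, bulk-design TSV and truth
#' TSV) for tests, examples and documentation. Scenarios:
#' `"null"` (no QTL), `"single_qtl"`, `"two_qtl"`, and `"paper_like_tgw"`
#' (a 1000-grain-weight-like design: 1,046 F2 plants in three pools of
#' 351/348/347, the largest holding 33.56% of individuals).
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario One of the scenario names above.
#' @param seed Integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir,
                          scenario = c("null", "single_qtl", "two_qtl",
                                       "paper_like_tgw"),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  small <- function(...) {
    sim_config(n_chrom = 2L, chrom_len_bp = 8e6, n_snps_per_chrom = 400L,
               n_f2 = 300L, seed = seed, ...)
  }
  cfg <- switch(scenario,
    null = small(qtls = NULL),
    single_qtl = small(
      qtls = tibble::tibble(chrom = 1L, pos_bp = 5e6,
                            a = effect_for_sd_fraction(0.8), d = 0)
    ),
    two_qtl = small(
      qtls = tibble::tibble(chrom = c(1L, 2L), pos_bp = c(5e6, 2.6e6),
                            a = effect_for_sd_fraction(0.7), d = 0)
    ),
    paper_like_tgw = sim_config(
      n_chrom = 2L, chrom_len_bp = 8e6, n_snps_per_chrom = 400L,
      n_f2 = 1046L, bulk_fractions = c(351, 348, 347) / 1046,
      qtls = tibble::tibble(chrom = 1L, pos_bp = 5e6,
                            a = effect_for_sd_fraction(0.5), d = 0),
      seed = seed
    )
  )
  sim <- simulate_gps(cfg, scan_cfg = NULL)
  f_vcf <- file.path(out_dir, paste0(scenario, ".vcf"))
  f_design <- file.path(out_dir, paste0(scenario, ".design.tsv"))
  f_truth <- file.path(out_dir, paste0(scenario, ".truth.tsv"))
  write_pooled_vcf(sim$variants, f_vcf)
  write_bulk_design(variants_design(sim$variants), f_design)
  truth_lines <- "#chrom\tpos_bp\ta\td"
  if (!is.null(cfg$qtls)) {
    truth_lines <- c(truth_lines, sprintf("chr%d\t%d\t%.6g\t%.6g",
                                          cfg$qtls$chrom,
                                          as.integer(cfg$qtls$pos_bp),
                                          cfg$qtls$a, cfg$qtls$d))
  }
  writeLines(truth_lines, f_truth)
  invisible(c(vcf = f_vcf, design = f_design, truth = f_truth))
}
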
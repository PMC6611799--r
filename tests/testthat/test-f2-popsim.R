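small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chrom = 1L, chrom_len_bp = 4e6, n_snps_per_chrom = 100L,
         n_f2 = 200L, qtls = NULL, seed = 11L),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("identical config and seed give bit-identical variant tables", {
  cfg <- small_cfg()
  a <- simulate_gps(cfg, scan_cfg = NULL)$variants
  b <- simulate_gps(cfg, scan_cfg = NULL)$variants
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- small_cfg(seed = 12L)
  c <- simulate_gps(cfg2, scan_cfg = NULL)$variants
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("zero recombination makes chromosomes fully parental", {
  cfg <- small_cfg(cM_per_Mb = 0)
  truth <- simulate_f2(cfg)
  # every individual's dosage is constant along the chromosome
  expect_true(all(apply(truth$dosage, 1, function(x) length(unique(x))) == 1))
})

test_that("F2 dosages segregate 1:2:1", {
  cfg <- sim_config(n_chrom = 1L, chrom_len_bp = 1e6, n_snps_per_chrom = 20L,
                    n_f2 = 10000L, qtls = NULL, seed = 3L)
  truth <- simulate_f2(cfg)
  freqs <- table(truth$dosage) / length(truth$dosage)
  se <- sqrt(0.25 * 0.75 / cfg$n_f2)     # binomial SE at one SNP
  expect_lt(abs(freqs[["0"]] - 0.25), 3 * se)
  expect_lt(abs(freqs[["1"]] - 0.50), 3 * sqrt(0.5 * 0.5 / cfg$n_f2))
  expect_lt(abs(freqs[["2"]] - 0.25), 3 * se)
})

test_that("complete dominance equalises heterozygote and high-homozygote means", {
  cfg <- sim_config(n_chrom = 1L, chrom_len_bp = 4e6, n_snps_per_chrom = 50L,
                    n_f2 = 500L, env_sd = 0,
                    qtls = tibble::tibble(chrom = 1L, pos_bp = 2e6,
                                          a = 1, d = 1),
                    seed = 5L)
  truth <- simulate_f2(cfg)
  y <- truth$phenotype
  dq <- truth$qtl_dosage[, 1]
  expect_equal(mean(y[dq == 1]), mean(y[dq == 2]))
  expect_equal(mean(y[dq == 2]) - mean(y[dq == 0]), 2)  # 2a
})

test_that("grading fills ordered bulks and honours cut points", {
  cfg <- small_cfg(bulk_fractions = c(0.25, 0.25, 0.25))
  y <- seq(1, 0, length.out = 200)   # already sorted, descending
  labels <- grade_population(y, cfg)
  expect_equal(sum(labels == 1, na.rm = TRUE), 50L)
  expect_equal(sum(is.na(labels)), 50L)
  # grade 1 holds the highest phenotypes
  expect_true(max(y[labels == 3], na.rm = TRUE) < min(y[labels == 1], na.rm = TRUE))

  single <- grade_population(y, small_cfg(bulk_fractions = 1.0))
  expect_true(all(single == 1L))

  # boundary-value grading with 1000-grain-weight-like classes
  tgw <- c(25.0, 29.0, 29.5, 31.0, 31.5, 37.0)
  lab <- grade_population(tgw, cfg, cuts = c(29.155, 31.095))
  expect_equal(lab, c(3L, 3L, 2L, 2L, 1L, 1L), ignore_attr = TRUE)
})

test_that("misclassification swaps exactly floor(m * n_b) members", {
  cfg <- small_cfg(n_f2 = 400L, bulk_fractions = c(0.25, 0.25, 0.25),
                   misclass_rate = 0.2, misclass_bulk = 2L)
  y <- rnorm(400)
  labels <- grade_population(y, cfg)
  truth <- attr(labels, "true_labels")
  expect_equal(sum(truth == 2 & (labels != 2 | is.na(labels)), na.rm = TRUE), 20L)
  expect_equal(sum(labels == 2, na.rm = TRUE), 100L)
  # other bulks only change through the swap partners
  expect_equal(sum(!is.na(labels)), sum(!is.na(truth)))
})

test_that("read sampling follows the binomial error model", {
  cfg <- small_cfg(n_f2 = 200L, bulk_fractions = c(0.5, 0.5),
                   per_individual_coverage = 1.0, seq_error = 0)
  truth <- simulate_f2(cfg)
  truth$dosage[] <- 0L                  # force all-reference bulks
  labels <- grade_population(truth$phenotype, cfg)
  v <- pool_reads(truth, labels, cfg)
  expect_true(all(gradedpool:::alt_matrix(v) == 0))
  # mean pool depth ~ n_b x coverage = 100
  depth <- gradedpool:::ref_matrix(v) + gradedpool:::alt_matrix(v)
  expect_lt(abs(mean(depth) - 100), 2)

  cfg2 <- small_cfg(n_f2 = 200L, bulk_fractions = c(0.5, 0.5),
                    per_individual_coverage = 5, seq_error = 0.01)
  truth2 <- simulate_f2(cfg2)
  truth2$dosage[] <- 0L
  v2 <- pool_reads(truth2, grade_population(truth2$phenotype, cfg2), cfg2)
  alt_frac <- sum(gradedpool:::alt_matrix(v2)) /
    sum(gradedpool:::ref_matrix(v2) + gradedpool:::alt_matrix(v2))
  expect_equal(alt_frac, 0.01, tolerance = 0.15)
})

test_that("simulated tables round-trip through VCF on disk", {
  sim <- simulate_gps(small_cfg(), scan_cfg = NULL)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_pooled_vcf(sim$variants, path)
  back <- read_pooled_vcf(path, attr(sim$variants, "design"))
  expect_equal(back$pos, sim$variants$pos)
  expect_equal(gradedpool:::ref_matrix(back),
               gradedpool:::ref_matrix(sim$variants), ignore_attr = TRUE)
  expect_equal(gradedpool:::alt_matrix(back),
               gradedpool:::alt_matrix(sim$variants), ignore_attr = TRUE)
})

test_that("detection scoring separates hits from false positives", {
  iv <- structure(
    tibble::tibble(chrom = c("chr1", "chr2"), start = c(400000L, 2000000L),
                   end = c(800000L, 2400000L), peak_ratio = c(0.9, 0.6),
                   n_snps = c(30L, 25L), n_significant = c(27L, 15L),
                   rank = 1:2),
    class = c("gps_intervals", "tbl_df", "tbl", "data.frame")
  )
  qtls <- tibble::tibble(chrom = 1L, pos_bp = 500000)
  ev <- evaluate_detection(iv, qtls, tolerance_windows = 1)
  expect_true(ev$hits$detected)
  expect_equal(ev$hits$best_rank, 1)
  expect_equal(ev$n_false_positive, 1L)   # chr2 interval matches no QTL

  # tolerance: QTL one window left of the interval still counts
  ev2 <- evaluate_detection(iv, tibble::tibble(chrom = 1L, pos_bp = 100000),
                            tolerance_windows = 1)
  expect_true(ev2$hits$detected)
  ev3 <- evaluate_detection(iv, tibble::tibble(chrom = 1L, pos_bp = 100000),
                            tolerance_windows = 0)
  expect_false(ev3$hits$detected)

  none <- iv[0, ]
  ev4 <- evaluate_detection(none, qtls)
  expect_false(ev4$hits$detected)
  expect_equal(ev4$n_false_positive, 0L)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(qtls = tibble::tibble(chrom = 1L, pos_bp = 99e6,
                                                a = 1, d = 0)),
               "outside")
  expect_error(sim_config(bulk_fractions = c(0.7, 0.6)), "bulk_fractions")
  expect_error(sim_config(seq_error = 0.7), "seq_error")
})

test_that("fixture generator writes consistent seeded scenarios", {
  dir <- withr::local_tempdir()
  files <- make_fixtures(dir, "single_qtl", seed = 2)
  expect_true(all(file.exists(files)))
  d <- read_bulk_design(files[["design"]])
  t <- read_pooled_vcf(files[["vcf"]], d)
  truth <- readr::read_tsv(files[["truth"]], comment = "",
                           col_names = c("chrom", "pos_bp", "a", "d"),
                           skip = 1, show_col_types = FALSE)
  res <- gps_scan(t, scan_cfg = scan_config(top_n = NULL, min_ratio = 0.5))
  ev <- evaluate_detection(res$intervals, truth, tolerance_windows = 1)
  expect_true(all(ev$hits$detected))

  files_null <- make_fixtures(dir, "null", seed = 2)
  tn <- read_pooled_vcf(files_null[["vcf"]],
                        read_bulk_design(files_null[["design"]]))
  resn <- gps_scan(tn, scan_cfg = scan_config(top_n = NULL, min_ratio = 0.5))
  expect_equal(nrow(resn$intervals), 0L)

  paper <- make_fixtures(dir, "paper_like_tgw", seed = 2)
  dp <- read_bulk_design(paper[["design"]])
  expect_equal(bulk_shares(dp)$share_pct[1], 33.56)
})
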
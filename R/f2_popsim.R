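#' Configure an F2 graded-pool sequencing simulation
#'
#' The simulator emulates the full experiment: an F2 population from a
#' cross of two inbred parents (Haldane/no-interference meiosis on a uniform
#' genetic map), a quantitative phenotype with additive/dominance QTL
#' effects plus Gaussian environmental noise, ranking into graded bulks
#' (with optional misclassification), and pooled short-read sampling of
#' allele depths at every SNP.
#'
#' Defaults are rice-like: 12 chromosomes of 30 Mb, 4 cM/Mb, 2,000 evenly
#' spaced SNPs per chromosome, 900 F2 individuals split into 3 equal bulks
#' of 300, 0.7x sequencing coverage per pooled individual, and a single
#' additive QTL whose effect is half a phenotypic standard deviation.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len_bp Chromosome length in bp (same for all chromosomes).
#' @param n_snps_per_chrom Evenly spaced SNPs per chromosome.
#' @param cM_per_Mb Uniform recombination rate (centiMorgan per megabase).
#' @param n_f2 Number of F2 individuals.
#' @param qtls Tibble/data frame with columns `chrom` (index), `pos_bp`,
#'   `a` (additive effect: half the difference between homozygotes) and `d`
#'   (dominance deviation of the heterozygote). `NULL` means no QTL.
#' @param env_sd Standard deviation of the environmental (residual) term.
#' @param bulk_fractions Ordered fractions of the phenotype-ranked
#'   population per grade, highest grade first; must sum to at most 1.
#' @param per_individual_coverage Mean sequencing depth contributed by each
#'   pooled individual; pool depth at a SNP is Poisson(bulk size x this).
#' @param seq_error Per-read probability of reading the wrong allele.
#' @param misclass_rate Fraction of a bulk's members swapped with random
#'   individuals outside the bulk after grading (0 = none).
#' @param misclass_bulk Grade index the misclassification applies to;
#'   `NULL` applies it to every bulk.
#' @param seed Integer seed; all randomness in the simulation derives from
#'   it through named substreams.
#' @return A `gps_sim_config` list.
#' @export
sim_config <- function(n_chrom = 12L, chrom_len_bp = 30e6,
                       n_snps_per_chrom = 2000L, cM_per_Mb = 4,
                       n_f2 = 900L, qtls = default_qtl(),
                       env_sd = 1, bulk_fractions = rep(1 / 3, 3),
                       per_individual_coverage = 0.7, seq_error = 0.001,
                       misclass_rate = 0, misclass_bulk = NULL, seed = 1L) {
  stopifnot(
    n_chrom >= 1, chrom_len_bp > 0, n_snps_per_chrom >= 1, cM_per_Mb >= 0,
    n_f2 >= 2, env_sd >= 0, per_individual_coverage > 0,
    seq_error >= 0, seq_error < 0.5, misclass_rate >= 0, misclass_rate < 1,
    all(bulk_fractions > 0), all(bulk_fractions <= 1),
    sum(bulk_fractions) <= 1 + 1e-9
  )
  if (!is.null(qtls)) {
    qtls <- tibble::as_tibble(qtls)
    stopifnot(all(c("chrom", "pos_bp", "a", "d") %in% names(qtls)))
    if (any(qtls$chrom < 1 | qtls$chrom > n_chrom) ||
        any(qtls$pos_bp < 1 | qtls$pos_bp > chrom_len_bp)) {
      abort("QTL position outside the simulated genome.")
    }
  }
  structure(
    list(n_chrom = as.integer(n_chrom), chrom_len_bp = chrom_len_bp,
         n_snps_per_chrom = as.integer(n_snps_per_chrom),
         cM_per_Mb = cM_per_Mb, n_f2 = as.integer(n_f2), qtls = qtls,
         env_sd = env_sd, bulk_fractions = bulk_fractions,
         per_individual_coverage = per_individual_coverage,
         seq_error = seq_error, misclass_rate = misclass_rate,
         misclass_bulk = misclass_bulk, seed = as.integer(seed)),
    class = "gps_sim_config"
  )
}

#' Additive effect giving a target fraction of the phenotypic SD
#'
#' For a single additive QTL in an F2 (genotype frequencies 1:2:1), the
#' genetic variance is `a^2/2 + d^2/4`, so the additive effect realising
#' `a = frac x phenotypic SD` at environmental SD `env_sd` (with d = 0) is
#' `frac * env_sd / sqrt(1 - frac^2 / 2)`.
#'
#' @param frac Target effect as a fraction of the phenotypic SD.
#' @param env_sd Environmental SD.
#' @return The additive effect `a` in trait units.
#' @export
effect_for_sd_fraction <- function(frac, env_sd = 1) {
  stopifnot(frac > 0, frac < sqrt(2))
  frac * env_sd / sqrt(1 - frac^2 / 2)
}

default_qtl <- function() {
  tibble::tibble(chrom = 1L, pos_bp = 17.4e6,
                 a = effect_for_sd_fraction(0.5), d = 0)
}

# One gamete's allele (0 = low parent, 1 = high parent) at each position.
# Haldane model: crossover count ~ Poisson(map length in Morgans),
# breakpoints uniform, no interference.
sim_gamete <- function(pos, chrom_len_bp, morgans) {
  start <- sample.int(2L, 1L) - 1L
  n_co <- rpois(1, morgans)
  if (n_co == 0) return(rep.int(start, length(pos)))
  bp <- sort(runif(n_co, 0, chrom_len_bp))
  (start + findInterval(pos, bp)) %% 2L
}

#' Simulate an F2 population
#'
#' Generates genotype dosages (copies of the high-parent allele, 0/1/2) at
#' every SNP and QTL position and phenotypes
#' `y = sum_q [a_q (dosage_q - 1) + d_q 1(dosage_q = 1)] + N(0, env_sd^2)`.
#'
#' @param cfg A [sim_config()].
#' @return A `gps_sim_truth` list: `snps` (tibble `chrom`, `pos`),
#'   `dosage` (n_f2 x n_snps integer matrix), `phenotype`, `qtl_dosage`
#'   (n_f2 x n_qtls), `cfg`.
#' @export
simulate_f2 <- function(cfg = sim_config()) {
  set.seed(derive_seed(cfg$seed, "meiosis"))
  n <- cfg$n_f2
  spacing <- cfg$chrom_len_bp / cfg$n_snps_per_chrom
  snp_pos <- round(spacing / 2 + spacing * (seq_len(cfg$n_snps_per_chrom) - 1))
  morgans <- cfg$chrom_len_bp / 1e6 * cfg$cM_per_Mb / 100

  snps <- tidyr::expand_grid(chrom = seq_len(cfg$n_chrom), pos = snp_pos)
  dosage <- matrix(0L, n, nrow(snps))
  n_qtl <- if (is.null(cfg$qtls)) 0L else nrow(cfg$qtls)
  qtl_dosage <- matrix(0L, n, max(n_qtl, 1L))

  for (ch in seq_len(cfg$n_chrom)) {
    q_here <- if (n_qtl) which(cfg$qtls$chrom == ch) else integer()
    qtl_pos <- if (length(q_here)) cfg$qtls$pos_bp[q_here] else numeric()
    pos_all <- sort(unique(c(snp_pos, qtl_pos)))
    snp_idx <- (ch - 1L) * cfg$n_snps_per_chrom + seq_len(cfg$n_snps_per_chrom)
    col_of_snp <- match(snp_pos, pos_all)
    col_of_qtl <- match(qtl_pos, pos_all)
    for (i in seq_len(n)) {
      g <- sim_gamete(pos_all, cfg$chrom_len_bp, morgans) +
        sim_gamete(pos_all, cfg$chrom_len_bp, morgans)
      dosage[i, snp_idx] <- g[col_of_snp]
      if (length(q_here)) qtl_dosage[i, q_here] <- g[col_of_qtl]
    }
  }

  pheno <- rnorm(n, 0, cfg$env_sd)
  if (n_qtl) {
    for (q in seq_len(n_qtl)) {
      dq <- qtl_dosage[, q]
      pheno <- pheno + cfg$qtls$a[q] * (dq - 1) + cfg$qtls$d[q] * (dq == 1)
    }
  }

  structure(
    list(snps = snps, dosage = dosage, phenotype = pheno,
         qtl_dosage = if (n_qtl) qtl_dosage[, seq_len(n_qtl), drop = FALSE] else NULL,
         cfg = cfg),
    class = "gps_sim_truth"
  )
}

#' Grade a phenotyped population into ordinal bulks
#'
#' Ranks individuals by phenotype in descending order and assigns the top
#' `fractions[1]` share to grade 1, the next share to grade 2, and so on;
#' individuals beyond the summed fractions stay unassigned (`NA`).
#' Alternatively, explicit phenotype cut points assign grades by value
#' (grade 1 above the highest cut). Misclassification then swaps
#' `floor(m * n_b)` random members of the target bulk(s) with uniformly
#' chosen individuals outside that bulk.
#'
#' @param phenotype Numeric phenotypes.
#' @param cfg A [sim_config()] supplying `bulk_fractions`,
#'   `misclass_rate` and `misclass_bulk`.
#' @param cuts Optional ascending phenotype cut points (boundary-value
#'   grading); overrides `bulk_fractions`.
#' @return Integer grade labels (`NA` = unassigned), with attribute
#'   `true_labels` holding the labels before misclassification.
#' @export
grade_population <- function(phenotype, cfg, cuts = NULL) {
  n <- length(phenotype)
  if (is.null(cuts)) {
    fr <- cfg$bulk_fractions
    if (sum(fr) > 1 + 1e-9) abort("Bulk fractions sum to more than 1.")
    ord <- order(phenotype, decreasing = TRUE)
    bounds <- floor(cumsum(fr) * n + 1e-9)   # guard against 351/1046*1046 = 350.999...
    sizes <- diff(c(0L, bounds))
    labels <- rep(NA_integer_, n)
    labels[ord] <- rep(c(seq_along(fr), NA_integer_),
                       c(sizes, n - sum(sizes)))
  } else {
    cuts <- sort(cuts)
    labels <- (length(cuts) + 1L) - findInterval(phenotype, cuts)
  }
  true_labels <- labels

  m <- cfg$misclass_rate
  if (m > 0) {
    set.seed(derive_seed(cfg$seed, "grading"))
    targets <- if (is.null(cfg$misclass_bulk)) {
      sort(unique(labels[!is.na(labels)]))
    } else {
      cfg$misclass_bulk
    }
    for (b in targets) {
      members <- which(!is.na(labels) & labels == b)
      outsiders <- which(is.na(labels) | labels != b)
      s <- floor(m * length(members))
      if (s == 0) next
      out_mem <- sample(members, s)
      in_new <- sample(outsiders, s)
      tmp <- labels[out_mem]
      labels[out_mem] <- labels[in_new]
      labels[in_new] <- tmp
    }
  }
  attr(labels, "true_labels") <- true_labels
  labels
}

#' Sample pooled sequencing reads for graded bulks
#'
#' Per SNP and bulk: pool depth `D ~ Poisson(n_b x coverage)`; the true
#' high-parent (alternate) allele frequency `f` is the mean dosage of the
#' bulk's observed members divided by 2; alternate reads are
#' `Binomial(D, f (1 - e) + (1 - f) e)` with sequencing error `e`, and
#' reference reads make up the remainder. Equal DNA contribution per pooled
#' individual is assumed. Parent genotypes are attached as `1/1` (high,
#' alternate) and `0/0` (low, reference) so the parent-informative filter
#' stage passes.
#'
#' @param truth A `gps_sim_truth` from [simulate_f2()].
#' @param labels Grade labels from [grade_population()].
#' @param cfg A [sim_config()].
#' @return A `gps_variants` tibble (chromosomes named `chr1`, `chr2`, ...).
#' @export
pool_reads <- function(truth, labels, cfg = truth$cfg) {
  set.seed(derive_seed(cfg$seed, "reads"))
  grades <- sort(unique(labels[!is.na(labels)]))
  k <- length(grades)
  if (k < 2) abort("Need at least 2 non-empty bulks.")
  m <- nrow(truth$snps)
  eps <- cfg$seq_error
  ref_counts <- matrix(0L, m, k)
  alt_counts <- matrix(0L, m, k)
  sizes <- integer(k)
  for (g in seq_len(k)) {
    members <- which(!is.na(labels) & labels == grades[g])
    if (!length(members)) abort("Empty bulk in pooling step.")
    sizes[g] <- length(members)
    f <- colMeans(truth$dosage[members, , drop = FALSE]) / 2
    depth <- rpois(m, sizes[g] * cfg$per_individual_coverage)
    alt <- rbinom(m, depth, f * (1 - eps) + (1 - f) * eps)
    alt_counts[, g] <- alt
    ref_counts[, g] <- depth - alt
  }
  design <- bulk_design(seq_len(k), paste0("G", seq_len(k)), sizes,
                        parent_high = "P_high", parent_low = "P_low")
  variant_table(
    chrom = paste0("chr", truth$snps$chrom), pos = truth$snps$pos,
    ref = "A", alt = "T", ref_counts = ref_counts, alt_counts = alt_counts,
    design = design, qual = 1000,
    parent_gt_high = rep("1/1", m), parent_gt_low = rep("0/0", m)
  )
}

#' Simulate one graded-pool experiment end to end
#'
#' Convenience wrapper: [simulate_f2()] then [grade_population()] then
#' [pool_reads()], optionally followed by [gps_scan()].
#'
#' @param cfg A [sim_config()].
#' @param scan_cfg A [scan_config()], or `NULL` to return only the variant
#'   table.
#' @param method Association test for the scan.
#' @return A list with `truth`, `labels`, `variants` and (when scanned)
#'   `scan`.
#' @export
simulate_gps <- function(cfg = sim_config(), scan_cfg = scan_config(),
                         method = "ridit") {
  truth <- simulate_f2(cfg)
  labels <- grade_population(truth$phenotype, cfg)
  variants <- pool_reads(truth, labels, cfg)
  out <- list(truth = truth, labels = labels, variants = variants)
  if (!is.null(scan_cfg)) {
    out$scan <- gps_scan(variants, scan_cfg = scan_cfg, method = method)
  }
  out
}

#' Score called intervals against the simulated truth
#'
#' A QTL counts as detected when a called interval (optionally restricted
#' to the best `max_rank` ranks) on its chromosome lies within
#' `tolerance_windows` windows of its position; called intervals within
#' tolerance of no QTL are false positives.
#'
#' @param intervals A `gps_intervals` tibble.
#' @param qtls Tibble with `chrom` (index or `chrN` name) and `pos_bp`.
#' @param window_bp Window width used by the scan.
#' @param tolerance_windows Allowed distance in windows (default 1).
#' @param max_rank Only intervals with `rank <= max_rank` count
#'   (default `NULL`: all).
#' @return A list: `hits` tibble (`chrom`, `pos_bp`, `detected`,
#'   `best_rank`), `n_false_positive`.
#' @export
evaluate_detection <- function(intervals, qtls, window_bp = 400000L,
                               tolerance_windows = 1L, max_rank = NULL) {
  qtls <- tibble::as_tibble(qtls)
  qtl_chrom <- if (is.numeric(qtls$chrom)) paste0("chr", qtls$chrom) else qtls$chrom
  iv <- intervals
  if (!is.null(max_rank)) iv <- dplyr::filter(iv, .data$rank <= max_rank)
  tol <- tolerance_windows * window_bp
  near <- function(chrom, pos) {
    same <- iv$chrom == chrom
    same & pos >= iv$start - tol & pos < iv$end + tol
  }
  hit_rank <- vapply(seq_len(nrow(qtls)), function(q) {
    hits <- near(qtl_chrom[q], qtls$pos_bp[q])
    if (any(hits)) min(iv$rank[hits]) else NA_integer_
  }, numeric(1))
  fp <- if (nrow(iv) == 0) 0L else {
    sum(!vapply(seq_len(nrow(iv)), function(i) {
      any(qtl_chrom == iv$chrom[i] &
            qtls$pos_bp >= iv$start[i] - tol & qtls$pos_bp < iv$end[i] + tol)
    }, logical(1)))
  }
  list(
    hits = tibble::tibble(chrom = qtl_chrom, pos_bp = qtls$pos_bp,
                          detected = !is.na(hit_rank), best_rank = hit_rank),
    n_false_positive = fp
  )
}

#' Detection power over a grid of experimental settings
#'
#' Runs seeded replicate simulations for every grid cell and summarises
#' detection power, the mean rank of the true window and the mean
#' false-positive count. Replicate r of every cell shares the seed
#' `seed + r` (common random numbers), so differences between cells are not
#' driven by Monte-Carlo noise.
#'
#' @param base A [sim_config()] giving the settings not varied.
#' @param grid Data frame whose columns name `sim_config` fields to
#'   override (`per_individual_coverage`, `n_f2`, `misclass_rate`, ...),
#'   plus optionally `n_bulks` (equal fractions) and `method`.
#' @param n_reps Replicates per cell.
#' @param seed Base seed.
#' @param scan_cfg A [scan_config()].
#' @param tolerance_windows,max_rank Passed to [evaluate_detection()].
#' @return Tibble: one row per grid cell with `power`, `mean_best_rank`,
#'   `mean_false_positives`, `n_reps`.
#' @export
power_grid <- function(base = sim_config(), grid, n_reps = 20, seed = 1,
                       scan_cfg = scan_config(), tolerance_windows = 1L,
                       max_rank = 1L) {
  grid <- tibble::as_tibble(grid)
  stopifnot(n_reps >= 1)
  res <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    cfg <- base
    method <- "ridit"
    for (col in names(grid)) {
      val <- grid[[col]][[cell]]
      if (col == "n_bulks") {
        cfg$bulk_fractions <- rep(1 / val, val)
      } else if (col == "method") {
        method <- val
      } else {
        cfg[[col]] <- val
      }
    }
    det <- logical(n_reps)
    ranks <- rep(NA_real_, n_reps)
    fps <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cfg$seed <- as.integer(seed + r)
      sim <- simulate_gps(cfg, scan_cfg = scan_cfg, method = method)
      ev <- evaluate_detection(sim$scan$intervals, cfg$qtls,
                               window_bp = scan_cfg$window_bp,
                               tolerance_windows = tolerance_windows,
                               max_rank = max_rank)
      det[r] <- all(ev$hits$detected)
      ranks[r] <- mean(ev$hits$best_rank)
      fps[r] <- ev$n_false_positive
    }
    res[[cell]] <- dplyr::bind_cols(
      grid[cell, ],
      tibble::tibble(power = mean(det),
                     mean_best_rank = mean(ranks, na.rm = TRUE),
                     mean_false_positives = mean(fps), n_reps = n_reps)
    )
  }
  dplyr::bind_rows(res)
}
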
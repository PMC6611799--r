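# Shared fixture builders and independent oracles.

make_design <- function(k = 3, n = rep(100L, k), parents = FALSE) {
  bulk_design(
    seq_len(k), paste0("G", seq_len(k)), n,
    parent_high = if (parents) "P_high",
    parent_low = if (parents) "P_low"
  )
}

make_variants <- function(ref_counts, alt_counts, design = NULL,
                          chrom = NULL, pos = NULL, qual = 1000,
                          parent_gt_high = NULL, parent_gt_low = NULL) {
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  m <- nrow(ref_counts)
  if (is.null(design)) design <- make_design(ncol(ref_counts))
  variant_table(
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq(1000L, by = 1000L, length.out = m),
    ref = "A", alt = "T",
    ref_counts = ref_counts, alt_counts = alt_counts,
    design = design, qual = qual,
    parent_gt_high = parent_gt_high, parent_gt_low = parent_gt_low
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force rank-sum oracle: expand the 2 x k count table into N single
# graded observations, rank them with base rank(), and form the
# tie-corrected normal-approximation z. Independent of the closed-form
# midrank path used by ridit_test().
oracle_ranksum_z <- function(ref_counts, alt_counts) {
  vals <- rep(seq_along(ref_counts), ref_counts + alt_counts)
  grp <- unlist(lapply(seq_along(ref_counts), function(j) {
    rep(c(1L, 2L), c(ref_counts[j], alt_counts[j]))
  }))
  r <- rank(vals)
  n1 <- sum(grp == 1L); n2 <- sum(grp == 2L); n <- n1 + n2
  w1 <- sum(r[grp == 1L])
  ties <- table(vals)
  varw <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (w1 - n1 * (n + 1) / 2) / sqrt(varw)
}

# Two-sided permutation p of the rank-sum (equivalently mean-ridit
# difference) statistic on the expanded observations.
oracle_permutation_p <- function(ref_counts, alt_counts, n_perm = 4000) {
  vals <- rep(seq_along(ref_counts), ref_counts + alt_counts)
  grp <- unlist(lapply(seq_along(ref_counts), function(j) {
    rep(c(1L, 2L), c(ref_counts[j], alt_counts[j]))
  }))
  r <- rank(vals)
  n1 <- sum(grp == 1L)
  obs <- abs(sum(r[grp == 1L]) - n1 * (length(vals) + 1) / 2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(r, n1)
    if (abs(sum(perm) - n1 * (length(vals) + 1) / 2) >= obs - 1e-9) {
      hits <- hits + 1L
    }
  }
  hits / n_perm
}

random_grade_table <- function(k = sample(2:6, 1), max_count = 80) {
  list(
    ref = sample(0:max_count, k, replace = TRUE),
    alt = sample(0:max_count, k, replace = TRUE)
  )
}

# skip tables the test conventions map to degenerate results
is_degenerate_table <- function(ref, alt) {
  tot <- ref + alt
  sum(ref) == 0 || sum(alt) == 0 || sum(tot > 0) < 2
}
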
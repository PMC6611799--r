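#' Ridit scores of ordered grade categories
#'
#' The ridit of grade j is the probability mass of the reference
#' distribution falling below the grade plus half the mass in the grade
#' itself: `r_j = (sum_{i<j} N_i + N_j / 2) / N`. Here the combined sample
#' (both allele groups pooled) serves as its own reference distribution, so
#' the count-weighted mean ridit is exactly 0.5.
#'
#' @param column_totals Non-negative counts per grade (highest grade first),
#'   not all zero.
#' @return Numeric vector of ridits, each in (0, 1), non-decreasing.
#' @examples
#' ridit_scores(c(10, 10, 20)) # 0.125 0.375 0.750
#' @export
ridit_scores <- function(column_totals) {
  n <- as.numeric(column_totals)
  if (length(n) < 1 || any(n < 0)) abort("Counts must be non-negative.")
  total <- sum(n)
  if (total == 0) abort("All grade counts are zero.")
  (cumsum(n) - n / 2) / total
}

# Vectorised ridit / rank-sum z over rows of two count matrices.
# Row = one SNP; columns = grades. Group 1 = reference-allele reads.
# Equivalent midrank form: midrank_j = N * r_j + 0.5; the z statistic is the
# tie-corrected normal approximation of the two-group Wilcoxon rank sum.
ridit_z_rows <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  tot <- ref + alt
  n1 <- rowSums(ref); n2 <- rowSums(alt); n <- n1 + n2
  k <- ncol(tot)
  cum <- tot %*% upper.tri(diag(k), diag = TRUE)  # row-wise cumulative sums
  midrank <- cum - tot / 2 + 0.5           # = N * r_j + 0.5
  w1 <- rowSums(ref * midrank)
  e_w1 <- n1 * (n + 1) / 2
  tie <- rowSums(tot^3 - tot)
  varw <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
  ok <- n1 > 0 & n2 > 0 & varw > 0 & n > 1
  z <- ifelse(ok, (w1 - e_w1) / sqrt(pmax(varw, 0)), 0)
  p <- ifelse(ok, 2 * pnorm(-abs(z)), 1)
  ridit_mat <- (cum - tot / 2) / ifelse(n > 0, n, 1)
  r1 <- ifelse(n1 > 0, rowSums(ref * ridit_mat) / n1, NA_real_)
  r2 <- ifelse(n2 > 0, rowSums(alt * ridit_mat) / n2, NA_real_)
  list(statistic = z, p_value = p, mean_ridit_ref = r1, mean_ridit_alt = r2,
       degenerate = !ok)
}

# Vectorised tie-corrected Kruskal-Wallis H with grades as groups and a
# binary (ref/alt) response per read.
kw_h_rows <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  tot <- ref + alt
  n1 <- rowSums(ref); n2 <- rowSums(alt); n <- n1 + n2
  mr0 <- (n1 + 1) / 2                      # midrank of the ref value class
  mr1 <- n1 + (n2 + 1) / 2                 # midrank of the alt value class
  rbar <- (ref * mr0 + alt * mr1) / ifelse(tot > 0, tot, 1)
  h <- 12 / (n * (n + 1)) *
    rowSums(tot * (rbar - (n + 1) / 2)^2 * (tot > 0))
  tiecor <- 1 - (n1^3 - n1 + n2^3 - n2) / (n^3 - n)
  groups <- rowSums(tot > 0)
  ok <- n > 1 & tiecor > 0 & groups >= 2
  h <- ifelse(ok, h / ifelse(tiecor > 0, tiecor, 1), 0)
  df <- pmax(groups - 1, 1)
  p <- ifelse(ok, pchisq(h, df, lower.tail = FALSE), 1)
  list(statistic = h, p_value = p, df = df, degenerate = !ok)
}

# Vectorised Pearson chi-square on 2 x k rows; zero-depth grades dropped
# (df reduced), degenerate rows (an empty allele group) get p = 1.
chisq_rows <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  tot <- ref + alt
  n1 <- rowSums(ref); n2 <- rowSums(alt); n <- n1 + n2
  e1 <- n1 * tot / ifelse(n > 0, n, 1)
  e2 <- n2 * tot / ifelse(n > 0, n, 1)
  x2 <- rowSums(ifelse(e1 > 0, (ref - e1)^2 / e1, 0) +
                  ifelse(e2 > 0, (alt - e2)^2 / e2, 0))
  groups <- rowSums(tot > 0)
  df <- pmax(groups - 1, 1)
  ok <- n1 > 0 & n2 > 0 & groups >= 2
  list(statistic = ifelse(ok, x2, 0), df = df,
       p_value = ifelse(ok, pchisq(x2, df, lower.tail = FALSE), 1),
       degenerate = !ok)
}

as_grade_counts <- function(ref_counts, alt_counts) {
  if (is.data.frame(ref_counts)) {
    stopifnot(all(c("ref", "alt") %in% names(ref_counts)))
    list(ref = as.numeric(ref_counts$ref), alt = as.numeric(ref_counts$alt))
  } else {
    list(ref = as.numeric(ref_counts), alt = as.numeric(alt_counts))
  }
}

new_gps_test <- function(method, statistic, p_value, df = NA_integer_,
                         mean_ridits = NULL, degenerate = FALSE) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         df = df, mean_ridits = mean_ridits, degenerate = degenerate),
    class = "gps_test"
  )
}

#' @export
print.gps_test <- function(x, ...) {
  cat(sprintf("Graded-pool %s test: statistic = %.4g, p = %.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate table)" else ""))
  if (!is.null(x$mean_ridits)) {
    cat(sprintf("  mean ridits: ref %.4f, alt %.4f\n",
                x$mean_ridits[[1]], x$mean_ridits[[2]]))
  }
  invisible(x)
}

#' @method tidy gps_test
#' @export
tidy.gps_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p.value = x$p_value,
    df = x$df,
    mean_ridit_ref = if (is.null(x$mean_ridits)) NA_real_ else x$mean_ridits[[1]],
    mean_ridit_alt = if (is.null(x$mean_ridits)) NA_real_ else x$mean_ridits[[2]]
  )
}

#' Ridit test of association between allele and ordinal grade
#'
#' Tests whether reference and alternate reads are distributed differently
#' across the k ordered bulks. Ridits are computed from the combined column
#' totals (the combined sample is the reference distribution); the test is
#' the equivalent tie-corrected Wilcoxon rank-sum normal approximation via
#' midranks (`midrank_j = N r_j + 0.5`), with group 1 the reference-allele
#' reads. A positive z means reference reads sit in higher-numbered (lower
#' phenotype) grades.
#'
#' Degenerate tables follow fixed conventions: an empty allele group, or all
#' mass in one grade (zero rank variance), yields `z = 0`, `p = 1` with the
#' `degenerate` flag set.
#'
#' @param ref_counts Reference-read counts per grade (or a data frame with
#'   `ref` and `alt` columns).
#' @param alt_counts Alternate-read counts per grade.
#' @param variance `"ranksum"` (default): tie-corrected rank-sum variance.
#'   `"bross"`: the classical large-sample approximation
#'   `Var(R1 - R2) = (1/12)(1/n1 + 1/n2)`, the no-ties large-sample form;
#'   it overstates the variance (hence is conservative) when a few grades
#'   hold most of the mass, since ties shrink the true rank variance.
#' @return A `gps_test` object with `statistic` (z), `p_value` (two-sided
#'   normal), and `mean_ridits` (ref, alt).
#' @examples
#' ridit_test(c(9, 0), c(0, 9))     # |z| ~ 4.12
#' ridit_test(c(50, 50, 50), c(50, 50, 50)) # z = 0, p = 1
#' @export
ridit_test <- function(ref_counts, alt_counts = NULL,
                       variance = c("ranksum", "bross")) {
  variance <- match.arg(variance)
  g <- as_grade_counts(ref_counts, alt_counts)
  if (length(g$ref) < 2) abort("Need k >= 2 grades.")
  r <- ridit_z_rows(matrix(g$ref, 1), matrix(g$alt, 1))
  if (variance == "bross" && !r$degenerate) {
    n1 <- sum(g$ref); n2 <- sum(g$alt)
    z <- (r$mean_ridit_ref - r$mean_ridit_alt) /
      sqrt((1 / n1 + 1 / n2) / 12)
    r$statistic <- z
    r$p_value <- 2 * pnorm(-abs(z))
  }
  new_gps_test("ridit", r$statistic, r$p_value,
               mean_ridits = c(ref = r$mean_ridit_ref, alt = r$mean_ridit_alt),
               degenerate = r$degenerate)
}

#' Kruskal-Wallis test on a graded 2 x k read-count table
#'
#' Treats the k grades as groups and every read as an observation with a
#' binary value (0 = reference, 1 = alternate); computes the tie-corrected H
#' via midranks, with p from a chi-square on (number of non-empty grades - 1)
#' degrees of freedom. For k = 2 the identity `H = z^2` with [ridit_test()]
#' holds exactly.
#'
#' @inheritParams ridit_test
#' @return A `gps_test` object.
#' @export
kruskal_wallis_test <- function(ref_counts, alt_counts = NULL) {
  g <- as_grade_counts(ref_counts, alt_counts)
  if (length(g$ref) < 2) abort("Need k >= 2 grades.")
  r <- kw_h_rows(matrix(g$ref, 1), matrix(g$alt, 1))
  new_gps_test("kruskal_wallis", r$statistic, r$p_value, df = r$df,
               degenerate = r$degenerate)
}

#' Pearson chi-square test on a graded 2 x k read-count table
#'
#' Plain Pearson chi-square (no continuity correction) of allele against
#' grade, computed by [stats::chisq.test()] after dropping zero-depth grades
#' (degrees of freedom reduced accordingly). Unlike the rank-based tests it
#' ignores the grade ordering.
#'
#' @inheritParams ridit_test
#' @return A `gps_test` object.
#' @export
chisq_test <- function(ref_counts, alt_counts = NULL) {
  g <- as_grade_counts(ref_counts, alt_counts)
  if (sum(g$ref) == 0 || sum(g$alt) == 0) {
    abort("One allele group is empty; the chi-square table is degenerate.")
  }
  keep <- (g$ref + g$alt) > 0
  if (sum(keep) < 2) abort("Fewer than 2 non-empty grades.")
  m <- rbind(g$ref[keep], g$alt[keep])
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_gps_test("chisq", unname(res$statistic), res$p.value,
               df = unname(res$parameter))
}

#' Per-SNP association track over a variant table
#'
#' Applies the chosen test to every SNP of a (filtered) variant table and
#' returns a sorted per-SNP track with `-ln(p)` ready for plotting. p-values
#' are floored at the smallest positive double before taking logs so
#' `neg_ln_p` is always finite.
#'
#' @param t A `gps_variants` tibble.
#' @param method `"ridit"` (default), `"kw"` or `"chisq"`.
#' @param effective_size Optional scaling `c` in (0, 1] applied to all read
#'   counts before testing, an effective-sample-size correction for
#'   pooled-individual overdispersion. Default `NULL` (counts used as-is,
#'   reads treated as independent observations).
#' @return A `gps_pvalues` tibble with `chrom`, `pos`, `statistic`,
#'   `p_value`, `neg_ln_p` (and mean ridits for the ridit method); the
#'   method is recorded as an attribute.
#' @export
test_track <- function(t, method = c("ridit", "kw", "chisq"),
                       effective_size = NULL) {
  method <- match.arg(method)
  out <- tibble::tibble(
    chrom = t$chrom, pos = t$pos,
    statistic = numeric(nrow(t)), p_value = numeric(nrow(t))
  )
  if (nrow(t) > 0) {
    ref <- ref_matrix(t); alt <- alt_matrix(t)
    if (!is.null(effective_size)) {
      stopifnot(effective_size > 0, effective_size <= 1)
      ref <- ref * effective_size
      alt <- alt * effective_size
    }
    res <- switch(method,
      ridit = ridit_z_rows(ref, alt),
      kw = kw_h_rows(ref, alt),
      chisq = chisq_rows(ref, alt)
    )
    out$statistic <- res$statistic
    out$p_value <- res$p_value
    if (method == "ridit") {
      out$mean_ridit_ref <- res$mean_ridit_ref
      out$mean_ridit_alt <- res$mean_ridit_alt
    }
  }
  out$neg_ln_p <- -log(pmax(out$p_value, .Machine$double.xmin))
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "method") <- method
  class(out) <- c("gps_pvalues", class(out))
  out
}
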
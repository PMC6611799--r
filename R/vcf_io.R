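#' Build a pooled variant table from per-grade allele counts
#'
#' The central container of the pipeline: one row per biallelic SNP with the
#' reference/alternate read counts of every graded bulk in grade order, held
#' in wide columns `ref_1..ref_k` / `alt_1..alt_k`. The bulk design travels
#' with the table as an attribute so downstream stages know k and pool sizes.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions (VCF convention).
#' @param ref,alt Single-base allele characters.
#' @param ref_counts,alt_counts Integer matrices, one row per SNP and one
#'   column per grade (grade order).
#' @param design A `gps_design` tibble.
#' @param qual Numeric variant qualities (default `Inf`, i.e. never dropped
#'   by the quality filter).
#' @param parent_gt_high,parent_gt_low Optional character vectors of diploid
#'   parent genotypes (`"0/0"`, `"0/1"`, `"1/1"`, `NA`).
#' @return A `gps_variants` tibble sorted by `(chrom, pos)`.
#' @export
variant_table <- function(chrom, pos, ref, alt, ref_counts, alt_counts,
                          design, qual = Inf,
                          parent_gt_high = NULL, parent_gt_low = NULL) {
  k <- design_k(design)
  ref_counts <- matrix(as.integer(ref_counts), ncol = k)
  alt_counts <- matrix(as.integer(alt_counts), ncol = k)
  m <- length(chrom)
  stopifnot(
    length(pos) == m, nrow(ref_counts) == m, nrow(alt_counts) == m,
    all(ref_counts >= 0, na.rm = TRUE), all(alt_counts >= 0, na.rm = TRUE)
  )
  out <- tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qual = rep_len(as.numeric(qual), m)
  )
  for (g in seq_len(k)) out[[paste0("ref_", g)]] <- ref_counts[, g]
  for (g in seq_len(k)) out[[paste0("alt_", g)]] <- alt_counts[, g]
  if (!is.null(parent_gt_high)) {
    out$parent_gt_high <- as.character(parent_gt_high)
    out$parent_gt_low <- as.character(parent_gt_low)
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  if (anyDuplicated(out[c("chrom", "pos")])) {
    abort("Duplicate (chrom, pos) in variant table.")
  }
  new_variants(out, design)
}

new_variants <- function(tbl, design, meta = list()) {
  attr(tbl, "design") <- design
  attr(tbl, "meta") <- meta
  class(tbl) <- unique(c("gps_variants", class(tbl)))
  tbl
}

#' @export
print.gps_variants <- function(x, ...) {
  k <- design_k(attr(x, "design"))
  cat(sprintf("# Pooled variant table: %d SNPs x %d graded bulks\n", nrow(x), k))
  NextMethod()
}

variants_design <- function(t) {
  d <- attr(t, "design")
  if (is.null(d)) abort("Variant table has lost its bulk design attribute.")
  d
}

ref_matrix <- function(t) {
  k <- design_k(variants_design(t))
  as.matrix(t[paste0("ref_", seq_len(k))])
}

alt_matrix <- function(t) {
  k <- design_k(variants_design(t))
  as.matrix(t[paste0("alt_", seq_len(k))])
}

is_snv <- function(a) a %in% c("A", "C", "G", "T")

#' Read a multi-sample pooled VCF into a variant table
#'
#' Reads a VCF (one sample per graded bulk, optionally two parental samples)
#' and extracts per-sample AD allele depths in the grade order of `design`,
#' regardless of the column order of the file. Only biallelic SNPs are kept:
#' multiallelic records and indels are excluded (and counted in the table
#' metadata), matching a model with one reference/alternate frequency per
#' site. Records with a missing AD in any bulk sample are dropped and
#' counted. Parent genotypes (GT) are attached when the design names parental
#' samples.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param design A `gps_design` tibble; every `sample` (and parent, if named)
#'   must be a sample column of the VCF.
#' @param keep_indels Keep biallelic indels too (default `FALSE`).
#' @return A `gps_variants` tibble; `attr(, "meta")` records the source file
#'   and exclusion counters (`n_multiallelic`, `n_non_snp`, `n_missing_ad`).
#' @export
read_pooled_vcf <- function(path, design, keep_indels = FALSE) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  wanted <- design$sample
  parents <- c(attr(design, "parent_high"), attr(design, "parent_low"))
  missing <- setdiff(c(wanted, parents), samples)
  if (length(missing)) {
    abort(sprintf(
      "Sample(s) named in the bulk design are absent from the VCF: %s",
      paste(missing, collapse = ", ")
    ))
  }

  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- Inf

  multi <- grepl(",", alt, fixed = TRUE)
  snv <- is_snv(ref) & is_snv(alt)
  if (keep_indels) {
    snv <- snv | (!multi & !grepl("[^ACGT]", ref) & !grepl("[^ACGT]", alt))
  }
  keep <- !multi & snv
  n_multi <- sum(multi)
  n_non_snp <- sum(!snv & !multi)

  ad <- vcfR::extract.gt(v, element = "AD")
  k <- design_k(design)
  m <- sum(keep)
  ref_counts <- matrix(NA_integer_, m, k)
  alt_counts <- matrix(NA_integer_, m, k)
  for (g in seq_len(k)) {
    pair <- parse_ad(ad[keep, wanted[g], drop = TRUE])
    ref_counts[, g] <- pair$ref
    alt_counts[, g] <- pair$alt
  }
  complete <- rowSums(is.na(ref_counts) | is.na(alt_counts)) == 0
  n_missing_ad <- sum(!complete)

  pg_high <- pg_low <- NULL
  if (length(parents) == 2) {
    gt <- vcfR::extract.gt(v, element = "GT")
    pg_high <- normalize_gt(gt[keep, parents[1], drop = TRUE])[complete]
    pg_low <- normalize_gt(gt[keep, parents[2], drop = TRUE])[complete]
  }

  out <- variant_table(
    chrom = chrom[keep][complete], pos = pos[keep][complete],
    ref = ref[keep][complete], alt = alt[keep][complete],
    ref_counts = ref_counts[complete, , drop = FALSE],
    alt_counts = alt_counts[complete, , drop = FALSE],
    design = design, qual = qual[keep][complete],
    parent_gt_high = pg_high, parent_gt_low = pg_low
  )
  attr(out, "meta") <- list(
    source = path, n_multiallelic = n_multi,
    n_non_snp = n_non_snp, n_missing_ad = n_missing_ad
  )
  out
}

# "30,70" -> ref 30, alt 70; "." or NA -> NA pair
parse_ad <- function(x) {
  x[x %in% c(".", "./.")] <- NA
  parts <- strsplit(x, ",", fixed = TRUE)
  ref <- vapply(parts, function(p) {
    if (length(p) < 2) NA_integer_ else suppressWarnings(as.integer(p[[1]]))
  }, integer(1))
  alt <- vapply(parts, function(p) {
    if (length(p) < 2) NA_integer_ else suppressWarnings(as.integer(p[[2]]))
  }, integer(1))
  list(ref = ref, alt = alt)
}

normalize_gt <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  g[g %in% c(".", "./.")] <- NA
  g
}

#' Write a variant table as a minimal VCFv4.2 file
#'
#' Emits one sample column per graded bulk (and parents, if genotypes are
#' attached) with GT:AD fields, so simulated tables round-trip through
#' [read_pooled_vcf()]. Pool-sample GT is reported as `./.` (a pool has no
#' single diploid genotype); AD carries the grade's read counts.
#'
#' @param t A `gps_variants` tibble.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(t, path) {
  design <- variants_design(t)
  k <- design_k(design)
  rc <- ref_matrix(t)
  ac <- alt_matrix(t)
  has_par <- "parent_gt_high" %in% names(t)
  sample_names <- design$sample
  if (has_par) {
    sample_names <- c(sample_names,
                      attr(design, "parent_high") %||% "P_high",
                      attr(design, "parent_low") %||% "P_low")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gradedpool",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  pool_cols <- vapply(seq_len(k), function(g) {
    sprintf("./.:%d,%d", rc[, g], ac[, g])
  }, character(nrow(t)))
  pool_cols <- matrix(pool_cols, nrow = nrow(t))
  body <- paste(
    t$chrom, t$pos, ".", t$ref, t$alt,
    ifelse(is.finite(t$qual), format(t$qual, trim = TRUE, scientific = FALSE), "."),
    "PASS", ".", "GT:AD",
    apply(pool_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  if (has_par) {
    par_depth <- 20L
    par_col <- function(g) {
      ad <- ifelse(is.na(g), ".,.",
                   ifelse(g == "0/0", sprintf("%d,0", par_depth),
                          ifelse(g == "1/1", sprintf("0,%d", par_depth),
                                 sprintf("%d,%d", par_depth %/% 2L, par_depth %/% 2L))))
      sprintf("%s:%s", ifelse(is.na(g), "./.", g), ad)
    }
    body <- paste(body, par_col(t$parent_gt_high), par_col(t$parent_gt_low),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the per-SNP, per-window and interval tracks of a scan
#'
#' Produces three plain-text files under a common prefix: a per-SNP TSV
#' (`<prefix>.pvalues.tsv`; 1-based positions as in the VCF), a per-window
#' BED (`<prefix>.ratios.bed`; 0-based half-open windows, the significant-SNP
#' ratio as score, skipped windows omitted) and an interval BED
#' (`<prefix>.intervals.bed`). All files are tab-delimited with `#`-prefixed
#' headers and sorted by genome position.
#'
#' @param pvals Per-SNP test track (see [test_track()]).
#' @param ratios Per-window ratio track (see [window_ratio()]).
#' @param intervals Candidate intervals (see [call_intervals()]); may have
#'   zero rows.
#' @param out_prefix Path prefix for the three files.
#' @return Named character vector of the files written, invisibly.
#' @export
write_tracks <- function(pvals, ratios, intervals, out_prefix) {
  stopifnot(nrow(pvals) > 0, nrow(ratios) > 0)
  f_p <- paste0(out_prefix, ".pvalues.tsv")
  f_r <- paste0(out_prefix, ".ratios.bed")
  f_i <- paste0(out_prefix, ".intervals.bed")

  p <- dplyr::arrange(pvals, .data$chrom, .data$pos)
  writeLines(c(
    "#chrom\tpos\ttest\tstatistic\tp\tneg_ln_p",
    sprintf("%s\t%d\t%s\t%.6g\t%.6g\t%.6g", p$chrom, p$pos,
            attr(pvals, "method") %||% "ridit",
            p$statistic, p$p_value, p$neg_ln_p)
  ), f_p)

  r <- dplyr::arrange(dplyr::filter(ratios, !.data$skipped),
                      .data$chrom, .data$start)
  writeLines(c(
    "#chrom\tstart\tend\tratio\tn_snps\tn_significant",
    sprintf("%s\t%d\t%d\t%.6g\t%d\t%d", r$chrom, r$start, r$end,
            r$ratio, r$n_snps, r$n_significant)
  ), f_r)

  iv <- dplyr::arrange(intervals, .data$chrom, .data$start)
  lines <- "#chrom\tstart\tend\tpeak_ratio\tn_snps\trank"
  if (nrow(iv) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g\t%d\t%d", iv$chrom, iv$start,
                              iv$end, iv$peak_ratio, iv$n_snps, iv$rank))
  }
  writeLines(lines, f_i)

  invisible(c(pvalues = f_p, ratios = f_r, intervals = f_i))
}
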
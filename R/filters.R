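#' Configuration of the staged variant filters
#'
#' Four stages are applied in order before statistical testing:
#' (1) drop low-quality variants; (2) keep variants whose per-pool depth is
#' appropriate, i.e. inside a window around that pool's median depth;
#' (3) keep only sites where both parental lines are homozygous for
#' different alleles; (4) drop sites where every pool shows only
#' non-reference reads. Stage (3) is skipped when no parent genotypes are
#' available (e.g. parent-free or simulated runs) unless
#' `require_parent_informative` is forced.
#'
#' @param min_qual Minimum Phred-scaled variant QUAL kept (boundary
#'   inclusive). Default 30, a conventional floor for GATK-called SNPs.
#' @param depth_low_frac,depth_high_frac Per-pool depth window as fractions
#'   of that pool's median depth (closed interval). Defaults 0.5 and 2.0.
#' @param require_parent_informative Apply stage (3); `NA` (default) means
#'   "apply iff parent genotypes are present".
#' @param drop_all_alt Apply stage (4): drop sites with zero reference reads
#'   in every pool (default `TRUE`).
#' @param drop_all_ref Also drop sites with zero alternate reads in every
#'   pool (default `FALSE`; the published criterion names only all
#'   non-reference sites).
#' @return A `gps_filter_config` list.
#' @export
filter_config <- function(min_qual = 30, depth_low_frac = 0.5,
                          depth_high_frac = 2.0,
                          require_parent_informative = NA,
                          drop_all_alt = TRUE, drop_all_ref = FALSE) {
  stopifnot(min_qual >= 0, depth_low_frac > 0,
            depth_low_frac < depth_high_frac)
  structure(
    list(min_qual = min_qual, depth_low_frac = depth_low_frac,
         depth_high_frac = depth_high_frac,
         require_parent_informative = require_parent_informative,
         drop_all_alt = drop_all_alt, drop_all_ref = drop_all_ref),
    class = "gps_filter_config"
  )
}

#' Stage 1: drop low-quality variants
#'
#' @param t A `gps_variants` tibble.
#' @param min_qual Minimum QUAL kept (inclusive).
#' @return Filtered `gps_variants`.
#' @export
filter_quality <- function(t, min_qual = 30) {
  subset_variants(t, t$qual >= min_qual)
}

#' Stage 2: keep variants with appropriate per-pool depth
#'
#' For each pool, the median depth over the input table defines the
#' acceptable window `[low_frac * median, high_frac * median]` (closed); a
#' variant is kept only if every pool's depth falls inside its window.
#' Medians are computed on the table as passed in, i.e. after the quality
#' stage in [run_filters()].
#'
#' @param t A `gps_variants` tibble.
#' @param cfg A [filter_config()].
#' @return Filtered `gps_variants`.
#' @export
filter_depth <- function(t, cfg = filter_config()) {
  if (nrow(t) == 0) return(t)
  depth <- ref_matrix(t) + alt_matrix(t)
  med <- apply(depth, 2, median)
  if (any(med == 0)) {
    abort("A pool has median depth 0 over this table (degenerate pool).")
  }
  lo <- matrix(cfg$depth_low_frac * med, nrow(t), ncol(depth), byrow = TRUE)
  hi <- matrix(cfg$depth_high_frac * med, nrow(t), ncol(depth), byrow = TRUE)
  keep <- rowSums(depth < lo | depth > hi) == 0
  subset_variants(t, keep)
}

#' Stage 3: keep sites informative between the parents
#'
#' Both parental lines must be homozygous, for different alleles
#' (`0/0` vs `1/1` in either orientation).
#'
#' @param t A `gps_variants` tibble with parent genotypes attached.
#' @return Filtered `gps_variants`.
#' @export
filter_parent_informative <- function(t) {
  if (!"parent_gt_high" %in% names(t)) {
    abort(paste("No parent genotypes attached; disable the",
                "parent-informative stage for parent-free runs."))
  }
  hom <- function(g) !is.na(g) & g %in% c("0/0", "1/1")
  keep <- hom(t$parent_gt_high) & hom(t$parent_gt_low) &
    t$parent_gt_high != t$parent_gt_low
  subset_variants(t, keep)
}

#' Stage 4: drop sites fixed for the non-reference base across all pools
#'
#' Drops sites whose pools contain no reference read at all (these carry no
#' segregation signal and typically mark reference errors). With
#' `drop_all_ref` the mirrored case (no alternate read anywhere) is dropped
#' too.
#'
#' @param t A `gps_variants` tibble.
#' @param cfg A [filter_config()].
#' @return Filtered `gps_variants`.
#' @export
filter_fixed_nonref <- function(t, cfg = filter_config()) {
  if (nrow(t) == 0) return(t)
  keep <- rep(TRUE, nrow(t))
  if (cfg$drop_all_alt) keep <- keep & rowSums(ref_matrix(t)) > 0
  if (cfg$drop_all_ref) keep <- keep & rowSums(alt_matrix(t)) > 0
  subset_variants(t, keep)
}

#' Run the four filter stages in order
#'
#' @param t A `gps_variants` tibble.
#' @param cfg A [filter_config()].
#' @return A list with `variants` (the filtered table) and `report`, a
#'   tibble of per-stage input/output counts plus the overall retention
#'   fraction as an attribute.
#' @export
run_filters <- function(t, cfg = filter_config()) {
  use_parents <- if (is.na(cfg$require_parent_informative)) {
    "parent_gt_high" %in% names(t)
  } else {
    cfg$require_parent_informative
  }
  stages <- list(
    quality = function(x) filter_quality(x, cfg$min_qual),
    depth = function(x) if (nrow(x)) filter_depth(x, cfg) else x,
    parent_informative = if (use_parents) filter_parent_informative else identity,
    fixed_nonref = function(x) filter_fixed_nonref(x, cfg)
  )
  report <- tibble::tibble(stage = names(stages), n_in = NA_integer_,
                           n_out = NA_integer_)
  for (i in seq_along(stages)) {
    report$n_in[i] <- nrow(t)
    t <- stages[[i]](t)
    report$n_out[i] <- nrow(t)
  }
  attr(report, "retention") <-
    if (report$n_in[1] > 0) report$n_out[4] / report$n_in[1] else NA_real_
  list(variants = t, report = report)
}

subset_variants <- function(t, keep) {
  design <- attr(t, "design")
  meta <- attr(t, "meta")
  out <- t[keep, , drop = FALSE]
  new_variants(out, design, meta %||% list())
}
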
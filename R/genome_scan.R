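#' Configuration of the window scan and interval calling
#'
#' The noise-reduction scheme tiles each chromosome with non-overlapping
#' windows from coordinate 0 and scores each window by the fraction of its
#' SNPs whose association p-value passes `alpha`. Windows holding fewer than
#' `min_snps` SNPs are skipped (too little information to estimate a ratio).
#'
#' @param window_bp Window width in bp (default 400,000 — the scheme's
#'   working resolution).
#' @param alpha Per-SNP significance threshold used to count a SNP as
#'   significant (default 0.001; the ratio statistic absorbs a permissive
#'   per-SNP cut, but results depend on this choice, so it is exposed).
#' @param min_snps Minimum SNPs per scored window (default 10).
#' @param top_n Number of top-ranked windows eligible for interval calling
#'   (default 10). `NULL` disables the rank cut.
#' @param min_ratio Minimum ratio for interval calling (default `NULL`: no
#'   ratio cut). When both `top_n` and `min_ratio` are set, a window must
#'   satisfy both.
#' @param merge_adjacent Merge adjacent called windows into one interval
#'   (default `TRUE`).
#' @return A `gps_scan_config` list.
#' @export
scan_config <- function(window_bp = 400000L, alpha = 0.001, min_snps = 10L,
                        top_n = 10L, min_ratio = NULL,
                        merge_adjacent = TRUE) {
  stopifnot(window_bp > 0, alpha > 0, alpha < 1, min_snps >= 1)
  structure(
    list(window_bp = as.integer(window_bp), alpha = alpha,
         min_snps = as.integer(min_snps), top_n = top_n,
         min_ratio = min_ratio, merge_adjacent = merge_adjacent),
    class = "gps_scan_config"
  )
}

#' Assign SNPs to non-overlapping genomic windows
#'
#' Windows tile each chromosome from coordinate 0 in steps of `window_bp`,
#' half-open `[start, end)` in 0-based coordinates; a SNP at 1-based
#' position p falls in window `floor((p - 1) / window_bp)`.
#'
#' @param track A `gps_pvalues` tibble (sorted per-SNP track).
#' @param cfg A [scan_config()].
#' @return The track with `win_start` and `win_end` columns added.
#' @export
assign_windows <- function(track, cfg = scan_config()) {
  w <- cfg$window_bp
  idx <- (track$pos - 1L) %/% w
  dplyr::mutate(tibble::as_tibble(track),
                win_start = as.integer(idx * w),
                win_end = as.integer(idx * w + w))
}

#' Score windows by their fraction of significant SNPs
#'
#' For every window holding at least `min_snps` SNPs, the ratio is the
#' number of SNPs with `p < alpha` over the total number of SNPs in the
#' window; sparser windows are flagged `skipped` and excluded from ranking.
#'
#' @inheritParams assign_windows
#' @return A `gps_ratios` tibble with one row per occupied window: `chrom`,
#'   `start`, `end` (0-based half-open), `midpoint`, `n_snps`,
#'   `n_significant`, `ratio` (`NA` when skipped), `skipped`.
#' @export
window_ratio <- function(track, cfg = scan_config()) {
  out <- assign_windows(track, cfg) |>
    dplyr::group_by(.data$chrom, .data$win_start, .data$win_end) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_significant = sum(.data$p_value < cfg$alpha),
      .groups = "drop"
    ) |>
    dplyr::rename(start = "win_start", end = "win_end") |>
    dplyr::mutate(
      skipped = .data$n_snps < cfg$min_snps,
      ratio = ifelse(.data$skipped, NA_real_,
                     .data$n_significant / .data$n_snps),
      midpoint = (.data$start + .data$end) / 2
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  class(out) <- c("gps_ratios", class(out))
  out
}

#' Call candidate QTL intervals from the ratio track
#'
#' Unskipped windows are ranked by ratio (ties broken by significant-SNP
#' count, then genome order); windows passing the `top_n` / `min_ratio`
#' criteria are selected and, optionally, adjacent selected windows are
#' merged into one interval carrying the maximum ratio and the best rank of
#' its members.
#'
#' @param ratios A `gps_ratios` tibble.
#' @param cfg A [scan_config()].
#' @return A `gps_intervals` tibble: `chrom`, `start`, `end`, `peak_ratio`,
#'   `n_snps`, `n_significant`, `rank`; zero rows (with a warning) when
#'   every window is skipped or none passes.
#' @export
call_intervals <- function(ratios, cfg = scan_config()) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    peak_ratio = numeric(), n_snps = integer(), n_significant = integer(),
    rank = integer()
  )
  cand <- dplyr::filter(ratios, !.data$skipped)
  if (nrow(cand) == 0) {
    warn("All windows were skipped (too few SNPs); no interval called.")
    return(structure(empty, class = c("gps_intervals", class(empty))))
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$ratio),
                         dplyr::desc(.data$n_significant),
                         .data$chrom, .data$start) |>
    dplyr::mutate(rank = dplyr::row_number())
  sel <- cand
  if (!is.null(cfg$min_ratio)) {
    sel <- dplyr::filter(sel, .data$ratio >= cfg$min_ratio)
  }
  if (!is.null(cfg$top_n)) sel <- dplyr::filter(sel, .data$rank <= cfg$top_n)
  if (nrow(sel) == 0) {
    return(structure(empty, class = c("gps_intervals", class(empty))))
  }
  sel <- dplyr::arrange(sel, .data$chrom, .data$start)
  if (isTRUE(cfg$merge_adjacent)) {
    run <- cumsum(
      c(TRUE, !(sel$chrom[-1] == sel$chrom[-nrow(sel)] &
                  sel$start[-1] == sel$end[-nrow(sel)]))
    )
    out <- sel |>
      dplyr::mutate(.run = run) |>
      dplyr::group_by(.data$chrom, .data$.run) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end),
        peak_ratio = max(.data$ratio), n_snps = sum(.data$n_snps),
        n_significant = sum(.data$n_significant),
        rank = min(.data$rank), .groups = "drop"
      ) |>
      dplyr::select(-".run")
  } else {
    out <- dplyr::transmute(sel, .data$chrom, .data$start, .data$end,
                            peak_ratio = .data$ratio, .data$n_snps,
                            .data$n_significant, .data$rank)
  }
  out <- dplyr::arrange(out, .data$rank) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("chrom", "start", "end", "peak_ratio", "n_snps",
                  "n_significant", "rank")
  structure(out, class = c("gps_intervals", class(out)))
}

#' Run the full graded-pool scan pipeline
#'
#' Composes the pipeline: read the VCF against the bulk design, apply the
#' staged filters, compute the per-SNP association track, score windows and
#' call candidate intervals; optionally write all tracks to files.
#'
#' @param vcf Path to the multi-sample pooled VCF, or an already-built
#'   `gps_variants` tibble.
#' @param design A `gps_design` tibble (ignored when `vcf` is a table).
#' @param filter_cfg A [filter_config()].
#' @param scan_cfg A [scan_config()].
#' @param method Association test, see [test_track()].
#' @param effective_size See [test_track()].
#' @param out_prefix Optional path prefix; when given, tracks are written
#'   via [write_tracks()].
#' @return A `gps_scan` list: `pvalues`, `ratios`, `intervals`,
#'   `filter_report`, `config`.
#' @export
gps_scan <- function(vcf, design = NULL, filter_cfg = filter_config(),
                     scan_cfg = scan_config(),
                     method = c("ridit", "kw", "chisq"),
                     effective_size = NULL, out_prefix = NULL) {
  method <- match.arg(method)
  t <- if (inherits(vcf, "gps_variants")) {
    vcf
  } else {
    read_pooled_vcf(vcf, design)
  }
  f <- run_filters(t, filter_cfg)
  pv <- test_track(f$variants, method = method,
                   effective_size = effective_size)
  ratios <- window_ratio(pv, scan_cfg)
  intervals <- call_intervals(ratios, scan_cfg)
  if (!is.null(out_prefix)) write_tracks(pv, ratios, intervals, out_prefix)
  structure(
    list(pvalues = pv, ratios = ratios, intervals = intervals,
         filter_report = f$report, config = scan_cfg, method = method),
    class = "gps_scan"
  )
}

#' @export
print.gps_scan <- function(x, ...) {
  cat(sprintf(
    "Graded-pool scan (%s test): %d SNPs tested, %d windows (%d skipped), %d interval(s) called\n",
    x$method, nrow(x$pvalues), nrow(x$ratios), sum(x$ratios$skipped),
    nrow(x$intervals)
  ))
  if (nrow(x$intervals)) {
    print(tibble::as_tibble(x$intervals))
  }
  invisible(x)
}

#' @method glance gps_scan
#' @export
glance.gps_scan <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_snps = nrow(x$pvalues),
    n_windows = nrow(x$ratios),
    n_skipped = sum(x$ratios$skipped),
    n_intervals = nrow(x$intervals),
    top_ratio = if (nrow(x$intervals)) max(x$intervals$peak_ratio) else NA_real_
  )
}

#' @method tidy gps_scan
#' @export
tidy.gps_scan <- function(x, ...) tibble::as_tibble(x$intervals)
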
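#' Heterosis contribution rate of an introgressed locus
#'
#' Quantifies the share of the hybrid-parent yield gap recovered by a
#' near-isogenic line (NIL) carrying the locus:
#' `rate = (Y_NIL - Y_parent) / (Y_F1 - Y_parent)`,
#' where `Y_parent` is the recurrent inbred parent, `Y_F1` the hybrid and
#' `Y_NIL` the NIL. The rate is affine-invariant: shifting or scaling all
#' three means together leaves it unchanged.
#'
#' @param y_f1 Mean trait value of the F1 hybrid.
#' @param y_parent Mean trait value of the recurrent parent.
#' @param y_nil Mean trait value of the NIL.
#' @return A `gps_contribution` list with `rate` (dimensionless),
#'   `rate_pct` (percentage at one decimal, half-away-from-zero), and the
#'   three inputs. An additional `rate_pct_rounded_means` gives the rate
#'   recomputed after rounding the three means to one decimal, since
#'   published rates are sometimes derived from already-rounded summaries.
#' @examples
#' # grain yield per plant (g): parent 42.644, NIL 46.615, hybrid 56.878
#' contribution_rate(56.878, 42.644, 46.615)
#' @export
contribution_rate <- function(y_f1, y_parent, y_nil) {
  if (isTRUE(all.equal(y_f1, y_parent))) {
    abort("y_f1 equals y_parent: contribution rate is undefined.")
  }
  rate <- (y_nil - y_parent) / (y_f1 - y_parent)
  r1 <- round(y_f1, 1); r2 <- round(y_parent, 1); r3 <- round(y_nil, 1)
  structure(
    list(rate = rate,
         rate_pct = round_half_up(100 * rate, 1),
         rate_pct_rounded_means = if (r1 != r2) {
           round_half_up(100 * (r3 - r2) / (r1 - r2), 1)
         } else NA_real_,
         y_f1 = y_f1, y_parent = y_parent, y_nil = y_nil),
    class = "gps_contribution"
  )
}

#' @export
print.gps_contribution <- function(x, ...) {
  cat(sprintf(
    "Heterosis contribution rate: %.1f%% (NIL %.3f, parent %.3f, F1 %.3f)\n",
    x$rate_pct, x$y_nil, x$y_parent, x$y_f1
  ))
  invisible(x)
}

#' @method tidy gps_contribution
#' @export
tidy.gps_contribution <- function(x, ...) {
  tibble::tibble(rate = x$rate, rate_pct = x$rate_pct,
                 y_f1 = x$y_f1, y_parent = x$y_parent, y_nil = x$y_nil)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pairwise mean differences with pooled standard errors
#'
#' Computes all pairwise mean differences between trait summaries and the
#' standard error of each difference under the one-way layout:
#' the pooled mean square error `MSE = sum (n_g - 1) sd_g^2 / sum (n_g - 1)`
#' across all groups, and `SE(I-J) = sqrt(MSE (1/n_I + 1/n_J))` — the SE
#' underlying Tukey-style comparison tables.
#'
#' @param summaries Data frame with columns `line`, `n`, `mean`, `sd`
#'   (one row per line, `n >= 2`).
#' @param tukey_p Also report an approximate Tukey HSD p-value from the
#'   studentized range distribution (computed from summary statistics with
#'   unequal n via the Tukey-Kramer SE; approximate, default `FALSE`).
#' @return Tibble with one row per ordered pair: `line_i`, `line_j`,
#'   `difference` (`mean_i - mean_j`), `se`, and optionally
#'   `p_tukey_approx`; pooled MSE and its degrees of freedom as attributes.
#' @examples
#' yields <- data.frame(
#'   line = c("FH", "NIL", "PYR", "F1"),
#'   n = c(70, 70, 70, 15),
#'   mean = c(42.644, 46.615, 48.968, 56.878),
#'   sd = c(2.796, 2.853, 6.330, 3.888)
#' )
#' pairwise_differences(yields)
#' @export
pairwise_differences <- function(summaries, tukey_p = FALSE) {
  s <- tibble::as_tibble(summaries)
  stopifnot(all(c("line", "n", "mean", "sd") %in% names(s)))
  if (nrow(s) < 2) abort("Need at least 2 lines.")
  if (any(s$n < 2) || any(s$sd < 0)) abort("Each line needs n >= 2, sd >= 0.")
  df <- sum(s$n - 1)
  mse <- sum((s$n - 1) * s$sd^2) / df
  pairs <- tidyr::expand_grid(i = seq_len(nrow(s)), j = seq_len(nrow(s))) |>
    dplyr::filter(.data$i != .data$j)
  out <- tibble::tibble(
    line_i = s$line[pairs$i], line_j = s$line[pairs$j],
    difference = s$mean[pairs$i] - s$mean[pairs$j],
    se = sqrt(mse * (1 / s$n[pairs$i] + 1 / s$n[pairs$j]))
  )
  if (tukey_p) {
    q <- abs(out$difference) / sqrt(mse / 2 * (1 / s$n[pairs$i] + 1 / s$n[pairs$j]))
    out$p_tukey_approx <- stats::ptukey(q, nmeans = nrow(s), df = df,
                                        lower.tail = FALSE)
  }
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  out
}

#' Percent change of one mean relative to a baseline
#'
#' @param mean_a New value.
#' @param mean_b Baseline (non-zero).
#' @return `100 * (mean_a - mean_b) / mean_b`.
#' @export
percent_change <- function(mean_a, mean_b) {
  if (mean_b == 0) abort("Baseline mean is zero; percent change undefined.")
  100 * (mean_a - mean_b) / mean_b
}
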
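#' Define the graded-bulk design of an F2 pooled-sequencing experiment
#'
#' A bulk design binds each ordinal phenotype grade to the VCF sample that
#' holds its pooled reads and to the number of F2 individuals pooled in it.
#' Grade 1 is the highest phenotypic class, grade k the lowest, mirroring how
#' an F2 population is ranked and split into graded bulks before sequencing.
#'
#' @param grade Integer vector of grade indices; must be exactly `1:k` with
#'   `k >= 2` after sorting.
#' @param sample Character vector of VCF sample names, one per grade.
#' @param n Integer vector of pooled individuals per grade (all `>= 1`).
#' @param parent_high,parent_low Optional VCF sample names of the
#'   high-phenotype and low-phenotype parental lines. Either both or neither
#'   must be given.
#'
#' @return A `gps_design` tibble with columns `grade`, `sample`, `n`, sorted
#'   by grade, carrying the parent sample names as attributes.
#' @examples
#' bulk_design(1:3, c("G1", "G2", "G3"), c(351, 348, 347))
#' @export
bulk_design <- function(grade, sample, n, parent_high = NULL, parent_low = NULL) {
  grade <- as.integer(grade)
  n <- as.integer(n)
  sample <- as.character(sample)
  if (length(grade) != length(sample) || length(grade) != length(n)) {
    abort("`grade`, `sample` and `n` must have equal length.")
  }
  if (anyDuplicated(grade)) abort("Duplicate grade indices in bulk design.")
  k <- length(grade)
  if (k < 2) abort("A bulk design needs at least 2 grades.")
  if (!setequal(grade, seq_len(k))) {
    abort(sprintf("Grade indices must be exactly 1..%d.", k))
  }
  if (anyDuplicated(sample)) abort("Sample names must be unique.")
  if (any(is.na(n)) || any(n < 1)) abort("Each grade needs n >= 1 individuals.")
  if (xor(is.null(parent_high), is.null(parent_low))) {
    abort("Name both `parent_high` and `parent_low`, or neither.")
  }
  out <- tibble::tibble(grade = grade, sample = sample, n = n) |>
    dplyr::arrange(.data$grade)
  attr(out, "parent_high") <- parent_high
  attr(out, "parent_low") <- parent_low
  class(out) <- c("gps_design", class(out))
  out
}

#' Read a bulk design from a tab-separated file
#'
#' The file has a header line `grade<TAB>sample<TAB>n` and one row per bulk.
#' Lines starting with `#` are comments, except the optional directives
#' `#parent_high=<sample>` and `#parent_low=<sample>` which name parental
#' samples in the VCF. Function arguments override file directives.
#'
#' @param path Path to the design TSV.
#' @inheritParams bulk_design
#' @return A `gps_design` tibble (see [bulk_design()]).
#' @export
read_bulk_design <- function(path, parent_high = NULL, parent_low = NULL) {
  if (!file.exists(path)) abort(sprintf("Design file not found: %s", path))
  lines <- readLines(path)
  dir_high <- sub("^#parent_high=", "", grep("^#parent_high=", lines, value = TRUE))
  dir_low <- sub("^#parent_low=", "", grep("^#parent_low=", lines, value = TRUE))
  tab <- readr::read_tsv(I(lines), comment = "#", show_col_types = FALSE)
  need <- c("grade", "sample", "n")
  if (!all(need %in% names(tab))) {
    abort("Design file needs columns: grade, sample, n.")
  }
  bulk_design(
    grade = tab$grade, sample = tab$sample, n = tab$n,
    parent_high = parent_high %||% (if (length(dir_high)) dir_high[[1]]),
    parent_low = parent_low %||% (if (length(dir_low)) dir_low[[1]])
  )
}

#' Write a bulk design to a tab-separated file
#'
#' @param design A `gps_design` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulk_design <- function(design, path) {
  hdr <- character()
  if (!is.null(attr(design, "parent_high"))) {
    hdr <- c(
      sprintf("#parent_high=%s", attr(design, "parent_high")),
      sprintf("#parent_low=%s", attr(design, "parent_low"))
    )
  }
  writeLines(c(hdr, "grade\tsample\tn",
               sprintf("%d\t%s\t%d", design$grade, design$sample, design$n)),
             path)
  invisible(path)
}

#' Share of each bulk in the total population
#'
#' @param design A `gps_design` tibble.
#' @return Tibble with `grade`, `n` and `share_pct` (percentage of all pooled
#'   individuals, two decimals).
#' @examples
#' # three grain-weight pools of 351/348/347 plants: largest holds 33.56%
#' bulk_shares(bulk_design(1:3, c("G1", "G2", "G3"), c(351, 348, 347)))
#' @export
bulk_shares <- function(design) {
  tibble::tibble(
    grade = design$grade,
    n = design$n,
    share_pct = round(100 * design$n / sum(design$n), 2)
  )
}

design_k <- function(design) nrow(design)

design_has_parents <- function(design) !is.null(attr(design, "parent_high"))
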
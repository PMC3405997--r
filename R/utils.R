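#' Percentage of a count, rounded to one decimal
#'
#' The reporting convention used throughout the package: fractions of sites,
#' reads or regions are printed on the 0-100 scale at one-decimal precision
#' (e.g. 1832 of 3683 X-chromosome MREs occupied -> 49.7).
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#'   Vectorised.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percent_of(1832, 3683)
#' percent_of(17591247, 29495696)
#' @export
percent_of <- function(numerator, denominator, digits = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "mslscreen_bad_denominator")
  }
  round(100 * numerator / denominator, digits)
}

# internal: validate a single positive scalar
check_scalar <- function(x, name, min = NULL, max = NULL, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single number."),
      class = "mslscreen_invalid_config")
  }
  if (integerish && x != round(x)) {
    abort(paste0("`", name, "` must be a whole number."),
      class = "mslscreen_invalid_config")
  }
  if (!is.null(min) && x < min) {
    abort(paste0("`", name, "` must be >= ", min, "."),
      class = "mslscreen_invalid_config")
  }
  if (!is.null(max) && x > max) {
    abort(paste0("`", name, "` must be <= ", max, "."),
      class = "mslscreen_invalid_config")
  }
  invisible(x)
}

# internal: required columns check with a friendly error
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")),
      class = "mslscreen_missing_columns")
  }
  invisible(df)
}

# internal: reverse complement of ACGTN character strings (vectorised)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
      collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# internal: tibble of intervals -> GRanges (BED convention: 0-based half-open)
intervals_to_granges <- function(df, what = "intervals") {
  check_columns(df, c("chrom", "start", "end"), what)
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    abort(paste0(what, " must satisfy 0 <= start < end."),
      class = "mslscreen_invalid_interval")
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
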
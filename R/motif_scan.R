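#' Toy position weight matrix for a GA-rich 21-mer MRE
#'
#' The MSL recognition element is a GA-rich ~21-bp motif. This constructor
#' returns a simple probability PWM concentrated on alternating GA with
#' modest degeneracy, suitable for simulations and tests; real analyses
#' should supply the published PWM via [read_pwm()].
#'
#' @param width Motif width (default 21).
#' @param ga_weight Probability mass on the favoured base at each position
#'   (default 0.7; the remainder is spread over the other three bases).
#' @return A `width` x 4 probability matrix with columns `A,C,G,T`.
#' @export
mre_pwm <- function(width = 21, ga_weight = 0.7) {
  check_scalar(width, "width", min = 1, integerish = TRUE)
  check_scalar(ga_weight, "ga_weight", min = 0.25, max = 1)
  rest <- (1 - ga_weight) / 3
  pwm <- matrix(rest, nrow = width, ncol = 4,
    dimnames = list(NULL, c("A", "C", "G", "T")))
  favoured <- rep(c("G", "A"), length.out = width)
  pwm[cbind(seq_len(width), match(favoured, colnames(pwm)))] <- ga_weight
  pwm
}

#' Read a PWM from a tab-delimited position x {A,C,G,T} table
#'
#' @param path TSV with columns `A`, `C`, `G`, `T`, one row per motif
#'   position; probabilities or counts (rows are renormalised to sum to 1).
#' @return A probability matrix as used by [scan_mres()].
#' @export
read_pwm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("A", "C", "G", "T"), "PWM file")
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(m < 0)) abort("PWM entries must be non-negative.",
    class = "mslscreen_invalid_pwm")
  sweep(m, 1, rowSums(m), "/")
}

# internal: probability PWM -> log2-odds against a background distribution
pwm_log_odds <- function(pwm, background = c(A = 0.25, C = 0.25, G = 0.25,
                                             T = 0.25), eps = 1e-6) {
  log2(sweep(pwm + eps, 2, background[colnames(pwm)] + eps, "/"))
}

#' Scan sequences for MRE motif matches above a log-odds threshold
#'
#' Every window on both strands whose log2-odds score (motif probability
#' over a uniform background) reaches `threshold` is reported. Windows
#' containing `N` are skipped. A reverse-strand match is reported at the
#' forward-strand coordinates of the window it covers, so the same
#' position can appear twice (once per strand); set `dedup = TRUE` to
#' keep only the best-scoring strand per window.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param pwm Probability PWM (positions x `A,C,G,T`), e.g. [mre_pwm()].
#' @param threshold Log2-odds score threshold; matches score `>= threshold`.
#' @param background Named base frequencies for the log-odds null
#'   (default uniform).
#' @param dedup Collapse opposite-strand matches at the same window,
#'   keeping the higher score (default `FALSE`).
#' @return Tibble `chrom, start, end, name, score, strand` (BED
#'   convention, 0-based half-open) sorted by `(chrom, start)`.
#' @examples
#' set.seed(1)
#' bg <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
#' consensus <- paste(rep(c("G", "A"), length.out = 21), collapse = "")
#' genome <- c(chr1 = paste0(substr(bg, 1, 200), consensus,
#'   substr(bg, 222, 500)))
#' scan_mres(genome, mre_pwm(), threshold = 25)
#' @export
scan_mres <- function(genome, pwm, threshold,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      dedup = FALSE) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) {
    abort("`genome` sequences must be named by chromosome.",
      class = "mslscreen_invalid_sequence")
  }
  if (!is.matrix(pwm) || ncol(pwm) != 4 ||
      !all(c("A", "C", "G", "T") %in% colnames(pwm))) {
    abort("`pwm` must be a positions x {A,C,G,T} matrix.",
      class = "mslscreen_invalid_pwm")
  }
  check_scalar(threshold, "threshold")
  w <- nrow(pwm)
  lo_fwd <- pwm_log_odds(pwm, background)[, c("A", "C", "G", "T")]
  # a reverse-strand match of the motif == forward match of the
  # reverse-complemented PWM
  lo_rev <- lo_fwd[rev(seq_len(w)), c("T", "G", "C", "A")]
  colnames(lo_rev) <- c("A", "C", "G", "T")

  scan_one <- function(seq, chrom) {
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq)) {
      abort(paste0("sequence '", chrom, "' contains letters outside ",
        "{A,C,G,T,N}."), class = "mslscreen_invalid_sequence")
    }
    n <- nchar(seq) - w + 1
    if (n < 1) return(tibble())
    code <- match(strsplit(seq, "", fixed = TRUE)[[1]],
      c("A", "C", "G", "T"))  # N -> NA
    score_fwd <- numeric(n)
    score_rev <- numeric(n)
    for (j in seq_len(w)) {
      b <- code[j:(j + n - 1)]
      score_fwd <- score_fwd + unname(lo_fwd[j, ])[b]
      score_rev <- score_rev + unname(lo_rev[j, ])[b]
    }
    # NA propagates from N-containing windows; those are skipped
    hits_f <- which(!is.na(score_fwd) & score_fwd >= threshold)
    hits_r <- which(!is.na(score_rev) & score_rev >= threshold)
    out <- bind_rows(
      tibble(start = hits_f - 1L, score = score_fwd[hits_f], strand = "+"),
      tibble(start = hits_r - 1L, score = score_rev[hits_r], strand = "-")
    )
    if (!nrow(out)) return(tibble())
    out <- mutate(out, chrom = chrom, end = .data$start + w)
    if (dedup) {
      out <- out |>
        group_by(.data$start) |>
        slice_max(.data$score, n = 1, with_ties = FALSE) |>
        ungroup()
    }
    out
  }
  res <- imap(as.list(genome), scan_one) |> list_rbind()
  if (!nrow(res)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
      name = character(), score = numeric(), strand = character()))
  }
  res |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(name = sprintf("mre_%05d", row_number())) |>
    select("chrom", "start", "end", "name", "score", "strand")
}
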
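#' Read a BED file into an interval tibble
#'
#' BED is 0-based half-open; so are all interval tibbles in this package,
#' so coordinates pass through unchanged.
#'
#' @param path BED3/BED6 file.
#' @return Tibble `chrom, start, end` plus `name`, `score`, `strand` when
#'   present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) out$strand <- strand
  out
}

#' Write an interval tibble as BED
#'
#' @param intervals Tibble `chrom, start, end` (+ optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  gr <- intervals_to_granges(intervals, "`intervals`")
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  if ("score" %in% names(intervals)) gr$score <- intervals$score
  if ("strand" %in% names(intervals)) {
    GenomicRanges::strand(gr) <- intervals$strand
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read read 5'-positions from a two-column TSV or a BED file
#'
#' @param path Either a headerless two-column TSV `chrom, pos` (0-based 5'
#'   positions) or a BED file (the interval start is taken as the 5'
#'   position).
#' @return Tibble `chrom, pos`.
#' @export
read_positions <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    bed <- read_bed(path)
    return(tibble(chrom = bed$chrom, pos = bed$start))
  }
  df <- readr::read_tsv(path, col_names = c("chrom", "pos"),
    col_types = "ci", show_col_types = FALSE)
  as_tibble(df)
}

#' Write read 5'-positions as a two-column TSV
#'
#' @param reads Tibble `chrom, pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(reads, path) {
  check_columns(reads, c("chrom", "pos"), "`reads`")
  readr::write_tsv(reads[, c("chrom", "pos")], path, col_names = FALSE)
  invisible(path)
}

#' Read transcript or genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
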
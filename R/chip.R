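#' qPCR ChIP enrichment normalised to input and a control locus
#'
#' Standard ChIP-qPCR quantification: the IP/input quantity ratio at each
#' target locus is divided by the same ratio at a non-transcribed internal
#' control locus, cancelling IP efficiency and input loading differences
#' between chromatin preparations.
#'
#' @param quants Tibble with columns `locus_id`, `sample` (`ip`|`input`),
#'   `antibody`, `quantity` (positive qPCR units).
#' @param control_locus Locus id of the internal control (e.g. a
#'   non-transcribed gene such as CG15570).
#' @return Tibble `antibody, locus_id, fold_enrichment` for every
#'   non-control locus with both IP and input measurements.
#' @examples
#' q <- tibble::tibble(
#'   locus_id = rep(c("CES5C2", "ctrl"), each = 2),
#'   sample = rep(c("ip", "input"), 2),
#'   antibody = "MSL2",
#'   quantity = c(12, 3, 5, 5))
#' qpcr_enrichment(q, "ctrl")  # (12/3)/(5/5) = 4
#' @export
qpcr_enrichment <- function(quants, control_locus) {
  quants <- as_tibble(quants)
  check_columns(quants, c("locus_id", "sample", "antibody", "quantity"),
    "`quants`")
  if (any(!quants$sample %in% c("ip", "input"))) {
    abort("`sample` must be 'ip' or 'input'.", class = "mslscreen_invalid_sample")
  }
  if (any(!is.finite(quants$quantity) | quants$quantity <= 0)) {
    abort("all qPCR quantities must be positive.", class = "nonpositive_quantity")
  }
  wide <- quants |>
    group_by(.data$antibody, .data$locus_id, .data$sample) |>
    summarise(quantity = mean(.data$quantity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "quantity")
  if (!all(c("ip", "input") %in% names(wide)) ||
      any(is.na(wide$ip) | is.na(wide$input))) {
    abort("every locus needs both an 'ip' and an 'input' quantity.",
      class = "mslscreen_missing_pair")
  }
  ctrl <- filter(wide, .data$locus_id == control_locus)
  if (!nrow(ctrl)) {
    abort(paste0("control locus '", control_locus, "' not found."),
      class = "mslscreen_missing_control_locus")
  }
  ctrl <- mutate(ctrl, ctrl_ratio = .data$ip / .data$input) |>
    select("antibody", "ctrl_ratio")
  wide |>
    filter(.data$locus_id != control_locus) |>
    left_join(ctrl, by = "antibody") |>
    mutate(fold_enrichment = (.data$ip / .data$input) / .data$ctrl_ratio) |>
    select("antibody", "locus_id", "fold_enrichment") |>
    arrange(.data$antibody, .data$locus_id)
}

#' Normalise H4K16ac enrichment to histone H3 occupancy
#'
#' Acetylation signal scales with nucleosome density, so H4K16ac fold
#' enrichment is divided by the H3 fold enrichment at the same locus to
#' obtain per-nucleosome acetylation.
#'
#' @param h4k16_fold,h3_fold Fold-enrichment values (vectorised);
#'   `h3_fold` must be positive.
#' @return `h4k16_fold / h3_fold`.
#' @examples
#' h3_normalized_enrichment(6, 2)
#' @export
h3_normalized_enrichment <- function(h4k16_fold, h3_fold) {
  if (any(!is.finite(h3_fold) | h3_fold <= 0)) {
    abort("`h3_fold` must be positive.", class = "nonpositive_quantity")
  }
  if (any(h4k16_fold < 0, na.rm = TRUE)) {
    abort("`h4k16_fold` must be non-negative.", class = "nonpositive_quantity")
  }
  h4k16_fold / h3_fold
}

#' Binned log2(IP/input) coverage track from read positions
#'
#' Reads (5' positions, 0-based) are counted in non-overlapping half-open
#' bins `[i*b, (i+1)*b)`; the final partial bin is kept. Per bin the value
#' is `log2(((ip + p)/IP_total) / ((input + p)/Input_total))` with
#' pseudocount `p` added before library-size scaling, so values are finite
#' for any bin when `p > 0`.
#'
#' @param ip,input Read-position tibbles `chrom, pos` (0-based 5' ends).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 200).
#' @param pseudocount Added to each bin count before scaling (default 1;
#'   0 gives exact library-size invariance but infinite values in empty
#'   bins).
#' @return A `coverage_track` tibble `chrom, bin_start, bin_end, ip_count,
#'   input_count, log2_ratio`, with attributes `bin_size` and
#'   `library_sizes`.
#' @export
binned_log2_track <- function(ip, input, chrom_lengths, bin_size = 200,
                              pseudocount = 1) {
  check_scalar(bin_size, "bin_size", min = 1, integerish = TRUE)
  check_scalar(pseudocount, "pseudocount", min = 0)
  if (is.null(names(chrom_lengths))) {
    abort("`chrom_lengths` must be named.", class = "mslscreen_invalid_config")
  }
  counts <- function(reads, label) {
    reads <- as_tibble(reads)
    check_columns(reads, c("chrom", "pos"), paste0("`", label, "`"))
    bad_chrom <- !reads$chrom %in% names(chrom_lengths)
    bad_pos <- !bad_chrom &
      (reads$pos < 0 | reads$pos >= chrom_lengths[reads$chrom])
    if (any(bad_chrom | bad_pos)) {
      off <- reads[bad_chrom | bad_pos, ]
      abort(paste0(label, " has ", nrow(off), " read(s) outside chromosome ",
        "bounds, e.g. ", off$chrom[1], ":", off$pos[1]),
        class = "mslscreen_position_out_of_bounds")
    }
    reads
  }
  ip <- counts(ip, "ip")
  input <- counts(input, "input")
  lib <- c(ip = nrow(ip), input = nrow(input))

  bins <- imap(as.list(chrom_lengths), function(len, ch) {
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1L) * bin_size
    tibble(chrom = ch, bin_start = starts,
      bin_end = pmin(starts + bin_size, len))
  }) |> list_rbind()

  bin_counts <- function(reads) {
    if (!nrow(reads)) return(integer(nrow(bins)))
    key <- paste(reads$chrom, reads$pos %/% bin_size)
    tab <- table(key)
    out <- as.integer(tab[paste(bins$chrom, bins$bin_start %/% bin_size)])
    out[is.na(out)] <- 0L
    out
  }
  bins$ip_count <- bin_counts(ip)
  bins$input_count <- bin_counts(input)
  p <- pseudocount
  bins$log2_ratio <- log2(((bins$ip_count + p) / max(lib[["ip"]], 1)) /
    ((bins$input_count + p) / max(lib[["input"]], 1)))
  structure(bins, class = c("coverage_track", class(bins)),
    bin_size = bin_size, library_sizes = lib, pseudocount = p)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track` from [binned_log2_track()].
#' @param path Output path.
#' @param value Column to write as the bedGraph score (default
#'   `"log2_ratio"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "log2_ratio") {
  check_columns(track, c("chrom", "bin_start", "bin_end", value), "`track`")
  gr <- GenomicRanges::GRanges(track$chrom,
    IRanges::IRanges(track$bin_start + 1L, track$bin_end))
  gr$score <- track[[value]]
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}
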
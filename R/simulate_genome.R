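#' Configuration for the toy-genome simulator
#'
#' Describes a miniature genome for testing the occupancy analyses: an X
#' chromosome and at least one autosome, planted GA-rich motif instances
#' (MREs), a designated subset of X-chromosome MREs acting as chromatin
#' entry sites (CES), binding-site peaks planted over MREs with
#' class-dependent probabilities, and IP/input read positions with the IP
#' density elevated inside peaks.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   must include `"X"` and at least one other (autosome) name.
#' @param n_mres_per_chrom MREs planted per chromosome (non-overlapping,
#'   uniform random positions).
#' @param mre_length Motif length in bp (default 21).
#' @param n_ces Number of X-chromosome MREs designated CES; each CES
#'   interval is the MRE expanded by `ces_pad` on both sides.
#' @param p_peak_given_ces Probability a CES MRE is covered by a planted
#'   peak.
#' @param p_peak_given_bg Background peak probability for non-CES MREs;
#'   either a single value or a named vector with elements `X` and `aut`.
#' @param reads_per_sample Read positions emitted for each of IP and input.
#' @param peak_read_enrichment Fold excess of IP read density inside peaks
#'   (>= 1; 1 gives a null IP indistinguishable from input).
#' @param peak_halfwidth Peak half-width in bp around the MRE midpoint
#'   (default 250).
#' @param ces_pad CES padding in bp around the CES MRE (default 100).
#' @param seed Integer seed.
#' @return A validated `genome_sim_config` list.
#' @seealso [simulate_genome()]
#' @export
genome_sim_config <- function(chrom_lengths = c(X = 1e6, `2L` = 1e6),
                              n_mres_per_chrom = 300,
                              mre_length = 21,
                              n_ces = 50,
                              p_peak_given_ces = 0.985,
                              p_peak_given_bg = c(X = 0.35, aut = 0.32),
                              reads_per_sample = 5e4,
                              peak_read_enrichment = 8,
                              peak_halfwidth = 250,
                              ces_pad = 100,
                              seed = 1L) {
  if (is.null(names(chrom_lengths)) || !"X" %in% names(chrom_lengths) ||
      length(chrom_lengths) < 2) {
    abort("`chrom_lengths` must be named and include \"X\" and an autosome.",
      class = "mslscreen_invalid_config")
  }
  check_scalar(n_mres_per_chrom, "n_mres_per_chrom", min = 1, integerish = TRUE)
  check_scalar(mre_length, "mre_length", min = 1, integerish = TRUE)
  check_scalar(n_ces, "n_ces", min = 0, integerish = TRUE)
  if (n_ces > n_mres_per_chrom) {
    abort("`n_ces` must be <= the number of MREs on X.",
      class = "mslscreen_invalid_config")
  }
  check_scalar(p_peak_given_ces, "p_peak_given_ces", min = 0, max = 1)
  if (!all(p_peak_given_bg >= 0 & p_peak_given_bg <= 1)) {
    abort("`p_peak_given_bg` must lie in [0, 1].",
      class = "mslscreen_invalid_config")
  }
  if (length(p_peak_given_bg) == 1L && is.null(names(p_peak_given_bg))) {
    p_peak_given_bg <- c(X = unname(p_peak_given_bg), aut = unname(p_peak_given_bg))
  }
  if (!all(c("X", "aut") %in% names(p_peak_given_bg))) {
    abort("`p_peak_given_bg` must be a single value or named c(X=, aut=).",
      class = "mslscreen_invalid_config")
  }
  check_scalar(reads_per_sample, "reads_per_sample", min = 1, integerish = TRUE)
  check_scalar(peak_read_enrichment, "peak_read_enrichment", min = 1)
  check_scalar(peak_halfwidth, "peak_halfwidth", min = 1, integerish = TRUE)
  check_scalar(ces_pad, "ces_pad", min = 0, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(
    list(
      chrom_lengths = chrom_lengths,
      n_mres_per_chrom = as.integer(n_mres_per_chrom),
      mre_length = as.integer(mre_length),
      n_ces = as.integer(n_ces),
      p_peak_given_ces = p_peak_given_ces,
      p_peak_given_bg = p_peak_given_bg,
      reads_per_sample = as.integer(reads_per_sample),
      peak_read_enrichment = peak_read_enrichment,
      peak_halfwidth = as.integer(peak_halfwidth),
      ces_pad = as.integer(ces_pad),
      seed = as.integer(seed)
    ),
    class = "genome_sim_config"
  )
}

# internal: place n non-overlapping intervals of width w uniformly in [0, len)
place_nonoverlapping <- function(n, w, len, chrom) {
  slack <- len - n * w
  if (slack < 0) {
    abort(sprintf("cannot place %d non-overlapping %d-bp MREs on %s (%g bp)",
      n, w, chrom, len), class = "mslscreen_placement_error")
  }
  # classic stars-and-bars: drop n points into the slack, then re-inflate
  gaps <- sort(sample.int(slack + 1, n, replace = TRUE) - 1L)
  starts <- gaps + (seq_len(n) - 1L) * w
  tibble(chrom = chrom, start = starts, end = starts + w)
}

#' Simulate a toy genome with planted MREs, CES, peaks, and reads
#'
#' MREs are placed non-overlapping at uniform random positions on each
#' chromosome and given a motif score drawn independently of CES status
#' (sequence alone does not predict which MREs are utilised). A random
#' subset of X-chromosome MREs becomes CES. Peaks are planted over MREs
#' with probability `p_peak_given_ces` (CES) or `p_peak_given_bg`
#' (background, X vs autosome). IP reads are drawn with density elevated
#' `peak_read_enrichment`-fold inside peaks; input reads are uniform.
#'
#' @param cfg A [genome_sim_config()].
#' @return A list of class `genome_sim` with interval tibbles `mres`
#'   (`chrom,start,end,name,score,in_ces`), `ces`, `peaks`, read-position
#'   tibbles `ip` and `input` (`chrom,pos`), and a ground-truth list
#'   `truth` (`ces_sites`, `planted_peaks`, `covered_mres`, `config`).
#' @export
simulate_genome <- function(cfg) {
  if (!inherits(cfg, "genome_sim_config")) {
    abort("`cfg` must be created by genome_sim_config().",
      class = "mslscreen_invalid_config")
  }
  withr::with_seed(cfg$seed, {
    mres <- imap(as.list(cfg$chrom_lengths), function(len, chrom) {
      place_nonoverlapping(cfg$n_mres_per_chrom, cfg$mre_length, len, chrom)
    }) |> list_rbind()
    mres <- mutate(mres,
      name = sprintf("mre_%04d", row_number()),
      score = rnorm(n(), mean = 10, sd = 2),
      in_ces = FALSE
    )

    ces_pick <- sample(which(mres$chrom == "X"), cfg$n_ces)
    mres$in_ces[ces_pick] <- TRUE
    ces <- mres[ces_pick, ] |>
      mutate(
        start = pmax(0, .data$start - cfg$ces_pad),
        end = pmin(cfg$chrom_lengths[["X"]], .data$end + cfg$ces_pad),
        name = sprintf("ces_%03d", row_number())
      ) |>
      select("chrom", "start", "end", "name") |>
      arrange(.data$start)

    p_peak <- case_when(
      mres$in_ces ~ cfg$p_peak_given_ces,
      mres$chrom == "X" ~ cfg$p_peak_given_bg[["X"]],
      TRUE ~ cfg$p_peak_given_bg[["aut"]]
    )
    has_peak <- runif(nrow(mres)) < p_peak
    mid <- (mres$start + mres$end) %/% 2
    peaks <- tibble(
      chrom = mres$chrom[has_peak],
      start = pmax(0, mid[has_peak] - cfg$peak_halfwidth),
      end = pmin(cfg$chrom_lengths[mres$chrom[has_peak]],
        mid[has_peak] + cfg$peak_halfwidth)
    ) |>
      mutate(name = sprintf("peak_%04d", row_number())) |>
      arrange(.data$chrom, .data$start)

    ip <- sample_reads(cfg$reads_per_sample, cfg$chrom_lengths, peaks,
      cfg$peak_read_enrichment)
    input <- sample_reads(cfg$reads_per_sample, cfg$chrom_lengths, peaks, 1)

    truth <- list(
      ces_sites = ces,
      planted_peaks = peaks,
      covered_mres = mres$name[has_peak],
      config = cfg
    )
    structure(
      list(mres = mres, ces = ces, peaks = peaks, ip = ip, input = input,
        truth = truth),
      class = "genome_sim"
    )
  })
}

# internal: sample read 5' positions with fold-elevated density inside peaks
sample_reads <- function(n, chrom_lengths, peaks, enrichment) {
  chroms <- names(chrom_lengths)
  peak_bp <- vapply(chroms, function(ch) {
    p <- peaks[peaks$chrom == ch, ]
    if (!nrow(p)) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(p$start + 1L, p$end))))
  }, numeric(1))
  weight <- unname(chrom_lengths) + (enrichment - 1) * peak_bp
  n_chrom <- as.vector(stats::rmultinom(1, n, weight))
  reads <- map(seq_along(chroms), function(i) {
    ch <- chroms[i]
    if (n_chrom[i] == 0L) {
      return(tibble(chrom = character(), pos = integer()))
    }
    p <- peaks[peaks$chrom == ch, ]
    ranges <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    p_in_peak <- enrichment * peak_bp[ch] / (chrom_lengths[[ch]] +
      (enrichment - 1) * peak_bp[ch])
    in_peak <- runif(n_chrom[i]) < p_in_peak
    pos <- integer(n_chrom[i])
    # background reads: uniform over the chromosome
    pos[!in_peak] <- sample.int(chrom_lengths[[ch]], sum(!in_peak),
      replace = TRUE) - 1L
    if (any(in_peak)) {
      # peak reads: uniform over the union of peak intervals
      offs <- sample.int(sum(IRanges::width(ranges)), sum(in_peak),
        replace = TRUE)
      cum <- cumsum(IRanges::width(ranges))
      which_range <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
      within <- offs - c(0L, cum)[which_range] - 1L
      pos[in_peak] <- IRanges::start(ranges)[which_range] - 1L + within
    }
    tibble(chrom = ch, pos = sort(pos))
  }) |> list_rbind()
  reads
}
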
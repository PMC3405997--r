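#' Fraction of MREs occupied by binding-site peaks
#'
#' An MRE is *occupied* when it overlaps at least one peak by >= 1 bp
#' (half-open BED intervals; an optional `max_gap` relaxes this to
#' proximity within that many bp). Fractions are reported per chromosome,
#' per site class, or overall, as counts plus a percentage on the 0-100
#' scale rounded to one decimal.
#'
#' @param mres Interval tibble `chrom, start, end` (+ optional `class_name`
#'   when `by = "class"`).
#' @param peaks Interval tibble `chrom, start, end`; may be empty.
#' @param by Grouping: `"chromosome"` (default), `"class"` (requires a
#'   `class_name` column), or `"all"`.
#' @param max_gap Maximum gap in bp still counted as occupied (default 0 =
#'   require a literal overlap).
#' @return Tibble `group, occupied, total, percent`.
#' @examples
#' mres <- tibble::tibble(chrom = "X", start = c(100, 300), end = c(121, 321))
#' peaks <- tibble::tibble(chrom = "X", start = 120, end = 200)
#' occupancy_fraction(mres, peaks)
#' @export
occupancy_fraction <- function(mres, peaks, by = c("chromosome", "class", "all"),
                               max_gap = 0) {
  by <- arg_match(by)
  check_scalar(max_gap, "max_gap", min = 0, integerish = TRUE)
  mres <- as_tibble(mres)
  occupied <- interval_overlaps_any(mres, peaks, max_gap)
  group <- switch(by,
    chromosome = as.character(mres$chrom),
    class = {
      check_columns(mres, "class_name", "`mres` (with by = \"class\")")
      as.character(mres$class_name)
    },
    all = rep("all", nrow(mres))
  )
  tibble(group = group, occupied = occupied) |>
    group_by(.data$group) |>
    summarise(occupied = sum(.data$occupied), total = n(), .groups = "drop") |>
    mutate(percent = percent_of(.data$occupied, .data$total)) |>
    arrange(.data$group)
}

#' Coverage of MRE-containing regions by peaks
#'
#' Same overlap rule as [occupancy_fraction()], collapsed to a single
#' count/total/percent row: used e.g. for "how many chromatin entry sites
#' have a binding site of factor X".
#'
#' @param regions Interval tibble `chrom, start, end`.
#' @param peaks Interval tibble; may be empty.
#' @param max_gap Maximum gap in bp still counted as covered (default 0).
#' @return One-row tibble `covered, total, percent`.
#' @export
ces_coverage <- function(regions, peaks, max_gap = 0) {
  hit <- interval_overlaps_any(as_tibble(regions), peaks, max_gap)
  n_hit <- sum(hit)
  n_total <- length(hit)
  tibble(
    covered = n_hit,
    total = n_total,
    percent = if (n_total) percent_of(n_hit, n_total) else NA_real_
  )
}

# internal: logical per query interval, TRUE if any subject within max_gap.
# max_gap = 0 demands a literal >=1 bp overlap (IRanges maxgap = -1).
interval_overlaps_any <- function(query, subject, max_gap = 0) {
  subject <- as_tibble(subject)
  if (!nrow(query)) return(logical())
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  q <- intervals_to_granges(query, "query intervals")
  s <- intervals_to_granges(subject, "subject intervals")
  IRanges::overlapsAny(q, s, maxgap = if (max_gap == 0) -1L else max_gap)
}

#' Build the five MRE site classes used for enrichment heatmaps
#'
#' Splits a scanned MRE set into the classes compared in occupancy
#' heatmaps: MREs inside chromatin entry sites; the `n` best-scoring
#' non-CES MREs on the X and on a reference autosome ("closest to the
#' consensus, but not utilised"); and `n` randomly chosen non-CES MREs
#' from each of those chromosomes.
#'
#' @param mres Tibble `chrom, start, end, name, score`.
#' @param ces_intervals Interval tibble of chromatin entry sites.
#' @param x_chrom,aut_chrom Chromosome names for the X and the reference
#'   autosome (defaults `"X"`, `"2L"`).
#' @param n Sites per best/random class (default 150); classes with fewer
#'   available sites are returned short with a warning.
#' @param seed Integer seed for the random classes.
#' @return Tibble of the input sites with `class_name` (`mre_in_ces`,
#'   `best_x`, `random_x`, `best_aut`, `random_aut`) and `in_ces` appended;
#'   one row per (site, class) membership.
#' @export
build_site_classes <- function(mres, ces_intervals, x_chrom = "X",
                               aut_chrom = "2L", n = 150, seed = 1L) {
  check_scalar(n, "n", min = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  mres <- as_tibble(mres)
  check_columns(mres, c("chrom", "start", "end", "score"), "`mres`")
  if (!"name" %in% names(mres)) {
    mres$name <- sprintf("mre_%05d", seq_len(nrow(mres)))
  }
  mres$in_ces <- interval_overlaps_any(mres, ces_intervals)

  take_best <- function(chrom, label) {
    pool <- mres |>
      filter(.data$chrom == !!chrom, !.data$in_ces) |>
      arrange(dplyr::desc(.data$score), .data$start)
    if (nrow(pool) < n) {
      warn(sprintf("class '%s': only %d of %d sites available.", label,
        nrow(pool), n))
    }
    mutate(head(pool, n), class_name = label)
  }
  take_random <- function(chrom, label) {
    pool <- filter(mres, .data$chrom == !!chrom, !.data$in_ces)
    if (nrow(pool) < n) {
      warn(sprintf("class '%s': only %d of %d sites available.", label,
        nrow(pool), n))
    }
    k <- min(n, nrow(pool))
    picked <- withr::with_seed(seed, sample(nrow(pool), k))
    mutate(pool[sort(picked), ], class_name = label)
  }

  bind_rows(
    mutate(filter(mres, .data$in_ces), class_name = "mre_in_ces"),
    take_best(x_chrom, "best_x"),
    take_random(x_chrom, "random_x"),
    take_best(aut_chrom, "best_aut"),
    take_random(aut_chrom, "random_aut")
  ) |>
    select("chrom", "start", "end", "name", "score", "in_ces", "class_name")
}

#' Sites x bins enrichment matrix around site midpoints
#'
#' For each site, the `+/-flank` region around the interval midpoint
#' (`floor((start+end)/2)`) is divided into non-overlapping `bin`-bp bins;
#' each cell is the length-weighted mean of the coverage-track value over
#' the bin. Bins extending beyond the chromosome (or on chromosomes absent
#' from the track) are `NA`, never zero, and are excluded from averages.
#'
#' @param track A `coverage_track` from [binned_log2_track()].
#' @param sites Interval tibble `chrom, start, end` (+ optional `name`,
#'   `class_name`); row order is preserved.
#' @param flank Half-window in bp (default 5000).
#' @param bin Output bin width in bp (default 200); `2*flank` must be a
#'   multiple of `bin`.
#' @param value Track column to average (default `"log2_ratio"`).
#' @return An `enrichment_matrix`: numeric matrix `|sites| x (2*flank/bin)`
#'   with sites as rownames, plus attributes `sites`, `flank`, `bin`,
#'   `bin_offsets` (bin start offsets relative to the midpoint).
#' @export
site_matrix <- function(track, sites, flank = 5000, bin = 200,
                        value = "log2_ratio") {
  check_scalar(flank, "flank", min = 1, integerish = TRUE)
  check_scalar(bin, "bin", min = 1, integerish = TRUE)
  if ((2 * flank) %% bin != 0) {
    abort("`2*flank` must be a multiple of `bin`.",
      class = "mslscreen_invalid_bins")
  }
  check_columns(track, c("chrom", "bin_start", "bin_end", value), "`track`")
  sites <- as_tibble(sites)
  check_columns(sites, c("chrom", "start", "end"), "`sites`")
  if (!"name" %in% names(sites)) {
    sites$name <- sprintf("site_%05d", seq_len(nrow(sites)))
  }
  n_bins <- as.integer(2 * flank / bin)
  offsets <- -flank + (seq_len(n_bins) - 1L) * bin

  track_chroms <- split(as_tibble(track)[, c("bin_start", "bin_end", value)],
    as.character(track$chrom))
  chrom_ends <- vapply(track_chroms, function(tc) max(tc$bin_end), numeric(1))

  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = n_bins,
    dimnames = list(sites$name, NULL))
  absent <- unique(as.character(sites$chrom[!sites$chrom %in%
    names(track_chroms)]))
  if (length(absent)) {
    warn(paste0("site chromosome(s) absent from track: ",
      paste(absent, collapse = ", "), "; rows are all-missing."))
  }
  for (i in seq_len(nrow(sites))) {
    ch <- as.character(sites$chrom[i])
    tc <- track_chroms[[ch]]
    if (is.null(tc)) next
    mid <- (sites$start[i] + sites$end[i]) %/% 2
    starts <- mid + offsets
    ends <- starts + bin
    inside <- starts >= 0 & ends <= chrom_ends[[ch]]
    if (!any(inside)) next
    # length-weighted mean of the step-function track over each output bin
    tr_ir <- IRanges::IRanges(tc$bin_start + 1L, tc$bin_end)
    q_ir <- IRanges::IRanges(starts[inside] + 1L, ends[inside])
    ov <- IRanges::findOverlaps(q_ir, tr_ir)
    if (length(ov)) {
      inter <- IRanges::pintersect(q_ir[S4Vectors::queryHits(ov)],
        tr_ir[S4Vectors::subjectHits(ov)])
      wsum <- tapply(IRanges::width(inter) *
        tc[[value]][S4Vectors::subjectHits(ov)],
        S4Vectors::queryHits(ov), sum)
      wlen <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      vals <- rep(NA_real_, sum(inside))
      idx <- as.integer(names(wsum))
      vals[idx] <- as.numeric(wsum) / as.numeric(wlen)
      mat[i, which(inside)] <- vals
    }
  }
  structure(mat, class = c("enrichment_matrix", "matrix", "array"),
    sites = sites, flank = flank, bin = bin, bin_offsets = offsets)
}

#' Missing-aware per-bin average profile of an enrichment matrix
#'
#' @param matrix An `enrichment_matrix` from [site_matrix()].
#' @return Tibble `bin, offset_start, mean, n` where `n` counts the
#'   non-missing sites per bin; all-missing bins have `mean = NA`.
#' @export
average_profile <- function(matrix) {
  if (!inherits(matrix, "enrichment_matrix")) {
    abort("`matrix` must come from site_matrix().",
      class = "mslscreen_invalid_matrix")
  }
  if (!nrow(matrix)) {
    abort("`matrix` has no rows.", class = "mslscreen_invalid_matrix")
  }
  n_ok <- colSums(!is.na(matrix))
  means <- suppressWarnings(colMeans(matrix, na.rm = TRUE))
  means[n_ok == 0] <- NA_real_
  tibble(
    bin = seq_len(ncol(matrix)),
    offset_start = attr(matrix, "bin_offsets"),
    mean = as.numeric(means),
    n = as.integer(n_ok)
  )
}

#' Long-format view of an enrichment matrix
#'
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @return Tibble `site, bin, offset_start, value` (+ `class_name` when
#'   the sites carried one).
#' @method tidy enrichment_matrix
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  sites <- attr(x, "sites")
  out <- tibble(
    site = rep(rownames(x), times = ncol(x)),
    bin = rep(seq_len(ncol(x)), each = nrow(x)),
    offset_start = rep(attr(x, "bin_offsets"), each = nrow(x)),
    value = as.numeric(x)
  )
  if (!is.null(sites) && "class_name" %in% names(sites)) {
    out$class_name <- rep(sites$class_name, times = ncol(x))
  }
  out
}

#' Heatmap of an enrichment matrix
#'
#' Rows are sites (input order, top to bottom), columns are bins across
#' the flanking window; the fill is the binned log2(IP/input) value.
#'
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_matrix
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  long <- tidy.enrichment_matrix(object)
  # rownames may repeat when a site belongs to several classes; plot rows
  # by position, labelled but not keyed by name
  long$row <- rep(seq_len(nrow(object)), times = ncol(object))
  long$site <- factor(long$row, levels = rev(seq_len(nrow(object))))
  p <- ggplot(long, aes(x = .data$offset_start + attr(object, "bin") / 2,
    y = .data$site, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
      midpoint = 0, na.value = "grey90") +
    labs(x = "distance from site midpoint (bp)", y = NULL,
      fill = "log2(IP/input)") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if ("class_name" %in% names(long)) {
    p <- p + facet_wrap(~class_name, scales = "free_y")
  }
  p
}

#' Average-profile line plot around site midpoints
#'
#' @param profile Tibble from [average_profile()], optionally with a
#'   `class_name` column for multiple overlaid classes.
#' @return A ggplot object.
#' @export
plot_average_profile <- function(profile) {
  check_columns(profile, c("offset_start", "mean"), "`profile`")
  aes_line <- if ("class_name" %in% names(profile)) {
    aes(x = .data$offset_start, y = .data$mean, colour = .data$class_name)
  } else {
    aes(x = .data$offset_start, y = .data$mean)
  }
  ggplot(profile, aes_line) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "distance from site midpoint (bp)", y = "mean log2(IP/input)",
      colour = NULL) +
    theme_minimal()
}
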
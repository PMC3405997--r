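#' Attach Firefly/Renilla ratios to a well table
#'
#' The screening statistic starts from the ratio of the MSL-dependent
#' Firefly reporter to the constitutive Renilla reporter in each well,
#' which cancels transfection-efficiency and cell-number differences.
#' Wells with non-positive Renilla cannot be normalised; they are flagged,
#' not dropped, and are excluded from all downstream statistics.
#'
#' @param wells Well tibble (`plate_id, replicate, well, amplicon_id, role,
#'   firefly, renilla`).
#' @return The input with columns `ratio`, `usable` (logical) and
#'   `flag_reason` (`NA` or `"renilla_nonpositive"`) appended.
#' @examples
#' compute_ratios(tibble::tibble(
#'   plate_id = "p1", replicate = 1L, well = "A03", amplicon_id = "a",
#'   role = "sample", firefly = 100, renilla = 50))
#' @export
compute_ratios <- function(wells) {
  wells <- as_tibble(wells)
  check_columns(wells, c("plate_id", "replicate", "well", "amplicon_id",
    "role", "firefly", "renilla"), "well table")
  if (any(wells$firefly < 0, na.rm = TRUE)) {
    abort("`firefly` must be non-negative.", class = "mslscreen_invalid_rlu")
  }
  mutate(wells,
    usable = !is.na(.data$renilla) & .data$renilla > 0,
    flag_reason = if_else(.data$usable, NA_character_, "renilla_nonpositive"),
    ratio = if_else(.data$usable, .data$firefly / .data$renilla, NA_real_)
  )
}

#' Per-plate QC statistics and control dynamic range
#'
#' For every plate x replicate, computes the median and standard deviation
#' of the Firefly/Renilla ratio over *sample* wells (controls are by design
#' extreme and would inflate the SD), the sample-well Renilla median used
#' by the viability filter, and the control dynamic range
#' `mean(neg_ctrl ratios) / mean(pos_ctrl ratios)`. A plate passes QC when
#' the dynamic range is at least `dynamic_range_min` (default 5-fold).
#'
#' @param wells Well tibble; ratios are computed with [compute_ratios()] if
#'   absent.
#' @param dynamic_range_min QC threshold on the control dynamic range.
#' @param robust_sd If `TRUE`, use the median absolute deviation (scaled to
#'   be consistent with the SD under normality) instead of the sample SD.
#' @return Tibble with one row per plate x replicate: `plate_id, replicate,
#'   median_ratio, sd_ratio, renilla_median, dynamic_range, n_sample_wells,
#'   qc_pass`.
#' @export
plate_qc <- function(wells, dynamic_range_min = 5, robust_sd = FALSE) {
  if (!"ratio" %in% names(wells)) wells <- compute_ratios(wells)
  usable <- filter(wells, .data$usable)
  ctrl_check <- usable |>
    group_by(.data$plate_id, .data$replicate) |>
    summarise(
      has_pos = any(.data$role == "pos_ctrl"),
      has_neg = any(.data$role == "neg_ctrl"),
      .groups = "drop"
    )
  if (any(!ctrl_check$has_pos | !ctrl_check$has_neg)) {
    bad <- ctrl_check[!ctrl_check$has_pos | !ctrl_check$has_neg, ]
    abort(paste0("plate(s) without usable control wells: ",
      paste(unique(bad$plate_id), collapse = ", ")),
      class = "controls_absent")
  }
  sd_fun <- if (robust_sd) function(x) stats::mad(x) else function(x) sd(x)
  usable |>
    group_by(.data$plate_id, .data$replicate) |>
    summarise(
      median_ratio = median(.data$ratio[.data$role == "sample"]),
      sd_ratio = sd_fun(.data$ratio[.data$role == "sample"]),
      renilla_median = median(.data$renilla[.data$role == "sample"]),
      dynamic_range = mean(.data$ratio[.data$role == "neg_ctrl"]) /
        mean(.data$ratio[.data$role == "pos_ctrl"]),
      n_sample_wells = sum(.data$role == "sample"),
      .groups = "drop"
    ) |>
    mutate(qc_pass = .data$dynamic_range >= dynamic_range_min)
}

#' Call screen hits from duplicate plates
#'
#' For each sample amplicon, the deviation on each replicate is
#' `(ratio - plate median) / plate SD`, computed against that replicate's
#' own plate statistics. An amplicon is a hit when the deviation exceeds
#' `k_sd` in magnitude on *both* replicates (strict inequality, "more than
#' two standard deviations"), by default with matching sign, and the well
#' is not excluded by the viability filter: a well is excluded when its
#' Renilla value falls more than `renilla_fold`-fold below the plate's
#' sample-well Renilla median on either replicate (such wells indicate
#' cell death or failed transfection rather than specific regulation).
#'
#' @param wells Well tibble covering both replicates of one or more plates.
#' @param k_sd Deviation threshold in plate-SD units (default 2).
#' @param renilla_fold Viability threshold: exclude wells with
#'   `renilla < renilla_median / renilla_fold` (default 3).
#' @param robust_sd Use MAD instead of SD for the plate scale.
#' @param require_matching_sign Require the two deviations to share a sign
#'   (default `TRUE`; a gene cannot be both activator and repressor).
#' @param enforce_qc Abort if any plate fails the 5-fold dynamic-range QC
#'   (default `TRUE`).
#' @return Tibble with one row per amplicon: `amplicon_id, plate_id,
#'   ratio_r1, ratio_r2, deviation_r1, deviation_r2, viability_excluded,
#'   unpaired, direction` (`decreased`/`increased`/`none`), `is_hit`.
#' @export
call_hits <- function(wells, k_sd = 2, renilla_fold = 3, robust_sd = FALSE,
                      require_matching_sign = TRUE, enforce_qc = TRUE) {
  check_scalar(k_sd, "k_sd", min = 0)
  check_scalar(renilla_fold, "renilla_fold", min = 1e-12)
  if (!"ratio" %in% names(wells)) wells <- compute_ratios(wells)
  qc <- plate_qc(wells, robust_sd = robust_sd)
  if (enforce_qc && any(!qc$qc_pass)) {
    bad <- unique(qc$plate_id[!qc$qc_pass])
    abort(paste0("plate(s) failing the dynamic-range QC: ",
      paste(bad, collapse = ", ")), class = "mslscreen_qc_fail")
  }

  samples <- wells |>
    filter(.data$role == "sample") |>
    left_join(qc, by = c("plate_id", "replicate"))

  # degenerate plates: zero SD with any well off the median is undefined
  degen <- samples$usable & samples$sd_ratio == 0 &
    samples$ratio != samples$median_ratio
  if (any(degen, na.rm = TRUE)) {
    abort(paste0("plate SD is zero but ratios deviate from the median on: ",
      paste(unique(samples$plate_id[which(degen)]), collapse = ", ")),
      class = "degenerate_plate_sd")
  }

  per_rep <- samples |>
    mutate(
      deviation = if_else(.data$usable & .data$sd_ratio > 0,
        (.data$ratio - .data$median_ratio) / .data$sd_ratio,
        if_else(.data$usable, 0, NA_real_)),
      low_renilla = .data$usable &
        .data$renilla < .data$renilla_median / renilla_fold
    ) |>
    select("amplicon_id", "plate_id", "replicate", "ratio", "deviation",
      "usable", "low_renilla")

  r1 <- filter(per_rep, .data$replicate == 1) |>
    rename(ratio_r1 = "ratio", deviation_r1 = "deviation",
      usable_r1 = "usable", low_renilla_r1 = "low_renilla") |>
    select(-"replicate")
  r2 <- filter(per_rep, .data$replicate == 2) |>
    rename(ratio_r2 = "ratio", deviation_r2 = "deviation",
      usable_r2 = "usable", low_renilla_r2 = "low_renilla") |>
    select(-"replicate")

  calls <- dplyr::full_join(r1, r2, by = c("amplicon_id", "plate_id")) |>
    mutate(
      unpaired = is.na(.data$usable_r1) | is.na(.data$usable_r2),
      viability_excluded = !.data$unpaired &
        (.data$low_renilla_r1 | .data$low_renilla_r2),
      both_usable = !.data$unpaired & .data$usable_r1 & .data$usable_r2,
      beyond = .data$both_usable &
        abs(.data$deviation_r1) > k_sd & abs(.data$deviation_r2) > k_sd,
      sign_match = .data$both_usable &
        sign(.data$deviation_r1) == sign(.data$deviation_r2),
      direction = case_when(
        beyond & sign_match & deviation_r1 < 0 ~ "decreased",
        beyond & sign_match & deviation_r1 > 0 ~ "increased",
        TRUE ~ "none"
      ),
      is_hit = .data$beyond &
        (!require_matching_sign | .data$sign_match) &
        !.data$viability_excluded
    ) |>
    select("amplicon_id", "plate_id", "ratio_r1", "ratio_r2",
      "deviation_r1", "deviation_r2", "viability_excluded", "unpaired",
      "direction", "is_hit") |>
    arrange(.data$plate_id, .data$amplicon_id)
  calls
}

#' Summarise a screen: directional hit counts and gene-level roll-up
#'
#' @param hits Hit-call tibble from [call_hits()].
#' @param amplicon_map Optional tibble `amplicon_id, gene_id`; amplicons
#'   without a mapping are rolled up under `"unannotated"` with a warning.
#' @return A `screen_summary` object; see [tidy.screen_summary()] for the
#'   gene table and [glance.screen_summary()] for one-row counts.
#' @export
summarize_screen <- function(hits, amplicon_map = NULL) {
  check_columns(hits, c("amplicon_id", "direction", "is_hit"), "hit table")
  hit_rows <- filter(hits, .data$is_hit)
  if (!is.null(amplicon_map)) {
    check_columns(amplicon_map, c("amplicon_id", "gene_id"), "`amplicon_map`")
    hit_rows <- left_join(hit_rows,
      distinct(as_tibble(amplicon_map), .data$amplicon_id, .data$gene_id),
      by = "amplicon_id")
    if (any(is.na(hit_rows$gene_id))) {
      warn(paste0(sum(is.na(hit_rows$gene_id)),
        " hit amplicon(s) lack a gene mapping; counted as 'unannotated'."))
      hit_rows$gene_id[is.na(hit_rows$gene_id)] <- "unannotated"
    }
  } else {
    hit_rows$gene_id <- hit_rows$amplicon_id
  }
  genes <- hit_rows |>
    group_by(.data$gene_id, .data$direction) |>
    summarise(
      n_supporting_amplicons = dplyr::n_distinct(.data$amplicon_id),
      amplicons = paste(sort(unique(.data$amplicon_id)), collapse = ","),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)
  structure(
    list(
      n_amplicons = nrow(hits),
      n_hits = nrow(hit_rows),
      n_decreased = sum(hit_rows$direction == "decreased"),
      n_increased = sum(hit_rows$direction == "increased"),
      n_viability_excluded = if ("viability_excluded" %in% names(hits))
        sum(hits$viability_excluded, na.rm = TRUE) else 0L,
      genes = genes
    ),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("RNAi screen summary\n")
  cat("  amplicons scored:     ", x$n_amplicons, "\n")
  cat("  hits:                 ", x$n_hits,
    sprintf(" (%d decreased, %d increased)", x$n_decreased, x$n_increased), "\n")
  cat("  viability-excluded:   ", x$n_viability_excluded, "\n")
  cat("  genes with >=1 hit:   ", nrow(x$genes), "\n")
  invisible(x)
}

#' Gene-level hit table of a screen summary
#'
#' @param x A `screen_summary`.
#' @param ... Unused.
#' @return Tibble `gene_id, direction, n_supporting_amplicons, amplicons`.
#' @method tidy screen_summary
#' @export
tidy.screen_summary <- function(x, ...) x$genes

#' One-row overview of a screen summary
#'
#' @param x A `screen_summary`.
#' @param ... Unused.
#' @method glance screen_summary
#' @export
glance.screen_summary <- function(x, ...) {
  tibble(
    n_amplicons = x$n_amplicons,
    n_hits = x$n_hits,
    n_decreased = x$n_decreased,
    n_increased = x$n_increased,
    n_viability_excluded = x$n_viability_excluded,
    n_genes = nrow(x$genes)
  )
}

#' Replicate-deviation scatter of hit calls
#'
#' Plots replicate-1 against replicate-2 deviations (in plate-SD units)
#' with the +/-`k_sd` decision boundaries; hits are coloured by direction.
#'
#' @param hits Hit-call tibble from [call_hits()].
#' @param k_sd Threshold drawn as guide lines (default 2).
#' @return A ggplot object.
#' @export
plot_screen_deviations <- function(hits, k_sd = 2) {
  check_columns(hits, c("deviation_r1", "deviation_r2", "is_hit", "direction"),
    "hit table")
  ggplot(filter(hits, !is.na(.data$deviation_r1) & !is.na(.data$deviation_r2)),
    aes(x = .data$deviation_r1, y = .data$deviation_r2,
      colour = if_else(.data$is_hit, .data$direction, "not a hit"))) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = c(-k_sd, k_sd), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-k_sd, k_sd), linetype = "dashed") +
    labs(x = "replicate 1 deviation (plate SD)",
      y = "replicate 2 deviation (plate SD)", colour = NULL) +
    theme_minimal()
}
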
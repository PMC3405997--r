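#' Configuration for the plate-screen simulator
#'
#' Describes a duplicate dual-luciferase RNAi screen: a set of 384-well
#' plates, each carrying positive-control wells (knockdown of the pathway
#' under study, strong Firefly suppression) and negative-control wells
#' (irrelevant dsRNA), sample wells with one dsRNA amplicon each, optional
#' spiked activator/repressor effects, and optional lethal wells in which
#' both reporters collapse together.
#'
#' Sample amplicons are labelled `amp_00001`, `amp_00002`, ... row-major
#' across plates; `spiked_hits` refers to these labels. Control wells occupy
#' the first `n_control_pos` positions of the first row (positive) and the
#' last `n_control_neg` positions of the last row (negative) of every plate,
#' and carry the shared reagent labels `msl2_dsRNA_*` / `gfp_dsRNA_*`.
#'
#' @param n_plates Number of plates (each assayed in duplicate).
#' @param wells_per_plate Wells per plate (default 384, a 16 x 24 grid).
#' @param n_control_pos,n_control_neg Positive / negative control wells per
#'   plate (default 2 each).
#' @param spiked_hits Tibble with columns `amplicon_id`, `effect_fold`:
#'   multiplicative effect on Firefly. `effect_fold < 1` emulates knocking
#'   down an activator of the reporter, `> 1` a repressor.
#' @param lethal_fraction Proportion of (non-spiked) sample wells in which an
#'   RNAi reagent kills the cells; both reporters are scaled by a shared
#'   factor drawn in (0, 1/3), so the ratio is preserved but Renilla drops
#'   more than three-fold below the plate centre.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise applied independently to each reporter.
#' @param plate_scale_sd SD (log scale) of per-plate, per-replicate,
#'   per-reporter multiplicative scaling; emulates day/batch luminescence
#'   drift, so the baseline ratio differs between plates.
#' @param baseline_ratio Expected Firefly/Renilla ratio of an unperturbed
#'   sample well. Arbitrary units; see the methods vignette.
#' @param renilla_center Expected Renilla RLU of a healthy well.
#' @param pos_ctrl_effect Firefly fold-change of the positive control
#'   (default 0.1, i.e. ten-fold suppression, comfortably beyond the
#'   five-fold dynamic range a plate must show to pass QC).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A validated `screen_sim_config` list.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_plates,
                              wells_per_plate = 384,
                              n_control_pos = 2,
                              n_control_neg = 2,
                              spiked_hits = NULL,
                              lethal_fraction = 0,
                              noise_cv = 0.15,
                              plate_scale_sd = 0.1,
                              baseline_ratio = 3,
                              renilla_center = 1e4,
                              pos_ctrl_effect = 0.1,
                              seed = 1L) {
  check_scalar(n_plates, "n_plates", min = 1, integerish = TRUE)
  check_scalar(wells_per_plate, "wells_per_plate", min = 1, integerish = TRUE)
  check_scalar(n_control_pos, "n_control_pos", min = 1, integerish = TRUE)
  check_scalar(n_control_neg, "n_control_neg", min = 1, integerish = TRUE)
  check_scalar(lethal_fraction, "lethal_fraction", min = 0)
  if (lethal_fraction >= 1) {
    abort("`lethal_fraction` must be < 1.", class = "mslscreen_invalid_config")
  }
  check_scalar(noise_cv, "noise_cv", min = 0)
  check_scalar(plate_scale_sd, "plate_scale_sd", min = 0)
  check_scalar(baseline_ratio, "baseline_ratio", min = 1e-12)
  check_scalar(renilla_center, "renilla_center", min = 1e-12)
  check_scalar(pos_ctrl_effect, "pos_ctrl_effect", min = 1e-12)
  check_scalar(seed, "seed", integerish = TRUE)
  if (wells_per_plate < n_control_pos + n_control_neg) {
    abort("`wells_per_plate` must be >= n_control_pos + n_control_neg.",
      class = "mslscreen_invalid_config")
  }
  if (!is.null(spiked_hits)) {
    spiked_hits <- as_tibble(spiked_hits)
    check_columns(spiked_hits, c("amplicon_id", "effect_fold"), "`spiked_hits`")
    if (any(spiked_hits$effect_fold <= 0)) {
      abort("`spiked_hits$effect_fold` must be > 0.",
        class = "mslscreen_invalid_config")
    }
    if (anyDuplicated(spiked_hits$amplicon_id)) {
      abort("`spiked_hits$amplicon_id` must be unique.",
        class = "mslscreen_invalid_config")
    }
  } else {
    spiked_hits <- tibble(amplicon_id = character(), effect_fold = numeric())
  }
  structure(
    list(
      n_plates = as.integer(n_plates),
      wells_per_plate = as.integer(wells_per_plate),
      n_control_pos = as.integer(n_control_pos),
      n_control_neg = as.integer(n_control_neg),
      spiked_hits = spiked_hits,
      lethal_fraction = lethal_fraction,
      noise_cv = noise_cv,
      plate_scale_sd = plate_scale_sd,
      baseline_ratio = baseline_ratio,
      renilla_center = renilla_center,
      pos_ctrl_effect = pos_ctrl_effect,
      seed = as.integer(seed)
    ),
    class = "screen_sim_config"
  )
}

# internal: row-major well labels ("A01", ..., "P24") for a plate
well_labels <- function(n_wells, n_cols = 24L) {
  n_rows <- ceiling(n_wells / n_cols)
  rows <- make.unique(rep(LETTERS, length.out = n_rows), sep = "")
  labs <- as.vector(t(outer(rows[seq_len(n_rows)], sprintf("%02d", seq_len(n_cols)),
    paste0)))
  labs[seq_len(n_wells)]
}

#' Simulate a duplicate dual-luciferase RNAi screen
#'
#' Draws Firefly and Renilla RLU values for every well of every plate in
#' both replicates under a multiplicative log-normal noise model (luminescence
#' is positive and right-skewed), with per-plate, per-reporter scaling,
#' spiked amplicon effects on Firefly, ten-fold Firefly suppression in the
#' positive-control wells, and lethal wells in which both reporters are
#' scaled by a shared factor below 1/3.
#'
#' @param cfg A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements
#'   * `wells`: tibble with columns `plate_id`, `replicate` (1|2), `well`,
#'     `amplicon_id`, `role` (`sample`|`pos_ctrl`|`neg_ctrl`), `firefly`,
#'     `renilla`;
#'   * `truth`: ground truth list with `true_hits` (tibble `amplicon_id`,
#'     `effect_fold`, `direction`), `lethal_wells` (tibble `plate_id`,
#'     `well`, `amplicon_id`), and the `config`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_plates = 1, seed = 7))
#' head(sim$wells)
#' @export
simulate_screen <- function(cfg) {
  if (!inherits(cfg, "screen_sim_config")) {
    abort("`cfg` must be created by screen_sim_config().",
      class = "mslscreen_invalid_config")
  }
  withr::with_seed(cfg$seed, {
    layout <- map(seq_len(cfg$n_plates), function(p) {
      labs <- well_labels(cfg$wells_per_plate)
      role <- rep("sample", cfg$wells_per_plate)
      role[seq_len(cfg$n_control_pos)] <- "pos_ctrl"
      role[cfg$wells_per_plate - seq_len(cfg$n_control_neg) + 1L] <- "neg_ctrl"
      tibble(
        plate_id = sprintf("plate_%02d", p),
        well = labs,
        role = role
      )
    }) |> list_rbind()

    n_samples <- sum(layout$role == "sample")
    layout$amplicon_id <- NA_character_
    layout$amplicon_id[layout$role == "sample"] <-
      sprintf("amp_%05d", seq_len(n_samples))
    layout$amplicon_id[layout$role == "pos_ctrl"] <-
      paste0("msl2_dsRNA_", ave(layout$role == "pos_ctrl", layout$plate_id,
        FUN = cumsum)[layout$role == "pos_ctrl"])
    layout$amplicon_id[layout$role == "neg_ctrl"] <-
      paste0("gfp_dsRNA_", ave(layout$role == "neg_ctrl", layout$plate_id,
        FUN = cumsum)[layout$role == "neg_ctrl"])

    unknown <- setdiff(cfg$spiked_hits$amplicon_id, layout$amplicon_id)
    if (length(unknown)) {
      abort(paste0("spiked amplicon(s) not present on any plate: ",
        paste(head(unknown, 5), collapse = ", ")),
        class = "mslscreen_invalid_config")
    }

    # lethal wells: sampled among non-spiked sample wells, lethal in both reps
    candidates <- which(layout$role == "sample" &
      !(layout$amplicon_id %in% cfg$spiked_hits$amplicon_id))
    n_lethal <- rbinom(1, length(candidates), cfg$lethal_fraction)
    lethal_idx <- sort(sample(candidates, n_lethal))
    lethal_wells <- layout[lethal_idx, c("plate_id", "well", "amplicon_id")]

    effect <- rep(1, nrow(layout))
    effect[layout$role == "pos_ctrl"] <- cfg$pos_ctrl_effect
    spike_match <- match(layout$amplicon_id, cfg$spiked_hits$amplicon_id)
    effect[!is.na(spike_match)] <-
      cfg$spiked_hits$effect_fold[spike_match[!is.na(spike_match)]]

    sigma <- sqrt(log(1 + cfg$noise_cv^2))
    plates <- unique(layout$plate_id)

    wells <- map(1:2, function(rep_i) {
      sf_f <- setNames(exp(rnorm(length(plates), 0, cfg$plate_scale_sd)), plates)
      sf_r <- setNames(exp(rnorm(length(plates), 0, cfg$plate_scale_sd)), plates)
      u <- rep(1, nrow(layout))
      u[lethal_idx] <- runif(length(lethal_idx), 0.01, 1 / 3)
      noise_f <- exp(rnorm(nrow(layout), 0, sigma))
      noise_r <- exp(rnorm(nrow(layout), 0, sigma))
      mutate(layout,
        replicate = rep_i,
        firefly = cfg$renilla_center * cfg$baseline_ratio * effect * u *
          sf_f[.data$plate_id] * noise_f,
        renilla = cfg$renilla_center * u * sf_r[.data$plate_id] * noise_r
      )
    }) |> list_rbind()

    wells <- select(wells, "plate_id", "replicate", "well", "amplicon_id",
      "role", "firefly", "renilla")

    truth <- list(
      true_hits = mutate(cfg$spiked_hits,
        direction = if_else(.data$effect_fold < 1, "decreased", "increased")),
      lethal_wells = as_tibble(lethal_wells),
      config = cfg
    )
    structure(list(wells = wells, truth = truth), class = "screen_sim")
  })
}

#' Write simulated plate readouts to CSV
#'
#' Emits the plate-readout schema consumed by [read_plate_csv()]:
#' `plate_id, replicate, well, amplicon_id, role, firefly, renilla`.
#'
#' @param sim A `screen_sim` object or a well tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(sim, path) {
  wells <- if (inherits(sim, "screen_sim")) sim$wells else as_tibble(sim)
  check_columns(wells, c("plate_id", "replicate", "well", "amplicon_id",
    "role", "firefly", "renilla"), "well table")
  readr::write_csv(wells, path)
  invisible(path)
}

#' Read a plate-readout CSV
#'
#' @param path CSV with columns `plate_id, replicate, well, amplicon_id,
#'   role, firefly, renilla`.
#' @return A well tibble.
#' @export
read_plate_csv <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      replicate = readr::col_integer(),
      well = readr::col_character(),
      amplicon_id = readr::col_character(),
      role = readr::col_character(),
      firefly = readr::col_double(),
      renilla = readr::col_double()
    ))
  check_columns(wells, c("plate_id", "replicate", "well", "amplicon_id",
    "role", "firefly", "renilla"), "plate CSV")
  bad <- setdiff(unique(wells$role), c("sample", "pos_ctrl", "neg_ctrl"))
  if (length(bad)) {
    abort(paste0("unknown role value(s): ", paste(bad, collapse = ", ")),
      class = "mslscreen_invalid_role")
  }
  wells
}
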
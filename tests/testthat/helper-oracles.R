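# Independent brute-force reimplementations used as oracles. These are kept
# deliberately naive (explicit loops, first-principles statistics) and do not
# share code with the package internals.

oracle_call_hits <- function(wells, k_sd = 2, renilla_fold = 3) {
  wells$ratio <- ifelse(wells$renilla > 0, wells$firefly / wells$renilla, NA)
  out <- list()
  for (plate in unique(wells$plate_id)) {
    stats <- list()
    for (rep_i in 1:2) {
      pw <- wells[wells$plate_id == plate & wells$replicate == rep_i &
        wells$role == "sample" & !is.na(wells$ratio), ]
      stats[[rep_i]] <- list(
        med = median(pw$ratio), sdev = sd(pw$ratio),
        ren_med = median(pw$renilla), wells = pw
      )
    }
    amps <- unique(wells$amplicon_id[wells$plate_id == plate &
      wells$role == "sample"])
    for (a in amps) {
      dev <- ren_low <- rep(NA, 2)
      for (rep_i in 1:2) {
        s <- stats[[rep_i]]
        row <- s$wells[s$wells$amplicon_id == a, ]
        if (nrow(row) == 1) {
          dev[rep_i] <- (row$ratio - s$med) / s$sdev
          ren_low[rep_i] <- row$renilla < s$ren_med / renilla_fold
        }
      }
      paired <- !any(is.na(dev))
      viab <- paired && any(ren_low)
      hit <- paired && !viab && abs(dev[1]) > k_sd && abs(dev[2]) > k_sd &&
        sign(dev[1]) == sign(dev[2])
      out[[length(out) + 1]] <- data.frame(
        amplicon_id = a, plate_id = plate,
        deviation_r1 = dev[1], deviation_r2 = dev[2],
        viability_excluded = viab, is_hit = hit
      )
    }
  }
  do.call(rbind, out)
}

oracle_off_targets <- function(dsrna, targets, transcriptome, k = 17) {
  rc <- function(s) chartr("ACGT", "TGCA",
    paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hits <- character()
  for (gene in names(transcriptome)) {
    tx <- transcriptome[[gene]]
    found <- FALSE
    for (query in c(dsrna, rc(dsrna))) {
      if (found) break
      if (nchar(query) < k) next
      for (i in seq_len(nchar(query) - k + 1)) {
        if (grepl(substr(query, i, i + k - 1), tx, fixed = TRUE)) {
          found <- TRUE
          break
        }
      }
    }
    if (found) hits <- c(hits, gene)
  }
  sort(setdiff(hits, targets))
}

oracle_occupied <- function(mres, peaks) {
  occ <- rep(FALSE, nrow(mres))
  for (i in seq_len(nrow(mres))) {
    for (j in seq_len(nrow(peaks))) {
      if (mres$chrom[i] == peaks$chrom[j] &&
          mres$start[i] < peaks$end[j] && peaks$start[j] < mres$end[i]) {
        occ[i] <- TRUE
        break
      }
    }
  }
  occ
}

oracle_scan <- function(seq, pwm, threshold) {
  lo <- log2((pwm + 1e-6) / (0.25 + 1e-6))
  w <- nrow(pwm)
  rc <- function(s) chartr("ACGT", "TGCA",
    paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_at <- function(s, i) {
    total <- 0
    for (j in 1:w) {
      base <- substr(s, i + j - 1, i + j - 1)
      if (!base %in% c("A", "C", "G", "T")) return(NA)
      total <- total + lo[j, base]
    }
    total
  }
  res <- list()
  for (i in seq_len(nchar(seq) - w + 1)) {
    sf <- score_at(seq, i)
    if (!is.na(sf) && sf >= threshold) {
      res[[length(res) + 1]] <- data.frame(start = i - 1, strand = "+",
        score = sf)
    }
    window_rc <- rc(substr(seq, i, i + w - 1))
    sr <- if (grepl("[^ACGT]", window_rc)) NA else score_at(window_rc, 1)
    if (!is.na(sr) && sr >= threshold) {
      res[[length(res) + 1]] <- data.frame(start = i - 1, strand = "-",
        score = sr)
    }
  }
  if (!length(res)) return(data.frame(start = integer(), strand = character(),
    score = numeric()))
  do.call(rbind, res)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny hand-buildable plate pair: `ratios` is a named vector per amplicon,
# shared by both replicates unless ratios2 given; controls appended
make_plate_pair <- function(ratios, ratios2 = ratios, renilla = 100,
                            plate_id = "p1",
                            neg_ratio = 10, pos_ratio = 1) {
  build <- function(r, rep_i, ren) {
    ren <- rep_len(ren, length(r))
    data.frame(
      plate_id = plate_id, replicate = rep_i,
      well = sprintf("A%02d", seq_along(r) + 2),
      amplicon_id = names(r), role = "sample",
      firefly = unname(r) * ren, renilla = ren
    )
  }
  ctrl <- function(rep_i) {
    data.frame(
      plate_id = plate_id, replicate = rep_i,
      well = c("A01", "A02", "P23", "P24"),
      amplicon_id = c("pos1", "pos2", "neg1", "neg2"),
      role = c("pos_ctrl", "pos_ctrl", "neg_ctrl", "neg_ctrl"),
      firefly = c(pos_ratio, pos_ratio, neg_ratio, neg_ratio) * 100,
      renilla = 100
    )
  }
  ren1 <- attr(ratios, "renilla") %||% renilla
  ren2 <- attr(ratios2, "renilla") %||% renilla
  rbind(build(ratios, 1, ren1), ctrl(1), build(ratios2, 2, ren2), ctrl(2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
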
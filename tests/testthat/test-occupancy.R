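consensus_21 <- paste(rep(c("G", "A"), length.out = 21), collapse = "")

test_that("a planted consensus motif is recovered at its exact position", {
  set.seed(3)
  bg <- random_dna(1000)
  genome <- c(chrT = paste0(substr(bg, 1, 400), consensus_21,
    substr(bg, 422, 1000)))
  pwm <- mre_pwm()
  consensus_score <- sum(log2((0.7 + 1e-6) / (0.25 + 1e-6)) * 21)
  hits <- scan_mres(genome, pwm, threshold = consensus_score - 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 400)
  expect_equal(hits$end, 421)
  expect_equal(hits$strand, "+")
  # a threshold above the maximum possible score yields nothing
  expect_equal(nrow(scan_mres(genome, pwm,
    threshold = consensus_score + 5)), 0)
  # N-containing windows are skipped, not scored
  genome_n <- c(chrT = paste0(substr(bg, 1, 400),
    sub("G", "N", consensus_21), substr(bg, 422, 1000)))
  expect_equal(nrow(scan_mres(genome_n, pwm,
    threshold = consensus_score - 1)), 0)
})

test_that("scanning equals exhaustive window scoring on random sequence", {
  set.seed(14)
  pwm <- mre_pwm(width = 8, ga_weight = 0.6)
  for (trial in 1:5) {
    seq <- random_dna(800)
    got <- scan_mres(c(z = seq), pwm, threshold = 6)
    want <- oracle_scan(seq, pwm, threshold = 6)
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("occupancy uses the half-open >=1 bp overlap rule", {
  mres <- tibble::tibble(chrom = "X", start = c(100, 100), end = c(121, 121))
  # peak starting at 120 overlaps [100,121); starting at 121 does not
  expect_equal(occupancy_fraction(mres[1, ],
    tibble::tibble(chrom = "X", start = 120, end = 200))$occupied, 1)
  expect_equal(occupancy_fraction(mres[1, ],
    tibble::tibble(chrom = "X", start = 121, end = 200))$occupied, 0)
  # empty peak set -> all fractions zero
  empty <- occupancy_fraction(mres, tibble::tibble(chrom = character(),
    start = integer(), end = integer()))
  expect_equal(empty$percent, 0)
  # max_gap relaxes to proximity
  expect_equal(occupancy_fraction(mres[1, ],
    tibble::tibble(chrom = "X", start = 140, end = 200),
    max_gap = 20)$occupied, 1)
})

test_that("fractions match the printed-count convention and the oracle", {
  # worked fractions at one-decimal rounding
  expect_equal(percent_of(1832, 3683), 49.7)
  expect_equal(percent_of(3787, 11619), 32.6)
  expect_equal(percent_of(135, 137), 98.5)
  expect_equal(percent_of(446, 484), 92.1)
  # toy 7 regions / 4 covered
  set.seed(10)
  regions <- tibble::tibble(chrom = "X", start = (0:6) * 100,
    end = (0:6) * 100 + 50)
  peaks <- tibble::tibble(chrom = "X", start = c(40, 140, 240, 340),
    end = c(60, 160, 260, 360))
  cov <- ces_coverage(regions, peaks)
  expect_equal(cov$covered, 4)
  expect_equal(cov$percent, 57.1)
  # random instances agree with the exhaustive pairwise oracle
  for (trial in 1:20) {
    mres <- tibble::tibble(chrom = sample(c("X", "2L"), 60, TRUE),
      start = sample.int(5000, 60)); mres$end <- mres$start + 21
    peaks <- tibble::tibble(chrom = sample(c("X", "2L"), 15, TRUE),
      start = sample.int(5000, 15)); peaks$end <- peaks$start +
        sample(50:300, 15, TRUE)
    frac <- occupancy_fraction(mres, peaks, by = "all")
    expect_equal(frac$occupied, sum(oracle_occupied(mres, peaks)))
  }
})

test_that("adding peaks never decreases any occupancy fraction", {
  set.seed(11)
  mres <- tibble::tibble(chrom = "X", start = sample.int(20000, 200))
  mres$end <- mres$start + 21
  peaks <- tibble::tibble(chrom = "X", start = sample.int(20000, 30))
  peaks$end <- peaks$start + 200
  f1 <- occupancy_fraction(mres, peaks[1:10, ], by = "all")
  f2 <- occupancy_fraction(mres, peaks, by = "all")
  expect_true(f2$percent >= f1$percent)
  expect_true(all(dplyr::between(c(f1$percent, f2$percent), 0, 100)))
})

test_that("site classes are disjoint from CES, seeded, and size-capped", {
  g <- simulate_genome(genome_sim_config(chrom_lengths = c(X = 5e5, `2L` = 5e5),
    n_mres_per_chrom = 250, n_ces = 40, reads_per_sample = 100, seed = 9))
  cls <- build_site_classes(g$mres, g$ces, n = 100, seed = 1)
  by_class <- split(cls$name, cls$class_name)
  expect_equal(sort(unique(cls$class_name)),
    sort(c("mre_in_ces", "best_x", "random_x", "best_aut", "random_aut")))
  for (cn in c("best_x", "random_x", "best_aut", "random_aut")) {
    expect_length(intersect(by_class$mre_in_ces, by_class[[cn]]), 0)
    expect_length(by_class[[cn]], 100)
  }
  expect_false(any(duplicated(by_class$random_x)))
  # best = top scores with coordinate tie-break; all non-CES X sites weaker
  best <- cls[cls$class_name == "best_x", ]
  pool <- g$mres[g$mres$chrom == "X" & !g$mres$name %in% by_class$mre_in_ces, ]
  expect_equal(sort(best$score, decreasing = TRUE),
    sort(pool$score, decreasing = TRUE)[1:100])
  # same seed reproduces the random classes; another seed changes them
  cls_b <- build_site_classes(g$mres, g$ces, n = 100, seed = 1)
  expect_identical(cls, cls_b)
  cls_c <- build_site_classes(g$mres, g$ces, n = 100, seed = 2)
  expect_false(identical(
    sort(cls$name[cls$class_name == "random_x"]),
    sort(cls_c$name[cls_c$class_name == "random_x"])))
  # degenerate: every MRE inside a CES -> best/random classes short + warned
  tiny <- g$mres[g$mres$in_ces, ][1:5, ]
  warns <- testthat::capture_warnings(
    short <- build_site_classes(tiny, g$ces, n = 10, seed = 1))
  expect_true(all(grepl("available", warns)))
  expect_length(warns, 4)
  expect_equal(nrow(short[short$class_name == "best_x", ]), 0)
})

test_that("site matrices have fixed geometry and honour chromosome ends", {
  lens <- c(X = 20000)
  set.seed(12)
  ip <- tibble::tibble(chrom = "X", pos = sample.int(20000, 2000, TRUE) - 1L)
  tr <- binned_log2_track(ip, ip, lens, bin_size = 200)
  # constant track (ip == input -> all zeros) gives a constant matrix
  sites <- tibble::tibble(chrom = "X", start = c(9990, 500),
    end = c(10011, 521), name = c("mid", "edge"))
  m <- site_matrix(tr, sites, flank = 5000, bin = 200)
  expect_equal(dim(m), c(2L, 50L))
  expect_true(all(m["mid", ] == 0))
  # the edge site has bins before position 0 marked missing, not zero
  expect_true(any(is.na(m["edge", ])))
  expect_equal(sum(is.na(m["edge", ])), sum(attr(m, "bin_offsets") + 510 < 0))
  # a site on a chromosome absent from the track is all-missing with warning
  expect_warning(m2 <- site_matrix(tr, tibble::tibble(chrom = "chrZ",
    start = 100, end = 121)), "absent")
  expect_true(all(is.na(m2)))
  expect_equal(dim(m2), c(1L, 50L))
})

test_that("average profiles are missing-aware column means", {
  lens <- c(X = 6000)
  tr <- binned_log2_track(
    tibble::tibble(chrom = "X", pos = c(100, 2100, 2150)),
    tibble::tibble(chrom = "X", pos = c(150, 4000, 5000)), lens,
    bin_size = 200)
  sites <- tibble::tibble(chrom = "X", start = c(2000, 210, 5990),
    end = c(2021, 231, 6000))
  m <- site_matrix(tr, sites, flank = 1000, bin = 200)
  prof <- average_profile(m)
  expect_equal(nrow(prof), 10)
  # brute-force column means ignoring NA
  want <- apply(unclass(m), 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) NA_real_ else mean(col[ok])
  })
  expect_equal(prof$mean, unname(want))
  expect_equal(prof$n, as.integer(colSums(!is.na(m))))
  # 2x2 example: [[1,3],[3,5]] -> [2,4]
  fake <- structure(matrix(c(1, 3, 3, 5), 2, 2),
    class = c("enrichment_matrix", "matrix", "array"),
    bin_offsets = c(-200, 0), sites = tibble::tibble(name = c("a", "b")))
  rownames(fake) <- c("a", "b")
  expect_equal(average_profile(fake)$mean, c(2, 4))
})

test_that("CES classes out-enrich background classes in simulated genomes", {
  g <- simulate_genome(genome_sim_config(chrom_lengths = c(X = 4e5, `2L` = 4e5),
    n_mres_per_chrom = 200, n_ces = 60, p_peak_given_ces = 0.985,
    p_peak_given_bg = c(X = 0.35, aut = 0.32), reads_per_sample = 4e4,
    peak_read_enrichment = 8, seed = 33))
  tr <- binned_log2_track(g$ip, g$input, g$truth$config$chrom_lengths)
  cls <- build_site_classes(g$mres, g$ces, n = 100, seed = 1)
  central_mean <- function(cn) {
    m <- site_matrix(tr, cls[cls$class_name == cn, ], flank = 1000, bin = 200)
    p <- average_profile(m)
    mean(p$mean[abs(p$offset_start + 100) <= 200], na.rm = TRUE)
  }
  ces_m <- central_mean("mre_in_ces")
  for (cn in c("best_x", "random_x", "best_aut", "random_aut")) {
    expect_gt(ces_m, central_mean(cn))
  }
})
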
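test_that("off-target prediction excludes the declared target and honours k", {
  set.seed(7)
  geneA <- random_dna(600)
  geneB <- random_dna(500)
  geneC <- random_dna(500)
  dsrna <- substr(geneA, 101, 400)
  amp <- tibble::tibble(amplicon_id = "a1", dsrna_sequence = dsrna,
    target_genes = list("geneA"))
  tx <- c(geneA = geneA, geneB = geneB, geneC = geneC)
  expect_equal(predict_off_targets(amp, tx)$off_target_genes[[1]], character(0))

  # plant a 17-mer of the dsRNA into geneB -> off-target; trim to 16 -> none
  frag17 <- substr(dsrna, 50, 66)
  tx17 <- tx
  tx17[["geneB"]] <- paste0(substr(geneB, 1, 200), frag17,
    substr(geneB, 201, 500))
  expect_equal(predict_off_targets(amp, tx17)$off_target_genes[[1]], "geneB")
  # guard bases prevent junction 17-mers from re-creating the trimmed k-mer
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  tx16 <- tx
  tx16[["geneB"]] <- paste0(substr(geneB, 1, 200),
    other(substr(dsrna, 49, 49)), substr(frag17, 1, 16),
    other(substr(dsrna, 66, 66)), substr(geneB, 201, 500))
  expect_equal(predict_off_targets(amp, tx16)$off_target_genes[[1]],
    character(0))

  # the reverse complement counts as sharing
  rc17 <- chartr("ACGT", "TGCA", paste(rev(strsplit(frag17, "")[[1]]),
    collapse = ""))
  txrc <- tx
  txrc[["geneC"]] <- paste0(substr(geneC, 1, 100), rc17, substr(geneC, 101, 500))
  expect_equal(predict_off_targets(amp, txrc)$off_target_genes[[1]], "geneC")

  expect_error(predict_off_targets(tibble::tibble(amplicon_id = "x",
    dsrna_sequence = NA_character_, target_genes = list("g")), tx),
    class = "no_sequence")
})

test_that("off-target sets equal the all-substring oracle and shrink with k", {
  set.seed(123)
  for (trial in 1:10) {
    tx <- setNames(replicate(30, random_dna(400)), sprintf("g%02d", 1:30))
    # seed shared stretches of random lengths into a few genes
    dsrna <- random_dna(250)
    for (g in sample(names(tx), 5)) {
      len <- sample(12:25, 1)
      at <- sample(nchar(dsrna) - len, 1)
      ins <- sample(350, 1)
      tx[[g]] <- paste0(substr(tx[[g]], 1, ins),
        substr(dsrna, at, at + len - 1), substr(tx[[g]], ins + 1, 400))
    }
    amp <- tibble::tibble(amplicon_id = "a", dsrna_sequence = dsrna,
      target_genes = list("g01"))
    prev <- NULL
    for (k in c(15, 17, 19, 21)) {
      got <- predict_off_targets(amp, tx, k = k)$off_target_genes[[1]]
      expect_equal(got, oracle_off_targets(dsrna, "g01", tx, k = k))
      if (!is.null(prev)) expect_true(all(got %in% prev))  # monotone in k
      prev <- got
    }
  }
})

test_that("the filtering cascade removes candidates with a single primary reason", {
  candidates <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    amplicon_id = sprintf("a%02d", 1:10),
    direction = "decreased")
  annotations <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    is_ribosomal = c(TRUE, TRUE, rep(FALSE, 8)))
  amplicons <- tibble::tibble(
    amplicon_id = sprintf("a%02d", 1:10),
    target_genes = c(as.list(sprintf("g%02d", 1:2)),
      list(character(0)),  # a03: no specific target
      as.list(sprintf("g%02d", 4:10))),
    n_off_targets = c(rep(0L, 3), 5L, rep(0L, 6)))
  out <- apply_filters(candidates, annotations, amplicons)
  expect_equal(sum(out$keep), 6)
  expect_equal(out$filter_reason[1:4],
    c("ribosomal", "ribosomal", "ambiguous_amplicon", "off_target"))
  # precedence: an ambiguous amplicon for a ribosomal gene reads 'ambiguous'
  amplicons2 <- amplicons
  amplicons2$target_genes[[1]] <- c("g01", "gXX")
  out2 <- apply_filters(candidates, annotations, amplicons2)
  expect_equal(out2$filter_reason[1], "ambiguous_amplicon")
  # unannotated candidates are warned, not silently dropped
  expect_warning(
    out3 <- apply_filters(tibble::tibble(gene_id = "novel", amplicon_id = "a01"),
      annotations, amplicons),
    "unannotated")
  expect_equal(out3$filter_reason, "unannotated")
  # a higher threshold lets the off-target amplicon through
  out4 <- apply_filters(candidates, annotations, amplicons,
    max_off_targets = 6)
  expect_true(out4$keep[4])
})

test_that("multi-reporter validation needs 2 amplicons, 3 reporters, 1 direction", {
  hit_row <- function(amp, dir, hit = TRUE) tibble::tibble(
    amplicon_id = amp, direction = dir, is_hit = hit)
  map <- tibble::tibble(amplicon_id = c("a1", "a2", "b1", "c1", "c2"),
    gene_id = c("gA", "gA", "gB", "gC", "gC"))
  hits <- list(
    original = dplyr::bind_rows(hit_row("a1", "decreased"),
      hit_row("b1", "decreased"), hit_row("c1", "decreased")),
    alt_promoter = dplyr::bind_rows(hit_row("a2", "decreased"),
      hit_row("b1", "decreased"), hit_row("c1", "decreased")),
    alt_ces = dplyr::bind_rows(hit_row("a1", "decreased"),
      hit_row("c2", "increased")))
  v <- validate_multireporter(hits, map)
  # gA: two amplicons, all three reporters, one direction -> validated
  expect_true(v$validated[v$gene_id == "gA"])
  expect_equal(v$direction[v$gene_id == "gA"], "decreased")
  # gB: hit in only two reporters (and a single amplicon) -> not validated
  expect_false(v$validated[v$gene_id == "gB"])
  # gC: direction flips between reporters -> not validated
  expect_false(v$validated[v$gene_id == "gC"])
  expect_true(is.na(v$direction[v$gene_id == "gC"]))
  expect_error(validate_multireporter(hits[1:2], map),
    class = "reporter_table_missing")
})

test_that("classification maps direction x annotation to classes 1-6", {
  ann <- tibble::tibble(
    gene_id = c("gtf", "zf", "gtf2", "zf2", "spl", "novel", "msl"),
    functional_role = c("general_transcription", "unknown_or_other",
      "general_transcription", "unknown_or_other", "rna_metabolism",
      "unknown_or_other", "unknown_or_other"),
    has_sequence_specific_dna_binding = c(FALSE, TRUE, FALSE, TRUE, FALSE,
      FALSE, FALSE),
    is_msl_core = c(rep(FALSE, 6), TRUE))
  rec <- tibble::tibble(
    gene_id = c("gtf", "zf", "gtf2", "zf2", "spl", "novel", "msl"),
    direction = c("activator", "activator", "repressor", "repressor",
      "activator", "repressor", "activator"))
  got <- classify_candidates(rec, ann)
  expect_equal(got$assigned_class,
    c("1", "2", "3", "4", "5", "6", "msl_core"))
  # hit-call vocabulary is accepted: decreased == activator
  got2 <- classify_candidates(
    tibble::tibble(gene_id = "gtf", direction = "decreased"), ann)
  expect_equal(got2$assigned_class, "1")
  # conflicting annotation resolves toward DNA binding with a warning
  ann_conflict <- tibble::tibble(gene_id = "g", functional_role =
    "general_transcription", has_sequence_specific_dna_binding = TRUE,
    is_msl_core = FALSE)
  expect_warning(
    got3 <- classify_candidates(tibble::tibble(gene_id = "g",
      direction = "activator"), ann_conflict),
    "DNA binding")
  expect_equal(got3$assigned_class, "2")
  # order independence
  perm <- sample(nrow(rec))
  got_perm <- classify_candidates(rec[perm, ], ann)
  expect_equal(got_perm$assigned_class, got$assigned_class[perm])
})

test_that("every candidate ends in exactly one bin of the partition", {
  # filtered(reason) or a class: run the cascade end-to-end on a toy screen
  candidates <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    amplicon_id = sprintf("a%02d", 1:8),
    direction = rep(c("decreased", "increased"), 4))
  annotations <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    is_ribosomal = c(TRUE, rep(FALSE, 7)),
    functional_role = c("unknown_or_other", "general_transcription",
      "general_transcription", "rna_metabolism", "unknown_or_other",
      "unknown_or_other", "general_transcription", "unknown_or_other"),
    has_sequence_specific_dna_binding = c(FALSE, FALSE, FALSE, FALSE, TRUE,
      TRUE, FALSE, FALSE),
    is_msl_core = c(rep(FALSE, 7), TRUE))
  amplicons <- tibble::tibble(
    amplicon_id = sprintf("a%02d", 1:8),
    target_genes = as.list(sprintf("g%02d", 1:8)),
    n_off_targets = c(0L, 3L, rep(0L, 6)))
  filt <- apply_filters(candidates, annotations, amplicons)
  survivors <- filt[filt$keep, ]
  classed <- classify_candidates(survivors[, c("gene_id", "direction")],
    annotations)
  final <- dplyr::left_join(filt,
    classed[, c("gene_id", "assigned_class")], by = "gene_id")
  bin <- ifelse(!final$keep, paste0("filtered(", final$filter_reason, ")"),
    final$assigned_class)
  expect_false(any(is.na(bin)))
  expect_equal(length(bin), 8)
  expect_equal(sum(!final$keep), 2)  # one ribosomal, one off-target
})
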
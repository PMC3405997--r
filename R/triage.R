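#' Predict dsRNA off-target genes by exact k-mer sharing
#'
#' An RNAi amplicon is processed into ~21-nt siRNAs, so any transcript
#' sharing a sufficiently long exact stretch with the dsRNA can be
#' silenced. Following the DRSC convention, a gene is a predicted
#' off-target when its transcript shares at least one exact `k`-mer
#' (default 17 nt) with the dsRNA sequence or its reverse complement.
#' Declared targets are excluded from the result.
#'
#' @param amplicons Tibble with columns `amplicon_id`, `dsrna_sequence`
#'   (ACGTN string) and `target_genes` (list-column of gene ids, or a
#'   comma-separated string).
#' @param transcriptome Named character vector of transcript sequences
#'   (names are gene ids), or a tibble `gene_id, sequence`.
#' @param k Exact-overlap cutoff in nt (default 17).
#' @return The input with list-column `off_target_genes` and integer
#'   `n_off_targets` appended.
#' @examples
#' tx <- c(geneA = strrep("ACGT", 100), geneB = strrep("TTAAC", 80))
#' amp <- tibble::tibble(amplicon_id = "a1",
#'   dsrna_sequence = substr(tx[["geneA"]], 101, 400),
#'   target_genes = list("geneA"))
#' predict_off_targets(amp, tx)$n_off_targets
#' @export
predict_off_targets <- function(amplicons, transcriptome, k = 17) {
  check_scalar(k, "k", min = 1, integerish = TRUE)
  amplicons <- as_tibble(amplicons)
  check_columns(amplicons, c("amplicon_id", "dsrna_sequence", "target_genes"),
    "`amplicons`")
  if (is_tibble(transcriptome) || is.data.frame(transcriptome)) {
    check_columns(transcriptome, c("gene_id", "sequence"), "`transcriptome`")
    transcriptome <- setNames(toupper(transcriptome$sequence),
      transcriptome$gene_id)
  } else {
    transcriptome <- setNames(toupper(as.character(transcriptome)),
      names(transcriptome))
  }
  if (!is.list(amplicons$target_genes)) {
    amplicons$target_genes <- strsplit(
      ifelse(is.na(amplicons$target_genes), "", amplicons$target_genes),
      "\\s*,\\s*")
  }
  tx_kmers <- map(transcriptome, kmer_set, k = k)
  off <- map2(amplicons$dsrna_sequence, amplicons$target_genes,
    function(seq, targets) {
      if (is.na(seq) || !nzchar(seq)) {
        abort("amplicon has no dsRNA sequence.", class = "no_sequence")
      }
      seq <- toupper(seq)
      if (grepl("[^ACGTN]", seq)) {
        abort("dsRNA sequence contains letters outside {A,C,G,T,N}.",
          class = "mslscreen_invalid_sequence")
      }
      query <- union(kmer_set(seq, k), kmer_set(revcomp(seq), k))
      hits <- names(tx_kmers)[map_lgl(tx_kmers, function(s) {
        any(query %in% s)
      })]
      sort(setdiff(hits, targets))
    })
  mutate(amplicons,
    off_target_genes = off,
    n_off_targets = lengths(off)
  )
}

# internal: unique k-mers of a sequence, N-containing windows dropped
kmer_set <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(character())
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1)
  unique(kmers[!grepl("N", kmers, fixed = TRUE)])
}

#' Apply the post-screen candidate filtering cascade
#'
#' Screens against arrayed dsRNA libraries routinely recover three classes
#' of spurious candidates, which are removed before follow-up: ribosomal
#' protein genes (generic viability/translation effects), amplicons with
#' many predicted off-targets, and amplicons that target no specific gene
#' or several genes at once. Each removed row carries exactly one primary
#' reason, with fixed precedence
#' `ambiguous_amplicon > ribosomal > off_target` so reasons are
#' reproducible.
#'
#' @param candidates Tibble with columns `gene_id`, `amplicon_id` (one row
#'   per supporting amplicon) and optionally `direction`.
#' @param annotations Tibble `gene_id, is_ribosomal, ...`; candidates
#'   without a row are filtered as `unannotated` with a warning.
#' @param amplicons Tibble `amplicon_id, target_genes` (list-column or
#'   comma string) and optionally `n_off_targets` (e.g. from
#'   [predict_off_targets()]; absent counts are treated as 0).
#' @param max_off_targets An amplicon with `n_off_targets >=` this value is
#'   filtered (default 1: any predicted off-target disqualifies it).
#' @return `candidates` with logical `keep` and `filter_reason`
#'   (`NA`, `"ambiguous_amplicon"`, `"ribosomal"`, `"off_target"`, or
#'   `"unannotated"`) appended.
#' @export
apply_filters <- function(candidates, annotations, amplicons,
                          max_off_targets = 1) {
  check_scalar(max_off_targets, "max_off_targets", min = 1, integerish = TRUE)
  candidates <- as_tibble(candidates)
  check_columns(candidates, c("gene_id", "amplicon_id"), "`candidates`")
  annotations <- as_tibble(annotations)
  check_columns(annotations, c("gene_id", "is_ribosomal"), "`annotations`")
  amplicons <- as_tibble(amplicons)
  check_columns(amplicons, "amplicon_id", "`amplicons`")
  if (!"n_off_targets" %in% names(amplicons)) amplicons$n_off_targets <- 0L
  if (!"target_genes" %in% names(amplicons)) {
    amplicons$target_genes <- as.list(amplicons$amplicon_id)
  }
  if (!is.list(amplicons$target_genes)) {
    amplicons$target_genes <- strsplit(
      ifelse(is.na(amplicons$target_genes), "", amplicons$target_genes),
      "\\s*,\\s*")
  }
  amp <- mutate(amplicons,
    n_targets = lengths(.data$target_genes),
    ambiguous = .data$n_targets != 1L
  ) |>
    select("amplicon_id", "ambiguous", "n_off_targets")

  out <- candidates |>
    left_join(amp, by = "amplicon_id") |>
    left_join(select(annotations, "gene_id", "is_ribosomal"), by = "gene_id")
  if (any(is.na(out$is_ribosomal))) {
    warn(paste0(sum(is.na(out$is_ribosomal)),
      " candidate(s) lack an annotation row; filtered as 'unannotated'."))
  }
  out |>
    mutate(
      filter_reason = case_when(
        is.na(.data$is_ribosomal) ~ "unannotated",
        .data$ambiguous %||% FALSE ~ "ambiguous_amplicon",
        .data$is_ribosomal ~ "ribosomal",
        .data$n_off_targets >= max_off_targets ~ "off_target",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$filter_reason)
    ) |>
    select(-"ambiguous", -"is_ribosomal")
}

#' Multi-reporter validation of candidate genes
#'
#' A gene is validated when (i) at least two distinct amplicons targeting
#' it are hits in any reporter configuration, and (ii) the gene is a hit
#' with the same direction in all three reporter configurations
#' (the original construct, one with an alternative promoter, and one
#' with an alternative CES).
#'
#' @param hits_by_reporter Named list of hit-call tibbles with names
#'   `original`, `alt_promoter`, `alt_ces` (each from [call_hits()]).
#' @param amplicon_map Tibble `amplicon_id, gene_id`.
#' @return Tibble `gene_id, direction, n_hit_amplicons, n_reporters_hit,
#'   direction_consistent, validated`; `direction` is `NA` when
#'   inconsistent across reporters.
#' @export
validate_multireporter <- function(hits_by_reporter, amplicon_map) {
  needed <- c("original", "alt_promoter", "alt_ces")
  missing <- setdiff(needed, names(hits_by_reporter))
  if (length(missing)) {
    abort(paste0("missing reporter hit table(s): ",
      paste(missing, collapse = ", ")), class = "reporter_table_missing")
  }
  check_columns(amplicon_map, c("amplicon_id", "gene_id"), "`amplicon_map`")
  per_reporter <- imap(hits_by_reporter[needed], function(hits, reporter) {
    check_columns(hits, c("amplicon_id", "direction", "is_hit"),
      paste0("hit table '", reporter, "'"))
    hits |>
      filter(.data$is_hit) |>
      left_join(distinct(as_tibble(amplicon_map), .data$amplicon_id,
        .data$gene_id), by = "amplicon_id") |>
      filter(!is.na(.data$gene_id)) |>
      mutate(reporter = reporter) |>
      select("gene_id", "amplicon_id", "direction", "reporter")
  }) |> list_rbind()

  if (!nrow(per_reporter)) {
    return(tibble(gene_id = character(), direction = character(),
      n_hit_amplicons = integer(), n_reporters_hit = integer(),
      direction_consistent = logical(), validated = logical()))
  }
  per_reporter |>
    group_by(.data$gene_id) |>
    summarise(
      n_hit_amplicons = dplyr::n_distinct(.data$amplicon_id),
      n_reporters_hit = dplyr::n_distinct(.data$reporter),
      direction_consistent = dplyr::n_distinct(.data$direction) == 1L,
      direction = if (dplyr::n_distinct(.data$direction) == 1L)
        .data$direction[1] else NA_character_,
      .groups = "drop"
    ) |>
    mutate(validated = .data$n_hit_amplicons >= 2L &
      .data$n_reporters_hit == 3L & .data$direction_consistent) |>
    select("gene_id", "direction", "n_hit_amplicons", "n_reporters_hit",
      "direction_consistent", "validated") |>
    arrange(.data$gene_id)
}

#' Assign candidate genes to functional classes 1-6
#'
#' Validated candidates are classified by the direction of their reporter
#' effect and prior functional knowledge:
#' * Class 1 - general transcriptional regulators that activate the
#'   reporter (RNAi decreased it);
#' * Class 2 - potential sequence-specific DNA-binding proteins that
#'   activate;
#' * Class 3 - general transcriptional regulators that repress;
#' * Class 4 - potential sequence-specific DNA-binding proteins that
#'   repress;
#' * Class 5 - RNA-metabolism proteins (splicing, NMD, ...), either
#'   direction;
#' * Class 6 - previously unstudied proteins or functions unrelated to
#'   transcription/RNA metabolism.
#' Known core MSL-complex subunits are set aside as `"msl_core"`. A gene
#' annotated as both general-transcription and DNA-binding is resolved
#' toward the DNA-binding class with a warning.
#'
#' @param records Tibble with `gene_id` and `direction`
#'   (`activator`/`repressor`, or the hit-call vocabulary
#'   `decreased`/`increased`, where an RNAi-decreased reporter implies the
#'   gene activates it).
#' @param annotations Tibble `gene_id, functional_role`
#'   (`general_transcription` | `rna_metabolism` | `unknown_or_other`),
#'   `has_sequence_specific_dna_binding`, `is_msl_core`.
#' @return `records` with `assigned_class` (`"1"`..`"6"` or `"msl_core"`)
#'   appended.
#' @export
classify_candidates <- function(records, annotations) {
  records <- as_tibble(records)
  check_columns(records, c("gene_id", "direction"), "`records`")
  annotations <- as_tibble(annotations)
  check_columns(annotations, c("gene_id", "functional_role",
    "has_sequence_specific_dna_binding", "is_msl_core"), "`annotations`")
  bad_role <- setdiff(unique(annotations$functional_role),
    c("general_transcription", "rna_metabolism", "unknown_or_other"))
  if (length(bad_role)) {
    abort(paste0("unknown functional_role value(s): ",
      paste(bad_role, collapse = ", ")), class = "mslscreen_invalid_annotation")
  }
  out <- records |>
    mutate(direction = case_when(
      .data$direction %in% c("activator", "decreased") ~ "activator",
      .data$direction %in% c("repressor", "increased") ~ "repressor",
      TRUE ~ NA_character_
    )) |>
    left_join(distinct(annotations, .data$gene_id, .keep_all = TRUE),
      by = "gene_id")
  if (any(is.na(out$functional_role))) {
    abort(paste0("no annotation for gene(s): ",
      paste(head(out$gene_id[is.na(out$functional_role)], 5), collapse = ", ")),
      class = "mslscreen_missing_annotation")
  }
  conflict <- out$has_sequence_specific_dna_binding &
    out$functional_role == "general_transcription"
  if (any(conflict)) {
    warn(paste0(sum(conflict), " gene(s) annotated both general-transcription",
      " and DNA-binding; classified by DNA binding."))
  }
  out |>
    mutate(assigned_class = case_when(
      .data$is_msl_core ~ "msl_core",
      .data$functional_role == "rna_metabolism" ~ "5",
      .data$direction == "activator" &
        .data$has_sequence_specific_dna_binding ~ "2",
      .data$direction == "activator" &
        .data$functional_role == "general_transcription" ~ "1",
      .data$direction == "repressor" &
        .data$has_sequence_specific_dna_binding ~ "4",
      .data$direction == "repressor" &
        .data$functional_role == "general_transcription" ~ "3",
      TRUE ~ "6"
    )) |>
    select(dplyr::all_of(names(records)), "assigned_class")
}
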
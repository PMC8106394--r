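#' Assembly statistics for one genome
#'
#' Computes the classic contiguity metrics over the contigs of one assembly.
#' With contigs sorted by descending length, `N50` is the length of the first
#' contig at which the cumulative length reaches 50% of the total assembly
#' length (ties, cumulative exactly 50%, count as reached) and `L50` is its
#' 1-based rank; `N75`/`L75` likewise at 75%. The ">1 kbp" and ">500 bp"
#' totals use strict inequalities. `n_per_100kbp` is the count of `N`
#' scaffolding characters per 100 kbp of assembly; `gc_percent` is computed
#' over unambiguous bases only; `largest_contig_ratio` is the largest contig
#' divided by the >1 kbp assembly length (the `quast.largest.contig.ratio`
#' quality metric).
#'
#' @param contigs A tibble as returned by [read_fasta()] (columns `id`,
#'   `seq`), or a character vector of contig sequences.
#' @return A one-row tibble with columns `n_seqs`, `n_seqs_gt1kb`,
#'   `total_len`, `total_len_gt1kb`, `total_len_gt500bp`, `largest_contig`,
#'   `gc_percent`, `n50`, `n75`, `l50`, `l75`, `n_per_100kbp`,
#'   `largest_contig_ratio`.
#' @export
compute_assembly_metrics <- function(contigs) {
  seqs <- if (is.data.frame(contigs)) contigs$seq else contigs
  if (length(seqs) == 0L) abort("compute_assembly_metrics() needs at least one contig")
  len <- nchar(seqs)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  cum <- cumsum(sorted)
  l50 <- which(cum >= 0.50 * total)[1]
  l75 <- which(cum >= 0.75 * total)[1]
  base_counts <- function(ch) sum(vapply(
    seqs, function(s) lengths(regmatches(s, gregexpr(ch, s))), numeric(1)
  ))
  n_count <- base_counts("N")
  gc <- base_counts("[GC]")
  at <- base_counts("[AT]")
  gt1kb <- len > 1000
  tibble(
    n_seqs = length(seqs),
    n_seqs_gt1kb = sum(gt1kb),
    total_len = total,
    total_len_gt1kb = sum(len[gt1kb]),
    total_len_gt500bp = sum(len[len > 500]),
    largest_contig = max(len),
    gc_percent = if (gc + at > 0) 100 * gc / (gc + at) else NA_real_,
    n50 = sorted[l50],
    n75 = sorted[l75],
    l50 = l50,
    l75 = l75,
    n_per_100kbp = n_count / total * 1e5,
    largest_contig_ratio = if (sum(len[gt1kb]) > 0) max(len) / sum(len[gt1kb]) else NA_real_
  )
}

#' Genome size-range filter
#'
#' Flags assemblies plausible as a complete, uncontaminated prokaryotic
#' genome: the defaults drop assemblies below 100 kbp (too small to be
#' complete) and above 15 Mbp (likely contaminated).
#'
#' @param total_len Assembly length(s) in bp.
#' @param min_bp,max_bp Inclusive bounds (defaults 100 kbp and 15 Mbp).
#' @return Logical: `TRUE` when within range.
#' @export
size_range_filter <- function(total_len, min_bp = 1e5, max_bp = 1.5e7) {
  total_len >= min_bp & total_len <= max_bp
}

#' Default vocabulary of annotation-uncertainty words
#'
#' Words whose presence in a protein description marks the protein as
#' uncertain. Configurable; matching is case-insensitive on whole words.
#' @export
UNCERTAINTY_VOCABULARY <- c(
  "probable", "putative", "hypothetical", "unknown",
  "uncharacterized", "predicted", "possible"
)

#' Annotation certainty of a proteome
#'
#' `certainty = 1 - (# uncertain proteins / # proteins)`, where a protein is
#' uncertain when its FASTA description contains any vocabulary word
#' (case-insensitive, whole-word).
#'
#' @param descriptions Character vector of per-protein descriptions (empty
#'   strings allowed).
#' @param vocabulary Uncertainty words; see [UNCERTAINTY_VOCABULARY].
#' @return One-row tibble with `n_proteins`, `n_uncertain`, `certainty`.
#' @export
annotation_certainty <- function(descriptions, vocabulary = UNCERTAINTY_VOCABULARY) {
  if (length(descriptions) == 0L) {
    abort("annotation certainty undefined for an empty proteome")
  }
  pat <- paste0("\\b(", paste(vocabulary, collapse = "|"), ")\\b")
  uncertain <- grepl(pat, descriptions, ignore.case = TRUE)
  tibble(
    n_proteins = length(descriptions),
    n_uncertain = sum(uncertain),
    certainty = 1 - sum(uncertain) / length(descriptions)
  )
}

#' Annotation completeness of a proteome
#'
#' `completeness = 1 - (# unannotated proteins / # proteins)`, where a
#' protein is unannotated when its description is empty or whitespace.
#'
#' @inheritParams annotation_certainty
#' @return One-row tibble with `n_proteins`, `n_unannotated`, `completeness`.
#' @export
annotation_completeness <- function(descriptions) {
  if (length(descriptions) == 0L) {
    abort("annotation completeness undefined for an empty proteome")
  }
  blank <- !nzchar(trimws(descriptions))
  tibble(
    n_proteins = length(descriptions),
    n_unannotated = sum(blank),
    completeness = 1 - sum(blank) / length(descriptions)
  )
}

#' Global pairwise identity of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, linear gap -2)
#' with identity defined as the number of identical aligned positions divided
#' by the length of the shorter sequence — the identity definition of greedy
#' incremental clusterers such as CD-HIT.
#'
#' @param seq1,seq2 Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("pairwise_identity() needs non-empty sequences")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    seq1, seq2, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  Biostrings::nmatch(aln) / min(nchar(seq1), nchar(seq2))
}

#' Flag a genome whose SSU rRNA sequences span several species
#'
#' A genome carrying at least two SSU (16S) rRNA sequences that fall into
#' different identity clusters is likely chimeric or contaminated. SSU
#' sequences are clustered greedily by descending length: each sequence joins
#' the first existing cluster whose founder it matches at `>= threshold`
#' identity, else founds a new cluster; the genome is flagged when two or
#' more clusters result. The conventional species-delineation thresholds are
#' 97.5% (default) and 99%.
#'
#' @param ssu_records Tibble from [read_fasta()] (or character vector) of the
#'   genome's SSU sequences; may be empty.
#' @param identity_threshold Identity fraction for species delineation.
#' @return One-row tibble with `n_ssu`, `n_clusters`, `flagged`,
#'   `identity_threshold`.
#' @export
flag_chimeric_genome <- function(ssu_records, identity_threshold = 0.975) {
  seqs <- if (is.data.frame(ssu_records)) ssu_records$seq else ssu_records
  n <- length(seqs)
  if (n <= 1L) {
    return(tibble(n_ssu = n, n_clusters = n, flagged = FALSE,
                  identity_threshold = identity_threshold))
  }
  seqs <- seqs[order(nchar(seqs), decreasing = TRUE)]
  founders <- seqs[1]
  for (s in seqs[-1]) {
    hit <- FALSE
    for (f in founders) {
      if (pairwise_identity(s, f) >= identity_threshold) { hit <- TRUE; break }
    }
    if (!hit) founders <- c(founders, s)
  }
  tibble(n_ssu = n, n_clusters = length(founders),
         flagged = length(founders) >= 2,
         identity_threshold = identity_threshold)
}

#' Pull externally computed metrics from a manifest row
#'
#' Contamination and completeness estimates produced by external marker-gene
#' tools (e.g. `42.contam.perc`, `42.added.ali`, `checkm.completeness`,
#' `checkm.contamination`) enter through manifest columns rather than being
#' recomputed. A genome missing a required metric is marked ineligible for
#' rankings that use it.
#'
#' @param manifest Manifest tibble.
#' @param required Character vector of metric column names that downstream
#'   ranking will need.
#' @return The manifest with a logical `eligible` column: `FALSE` where any
#'   required metric is absent (`NA`).
#' @export
ingest_external_metrics <- function(manifest, required = character(0)) {
  eligible <- rep(TRUE, nrow(manifest))
  for (col in required) {
    if (!col %in% names(manifest)) {
      eligible[] <- FALSE
    } else {
      eligible <- eligible & !is.na(manifest[[col]])
    }
  }
  manifest$eligible <- eligible
  manifest
}

#' Compute the per-genome metric table for a manifest
#'
#' Reads each genome's contig FASTA (and, when present, proteome and SSU
#' FASTA) and assembles one row per genome holding the assembly statistics,
#' annotation certainty/completeness, SSU count and chimera flag, alongside
#' any external metric columns carried by the manifest. Metric columns use
#' the field's dotted naming (`quast.N.per.100.kbp`,
#' `quast.largest.contig.ratio`, `annot.certainty`, ...), so they can be
#' referenced directly in a [ranking_spec()].
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param identity_threshold SSU species-delineation threshold for the
#'   chimera flag.
#' @param vocabulary Uncertainty vocabulary for [annotation_certainty()].
#' @return A tibble: `accession`, computed metric columns, external metric
#'   columns.
#' @export
compute_genome_metrics <- function(manifest, identity_threshold = 0.975,
                                   vocabulary = UNCERTAINTY_VOCABULARY) {
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    contigs <- read_fasta(rec$genome_path)
    am <- compute_assembly_metrics(contigs)
    out <- tibble(
      accession = rec$accession,
      quast.n.seqs = am$n_seqs,
      quast.total.len = am$total_len,
      quast.total.len.1000.bp = am$total_len_gt1kb,
      quast.total.len.500.bp = am$total_len_gt500bp,
      quast.largest.contig = am$largest_contig,
      quast.gc.percent = am$gc_percent,
      quast.N50 = am$n50, quast.N75 = am$n75,
      quast.L50 = am$l50, quast.L75 = am$l75,
      quast.N.per.100.kbp = am$n_per_100kbp,
      quast.largest.contig.ratio = am$largest_contig_ratio,
      annot.certainty = NA_real_,
      annot.completeness = NA_real_,
      ssu.count = 0L,
      ssu.flagged = FALSE
    )
    has_prot <- "proteome_path" %in% names(rec) && !is.na(rec$proteome_path) &&
      nzchar(rec$proteome_path)
    if (has_prot) {
      prot <- read_fasta(rec$proteome_path)
      out$annot.certainty <- annotation_certainty(prot$description, vocabulary)$certainty
      out$annot.completeness <- annotation_completeness(prot$description)$completeness
    }
    has_ssu <- "ssu_path" %in% names(rec) && !is.na(rec$ssu_path) && nzchar(rec$ssu_path)
    if (has_ssu) {
      ssu <- read_fasta(rec$ssu_path)
      ca <- flag_chimeric_genome(ssu, identity_threshold)
      out$ssu.count <- ca$n_ssu
      out$ssu.flagged <- ca$flagged
    }
    out
  })
  computed <- bind_rows(rows)
  ext_cols <- setdiff(names(manifest), MANIFEST_FIXED_COLS)
  if (length(ext_cols) > 0) {
    computed <- left_join(computed,
                          manifest[, c("accession", ext_cols), drop = FALSE],
                          by = "accession")
  }
  computed
}
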
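#' Reverse complement of a nucleotide sequence
#'
#' @param seq A character string over `A`,`C`,`G`,`T`.
#' @return The Watson-Crick reverse complement.
#' @export
#' @examples
#' reverse_complement("AAAC") # "GTTT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGT]", seq)) {
    abort("reverse_complement() requires a sequence over A/C/G/T only")
  }
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement. Working with canonical k-mers makes genome comparison
#' strand-insensitive, at the cost of roughly halving the vocabulary.
#'
#' @param kmer A k-mer (or vector of k-mers) over `A`,`C`,`G`,`T`.
#' @return The canonical k-mer(s).
#' @export
#' @examples
#' canonical_form("TTTT") # "AAAA"
canonical_form <- function(kmer) {
  rc <- vapply(kmer, reverse_complement, character(1), USE.NAMES = FALSE)
  ifelse(rc < kmer, rc, kmer)
}

#' Extract the set of distinct k-mers of a sequence
#'
#' All length-`k` windows made only of `A`,`C`,`G`,`T` are collected and
#' deduplicated (presence/absence, no counts). Windows containing any other
#' character (`N`, ambiguity codes) are skipped entirely. In canonical mode
#' each window is first replaced by its [canonical_form()].
#'
#' @param seq An uppercased nucleotide string, or a character vector of
#'   contigs (windows never span contigs).
#' @param k K-mer size (>= 1); the production default in this field is 12,
#'   small k (3-7) keeps exact engines fast for testing.
#' @param strandedness `"specific"` (strand-sensitive, suited to fully
#'   assembled genomes) or `"canonical"` (strand-insensitive, recommended for
#'   draft assemblies).
#' @return Character vector of distinct k-mers (empty if `k > nchar(seq)`).
#' @export
#' @examples
#' extract_kmers("ACGTA", 3)               # "ACG" "CGT" "GTA"
#' extract_kmers("ACGTA", 3, "canonical")  # "ACG" "GTA"
extract_kmers <- function(seq, k, strandedness = c("specific", "canonical")) {
  strandedness <- match.arg(strandedness)
  stopifnot(k >= 1)
  out <- unlist(lapply(seq, .extract_kmers_cpp, k = as.integer(k),
                       canonical = strandedness == "canonical"))
  unique(out)
}

#' Build a k-mer index for one genome
#'
#' Convenience wrapper tying a genome's distinct-k-mer set to its identifier
#' and extraction parameters, so that similarity functions can refuse to
#' compare indexes built under different settings.
#'
#' @inheritParams extract_kmers
#' @param genome_id Identifier (accession) of the genome.
#' @return An object of class `kmer_index` with fields `genome_id`, `k`,
#'   `strandedness`, `kmers`.
#' @export
kmer_index <- function(seq, k, strandedness = c("specific", "canonical"),
                       genome_id = "genome") {
  strandedness <- match.arg(strandedness)
  structure(
    list(genome_id = genome_id, k = as.integer(k), strandedness = strandedness,
         kmers = extract_kmers(seq, k, strandedness)),
    class = "kmer_index"
  )
}

.as_kmer_set <- function(x) if (inherits(x, "kmer_index")) x$kmers else x

.check_compatible <- function(a, b) {
  if (inherits(a, "kmer_index") && inherits(b, "kmer_index")) {
    if (a$k != b$k || a$strandedness != b$strandedness) {
      abort("k-mer indexes built with different k or strandedness are not comparable")
    }
  }
}

#' Jaccard index of two k-mer sets
#'
#' `JI(A, B) = |A ∩ B| / |A ∪ B|`, the similarity between two genome
#' "dictionaries" of observed words.
#'
#' @param a,b Character vectors of distinct k-mers, or `kmer_index` objects
#'   built with identical `k` and strandedness.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  .check_compatible(a, b)
  a <- .as_kmer_set(a); b <- .as_kmer_set(b)
  if (length(a) == 0L && length(b) == 0L) {
    abort("Jaccard index undefined for two empty sets")
  }
  inter <- sum(!is.na(match(a, b)))
  inter / (length(a) + length(b) - inter)
}

#' Identical Genome Fraction of two k-mer sets
#'
#' `IGF(A, B) = |A ∩ B| / min(|A|, |B|)`: the union of the Jaccard index
#' is replaced by the size of the smaller set, giving a containment-style
#' similarity that is robust when one genome is partial or strongly reduced
#' (streamlined endosymbionts, MAGs).
#'
#' @inheritParams jaccard_index
#' @return Similarity in `[0, 1]`; always `>=` the Jaccard index.
#' @export
identical_genome_fraction <- function(a, b) {
  .check_compatible(a, b)
  a <- .as_kmer_set(a); b <- .as_kmer_set(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("Identical Genome Fraction undefined when either set is empty")
  }
  sum(!is.na(match(a, b))) / min(length(a), length(b))
}

#' Convert a similarity to a distance
#'
#' @param sim Similarity in `[0, 1]`.
#' @return `1 - sim`.
#' @export
similarity_to_distance <- function(sim) {
  if (any(sim < 0 | sim > 1)) abort("similarity must lie in [0, 1]")
  1 - sim
}

#' Build a bottom-s sketch of a k-mer set
#'
#' Each k-mer is hashed with a seeded 64-bit non-cryptographic hash and the
#' `s` smallest distinct hash values are kept, sorted ascending. Two sketches
#' built with the same `k`, `s` and `seed` support [estimate_jaccard()];
#' genomes with fewer than `s` distinct k-mers are represented exactly.
#'
#' @param kmers Character vector of distinct k-mers or a `kmer_index`.
#' @param s Sketch size (>= 1); 1000 gives a Jaccard standard error around
#'   `sqrt(j(1-j)/s)` ~ 0.016 at `j = 0.5`.
#' @param seed Integer hash seed, recorded in the sketch for reproducibility.
#' @return An object of class `kmer_sketch` with fields `genome_id`, `k`,
#'   `s`, `seed`, `hashes` (strictly increasing doubles in `[0, 1)`).
#' @export
build_sketch <- function(kmers, s, seed = 42L) {
  stopifnot(s >= 1)
  genome_id <- if (inherits(kmers, "kmer_index")) kmers$genome_id else NA_character_
  k <- if (inherits(kmers, "kmer_index")) kmers$k else NA_integer_
  kmers <- .as_kmer_set(kmers)
  h <- sort(unique(.hash_kmers_cpp(kmers, as.double(seed))))
  structure(
    list(genome_id = genome_id, k = k, s = as.integer(s),
         seed = as.integer(seed), hashes = head(h, s)),
    class = "kmer_sketch"
  )
}

#' Estimate the Jaccard index from two bottom sketches
#'
#' Merge-bottom estimator: among the `s` smallest hash values of the union of
#' the two sketches (fewer if fewer exist), the fraction present in both
#' sketches estimates the Jaccard index of the full k-mer sets. Exact
#' whenever both genomes have at most `s` distinct k-mers.
#'
#' @param sa,sb `kmer_sketch` objects sharing `k`, `s` and `seed`.
#' @return Estimated Jaccard index in `[0, 1]`.
#' @export
estimate_jaccard <- function(sa, sb) {
  stopifnot(inherits(sa, "kmer_sketch"), inherits(sb, "kmer_sketch"))
  if (!identical(sa$s, sb$s) || !identical(sa$seed, sb$seed) ||
      !identical(sa$k, sb$k)) {
    abort("Sketches built with different k, s or seed are not comparable")
  }
  merged <- head(sort(unique(c(sa$hashes, sb$hashes))), sa$s)
  if (length(merged) == 0L) abort("Cannot estimate Jaccard from two empty sketches")
  shared <- sum(merged %in% sa$hashes & merged %in% sb$hashes)
  shared / length(merged)
}

#' Mash-style evolutionary distance from an estimated Jaccard index
#'
#' `D = -(1/k) * log(2j / (1 + j))`, the standard conversion from a k-mer
#' Jaccard index to an approximate per-base mutation distance. Capped at 1
#' when `j = 0` (the logarithm is undefined there); 0 when `j = 1`.
#'
#' @param j_est (Estimated) Jaccard index in `[0, 1]`.
#' @param k K-mer size used to build the sets.
#' @return Distance `>= 0`.
#' @export
#' @examples
#' mash_distance(0.5, 12) # ~0.0338
mash_distance <- function(j_est, k) {
  if (any(j_est < 0 | j_est > 1)) abort("j_est must lie in [0, 1]")
  stopifnot(k >= 1)
  ifelse(j_est == 0, 1,
         ifelse(j_est == 1, 0, -(1 / k) * log(2 * j_est / (1 + j_est))))
}

#' Size of the k-mer vocabulary
#'
#' Number of distinct possible words of length `k` over the DNA alphabet:
#' `4^k` strand-specific k-mers; in canonical mode, k-mers pair up with their
#' reverse complements, so for odd `k` (no palindromes) exactly `4^k / 2`
#' classes exist, and for even `k` the `4^(k/2)` self-complementary
#' palindromes are their own class, giving `(4^k + 4^(k/2)) / 2`.
#'
#' @param k K-mer size.
#' @param strandedness `"specific"` or `"canonical"`.
#' @return The vocabulary size (double; exact up to `k = 26`).
#' @export
#' @examples
#' kmer_vocabulary_size(12)            # 16777216
#' kmer_vocabulary_size(11)            # 4194304
#' kmer_vocabulary_size(5, "canonical") # 512
kmer_vocabulary_size <- function(k, strandedness = c("specific", "canonical")) {
  strandedness <- match.arg(strandedness)
  stopifnot(k >= 1)
  if (strandedness == "specific") return(4^k)
  if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2
}
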
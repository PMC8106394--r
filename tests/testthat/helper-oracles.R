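# Independent brute-force oracles used to cross-check the implementation.

# Set similarity oracles via explicit membership tabulation (no set ops that
# mirror the implementation path).
oracle_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  in_a <- u %in% a
  in_b <- u %in% b
  sum(in_a & in_b) / length(u)
}

oracle_igf <- function(a, b) {
  u <- unique(c(a, b))
  sum(u %in% a & u %in% b) / min(length(unique(a)), length(unique(b)))
}

# Prefix-scan Nx/Lx oracle.
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + s[i]
    if (cum >= x / 100 * total) return(list(n = s[i], l = i))
  }
}

# All k-mers over ACGT, enumerated.
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

random_kmer_set <- function(k, size) {
  vocab <- all_kmers(k)
  sample(vocab, min(size, length(vocab)))
}

# Distance matrix with guaranteed separation: within-group distances below,
# between-group distances above the threshold.
separated_instance <- function(n, n_groups, threshold) {
  groups <- sort(sample.int(n_groups, n, replace = TRUE))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (groups[i] == groups[j]) {
      runif(1, 0, threshold * 0.9)
    } else {
      runif(1, min(1, threshold * 1.1), 1)
    }
  }
  list(d = d, groups = groups)
}

fasta_tempfile <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

manifest_tempfile <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, tf)
  tf
}
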
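# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

BASES <- c("A", "C", "G", "T")

# Mutation core operating on the current RNG stream (no seeding).
.mutate_chars <- function(chars, rate) {
  n <- length(chars)
  hit <- runif(n) < rate
  if (any(hit)) {
    # substitute with one of the three alternative bases, never the original
    offsets <- sample.int(3L, sum(hit), replace = TRUE)
    cur <- match(chars[hit], BASES)
    chars[hit] <- BASES[((cur - 1L + offsets) %% 4L) + 1L]
  }
  chars
}

.random_chars <- function(length) sample(BASES, length, replace = TRUE)

#' Random nucleotide sequence
#'
#' @param length Sequence length in bp.
#' @param seed Integer seed; output is a pure function of `(length, seed)`.
#' @return A nucleotide string.
#' @export
random_sequence <- function(length, seed = 1L) {
  .with_seed(seed, paste(.random_chars(length), collapse = ""))
}

#' Mutate a sequence by independent substitutions
#'
#' Each position is substituted with probability `rate`, uniformly over the
#' three alternative bases (never the original base, so `rate = 1` changes
#' every position). Length is preserved; no indels are introduced, which
#' keeps the expected k-mer overlap between relatives analytically
#' tractable.
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`T`.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  .with_seed(seed, {
    paste(.mutate_chars(strsplit(seq, "", fixed = TRUE)[[1]], rate), collapse = "")
  })
}

#' Generate a synthetic proteome with controlled annotation quality
#'
#' Produces exactly `round(n_proteins * f_uncertain)` proteins described as
#' `"hypothetical protein"`, exactly `round(n_proteins * f_blank)` with a
#' blank description, and informative descriptions for the rest, so that
#' [annotation_certainty()] and [annotation_completeness()] equal
#' `1 - round(n*f)/n` by construction.
#'
#' @param n_proteins Number of proteins.
#' @param f_uncertain,f_blank Fractions (summing to at most 1).
#' @param seed Integer seed.
#' @return A tibble (`id`, `description`, `seq`) writable with
#'   [write_fasta()].
#' @export
generate_proteome <- function(n_proteins, f_uncertain = 0, f_blank = 0, seed = 1L) {
  stopifnot(f_uncertain + f_blank <= 1)
  n_u <- round(n_proteins * f_uncertain)
  n_b <- round(n_proteins * f_blank)
  informative <- c(
    "DNA polymerase III subunit alpha", "30S ribosomal protein S12",
    "elongation factor Tu", "ATP synthase subunit beta",
    "chaperonin GroEL", "DNA gyrase subunit A", "citrate synthase",
    "phosphoglycerate kinase", "recombinase RecA", "RNA polymerase subunit beta"
  )
  .with_seed(seed, {
    desc <- c(
      rep("hypothetical protein", n_u),
      rep("", n_b),
      sample(informative, n_proteins - n_u - n_b, replace = TRUE)
    )
    desc <- sample(desc)
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
            "Q", "R", "S", "T", "V", "W", "Y")
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(sample(aa, 120, replace = TRUE), collapse = "")
    }, character(1))
    tibble(id = sprintf("prot_%04d", seq_len(n_proteins)),
           description = desc, seq = seqs)
  })
}

#' Generate a synthetic SSU rRNA set for one genome
#'
#' Non-chimeric genomes receive `n_copies` near-identical copies of the
#' group's SSU (pairwise identity > 0.99, as real rRNA operon copies are).
#' Chimeric genomes receive two SSUs diverged at approximately
#' `1 - divergence` identity, mimicking a genome assembled from two
#' organisms, so [flag_chimeric_genome()] flags them at the conventional
#' thresholds.
#'
#' @param base_ssu The group's reference SSU sequence.
#' @param divergence Between-species divergence used for the chimeric pair.
#' @param chimeric Whether to emit a two-species SSU pair.
#' @param seed Integer seed.
#' @param n_copies Copies for the non-chimeric case (1 or 2).
#' @return A tibble (`id`, `description`, `seq`).
#' @export
generate_ssu_set <- function(base_ssu, divergence = 0.1, chimeric = FALSE,
                             seed = 1L, n_copies = 2L) {
  .with_seed(seed, {
    if (chimeric) {
      other <- paste(.mutate_chars(strsplit(base_ssu, "", fixed = TRUE)[[1]],
                                   divergence), collapse = "")
      seqs <- c(base_ssu, other)
    } else {
      seqs <- vapply(seq_len(n_copies), function(i) {
        paste(.mutate_chars(strsplit(base_ssu, "", fixed = TRUE)[[1]], 0.002),
              collapse = "")
      }, character(1))
    }
    tibble(id = sprintf("ssu_%d", seq_along(seqs)),
           description = "16S ribosomal RNA", seq = seqs)
  })
}

#' Generate a hierarchically structured synthetic genome family set
#'
#' Emulates a collection of genome families with phylum-like structure: one
#' random root sequence is diverged into `n_groups` group ancestors at the
#' between-group substitution rate `mu_b`, and each group's members are
#' drawn from its ancestor at the (much smaller) within-group rate `mu_w`.
#' Lineage strings encode the group labels
#' (`"Bacteria;Group<i>;Family<i>"`), so taxonomic sorting and diversity
#' reporting can be tested end to end against the returned truth table.
#' Optional chimeras concatenate the halves of two different group
#' ancestors and carry a two-species SSU pair — a caricature of the
#' bridge genomes that defeat pure single-linkage clustering.
#'
#' Everything needed by the full pipeline is written to `dir`: per-genome
#' contig FASTA (the genome is cut into a few contigs), proteome FASTA with
#' controlled uncertain/blank description fractions, SSU FASTA, a manifest
#' TSV with lineages and synthetic external contamination metrics
#' (`42.contam.perc`, `42.added.ali`), and the truth table TSV.
#'
#' @param n_groups Number of groups (default 10).
#' @param members_per_group Genomes per group (default 5).
#' @param genome_length Genome length in bp (default 50000).
#' @param mu_w,mu_b Within- and between-group per-site substitution rates
#'   (defaults 0.01 and 0.3; `mu_w < mu_b` is required for the groups to be
#'   separable).
#' @param seed Integer seed; all output is a pure function of the arguments.
#' @param chimera_count Number of two-group chimeric genomes to add.
#' @param f_uncertain,f_blank Annotation profile passed to
#'   [generate_proteome()].
#' @param n_proteins Proteome size per genome.
#' @param ssu_length,ssu_divergence SSU profile (length; divergence of the
#'   chimeric second SSU).
#' @param dir Output directory (default a fresh temporary directory).
#' @param with_proteomes,with_ssu Toggle the optional annotation layers.
#' @return A list: `manifest` (tibble, as [read_manifest()] would return),
#'   `truth` (tibble `accession`, `group`, `chimera`), `dir`.
#' @export
generate_family_set <- function(n_groups = 10L, members_per_group = 5L,
                                genome_length = 50000L,
                                mu_w = 0.01, mu_b = 0.3, seed = 1L,
                                chimera_count = 0L,
                                f_uncertain = 0.2, f_blank = 0.1,
                                n_proteins = 50L,
                                ssu_length = 1500L, ssu_divergence = 0.1,
                                dir = tempfile("famset"),
                                with_proteomes = TRUE, with_ssu = TRUE) {
  stopifnot(mu_w >= 0, mu_w < mu_b, mu_b <= 1)
  if (chimera_count > 0 && n_groups < 2) abort("Chimeras need at least 2 groups")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    root <- .random_chars(genome_length)
    root_ssu <- .random_chars(ssu_length)
    ancestors <- purrr::map(seq_len(n_groups), function(i) .mutate_chars(root, mu_b))
    group_ssu <- purrr::map(seq_len(n_groups), function(i) {
      paste(.mutate_chars(root_ssu, mu_b / 3), collapse = "")
    })
    rows <- list(); truth <- list()
    emit_genome <- function(accession, chars, group, lineage, chimera,
                            ssu_seq, ssu_chimeric) {
      # cut into 1-4 contigs so assembly metrics vary between genomes
      n_contig <- sample.int(4L, 1L)
      cuts <- sort(sample.int(length(chars) - 1L, n_contig - 1L))
      bounds <- c(0L, cuts, length(chars))
      contigs <- vapply(seq_len(n_contig), function(j) {
        paste(chars[(bounds[j] + 1L):bounds[j + 1L]], collapse = "")
      }, character(1))
      gpath <- file.path(dir, paste0(accession, ".fna"))
      write_fasta(tibble(id = sprintf("%s_ctg%d", accession, seq_len(n_contig)),
                         description = "", seq = contigs), gpath)
      ppath <- NA_character_; spath <- NA_character_
      if (with_proteomes) {
        ppath <- file.path(dir, paste0(accession, ".faa"))
        write_fasta(generate_proteome(n_proteins, f_uncertain, f_blank,
                                      seed = sample.int(2^30, 1L)), ppath)
      }
      if (with_ssu) {
        spath <- file.path(dir, paste0(accession, ".ssu.fna"))
        write_fasta(generate_ssu_set(ssu_seq, ssu_divergence,
                                     chimeric = ssu_chimeric,
                                     seed = sample.int(2^30, 1L)), spath)
      }
      rows[[length(rows) + 1L]] <<- tibble(
        accession = accession, genome_path = gpath,
        proteome_path = ppath, ssu_path = spath,
        lineage = lineage, source = "custom",
        `42.contam.perc` = round(runif(1, 0, 5), 3),
        `42.added.ali` = as.numeric(sample.int(50L, 1L))
      )
      truth[[length(truth) + 1L]] <<- tibble(
        accession = accession, group = group, chimera = chimera
      )
    }
    for (i in seq_len(n_groups)) {
      lineage <- sprintf("Bacteria;Group%02d;Family%02d", i, i)
      for (j in seq_len(members_per_group)) {
        emit_genome(sprintf("SYN%02d_%02d", i, j),
                    .mutate_chars(ancestors[[i]], mu_w),
                    sprintf("Group%02d", i), lineage, FALSE,
                    group_ssu[[i]], FALSE)
      }
    }
    if (chimera_count > 0) {
      pairs <- purrr::map(seq_len(chimera_count), function(j) {
        sort(sample.int(n_groups, 2L))
      })
      for (j in seq_len(chimera_count)) {
        g1 <- pairs[[j]][1]; g2 <- pairs[[j]][2]
        half <- genome_length %/% 2L
        chars <- c(ancestors[[g1]][seq_len(half)],
                   ancestors[[g2]][(half + 1L):genome_length])
        emit_genome(sprintf("SYNCHIM_%02d", j), chars,
                    sprintf("Group%02d", g1),
                    sprintf("Bacteria;Group%02d;Family%02d", g1, g1), TRUE,
                    group_ssu[[g1]], TRUE)
      }
    }
    manifest <- bind_rows(rows)
    truth <- bind_rows(truth)
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    list(manifest = manifest, truth = truth, dir = dir)
  })
}

#' Purity of a dereplication result against a truth table
#'
#' Fraction of non-chimeric genomes whose final representative belongs to
#' their own ground-truth group: 1 means no cluster ever merged genomes
#' from different groups.
#'
#' @param result A `derep_result`.
#' @param truth Truth tibble from [generate_family_set()].
#' @return A single number in `[0, 1]`.
#' @export
membership_purity <- function(result, truth) {
  grp <- setNames(truth$group, truth$accession)
  keep <- !truth$chimera[match(result$membership$genome, truth$accession)]
  mem <- result$membership[keep, , drop = FALSE]
  mean(grp[mem$genome] == grp[mem$final_representative])
}
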
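make_contigs <- function(lengths, n_count = 0) {
  seqs <- vapply(lengths, function(l) {
    paste(rep("A", l), collapse = "")
  }, character(1))
  if (n_count > 0) {
    # put the Ns inside the first contig
    s <- seqs[1]
    substr(s, 2, 1 + n_count) <- paste(rep("N", n_count), collapse = "")
    seqs[1] <- s
  }
  tibble::tibble(id = paste0("c", seq_along(seqs)), seq = seqs)
}

test_that("assembly metrics match the worked example", {
  am <- compute_assembly_metrics(make_contigs(c(5000, 3000, 1500, 500), n_count = 10))
  expect_equal(am$total_len, 10000)
  expect_equal(am$total_len_gt1kb, 9500)
  expect_equal(am$total_len_gt500bp, 9500)
  expect_equal(am$largest_contig, 5000)
  expect_equal(am$largest_contig_ratio, 5000 / 9500)
  expect_equal(am$n50, 5000); expect_equal(am$l50, 1)
  expect_equal(am$n75, 3000); expect_equal(am$l75, 2)
  expect_equal(am$n_per_100kbp, 100)
  expect_equal(am$n_seqs, 4); expect_equal(am$n_seqs_gt1kb, 3)

  single <- compute_assembly_metrics(make_contigs(2000))
  expect_equal(single$n50, 2000); expect_equal(single$n75, 2000)
  expect_equal(single$l50, 1); expect_equal(single$l75, 1)
  expect_equal(single$largest_contig_ratio, 1)

  tie <- compute_assembly_metrics(make_contigs(c(50, 30, 10, 10)))
  expect_equal(tie$n50, 50)  # cumulative 50 reaches exactly 50%
  expect_equal(tie$n75, 30); expect_equal(tie$l75, 2)

  expect_error(compute_assembly_metrics(character(0)), "at least one contig")
})

test_that("gc_percent ignores ambiguous bases", {
  am <- compute_assembly_metrics(tibble::tibble(id = "c", seq = "GGCCAANN"))
  expect_equal(am$gc_percent, 100 * 4 / 6)
})

test_that("Nx/Lx agree with the prefix-scan oracle on random multisets", {
  set.seed(11)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:15, 1), replace = TRUE)
    am <- compute_assembly_metrics(make_contigs(lens))
    o50 <- oracle_nx(lens, 50); o75 <- oracle_nx(lens, 75)
    expect_equal(am$n50, o50$n); expect_equal(am$l50, o50$l)
    expect_equal(am$n75, o75$n); expect_equal(am$l75, o75$l)
    expect_gte(am$n50, am$n75); expect_lte(am$l50, am$l75)
  }
})

test_that("size range filter keeps plausible prokaryotic genome sizes", {
  expect_true(size_range_filter(1e6))
  expect_false(size_range_filter(5e4))
  expect_false(size_range_filter(2e7))
  expect_true(size_range_filter(1e5))  # bounds inclusive
  expect_true(size_range_filter(1.5e7))
})

test_that("annotation certainty counts whole-word uncertainty matches", {
  desc <- c(rep("hypothetical protein", 3), rep("citrate synthase", 7))
  expect_equal(annotation_certainty(desc)$certainty, 0.7)
  expect_equal(annotation_certainty(rep("enolase", 4))$certainty, 1)
  expect_equal(annotation_certainty(rep("unknown function", 4))$certainty, 0)
  # whole-word: a containing word does not count
  expect_equal(annotation_certainty("unknowable catalase")$certainty, 1)
  expect_equal(annotation_certainty("Probable kinase")$certainty, 0)
  expect_error(annotation_certainty(character(0)), "empty proteome")
  # adding an uncertain protein strictly decreases certainty
  expect_lt(annotation_certainty(c(desc, "putative thing"))$certainty,
            annotation_certainty(desc)$certainty)
})

test_that("annotation completeness counts blank descriptions", {
  expect_equal(annotation_completeness(c("", "a", "b", "c"))$completeness, 0.75)
  expect_equal(annotation_completeness(c("a", "b"))$completeness, 1)
  expect_equal(annotation_completeness(c("", "  "))$completeness, 0)
  expect_error(annotation_completeness(character(0)), "empty proteome")
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  s <- random_sequence(100, seed = 3)
  expect_equal(pairwise_identity(s, s), 1)
  s2 <- paste0("T", substr(s, 2, 100))
  if (substr(s, 1, 1) == "T") s2 <- paste0("A", substr(s, 2, 100))
  expect_equal(pairwise_identity(s, s2), 0.99)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("chimera flagging clusters SSUs greedily at the identity threshold", {
  ssu <- random_sequence(800, seed = 4)
  same <- tibble::tibble(id = c("s1", "s2"), seq = c(ssu, ssu))
  expect_false(flag_chimeric_genome(same)$flagged)
  expect_equal(flag_chimeric_genome(same)$n_clusters, 1)

  far <- mutate_sequence(ssu, 0.10, seed = 5)
  mixed <- tibble::tibble(id = c("s1", "s2"), seq = c(ssu, far))
  res <- flag_chimeric_genome(mixed, 0.975)
  expect_true(res$flagged)
  expect_equal(res$n_clusters, 2)
  # order invariance when identities are clearly on one side
  res_rev <- flag_chimeric_genome(mixed[2:1, ], 0.975)
  expect_equal(res_rev$n_clusters, 2)

  expect_false(flag_chimeric_genome(tibble::tibble(id = "s", seq = ssu))$flagged)
  expect_false(flag_chimeric_genome(tibble::tibble(id = character(0),
                                                   seq = character(0)))$flagged)
})

test_that("external metrics pass through and gate eligibility", {
  m <- tibble::tibble(accession = c("g1", "g2"), genome_path = "x",
                      `42.contam.perc` = c(2.5, NA))
  out <- ingest_external_metrics(m, required = "42.contam.perc")
  expect_equal(out$`42.contam.perc`[1], 2.5)
  expect_equal(out$eligible, c(TRUE, FALSE))
  out2 <- ingest_external_metrics(m, required = "checkm.completeness")
  expect_false(any(out2$eligible))
})

test_that("compute_genome_metrics assembles the per-genome table", {
  fs <- generate_family_set(n_groups = 2, members_per_group = 2,
                            genome_length = 3000, seed = 21,
                            f_uncertain = 0.2, f_blank = 0.1, n_proteins = 10)
  mt <- compute_genome_metrics(fs$manifest)
  expect_equal(nrow(mt), 4)
  expect_true(all(c("quast.N.per.100.kbp", "quast.largest.contig.ratio",
                    "annot.certainty", "annot.completeness", "ssu.count",
                    "ssu.flagged", "42.contam.perc", "42.added.ali") %in% names(mt)))
  expect_equal(mt$annot.certainty, rep(0.8, 4))
  expect_equal(mt$annot.completeness, rep(0.9, 4))
  expect_true(all(mt$ssu.count >= 1))
  expect_false(any(mt$ssu.flagged))
})
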
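# small shared fixture: 3 groups x 3 members, cheap to cluster exactly
small_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_family_set(
        n_groups = 3, members_per_group = 3, genome_length = 8000,
        mu_w = 0.01, mu_b = 0.3, seed = 31, n_proteins = 10
      )
    }
    cache
  }
})

small_config <- function(...) {
  args <- utils::modifyList(
    list(k = 6, threshold = 0.1, pack_size = 9, size_filter = FALSE,
         sort_scheme = "taxonomic"),
    list(...)
  )
  do.call(derep_config, args)
}

test_that("packs are consecutive slices after taxonomic or seeded random sort", {
  g <- tibble::tibble(
    accession = c("g1", "g2", "g3", "g4", "g5"),
    lineage = c("Bacteria;Proteobacteria;X", "Bacteria;Firmicutes;Y",
                "", "Bacteria;Firmicutes;Z", "Bacteria;Proteobacteria;W")
  )
  packs <- partition_into_packs(g, 2, "taxonomic")
  expect_equal(lengths(packs, use.names = FALSE), c(2, 2, 1))
  flat <- unlist(packs, use.names = FALSE)
  # Firmicutes sort together before Proteobacteria; unclassified last
  expect_equal(flat, c("g2", "g4", "g5", "g1", "g3"))

  r1 <- partition_into_packs(g, 2, "random", seed = 5)
  r2 <- partition_into_packs(g, 2, "random", seed = 5)
  expect_identical(r1, r2)
  expect_setequal(unlist(r1), g$accession)
  expect_error(partition_into_packs(g[0, ], 2), "at least one")
})

test_that("stop criteria fire in the documented priority", {
  cfg <- derep_config(max_rounds = 1, size_filter = FALSE)
  st <- tibble::tibble(round = 1L, genomes_in = 10L, representatives_out = 5L,
                       clustering_ratio = 50, packs = 1L)
  expect_equal(check_stop(st, 5, cfg), list(stop = TRUE, reason = "max_rounds"))

  cfg2 <- derep_config(max_rounds = 10, max_representatives = 50)
  expect_equal(check_stop(st, 40, cfg2)$reason, "max_representatives")

  st0 <- dplyr::mutate(st, clustering_ratio = 0)
  expect_equal(check_stop(st0, 10, cfg2)$reason, "fixed_point")

  cfg3 <- derep_config(max_rounds = 10, min_clustering_ratio = 5)
  st_slow <- dplyr::mutate(st, clustering_ratio = 2)
  expect_equal(check_stop(st_slow, 8, cfg3)$reason, "min_clustering_ratio")
  expect_false(check_stop(st, 8, cfg3)$stop)
})

test_that("run_round honors threshold extremes and reports the ratio", {
  g <- tibble::tibble(accession = paste0("g", 1:6), lineage = "")
  pos <- setNames(1:6, g$accession)
  d0 <- function(a, b) 0.5
  cfg <- small_config(threshold = 0)
  rr <- run_round(g, cfg, pos, d0)
  expect_equal(sort(rr$representatives), sort(g$accession))
  expect_equal(rr$stats$clustering_ratio, 0)

  cfg2 <- small_config(threshold = 0.99, pack_size = 10)
  rr2 <- run_round(g, cfg2, pos, function(a, b) 0.1)
  expect_equal(rr2$representatives, "g1")
  expect_equal(rr2$stats$clustering_ratio, 100 * 5 / 6)
})

test_that("prefilter drops by size, SSU presence and chimera flag with reasons", {
  man <- tibble::tibble(accession = c("a", "b", "c"), genome_path = "x",
                        lineage = "")
  met <- tibble::tibble(accession = c("a", "b", "c"),
                        quast.total.len = c(5e4, 2e5, 3e5),
                        ssu.count = c(1L, 0L, 2L),
                        ssu.flagged = c(FALSE, FALSE, TRUE))
  cfg <- derep_config(require_ssu = TRUE, chimera_exclude = TRUE)
  pf <- prefilter(man, met, cfg)
  expect_equal(nrow(pf$manifest), 0)
  expect_setequal(pf$dropped$accession, c("a", "b", "c"))
  expect_match(pf$dropped$reason[pf$dropped$accession == "a"], "size range")
  expect_match(pf$dropped$reason[pf$dropped$accession == "b"], "SSU")
  expect_match(pf$dropped$reason[pf$dropped$accession == "c"], "chimeric")

  cfg_off <- derep_config(size_filter = FALSE)
  expect_equal(prefilter(man, met, cfg_off)$manifest, man)
})

test_that("full dereplication recovers the synthetic groups", {
  fs <- small_family()
  res <- run_dereplication(fs$manifest, small_config())
  expect_equal(length(res$representatives), 3)
  expect_equal(membership_purity(res, fs$truth), 1)
  # membership idempotence and self-mapping representatives
  mem <- setNames(res$membership$final_representative, res$membership$genome)
  expect_equal(unname(mem[unname(mem)]), unname(mem))
  expect_true(all(mem[res$representatives] == res$representatives))
  # representative sets nested across rounds
  reps_by_round <- lapply(split(res$provenance, res$provenance$round),
                          function(p) unique(p$representative))
  if (length(reps_by_round) > 1) {
    for (r in 2:length(reps_by_round)) {
      expect_true(all(reps_by_round[[r]] %in% reps_by_round[[r - 1]]))
    }
  }
  expect_true(all(diff(res$round_stats$representatives_out) <= 0))
})

test_that("a single surviving genome is its own representative", {
  fs <- small_family()
  one <- fs$manifest[1, ]
  res <- run_dereplication(one, small_config())
  expect_equal(res$representatives, one$accession)
  expect_equal(res$membership$final_representative, one$accession)
  expect_equal(nrow(res$round_stats), 1)
})

test_that("a single full-size pack reproduces plain greedy clustering", {
  fs <- small_family()
  cfg <- small_config(max_rounds = 1, pack_size = 20)
  res <- run_dereplication(fs$manifest, cfg)
  # oracle: cluster the globally ranked list directly
  mt <- compute_genome_metrics(fs$manifest)
  ranked <- sum_of_ranks(mt, cfg$ranking)
  idx <- lapply(seq_len(nrow(fs$manifest)), function(i) {
    kmer_index(read_fasta(fs$manifest$genome_path[i])$seq, cfg$k,
               genome_id = fs$manifest$accession[i])
  })
  names(idx) <- fs$manifest$accession
  pr <- cluster_pack(ranked$accession,
                     function(a, b) 1 - jaccard_index(idx[[a]], idx[[b]]),
                     cfg$threshold, cfg$mode)
  expect_setequal(res$representatives, unique(pr$clusters$representative))
})

test_that("priority list promotes its genome to representative", {
  fs <- small_family()
  # pick a genome that is certainly not the best-ranked in its group
  mt <- compute_genome_metrics(fs$manifest)
  ranked <- sum_of_ranks(mt, ranking_spec())
  worst <- ranked$accession[nrow(ranked)]
  cfg <- small_config(lists = list(accession_list(worst, "priority")))
  res <- run_dereplication(fs$manifest, cfg)
  expect_true(worst %in% res$representatives)
})

test_that("exclude lists and transitive membership interact correctly", {
  fs <- small_family()
  drop_acc <- fs$manifest$accession[1]
  cfg <- small_config(lists = list(accession_list(drop_acc, "exclude")))
  res <- run_dereplication(fs$manifest, cfg)
  expect_false(drop_acc %in% res$membership$genome)
  expect_true(drop_acc %in% res$dropped$accession)
})

test_that("diversity report counts phyla, purity and mixity", {
  fs <- small_family()
  res <- run_dereplication(fs$manifest, small_config())
  dr <- diversity_report(res, fs$manifest)
  expect_equal(dr$n_groups, 3)
  expect_equal(dr$n_phyla_represented, 3)
  expect_equal(dr$redundancy_index, 1)
  expect_equal(dr$n_mixed, 0)
  expect_equal(dr$n_pure, 3)

  # an aggressive threshold merges everything into one mixed group
  res_all <- run_dereplication(fs$manifest, small_config(threshold = 1))
  dr_all <- diversity_report(res_all, fs$manifest)
  expect_equal(dr_all$n_groups, 1)
  expect_equal(dr_all$n_mixed, 1)
  expect_equal(dr_all$n_singletons, 0)

  no_lineage <- dplyr::mutate(fs$manifest, lineage = "")
  expect_error(diversity_report(res, no_lineage), "lineage")
})

test_that("tidy, glance, autoplot and result writing work end to end", {
  fs <- small_family()
  res <- run_dereplication(fs$manifest, small_config())
  td <- tidy(res)
  expect_true(all(c("genome", "final_representative", "is_representative")
                  %in% names(td)))
  expect_equal(sum(td$is_representative), 3)
  gl <- glance(res)
  expect_equal(gl$n_representatives, 3)
  expect_equal(gl$n_genomes, 9)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  out <- write_derep_result(res, tempfile("out"))
  expect_true(file.exists(file.path(out, "representatives.txt")))
  expect_equal(readLines(file.path(out, "representatives.txt")),
               res$representatives)
})

test_that("YAML config round-trips into a derep_config", {
  tf <- tempfile(fileext = ".yml")
  writeLines(c(
    "k: 6", "threshold: 0.1", "pack_size: 9", "sort_scheme: taxonomic",
    "size_filter: no",
    "ranking:", "  quast.N.per.100.kbp: lower_better",
    "  annot.certainty: higher_better"
  ), tf)
  cfg <- read_derep_config(tf)
  expect_s3_class(cfg, "derep_config")
  expect_equal(cfg$k, 6L)
  expect_equal(cfg$threshold, 0.1)
  expect_false(cfg$size_filter)
  expect_equal(cfg$ranking$metric,
               c("quast.N.per.100.kbp", "annot.certainty"))
})

test_that("sketch engine reproduces the exact-engine clusters here", {
  fs <- small_family()
  exact <- run_dereplication(fs$manifest, small_config())
  sk <- run_dereplication(fs$manifest,
                          small_config(engine = "sketch_ji",
                                       sketch_size = 2000))
  expect_setequal(sk$representatives, exact$representatives)
})
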
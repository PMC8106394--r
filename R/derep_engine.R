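#' Configuration for a dereplication run
#'
#' Collects every knob of the iterative divide-and-conquer engine. The main
#' control is `threshold`, the distance (`1 - similarity`) below which two
#' genomes join the same cluster: the higher the threshold, the more
#' aggressive the dereplication.
#'
#' @param k K-mer size (default 12: the 4^12 vocabulary of ~16.8 million
#'   words is not exhausted by prokaryotic genomes, while 4^11 nearly is).
#' @param strandedness `"specific"` for finished assemblies where strand
#'   orientation is informative, `"canonical"` (recommended for draft
#'   assemblies) for strand-insensitive comparison.
#' @param engine `"exact_ji"` (exact Jaccard), `"exact_igf"` (Identical
#'   Genome Fraction) or `"sketch_ji"` (bottom-sketch Jaccard estimate).
#' @param sketch_size,sketch_seed Sketch parameters for `engine =
#'   "sketch_ji"`.
#' @param threshold Distance threshold in `[0, 1]`.
#' @param pack_size Number of genomes clustered together in one pack
#'   (default 200); larger packs merge more but cost quadratically more
#'   comparisons.
#' @param sort_scheme `"taxonomic"` (stable sort by lineage string, so
#'   related genomes share packs and converge in few rounds) or `"random"`
#'   (seeded shuffle, reshuffled every round).
#' @param random_seed Seed for the random sort scheme.
#' @param mode `"loose"` or `"strict"` clustering (see [cluster_pack()]).
#' @param max_rounds Stop after this many rounds (default 20; typical runs
#'   converge in 4-5).
#' @param max_representatives Stop once the representative count falls to or
#'   below this limit (`NULL` = unused).
#' @param min_clustering_ratio Stop when the per-round clustering ratio (%)
#'   falls below this value (default 0.1%); a ratio of exactly 0 (fixed
#'   point) always stops the engine.
#' @param size_filter,min_bp,max_bp Drop assemblies outside
#'   `[min_bp, max_bp]` (defaults 100 kbp - 15 Mbp) before clustering.
#' @param require_ssu Drop genomes without any SSU rRNA sequence (rules out
#'   most MAGs).
#' @param chimera_exclude Drop genomes flagged by [flag_chimeric_genome()].
#' @param ssu_identity_threshold Species-delineation identity for the
#'   chimera flag (0.975 or 0.99 conventionally).
#' @param ranking A [ranking_spec()].
#' @param lists List of [accession_list()] objects (include / exclude /
#'   priority).
#' @return A `derep_config` object (named list).
#' @export
derep_config <- function(k = 12L,
                         strandedness = c("specific", "canonical"),
                         engine = c("exact_ji", "exact_igf", "sketch_ji"),
                         sketch_size = 1000L, sketch_seed = 42L,
                         threshold = 0.16,
                         pack_size = 200L,
                         sort_scheme = c("taxonomic", "random"),
                         random_seed = 1L,
                         mode = c("loose", "strict"),
                         max_rounds = 20L,
                         max_representatives = NULL,
                         min_clustering_ratio = 0.1,
                         size_filter = TRUE, min_bp = 1e5, max_bp = 1.5e7,
                         require_ssu = FALSE,
                         chimera_exclude = FALSE,
                         ssu_identity_threshold = 0.975,
                         ranking = ranking_spec(),
                         lists = list()) {
  strandedness <- match.arg(strandedness)
  engine <- match.arg(engine)
  sort_scheme <- match.arg(sort_scheme)
  mode <- match.arg(mode)
  if (pack_size < 2) abort("pack_size must be at least 2")
  if (threshold < 0) abort("threshold must be non-negative")
  if (is.null(max_rounds) && is.null(max_representatives) &&
      is.null(min_clustering_ratio)) {
    abort("At least one stop criterion must be set")
  }
  structure(list(
    k = as.integer(k), strandedness = strandedness, engine = engine,
    sketch_size = as.integer(sketch_size), sketch_seed = as.integer(sketch_seed),
    threshold = threshold, pack_size = as.integer(pack_size),
    sort_scheme = sort_scheme, random_seed = as.integer(random_seed),
    mode = mode, max_rounds = max_rounds,
    max_representatives = max_representatives,
    min_clustering_ratio = min_clustering_ratio,
    size_filter = size_filter, min_bp = min_bp, max_bp = max_bp,
    require_ssu = require_ssu, chimera_exclude = chimera_exclude,
    ssu_identity_threshold = ssu_identity_threshold,
    ranking = ranking, lists = lists
  ), class = "derep_config")
}

#' Read a dereplication config from a YAML file
#'
#' Keys mirror the arguments of [derep_config()]; `ranking` is given as a
#' named mapping `metric: direction`; `lists` as a mapping
#' `purpose: path-to-plain-text-list`.
#'
#' @param path Path to a YAML file.
#' @return A `derep_config` object.
#' @export
read_derep_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ranking)) {
    y$ranking <- ranking_spec(unlist(y$ranking))
  }
  if (!is.null(y$lists)) {
    y$lists <- purrr::imap(y$lists, function(p, purpose) {
      read_accession_list(p, purpose)
    })
  }
  do.call(derep_config, y)
}

#' Pre-clustering eligibility filter
#'
#' Applies, in order: the genome size-range filter, the SSU-presence
#' requirement and the chimera exclusion, as switched on in the config.
#' Accession include/exclude lists are applied earlier by
#' [apply_list_filters()].
#'
#' @param manifest Manifest tibble.
#' @param metrics Metric table from [compute_genome_metrics()].
#' @param config A [derep_config()].
#' @return List with `manifest` (eligible rows) and `dropped` (tibble
#'   `accession`, `reason`).
#' @export
prefilter <- function(manifest, metrics, config) {
  m <- left_join(manifest, metrics[, intersect(
    c("accession", "quast.total.len", "ssu.count", "ssu.flagged"),
    names(metrics)), drop = FALSE], by = "accession")
  reason <- rep(NA_character_, nrow(m))
  if (isTRUE(config$size_filter)) {
    bad <- !size_range_filter(m$quast.total.len, config$min_bp, config$max_bp)
    reason[bad & is.na(reason)] <- "outside genome size range"
  }
  if (isTRUE(config$require_ssu)) {
    bad <- is.na(m$ssu.count) | m$ssu.count == 0
    reason[bad & is.na(reason)] <- "no SSU rRNA sequence"
  }
  if (isTRUE(config$chimera_exclude)) {
    bad <- !is.na(m$ssu.flagged) & m$ssu.flagged
    reason[bad & is.na(reason)] <- "flagged as chimeric (SSU clusters)"
  }
  dropped <- tibble(accession = m$accession[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  list(manifest = manifest[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Split a genome list into packs
#'
#' The taxonomic scheme stable-sorts genomes by their semicolon-joined
#' lineage string (unclassified genomes last, ties broken by accession) so
#' that related genomes land in the same pack and can be dereplicated early;
#' the random scheme applies a seeded shuffle. The ordered list is then cut
#' into consecutive slices of `pack_size` (the last pack may be smaller).
#'
#' @param genomes Tibble with columns `accession` and `lineage`.
#' @param pack_size Pack size (>= 2).
#' @param sort_scheme `"taxonomic"` or `"random"`.
#' @param seed Seed for the random scheme.
#' @return List of character vectors of accessions.
#' @export
partition_into_packs <- function(genomes, pack_size,
                                 sort_scheme = c("taxonomic", "random"),
                                 seed = 1L) {
  sort_scheme <- match.arg(sort_scheme)
  if (nrow(genomes) == 0L) abort("partition_into_packs() needs at least one genome")
  if (pack_size < 2) abort("pack_size must be at least 2")
  if (sort_scheme == "taxonomic") {
    unclassified <- !nzchar(genomes$lineage) | is.na(genomes$lineage)
    ord <- order(unclassified, genomes$lineage, genomes$accession)
    acc <- genomes$accession[ord]
  } else {
    rng <- .seeded_rng(seed)
    acc <- genomes$accession[rng$sample_int(nrow(genomes))]
  }
  split(acc, ceiling(seq_along(acc) / pack_size))
}

# Private RNG stream: keeps engine randomness independent of the caller's
# RNG state and reproducible from config seeds alone.
.seeded_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state$seed <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state$seed, globalenv())
    on.exit({
      state$seed <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    sample_int = function(n) with_state(sample.int(n)),
    runif = function(n) with_state(runif(n)),
    sample = function(x, size, replace = FALSE) with_state(sample(x, size, replace))
  )
}

# Build the memoized pairwise distance function for the configured engine.
.make_distance_fn <- function(indexes, config) {
  cache <- new.env(parent = emptyenv())
  sim_fn <- switch(config$engine,
    exact_ji = function(a, b) jaccard_index(indexes[[a]], indexes[[b]]),
    exact_igf = function(a, b) identical_genome_fraction(indexes[[a]], indexes[[b]]),
    sketch_ji = function(a, b) estimate_jaccard(indexes[[a]], indexes[[b]])
  )
  calls <- new.env(parent = emptyenv()); calls$n <- 0L
  fn <- function(a, b) {
    key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
    if (!is.null(cache[[key]])) return(cache[[key]])
    calls$n <- calls$n + 1L
    d <- similarity_to_distance(sim_fn(a, b))
    cache[[key]] <- d
    d
  }
  attr(fn, "calls") <- calls
  fn
}

# Load genome sequences and build per-genome k-mer indexes or sketches.
.build_indexes <- function(manifest, config) {
  idx <- purrr::map(seq_len(nrow(manifest)), function(i) {
    contigs <- read_fasta(manifest$genome_path[i])
    ki <- kmer_index(contigs$seq, config$k, config$strandedness,
                     genome_id = manifest$accession[i])
    if (config$engine == "sketch_ji") {
      build_sketch(ki, s = config$sketch_size, seed = config$sketch_seed)
    } else {
      ki
    }
  })
  setNames(idx, manifest$accession)
}

#' Run one dereplication round
#'
#' Partitions the surviving genomes into packs, orders each pack by the
#' global ranking (priority genomes first) and clusters it with
#' [cluster_pack()]. Packs are independent by construction, so results do
#' not depend on the order in which packs are processed (the
#' parallelization contract).
#'
#' @param genomes Tibble with `accession` and `lineage` of the genomes still
#'   in play.
#' @param config A [derep_config()].
#' @param ranking_position Named integer vector: accession -> global
#'   position (1 = best, priority applied).
#' @param distance_fn Memoized distance function (accession, accession) ->
#'   distance.
#' @param round_index Round number (used to vary the random-sort shuffle).
#' @return List with `representatives` (character), `stats` (one-row
#'   tibble), `clusters` (tibble `round`, `pack`, `cluster`, `member`,
#'   `representative`, `join_order`).
#' @export
run_round <- function(genomes, config, ranking_position, distance_fn,
                      round_index = 1L) {
  if (nrow(genomes) == 0L) abort("run_round() needs at least one genome")
  packs <- partition_into_packs(
    genomes, config$pack_size, config$sort_scheme,
    seed = config$random_seed + round_index - 1L
  )
  res <- purrr::imap(packs, function(acc, pack_id) {
    ordered <- acc[order(ranking_position[acc])]
    pr <- cluster_pack(ordered, distance_fn, config$threshold, config$mode)
    mutate(pr$clusters, pack = as.integer(pack_id), round = as.integer(round_index))
  })
  clusters <- bind_rows(res)
  reps <- unique(clusters$representative)
  n_in <- nrow(genomes)
  stats <- tibble(
    round = as.integer(round_index),
    genomes_in = n_in,
    representatives_out = length(reps),
    clustering_ratio = 100 * (n_in - length(reps)) / n_in,
    packs = length(packs)
  )
  list(representatives = reps, stats = stats,
       clusters = clusters[, c("round", "pack", "cluster", "member",
                               "representative", "join_order")])
}

#' Decide whether the engine should stop
#'
#' The engine stops as soon as any active criterion fires: the maximum
#' number of rounds is reached, the representative count has fallen to or
#' below the requested ceiling, or the clustering ratio of the last round
#' fell below the minimum. A round that merged nothing (ratio exactly 0) is
#' a fixed point — no later round can merge anything either — and always
#' stops the engine.
#'
#' @param stats Tibble of per-round stats so far (last row = latest round).
#' @param n_representatives Current representative count.
#' @param config A [derep_config()].
#' @return List `stop` (logical) and `reason` (string or `NA`).
#' @export
check_stop <- function(stats, n_representatives, config) {
  last <- stats[nrow(stats), ]
  if (last$clustering_ratio == 0) {
    return(list(stop = TRUE, reason = "fixed_point"))
  }
  if (!is.null(config$max_rounds) && last$round >= config$max_rounds) {
    return(list(stop = TRUE, reason = "max_rounds"))
  }
  if (!is.null(config$max_representatives) &&
      n_representatives <= config$max_representatives) {
    return(list(stop = TRUE, reason = "max_representatives"))
  }
  if (!is.null(config$min_clustering_ratio) &&
      last$clustering_ratio < config$min_clustering_ratio) {
    return(list(stop = TRUE, reason = "min_clustering_ratio"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Dereplicate a genome collection
#'
#' The full iterative pipeline: list filters, metric computation,
#' prerequisite filters, global sum-of-ranks ranking (priority applied),
#' k-mer index or sketch construction, then rounds of pack-wise greedy
#' clustering until a stop criterion fires. Membership is composed
#' transitively across rounds, so every input genome maps to its final
#' representative.
#'
#' @param manifest Manifest tibble or path to a manifest TSV.
#' @param config A [derep_config()].
#' @param metrics Optional precomputed metric table (from
#'   [compute_genome_metrics()]); computed from the manifest when `NULL`.
#' @param verbose Print one line per round.
#' @return A `derep_result` object with elements `representatives`
#'   (character vector), `membership` (tibble `genome`,
#'   `final_representative`, `round_joined`), `round_stats` (tibble),
#'   `provenance` (per-round cluster records), `dropped` (tibble of
#'   filtered-out genomes with reasons), `stop_reason`, `config`, `ranking`.
#' @export
run_dereplication <- function(manifest, config = derep_config(),
                              metrics = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lf <- apply_list_filters(manifest, config$lists)
  manifest_kept <- lf$manifest
  dropped <- tibble(
    accession = setdiff(manifest$accession, manifest_kept$accession),
    reason = "accession list filter"
  )
  if (nrow(manifest_kept) == 0L) abort("No genome survives the accession lists")
  if (is.null(metrics)) {
    metrics <- compute_genome_metrics(
      manifest_kept, identity_threshold = config$ssu_identity_threshold
    )
  }
  pf <- prefilter(manifest_kept, metrics, config)
  dropped <- bind_rows(dropped, pf$dropped)
  eligible <- pf$manifest
  if (nrow(eligible) == 0L) abort("No genome survives the prerequisite filters")

  ranking <- sum_of_ranks(
    metrics[metrics$accession %in% eligible$accession, , drop = FALSE],
    config$ranking
  )
  excl <- attr(ranking, "excluded")
  if (nrow(excl) > 0) {
    dropped <- bind_rows(dropped, excl)
    eligible <- eligible[eligible$accession %in% ranking$accession, , drop = FALSE]
  }
  ranking <- apply_priority(ranking, lf$priority)
  position <- setNames(ranking$position, ranking$accession)

  indexes <- .build_indexes(eligible, config)
  distance_fn <- .make_distance_fn(indexes, config)

  survivors <- eligible[, c("accession", "lineage")]
  membership <- setNames(survivors$accession, survivors$accession)
  round_joined <- setNames(rep(NA_integer_, nrow(survivors)), survivors$accession)
  stats <- NULL
  provenance <- NULL
  stop_reason <- NA_character_
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    rr <- run_round(survivors, config, position, distance_fn, round_i)
    stats <- bind_rows(stats, rr$stats)
    provenance <- bind_rows(provenance, rr$clusters)
    merged <- rr$clusters$member[rr$clusters$member != rr$clusters$representative]
    round_joined[merged] <- round_i
    membership[rr$clusters$member] <- rr$clusters$representative
    # compose transitively: anything pointing at a merged genome follows it
    membership <- membership[match(membership, names(membership))] |>
      setNames(names(membership))
    survivors <- survivors[survivors$accession %in% rr$representatives, , drop = FALSE]
    if (verbose) {
      message(sprintf("round %d: %d -> %d representatives (ratio %.2f%%)",
                      round_i, rr$stats$genomes_in, rr$stats$representatives_out,
                      rr$stats$clustering_ratio))
    }
    cs <- check_stop(stats, length(rr$representatives), config)
    if (cs$stop) { stop_reason <- cs$reason; break }
  }
  # fully resolve chains (a genome's representative may itself be merged later)
  resolve <- function(m) {
    repeat {
      nxt <- m[match(m, names(m))]
      if (identical(unname(nxt), unname(m))) return(m)
      m <- setNames(unname(nxt), names(m))
    }
  }
  membership <- resolve(membership)
  structure(list(
    representatives = survivors$accession,
    membership = tibble(
      genome = names(membership),
      final_representative = unname(membership),
      round_joined = unname(round_joined[names(membership)])
    ),
    round_stats = stats,
    provenance = provenance,
    dropped = dropped,
    stop_reason = stop_reason,
    config = config,
    ranking = ranking
  ), class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat("<derep_result>\n")
  cat("  genomes in: ", nrow(x$membership), " (+", nrow(x$dropped),
      " dropped by filters)\n", sep = "")
  cat("  representatives: ", length(x$representatives), " after ",
      nrow(x$round_stats), " round(s)\n", sep = "")
  cat("  engine: ", x$config$engine, ", k=", x$config$k,
      ", threshold=", x$config$threshold, ", mode=", x$config$mode, "\n", sep = "")
  cat("  stopped: ", x$stop_reason, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the genome-to-representative mapping
#'
#' @param x A `derep_result`.
#' @param ... Unused.
#' @return The membership tibble (`genome`, `final_representative`,
#'   `round_joined`, `is_representative`).
#' @method tidy derep_result
#' @export
tidy.derep_result <- function(x, ...) {
  mutate(x$membership,
         is_representative = .data$genome == .data$final_representative)
}

#' One-row summary of a dereplication run
#'
#' @param x A `derep_result`.
#' @param ... Unused.
#' @return One-row tibble: genomes in/out, rounds, overall clustering ratio,
#'   stop reason.
#' @method glance derep_result
#' @export
glance.derep_result <- function(x, ...) {
  n_in <- nrow(x$membership)
  tibble(
    n_genomes = n_in,
    n_dropped = nrow(x$dropped),
    n_representatives = length(x$representatives),
    n_rounds = nrow(x$round_stats),
    overall_clustering_ratio = 100 * (n_in - length(x$representatives)) / n_in,
    stop_reason = x$stop_reason
  )
}

#' Plot the dereplication kinetics of a run
#'
#' Remaining representative count (log10 scale) per round, the standard way
#' to visualize how fast the engine converges to its plateau.
#'
#' @param object A `derep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot derep_result
#' @export
autoplot.derep_result <- function(object, ...) {
  st <- object$round_stats
  df <- tibble(
    round = c(0L, st$round),
    genomes = c(st$genomes_in[1], st$representatives_out)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$genomes)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dereplication round", y = "remaining genomes (log10)",
                  title = "Dereplication kinetics") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diversity, redundancy and mixity of a representative set
#'
#' Groups the original genomes by final representative and reports: the
#' number of groups; the number of distinct taxa (by default phyla, the
#' second field of an NCBI-style lineage) with at least one representative
#' ("diversity"); the redundancy index `RI = n_groups /
#' n_phyla_represented` (lower is better — fewer redundant representatives
#' per phylum); and how many groups are taxonomically pure versus mixed. A
#' group is mixed when its members span two or more distinct taxa at the
#' chosen rank (unclassified members are ignored).
#'
#' @param result A `derep_result`.
#' @param manifest The manifest tibble the run was made from (for lineages).
#' @param rank_index 1-based position in the lineage used as the reporting
#'   rank (default 2, the phylum in `"Bacteria;<phylum>;..."`).
#' @return A one-row tibble: `rank_index`, `n_groups`,
#'   `n_phyla_represented`, `redundancy_index`, `n_pure`, `n_mixed`,
#'   `n_singletons`.
#' @export
diversity_report <- function(result, manifest, rank_index = 2L) {
  lin <- split_lineage(manifest$lineage)
  taxon <- vapply(lin, function(l) {
    if (length(l) >= rank_index) l[[rank_index]] else NA_character_
  }, character(1))
  names(taxon) <- manifest$accession
  if (all(is.na(taxon[result$membership$genome]))) {
    abort(paste0("No genome has a lineage at rank index ", rank_index))
  }
  mem <- result$membership
  mem$taxon <- taxon[mem$genome]
  groups <- mem |>
    group_by(.data$final_representative) |>
    summarise(
      n_members = n(),
      n_taxa = dplyr::n_distinct(.data$taxon[!is.na(.data$taxon)]),
      .groups = "drop"
    )
  rep_taxa <- taxon[result$representatives]
  n_phyla <- dplyr::n_distinct(rep_taxa[!is.na(rep_taxa)])
  tibble(
    rank_index = as.integer(rank_index),
    n_groups = nrow(groups),
    n_phyla_represented = n_phyla,
    redundancy_index = nrow(groups) / n_phyla,
    n_pure = sum(groups$n_taxa <= 1),
    n_mixed = sum(groups$n_taxa >= 2),
    n_singletons = sum(groups$n_members == 1)
  )
}

#' Write the outputs of a dereplication run to a directory
#'
#' Emits `representatives.txt` (one accession per line), `membership.tsv`
#' (`genome`, `final_representative`, `round_joined`) and
#' `round_stats.tsv`.
#'
#' @param result A `derep_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_derep_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_lines(result$representatives, file.path(dir, "representatives.txt"))
  readr::write_tsv(result$membership, file.path(dir, "membership.tsv"))
  readr::write_tsv(result$round_stats, file.path(dir, "round_stats.tsv"))
  invisible(dir)
}
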
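#' Specify the metrics and directions of the representative ranking
#'
#' A ranking spec is an ordered set of metric names, each tagged with the
#' direction in which the metric is better. The default is the classic
#' five-metric equal-weight set: scaffolding N content down, largest-contig
#' ratio up, annotation certainty up, and the two external contamination
#' indicators down.
#'
#' @param metrics Named character vector: names are metric column names,
#'   values are `"higher_better"` or `"lower_better"`.
#' @return A `ranking_spec` object (tibble with columns `metric`,
#'   `direction`).
#' @export
#' @examples
#' ranking_spec(c(quast.N.per.100.kbp = "lower_better",
#'                annot.certainty = "higher_better"))
ranking_spec <- function(metrics = c(
  "quast.N.per.100.kbp" = "lower_better",
  "quast.largest.contig.ratio" = "higher_better",
  "annot.certainty" = "higher_better",
  "42.contam.perc" = "lower_better",
  "42.added.ali" = "lower_better"
)) {
  if (length(metrics) == 0L) abort("A ranking spec needs at least one metric")
  if (is.null(names(metrics)) || any(!nzchar(names(metrics)))) {
    abort("Every ranking metric must be named")
  }
  if (!all(metrics %in% c("higher_better", "lower_better"))) {
    abort("Directions must be 'higher_better' or 'lower_better'")
  }
  structure(tibble(metric = names(metrics), direction = unname(metrics)),
            class = c("ranking_spec", class(tibble())))
}

#' Rank genomes on a single metric
#'
#' Rank 1 is the best value under the stated direction; tied values receive
#' the average (fractional) rank of the positions they span.
#'
#' @param values Named numeric vector (names are accessions).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Named numeric vector of ranks.
#' @export
rank_single_metric <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (any(is.na(values))) abort("rank_single_metric() requires complete values")
  x <- if (direction == "higher_better") -values else values
  setNames(rank(x, ties.method = "average"), names(values))
}

#' Global sum-of-ranks ordering of genomes
#'
#' For each metric in the spec a ranking is produced across all genomes;
#' a genome's total score is the unweighted sum of its per-metric ranks, so
#' no metric is favored over another. Genomes are ordered by ascending total
#' (best representative candidate first); exact ties are broken by accession
#' lexicographic order so runs are reproducible. Genomes missing any spec
#' metric are excluded with a reason.
#'
#' @param metric_table Tibble with an `accession` column and one column per
#'   metric (see [compute_genome_metrics()]).
#' @param spec A [ranking_spec()].
#' @return A tibble (class `global_ranking`) ordered best-first with columns
#'   `accession`, `rank.<metric>` per metric, `total_rank` and `position`;
#'   excluded genomes are recorded in the `excluded` attribute (tibble
#'   `accession`, `reason`).
#' @export
sum_of_ranks <- function(metric_table, spec = ranking_spec()) {
  stopifnot(is.data.frame(metric_table), "accession" %in% names(metric_table))
  missing_cols <- setdiff(spec$metric, names(metric_table))
  excluded <- tibble(accession = character(0), reason = character(0))
  tbl <- metric_table
  if (length(missing_cols) > 0) {
    abort(paste0("Metric table lacks column(s) required by the ranking spec: ",
                 paste(missing_cols, collapse = ", ")))
  }
  has_na <- rowSums(is.na(tbl[, spec$metric, drop = FALSE])) > 0
  if (any(has_na)) {
    na_cols <- apply(is.na(tbl[has_na, spec$metric, drop = FALSE]), 1,
                     function(r) paste(spec$metric[r], collapse = ","))
    excluded <- tibble(accession = tbl$accession[has_na],
                       reason = paste0("missing metric(s): ", na_cols))
    tbl <- tbl[!has_na, , drop = FALSE]
  }
  if (nrow(tbl) == 0L) abort("No genome has complete values for the ranking spec")
  ranks <- purrr::map2(spec$metric, spec$direction, function(m, d) {
    rank_single_metric(setNames(tbl[[m]], tbl$accession), d)
  })
  out <- tibble(accession = tbl$accession)
  for (i in seq_along(ranks)) out[[paste0("rank.", spec$metric[i])]] <- unname(ranks[[i]])
  out$total_rank <- Reduce(`+`, purrr::map(ranks, unname))
  out <- arrange(out, .data$total_rank, .data$accession)
  out$position <- seq_len(nrow(out))
  attr(out, "excluded") <- excluded
  class(out) <- c("global_ranking", class(tibble()))
  out
}

#' Move priority genomes to the head of a ranking
#'
#' Priority accessions (e.g. model organisms that must stay in the
#' representative set) are moved to the front while preserving their
#' relative sum-of-ranks order; the order of the remaining genomes is
#' unchanged.
#'
#' @param ranking A `global_ranking` tibble from [sum_of_ranks()].
#' @param priority Character vector of accessions.
#' @return The reordered ranking with refreshed `position`.
#' @export
apply_priority <- function(ranking, priority = character(0)) {
  is_pri <- ranking$accession %in% priority
  out <- bind_rows(ranking[is_pri, , drop = FALSE], ranking[!is_pri, , drop = FALSE])
  out$position <- seq_len(nrow(out))
  attr(out, "excluded") <- attr(ranking, "excluded")
  class(out) <- class(ranking)
  out
}
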
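#' Greedy single-linkage clustering of one pack of ranked genomes
#'
#' Genomes must arrive best-first (global sum-of-ranks order, priority
#' applied). The first genome founds cluster 1. Each subsequent genome scans
#' the existing clusters in creation order and joins the first cluster where
#' it finds a genome at distance strictly below the threshold; if no cluster
#' accepts it, it founds a new one. In `"loose"` mode the genome is compared
#' to every member of a cluster (founder first, then join order) — pure
#' single-linkage, so one intermediate genome can bridge two groups. In
#' `"strict"` mode only cluster founders are compared, which cuts the number
#' of comparisons and mitigates single-linkage bridging. Because genomes are
#' processed best first, each cluster's founder is automatically the
#' best-ranked member and becomes the cluster representative.
#'
#' @param ordered_genomes Character vector of genome identifiers, best
#'   first.
#' @param distance_fn Function of two identifiers returning a symmetric
#'   distance (e.g. `1 - JI`).
#' @param threshold Join threshold: a genome joins a cluster when
#'   `distance < threshold` (strict inequality, so threshold 0 yields all
#'   singletons).
#' @param mode `"loose"` or `"strict"`.
#' @return A list of class `pack_result`: `clusters`, a tibble with columns
#'   `member`, `representative`, `cluster` (creation index) and `join_order`
#'   (1 = founder); and `distance_calls`, the number of distance evaluations
#'   performed.
#' @export
#' @examples
#' d <- function(a, b) abs(as.numeric(a) - as.numeric(b)) / 10
#' cluster_pack(c("1", "2", "3"), d, threshold = 0.2, mode = "loose")
cluster_pack <- function(ordered_genomes, distance_fn, threshold,
                         mode = c("loose", "strict")) {
  mode <- match.arg(mode)
  if (length(ordered_genomes) == 0L) abort("cluster_pack() needs a non-empty pack")
  clusters <- list(ordered_genomes[1])
  calls <- 0L
  for (g in ordered_genomes[-1]) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      targets <- if (mode == "loose") clusters[[ci]] else clusters[[ci]][1]
      for (t in targets) {
        calls <- calls + 1L
        if (distance_fn(g, t) < threshold) {
          clusters[[ci]] <- c(clusters[[ci]], g)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- g
  }
  tbl <- purrr::imap(clusters, function(members, ci) {
    tibble(member = members, representative = members[1],
           cluster = as.integer(ci), join_order = seq_along(members))
  })
  structure(list(clusters = bind_rows(tbl), distance_calls = calls),
            class = "pack_result")
}

#' @export
print.pack_result <- function(x, ...) {
  n_clu <- max(x$clusters$cluster)
  cat("<pack_result> ", nrow(x$clusters), " genomes in ", n_clu,
      " cluster(s); ", x$distance_calls, " distance calls\n", sep = "")
  invisible(x)
}
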
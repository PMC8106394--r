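#' Read a FASTA file into a tibble
#'
#' Parses nucleotide or amino-acid FASTA. Each definition line starts a
#' record; the first whitespace-delimited token is the `id`, the remainder of
#' the line (possibly empty) is the `description`. Multi-line sequences are
#' concatenated and uppercased; `U` is mapped to `T` so RNA input behaves as
#' DNA downstream.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, one row per
#'   record.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 a plasmid", "acgt", "ACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  is_def <- startsWith(lines, ">")
  if (!is_def[1]) {
    abort(paste0("Not FASTA (first non-blank line must start with '>'): ", path))
  }
  rec <- cumsum(is_def)
  defs <- sub("^>", "", lines[is_def])
  ids <- sub("\\s.*$", "", defs)
  desc <- ifelse(grepl("\\s", defs), trimws(sub("^\\S+\\s+", "", defs)), "")
  seqs <- vapply(
    split(lines[!is_def], rec[!is_def]),
    function(x) paste(x, collapse = ""),
    character(1)
  )
  # records with no sequence line at all are absent from `seqs`
  all_seq <- character(length(ids))
  all_seq[as.integer(names(seqs))] <- seqs
  all_seq <- chartr("u", "t", all_seq)
  all_seq <- chartr("U", "T", toupper(all_seq))
  empty <- !nzchar(all_seq)
  if (any(empty)) {
    abort(paste0(
      "FASTA record with empty sequence: ",
      paste(ids[empty], collapse = ", "), " in ", path
    ))
  }
  if (any(!nzchar(ids))) {
    abort(paste0("FASTA record with empty id in ", path))
  }
  tibble(id = ids, description = unname(desc), seq = unname(all_seq))
}

#' Write a tibble of sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` returns `x` for
#' any uppercased record table.
#'
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc), paste0(">", records$id, " ", desc),
                   paste0(">", records$id))
  lines <- purrr::map2(header, records$seq, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

# Columns of the manifest that are not free-form numeric metrics.
MANIFEST_FIXED_COLS <- c(
  "accession", "genome_path", "proteome_path", "ssu_path", "lineage", "source"
)

#' Read a genome manifest (TSV)
#'
#' The manifest is the flat-file inventory of a genome collection: one row
#' per assembly. Required columns are `accession` and `genome_path`. Optional
#' columns: `proteome_path`, `ssu_path`, `source` (`refseq`, `genbank` or
#' `custom`) and `lineage`, a semicolon-joined NCBI-style lineage string with
#' the highest rank first (e.g. `"Bacteria;Proteobacteria;..."`; empty means
#' unclassified). Any other column must be numeric and is carried along as an
#' externally computed metric (e.g. `42.contam.perc`, `checkm.completeness`)
#' usable in a [ranking_spec()].
#'
#' @param path Path to a tab-separated manifest with a header line.
#' @return A tibble, one row per genome, with external-metric columns kept
#'   numeric.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("Manifest not found: ", path))
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  required <- c("accession", "genome_path")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("Manifest missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- m$accession[duplicated(m$accession)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate accession(s) in manifest: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!"lineage" %in% names(m)) m$lineage <- ""
  m$lineage[is.na(m$lineage)] <- ""
  if (!"source" %in% names(m)) m$source <- "custom"
  metric_cols <- setdiff(names(m), MANIFEST_FIXED_COLS)
  for (col in metric_cols) {
    vals <- m[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- !is.na(vals) & is.na(num)
    if (any(bad)) {
      abort(paste0("Non-numeric value in metric column '", col, "' for accession ",
                   paste(m$accession[bad], collapse = ", ")))
    }
    m[[col]] <- num
  }
  as_tibble(m)
}

#' Split a lineage string into taxon names
#'
#' @param lineage Semicolon-joined lineage string(s), highest rank first.
#' @return A list of character vectors (empty vector for unclassified).
#' @export
split_lineage <- function(lineage) {
  purrr::map(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  })
}

#' Read a plain-text accession list
#'
#' One accession per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @param purpose One of `"include"`, `"exclude"`, `"priority"`.
#' @return An object of class `accession_list`: a character vector with a
#'   `purpose` attribute.
#' @export
read_accession_list <- function(path, purpose = c("include", "exclude", "priority")) {
  purpose <- match.arg(purpose)
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  accession_list(lines, purpose)
}

#' Construct an accession list
#'
#' @param accessions Character vector of accessions.
#' @param purpose One of `"include"`, `"exclude"`, `"priority"`.
#' @return An `accession_list` object.
#' @export
accession_list <- function(accessions, purpose = c("include", "exclude", "priority")) {
  purpose <- match.arg(purpose)
  accessions <- unique(as.character(accessions))
  if (any(!nzchar(accessions))) abort("Empty accession in list")
  structure(accessions, purpose = purpose, class = "accession_list")
}

#' Apply include / exclude / priority lists to a manifest
#'
#' If any include list is given, only its members are kept; exclude-list
#' members are then dropped (exclusion wins over inclusion on conflict).
#' Priority accessions that survive filtering are returned so that the
#' ranking step can move them to the head of the order. Accessions in a list
#' that do not occur in the manifest are ignored with a warning: lists are
#' curated by hand and often cover more genomes than one run sees.
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param lists A list of `accession_list` objects (any mix of purposes).
#' @return A list with elements `manifest` (filtered tibble, original row
#'   order) and `priority` (character vector of surviving priority
#'   accessions).
#' @export
apply_list_filters <- function(manifest, lists = list()) {
  if (inherits(lists, "accession_list")) lists <- list(lists)
  purpose <- vapply(lists, function(l) attr(l, "purpose"), character(1))
  pool <- function(p) unique(unlist(lists[purpose == p]))
  inc <- pool("include"); exc <- pool("exclude"); pri <- pool("priority")
  unknown <- setdiff(c(inc, exc, pri), manifest$accession)
  if (length(unknown) > 0) {
    warn(paste0("Accession(s) in lists not present in manifest (ignored): ",
                paste(unknown, collapse = ", ")))
  }
  keep <- manifest$accession
  if (length(inc) > 0) keep <- intersect(keep, inc)
  keep <- setdiff(keep, exc)
  out <- manifest[manifest$accession %in% keep, , drop = FALSE]
  list(manifest = out, priority = intersect(pri, out$accession))
}
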
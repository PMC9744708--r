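#' Build a per-study dataset from genotypes
#'
#' Convenience composition: allele frequencies, per-cell summaries, and the
#' population table bundled as one study, ready for [merge_studies()].
#'
#' @param g A [genotype_table()].
#' @return A list with `populations`, `summaries`, `frequencies`.
#' @export
study_dataset <- function(g) {
  f <- allele_frequencies(g)
  list(
    populations = g$populations,
    summaries = locus_population_summary(f),
    frequencies = f
  )
}

#' Merge per-study datasets into a meta-dataset
#'
#' Combines studies into a single table of per-cell summaries, applying a
#' locus alias map so that the same marker published under different names
#' (e.g. `FS1-15` vs `fs1_15`) is analyzed as one canonical locus. Aliasing
#' is a user-supplied table — marker identity is a curation decision, not
#' inferred here. Per-study provenance (`study_id`) is retained on every
#' cell.
#'
#' @param datasets List of per-study datasets as returned by
#'   [study_dataset()] (each a list with `populations`, `summaries`, and
#'   optionally `frequencies`).
#' @param alias_map Optional tibble with columns `raw`, `canonical`; loci not
#'   listed keep their name (identity default).
#' @return A `meta_dataset`: list with `populations`, `summaries`,
#'   `frequencies` (possibly `NULL`), `loci`, `studies`.
#' @export
merge_studies <- function(datasets, alias_map = NULL) {
  if (length(datasets) == 0L) stop_data("no datasets to merge")
  if (!is.null(alias_map)) {
    alias_map <- tibble::as_tibble(alias_map)
    if (!all(c("raw", "canonical") %in% names(alias_map))) {
      stop_config("alias_map needs columns `raw` and `canonical`")
    }
  }
  canon <- function(x) {
    if (is.null(alias_map)) return(x)
    i <- match(x, alias_map$raw)
    ifelse(is.na(i), x, alias_map$canonical[i])
  }
  pops <- dplyr::bind_rows(lapply(datasets, function(d) d$populations))
  key <- paste(pops$study_id, pops$population_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop_data(sprintf(
      "(study_id, population_id) collision across inputs: ('%s', '%s')",
      pops$study_id[d], pops$population_id[d]
    ))
  }
  summ <- dplyr::bind_rows(lapply(datasets, function(d) d$summaries))
  summ$locus <- canon(summ$locus)
  freq_list <- lapply(datasets, function(d) d$frequencies)
  freqs <- NULL
  if (!any(vapply(freq_list, is.null, logical(1)))) {
    freqs <- dplyr::bind_rows(freq_list)
    freqs$locus <- canon(freqs$locus)
  }
  orphan <- !paste(summ$study_id, summ$population_id, sep = "\r") %in% key
  if (any(orphan)) {
    stop_data(sprintf(
      "%d summary cell(s) reference unknown populations", sum(orphan)
    ))
  }
  structure(
    list(
      populations = pops,
      summaries = summ,
      frequencies = freqs,
      loci = sort(unique(summ$locus)),
      studies = unique(pops$study_id)
    ),
    class = "meta_dataset"
  )
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf(
    "<meta_dataset> %d study/studies, %d population(s), %d locus/loci, %d cell(s)\n",
    length(x$studies), nrow(x$populations), length(x$loci), nrow(x$summaries)
  ))
  invisible(x)
}

#' Cluster studies by locus-panel similarity
#'
#' Studies genotyped with similar marker panels form natural groups for
#' panel-effect testing. Computes the Jaccard distance between each pair of
#' study locus sets and cuts an average-linkage dendrogram at `cut`.
#'
#' @param meta A `meta_dataset`.
#' @param cut Distance threshold at which to cut the tree (default 0.5).
#' @return Named integer vector: cluster label per study.
#' @export
cluster_studies_by_loci <- function(meta, cut = 0.5) {
  stopifnot(inherits(meta, "meta_dataset"))
  panels <- split(meta$summaries$locus, meta$summaries$study_id)
  panels <- lapply(panels, unique)
  ids <- names(panels)
  n <- length(ids)
  if (n == 1L) return(setNames(1L, ids))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- panels[[i]]
      b <- panels[[j]]
      jac <- 1 - length(intersect(a, b)) / length(union(a, b))
      d[i, j] <- d[j, i] <- jac
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, h = cut)
}

#' Serialize / restore a meta-dataset as two delimited tables
#'
#' Writes `<stem>_populations.tsv` and `<stem>_cells.tsv` (per-cell
#' summaries with the `study_id` provenance column); [read_meta_dataset()]
#' restores the object (without raw frequencies).
#'
#' @param meta A `meta_dataset`.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_meta_dataset <- function(meta, stem) {
  stopifnot(inherits(meta, "meta_dataset"))
  p1 <- paste0(stem, "_populations.tsv")
  p2 <- paste0(stem, "_cells.tsv")
  readr::write_tsv(meta$populations, p1, progress = FALSE)
  readr::write_tsv(meta$summaries, p2, progress = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_meta_dataset
#' @export
read_meta_dataset <- function(stem) {
  p1 <- paste0(stem, "_populations.tsv")
  p2 <- paste0(stem, "_cells.tsv")
  for (p in c(p1, p2)) {
    if (!file.exists(p)) stop_config(sprintf("file not found: %s", p))
  }
  pops <- readr::read_tsv(p1, show_col_types = FALSE, progress = FALSE)
  summ <- readr::read_tsv(p2, show_col_types = FALSE, progress = FALSE)
  structure(
    list(
      populations = pops, summaries = summ, frequencies = NULL,
      loci = sort(unique(summ$locus)), studies = unique(pops$study_id)
    ),
    class = "meta_dataset"
  )
}
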
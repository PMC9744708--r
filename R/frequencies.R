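#' Per-cell allele frequencies from genotypes
#'
#' Counts alleles per (population, locus) cell, excluding missing calls from
#' the denominator. Cells with zero non-missing calls are absent from the
#' result (never zero-filled or imputed); a warning reports how many cells
#' were dropped.
#'
#' @param g A [genotype_table()].
#' @return An allele-frequency tibble with columns `study_id`,
#'   `population_id`, `locus`, `allele`, `frequency`, `gene_copies`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  long <- tidyr::pivot_longer(
    g$calls[, c("study_id", "population_id", "locus", "allele1", "allele2")],
    cols = c("allele1", "allele2"), values_to = "allele"
  )
  n_cells_total <- nrow(dplyr::distinct(
    g$calls, .data$study_id, .data$population_id, .data$locus
  ))
  long <- long[!is.na(long$allele), ]
  freqs <- long |>
    dplyr::count(
      .data$study_id, .data$population_id, .data$locus, .data$allele
    ) |>
    dplyr::group_by(.data$study_id, .data$population_id, .data$locus) |>
    dplyr::mutate(
      gene_copies = sum(.data$n),
      frequency = .data$n / .data$gene_copies
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "study_id", "population_id", "locus", "allele", "frequency", "gene_copies"
    )
  n_dropped <- n_cells_total - nrow(dplyr::distinct(
    freqs, .data$study_id, .data$population_id, .data$locus
  ))
  if (n_dropped > 0L) {
    warn(sprintf(
      "%d cell(s) with zero non-missing calls omitted", n_dropped
    ))
  }
  freqs
}

#' Read a per-cell allele-frequency table
#'
#' Delimited text with columns `population_id`, `locus`, `allele`,
#' `frequency` and optional `gene_copies` / `study_id`. Frequencies within a
#' cell must sum to 1 within `1e-6` (publication rounding); within tolerance
#' they are renormalized to sum exactly 1, outside it the cell is reported as
#' a data error.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return An allele-frequency tibble (see [allele_frequencies()]).
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  )
  req <- c("population_id", "locus", "allele", "frequency")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop_parse(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"study_id" %in% names(df)) df$study_id <- NA_character_
  if (!"gene_copies" %in% names(df)) df$gene_copies <- NA_integer_
  if (any(df$frequency < 0)) {
    stop_data("negative allele frequency")
  }
  df <- df |>
    dplyr::group_by(.data$study_id, .data$population_id, .data$locus) |>
    dplyr::mutate(.cell_sum = sum(.data$frequency)) |>
    dplyr::ungroup()
  bad <- abs(df$.cell_sum - 1) > 1e-6 * (1 + 1e-6)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_data(sprintf(
      "frequencies in cell (%s, %s) sum to %.8g, outside 1 +/- 1e-6",
      df$population_id[i], df$locus[i], df$.cell_sum[i]
    ))
  }
  df$frequency <- df$frequency / df$.cell_sum
  df$.cell_sum <- NULL
  df[, c("study_id", "population_id", "locus", "allele", "frequency",
         "gene_copies")]
}

#' Write an allele-frequency table
#'
#' @param f Allele-frequency tibble.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(f, path) {
  readr::write_tsv(f, path, progress = FALSE)
  invisible(path)
}

#' Per-cell diversity summary: K, M, H, He
#'
#' For each (population, locus) cell: `K` = number of alleles with positive
#' frequency, `M` = frequency of the most frequent allele, `H` = homozygosity
#' \eqn{\sum p^2}, `He` = expected heterozygosity `1 - H` (the plain
#' Gini-Simpson form, without a small-sample correction: the scaling bounds
#' constrain exactly \eqn{\sum p^2}, so He must be its complement;
#' `gene_copies` is carried so a corrected variant can be derived later).
#'
#' @param f Allele-frequency tibble (see [allele_frequencies()]).
#' @return Tibble with columns `study_id`, `population_id`, `locus`, `K`,
#'   `M`, `H`, `He`, `gene_copies`.
#' @export
locus_population_summary <- function(f) {
  f <- tibble::as_tibble(f)
  req <- c("population_id", "locus", "allele", "frequency")
  if (!all(req %in% names(f))) {
    stop_data(paste0(
      "frequency table must contain columns: ", paste(req, collapse = ", ")
    ))
  }
  if (!"study_id" %in% names(f)) f$study_id <- NA_character_
  if (!"gene_copies" %in% names(f)) f$gene_copies <- NA_integer_
  f |>
    dplyr::filter(.data$frequency > 0) |>
    dplyr::group_by(.data$study_id, .data$population_id, .data$locus) |>
    dplyr::summarise(
      K = dplyr::n(),
      M = max(.data$frequency),
      H = sum(.data$frequency^2),
      He = 1 - sum(.data$frequency^2),
      gene_copies = .data$gene_copies[1],
      .groups = "drop"
    )
}
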
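#' Construct a genotype table
#'
#' Container for diploid microsatellite calls grouped into georeferenced
#' populations. Alleles are positive integers (fragment length in base
#' pairs); a missing call has both alleles `NA` — half-calls are not
#' represented, since a single observed allele cannot enter frequency-based
#' statistics without biasing the most-frequent-allele frequency.
#'
#' @param populations Tibble with columns `study_id`, `population_id`,
#'   `latitude`, `longitude`, `n_individuals`.
#' @param calls Tibble with columns `study_id`, `population_id`,
#'   `individual_id`, `locus`, `allele1`, `allele2`.
#' @param loci Character vector giving locus order (defaults to order of
#'   appearance in `calls`).
#' @return A `genotype_table` (list with `populations`, `calls`, `loci`).
#' @export
genotype_table <- function(populations, calls, loci = NULL) {
  populations <- tibble::as_tibble(populations)
  calls <- tibble::as_tibble(calls)
  if (is.null(loci)) loci <- unique(calls$locus)
  key <- paste(populations$study_id, populations$population_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_data("(study_id, population_id) must be unique")
  }
  ok_lat <- is.na(populations$latitude) |
    (populations$latitude >= -90 & populations$latitude <= 90)
  ok_lon <- is.na(populations$longitude) |
    (populations$longitude >= -180 & populations$longitude <= 180)
  if (!all(ok_lat, ok_lon)) {
    stop_data("coordinates must be within WGS84 ranges")
  }
  bad_allele <- (!is.na(calls$allele1) & calls$allele1 <= 0) |
    (!is.na(calls$allele2) & calls$allele2 <= 0)
  if (any(bad_allele)) stop_data("allele labels must be positive integers")
  half <- xor(is.na(calls$allele1), is.na(calls$allele2))
  if (any(half)) {
    stop_data("half-missing calls are not allowed; set both alleles to NA")
  }
  structure(
    list(populations = populations, calls = calls, loci = as.character(loci)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype_table> %d population(s), %d individual(s), %d locus/loci\n",
    nrow(x$populations),
    nrow(dplyr::distinct(
      x$calls, .data$study_id, .data$population_id, .data$individual_id
    )),
    length(x$loci)
  ))
  invisible(x)
}

#' Read a GENEPOP file
#'
#' Parses the GENEPOP dialect: a title line, locus names (one per line or
#' comma-separated on one line), `POP` separators, then individual lines of
#' the form `name , 0101 0202 ...`. Allele coding width (2- or 3-digit) is
#' auto-detected from the genotype field width. An allele code of zero marks
#' a missing half; any call with a missing half is recorded as fully missing.
#'
#' GENEPOP files carry no coordinates: populations are named `pop1`,
#' `pop2`, ... in file order with `NA` coordinates, to be joined with a
#' population table downstream.
#'
#' @param path Path to a GENEPOP text file.
#' @param study_id Study identifier to attach (default: file name sans
#'   extension).
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, study_id = NULL) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop_parse("GENEPOP file too short")

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop_parse("no POP separator found")
  if (first_pop < 3L) stop_parse("expected title and locus names before POP")

  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop_parse("no locus names found")

  pop_idx <- 0L
  recs <- vector("list", length(lines))
  pop_of_line <- integer(0)
  for (i in seq(first_pop, length(lines))) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      stop_parse(sprintf(
        "line %d: expected 'name , genotypes' with a comma", i
      ))
    }
    ind <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != length(loci)) {
      stop_data(sprintf(
        "line %d: %d genotype field(s) for %d locus/loci",
        i, length(fields), length(loci)
      ))
    }
    if (!all(grepl("^[0-9]+$", fields))) {
      stop_parse(sprintf("line %d: non-numeric genotype field", i))
    }
    w <- nchar(fields)
    if (!all(w %in% c(4L, 6L))) {
      stop_parse(sprintf(
        "line %d: genotype fields must be 4 (2-digit) or 6 (3-digit) chars",
        i
      ))
    }
    half <- w / 2L
    a1 <- as.integer(substr(fields, 1L, half))
    a2 <- as.integer(substr(fields, half + 1L, w))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    recs[[i]] <- tibble::tibble(
      study_id = study_id,
      population_id = paste0("pop", pop_idx),
      individual_id = ind,
      locus = loci,
      allele1 = a1,
      allele2 = a2
    )
  }
  calls <- dplyr::bind_rows(recs)
  if (nrow(calls) == 0L) stop_parse("no individuals found")
  pops <- calls |>
    dplyr::distinct(.data$study_id, .data$population_id, .data$individual_id) |>
    dplyr::count(.data$study_id, .data$population_id, name = "n_individuals") |>
    dplyr::mutate(latitude = NA_real_, longitude = NA_real_) |>
    dplyr::select(
      "study_id", "population_id", "latitude", "longitude", "n_individuals"
    )
  genotype_table(pops, calls, loci)
}

#' Read genotypes from long-format delimited text
#'
#' One row per (individual, locus): columns `study_id`, `population_id`,
#' `individual_id`, `latitude`, `longitude`, `locus`, `allele1`, `allele2`.
#' A blank/`NA` allele marks a missing half; any call with a missing half is
#' stored fully missing.
#'
#' @param path Path to a tab- or comma-delimited text file (delimiter
#'   sniffed from the header line).
#' @return A [genotype_table()].
#' @export
read_long_genotypes <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      study_id = readr::col_character(),
      population_id = readr::col_character(),
      individual_id = readr::col_character(),
      latitude = readr::col_double(),
      longitude = readr::col_double(),
      locus = readr::col_character(),
      allele1 = readr::col_character(),
      allele2 = readr::col_character(),
      .default = readr::col_character()
    )
  )
  req <- c("study_id", "population_id", "individual_id", "latitude",
           "longitude", "locus", "allele1", "allele2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop_parse(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  parse_allele <- function(x) {
    x <- trimws(x)
    x[!nzchar(x) | is.na(x)] <- NA_character_
    bad <- !is.na(x) & !grepl("^[0-9]+$", x)
    if (any(bad)) {
      stop_parse(sprintf(
        "non-integer allele value '%s'", x[which(bad)[1]]
      ))
    }
    as.integer(x)
  }
  df$allele1 <- parse_allele(df$allele1)
  df$allele2 <- parse_allele(df$allele2)
  half <- xor(is.na(df$allele1), is.na(df$allele2))
  df$allele1[half] <- NA_integer_
  df$allele2[half] <- NA_integer_

  dup <- duplicated(df[, c("study_id", "population_id", "individual_id", "locus")])
  if (any(dup)) {
    stop_data(sprintf(
      "duplicate (individual, locus) row(s); first: individual '%s', locus '%s'",
      df$individual_id[which(dup)[1]], df$locus[which(dup)[1]]
    ))
  }
  coords <- df |>
    dplyr::distinct(
      .data$study_id, .data$population_id, .data$latitude, .data$longitude
    )
  key <- paste(coords$study_id, coords$population_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_data(sprintf(
      "conflicting coordinates for population '%s'",
      coords$population_id[which(duplicated(key))[1]]
    ))
  }
  pops <- df |>
    dplyr::distinct(
      .data$study_id, .data$population_id, .data$individual_id,
      .data$latitude, .data$longitude
    ) |>
    dplyr::count(
      .data$study_id, .data$population_id, .data$latitude, .data$longitude,
      name = "n_individuals"
    ) |>
    dplyr::select(
      "study_id", "population_id", "latitude", "longitude", "n_individuals"
    )
  calls <- df[, c("study_id", "population_id", "individual_id", "locus",
                  "allele1", "allele2")]
  genotype_table(pops, calls, unique(df$locus))
}

#' Write a genotype table to long format
#'
#' Inverse of [read_long_genotypes()]; a round-trip reproduces the calls
#' exactly.
#'
#' @param g A [genotype_table()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_long_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_table"))
  df <- g$calls |>
    dplyr::left_join(
      g$populations[, c("study_id", "population_id", "latitude", "longitude")],
      by = c("study_id", "population_id")
    ) |>
    dplyr::select(
      "study_id", "population_id", "individual_id", "latitude", "longitude",
      "locus", "allele1", "allele2"
    )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
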
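#' Validate a pipeline configuration
#'
#' Accepts a flat key-value list (or a YAML file path) and returns a
#' validated configuration with defaults filled in: `power = 5`,
#' `cell_size = 0.5`, `block = 2`, `degenerate_policy = "exclude"`,
#' `k_mode = "study"`, `seed = 1`, `origin = default_origin()`. Referenced
#' input paths must exist. The gradient, bias-validation and interpolation
#' stages require an origin.
#'
#' @param raw A named list, or the path of a YAML config file.
#' @return A list of class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) stop_config(sprintf("config file not found: %s", raw))
    raw <- yaml::read_yaml(raw)
  }
  if (!is.list(raw)) stop_config("config must be a named list or a YAML path")
  known <- c(
    "genotypes", "frequencies", "populations", "mask", "out_dir", "origin",
    "power", "cell_size", "block", "degenerate_policy", "k_mode", "seed",
    "stages"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    genotypes = raw$genotypes,
    frequencies = raw$frequencies,
    populations = raw$populations,
    mask = raw$mask,
    out_dir = raw$out_dir %||% "hescale_out",
    origin = raw$origin %||% default_origin(),
    power = raw$power %||% 5,
    cell_size = raw$cell_size %||% 0.5,
    block = raw$block %||% 2L,
    degenerate_policy = raw$degenerate_policy %||% "exclude",
    k_mode = raw$k_mode %||% "study",
    seed = raw$seed %||% 1L
  )
  if (is.null(cfg$genotypes) && is.null(cfg$frequencies)) {
    stop_config("config needs `genotypes` or `frequencies`")
  }
  for (key in c("genotypes", "frequencies", "populations", "mask")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_config(sprintf("config key `%s`: file not found: %s", key, cfg[[key]]))
    }
  }
  cfg$origin <- as.numeric(unlist(cfg$origin))
  if (length(cfg$origin) != 2L || any(is.na(cfg$origin))) {
    stop_config("config key `origin`: need c(lat, lon)")
  }
  names(cfg$origin) <- c("lat", "lon")
  if (!is.numeric(cfg$power) || cfg$power <= 0) {
    stop_config("config key `power`: must be > 0")
  }
  if (!is.numeric(cfg$cell_size) || cfg$cell_size <= 0) {
    stop_config("config key `cell_size`: must be > 0")
  }
  if (!cfg$degenerate_policy %in% c("exclude", "midpoint")) {
    stop_config("config key `degenerate_policy`: must be exclude or midpoint")
  }
  if (!cfg$k_mode %in% c("cell", "study")) {
    stop_config("config key `k_mode`: must be cell or study")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages over the configured inputs, writing each stage's
#' tables to the output directory plus a JSON run manifest. Stages
#' communicate only through files; a rerun with identical config and seed
#' produces byte-identical outputs.
#'
#' Stages: `summarize` (allele frequencies and per-cell K/M/H/He),
#' `scale` (scaled-cell and per-population scaled-He tables), `gradient`
#' (raw and scaled gradient correlations), `validate-bias` (the
#' seven-scenario report), `interpolate` (IDW surface of mean scaled He,
#' optional polygon mask, LOO residuals, jackknife CIs).
#'
#' @param cfg A [validate_config()] result (or raw config accepted by it).
#' @param stages Character subset of
#'   `c("summarize", "scale", "gradient", "validate-bias", "interpolate")`.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(cfg,
                         stages = c("summarize", "scale", "gradient",
                                    "validate-bias", "interpolate")) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  all_stages <- c("summarize", "scale", "gradient", "validate-bias",
                  "interpolate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  n_warnings <- 0L
  log_msg <- function(...) message("[hescale] ", sprintf(...))

  # --- load inputs -------------------------------------------------------
  withCallingHandlers({
    if (!is.null(cfg$genotypes)) {
      g <- read_long_genotypes(cfg$genotypes)
      freqs <- allele_frequencies(g)
      pops <- g$populations
    } else {
      freqs <- read_frequency_table(cfg$frequencies)
      if (is.null(cfg$populations)) {
        stop_config("frequency input requires a `populations` table")
      }
      pops <- readr::read_tsv(cfg$populations, show_col_types = FALSE,
                              progress = FALSE)
    }
    summ <- locus_population_summary(freqs)
    meta <- structure(
      list(populations = pops, summaries = summ, frequencies = freqs,
           loci = sort(unique(summ$locus)),
           studies = unique(pops$study_id)),
      class = "meta_dataset"
    )
    log_msg("loaded %d population(s), %d cell(s)", nrow(pops), nrow(summ))

    if ("summarize" %in% stages) {
      p <- file.path(cfg$out_dir, "cell_summaries.tsv")
      readr::write_tsv(summ, p, progress = FALSE)
      pf <- file.path(cfg$out_dir, "allele_frequencies.tsv")
      write_frequency_table(freqs, pf)
      outputs <- c(outputs, p, pf)
    }

    scaled <- scaled_he(meta, degenerate_policy = cfg$degenerate_policy,
                        k_mode = cfg$k_mode)
    log_msg("scaled %d cell(s); %d degenerate",
            nrow(scaled$cells), sum(scaled$cells$degenerate))
    if ("scale" %in% stages) {
      p1 <- file.path(cfg$out_dir, "scaled_cells.tsv")
      p2 <- file.path(cfg$out_dir, "population_scaled_he.tsv")
      readr::write_tsv(scaled$cells, p1, progress = FALSE)
      readr::write_tsv(scaled$populations, p2, progress = FALSE)
      outputs <- c(outputs, p1, p2)
    }

    pop_he <- scaled$populations[
      match(pops$population_id, scaled$populations$population_id),
    ]

    if ("gradient" %in% stages) {
      grad <- dplyr::bind_rows(
        gradient_analysis(pops, pop_he$mean_raw_he, cfg$origin, "raw"),
        gradient_analysis(pops, pop_he$mean_scaled_he, cfg$origin, "scaled")
      )
      p <- file.path(cfg$out_dir, "gradient_report.tsv")
      readr::write_tsv(grad, p, progress = FALSE)
      outputs <- c(outputs, p)
      log_msg("gradient correlations written")
    }

    if ("validate-bias" %in% stages) {
      rep <- run_bias_scenarios(meta, origin = cfg$origin, seed = cfg$seed,
                                degenerate_policy = cfg$degenerate_policy,
                                k_mode = cfg$k_mode)
      p <- file.path(cfg$out_dir, "bias_scenarios.tsv")
      readr::write_tsv(rep, p, progress = FALSE)
      outputs <- c(outputs, p)
      log_msg("bias scenarios written (seed %d)", cfg$seed)
    }

    if ("interpolate" %in% stages) {
      keep <- !is.na(pop_he$mean_scaled_he)
      spec <- grid_spec(cell_size = cfg$cell_size, block = cfg$block,
                        power = cfg$power)
      surf <- jackknife_intervals(
        pops$latitude[keep], pops$longitude[keep],
        pop_he$mean_scaled_he[keep], spec
      )
      if (!is.null(cfg$mask)) {
        rings <- read_geojson_rings(cfg$mask)
        surf <- mask_surface(surf, rings)
      }
      cv <- loo_cross_validate(
        pops$latitude[keep], pops$longitude[keep],
        pop_he$mean_scaled_he[keep], cfg$power
      )
      p1 <- file.path(cfg$out_dir, "surface.tsv")
      write_surface(surf, p1)
      p2 <- file.path(cfg$out_dir, "loo_cv.tsv")
      readr::write_tsv(tibble::tibble(
        population_id = pops$population_id[keep],
        observed = pop_he$mean_scaled_he[keep],
        predicted = cv$predicted, residual = cv$residuals
      ), p2, progress = FALSE)
      outputs <- c(outputs, p1, p2)
      log_msg("interpolation done; LOO RMSE %.5f", cv$rmse)
    }
  }, warning = function(w) {
    n_warnings <<- n_warnings + 1L
    log_msg("warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  manifest <- list(
    package = "hescale",
    version = as.character(utils::packageVersion("hescale")),
    config = cfg[setdiff(names(cfg), NULL)],
    stages = stages,
    seed = cfg$seed,
    outputs = basename(outputs),
    n_warnings = n_warnings
  )
  jsonlite::write_json(
    manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(manifest)
}
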
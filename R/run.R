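# Config-driven entry points: each run_* function is a pure function of
# (config, seed) writing deterministic CSV output. inst/scripts/ctpta.R is a
# thin command-line wrapper over these.

#' Load a run configuration
#'
#' YAML with fields `drug_files` (paths, or omitted for the packaged
#' defaults), `n_per_stratum` (default 1000), `seed`, `dt` (simulation grid
#' resolution, h), `out_dir`, and optional `grids` overriding the doubling
#' dilution defaults per drug.
#'
#' @param path YAML file, or `NULL` for the packaged default configuration.
#' @return validated config list of class `ct_config`.
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "run_config.yaml", package = "ctpta",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop_input("config file not found: ", path)
  y <- yaml::read_yaml(path)
  y$n_per_stratum <- if (is.null(y$n_per_stratum)) 1000L else as.integer(y$n_per_stratum)
  if (is.na(y$n_per_stratum) || y$n_per_stratum < 1) {
    stop_input("n_per_stratum must be >= 1")
  }
  y$seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  y$dt <- if (is.null(y$dt)) 0.005 else as.numeric(y$dt)
  if (!is.null(y$drug_files) && !all(file.exists(y$drug_files))) {
    stop_input("drug parameter file(s) not found: ",
               paste(y$drug_files[!file.exists(y$drug_files)], collapse = ", "))
  }
  y$config_path <- path
  structure(y, class = "ct_config")
}

config_models <- function(config) {
  if (is.null(config$drug_files)) {
    default_drug_models()
  } else {
    models <- lapply(config$drug_files, read_drug_model)
    names(models) <- vapply(models, function(m) m$drug, character(1))
    models
  }
}

log_run <- function(config, what) {
  files <- if (is.null(config$drug_files)) {
    c(system.file("extdata", "ceftolozane.yaml", package = "ctpta"),
      system.file("extdata", "tazobactam.yaml", package = "ctpta"))
  } else {
    config$drug_files
  }
  sums <- tools::md5sum(files)
  message(sprintf("[ctpta] %s: seed=%d n_per_stratum=%d", what, config$seed,
                  config$n_per_stratum))
  for (i in seq_along(sums)) {
    message(sprintf("[ctpta]   parameter file %s md5=%s", names(sums)[i],
                    unname(sums[i])))
  }
}

#' Build the stratified PTA cohort for a configuration
#'
#' One [sample_stratum()] call per canonical stratum, each on its own named
#' seed substream.
#'
#' @param config a [load_run_config()] result.
#' @param demo demographic model; default [demographic_model()].
#' @return row-bound cohort data frame covering all four strata.
#' @export
config_cohort <- function(config, demo = demographic_model()) {
  do.call(rbind, lapply(canonical_strata(), function(st) {
    sample_stratum(st, config$n_per_stratum, demo,
                   seed = substream_seed(config$seed, paste0("pop-", st$label)))
  }))
}

#' Run the stratified PTA simulation and write results
#'
#' Simulates PTA for every configured drug, all four canonical strata, in
#' plasma and ELF, and writes a CSV (`stratum`, `matrix`, `drug`,
#' `threshold`, `pta`, `n`, `seed`). Identical config and seed give a
#' byte-identical file.
#'
#' @param config a config list from [load_run_config()] (or a path).
#' @param out_dir output directory; created if needed. Defaults to the
#'   config's `out_dir` or `"."`.
#' @return the PTA data frame, invisibly.
#' @export
run_simulate_pta <- function(config = load_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(config, "simulate-pta")
  cohort <- config_cohort(config)
  models <- config_models(config)
  res <- do.call(rbind, lapply(models, function(m) {
    grid <- config$grids[[m$drug]] %||% NULL
    simulate_pta(cohort, m, grid = grid,
                 times = ss_time_grid(m$regimen, config$dt),
                 seed = config$seed)
  }))
  rownames(res) <- NULL
  path <- file.path(out_dir, "pta.csv")
  utils::write.csv(res[, c("stratum", "matrix", "drug", "threshold", "pta",
                           "n", "seed")], path, row.names = FALSE)
  message("[ctpta] wrote ", path)
  invisible(res)
}

#' Summarize simulated exposures by CrCl bin and write results
#'
#' Samples one cohort over the exposure bins, computes per-subject AUC and
#' Cmax in plasma and ELF, and writes geometric-mean (geometric %CV)
#' summaries per bin.
#'
#' @inheritParams run_simulate_pta
#' @return the summary data frame, invisibly.
#' @export
run_summarize_exposure <- function(config = load_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(config, "summarize-exposure")
  models <- config_models(config)
  bins <- exposure_bins()
  cohort <- do.call(rbind, lapply(bins, function(st) {
    sample_stratum(st, config$n_per_stratum, demographic_model(),
                   seed = substream_seed(config$seed, paste0("pop-", st$label)))
  }))
  res <- do.call(rbind, lapply(models, function(m) {
    exp_df <- cohort_exposures(cohort, m,
                               times = ss_time_grid(m$regimen, config$dt),
                               seed = config$seed)
    do.call(rbind, lapply(c("plasma", "elf"), function(mx) {
      sub <- exp_df[exp_df$matrix == mx, ]
      do.call(rbind, lapply(c("auc_0_tau", "cmax"), function(metric) {
        s <- summarize_exposures(sub, bins, value_col = metric)
        cbind(drug = m$drug, matrix = mx, metric = metric, s)
      }))
    }))
  }))
  rownames(res) <- NULL
  path <- file.path(out_dir, "exposure_summary.csv")
  utils::write.csv(res, path, row.names = FALSE)
  message("[ctpta] wrote ", path)
  invisible(res)
}

#' Compare outcomes from counts or a participant table
#'
#' With no input, runs the packaged fixture counts through the Newcombe
#' pipeline (reproducing the published comparison table). A counts CSV
#' (`label, x1, n1, x2, n2[, direction]`) is used as is; a participant CSV
#' (recognized by a `renal_category` column) is aggregated per arm and
#' outcome first, mortality oriented ARC-minus-normal and the cure outcomes
#' normal-minus-ARC, matching the fixtures' orientation.
#'
#' @param input path to a CSV, or `NULL` for the packaged fixtures.
#' @param out_dir output directory.
#' @param alpha two-sided level.
#' @return the comparison data frame, invisibly.
#' @export
run_compare_outcomes <- function(input = NULL, out_dir = ".", alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- if (is.null(input)) {
    trial_count_fixtures()
  } else {
    if (!file.exists(input)) stop_input("input file not found: ", input)
    df <- utils::read.csv(input, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop_input("input file has no rows")
    if ("renal_category" %in% names(df)) {
      do.call(rbind, lapply(unique(df$arm), function(a) {
        rbind(
          participant_counts(df, a, "mortality_day28", "itt",
                             "arc_minus_normal",
                             label = paste0("acm_itt_", a)),
          participant_counts(df, a, "clinical_cure_toc", "itt",
                             "normal_minus_arc",
                             label = paste0("cure_itt_", a)),
          participant_counts(df, a, "micro_cure_toc", "mitt",
                             "normal_minus_arc",
                             label = paste0("micro_mitt_", a)))
      }))
    } else {
      df
    }
  }
  res <- build_outcome_table(counts, alpha = alpha)
  path <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(res, path, row.names = FALSE)
  jsonlite::write_json(res, file.path(out_dir, "comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  message("[ctpta] wrote ", path)
  invisible(res)
}

#' Generate a synthetic participant CSV
#'
#' @param spec_file YAML overriding [cohort_spec()] fields (any subset), or
#'   `NULL` for defaults.
#' @param out_dir output directory.
#' @param seed optional seed override.
#' @return the participant data frame, invisibly.
#' @export
run_generate_cohort <- function(spec_file = NULL, out_dir = ".", seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- if (is.null(spec_file)) list() else yaml::read_yaml(spec_file)
  if (!is.null(seed)) args$seed <- seed
  spec <- do.call(cohort_spec, args)
  records <- generate_cohort(spec)
  path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(records, path, row.names = FALSE)
  message("[ctpta] wrote ", path)
  invisible(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
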
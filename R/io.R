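.cohort_numeric_cols <- c("stage", "fib4", "nfs", "fmv3g", "cmv3g", "vcte_kpa",
                          "agile3p", "agile4", "age", "bmi", "ast", "alt",
                          "platelets", "albumin", "biopsy_length_mm",
                          "area_fibrosis_pct", "area_portal_fibrosis_pct")

#' Write a cohort to tab-separated text
#'
#' @param cohort a cohort data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as.data.frame(cohort), path, na = "NA")
  invisible(path)
}

#' Read a patient cohort from delimited text
#'
#' Expects a header row. Known numeric columns are validated cell by cell:
#' rows with unparseable numeric cells are rejected (collected with their
#' line numbers in the `row_errors` attribute and reported in a message),
#' the remaining rows load normally. Unknown columns are preserved verbatim.
#' Missing any column named in `required` is a hard failure.
#'
#' @param path delimited text file with header.
#' @param delim field delimiter (default tab).
#' @param na missing-value token(s).
#' @param required character vector of mandatory columns (default none).
#' @return tibble of class `fib_cohort`; attribute `row_errors` holds a
#'   tibble (line, column, value) of rejected cells.
#' @export
read_cohort <- function(path, delim = "\t", na = c("", "NA"), required = NULL) {
  raw <- readr::read_delim(path, delim = delim, na = na, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(required, names(raw))
  if (length(miss)) stopf("missing mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  num_cols <- intersect(.cohort_numeric_cols, names(raw))
  bad_rows <- logical(nrow(raw))
  errors <- list()
  out <- raw
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- !is.na(raw[[cc]]) & is.na(v)
    if (any(bad)) {
      errors[[cc]] <- tibble::tibble(line = which(bad) + 1L, column = cc,
                                     value = raw[[cc]][bad])
      bad_rows <- bad_rows | bad
    }
    out[[cc]] <- v
  }
  if ("t2dm" %in% names(out)) out$t2dm <- as.logical(out$t2dm)
  if ("id" %in% names(out)) out$id <- suppressWarnings(as.integer(out$id))
  row_errors <- if (length(errors)) do.call(rbind, errors) else
    tibble::tibble(line = integer(0), column = character(0), value = character(0))
  if (any(bad_rows)) {
    message(sprintf("read_cohort: rejected %d row(s) with malformed numeric cells (see attr 'row_errors')",
                    sum(bad_rows)))
  }
  out <- out[!bad_rows, , drop = FALSE]
  class(out) <- c("fib_cohort", class(out))
  attr(out, "row_errors") <- row_errors
  out
}

#' Assemble a run configuration
#'
#' One flat, serialisable object governs a whole pipeline run: thresholds,
#' combination map, risk-model settings, simulation settings and the root
#' seed, so that a run is reproducible from config alone.
#'
#' @param seed root seed.
#' @param n_derivation,n_validation simulated cohort sizes for the two sets.
#' @param thresholds from [default_thresholds()].
#' @param combination_map a 12-row map (default [default_combination_map()]).
#' @param cutpoints_f4,cutpoints_f34 risk-band boundaries.
#' @param sim extra arguments passed to [sim_config()] (list).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed,
                       n_derivation = 5000,
                       n_validation = 5000,
                       thresholds = default_thresholds(),
                       combination_map = default_combination_map(),
                       cutpoints_f4 = default_band_cutpoints("F4"),
                       cutpoints_f34 = default_band_cutpoints("F34"),
                       sim = list()) {
  check_combination_map(combination_map)
  structure(list(seed = as.integer(seed),
                 n_derivation = as.integer(n_derivation),
                 n_validation = as.integer(n_validation),
                 thresholds = thresholds,
                 combination_map = combination_map,
                 cutpoints_f4 = cutpoints_f4,
                 cutpoints_f34 = cutpoints_f34,
                 sim = sim),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$combination_map <- as.data.frame(config$combination_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  map <- tibble::as_tibble(as.data.frame(x$combination_map))
  map$agile_group <- as.integer(map$agile_group)
  map$fmcm_group <- as.integer(map$fmcm_group)
  run_config(seed = x$seed,
             n_derivation = x$n_derivation,
             n_validation = x$n_validation,
             thresholds = x$thresholds,
             combination_map = map,
             cutpoints_f4 = as.numeric(x$cutpoints_f4),
             cutpoints_f34 = as.numeric(x$cutpoints_f34),
             sim = x$sim %||% list())
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: simulate, classify, fit risk charts, evaluate
#'
#' Simulates a derivation and a validation cohort (seeds derived from the
#' config's root seed), applies the study algorithm and the EASL comparator
#' to both, fits the F4 and F34 risk models on the derivation set only, and
#' evaluates everything on the validation set: per-test AUROCs, the accuracy
#' report, and the calibration of both risk charts. All artefacts are
#' written to `outdir` as TSV plus a JSON summary embedding the package
#' version, the config hash and the seed.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @param cohorts optional list with pre-loaded `derivation` and `validation`
#'   cohorts (e.g. from [read_cohort()]); when supplied, simulation is
#'   skipped and downstream behaviour is identical.
#' @return list of class `run_report`: cohorts, classification results,
#'   risk models, evaluation summaries, and provenance metadata.
#' @export
run_pipeline <- function(config, outdir = NULL, cohorts = NULL) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  co <- stage("simulate", {
    if (!is.null(cohorts)) {
      list(derivation = cohorts$derivation, validation = cohorts$validation)
    } else {
      mk <- function(n, seed) {
        simulate_cohort(do.call(sim_config, c(list(n = n, seed = seed), config$sim)))
      }
      list(derivation = mk(config$n_derivation, derive_seed(config$seed, 101)),
           validation = mk(config$n_validation, derive_seed(config$seed, 202)))
    }
  })

  cls <- stage("classify", lapply(co, function(x) {
    res <- study_algorithm(x, config$combination_map, config$thresholds)
    res$zone <- cirrhosis_zones(res$final_diagnosis)
    res$easl_diagnosis <- easl_pathway(x)$easl_diagnosis
    res
  }))

  models <- stage("fit_risk_models", list(
    F4 = fit_risk_model(co$derivation, "F4", config$cutpoints_f4),
    F34 = fit_risk_model(co$derivation, "F34", config$cutpoints_f34)
  ))

  ev <- stage("evaluate", {
    val <- co$validation
    auc_tab <- do.call(rbind, lapply(
      c(fib4 = "fib4", nfs = "nfs", fmv3g = "fmv3g", cmv3g = "cmv3g",
        vcte = "vcte_kpa", agile3p = "agile3p", agile4 = "agile4"),
      function(colname) {
        a34 <- auroc(val[[colname]], val$stage >= 3)
        a4 <- auroc(val[[colname]], val$stage == 4)
        tibble::tibble(auroc_f34 = a34$auroc, auroc_f4 = a4$auroc)
      }))
    auc_tab <- tibble::add_column(auc_tab, test = .fib_tests, .before = 1)
    risk_f4 <- predict_risk(models$F4, val)
    risk_f34 <- predict_risk(models$F34, val)
    list(
      auroc = auc_tab,
      accuracy = accuracy_report(cls$validation$final_diagnosis, val$stage),
      calibration_f4 = calibration_analysis(risk_f4, val$stage == 4),
      calibration_f34 = calibration_analysis(risk_f34, val$stage >= 3)
    )
  })

  meta <- list(package_version = as.character(packageVersion("fibrostage")),
               config_hash = config_hash(config),
               seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  report <- structure(list(cohorts = co, classifications = cls,
                           models = models, evaluation = ev, meta = meta),
                      class = "run_report")

  if (!is.null(outdir)) stage("write", write_report(report, config, outdir))
  report
}

write_report <- function(report, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (set in names(report$cohorts)) {
    write_cohort(report$cohorts[[set]], file.path(outdir, paste0(set, "_cohort.tsv")))
    readr::write_tsv(as.data.frame(report$classifications[[set]]),
                     file.path(outdir, paste0(set, "_classified.tsv")))
  }
  readr::write_tsv(as.data.frame(report$evaluation$auroc),
                   file.path(outdir, "validation_auroc.tsv"))
  readr::write_tsv(as.data.frame(report$evaluation$calibration_f4$table),
                   file.path(outdir, "calibration_f4.tsv"))
  readr::write_tsv(as.data.frame(report$evaluation$calibration_f34$table),
                   file.path(outdir, "calibration_f34.tsv"))
  write_run_config(config, file.path(outdir, "config.yaml"))
  acc <- report$evaluation$accuracy
  summary <- c(report$meta, list(
    accuracy_excluding_biopsy = acc$accuracy_excluding_biopsy,
    accuracy_including_biopsy = acc$accuracy_including_biopsy,
    biopsy_rate = acc$biopsy_rate,
    calibration_msd_f4 = report$evaluation$calibration_f4$mean_signed_diff,
    calibration_msd_f34 = report$evaluation$calibration_f34$mean_signed_diff,
    risk_model_f4 = as.list(report$models$F4$coefficients),
    risk_model_f34 = as.list(report$models$F34$coefficients)
  ))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: derivation n = %d, validation n = %d, seed = %d>\n",
              nrow(x$cohorts$derivation), nrow(x$cohorts$validation),
              x$meta$seed))
  print(x$evaluation$accuracy)
  invisible(x)
}
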
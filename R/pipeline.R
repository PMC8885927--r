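#' Run the full congener-selection / surrogate-model / prediction pipeline
#'
#' Orchestrates the end-to-end analysis from one configuration:
#' characteristic-congener selection on the emission-factor and sediment
#' tables, four-congener surrogate fits for both total EF and total
#' concentration, the emission inventory, transfer-model prediction of
#' regional total concentrations against observed geometric means, and the
#' coefficient-ratio-versus-logKow analysis. Each stage failure is reported
#' with the stage named.
#'
#' The configuration is a named list (or path to a YAML file holding one):
#'
#' * `paths`: named list of input files read via [read_pah_table()]
#'   (`sediments`, `ef`, `activities`, and optionally `transitions`,
#'   `physchem`, `observed`); *or*
#' * `simulate`: a list of [sim_config()] arguments — the synthetic study
#'   generator supplies every table;
#' * `g`: number of subgroups (default 4);
#' * `sdev_k`: k convention for fit SDEVs (default: fitted parameter count);
#' * `transfer`: optional list of [transfer_params()] overrides;
#' * `seed`: seed for the simulate route (default 1).
#'
#' @param config Named list or YAML file path.
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `selection_ef.csv`, `selection_sediment.csv`,
#'   `emissions.csv` and `predictions.csv`.
#' @return A `pah_report` list: `selected` (EF and sediment characteristic
#'   sets), `fits` (tidy + glance of both surrogate fits), `ratio` (the
#'   coefficient-ratio analysis), `predictions` (a `pah_prediction`),
#'   `sdev` (named SDEV summary), `emissions`, `config` echo and package
#'   `version`.
#' @examples
#' report <- run_pipeline(list(simulate = list(n_samples = 80), seed = 3))
#' report$selected
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  g <- config$g %||% 4
  if (g < 2 || g > 16) abort("`g` must lie in [2, 16]")
  seed <- config$seed %||% 1L
  transfer <- do.call(transfer_params, config$transfer %||% list())

  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  tables <- stage("load", {
    if (!is.null(config$simulate) || is.null(config$paths)) {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- seed
      sim_args$transfer <- transfer
      simulate_study(do.call(sim_config, sim_args))
    } else {
      p <- config$paths
      needed <- c("sediments", "ef", "activities")
      missing_p <- setdiff(needed, names(p))
      if (length(missing_p) > 0) {
        abort(sprintf("config$paths is missing: %s", paste(missing_p, collapse = ", ")))
      }
      sediments <- read_pah_table(p$sediments, "concentration")
      list(
        sediments = sediments,
        ef = read_pah_table(p$ef, "ef"),
        activities = read_pah_table(p$activities, "activity"),
        transitions = if (!is.null(p$transitions)) {
          readr::read_csv(p$transitions, show_col_types = FALSE, progress = FALSE)
        },
        physchem = if (!is.null(p$physchem)) read_pah_table(p$physchem, "physchem"),
        observed = if (!is.null(p$observed)) {
          readr::read_csv(p$observed, show_col_types = FALSE, progress = FALSE)
        } else {
          sediments |>
            pah_total() |>
            aggregate_geomean(.data$region, .data$year) |>
            dplyr::select("region", "year", "total")
        }
      )
    }
  })
  physchem <- tables$physchem %||% pah_physchem()

  sel_ef <- stage("select-congeners (EF)", {
    select_representatives(tables$ef, cluster_congeners(profile_distance(tables$ef), g))
  })
  sel_sed <- stage("select-congeners (sediments)", {
    select_representatives(tables$sediments,
                           cluster_congeners(profile_distance(tables$sediments), g))
  })
  reps_ef <- sel_ef$congener[sel_ef$representative]
  reps_sed <- sel_sed$congener[sel_sed$representative]

  fit_ef <- stage("fit-model (EF)", {
    fit_pah_ols(pah_total(tables$ef), "total", reps_ef, sdev_k = config$sdev_k)
  })
  fit_sed <- stage("fit-model (sediments)", {
    fit_pah_ols(pah_total(tables$sediments), "total", reps_sed,
                sdev_k = config$sdev_k)
  })

  emissions <- stage("build-inventory", {
    tables$emissions %||%
      total_emission(tables$ef, tables$transitions, tables$activities)
  })

  predictions <- stage("predict", {
    predict_total(emissions, physchem = physchem, sediment_fit = fit_sed,
                  observed = tables$observed, params = transfer)
  })

  ratio <- stage("coefficient-ratio", {
    if (setequal(reps_ef, reps_sed)) {
      coefficient_ratio_analysis(fit_sed, fit_ef, physchem)
    } else {
      NULL # the two tables selected different characteristic sets
    }
  })

  report <- structure(
    list(
      selected = list(ef = reps_ef, sediments = reps_sed),
      fits = list(
        ef = list(tidy = tidy(fit_ef), glance = glance(fit_ef)),
        sediments = list(tidy = tidy(fit_sed), glance = glance(fit_sed))
      ),
      fit_objects = list(ef = fit_ef, sediments = fit_sed),
      selection = list(ef = sel_ef, sediments = sel_sed),
      ratio = ratio,
      predictions = predictions,
      emissions = emissions,
      sdev = c(
        ef_fit = fit_ef$sdev_pct,
        sediment_fit = fit_sed$sdev_pct,
        prediction = unname(attr(predictions, "sdev_pct"))
      ),
      config = config,
      version = as.character(utils::packageVersion("pahcast"))
    ),
    class = "pah_report"
  )

  if (!is.null(out_dir)) {
    stage("write-report", write_report(report, out_dir))
  }
  report
}

#' @export
print.pah_report <- function(x, ...) {
  cat("<pah_report>\n")
  cat("  characteristic congeners (EF):       ",
      paste(x$selected$ef, collapse = ", "), "\n")
  cat("  characteristic congeners (sediment): ",
      paste(x$selected$sediments, collapse = ", "), "\n")
  cat(sprintf("  EF fit:       R2 = %.3f, SDEV = %.1f%%\n",
              x$fits$ef$glance$r_squared, x$fits$ef$glance$sdev_pct))
  cat(sprintf("  sediment fit: R2 = %.3f, SDEV = %.1f%%\n",
              x$fits$sediments$glance$r_squared, x$fits$sediments$glance$sdev_pct))
  if (!is.na(x$sdev[["prediction"]])) {
    cat(sprintf("  emission-based prediction SDEV = %.1f%% (N = %d)\n",
                x$sdev[["prediction"]], attr(x$predictions, "n")))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    schema_version = "1.0",
    package_version = report$version,
    selected = report$selected,
    fits = list(
      ef = c(as.list(report$fits$ef$glance),
             list(coefficients = report$fits$ef$tidy)),
      sediments = c(as.list(report$fits$sediments$glance),
                    list(coefficients = report$fits$sediments$tidy))
    ),
    ratio = if (!is.null(report$ratio)) {
      list(ratios = report$ratio$ratios, glance = glance(report$ratio$fit))
    },
    sdev = as.list(report$sdev),
    sdev_bracket = as.list(attr(report$predictions, "sdev_bracket")),
    n_predictions = attr(report$predictions, "n"),
    config = report$config
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  readr::write_csv(report$selection$ef, file.path(out_dir, "selection_ef.csv"))
  readr::write_csv(report$selection$sediments,
                   file.path(out_dir, "selection_sediment.csv"))
  readr::write_csv(as_tibble(report$emissions), file.path(out_dir, "emissions.csv"))
  readr::write_csv(as_tibble(report$predictions), file.path(out_dir, "predictions.csv"))
  invisible(report)
}
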
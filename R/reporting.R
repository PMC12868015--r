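# Result serialization: CSV/JSON reports and run manifests.

.result_tables <- function(x) {
  if (inherits(x, "cea_comparison")) {
    list(base_case = glance(x), strategies = tidy(x),
         trace_bca = x$bca$trace, trace_bcs = x$bcs$trace)
  } else if (inherits(x, "psa_result")) {
    list(psa_summary = glance(x), psa_draws = x$draws, ceac = x$ceac)
  } else if (inherits(x, "threshold_result")) {
    list(threshold = tidy(x))
  } else if (inherits(x, "strategy_result")) {
    list(strategy = glance(x), trace = x$trace)
  } else if (inherits(x, "owsa_result")) {
    list(owsa = tibble::as_tibble(x))
  } else if (inherits(x, "twsa_result")) {
    list(twsa = tibble::as_tibble(x))
  } else if (inherits(x, "tornado_result")) {
    list(tornado = tibble::as_tibble(x))
  } else {
    rlang::abort("write_report(): unsupported result type")
  }
}

#' Write an analysis result to disk
#'
#' Serializes any result object (base-case comparison, PSA, sweep,
#' two-way map, tornado, or threshold) to one file per component table,
#' either CSV (one file per table) or a single JSON document.  Floats are
#' written at full precision; files are round-trippable.
#'
#' @param x A result object.
#' @param dir Output directory (created if absent).
#' @param format `"csv"` (default) or `"json"`.
#' @param stem Filename stem (default: derived from the result class).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(x, dir, format = c("csv", "json"), stem = NULL) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- .result_tables(x)
  stem <- stem %||% sub("_result$", "", class(x)[1])
  files <- if (identical(format, "json")) {
    f <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(tabs, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    f
  } else {
    vapply(names(tabs), function(nm) {
      f <- file.path(dir, paste0(stem, "_", nm, ".csv"))
      utils::write.csv(tabs[[nm]], f, row.names = FALSE)
      f
    }, character(1))
  }
  invisible(unname(files))
}

#' Write a run manifest
#'
#' Records the scenario name and configuration hash, the analysis kind,
#' the seed, the package version, a timestamp, and the list of output
#' files, as `manifest.json` in `dir`.  The hash changes exactly when the
#' scenario configuration changes.
#'
#' @param dir Output directory.
#' @param scn The `cryo_scenario` analysed.
#' @param analysis Analysis kind label (e.g. `"base"`, `"psa"`).
#' @param files Character vector of output files written.
#' @param seed Seed used, or `NA` for deterministic analyses.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, scn, analysis, files, seed = NA_integer_) {
  manifest <- list(
    scenario = scn$name,
    scenario_hash = scenario_hash(scn),
    analysis = analysis,
    seed = seed,
    package_version = as.character(utils::packageVersion("cryocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(basename(files))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Configuration hash of a scenario
#'
#' @param scn A `cryo_scenario`.
#' @return A short hash string that changes iff the configuration changes.
#' @export
scenario_hash <- function(scn) {
  rlang::hash(scenario_to_list(scn))
}
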
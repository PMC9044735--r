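#' Read a registry CSV with per-row validation
#'
#' Expects UTF-8 with a header row and at least the columns `record_id`,
#' `sex`, `date_of_birth` (ISO-8601), `postal_code`; any further columns are
#' carried as clinical attributes. Diagnoses may be supplied as a companion
#' long-format CSV (`record_id`, `code_system`, `code`, `year`).
#'
#' @param path registry CSV path.
#' @param diagnoses_path optional companion diagnosis CSV.
#' @param registry_id `"A"` or `"B"`, if not present as a column.
#' @param max_error_fraction abort when more than this fraction of rows fails
#'   validation (default 1%); below it, bad rows are reported and skipped.
#' @return list with `records` (validated tibble), `errors` (per-row report
#'   with original row numbers) and `diagnoses` (tibble or `NULL`).
#' @export
read_registry <- function(path, diagnoses_path = NULL, registry_id = NULL,
                          max_error_fraction = 0.01) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    sex = readr::col_character(),
    date_of_birth = readr::col_character(),
    postal_code = readr::col_character(),
    .default = readr::col_guess()
  ))
  v <- validate_registry(raw, registry_id = registry_id)
  if (nrow(raw) > 0 && nrow(v$errors) / nrow(raw) > max_error_fraction) {
    abort(sprintf(
      "%d of %d rows (%.1f%%) failed validation, above the %.1f%% tolerance",
      nrow(v$errors), nrow(raw), 100 * nrow(v$errors) / nrow(raw),
      100 * max_error_fraction))
  }
  diagnoses <- NULL
  if (!is.null(diagnoses_path)) {
    diagnoses <- readr::read_csv(diagnoses_path, col_types = readr::cols(
      record_id = readr::col_character(),
      code_system = readr::col_character(),
      code = readr::col_character(),
      year = readr::col_integer()
    ))
  }
  list(records = v$records, errors = v$errors, diagnoses = diagnoses)
}

#' Write a flow report as JSON and an aligned text table
#'
#' @param report a [flow_report()].
#' @param json_path,txt_path output paths (`NULL` to skip either).
#' @return the report, invisibly.
#' @export
write_flow_report <- function(report, json_path = NULL, txt_path = NULL) {
  stopifnot(inherits(report, "flow_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(denominator_total = attr(report, "denominator_total"),
           nodes = tibble::as_tibble(report)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(txt_path)) {
    writeLines(utils::capture.output(print(report)), txt_path)
  }
  invisible(report)
}

#' Run the full linkage pipeline and write its artifacts
#'
#' Composes the stages end to end: read (or simulate) the two registries,
#' pseudonymize them through the three-party chain, link on final pseudonyms,
#' write the flow report, inclusion-bias table and — when ground truth is
#' available — performance metrics, together with a manifest recording
#' versions, seeds, input checksums and per-stage status. A rerun with the
#' same configuration is byte-identical for the deterministic stages. Secrets
#' are read from files and never written to any output or log; record-level
#' messages reference `record_id` only.
#'
#' @param config a named list with elements:
#'   \describe{
#'     \item{`out_dir`}{output directory (created if needed)}
#'     \item{`sender_key_file`, `ttp_key_file`}{files holding the two
#'       secrets; checked before anything is read}
#'     \item{`a_path`, `b_path`, `a_diagnoses_path`, `b_diagnoses_path`}{input
#'       CSVs — or instead:}
#'     \item{`simulate`}{a [sim_config()] to generate the registries}
#'     \item{`seed`}{integer seed for simulation}
#'     \item{`characteristics`}{attribute columns for the inclusion table
#'       (default: those of the synthetic generator present in A)}
#'   }
#' @return (invisibly) a list of the in-memory stage results, including the
#'   `manifest` written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  for (kf in c("sender_key_file", "ttp_key_file")) {
    if (is.null(config[[kf]]) || !file.exists(config[[kf]])) {
      abort(paste0("missing key file for `", kf, "`; refusing to read any registry"))
    }
  }
  sender_secret <- readLines(config$sender_key_file, n = 1, warn = FALSE)
  ttp_secret <- readLines(config$ttp_key_file, n = 1, warn = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("registrylink")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    inputs = list(),
    stages = list()
  )
  results <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(out, "error")
    manifest$stages[[name]] <<- if (ok) "completed" else
      paste0("failed: ", conditionMessage(out))
    if (!ok) {
      write_manifest(manifest, config$out_dir)
      abort(paste0("stage `", name, "` failed: ", conditionMessage(out)))
    }
    out
  }

  data <- stage("input", {
    if (!is.null(config$simulate)) {
      pop <- generate_population(config$simulate, seed = config$seed)
      generate_registries(pop, seed = config$seed + 1L)
    } else {
      ra <- read_registry(config$a_path, config$a_diagnoses_path, "A")
      rb <- read_registry(config$b_path, config$b_diagnoses_path, "B")
      manifest$inputs <<- list(a = file_checksum(config$a_path),
                               b = file_checksum(config$b_path))
      list(a = ra$records, b = rb$records,
           a_diagnoses = ra$diagnoses, b_diagnoses = rb$diagnoses,
           truth = NULL)
    }
  })

  results$pseudonymized <- stage("pseudonymize", {
    a_dx <- has_breast_cancer_dx(data$a, data$a_diagnoses)
    b_dx <- has_breast_cancer_dx(data$b, data$b_diagnoses)
    ps <- pseudonymize_registries(a_dx, b_dx, sender_secret, ttp_secret)
    readr::write_csv(ps$a, file.path(config$out_dir, "pseudonymized_a.csv"))
    readr::write_csv(ps$b, file.path(config$out_dir, "pseudonymized_b.csv"))
    ps
  })

  results$linkage <- stage("link", {
    res <- link_registries(results$pseudonymized$a, results$pseudonymized$b)
    readr::write_csv(res$pairs, file.path(config$out_dir, "matched_pairs.csv"))
    readr::write_csv(res$dispositions,
                     file.path(config$out_dir, "dispositions.csv"))
    res
  })

  results$flow <- stage("flow_report", {
    fr <- flow_report(results$linkage)
    write_flow_report(fr, file.path(config$out_dir, "flow_report.json"),
                      file.path(config$out_dir, "flow_report.txt"))
    fr
  })

  results$inclusion <- stage("assess", {
    chars <- config$characteristics %||%
      intersect(c("diagnosis_year", "age_at_diagnosis", "stage", "surgery"),
                names(data$a))
    if (length(chars) == 0) return(NULL)
    cohort <- data$a |>
      dplyr::filter(.data$sex == "female") |>
      dplyr::select(dplyr::all_of(c("record_id", chars)))
    inc <- inclusion_table(
      cohort,
      included = results$linkage$pairs$record_id_a,
      characteristics = chars)
    readr::write_csv(inc$table, file.path(config$out_dir, "inclusion_table.csv"))
    readr::write_csv(inc$tests, file.path(config$out_dir, "inclusion_tests.csv"))
    inc
  })

  if (!is.null(data$truth)) {
    results$metrics <- stage("analyze", {
      perf <- linkage_performance(results$linkage, data$truth)
      jsonlite::write_json(as.list(perf),
                           file.path(config$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      perf
    })
  }

  results$manifest <- manifest
  write_manifest(manifest, config$out_dir)
  invisible(results)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

file_checksum <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  as.character(openssl::md5(con))
}
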
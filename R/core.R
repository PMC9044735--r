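#' Registry tables
#'
#' All linkage functions in this package operate on plain tibbles, one row per
#' person-record. A *registry* table has at least the columns
#'
#' \describe{
#'   \item{`record_id`}{character, opaque, unique within the registry}
#'   \item{`registry_id`}{`"A"` (cancer registry) or `"B"` (primary-care
#'     registry)}
#'   \item{`sex`}{`"female"`, `"male"` or `"unknown"`}
#'   \item{`date_of_birth`}{a `Date`}
#'   \item{`postal_code`}{Dutch format: 4 digits optionally followed by two
#'     upper-case letters, e.g. `"1234AB"` or `"1234"`}
#' }
#'
#' plus any number of clinical/stratification attribute columns (diagnosis
#' year, tumour stage, practice identifier, ...). Diagnoses live in a
#' companion long table with columns `record_id`, `code_system` (`"ICD10"` or
#' `"ICPC1"`), `code`, `year`.
#'
#' @name registry-tables
NULL

.sex_levels <- c("female", "male", "unknown")
.pc_regex <- "^[0-9]{4}([A-Z]{2})?$"

#' Validate the structural invariants of a registry table
#'
#' Checks required columns, sex levels, date validity, postal-code format and
#' record-id uniqueness. Invalid rows are returned in a per-row error report
#' rather than silently dropped.
#'
#' @param records a registry tibble (see [registry-tables]).
#' @param registry_id optional; if given, overrides/creates the `registry_id`
#'   column.
#' @return a list with elements `records` (the valid rows, as a tibble) and
#'   `errors` (tibble with `record_id`, `row`, `reason`).
#' @export
validate_registry <- function(records, registry_id = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("record_id", "sex", "date_of_birth", "postal_code")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("registry is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.null(registry_id)) records$registry_id <- registry_id
  if (!"registry_id" %in% names(records)) {
    abort("registry needs a `registry_id` column (\"A\" or \"B\"), or pass `registry_id =`")
  }
  records$record_id <- as.character(records$record_id)
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record_id within registry: ",
                 paste(unique(head(dup, 5)), collapse = ", ")))
  }

  dob <- records$date_of_birth
  if (!inherits(dob, "Date")) {
    # strict ISO-8601; anything else (e.g. "14/05/1957") becomes NA and is
    # reported below
    dob <- as.Date(suppressWarnings(
      readr::parse_date(as.character(records$date_of_birth), format = "%Y-%m-%d")))
  }
  bad_dob <- is.na(dob)
  bad_sex <- !(records$sex %in% .sex_levels)
  bad_pc <- is.na(records$postal_code) |
    !stringr::str_detect(records$postal_code, .pc_regex)

  reason <- dplyr::case_when(
    bad_dob ~ "date_of_birth is not a valid ISO-8601 date",
    bad_pc ~ "postal_code does not match 4 digits + optional 2 letters",
    bad_sex ~ "sex is not one of female/male/unknown",
    TRUE ~ NA_character_
  )
  bad <- !is.na(reason)
  errors <- tibble::tibble(
    record_id = records$record_id[bad],
    row = which(bad),
    reason = reason[bad]
  )
  records$date_of_birth <- dob
  list(records = records[!bad, , drop = FALSE], errors = errors)
}

#' Extract the exact linkage key (date of birth, 4-digit postal code)
#'
#' The deterministic linkage key is the combination of date of birth and the
#' neighbourhood-level 4-digit prefix of the postal code (pc4). The 2-letter
#' suffix, which identifies the street level, is discarded.
#'
#' @param records a registry tibble.
#' @return a tibble with columns `record_id`, `dob`, `pc4` and `key` (a
#'   canonical `"YYYY-MM-DD|PPPP"` serialization usable for grouping).
#' @examples
#' r <- tibble::tibble(record_id = "x", registry_id = "A", sex = "female",
#'                     date_of_birth = as.Date("1957-05-14"),
#'                     postal_code = "1234AB")
#' extract_linkage_key(r)
#' @export
extract_linkage_key <- function(records) {
  records <- tibble::as_tibble(records)
  bad <- is.na(records$date_of_birth) |
    !inherits(records$date_of_birth, "Date") |
    is.na(records$postal_code) |
    !stringr::str_detect(records$postal_code, .pc_regex)
  if (any(bad)) {
    abort(paste0(
      "malformed date of birth or postal code for record_id: ",
      paste(head(records$record_id[bad], 5), collapse = ", "),
      if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else ""
    ))
  }
  pc4 <- stringr::str_sub(records$postal_code, 1, 4)
  tibble::tibble(
    record_id = records$record_id,
    dob = records$date_of_birth,
    pc4 = pc4,
    key = paste0(format(records$date_of_birth, "%Y-%m-%d"), "|", pc4)
  )
}

#' Aggregate quasi-identifiers to (birth year, birth quarter, pc4)
#'
#' The receiving party never sees the exact date of birth or the full postal
#' code: before transfer the sender coarsens them to birth year, calendar
#' quarter of birth (Q1 = Jan-Mar) and the 4-digit postal prefix.
#'
#' @inheritParams extract_linkage_key
#' @return a tibble with `record_id`, `birth_year`, `birth_quarter`, `pc4`.
#' @export
aggregate_qid <- function(records) {
  key <- extract_linkage_key(records)
  month <- as.integer(format(key$dob, "%m"))
  tibble::tibble(
    record_id = key$record_id,
    birth_year = as.integer(format(key$dob, "%Y")),
    birth_quarter = as.integer(ceiling(month / 3)),
    pc4 = key$pc4
  )
}

#' Flag records carrying the qualifying breast-cancer diagnosis
#'
#' A cancer-registry (A) record qualifies if any of its ICD-10 codes starts
#' with `"C50"` (malignant neoplasm of breast, any subsite); a primary-care
#' (B) record qualifies if any of its ICPC-1 codes equals `"X76"`. The year of
#' the code is deliberately not constrained: requiring diagnosis years to
#' agree across registries would make the inclusion requirement stronger than
#' intended.
#'
#' @param records a registry tibble.
#' @param diagnoses long diagnosis tibble (`record_id`, `code_system`, `code`,
#'   `year`).
#' @return `records` with an added logical column `breast_cancer_dx`.
#' @export
has_breast_cancer_dx <- function(records, diagnoses) {
  records <- tibble::as_tibble(records)
  diagnoses <- tibble::as_tibble(diagnoses)
  qualifying <- diagnoses |>
    dplyr::inner_join(
      dplyr::select(records, "record_id", "registry_id"),
      by = "record_id"
    ) |>
    dplyr::filter(
      (.data$registry_id == "A" & .data$code_system == "ICD10" &
         stringr::str_starts(.data$code, "C50")) |
      (.data$registry_id == "B" & .data$code_system == "ICPC1" &
         .data$code == "X76")
    ) |>
    dplyr::distinct(.data$record_id)
  records$breast_cancer_dx <- records$record_id %in% qualifying$record_id
  records
}
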
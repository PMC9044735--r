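#' Pearson chi-square test of independence for a contingency table
#'
#' Plain Pearson statistic sum((O-E)^2/E) with df = (r-1)(c-1) and an
#' upper-tail chi-square p-value; no continuity correction. Thin wrapper
#' around [stats::chisq.test()] with explicit handling of degenerate tables.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @return one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(rbind(c(10, 90), c(30, 70)))  # statistic 12.5
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("contingency table must have at least 2 rows and 2 columns")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("contingency table must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("degenerate table: a row or column sums to zero")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

#' Inclusion-bias table: who made it into the linked registry?
#'
#' For each stratification characteristic, cross-tabulates the full cohort
#' against linked-inclusion status and tests homogeneity of the inclusion
#' fraction across categories with a Pearson chi-square test. This is the
#' standard check for selective linkage loss (e.g. women diagnosed long ago,
#' or with advanced disease, being linked less often). No multiple-testing
#' adjustment is applied across characteristics; interpret the per-table
#' p-values accordingly.
#'
#' @param cohort tibble with `record_id` plus one column per characteristic.
#' @param included character vector of `record_id`s that were included in the
#'   linked registry.
#' @param characteristics names of `cohort` columns to tabulate. `NA` values
#'   form an explicit `"Unknown"` category.
#' @return an object of class `inclusion_table`: list with `table` (tibble
#'   `characteristic`, `category`, `n`, `n_included`, `pct_included`) and
#'   `tests` (tibble `characteristic`, `statistic`, `df`, `p_value`, `note`).
#'   Categories with zero cohort records are flagged in `note` and excluded
#'   from the test.
#' @export
inclusion_table <- function(cohort, included, characteristics) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(characteristics %in% names(cohort)))
  if (nrow(cohort) == 0) {
    return(structure(list(
      table = tibble::tibble(characteristic = character(), category = character(),
                             n = integer(), n_included = integer(),
                             pct_included = double()),
      tests = tibble::tibble(characteristic = character(), statistic = double(),
                             df = double(), p_value = double(),
                             note = character())
    ), class = "inclusion_table"))
  }
  is_in <- cohort$record_id %in% included

  one_char <- function(ch) {
    cat_raw <- cohort[[ch]]
    category <- as.character(cat_raw)
    category[is.na(category)] <- "Unknown"
    lev <- if (is.factor(cat_raw)) {
      # declared-but-empty factor levels are kept so they can be flagged
      unique(c(levels(cat_raw), intersect("Unknown", category)))
    } else sort(unique(category))
    category <- factor(category, levels = lev)
    tab <- tibble::tibble(category = category, included = is_in) |>
      dplyr::count(.data$category, .data$included, .drop = FALSE) |>
      tidyr::pivot_wider(names_from = "included", values_from = "n",
                         values_fill = 0L)
    n_inc <- if ("TRUE" %in% names(tab)) tab[["TRUE"]] else rep(0L, nrow(tab))
    n_out <- if ("FALSE" %in% names(tab)) tab[["FALSE"]] else rep(0L, nrow(tab))
    n <- n_inc + n_out
    block <- tibble::tibble(
      characteristic = ch, category = as.character(tab$category),
      n = n, n_included = n_inc,
      pct_included = ifelse(n == 0, NA_real_, 100 * n_inc / n)
    )
    nonzero <- n > 0
    note <- if (all(nonzero)) NA_character_ else {
      paste0("zero-count categories excluded from test: ",
             paste(block$category[!nonzero], collapse = ", "))
    }
    m <- cbind(included = n_inc[nonzero], not_included = n_out[nonzero])
    test <- tryCatch(
      chi_square_independence(m),
      error = function(e) tibble::tibble(statistic = NA_real_, df = NA_real_,
                                         p_value = NA_real_)
    )
    test$characteristic <- ch
    test$note <- note
    list(block = block, test = dplyr::select(
      test, "characteristic", "statistic", "df", "p_value", "note"))
  }

  parts <- purrr::map(characteristics, one_char)
  structure(list(
    table = purrr::list_rbind(purrr::map(parts, "block")),
    tests = purrr::list_rbind(purrr::map(parts, "test"))
  ), class = "inclusion_table")
}

#' @export
tidy.inclusion_table <- function(x, ...) x$table

#' @export
glance.inclusion_table <- function(x, ...) x$tests

#' @export
print.inclusion_table <- function(x, ...) {
  cat("Inclusion by subgroup\n")
  for (ch in unique(x$table$characteristic)) {
    t <- x$tests[x$tests$characteristic == ch, ]
    p <- if (is.na(t$p_value)) "test not computed" else {
      if (t$p_value < 0.001) "p < 0.001" else sprintf("p = %.3f", t$p_value)
    }
    cat("\n", ch, "  (", p, ")\n", sep = "")
    b <- x$table[x$table$characteristic == ch, ]
    cat(sprintf("  %-20s %9s %9s %7s\n", "category", "N", "included", "%"))
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-20s %9d %9d %6.1f%%\n", b$category[i], b$n[i],
                  b$n_included[i], b$pct_included[i]))
    }
  }
  invisible(x)
}

#' @export
autoplot.inclusion_table <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$pct_included, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$characteristic), scales = "free_y") +
    ggplot2::labs(x = "% included", y = NULL,
                  title = "Inclusion fraction by subgroup") +
    ggplot2::theme_minimal()
}

#' Build a GP validation sample of linked patients
#'
#' To spot-check linkage accuracy, general practices are asked to confirm the
#' diagnosis of a handful of their linked patients. Practices are ranked by
#' number of linked patients; from the larger half, practices are drawn at
#' random with probability proportional to size, and *all* linked patients of
#' each drawn practice are added until the cumulative sample reaches
#' `target_n`. Each patient's validation sheet carries only what the GP needs
#' to find the patient in their own records — year and quarter of birth,
#' registration date, diagnosis years in both registries, last known visit —
#' never a full date of birth or postal code.
#'
#' @param linked tibble of linked patients with columns `record_id`,
#'   `practice_id`, `birth_year`, `birth_quarter`, and optionally
#'   `registration_date`, `dx_year_cancer_registry`, `dx_year_gp`,
#'   `last_visit_date`, `last_visit_codes` (missing ones are emitted as `NA`).
#' @param target_n number of patients to validate (default 44; 40 to 50 is a
#'   feasible ask of volunteer practices).
#' @param seed optional integer seed for the practice draw.
#' @return tibble of validation sheets, one row per sampled patient, with
#'   `confirmation_status = "pending"`. If fewer than `target_n` patients are
#'   available, all are returned with a shortfall warning.
#' @export
gp_validation_sample <- function(linked, target_n = 44, seed = NULL) {
  stopifnot(target_n >= 0)
  linked <- tibble::as_tibble(linked)
  sheet_cols <- c("practice_id", "record_id", "birth_year", "birth_quarter",
                  "registration_date", "dx_year_cancer_registry", "dx_year_gp",
                  "last_visit_date", "last_visit_codes")
  if (target_n == 0 || nrow(linked) == 0) {
    if (target_n > 0) warn("fewer linked patients than target_n; returning all")
    out <- linked[0, intersect(sheet_cols, names(linked)), drop = FALSE]
    out$confirmation_status <- character(0)
    return(out)
  }
  stopifnot("practice_id" %in% names(linked))

  draw <- function() {
    sizes <- linked |>
      dplyr::count(.data$practice_id, name = "n_linked") |>
      dplyr::arrange(dplyr::desc(.data$n_linked))
    top <- sizes[seq_len(ceiling(nrow(sizes) / 2)), , drop = FALSE]
    if (nrow(linked) < target_n) {
      warn("fewer linked patients than target_n; returning all")
      return(linked)
    }
    chosen <- character(0)
    cum <- 0
    pool <- top
    while (cum < target_n && nrow(pool) > 0) {
      i <- sample.int(nrow(pool), 1, prob = pool$n_linked)
      chosen <- c(chosen, pool$practice_id[i])
      cum <- cum + pool$n_linked[i]
      pool <- pool[-i, , drop = FALSE]
    }
    if (cum < target_n) {
      # top half exhausted before reaching the target: fall back to the rest
      rest <- sizes[!sizes$practice_id %in% chosen, , drop = FALSE]
      while (cum < target_n && nrow(rest) > 0) {
        i <- sample.int(nrow(rest), 1, prob = rest$n_linked)
        chosen <- c(chosen, rest$practice_id[i])
        cum <- cum + rest$n_linked[i]
        rest <- rest[-i, , drop = FALSE]
      }
    }
    linked[linked$practice_id %in% chosen, , drop = FALSE]
  }
  sampled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  for (col in sheet_cols) if (!col %in% names(sampled)) sampled[[col]] <- NA
  out <- sampled[, sheet_cols, drop = FALSE]
  out$confirmation_status <- "pending"
  # privacy invariant of the sheet: no raw date of birth, no postal code
  stopifnot(!any(c("date_of_birth", "postal_code", "pc4", "dob") %in% names(out)))
  out
}
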
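#' @rdname link_registries
#' @format NULL
#' @export
linkage_dispositions <- c(
  "excluded_nonunique_in_A",
  "unmatched",
  "matched_unique_no_dx",
  "included_unique_with_dx",
  "matched_nonunique_ambiguous_or_no_dx",
  "included_nonunique_resolved"
)

#' Partition a registry by uniqueness of its linkage key
#'
#' A record is *unique* iff no other record in the same registry shares its
#' linkage key (or pseudonym). Non-unique records are returned grouped by
#' their shared key.
#'
#' @param records a registry tibble, raw or pseudonymized (a `pseudonym`
#'   column, if present, is used as the key).
#' @return list with `unique` (tibble of unique records) and `groups` (tibble
#'   of non-unique records with their shared `key` and group size `n`).
#' @export
partition_by_key_uniqueness <- function(records) {
  records <- tibble::as_tibble(records)
  key <- registry_key(records)
  n <- as.integer(table(key)[key])
  grouped <- dplyr::arrange(
    dplyr::bind_cols(tibble::tibble(key = key, n = n), records)[n > 1, ],
    .data$key)
  list(unique = records[n == 1, , drop = FALSE], groups = grouped)
}

registry_key <- function(records) {
  if ("pseudonym" %in% names(records)) {
    as.character(records$pseudonym)
  } else {
    extract_linkage_key(records)$key
  }
}

# Restrict to females, count what was removed. Works for raw and
# pseudonymized tables alike (sex travels in the clinical payload).
restrict_female <- function(records) {
  if (!"sex" %in% names(records)) {
    abort("registry has no `sex` column; cannot apply the female restriction")
  }
  list(
    records = records[records$sex == "female", , drop = FALSE],
    n_male = sum(records$sex == "male"),
    n_unknown_sex = sum(!records$sex %in% c("female", "male"))
  )
}

resolve_dx_flag <- function(records, diagnoses, side) {
  if ("breast_cancer_dx" %in% names(records)) return(records)
  if (is.null(diagnoses)) {
    abort(paste0("registry ", side, " has no `breast_cancer_dx` column and no ",
                 "diagnosis table was supplied"))
  }
  has_breast_cancer_dx(records, diagnoses)
}

#' Deterministic linkage of two registries with diagnosis disambiguation
#'
#' Links a cancer-registry cohort (A) to a primary-care registry (B) on exact
#' equality of the key (date of birth, 4-digit postal code) — or of final
#' pseudonyms, on which the algorithm operates identically. Both registries
#' are first restricted to females (removals are audited). Each A-record is
#' then classified:
#'
#' 1. key shared with another A-record — **excluded**: correct linkage cannot
#'    be ascertained;
#' 2. key absent from B — **unmatched**;
#' 3. key held by exactly one B-record — **included** iff that record carries
#'    the qualifying ICPC X76 diagnosis, else matched-without-diagnosis;
#' 4. key held by several B-records — **included** iff exactly one of them
#'    carries X76 (that record is the match); with zero or two or more
#'    diagnosis-bearing candidates the record stays out.
#'
#' @param a,b registry tibbles (raw or pseudonymized); record-id namespaces
#'   must not overlap.
#' @param a_diagnoses,b_diagnoses long diagnosis tables, required when the
#'   corresponding registry lacks a precomputed `breast_cancer_dx` column
#'   (only B's diagnoses drive the algorithm; A's are accepted for symmetry).
#' @return an object of class `linkage_result`: list with `dispositions`
#'   (tibble: `record_id`, `key`, `disposition`, candidate counts `n_b`,
#'   `n_b_dx`, and `record_id_b` where a unique match exists), `pairs`
#'   (tibble `record_id_a`, `record_id_b` of included matches), and `audit`
#'   (input sizes and sex-restriction removals).
#' @seealso [flow_report()], [brute_force_link()]
#' @export
link_registries <- function(a, b, a_diagnoses = NULL, b_diagnoses = NULL) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  shared <- intersect(a$record_id, b$record_id)
  if (length(shared) > 0) {
    abort(paste0("record_id namespaces of A and B overlap: ",
                 paste(head(shared, 5), collapse = ", ")))
  }
  keyed_on <- if ("pseudonym" %in% names(a)) "pseudonym" else "raw_key"

  fa <- restrict_female(a)
  fb <- restrict_female(b)
  bdx <- resolve_dx_flag(fb$records, b_diagnoses, "B")

  ak <- tibble::tibble(record_id = fa$records$record_id,
                       key = registry_key(fa$records))
  bk <- tibble::tibble(record_id = bdx$record_id,
                       key = registry_key(bdx),
                       dx = bdx$breast_cancer_dx)

  bstats <- bk |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_b = dplyr::n(), n_b_dx = sum(.data$dx),
                     .groups = "drop")
  # the B record a disposition can point at: the sole key-holder, or the sole
  # diagnosis-bearing candidate within a colliding group
  b_single <- bk |>
    dplyr::semi_join(dplyr::filter(bstats, .data$n_b == 1), by = "key") |>
    dplyr::select("key", record_id_b = "record_id")
  b_resolved <- bk |>
    dplyr::filter(.data$dx) |>
    dplyr::semi_join(dplyr::filter(bstats, .data$n_b > 1, .data$n_b_dx == 1),
                     by = "key") |>
    dplyr::select("key", record_id_b = "record_id")
  b_match <- dplyr::bind_rows(b_single, b_resolved)

  disp <- ak |>
    dplyr::add_count(.data$key, name = "n_a") |>
    dplyr::left_join(bstats, by = "key") |>
    dplyr::left_join(b_match, by = "key") |>
    dplyr::mutate(
      n_b = dplyr::coalesce(.data$n_b, 0L),
      n_b_dx = dplyr::coalesce(.data$n_b_dx, 0L),
      disposition = dplyr::case_when(
        .data$n_a > 1 ~ "excluded_nonunique_in_A",
        .data$n_b == 0 ~ "unmatched",
        .data$n_b == 1 & .data$n_b_dx == 1 ~ "included_unique_with_dx",
        .data$n_b == 1 ~ "matched_unique_no_dx",
        .data$n_b_dx == 1 ~ "included_nonunique_resolved",
        TRUE ~ "matched_nonunique_ambiguous_or_no_dx"
      ),
      disposition = factor(.data$disposition, levels = linkage_dispositions),
      record_id_b = dplyr::if_else(.data$disposition == "excluded_nonunique_in_A",
                                   NA_character_, .data$record_id_b)
    ) |>
    dplyr::select("record_id", "key", "disposition", "n_b", "n_b_dx",
                  "record_id_b")

  pairs <- disp |>
    dplyr::filter(.data$disposition %in% c("included_unique_with_dx",
                                           "included_nonunique_resolved")) |>
    dplyr::select(record_id_a = "record_id", "record_id_b")
  # every A-record surviving step 1 holds a distinct key, so no B-record can
  # be claimed by two included A-records
  stopifnot(!anyDuplicated(pairs$record_id_b))

  new_linkage_result(disp, pairs, audit = list(
    n_input_a = nrow(a), n_input_b = nrow(b),
    n_male_a = fa$n_male, n_unknown_sex_a = fa$n_unknown_sex,
    n_male_b = fb$n_male, n_unknown_sex_b = fb$n_unknown_sex
  ), keyed_on = keyed_on)
}

new_linkage_result <- function(dispositions, pairs, audit, keyed_on) {
  structure(
    list(dispositions = dispositions, pairs = pairs, audit = audit,
         keyed_on = keyed_on),
    class = "linkage_result"
  )
}

#' All-pairs reference implementation of the linkage algorithm
#'
#' Classifies every A-record by naive comparison against every other record —
#' no grouping, no joins. Same contract as [link_registries()]; intended as
#' an independent cross-check on small instances and refuses problems larger
#' than 10^6 record pairs.
#'
#' @inheritParams link_registries
#' @return a `linkage_result`, as [link_registries()].
#' @export
brute_force_link <- function(a, b, a_diagnoses = NULL, b_diagnoses = NULL) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  if (nrow(a) * nrow(b) > 1e6) {
    abort("brute_force_link refuses instances above 10^6 record pairs")
  }
  if (length(intersect(a$record_id, b$record_id)) > 0) {
    abort("record_id namespaces of A and B overlap")
  }
  keyed_on <- if ("pseudonym" %in% names(a)) "pseudonym" else "raw_key"
  n_male_a <- sum(a$sex == "male"); n_unk_a <- sum(!a$sex %in% c("female", "male"))
  n_male_b <- sum(b$sex == "male"); n_unk_b <- sum(!b$sex %in% c("female", "male"))
  af <- a[a$sex == "female", , drop = FALSE]
  bf <- b[b$sex == "female", , drop = FALSE]
  bf <- resolve_dx_flag(bf, b_diagnoses, "B")

  key_a <- registry_key(af)
  key_b <- registry_key(bf)
  dx_b <- bf$breast_cancer_dx

  n <- length(key_a)
  disposition <- character(n)
  n_b <- integer(n); n_b_dx <- integer(n); rid_b <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (n > 1 && any(key_a[-i] == key_a[i])) {
      disposition[i] <- "excluded_nonunique_in_A"
      next
    }
    cand <- which(key_b == key_a[i])
    n_b[i] <- length(cand)
    n_b_dx[i] <- sum(dx_b[cand])
    if (length(cand) == 0) {
      disposition[i] <- "unmatched"
    } else if (length(cand) == 1) {
      if (dx_b[cand]) {
        disposition[i] <- "included_unique_with_dx"
        rid_b[i] <- bf$record_id[cand]
      } else {
        disposition[i] <- "matched_unique_no_dx"
        rid_b[i] <- bf$record_id[cand]
      }
    } else if (sum(dx_b[cand]) == 1) {
      disposition[i] <- "included_nonunique_resolved"
      rid_b[i] <- bf$record_id[cand[dx_b[cand]]]
    } else {
      disposition[i] <- "matched_nonunique_ambiguous_or_no_dx"
    }
  }
  disp <- tibble::tibble(
    record_id = af$record_id, key = key_a,
    disposition = factor(disposition, levels = linkage_dispositions),
    n_b = n_b, n_b_dx = n_b_dx, record_id_b = rid_b
  )
  pairs <- disp[disp$disposition %in%
                  c("included_unique_with_dx", "included_nonunique_resolved"),
                c("record_id", "record_id_b")]
  names(pairs) <- c("record_id_a", "record_id_b")
  new_linkage_result(disp, tibble::as_tibble(pairs), audit = list(
    n_input_a = nrow(a), n_input_b = nrow(b),
    n_male_a = n_male_a, n_unknown_sex_a = n_unk_a,
    n_male_b = n_male_b, n_unknown_sex_b = n_unk_b
  ), keyed_on = keyed_on)
}

#' Flow accounting over a linkage result
#'
#' Tallies the record counts at every node of the linkage decision flow and
#' attaches two percentages per node: one against the node's natural local
#' denominator (e.g. matched among remaining, diagnosis-confirmed among
#' unique matches) and one against the overall cohort denominator.
#'
#' @param result a `linkage_result`.
#' @param denominator_total denominator for the cohort-level percentages;
#'   defaults to the female A-cohort size in `result`. Supply a different
#'   value (and label it in reporting) for e.g. stage-specific denominators.
#' @return a tibble of class `flow_report` with columns `node`, `count`,
#'   `denom_label`, `denom`, `pct` (local), `pct_of_total`, and
#'   `pct_undefined` flagging zero denominators (percentages are `NA`, never
#'   `NaN`).
#' @export
flow_report <- function(result, denominator_total = NULL) {
  stopifnot(inherits(result, "linkage_result"))
  d <- result$dispositions$disposition
  total <- length(d)
  excluded <- sum(d == "excluded_nonunique_in_A")
  remaining <- total - excluded
  unmatched <- sum(d == "unmatched")
  matched <- remaining - unmatched
  unique_in_b <- sum(d %in% c("included_unique_with_dx", "matched_unique_no_dx"))
  unique_with_dx <- sum(d == "included_unique_with_dx")
  nonunique_in_b <- matched - unique_in_b
  nonunique_resolved <- sum(d == "included_nonunique_resolved")
  included <- unique_with_dx + nonunique_resolved
  dt <- denominator_total %||% total

  rep <- tibble::tibble(
    node = c("total_a", "excluded_nonunique_a", "remaining", "matched_in_b",
             "unique_in_b", "unique_with_dx", "nonunique_in_b",
             "nonunique_resolved", "included"),
    count = c(total, excluded, remaining, matched, unique_in_b,
              unique_with_dx, nonunique_in_b, nonunique_resolved, included),
    denom_label = c("total cohort", "total cohort", "total cohort",
                    "remaining after exclusion", "matched in B",
                    "unique in B", "matched in B", "non-unique in B",
                    "total cohort"),
    denom = c(dt, total, total, remaining, matched, unique_in_b, matched,
              nonunique_in_b, dt)
  )
  rep$pct_undefined <- rep$denom == 0
  rep$pct <- ifelse(rep$pct_undefined, NA_real_, 100 * rep$count / rep$denom)
  rep$pct_of_total <- if (dt == 0) NA_real_ else 100 * rep$count / dt
  # arithmetic identities of the flow
  stopifnot(remaining == total - excluded,
            matched == unique_in_b + nonunique_in_b,
            included == unique_with_dx + nonunique_resolved,
            all(rep$count >= 0))
  structure(rep, class = c("flow_report", class(rep)),
            denominator_total = dt)
}

#' @export
print.flow_report <- function(x, ...) {
  cat("Linkage flow (cohort denominator:",
      format(attr(x, "denominator_total"), big.mark = ","), "records)\n\n")
  lab <- format(x$node, width = max(nchar(x$node)))
  cnt <- format(x$count, big.mark = ",", width = 10)
  pct <- ifelse(x$pct_undefined, "   -",
                sprintf("%5.1f%% of %s", x$pct, x$denom_label))
  cat(paste0("  ", lab, cnt, "  ", pct, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.linkage_result <- function(x, ...) x$dispositions

#' @export
glance.linkage_result <- function(x, ...) {
  fr <- flow_report(x)
  out <- tibble::as_tibble(setNames(as.list(fr$count), fr$node))
  out$keyed_on <- x$keyed_on
  out
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result> keyed on", x$keyed_on, "\n")
  print(flow_report(x))
  invisible(x)
}

#' @describeIn link_registries bar chart of A-record dispositions.
#' @param object,... a `linkage_result` (for `autoplot`); further arguments
#'   are ignored.
#' @export
autoplot.linkage_result <- function(object, ...) {
  counts <- object$dispositions |>
    dplyr::count(.data$disposition, .drop = FALSE)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$n, y = .data$disposition)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "A-records", y = NULL,
                  title = "Linkage dispositions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$node)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "records", y = NULL, title = "Linkage flow") +
    ggplot2::theme_minimal()
}
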
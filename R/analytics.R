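#' Expected key-collision rate under random cell occupancy
#'
#' The linkage key (date of birth, 4-digit postal code) is not unique: two
#' women born the same day in the same neighbourhood share it. Under the
#' occupancy model where each of `n_records` records falls independently into
#' one of `n_cells` equally likely key cells, a given record collides with
#' probability `1 - (1 - 1/C)^(N-1)`; with a non-uniform cell-probability
#' vector `q` the per-record probability is `sum_j q_j (1 - (1-q_j)^(N-1))`.
#'
#' @param n_records number of records `N` (at least 1).
#' @param n_cells number of equally likely key cells `C`; ignored when
#'   `cell_probs` is given.
#' @param cell_probs optional probability vector over cells (summing to 1)
#'   for non-uniform occupancy.
#' @return one-row tibble with `per_record_prob` (probability that a record
#'   shares its key with at least one other) and `expected_colliding`
#'   (`N` times that probability).
#' @examples
#' expected_collision_rate(2, 4)   # per-record 1/4, expected 0.5 records
#' @export
expected_collision_rate <- function(n_records, n_cells = NULL,
                                    cell_probs = NULL) {
  if (n_records < 1) abort("n_records must be at least 1")
  if (is.null(cell_probs)) {
    stopifnot(!is.null(n_cells), n_cells >= 1)
    p <- 1 - (1 - 1 / n_cells)^(n_records - 1)
  } else {
    stopifnot(all(cell_probs >= 0),
              abs(sum(cell_probs) - 1) < 1e-8)
    p <- sum(cell_probs * (1 - (1 - cell_probs)^(n_records - 1)))
  }
  tibble::tibble(per_record_prob = p, expected_colliding = n_records * p)
}

#' Linkage performance against ground truth
#'
#' Pair-level sensitivity and positive predictive value of a linkage result,
#' judged against the person identities of a synthetic ground truth. A
#' reported pair is *correct* iff both records belong to the same person. The
#' sensitivity denominator counts persons who truly appear in both registries
#' with an intact key — i.e. who did not move between the A and B address
#' captures — since only those pairs are recoverable by exact key matching.
#'
#' @param result a `linkage_result`.
#' @param truth tibble with `person_id`, `record_id_a`, `record_id_b`,
#'   `true_case` and `moved` (as produced by [generate_registries()]). Must
#'   cover every record appearing in `result`.
#' @return one-row tibble: `n_true_linkable`, `n_reported`, `n_correct`,
#'   `false_match_count`, `sensitivity`, `ppv`. With no reported pairs, PPV
#'   is `NA`; with no true linkable pairs, sensitivity is `NA`.
#' @export
linkage_performance <- function(result, truth) {
  stopifnot(inherits(result, "linkage_result"))
  truth <- tibble::as_tibble(truth)
  known <- c(stats::na.omit(truth$record_id_a), stats::na.omit(truth$record_id_b))
  unknown <- setdiff(c(result$dispositions$record_id, result$pairs$record_id_b),
                     known)
  if (length(unknown) > 0) {
    abort(paste0("records absent from ground truth: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  in_result <- truth$record_id_a %in% result$dispositions$record_id
  linkable <- in_result & !is.na(truth$record_id_b) &
    !is.na(truth$moved) & !truth$moved
  pairs <- result$pairs
  person_a <- truth$person_id[match(pairs$record_id_a, truth$record_id_a)]
  person_b <- truth$person_id[match(pairs$record_id_b, truth$record_id_b)]
  correct <- sum(person_a == person_b)
  tibble::tibble(
    n_true_linkable = sum(linkable),
    n_reported = nrow(pairs),
    n_correct = correct,
    false_match_count = nrow(pairs) - correct,
    sensitivity = if (sum(linkable) == 0) NA_real_ else correct / sum(linkable),
    ppv = if (nrow(pairs) == 0) NA_real_ else correct / nrow(pairs)
  )
}

#' Recover generator parameters from a linkage run
#'
#' Consistency check between the simulation and the pipeline: estimates the
#' registry-B coverage fraction (share of the true case cohort holding a B
#' record) and the GP recording sensitivity (share of correctly, uniquely
#' matched cases whose diagnosis was recorded) from a linkage result plus
#' ground truth.
#'
#' @inheritParams linkage_performance
#' @return one-row tibble with `coverage_hat` and `sensitivity_hat` plus the
#'   sizes `n_cases` and `n_unique_true_matches` they are based on.
#' @export
recover_parameters <- function(result, truth) {
  stopifnot(inherits(result, "linkage_result"))
  truth <- tibble::as_tibble(truth)
  cases <- truth[!is.na(truth$record_id_a), , drop = FALSE]
  coverage_hat <- mean(!is.na(cases$record_id_b))

  d <- result$dispositions
  um <- d[d$disposition %in% c("included_unique_with_dx", "matched_unique_no_dx"), ]
  person_a <- truth$person_id[match(um$record_id, truth$record_id_a)]
  person_b <- truth$person_id[match(um$record_id_b, truth$record_id_b)]
  same <- !is.na(person_a) & !is.na(person_b) & person_a == person_b
  um <- um[same, , drop = FALSE]
  tibble::tibble(
    coverage_hat = coverage_hat,
    sensitivity_hat = if (nrow(um) == 0) NA_real_ else
      mean(um$disposition == "included_unique_with_dx"),
    n_cases = nrow(cases),
    n_unique_true_matches = nrow(um)
  )
}

#' Contamination of a control pool by unlinked true cases
#'
#' Women who truly have the disease but could not be linked (moved, GP did
#' not record the diagnosis, ambiguous keys) remain in registry B looking
#' like anyone else — and may be drawn as controls in later case-control
#' studies. This computes the fraction `f` of the B-side control pool (B
#' records not claimed as a linked case) that is actually a true case.
#'
#' @inheritParams linkage_performance
#' @return one-row tibble with `f`, `n_control_pool`, `n_contaminated`.
#' @export
contamination_rate <- function(result, truth) {
  stopifnot(inherits(result, "linkage_result"))
  truth <- tibble::as_tibble(truth)
  in_b <- !is.na(truth$record_id_b)
  linked_b <- truth$record_id_b %in% result$pairs$record_id_b
  pool <- in_b & !linked_b
  contaminated <- pool & truth$true_case
  tibble::tibble(
    f = if (sum(pool) == 0) NA_real_ else sum(contaminated) / sum(pool),
    n_control_pool = sum(pool),
    n_contaminated = sum(contaminated)
  )
}

#' Attenuation of a case-control odds ratio under control contamination
#'
#' Mixture model for the dilution caused by true cases hiding in the control
#' pool: a fraction `f` of controls is replaced by draws from the case
#' exposure distribution. With control exposure prevalence `p0` and true odds
#' ratio `OR`, case prevalence is `p1 = OR*p0 / (1 - p0 + OR*p0)`, the
#' contaminated control prevalence is `(1-f)*p0 + f*p1`, and the observed
#' odds ratio is `odds(p1) / odds(contaminated p0)`. The observed effect
#' moves monotonically toward the null as `f` grows, and a true null
#' (`OR = 1`) is preserved for every `f`.
#'
#' @param true_odds_ratio the true exposure-disease odds ratio (> 0).
#' @param exposure_prev_controls exposure prevalence among uncontaminated
#'   controls, strictly inside (0, 1).
#' @param f contamination fraction(s) in `[0, 1]`; vectorised.
#' @param result,truth optionally, a `linkage_result` and ground truth from
#'   which `f` is derived via [contamination_rate()] when `f` is missing.
#' @return tibble with one row per `f`: `f`, `true_odds_ratio`,
#'   `exposure_prev_cases`, `exposure_prev_controls_observed`, `observed_odds_ratio`.
#' @export
dilution_analysis <- function(true_odds_ratio, exposure_prev_controls, f = NULL,
                              result = NULL, truth = NULL) {
  if (is.null(f)) {
    if (is.null(result) || is.null(truth)) {
      abort("supply `f` directly, or `result` and `truth` to derive it")
    }
    f <- contamination_rate(result, truth)$f
  }
  stopifnot(true_odds_ratio > 0, all(f >= 0), all(f <= 1))
  p0 <- exposure_prev_controls
  if (p0 <= 0 || p0 >= 1) {
    abort("exposure_prev_controls must be strictly between 0 and 1")
  }
  odds0 <- p0 / (1 - p0)
  p1 <- true_odds_ratio * odds0 / (1 + true_odds_ratio * odds0)
  p0_obs <- (1 - f) * p0 + f * p1
  or_obs <- (p1 / (1 - p1)) / (p0_obs / (1 - p0_obs))
  tibble::tibble(
    f = f,
    true_odds_ratio = true_odds_ratio,
    exposure_prev_cases = p1,
    exposure_prev_controls_observed = p0_obs,
    observed_odds_ratio = or_obs
  )
}
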
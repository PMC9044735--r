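#' Configuration for the synthetic two-registry simulation
#'
#' The generator emulates the study setting the linkage toolkit is built for:
#' a nationwide cancer registry (A) holding every incident breast-cancer
#' diagnosis in a calendar window, and a primary-care registry (B) covering
#' roughly 10% of the population through a sample of GP practices, with
#' imperfect GP recording of the diagnosis and residential mobility that
#' breaks the (date of birth, pc4) key over time.
#'
#' @param n_neighbourhoods number of pc4 neighbourhoods.
#' @param mean_households mean households per neighbourhood (Dutch pc4 areas
#'   average about 2,000).
#' @param women_per_household average adult women per household; together
#'   with `mean_households` this sets the female population size.
#' @param birth_year_range inclusive birth-year range of the simulated women.
#' @param diagnosis_window inclusive calendar years in which incident
#'   diagnoses are generated.
#' @param snapshot_year calendar year at which registry B's addresses and
#'   enrolment are observed; the lag between diagnosis and snapshot is what
#'   lets residential moves break linkage keys.
#' @param incidence data frame with `age_min` (ascending) and `rate`
#'   (per-woman-year diagnosis hazard for that open-ended age band). The
#'   defaults are arbitrary round numbers that rise with age.
#' @param practices_per_neighbourhood GP practices per neighbourhood; every
#'   woman is registered with one practice in her home neighbourhood.
#' @param coverage fraction of practices (hence, approximately, of the
#'   population) enrolled in registry B.
#' @param gp_recording_sensitivity probability that a true breast-cancer
#'   diagnosis is recorded as ICPC X76 in the GP record.
#' @param background_x76_rate probability that a woman without an incident
#'   diagnosis in the window nevertheless carries an X76 code (e.g. disease
#'   predating the window).
#' @param move_prob per-woman, per-year probability of moving to another
#'   neighbourhood.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_neighbourhoods = 50,
                       mean_households = 2000,
                       women_per_household = 1,
                       birth_year_range = c(1920, 1984),
                       diagnosis_window = c(2000, 2016),
                       snapshot_year = 2017,
                       incidence = data.frame(
                         age_min = c(0, 45, 60, 75),
                         rate = c(2e-4, 2e-3, 3e-3, 3e-3)),
                       practices_per_neighbourhood = 10,
                       coverage = 0.10,
                       gp_recording_sensitivity = 0.80,
                       background_x76_rate = 0.002,
                       move_prob = 0.02) {
  stopifnot(
    n_neighbourhoods >= 1, n_neighbourhoods <= 9000,
    mean_households > 0, women_per_household > 0,
    diff(birth_year_range) >= 0, diff(diagnosis_window) >= 0,
    snapshot_year >= diagnosis_window[2],
    all(diff(incidence$age_min) > 0), all(incidence$rate >= 0),
    all(incidence$rate <= 1),
    practices_per_neighbourhood >= 1,
    coverage > 0, coverage <= 1,
    gp_recording_sensitivity >= 0, gp_recording_sensitivity <= 1,
    background_x76_rate >= 0, background_x76_rate <= 1,
    move_prob >= 0, move_prob <= 1
  )
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic female population with residence histories
#'
#' Neighbourhood sizes are Poisson around the configured mean household
#' count; each woman gets a date of birth, a home neighbourhood (pc4), a GP
#' practice within that neighbourhood, and a sparse residence history of
#' year-stamped moves realized from the per-year move probability.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; generation is fully reproducible.
#' @return list of class `sim_population` with tibbles `persons` (`person_id`,
#'   `dob`, `birth_year`, `neighbourhood`, `pc4_home`, `practice_id`),
#'   `practices` (`practice_id`, `neighbourhood`, `covered`), `moves`
#'   (`person_id`, `year`, `pc4_new`), and the `config`.
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    nb <- config$n_neighbourhoods
    households <- stats::rpois(nb, config$mean_households)
    women <- pmax(0L, as.integer(round(households * config$women_per_household)))
    n <- sum(women)
    if (n == 0) abort("infeasible config: zero women generated")
    pc4_codes <- sprintf("%04d", sample(1000:9999, nb))

    nb_idx <- rep(seq_len(nb), women)
    d0 <- as.Date(paste0(config$birth_year_range[1], "-01-01"))
    d1 <- as.Date(paste0(config$birth_year_range[2], "-12-31"))
    dob <- d0 + floor(runif(n, 0, as.numeric(d1 - d0) + 1))

    ppn <- config$practices_per_neighbourhood
    n_pr <- nb * ppn
    practice_ids <- sprintf("GP%05d", seq_len(n_pr))
    n_cov <- max(1L, round(config$coverage * n_pr))
    covered <- seq_len(n_pr) %in% sample.int(n_pr, n_cov)
    practices <- tibble::tibble(
      practice_id = practice_ids,
      neighbourhood = rep(seq_len(nb), each = ppn),
      covered = covered
    )
    person_practice <- practice_ids[(nb_idx - 1L) * ppn +
                                      sample.int(ppn, n, replace = TRUE)]

    persons <- tibble::tibble(
      person_id = sprintf("P%08d", seq_len(n)),
      dob = dob,
      birth_year = as.integer(format(dob, "%Y")),
      neighbourhood = nb_idx,
      pc4_home = pc4_codes[nb_idx],
      practice_id = person_practice
    )

    years <- seq(config$diagnosis_window[1], config$snapshot_year)
    ny <- length(years)
    moved <- runif(n * ny) < config$move_prob
    moves <- tibble::tibble(
      person_id = rep(persons$person_id, ny)[moved],
      year = rep(years, each = n)[moved],
      pc4_new = pc4_codes[sample.int(nb, sum(moved), replace = TRUE)]
    )
    structure(list(persons = persons, practices = practices, moves = moves,
                   households = tibble::tibble(
                     neighbourhood = seq_len(nb), n_households = households),
                   config = config),
              class = "sim_population")
  })
}

#' pc4 of residence at given calendar years
#'
#' Replays each woman's move history: the pc4 in force at `year` is the home
#' neighbourhood unless a move with an event year at or before `year`
#' happened, in which case it is the destination of the latest such move.
#'
#' @param population a `sim_population`.
#' @param person_id,year equal-length vectors of query persons and years.
#' @return character vector of pc4 codes.
#' @export
pc4_at <- function(population, person_id, year) {
  persons <- population$persons
  base <- persons$pc4_home[match(person_id, persons$person_id)]
  if (nrow(population$moves) == 0) return(base)
  q <- tibble::tibble(person_id = person_id, qyear = year,
                      ord = seq_along(person_id))
  hit <- q |>
    dplyr::inner_join(population$moves, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$year <= .data$qyear) |>
    dplyr::group_by(.data$ord) |>
    dplyr::slice_max(.data$year, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  base[hit$ord] <- hit$pc4_new
  base
}

.stage_levels <- c("DCIS", "I", "II", "III", "IV", "Unknown")
.stage_probs <- c(0.007, 0.418, 0.396, 0.121, 0.049, 0.009)
.surgery_levels <- c("breast_conserving", "amputation", "unknown_other", "none")
.surgery_probs <- c(0.486, 0.415, 0.003, 0.096)

#' Generate the paired registries and ground truth from a population
#'
#' Registry A receives one record per woman with an incident diagnosis in the
#' window, carrying her pc4 *at diagnosis* and clinical attributes sampled
#' independently of linkage success (so inclusion-bias tests have a clean
#' null). Registry B receives every woman registered at a covered practice,
#' carrying her pc4 *at the snapshot year*; her true diagnosis is recorded as
#' ICPC X76 with probability `gp_recording_sensitivity`. Ground truth maps
#' every record back to its person, so linkage sensitivity and false matches
#' are measurable.
#'
#' @param population a [generate_population()] result.
#' @param seed integer seed.
#' @return list of class `synthetic_registries` with registry tibbles `a` and
#'   `b`, diagnosis tables `a_diagnoses` and `b_diagnoses`, and `truth`
#'   (`person_id`, `record_id_a`, `record_id_b`, `true_case`, `moved`,
#'   `diagnosis_year`).
#' @export
generate_registries <- function(population, seed) {
  stopifnot(inherits(population, "sim_population"))
  config <- population$config
  persons <- population$persons
  n <- nrow(persons)
  withr::with_seed(seed, {
    years <- seq(config$diagnosis_window[1], config$diagnosis_window[2])
    ny <- length(years)
    # per-woman-year hazard by age band, then lifetime-in-window draw
    age <- outer(persons$birth_year, years, function(b, y) y - b)
    rate <- matrix(
      config$incidence$rate[pmax(1L, findInterval(age, config$incidence$age_min))],
      nrow = n)
    rate[age < 0] <- 0
    p_none <- exp(rowSums(log1p(-rate)))
    diagnosed <- runif(n) < 1 - p_none
    idx <- which(diagnosed)
    dx_year <- integer(length(idx))
    for (j in seq_along(idx)) {
      r <- rate[idx[j], ]
      w <- r * cumprod(c(1, 1 - r[-ny]))  # first-event year weights
      dx_year[j] <- years[sample.int(ny, 1, prob = w)]
    }

    rand_letters <- function(k) {
      paste0(sample(LETTERS, k, replace = TRUE),
             sample(LETTERS, k, replace = TRUE))
    }

    a <- tibble::tibble(
      record_id = paste0("A", persons$person_id[idx]),
      registry_id = "A",
      sex = "female",
      date_of_birth = persons$dob[idx],
      postal_code = paste0(pc4_at(population, persons$person_id[idx], dx_year),
                           rand_letters(length(idx))),
      diagnosis_year = dx_year,
      age_at_diagnosis = dx_year - persons$birth_year[idx],
      stage = sample(.stage_levels, length(idx), replace = TRUE,
                     prob = .stage_probs),
      surgery = sample(.surgery_levels, length(idx), replace = TRUE,
                       prob = .surgery_probs),
      axillary_dissection = runif(length(idx)) < 0.383,
      radiotherapy = runif(length(idx)) < 0.599,
      chemotherapy = runif(length(idx)) < 0.373,
      hormone_therapy = runif(length(idx)) < 0.517
    )
    a_diagnoses <- tibble::tibble(
      record_id = a$record_id,
      code_system = "ICD10",
      code = paste0("C50.", sample(0:9, nrow(a), replace = TRUE)),
      year = a$diagnosis_year
    )

    covered_practices <- population$practices$practice_id[population$practices$covered]
    in_b <- persons$practice_id %in% covered_practices
    bi <- which(in_b)
    snap <- config$snapshot_year
    b <- tibble::tibble(
      record_id = paste0("B", persons$person_id[bi]),
      registry_id = "B",
      sex = "female",
      date_of_birth = persons$dob[bi],
      postal_code = paste0(pc4_at(population, persons$person_id[bi],
                                  rep(snap, length(bi))),
                           rand_letters(length(bi))),
      practice_id = persons$practice_id[bi],
      registration_date = as.Date(paste0(
        sample(seq(config$diagnosis_window[1] - 5, config$diagnosis_window[1]),
               length(bi), replace = TRUE), "-01-01")),
      last_encounter_date = as.Date(paste0(snap, "-01-01")) +
        sample.int(300, length(bi), replace = TRUE)
    )

    is_case_b <- diagnosed[bi]
    recorded <- is_case_b & runif(length(bi)) < config$gp_recording_sensitivity
    background <- !is_case_b & runif(length(bi)) < config$background_x76_rate
    dx_year_b <- rep(NA_integer_, length(bi))
    dx_year_b[is_case_b] <- dx_year[match(persons$person_id[bi][is_case_b],
                                          persons$person_id[idx])]
    dx_year_b[background] <- sample(years, sum(background), replace = TRUE)
    keep <- recorded | background
    b_diagnoses <- tibble::tibble(
      record_id = b$record_id[keep],
      code_system = "ICPC1",
      code = "X76",
      year = dx_year_b[keep]
    )

    truth <- tibble::tibble(
      person_id = persons$person_id,
      record_id_a = ifelse(diagnosed, paste0("A", persons$person_id), NA),
      record_id_b = ifelse(in_b, paste0("B", persons$person_id), NA),
      true_case = diagnosed,
      diagnosis_year = NA_integer_
    )
    truth$diagnosis_year[idx] <- dx_year
    moved <- rep(NA, n)
    moved[idx] <- pc4_at(population, persons$person_id[idx], dx_year) !=
      pc4_at(population, persons$person_id[idx], rep(snap, length(idx)))
    truth$moved <- moved

    structure(list(a = a, b = b, a_diagnoses = a_diagnoses,
                   b_diagnoses = b_diagnoses, truth = truth),
              class = "synthetic_registries")
  })
}

#' Construct registries that reproduce requested linkage-flow branch counts
#'
#' Builds two registries deterministically such that running
#' [link_registries()] on them lands exactly the requested number of
#' A-records on every branch of the linkage flow: records excluded for key
#' collisions within A, records unmatched in B, unique matches with and
#' without the GP diagnosis, and non-unique matches that are or are not
#' resolvable by the single-diagnosis rule. Useful for worked examples at
#' full registry scale without any real data.
#'
#' @param branch_counts named list or vector with `total_a`, `nonunique_a`
#'   (records in colliding A-groups; 0 or at least 2), `matched` (of the
#'   remainder, keys present in B), `unique_b` (of those, keys unique in B),
#'   `unique_with_dx`, and `nonunique_resolved`. Derived quantities
#'   (`remaining`, `unmatched`, `nonunique_b`, ambiguous) are computed and
#'   checked for consistency; an inconsistent request is refused with the
#'   violated identity named.
#' @param seed integer seed (only row order and cosmetic attributes are
#'   random; the flow counts are exact by construction).
#' @return list with registry tibbles `a`, `b`, diagnosis tables
#'   `a_diagnoses`, `b_diagnoses`, and the resolved `branch` counts.
#' @export
exact_flow_fixture <- function(branch_counts, seed = 1) {
  bc <- as.list(branch_counts)
  need <- c("total_a", "nonunique_a", "matched", "unique_b", "unique_with_dx",
            "nonunique_resolved")
  missing <- setdiff(need, names(bc))
  if (length(missing) > 0) {
    abort(paste0("branch_counts missing: ", paste(missing, collapse = ", ")))
  }
  for (f in need) {
    bc[[f]] <- as.integer(bc[[f]])
    if (is.na(bc[[f]]) || bc[[f]] < 0) abort(paste0(f, " must be >= 0"))
  }
  if (bc$nonunique_a == 1) {
    abort("violated identity: nonunique_a counts records in colliding groups, so it is 0 or >= 2")
  }
  remaining <- bc$total_a - bc$nonunique_a
  if (remaining < 0) abort("violated identity: nonunique_a <= total_a")
  if (bc$matched > remaining) {
    abort("violated identity: matched <= remaining = total_a - nonunique_a")
  }
  if (bc$unique_b > bc$matched) abort("violated identity: unique_b <= matched")
  nonunique_b <- bc$matched - bc$unique_b
  if (bc$unique_with_dx > bc$unique_b) {
    abort("violated identity: unique_with_dx <= unique_b")
  }
  if (bc$nonunique_resolved > nonunique_b) {
    abort("violated identity: nonunique_resolved <= nonunique_b = matched - unique_b")
  }

  # deterministic distinct key pool: (date, pc4) by index
  n_dates <- 25000L
  key_date <- function(i) as.Date("1920-01-01") + ((i - 1L) %% n_dates)
  key_pc4 <- function(i) sprintf("%04d", 1000L + ((i - 1L) %/% n_dates))

  n_groups <- bc$nonunique_a %/% 2L
  group_sizes <- if (n_groups > 0) {
    s <- rep(2L, n_groups)
    s[1] <- s[1] + bc$nonunique_a %% 2L  # odd count: one group of 3
    s
  } else integer(0)

  a_key_idx <- c(rep(seq_len(n_groups), group_sizes),
                 n_groups + seq_len(remaining))
  a <- tibble::tibble(
    record_id = sprintf("a%07d", seq_along(a_key_idx)),
    registry_id = "A",
    sex = "female",
    date_of_birth = key_date(a_key_idx),
    postal_code = key_pc4(a_key_idx)
  )
  a_diagnoses <- tibble::tibble(
    record_id = a$record_id,
    code_system = "ICD10",
    code = "C50.9",
    year = 2000L + (seq_len(nrow(a)) %% 17L)
  )

  # B: unique keys first, then colliding pairs
  uniq_idx <- n_groups + seq_len(bc$unique_b)
  nonuniq_idx <- n_groups + bc$unique_b + seq_len(nonunique_b)
  b_key_idx <- c(uniq_idx, rep(nonuniq_idx, each = 2L))
  b <- tibble::tibble(
    record_id = sprintf("b%07d", seq_along(b_key_idx)),
    registry_id = "B",
    sex = "female",
    date_of_birth = key_date(b_key_idx),
    postal_code = key_pc4(b_key_idx),
    practice_id = sprintf("GP%05d", 1L + (seq_along(b_key_idx) %% 500L))
  )
  dx <- logical(nrow(b))
  dx[seq_len(bc$unique_with_dx)] <- TRUE  # unique matches with the diagnosis
  if (nonunique_b > 0) {
    # per colliding pair: resolved -> exactly one dx; ambiguous -> alternate
    # between both-dx and no-dx so both audit buckets occur
    first_of_pair <- bc$unique_b + 2L * (seq_len(nonunique_b) - 1L) + 1L
    resolved <- seq_len(nonunique_b) <= bc$nonunique_resolved
    dx[first_of_pair[resolved]] <- TRUE
    amb <- which(!resolved)
    both <- amb[seq_along(amb) %% 2L == 1L]
    dx[first_of_pair[both]] <- TRUE
    dx[first_of_pair[both] + 1L] <- TRUE
  }
  b_diagnoses <- tibble::tibble(
    record_id = b$record_id[dx],
    code_system = "ICPC1",
    code = "X76",
    year = 2000L + (seq_len(sum(dx)) %% 17L)
  )

  withr::with_seed(seed, {
    a <- a[sample.int(nrow(a)), , drop = FALSE]
    b <- b[sample.int(nrow(b)), , drop = FALSE]
  })
  list(a = a, b = b, a_diagnoses = a_diagnoses, b_diagnoses = b_diagnoses,
       branch = list(total_a = bc$total_a, nonunique_a = bc$nonunique_a,
                     remaining = remaining, matched = bc$matched,
                     unique_b = bc$unique_b, unique_with_dx = bc$unique_with_dx,
                     nonunique_b = nonunique_b,
                     nonunique_resolved = bc$nonunique_resolved,
                     included = bc$unique_with_dx + bc$nonunique_resolved))
}
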
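small_config <- function(...) {
  args <- utils::modifyList(
    list(n_neighbourhoods = 5, mean_households = 400,
         practices_per_neighbourhood = 4, coverage = 0.25),
    list(...))
  do.call(sim_config, args)
}

test_that("population generation is seed-reproducible and respects the household mean", {
  cfg <- sim_config(n_neighbourhoods = 5, mean_households = 2000)
  p1 <- generate_population(cfg, seed = 11)
  p2 <- generate_population(cfg, seed = 11)
  expect_identical(p1$persons, p2$persons)
  expect_identical(p1$moves, p2$moves)
  # empirical mean household count within 10% of the configured 2,000
  expect_lt(abs(mean(p1$households$n_households) - 2000) / 2000, 0.10)
  expect_equal(dplyr::n_distinct(p1$persons$pc4_home), 5)
  expect_error(generate_population(sim_config(n_neighbourhoods = 0), 1))
})

test_that("with zero move probability every pc4 is constant over time", {
  pop <- generate_population(small_config(move_prob = 0), seed = 3)
  expect_equal(nrow(pop$moves), 0)
  yrs <- c(2000L, 2008L, 2017L)
  for (y in yrs) {
    expect_equal(pc4_at(pop, pop$persons$person_id, rep(y, nrow(pop$persons))),
                 pop$persons$pc4_home)
  }
})

test_that("residence lookups replay the latest move at or before the query year", {
  pop <- generate_population(small_config(move_prob = 0), seed = 4)
  pop$moves <- tibble::tibble(
    person_id = pop$persons$person_id[1],
    year = c(2005L, 2010L),
    pc4_new = c("7001", "7002")
  )
  pid <- pop$persons$person_id[1]
  expect_equal(pc4_at(pop, pid, 2004L), pop$persons$pc4_home[1])
  expect_equal(pc4_at(pop, pid, 2005L), "7001")
  expect_equal(pc4_at(pop, pid, 2012L), "7002")
})

test_that("full coverage, perfect recording and no mobility link every unique-key woman", {
  cfg <- small_config(coverage = 1, gp_recording_sensitivity = 1,
                      background_x76_rate = 0, move_prob = 0)
  pop <- generate_population(cfg, seed = 5)
  reg <- generate_registries(pop, seed = 6)
  res <- link_registries(reg$a, reg$b, reg$a_diagnoses, reg$b_diagnoses)
  d <- as.character(res$dispositions$disposition)
  expect_equal(sum(d == "unmatched"), 0)
  # with X76 only on true cases, every woman unique in both registries is in
  expect_equal(sum(d == "matched_unique_no_dx"), 0)
  expect_true(all(d %in% c("excluded_nonunique_in_A", "included_unique_with_dx",
                           "included_nonunique_resolved",
                           "matched_nonunique_ambiguous_or_no_dx")))
  perf <- linkage_performance(res, reg$truth)
  expect_equal(perf$ppv, 1)
})

test_that("registry generation records ground truth consistently", {
  pop <- generate_population(small_config(), seed = 7)
  reg <- generate_registries(pop, seed = 8)
  expect_identical(reg$a, generate_registries(pop, seed = 8)$a)
  expect_equal(sum(!is.na(reg$truth$record_id_a)), nrow(reg$a))
  expect_equal(sum(!is.na(reg$truth$record_id_b)), nrow(reg$b))
  expect_setequal(stats::na.omit(reg$truth$record_id_a), reg$a$record_id)
  expect_setequal(stats::na.omit(reg$truth$record_id_b), reg$b$record_id)
  expect_true(all(reg$a$diagnosis_year >= 2000 & reg$a$diagnosis_year <= 2016))
  # every record maps to exactly one person
  expect_equal(anyDuplicated(stats::na.omit(reg$truth$record_id_a)), 0)
  expect_equal(anyDuplicated(stats::na.omit(reg$truth$record_id_b)), 0)
})

test_that("the exact-flow fixture reproduces small requested branch counts verbatim", {
  fx <- exact_flow_fixture(list(total_a = 20, nonunique_a = 4, matched = 9,
                                unique_b = 6, unique_with_dx = 3,
                                nonunique_resolved = 2), seed = 2)
  res <- link_registries(fx$a, fx$b, fx$a_diagnoses, fx$b_diagnoses)
  cnt <- setNames(flow_report(res)$count, flow_report(res)$node)
  expect_equal(cnt[["total_a"]], 20)
  expect_equal(cnt[["excluded_nonunique_a"]], 4)
  expect_equal(cnt[["matched_in_b"]], 9)
  expect_equal(cnt[["unique_in_b"]], 6)
  expect_equal(cnt[["unique_with_dx"]], 3)
  expect_equal(cnt[["nonunique_in_b"]], 3)
  expect_equal(cnt[["nonunique_resolved"]], 2)
  expect_equal(cnt[["included"]], 5)
  # both ambiguity flavours occur in the remaining non-unique group
  amb <- res$dispositions[res$dispositions$disposition ==
                            "matched_nonunique_ambiguous_or_no_dx", ]
  expect_equal(nrow(amb), 1)
})

test_that("an all-unmatched fixture produces a disjoint B", {
  fx <- exact_flow_fixture(list(total_a = 5, nonunique_a = 0, matched = 0,
                                unique_b = 0, unique_with_dx = 0,
                                nonunique_resolved = 0), seed = 1)
  expect_equal(nrow(fx$b), 0)
  res <- link_registries(fx$a, fx$b, fx$a_diagnoses, fx$b_diagnoses)
  expect_true(all(res$dispositions$disposition == "unmatched"))
})

test_that("inconsistent branch requests are refused with the violated identity named", {
  base <- list(total_a = 10, nonunique_a = 2, matched = 5, unique_b = 3,
               unique_with_dx = 2, nonunique_resolved = 1)
  expect_error(exact_flow_fixture(modifyList(base, list(matched = 9))),
               "matched <= remaining")
  expect_error(exact_flow_fixture(modifyList(base, list(unique_b = 6))),
               "unique_b <= matched")
  expect_error(exact_flow_fixture(modifyList(base, list(nonunique_resolved = 3))),
               "nonunique_resolved <=")
  expect_error(exact_flow_fixture(modifyList(base, list(nonunique_a = 1))),
               "0 or >= 2")
  expect_error(exact_flow_fixture(modifyList(base, list(unique_with_dx = 4))),
               "unique_with_dx <= unique_b")
})

test_that("rising mobility strictly erodes inclusion of long-lag diagnoses", {
  move_grid <- c(0, 0.03, 0.06, 0.12, 0.25)
  frac <- vapply(seq_along(move_grid), function(i) {
    cfg <- sim_config(n_neighbourhoods = 10, mean_households = 1000,
                      coverage = 1, gp_recording_sensitivity = 1,
                      background_x76_rate = 0, move_prob = move_grid[i])
    pop <- generate_population(cfg, seed = 100 + i)
    reg <- generate_registries(pop, seed = 200 + i)
    res <- link_registries(reg$a, reg$b, reg$a_diagnoses, reg$b_diagnoses)
    early <- reg$a$record_id[reg$a$diagnosis_year <= 2007]
    mean(early %in% res$pairs$record_id_a)
  }, numeric(1))
  expect_equal(stats::cor(move_grid, frac, method = "kendall"), -1)
})

test_that("with mobility active, inclusion declines with time since diagnosis", {
  cfg <- sim_config(n_neighbourhoods = 10, mean_households = 1000,
                    coverage = 1, gp_recording_sensitivity = 1,
                    background_x76_rate = 0, move_prob = 0.06)
  pop <- generate_population(cfg, seed = 31)
  reg <- generate_registries(pop, seed = 32)
  res <- link_registries(reg$a, reg$b, reg$a_diagnoses, reg$b_diagnoses)
  cohort <- reg$a
  cohort$year_band <- cut(cohort$diagnosis_year, c(1999, 2004, 2009, 2016),
                          labels = c("2000-2004", "2005-2009", "2010-2016"))
  it <- inclusion_table(cohort, res$pairs$record_id_a, "year_band")
  pct <- tidy(it)$pct_included
  # older diagnoses (longer diagnosis-to-snapshot lag) are included less
  expect_true(all(diff(pct) >= 0))
})
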
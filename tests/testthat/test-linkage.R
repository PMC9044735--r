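# the worked instance: A holds keys K1, K2, K2, K3, K4; B holds K1 (with
# diagnosis), K3 (without), and two records on K4 of which one has the
# diagnosis. Expected dispositions computed independently by hand and by the
# all-pairs oracle.
worked_instance <- function() {
  a <- make_records(c("a1", "a2", "a3", "a4", "a5"), c(1, 2, 2, 3, 4), "A")
  b <- make_records(c("b1", "b2", "b3", "b4"), c(1, 3, 4, 4), "B")
  list(a = a, b = b, adx = make_dx(a$record_id, "A"),
       bdx = make_dx(c("b1", "b3"), "B"))
}

test_that("the worked 5x4 instance lands every record on its expected branch", {
  w <- worked_instance()
  r <- link_registries(w$a, w$b, w$adx, w$bdx)
  d <- setNames(as.character(r$dispositions$disposition), r$dispositions$record_id)
  expect_equal(d[["a1"]], "included_unique_with_dx")
  expect_equal(d[["a2"]], "excluded_nonunique_in_A")
  expect_equal(d[["a3"]], "excluded_nonunique_in_A")
  expect_equal(d[["a4"]], "matched_unique_no_dx")
  expect_equal(d[["a5"]], "included_nonunique_resolved")
  expect_equal(dplyr::arrange(r$pairs, record_id_a),
               tibble::tibble(record_id_a = c("a1", "a5"),
                              record_id_b = c("b1", "b3")))
  expect_equivalent_results(r, brute_force_link(w$a, w$b, w$adx, w$bdx))
})

test_that("an empty B leaves every surviving A-record unmatched", {
  w <- worked_instance()
  r <- link_registries(w$a, w$b[0, ], w$adx, w$bdx[0, ])
  d <- as.character(r$dispositions$disposition)
  expect_equal(sum(d == "excluded_nonunique_in_A"), 2)
  expect_equal(sum(d == "unmatched"), 3)
  expect_equal(nrow(r$pairs), 0)
})

test_that("a B-group with two diagnosis-bearing women stays ambiguous; with none it stays out", {
  a <- make_records(c("a1", "a2"), c(1, 2), "A")
  b <- make_records(c("b1", "b2", "b3", "b4"), c(1, 1, 2, 2), "B")
  r <- link_registries(a, b, b_diagnoses = make_dx(c("b1", "b2"), "B"))
  d <- setNames(as.character(r$dispositions$disposition), r$dispositions$record_id)
  expect_equal(d[["a1"]], "matched_nonunique_ambiguous_or_no_dx")
  expect_equal(d[["a2"]], "matched_nonunique_ambiguous_or_no_dx")
  expect_equal(nrow(r$pairs), 0)
  # the audit columns separate the two reasons
  expect_equal(r$dispositions$n_b_dx[r$dispositions$record_id == "a1"], 2L)
  expect_equal(r$dispositions$n_b_dx[r$dispositions$record_id == "a2"], 0L)
})

test_that("key-uniqueness partition counts groups correctly", {
  r <- make_records(sprintf("r%d", 1:4), c(1, 2, 2, 3), "A")
  p <- partition_by_key_uniqueness(r)
  expect_setequal(p$unique$record_id, c("r1", "r4"))
  expect_equal(nrow(p$groups), 2)
  expect_equal(unique(p$groups$n), 2L)

  all_distinct <- make_records(sprintf("r%d", 1:5), 1:5, "A")
  expect_equal(nrow(partition_by_key_uniqueness(all_distinct)$groups), 0)

  one_pile <- make_records(sprintf("r%d", 1:6), 7, "A")
  p6 <- partition_by_key_uniqueness(one_pile)
  expect_equal(nrow(p6$unique), 0)
  expect_equal(nrow(p6$groups), 6)
})

test_that("non-female records are removed and audited, never silently linked", {
  a <- make_records(c("a1", "a2", "a3"), c(1, 2, 3), "A",
                    sex = c("female", "male", "unknown"))
  b <- make_records(c("b1", "b2", "b3"), c(1, 2, 3), "B",
                    sex = c("female", "male", "unknown"))
  r <- link_registries(a, b, b_diagnoses = make_dx("b1", "B"))
  expect_equal(nrow(r$dispositions), 1)
  expect_equal(r$audit$n_male_a, 1)
  expect_equal(r$audit$n_unknown_sex_a, 1)
  expect_equal(r$audit$n_male_b, 1)
  expect_equal(r$audit$n_unknown_sex_b, 1)
})

test_that("overlapping record-id namespaces are rejected", {
  a <- make_records("x1", 1, "A")
  b <- make_records("x1", 1, "B")
  expect_error(link_registries(a, b, b_diagnoses = make_dx("x1", "B")),
               "namespaces")
  expect_error(brute_force_link(a, b, b_diagnoses = make_dx("x1", "B")),
               "namespaces")
})

test_that("fast and all-pairs implementations agree on randomized instances", {
  for (seed in 1:40) {
    w <- random_instance(seed)
    r1 <- link_registries(w$a, w$b, w$adx, w$bdx)
    r2 <- brute_force_link(w$a, w$b, w$adx, w$bdx)
    expect_equivalent_results(r1, r2)
  }
})

test_that("every flow report satisfies the flow-conservation identities", {
  for (seed in 41:70) {
    w <- random_instance(seed)
    fr <- flow_report(link_registries(w$a, w$b, w$adx, w$bdx))
    cnt <- setNames(fr$count, fr$node)
    expect_equal(cnt[["remaining"]], cnt[["total_a"]] - cnt[["excluded_nonunique_a"]])
    expect_equal(cnt[["matched_in_b"]], cnt[["unique_in_b"]] + cnt[["nonunique_in_b"]])
    expect_equal(cnt[["included"]],
                 cnt[["unique_with_dx"]] + cnt[["nonunique_resolved"]])
    expect_true(all(fr$count >= 0))
    # no included B-record is claimed twice
    res <- link_registries(w$a, w$b, w$adx, w$bdx)
    expect_equal(anyDuplicated(res$pairs$record_id_b), 0)
  }
})

test_that("zero denominators yield flagged NA percentages, never NaN", {
  empty <- link_registries(make_records(character(0), integer(0), "A"),
                           make_records(character(0), integer(0), "B"),
                           b_diagnoses = make_dx(character(0), "B"))
  fr <- flow_report(empty)
  expect_true(all(fr$count == 0))
  expect_true(all(fr$pct_undefined))
  expect_true(all(is.na(fr$pct)))
  expect_false(any(is.nan(fr$pct)))
})

test_that("linkage on final pseudonyms reproduces linkage on raw keys", {
  for (seed in c(3, 17, 29)) {
    w <- random_instance(seed)
    a_dx <- has_breast_cancer_dx(w$a, w$adx)
    b_dx <- has_breast_cancer_dx(w$b, w$bdx)
    raw <- link_registries(a_dx, b_dx)
    ps <- pseudonymize_registries(a_dx, b_dx, "sender-k", "ttp-k")
    pseudo <- link_registries(ps$a, ps$b)
    expect_equal(pseudo$keyed_on, "pseudonym")
    expect_equivalent_results(raw, pseudo)
  }
})

test_that("removing a B-record adds inclusions only via single-diagnosis resolution of that record's group", {
  for (seed in 71:90) {
    w <- random_instance(seed, max_n = 25, key_space = 8)
    if (nrow(w$b) == 0) next
    base <- link_registries(w$a, w$b, w$adx, w$bdx)
    base_included <- base$pairs$record_id_a
    bkeys <- extract_linkage_key(w$b)
    for (i in seq_len(nrow(w$b))) {
      r2 <- link_registries(w$a, w$b[-i, ], w$adx,
                            w$bdx[w$bdx$record_id != w$b$record_id[i], ])
      gained <- setdiff(r2$pairs$record_id_a, base_included)
      if (length(gained) == 0) next
      gd <- r2$dispositions[r2$dispositions$record_id %in% gained, ]
      # new inclusions must sit on the removed record's key and be resolved
      # to exactly one diagnosis-bearing candidate after removal
      expect_true(all(gd$key == bkeys$key[i]))
      expect_true(all(gd$n_b_dx == 1L))
    }
  }
})
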
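# Builders for small in-code registry fixtures. Keys are abstract integers
# mapped to distinct dates of birth on a fixed pc4, so key equality in tests
# is exactly integer equality.

make_records <- function(ids, key, registry_id, sex = "female", pc4 = "1234") {
  tibble::tibble(
    record_id = ids,
    registry_id = registry_id,
    sex = rep_len(sex, length(ids)),
    date_of_birth = as.Date("1950-01-01") + as.integer(key),
    postal_code = rep_len(pc4, length(ids))
  )
}

make_dx <- function(ids, registry) {
  tibble::tibble(
    record_id = ids,
    code_system = if (registry == "A") "ICD10" else "ICPC1",
    code = if (registry == "A") "C50.9" else "X76",
    year = rep_len(2005L, length(ids))
  )
}

# random small linkage instance with key collisions on both sides and a
# random subset of diagnosis-bearing B records
random_instance <- function(seed, max_n = 40, key_space = 15) {
  withr::with_seed(seed, {
    n_a <- sample(0:max_n, 1)
    n_b <- sample(0:max_n, 1)
    a <- make_records(sprintf("a%03d", seq_len(n_a)),
                      sample.int(key_space, n_a, replace = TRUE), "A",
                      sex = sample(c("female", "male", "unknown"), n_a,
                                   replace = TRUE, prob = c(0.8, 0.1, 0.1)))
    b <- make_records(sprintf("b%03d", seq_len(n_b)),
                      sample.int(key_space, n_b, replace = TRUE), "B",
                      sex = sample(c("female", "male", "unknown"), n_b,
                                   replace = TRUE, prob = c(0.8, 0.1, 0.1)))
    list(a = a, b = b,
         adx = make_dx(a$record_id, "A"),
         bdx = make_dx(b$record_id[stats::runif(n_b) < 0.5], "B"))
  })
}

# canonical comparison form of a linkage result
result_snapshot <- function(result) {
  d <- dplyr::arrange(result$dispositions, .data$record_id)
  list(
    dispositions = d[, c("record_id", "disposition", "n_b", "n_b_dx",
                         "record_id_b")],
    pairs = dplyr::arrange(result$pairs, .data$record_id_a)
  )
}

expect_equivalent_results <- function(r1, r2) {
  s1 <- result_snapshot(r1)
  s2 <- result_snapshot(r2)
  expect_equal(as.character(s1$dispositions$disposition),
               as.character(s2$dispositions$disposition))
  expect_equal(s1$dispositions$record_id_b, s2$dispositions$record_id_b)
  expect_equal(s1$pairs, s2$pairs)
}
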
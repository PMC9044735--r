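#' Three-party pseudonymization chain
#'
#' Record linkage without exchanging identifiable data is organised as a chain
#' of three parties with strictly separated knowledge:
#'
#' 1. **Sender** ([sender_prepare()]): validates each record's format, replaces
#'    the linkage key (date of birth + 4-digit postal code) by a
#'    *pre-pseudonym* — a keyed one-way transform under the sender secret —
#'    and coarsens the quasi-identifiers to (birth year, birth quarter, pc4).
#' 2. **Trusted third party** ([ttp_transform()]): re-keys the pre-pseudonyms
#'    into *final pseudonyms* under its own secret. Its interface accepts a
#'    bare character vector of pre-pseudonyms, so quasi-identifiers cannot
#'    even be passed to it.
#' 3. **Receiver** ([receiver_combine()]): re-attaches the final pseudonym to
#'    the aggregated quasi-identifiers and clinical payload.
#'
#' Two records share a final pseudonym exactly when they share a linkage key,
#' so deterministic linkage can run on pseudonyms in place of raw keys.
#' The transform is HMAC-SHA256 over the canonical serialization
#' `"YYYY-MM-DD|PPPP"`; any keyed pseudo-random function satisfies the same
#' contracts. This simulates the data-flow separation, not production key
#' management.
#'
#' @name pseudonymization-chain
NULL

.hmac_hex <- function(x, secret) {
  as.character(openssl::sha256(x, key = secret))
}

#' Sender stage: validate, pre-pseudonymize, aggregate
#'
#' @param records a registry tibble (see [registry-tables]).
#' @param sender_secret non-empty character or raw secret shared by both
#'   senders (never written to any output).
#' @param payload_cols which clinical attribute columns to carry along;
#'   defaults to everything except the quasi-identifiers. `date_of_birth` and
#'   `postal_code` are always stripped.
#' @return a list with `prepared` — tibble of `pre_pseudonym`, `registry_id`,
#'   `birth_year`, `birth_quarter`, `pc4` and payload columns — and `errors`,
#'   the per-row validation report (`record_id`, `row`, `reason`). Rows that
#'   fail format checks appear in `errors` and not in `prepared`.
#' @export
sender_prepare <- function(records, sender_secret, payload_cols = NULL) {
  check_secret(sender_secret, "sender_secret")
  v <- validate_registry(records)
  key <- extract_linkage_key(v$records)
  qid <- aggregate_qid(v$records)
  payload_cols <- payload_cols %||%
    setdiff(names(v$records),
            c("date_of_birth", "postal_code", "registry_id"))
  payload_cols <- setdiff(payload_cols, c("date_of_birth", "postal_code"))
  prepared <- dplyr::bind_cols(
    tibble::tibble(
      pre_pseudonym = .hmac_hex(key$key, sender_secret),
      registry_id = v$records$registry_id
    ),
    dplyr::select(qid, "birth_year", "birth_quarter", "pc4"),
    dplyr::select(v$records, dplyr::all_of(payload_cols))
  )
  list(prepared = prepared, errors = v$errors)
}

#' Trusted-third-party stage: re-key pre-pseudonyms
#'
#' Accepts *only* a character vector of pre-pseudonyms — by construction the
#' TTP never sees quasi-identifiers, aggregated or otherwise. The output is
#' order- and length-preserving.
#'
#' @param pre_pseudonyms character vector of pre-pseudonyms.
#' @param ttp_secret non-empty secret known only to the trusted third party.
#' @return character vector of final pseudonyms, same length and order.
#' @export
ttp_transform <- function(pre_pseudonyms, ttp_secret) {
  check_secret(ttp_secret, "ttp_secret")
  if (!is.character(pre_pseudonyms)) {
    abort("`pre_pseudonyms` must be a character vector of pseudonyms only; refusing data frames or other structures")
  }
  if (length(pre_pseudonyms) == 0) return(character(0))
  .hmac_hex(pre_pseudonyms, ttp_secret)
}

#' Receiver stage: combine final pseudonyms with aggregated data
#'
#' @param prepared the `prepared` tibble from [sender_prepare()] (its
#'   `pre_pseudonym` column is dropped).
#' @param final_pseudonyms the character vector returned by [ttp_transform()]
#'   for the same rows, in the same order.
#' @return a *pseudonymized registry*: tibble with `pseudonym`, `registry_id`,
#'   aggregated quasi-identifiers and the clinical payload. No raw date of
#'   birth or full postal code is present.
#' @export
receiver_combine <- function(prepared, final_pseudonyms) {
  prepared <- tibble::as_tibble(prepared)
  if (length(final_pseudonyms) != nrow(prepared)) {
    abort(sprintf(
      "alignment error: %d final pseudonyms for %d payload rows",
      length(final_pseudonyms), nrow(prepared)))
  }
  out <- dplyr::select(prepared, -dplyr::any_of("pre_pseudonym"))
  out <- dplyr::bind_cols(tibble::tibble(pseudonym = final_pseudonyms), out)
  stopifnot(!any(c("date_of_birth", "postal_code") %in% names(out)))
  out
}

#' Run the full pseudonymization chain over both registries
#'
#' Convenience wrapper: sender stage on each registry, one TTP pass over the
#' concatenated pre-pseudonym stream, receiver stage per registry. Records of
#' registries A and B that share a linkage key end up with identical final
#' pseudonyms.
#'
#' @param a,b registry tibbles.
#' @param sender_secret,ttp_secret the two parties' secrets.
#' @return list with pseudonymized registries `a` and `b` and the combined
#'   validation `errors` report.
#' @export
pseudonymize_registries <- function(a, b, sender_secret, ttp_secret) {
  sa <- sender_prepare(a, sender_secret)
  sb <- sender_prepare(b, sender_secret)
  fin_a <- ttp_transform(sa$prepared$pre_pseudonym, ttp_secret)
  fin_b <- ttp_transform(sb$prepared$pre_pseudonym, ttp_secret)
  list(
    a = receiver_combine(sa$prepared, fin_a),
    b = receiver_combine(sb$prepared, fin_b),
    errors = dplyr::bind_rows(
      dplyr::mutate(sa$errors, registry_id = "A"),
      dplyr::mutate(sb$errors, registry_id = "B")
    )
  )
}

check_secret <- function(secret, what) {
  if (is.raw(secret)) {
    if (length(secret) == 0) abort(paste0(what, " must be non-empty"))
    return(invisible(TRUE))
  }
  if (!is.character(secret) || length(secret) != 1 || is.na(secret) ||
      nchar(secret) == 0) {
    abort(paste0(what, " must be a non-empty secret (single string or raw vector)"))
  }
  invisible(TRUE)
}
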
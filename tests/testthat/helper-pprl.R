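# shared fixtures, all built in code

test_key <- "unit-test-key"

# a bloom_filter with exactly the given 1-based bit positions set
make_filter <- function(positions, length_bits = 64L) {
  bits <- raw((length_bits + 7) %/% 8)
  for (p in positions) {
    byte <- (p - 1) %/% 8 + 1
    bit <- (p - 1) %% 8
    bits[byte] <- as.raw(bitwOr(as.integer(bits[byte]), bitwShiftL(1L, bit)))
  }
  pprlink:::new_bloom_filter(bits, length_bits)
}

# a small hand-built person dataset: n_entities individuals, k records each,
# drawn from the bundled tables so field values are realistic
small_dataset <- function(n_records = 300, seed = 101) {
  generate_master(generator_config(n_records, seed = seed))
}

# person record rows built explicitly (for blocking / comparison edge cases)
person_row <- function(record_id, entity_id = "E1",
                       first_name = "Anna", middle_name = "May",
                       last_name = "Smith", sex = "F",
                       dob_year = "1980", dob_month = "6", dob_day = "15",
                       address = "12 River Road", suburb = "Glenvale",
                       postcode = "6001") {
  data.frame(
    record_id = record_id, entity_id = entity_id, first_name = first_name,
    middle_name = middle_name, last_name = last_name, sex = sex,
    dob_year = dob_year, dob_month = dob_month, dob_day = dob_day,
    address = address, suburb = suburb, postcode = postcode,
    stringsAsFactors = FALSE
  )
}

# build a field_state_table directly from integer state codes (0 agree,
# 1 disagree, 2 missing)
state_table <- function(states, counts, fields = NULL) {
  states <- as.matrix(states)
  if (is.null(fields)) fields <- paste0("f", seq_len(ncol(states)))
  pprlink:::new_field_state_table(states, counts, fields)
}

# simulate a field-state table of `n_pairs` pairs from the trinary product
# model with known parameters (multinomial over the full 3^n space)
simulate_state_table <- function(m, u, mm, um, p, n_pairs, seed) {
  nf <- length(m)
  codes <- 0:(3^nf - 1)
  states <- pprlink:::code_to_states(codes, nf)
  recall <- fpr <- rep(1, length(codes))
  for (f in seq_len(nf)) {
    st <- states[, f]
    recall <- recall * ifelse(st == 0, m[f], ifelse(st == 1, 1 - m[f] - mm[f], mm[f]))
    fpr <- fpr * ifelse(st == 0, u[f], ifelse(st == 1, 1 - u[f] - um[f], um[f]))
  }
  prob <- p * recall + (1 - p) * fpr
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n_pairs, prob))
  keep <- counts > 0
  state_table(states[keep, , drop = FALSE], counts[keep])
}

# exhaustive (quadratic) linkage evaluation oracle over all record pairs
brute_force_evaluation <- function(matches, truth) {
  ids <- truth$record_id
  ent <- truth$entity_id
  tp <- fp <- fn <- 0L
  mk <- paste(pmin(matches$id_a, matches$id_b), pmax(matches$id_a, matches$id_b))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      is_true <- ent[i] == ent[j]
      key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
      is_match <- key %in% mk
      if (is_match && is_true) tp <- tp + 1L
      if (is_match && !is_true) fp <- fp + 1L
      if (!is_match && is_true) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}
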
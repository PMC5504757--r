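#' Bloom filter encoding parameters
#'
#' Field values are split into q-grams (after normalisation and optional
#' sentinel padding) and each q-gram sets `num_hashes` bit positions obtained
#' by keyed double hashing: two independent keyed hash values `g1`, `g2` of
#' the q-gram give positions `(g1 + i * g2) mod length_bits` for
#' `i = 0, ..., num_hashes - 1`.
#'
#' @param length_bits filter length in bits (>= 8).
#' @param num_hashes number of bit positions per q-gram (>= 1).
#' @param qgram_length q-gram length (bigrams by default).
#' @param pad frame values with `q - 1` sentinel characters on each side
#'   before q-gram extraction.
#' @param secret_key character scalar; the shared linkage secret. All hashing
#'   (Bloom positions, tokens, blocking keys) is keyed so the encoded output
#'   cannot be reproduced without it.
#' @return an object of class `bloom_params`.
#' @export
bloom_params <- function(length_bits = 1000L, num_hashes = 30L,
                         qgram_length = 2L, pad = TRUE,
                         secret_key = "change-me") {
  length_bits <- as.integer(length_bits)
  num_hashes <- as.integer(num_hashes)
  qgram_length <- as.integer(qgram_length)
  if (is.na(length_bits) || length_bits < 8) {
    stop("`length_bits` must be >= 8", call. = FALSE)
  }
  if (is.na(num_hashes) || num_hashes < 1) {
    stop("`num_hashes` must be >= 1", call. = FALSE)
  }
  if (is.na(qgram_length) || qgram_length < 1) {
    stop("`qgram_length` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      length_bits = length_bits, num_hashes = num_hashes,
      qgram_length = qgram_length, pad = isTRUE(pad),
      secret_key = as.character(secret_key)
    ),
    class = "bloom_params"
  )
}

#' @export
print.bloom_params <- function(x, ...) {
  cat(sprintf(
    "<bloom_params> %d bits, %d hashes, q = %d, pad = %s, key set: %s\n",
    x$length_bits, x$num_hashes, x$qgram_length, x$pad,
    nzchar(x$secret_key)
  ))
  invisible(x)
}

#' Extract the set of q-grams of a value
#'
#' The value is normalised first ([normalise_value()]); with `pad = TRUE` it
#' is framed with `q - 1` sentinel (`_`) characters on each side. Duplicate
#' q-grams collapse (set semantics). A value that yields no q-grams (empty
#' after normalisation, or shorter than `q` without padding) returns an empty
#' character vector, which callers treat as missing.
#'
#' @param value character scalar.
#' @param q q-gram length.
#' @param pad logical.
#' @return character vector of distinct q-grams.
#' @export
qgram_set <- function(value, q = 2L, pad = TRUE) {
  v <- normalise_value(value)
  if (length(v) != 1) stop("`value` must be a single string", call. = FALSE)
  cpp_qgram_sets(v, as.integer(q), isTRUE(pad))[[1]]
}

#' Encode a single value as a Bloom filter
#'
#' @param value character scalar (normalised internally).
#' @param params a [bloom_params()].
#' @return an object of class `bloom_filter` (bits as a raw vector plus the
#'   cached popcount), or `NULL` if the value is missing/empty — a missing
#'   value is never encoded as an all-zero filter.
#' @export
bloom_encode <- function(value, params = bloom_params()) {
  stopifnot(inherits(params, "bloom_params"))
  v <- normalise_value(value)
  enc <- cpp_bloom_encode(
    v, params$qgram_length, params$pad, params$length_bits,
    params$num_hashes, params$secret_key
  )
  if (enc$missing[1]) {
    return(NULL)
  }
  new_bloom_filter(enc$bits[, 1], params$length_bits)
}

new_bloom_filter <- function(bits, length_bits) {
  structure(
    list(
      bits = bits, length_bits = as.integer(length_bits),
      popcount = cpp_popcount_raw(bits)
    ),
    class = "bloom_filter"
  )
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat(sprintf(
    "<bloom_filter> %d bits, %d set (fill %.1f%%)\n",
    x$length_bits, x$popcount, 100 * x$popcount / x$length_bits
  ))
  invisible(x)
}

#' Keyed hash token for exact-match fields
#'
#' @param value character scalar; normalised before hashing, so case and
#'   surrounding whitespace do not change the token.
#' @param secret_key character scalar.
#' @return a 16-character hex token, or `NA` for missing/empty values.
#' @export
hash_token <- function(value, secret_key) {
  v <- normalise_value(value)
  as.character(cpp_hash_tokens(v, as.character(secret_key)))
}

#' American Soundex code of a name
#'
#' Standard Soundex: initial letter retained, remaining letters mapped to
#' digit classes (BFPV=1, CGJKQSXZ=2, DT=3, L=4, MN=5, R=6), adjacent equal
#' codes collapsed (also across H/W), vowels (and Y) acting as separators,
#' zero-padded to letter + 3 digits.
#'
#' @param name character vector.
#' @return character vector of 4-character codes; `NA` where the value has
#'   no leading alphabetic character after normalisation.
#' @export
soundex <- function(name) {
  codes <- c(
    B = "1", F = "1", P = "1", V = "1",
    C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2", Z = "2",
    D = "3", T = "3", L = "4", M = "5", N = "5", R = "6",
    A = "0", E = "0", I = "0", O = "0", U = "0", Y = "0",
    H = "-", W = "-"
  )
  vapply(name, function(v) {
    v <- normalise_value(v)
    if (is.na(v)) {
      return(NA_character_)
    }
    letters_only <- gsub("[^A-Z]", "", v)
    if (!nchar(letters_only)) {
      return(NA_character_)
    }
    ch <- strsplit(letters_only, "")[[1]]
    code <- unname(codes[ch])
    out <- character(0)
    prev <- code[1]
    for (i in seq_along(ch)[-1]) {
      ci <- code[i]
      if (ci == "-") next # H/W: invisible, previous code carries over
      if (ci == "0") { # vowel: separator, resets the previous code
        prev <- "0"
        next
      }
      if (ci != prev) out <- c(out, ci)
      prev <- ci
    }
    paste0(ch[1], substr(paste0(paste(out, collapse = ""), "000"), 1, 3))
  }, character(1), USE.NAMES = FALSE)
}

#' Blocking keys for a person record
#'
#' Two strategies: (A) Soundex of the last name concatenated with the first
#' initial; (B) date of birth (year, month, day) concatenated with sex. Each
#' key is emitted as a keyed hash token, so the encoded file leaks no
#' phonetic codes or dates; a strategy produces no key when any of its
#' components is missing.
#'
#' @param record a one-row data.frame (or list) with the person fields.
#' @param secret_key character scalar.
#' @return named character vector with elements `A` and/or `B`.
#' @export
make_blocking_keys <- function(record, secret_key) {
  keys <- blocking_key_strings(
    record$last_name, record$first_name,
    record$dob_year, record$dob_month, record$dob_day, record$sex
  )
  out <- c(
    A = hash_token(keys$A, secret_key)[1],
    B = hash_token(keys$B, secret_key)[1]
  )
  out[!is.na(out)]
}

# vectorised plaintext key strings (pre-hash); NA where a component is
# missing
blocking_key_strings <- function(last_name, first_name, dob_year, dob_month,
                                 dob_day, sex) {
  sx <- soundex(last_name)
  fn <- normalise_value(first_name)
  a <- ifelse(is.na(sx) | is.na(fn), NA_character_,
    paste0("A|", sx, "|", substr(fn, 1, 1))
  )
  y <- normalise_value(dob_year)
  m <- normalise_value(dob_month)
  d <- normalise_value(dob_day)
  s <- normalise_value(sex)
  b <- ifelse(is.na(y) | is.na(m) | is.na(d) | is.na(s), NA_character_,
    paste0("B|", y, "|", m, "|", d, "|", s)
  )
  list(A = a, B = b)
}

#' Field encoding scheme
#'
#' Assigns each linkage field a privacy encoding and a comparator: names,
#' address and suburb are Bloom-filter encoded and compared with the
#' Sorensen-Dice coefficient; sex, date-of-birth components and postcode are
#' keyed hash tokens compared exactly. `agree_cutoff` discretises a Dice
#' similarity into the agree/disagree states used for tabulation; scoring
#' itself uses the continuous partial-agreement curve.
#'
#' @param agree_cutoff Dice similarity at or above which a Bloom comparison
#'   counts as agreement; in (0, 1].
#' @param partial_curve a [partial_curve()] used to convert Dice similarity
#'   into a fraction of the agreement weight.
#' @return an object of class `field_scheme`: a data.frame with one row per
#'   linkage field and the curve as an attribute.
#' @export
field_scheme <- function(agree_cutoff = 0.8, partial_curve = pprlink::partial_curve()) {
  if (!is.numeric(agree_cutoff) || agree_cutoff <= 0 || agree_cutoff > 1) {
    stop("`agree_cutoff` must be in (0, 1]", call. = FALSE)
  }
  bloom_fields <- c("first_name", "middle_name", "last_name", "address", "suburb")
  sch <- data.frame(
    field = LINKAGE_FIELDS,
    encode = ifelse(LINKAGE_FIELDS %in% bloom_fields, "bloom", "token"),
    comparator = ifelse(LINKAGE_FIELDS %in% bloom_fields, "dice", "exact"),
    agree_cutoff = ifelse(LINKAGE_FIELDS %in% bloom_fields, agree_cutoff, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(sch, partial_curve = partial_curve, class = c("field_scheme", "data.frame"))
}

#' Encode a plaintext dataset into privacy-preserved records
#'
#' Produces, per record: a Bloom filter or keyed hash token for each linkage
#' field (missing exactly where the plaintext is missing) and the two
#' blocking keys. The `entity_id` column, if present, is dropped — no truth
#' information and no plaintext value appears in the encoded output.
#'
#' @param dataset person-record data.frame.
#' @param params a [bloom_params()] (carries the secret key).
#' @param scheme a [field_scheme()].
#' @return an object of class `encoded_dataset`.
#' @export
encode_dataset <- function(dataset, params = bloom_params(), scheme = field_scheme()) {
  stopifnot(inherits(params, "bloom_params"), inherits(scheme, "field_scheme"))
  if (anyDuplicated(dataset$record_id)) {
    stop("duplicate record_id in input", call. = FALSE)
  }
  n <- nrow(dataset)
  fields <- vector("list", nrow(scheme))
  names(fields) <- scheme$field
  for (i in seq_len(nrow(scheme))) {
    f <- scheme$field[i]
    vals <- normalise_value(dataset[[f]])
    if (scheme$encode[i] == "bloom") {
      enc <- cpp_bloom_encode(
        vals, params$qgram_length, params$pad,
        params$length_bits, params$num_hashes, params$secret_key
      )
      fields[[f]] <- list(type = "bloom", bits = enc$bits, missing = enc$missing)
    } else {
      fields[[f]] <- list(
        type = "token",
        token = as.character(cpp_hash_tokens(vals, params$secret_key))
      )
    }
  }
  keys <- blocking_key_strings(
    dataset$last_name, dataset$first_name, dataset$dob_year,
    dataset$dob_month, dataset$dob_day, dataset$sex
  )
  structure(
    list(
      record_id = as.character(dataset$record_id),
      n = n,
      fields = fields,
      block_a = as.character(cpp_hash_tokens(keys$A, params$secret_key)),
      block_b = as.character(cpp_hash_tokens(keys$B, params$secret_key)),
      params = params,
      scheme = scheme
    ),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  nb <- sum(vapply(x$fields, function(f) f$type == "bloom", logical(1)))
  cat(sprintf(
    "<encoded_dataset> %d records, %d fields (%d Bloom, %d token), %d-bit filters\n",
    x$n, length(x$fields), nb, length(x$fields) - nb, x$params$length_bits
  ))
  invisible(x)
}

field_missing <- function(encoded, field) {
  enc <- encoded$fields[[field]]
  if (enc$type == "bloom") enc$missing else is.na(enc$token)
}

#' Write / read an encoded dataset as CSV plus a JSON sidecar
#'
#' Bloom fields are serialised as base64 of the bit vector, token fields and
#' blocking keys as hex strings; missing encodings are empty cells. The
#' sidecar JSON records the Bloom parameters (without the secret key) and the
#' field scheme, so a round trip reproduces bit-identical filters.
#'
#' @param encoded an `encoded_dataset`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `read_encoded_csv()` returns an `encoded_dataset` (with an empty
#'   secret key — the key is never persisted); `write_encoded_csv()` returns
#'   `path` invisibly.
#' @name encoded_csv
#' @export
write_encoded_csv <- function(encoded, path) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  df <- data.frame(record_id = encoded$record_id, stringsAsFactors = FALSE)
  for (f in names(encoded$fields)) {
    enc <- encoded$fields[[f]]
    if (enc$type == "bloom") {
      col <- vapply(seq_len(encoded$n), function(i) {
        if (enc$missing[i]) "" else gsub("[\r\n]", "", jsonlite::base64_enc(enc$bits[, i]))
      }, character(1))
    } else {
      col <- ifelse(is.na(enc$token), "", enc$token)
    }
    df[[f]] <- col
  }
  df$block_a <- ifelse(is.na(encoded$block_a), "", encoded$block_a)
  df$block_b <- ifelse(is.na(encoded$block_b), "", encoded$block_b)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    params = encoded$params[c("length_bits", "num_hashes", "qgram_length", "pad")],
    scheme = as.data.frame(encoded$scheme),
    partial_curve = unclass(attr(encoded$scheme, "partial_curve"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname encoded_csv
#' @export
read_encoded_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- bloom_params(
    length_bits = side$params$length_bits,
    num_hashes = side$params$num_hashes,
    qgram_length = side$params$qgram_length,
    pad = side$params$pad,
    secret_key = ""
  )
  curve <- partial_curve(side$partial_curve$sim, side$partial_curve$frac)
  sch <- side$scheme
  scheme <- structure(as.data.frame(sch, stringsAsFactors = FALSE),
    partial_curve = curve, class = c("field_scheme", "data.frame")
  )
  n <- nrow(df)
  nbytes <- (params$length_bits + 7) %/% 8
  fields <- vector("list", nrow(scheme))
  names(fields) <- scheme$field
  for (i in seq_len(nrow(scheme))) {
    f <- scheme$field[i]
    col <- df[[f]]
    col[is.na(col)] <- ""
    if (scheme$encode[i] == "bloom") {
      bits <- matrix(as.raw(0), nrow = nbytes, ncol = n)
      missing <- col == ""
      for (j in which(!missing)) bits[, j] <- jsonlite::base64_dec(col[j])
      fields[[f]] <- list(type = "bloom", bits = bits, missing = missing)
    } else {
      fields[[f]] <- list(
        type = "token",
        token = ifelse(col == "", NA_character_, col)
      )
    }
  }
  ba <- df$block_a
  bb <- df$block_b
  ba[is.na(ba)] <- ""
  bb[is.na(bb)] <- ""
  structure(
    list(
      record_id = df$record_id, n = n, fields = fields,
      block_a = ifelse(ba == "", NA_character_, ba),
      block_b = ifelse(bb == "", NA_character_, bb),
      params = params, scheme = scheme
    ),
    class = "encoded_dataset"
  )
}
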
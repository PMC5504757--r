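#' Partial-agreement curve
#'
#' Winkler-style conversion of a similarity into a fraction of the agreement
#' weight: below the lowest anchor the full disagreement weight applies; at
#' and above it the weight is `frac(sim) * w_agree` with `frac` linearly
#' interpolated between the anchors (and 1 at similarity 1). The default
#' curve anchors fraction 0 at similarity 0.8 rising to 1 at similarity 1.
#'
#' @param sim anchor similarities, non-decreasing, in \[0, 1\].
#' @param frac anchor weight fractions, non-decreasing, in \[0, 1\].
#' @return an object of class `partial_curve`.
#' @export
partial_curve <- function(sim = c(0.8, 1), frac = c(0, 1)) {
  sim <- as.numeric(sim)
  frac <- as.numeric(frac)
  if (length(sim) != length(frac) || length(sim) < 2) {
    stop("`sim` and `frac` must be equal-length vectors of >= 2 anchors", call. = FALSE)
  }
  if (is.unsorted(sim) || is.unsorted(frac)) {
    stop("partial-curve anchors must be non-decreasing", call. = FALSE)
  }
  structure(list(sim = sim, frac = frac), class = "partial_curve")
}

#' Sorensen-Dice coefficient of two Bloom filters
#'
#' `2 |A & B| / (|A| + |B|)` over set bits; symmetric, in \[0, 1\], and 1 for
#' bit-identical non-empty filters.
#'
#' @param a,b `bloom_filter` objects of the same length.
#' @return similarity in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "bloom_filter"), inherits(b, "bloom_filter"))
  if (a$length_bits != b$length_bits) {
    stop("Bloom filters have different lengths", call. = FALSE)
  }
  if (a$popcount + b$popcount == 0) {
    stop("degenerate input: both filters have no set bits", call. = FALSE)
  }
  cpp_dice_raw(a$bits, b$bits)
}

#' Comparison state of a single field
#'
#' Either encoding missing gives the `missing` state. Exact (token) fields
#' agree iff the tokens are equal. Dice (Bloom) fields agree iff the Dice
#' similarity reaches `agree_cutoff`; the similarity is retained for
#' partial-weight scoring either way.
#'
#' @param encoding_a,encoding_b `bloom_filter` objects, token strings, or
#'   `NULL`/`NA` for missing.
#' @param comparator `"dice"` or `"exact"`.
#' @param agree_cutoff Dice cutoff for the agree state.
#' @return list with elements `state` (`"agree"`, `"disagree"` or
#'   `"missing"`) and `similarity` (`NA` for missing or exact comparisons
#'   unless 0/1).
#' @export
field_state <- function(encoding_a, encoding_b, comparator = c("dice", "exact"),
                        agree_cutoff = 0.8) {
  comparator <- match.arg(comparator)
  is_missing <- function(e) {
    is.null(e) || (!inherits(e, "bloom_filter") && (length(e) == 0 || is.na(e)))
  }
  if (is_missing(encoding_a) || is_missing(encoding_b)) {
    return(list(state = "missing", similarity = NA_real_))
  }
  if (comparator == "exact") {
    agree <- identical(as.character(encoding_a), as.character(encoding_b))
    return(list(
      state = if (agree) "agree" else "disagree",
      similarity = as.numeric(agree)
    ))
  }
  d <- dice_coefficient(encoding_a, encoding_b)
  list(
    state = if (d >= agree_cutoff) "agree" else "disagree",
    similarity = d
  )
}

#' Candidate record pairs by blocking
#'
#' Takes the union over the two blocking strategies of all within-block
#' pairs. Each unordered pair appears once, a record is never paired with
#' itself, and records lacking a strategy's key contribute no pairs under
#' that strategy.
#'
#' @param encoded an `encoded_dataset`.
#' @param max_block_size blocks larger than this raise a warning (they can
#'   dominate run time quadratically).
#' @return a `data.table` with integer record indices `ia < ib` and the
#'   record ids `id_a`, `id_b`.
#' @export
candidate_pairs <- function(encoded, max_block_size = 10000L) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  pairs_for <- function(keys, strategy) {
    dt <- data.table::data.table(blk = keys, i = seq_along(keys))
    dt <- dt[!is.na(blk)]
    if (nrow(dt) == 0) {
      return(data.table::data.table(ia = integer(0), ib = integer(0)))
    }
    sizes <- dt[, .N, by = blk]
    big <- sizes[sizes$N > max_block_size]
    if (nrow(big)) {
      warning(sprintf(
        "blocking strategy %s has %d block(s) larger than %d records (largest: %d)",
        strategy, nrow(big), max_block_size, max(big$N)
      ), call. = FALSE)
    }
    j <- dt[dt, on = "blk", allow.cartesian = TRUE]
    j <- j[j$i < j$i.i]
    data.table::data.table(ia = j$i, ib = j$i.i)
  }
  out <- unique(rbind(
    pairs_for(encoded$block_a, "A"),
    pairs_for(encoded$block_b, "B")
  ))
  data.table::setorder(out, ia, ib)
  out[, `:=`(
    id_a = encoded$record_id[ia],
    id_b = encoded$record_id[ib]
  )]
  out[]
}

#' Compare encoded fields over a set of candidate pairs
#'
#' @param encoded an `encoded_dataset`.
#' @param pairs a data.frame with integer index columns `ia`, `ib` (as from
#'   [candidate_pairs()]).
#' @return an object of class `pair_comparisons`: the pair indices/ids, a
#'   state matrix (one column per field, values `agree` / `disagree` /
#'   `missing` coded 0/1/2) and a Dice similarity matrix for the Bloom
#'   fields.
#' @export
compare_pairs <- function(encoded, pairs) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  scheme <- encoded$scheme
  bloom_idx <- which(scheme$encode == "bloom")
  token_idx <- which(scheme$encode == "token")
  bloom_bits <- lapply(scheme$field[bloom_idx], function(f) encoded$fields[[f]]$bits)
  bloom_miss <- lapply(scheme$field[bloom_idx], function(f) encoded$fields[[f]]$missing)
  cutoffs <- scheme$agree_cutoff[bloom_idx]
  # integer-code the tokens once for fast equality in C++
  tokens <- matrix(NA_integer_, nrow = encoded$n, ncol = length(token_idx))
  for (j in seq_along(token_idx)) {
    tok <- encoded$fields[[scheme$field[token_idx[j]]]]$token
    tokens[, j] <- match(tok, unique(tok[!is.na(tok)]))
  }
  kind <- ifelse(scheme$encode == "bloom", 0L, 1L)
  slot <- integer(nrow(scheme))
  slot[bloom_idx] <- seq_along(bloom_idx)
  slot[token_idx] <- seq_along(token_idx)
  cmp <- cpp_compare_pairs(
    as.integer(pairs$ia), as.integer(pairs$ib),
    bloom_bits, bloom_miss, as.numeric(cutoffs), tokens, kind, slot
  )
  colnames(cmp$states) <- scheme$field
  colnames(cmp$sims) <- scheme$field[bloom_idx]
  structure(
    list(
      ia = as.integer(pairs$ia), ib = as.integer(pairs$ib),
      id_a = encoded$record_id[pairs$ia], id_b = encoded$record_id[pairs$ib],
      states = cmp$states, sims = cmp$sims, scheme = scheme
    ),
    class = "pair_comparisons"
  )
}

#' @export
print.pair_comparisons <- function(x, ...) {
  cat(sprintf(
    "<pair_comparisons> %d pairs x %d fields\n",
    length(x$ia), ncol(x$states)
  ))
  invisible(x)
}

#' Partial agreement weight for a similarity value
#'
#' Similarity 1 maps to the full agreement weight; below the curve's lowest
#' anchor the full disagreement weight applies; in between, the weight is the
#' interpolated fraction of the agreement weight. Monotone non-decreasing in
#' the similarity.
#'
#' @param similarity numeric vector in \[0, 1\].
#' @param w_agree,w_disagree field agreement/disagreement weights.
#' @param curve a [partial_curve()].
#' @return numeric vector of weights.
#' @export
partial_weight <- function(similarity, w_agree, w_disagree,
                           curve = partial_curve()) {
  stopifnot(inherits(curve, "partial_curve"))
  lo <- curve$sim[1]
  frac <- stats::approx(curve$sim, curve$frac,
    xout = pmin(pmax(similarity, lo), max(curve$sim)), rule = 2
  )$y
  out <- frac * w_agree
  out[similarity < lo] <- w_disagree
  out
}

# vectorised scores for a pair_comparisons object
score_states <- function(comparisons, weights) {
  scheme <- comparisons$scheme
  curve <- attr(scheme, "partial_curve")
  wa <- stats::setNames(weights$w_agree, weights$field)
  wd <- stats::setNames(weights$w_disagree, weights$field)
  n <- length(comparisons$ia)
  score <- numeric(n)
  for (i in seq_len(nrow(scheme))) {
    f <- scheme$field[i]
    st <- comparisons$states[, f]
    if (scheme$comparator[i] == "dice") {
      sim <- comparisons$sims[, f]
      w <- partial_weight(sim, wa[[f]], wd[[f]], curve)
      w[st == 2L] <- 0
      score <- score + ifelse(st == 2L, 0, w)
    } else {
      score <- score + ifelse(st == 2L, 0, ifelse(st == 0L, wa[[f]], wd[[f]]))
    }
  }
  score
}

#' Score record pairs under the Fellegi-Sunter model
#'
#' Sums per-field scores: missing contributes zero; exact fields contribute
#' the agreement or disagreement weight; Dice fields contribute the partial
#' weight of their similarity.
#'
#' @param comparisons a `pair_comparisons` object.
#' @param weights a weight table (see [weights_from_parameters()] /
#'   [weight_set()]): data.frame with `field`, `w_agree`, `w_disagree`.
#' @return numeric vector of pair scores.
#' @export
score_pairs <- function(comparisons, weights) {
  stopifnot(inherits(comparisons, "pair_comparisons"))
  if (!all(comparisons$scheme$field %in% weights$field)) {
    stop("weights missing for some fields", call. = FALSE)
  }
  score_states(comparisons, weights)
}

#' @rdname score_pairs
#' @param index row index of the single pair to score.
#' @export
score_pair <- function(comparisons, weights, index = 1L) {
  score_pairs(comparisons, weights)[index]
}

#' Run a linkage: candidate pairs scoring at or above a threshold
#'
#' @param encoded an `encoded_dataset`.
#' @param weights per-field weight table.
#' @param threshold decision threshold; pairs with score >= threshold are
#'   matches (use `strict_gt = TRUE` for strictly greater).
#' @param pairs optional precomputed candidate pairs.
#' @param comparisons optional precomputed `pair_comparisons`.
#' @param strict_gt logical; match on `score > threshold` instead of `>=`.
#' @return `data.table(id_a, id_b, score)` with `id_a < id_b`
#'   lexicographically.
#' @export
run_linkage <- function(encoded, weights, threshold, pairs = NULL,
                        comparisons = NULL, strict_gt = FALSE) {
  if (is.null(comparisons)) {
    if (is.null(pairs)) pairs <- candidate_pairs(encoded)
    comparisons <- compare_pairs(encoded, pairs)
  }
  score <- score_pairs(comparisons, weights)
  keep <- if (strict_gt) score > threshold else score >= threshold
  out <- data.table::data.table(
    id_a = pmin(comparisons$id_a[keep], comparisons$id_b[keep]),
    id_b = pmax(comparisons$id_a[keep], comparisons$id_b[keep]),
    score = score[keep]
  )
  data.table::setorder(out, id_a, id_b)
  out[]
}
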
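#' De-duplicate one dataset end to end
#'
#' Runs the whole privacy-preserving pipeline on a single file: encode (if
#' given plaintext), block, compare, tabulate field states, fit the extended
#' EM, estimate u from unblocked value frequencies, adopt EM m with
#' frequency u, derive weights, estimate the optimal threshold from the
#' predicted quality curve over the full field-state space, and link. If the
#' input carries an `entity_id` column (or `truth` is supplied) the realised
#' quality at the chosen threshold and over all thresholds is evaluated too
#' — the truth is used for evaluation only, never for estimation.
#'
#' Pair comparison runs in chunks of `chunk_size` pairs so memory stays flat
#' for large block unions.
#'
#' @param dataset plaintext person-record data.frame, or an
#'   `encoded_dataset`.
#' @param params [bloom_params()] used when encoding plaintext.
#' @param scheme [field_scheme()].
#' @param truth optional `data.frame(record_id, entity_id)`.
#' @param init,tol,max_iter EM controls, see [run_em()].
#' @param integer_thresholds see [quality_curve()].
#' @param chunk_size pairs per comparison chunk.
#' @return list of class `pprl_result` with elements `encoded`, `n_pairs`,
#'   `state_table`, `em`, `u_freq`, `adopted`, `weights`, `curve`,
#'   `threshold`, `matches`, and (when truth is available) `evaluation` and
#'   `actual_curve`.
#' @export
pprl_deduplicate <- function(dataset, params = bloom_params(),
                             scheme = field_scheme(), truth = NULL,
                             init = NULL, tol = 1e-6, max_iter = 1000L,
                             integer_thresholds = FALSE,
                             chunk_size = 1e6) {
  if (inherits(dataset, "encoded_dataset")) {
    encoded <- dataset
  } else {
    if (is.null(truth) && "entity_id" %in% names(dataset)) {
      truth <- truth_from_dataset(dataset)
    }
    encoded <- encode_dataset(dataset, params, scheme)
  }
  pairs <- candidate_pairs(encoded)
  if (nrow(pairs) == 0) stop("no candidate pairs produced by blocking", call. = FALSE)

  nf <- nrow(encoded$scheme)
  counts <- numeric(3^nf)
  scores <- numeric(nrow(pairs))
  chunks <- split(
    seq_len(nrow(pairs)),
    ceiling(seq_len(nrow(pairs)) / chunk_size)
  )
  comparisons_list <- vector("list", length(chunks))
  for (k in seq_along(chunks)) {
    idx <- chunks[[k]]
    cmp <- compare_pairs(encoded, pairs[idx, ])
    codes <- state_codes(cmp$states)
    counts <- counts + tabulate(codes + 1L, nbins = 3^nf)
    comparisons_list[[k]] <- cmp
  }
  nz <- which(counts > 0)
  state_table <- new_field_state_table(
    code_to_states(nz - 1L, nf), counts[nz], encoded$scheme$field
  )

  em <- run_em(state_table, init = init, tol = tol, max_iter = max_iter)
  u_freq <- estimate_u_frequencies(encoded)
  adopted <- adopt_parameters(em, u_freq)
  weights <- weight_set(adopted)

  stats <- em_expectation(state_table, adopted)
  totals <- estimate_match_totals(state_table, stats, encoded$n)
  space <- enumerate_full_space(state_table, adopted)
  curve <- quality_curve(space, totals, integer_thresholds = integer_thresholds)
  threshold <- select_threshold(curve)

  for (k in seq_along(chunks)) {
    scores[chunks[[k]]] <- score_pairs(comparisons_list[[k]], weights)
  }
  keep <- scores >= threshold
  matches <- data.table::data.table(
    id_a = pmin(pairs$id_a[keep], pairs$id_b[keep]),
    id_b = pmax(pairs$id_a[keep], pairs$id_b[keep]),
    score = scores[keep]
  )
  data.table::setorder(matches, id_a, id_b)

  out <- list(
    encoded = encoded, n_pairs = nrow(pairs), state_table = state_table,
    em = em, u_freq = u_freq, adopted = adopted, weights = weights,
    curve = curve, threshold = threshold, matches = matches,
    scores = scores, pairs = pairs
  )
  if (!is.null(truth)) {
    out$evaluation <- evaluate_linkage(matches, truth)
    entity <- truth$entity_id[match(encoded$record_id, truth$record_id)]
    is_true <- !is.na(entity[pairs$ia]) & !is.na(entity[pairs$ib]) &
      entity[pairs$ia] == entity[pairs$ib]
    n_true <- nrow(true_pairs(truth))
    out$actual_curve <- actual_quality_curve(scores, is_true, n_true)
  }
  class(out) <- "pprl_result"
  out
}

#' @export
print.pprl_result <- function(x, ...) {
  cat("<pprl_result>\n")
  cat(sprintf(
    "  %d records, %s candidate pairs, %d observed field-state combinations\n",
    x$encoded$n, format(x$n_pairs, big.mark = ","), nrow(x$state_table)
  ))
  cat(sprintf(
    "  EM: %d iterations (converged: %s), estimated match proportion p = %.4g\n",
    x$em$iterations, x$em$converged, x$em$p
  ))
  cat(sprintf(
    "  chosen threshold %.4f -> %s matched pairs\n",
    x$threshold, format(nrow(x$matches), big.mark = ",")
  ))
  if (!is.null(x$evaluation)) {
    ev <- x$evaluation
    cat(sprintf(
      "  at threshold: precision %.4f, recall %.4f, F %.4f | best achievable F %.4f\n",
      ev$precision, ev$recall, ev$fmeasure, max(x$actual_curve$fmeasure)
    ))
  }
  invisible(x)
}
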
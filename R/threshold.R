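#' Enumerate the full field-state space
#'
#' All `3^n` agree/disagree/missing combinations over the linkage fields,
#' with the observed counts carried over from the tabulated table (zero for
#' combinations never observed) and `recall_j` / `fpr_j` computed under the
#' supplied parameter set. Unseen combinations still receive non-zero
#' recall/fpr, which is what lets the predicted quality curve cover score
#' regions the blocked data never produced.
#'
#' @param table a `field_state_table` of observed combinations.
#' @param params the adopted `parameter_set`.
#' @param max_fields capacity guard: `3^n` rows are materialised, so more
#'   than 12 fields is refused.
#' @return an object of class `full_state_space`: data.frame with one row
#'   per combination (`count`, `recall`, `fpr`, `weight`) and the state
#'   matrix as an attribute.
#' @export
enumerate_full_space <- function(table, params, max_fields = 12L) {
  fields <- attr(table, "fields") %||% setdiff(names(table), "count")
  nf <- length(fields)
  if (nf > max_fields) {
    stop(sprintf(
      "%d fields would enumerate 3^%d = %.3g combinations; raise `max_fields` only if you mean it",
      nf, nf, 3^nf
    ), call. = FALSE)
  }
  codes <- 0:(3^nf - 1)
  states <- code_to_states(codes, nf)
  colnames(states) <- fields
  counts <- numeric(length(codes))
  obs_states <- table_states_matrix(table)
  obs_codes <- state_codes(obs_states)
  counts[obs_codes + 1L] <- table$count
  recall <- state_products(states, params$m, 1 - params$m - params$mm, params$mm)
  fpr <- state_products(states, params$u, 1 - params$u - params$um, params$um)
  w <- weight_set(params)
  weight <- combination_weights_matrix(states, w)
  out <- data.frame(count = counts, recall = recall, fpr = fpr, weight = weight)
  structure(out,
    states = states, fields = fields, params = params,
    class = c("full_state_space", "data.frame")
  )
}

#' @export
print.full_state_space <- function(x, ...) {
  cat(sprintf(
    "<full_state_space> %d combinations over %d fields (sum recall = %.6f, sum fpr = %.6f)\n",
    nrow(x), length(attr(x, "fields")), sum(x$recall), sum(x$fpr)
  ))
  invisible(x)
}

combination_weights_matrix <- function(states, weights) {
  out <- numeric(nrow(states))
  for (f in seq_len(ncol(states))) {
    st <- states[, f]
    out <- out + ifelse(st == 0L, weights$w_agree[f],
      ifelse(st == 1L, weights$w_disagree[f], 0)
    )
  }
  out
}

#' Weight of a single field-state combination
#'
#' Sum over fields of the agreement weight for agreements, the disagreement
#' weight for disagreements, and zero for missing.
#'
#' @param combination character states (`agree`/`disagree`/`missing`) or
#'   integer codes 0/1/2, one per field.
#' @param weights per-field weight table (`field`, `w_agree`, `w_disagree`).
#' @return numeric scalar.
#' @export
combination_weight <- function(combination, weights) {
  st <- combination_as_codes(combination, weights$field)
  combination_weights_matrix(matrix(st, nrow = 1), weights)
}

#' Estimated totals of true and false matches
#'
#' The total true matches is the posterior match mass of the final EM
#' expectation, `sum_j p_j c_j`; the total comparison space of a single-file
#' de-duplication is `N (N - 1) / 2`; false matches are re-estimated as the
#' comparison space less the true matches.
#'
#' @param table a `field_state_table`.
#' @param stats an [em_expectation()] result for `table` (column `p_j`).
#' @param n_records number of records `N` in the dataset.
#' @return list with `true_matches`, `false_matches`, `total_comparisons`.
#' @export
estimate_match_totals <- function(table, stats, n_records) {
  stopifnot(n_records >= 2)
  tm <- sum(stats$p_j * table$count)
  total <- n_records * (n_records - 1) / 2
  if (tm > total) {
    stop("estimated true matches exceed the comparison space", call. = FALSE)
  }
  list(true_matches = tm, false_matches = total - tm, total_comparisons = total)
}

#' Predicted linkage quality at every candidate threshold
#'
#' Apportions the estimated totals over the full state space —
#' `TP_j = true_matches * recall_j`, `FP_j = false_matches * fpr_j` — and,
#' for every candidate threshold `t`, sums the mass of combinations with
#' weight `>= t` to obtain estimated TP and FP, hence precision
#' (`TP / (TP + FP)`), recall (`TP / true_matches`) and F-measure. Candidate
#' thresholds are the distinct combination weights by default;
#' `integer_thresholds = TRUE` uses the whole numbers spanning the weight
#' range instead (a coarser grid that reproduces whole-number threshold
#' reporting).
#'
#' @param space a `full_state_space`.
#' @param totals output of [estimate_match_totals()].
#' @param integer_thresholds logical.
#' @return an object of class `quality_curve`: data.frame
#'   (`threshold`, `est_tp`, `est_fp`, `precision`, `recall`, `fmeasure`)
#'   sorted by increasing threshold, with `chosen_threshold` and the totals
#'   as attributes.
#' @export
quality_curve <- function(space, totals, integer_thresholds = FALSE) {
  stopifnot(inherits(space, "full_state_space"))
  if (totals$true_matches <= 0) {
    stop("estimated true matches is zero: quality curve undefined", call. = FALSE)
  }
  tp_j <- totals$true_matches * space$recall
  fp_j <- totals$false_matches * space$fpr
  ord <- order(space$weight, decreasing = TRUE)
  w_sorted <- space$weight[ord]
  ctp <- cumsum(tp_j[ord])
  cfp <- cumsum(fp_j[ord])
  if (integer_thresholds) {
    thresholds <- seq(floor(min(w_sorted)), ceiling(max(w_sorted)))
  } else {
    thresholds <- sort(unique(w_sorted))
  }
  # number of combinations with weight >= t (w_sorted is decreasing)
  n_ge <- length(w_sorted) - findInterval(thresholds - 1e-12, rev(w_sorted))
  est_tp <- ifelse(n_ge > 0, ctp[pmax(n_ge, 1)], 0)
  est_fp <- ifelse(n_ge > 0, cfp[pmax(n_ge, 1)], 0)
  est_tp[n_ge == 0] <- 0
  est_fp[n_ge == 0] <- 0
  precision <- ifelse(est_tp + est_fp > 0, est_tp / (est_tp + est_fp), 1)
  recall <- est_tp / totals$true_matches
  fmeasure <- ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
  out <- data.frame(
    threshold = thresholds, est_tp = est_tp, est_fp = est_fp,
    precision = precision, recall = recall, fmeasure = fmeasure
  )
  chosen <- out$threshold[which.max(out$fmeasure)]
  ties <- out$threshold[out$fmeasure >= max(out$fmeasure) - 1e-12]
  chosen <- min(ties)
  structure(out,
    chosen_threshold = chosen,
    true_matches = totals$true_matches,
    false_matches = totals$false_matches,
    total_comparisons = totals$total_comparisons,
    class = c("quality_curve", "data.frame")
  )
}

#' @export
print.quality_curve <- function(x, ...) {
  ch <- attr(x, "chosen_threshold")
  at <- x[which.min(abs(x$threshold - ch)), ]
  cat(sprintf(
    "<quality_curve> %d thresholds; chosen %.4f (est precision %.4f, recall %.4f, F %.4f)\n",
    nrow(x), ch, at$precision, at$recall, at$fmeasure
  ))
  cat(sprintf(
    "  estimated true matches %.1f of %s comparisons\n",
    attr(x, "true_matches"), format(attr(x, "total_comparisons"), big.mark = ",")
  ))
  invisible(x)
}

#' Select the optimal threshold from a quality curve
#'
#' The smallest candidate threshold attaining the maximal estimated
#' F-measure (ties break toward the smaller threshold, i.e. toward recall).
#'
#' @param curve a `quality_curve`.
#' @return numeric threshold.
#' @export
select_threshold <- function(curve) {
  stopifnot(inherits(curve, "quality_curve"), nrow(curve) > 0)
  fmax <- max(curve$fmeasure)
  min(curve$threshold[curve$fmeasure >= fmax - 1e-12])
}

#' Write a quality curve as CSV plus a JSON summary
#'
#' @param curve a `quality_curve`.
#' @param path CSV path; the summary is written to `<path>.json`.
#' @export
write_quality_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      chosen_threshold = attr(curve, "chosen_threshold"),
      true_matches = attr(curve, "true_matches"),
      false_matches = attr(curve, "false_matches"),
      total_comparisons = attr(curve, "total_comparisons")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
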
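pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' All true (same-entity) record pairs of a truth file
#'
#' Enumerated per entity — `sum_e k_e (k_e - 1) / 2` pairs — never
#' materialising the full pairwise space.
#'
#' @param truth `data.frame(record_id, entity_id)`.
#' @return `data.table(id_a, id_b)` with `id_a < id_b`.
#' @export
true_pairs <- function(truth) {
  dt <- data.table::as.data.table(truth)[!is.na(entity_id) & entity_id != ""]
  dt <- dt[, if (.N > 1) {
    idx <- utils::combn(sort(record_id), 2)
    list(id_a = idx[1, ], id_b = idx[2, ])
  }, by = entity_id][, .(id_a, id_b)]
  dt
}

#' Evaluate linkage output against a truth set
#'
#' The true-pair set is all unordered same-entity pairs in the truth file,
#' so pairs a blocking strategy never produced still count as false
#' negatives.
#'
#' @param matches data.frame with `id_a`, `id_b` (order within a pair does
#'   not matter).
#' @param truth `data.frame(record_id, entity_id)`.
#' @return list of class `evaluation_report` with `true_positives`,
#'   `false_positives`, `false_negatives`, `precision`, `recall`,
#'   `fmeasure`.
#' @export
evaluate_linkage <- function(matches, truth) {
  known <- unique(truth$record_id)
  ids <- unique(c(matches$id_a, matches$id_b))
  unknown <- setdiff(ids, known)
  if (length(unknown)) {
    stop(
      "matched record_id(s) absent from truth: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }
  tp_keys <- pair_key(true_pairs(truth)$id_a, true_pairs(truth)$id_b)
  match_keys <- unique(pair_key(matches$id_a, matches$id_b))
  tp <- sum(match_keys %in% tp_keys)
  fp <- length(match_keys) - tp
  fn <- length(tp_keys) - tp
  new_evaluation_report(tp, fp, fn)
}

new_evaluation_report <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 1
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  fmeasure <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(
    list(
      true_positives = tp, false_positives = fp, false_negatives = fn,
      precision = precision, recall = recall, fmeasure = fmeasure
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> TP %d, FP %d, FN %d | precision %.4f, recall %.4f, F %.4f\n",
    x$true_positives, x$false_positives, x$false_negatives,
    x$precision, x$recall, x$fmeasure
  ))
  invisible(x)
}

#' Actual quality at every observed score threshold
#'
#' Given scored candidate pairs and the truth set, computes the realised
#' precision/recall/F-measure when the threshold is set at each distinct
#' score (pairs with score >= threshold are matches). False negatives
#' include true pairs that blocking never produced.
#'
#' @param scores numeric vector of candidate-pair scores.
#' @param is_true logical vector: is the candidate pair a true pair?
#' @param n_true_total total number of true pairs in the dataset.
#' @return data.frame (`threshold`, `tp`, `fp`, `precision`, `recall`,
#'   `fmeasure`), thresholds increasing.
#' @export
actual_quality_curve <- function(scores, is_true, n_true_total) {
  stopifnot(length(scores) == length(is_true))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- is_true[ord]
  ctp <- cumsum(t)
  cfp <- cumsum(!t)
  # last index of each distinct score block = all pairs with score >= s
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- ctp[last]
  fp <- cfp[last]
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  recall <- if (n_true_total > 0) tp / n_true_total else rep(1, length(tp))
  fmeasure <- ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
  out <- data.frame(
    threshold = s[last], tp = tp, fp = fp,
    precision = precision, recall = recall, fmeasure = fmeasure
  )
  out[order(out$threshold), , drop = FALSE]
}

#' Root-mean-square error between estimated and actual values
#'
#' @param estimated,actual equal-length numeric vectors.
#' @return `sqrt(mean((estimated - actual)^2))`.
#' @export
rmse <- function(estimated, actual) {
  if (length(estimated) != length(actual) || length(estimated) == 0) {
    stop("`estimated` and `actual` must have equal non-zero length", call. = FALSE)
  }
  sqrt(mean((estimated - actual)^2))
}

#' Discriminating power (entropy) of a field
#'
#' Shannon entropy, base 2, of the empirical value distribution over
#' non-missing values: how many bits of identifying information the field
#' carries.
#'
#' @param values vector of field values; `NA`/empty are excluded.
#' @return entropy in bits.
#' @export
discriminating_power <- function(values) {
  v <- values[!is.na(values) & values != ""]
  if (length(v) == 0) {
    stop("all values missing: discriminating power undefined", call. = FALSE)
  }
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

#' Profile the linkage fields of a dataset
#'
#' @param dataset person-record data.frame.
#' @return data.frame with per-field `unique_values` (distinct non-missing),
#'   `missing_pct` and `discriminating_power` (bits).
#' @export
profile_dataset <- function(dataset) {
  res <- lapply(LINKAGE_FIELDS, function(f) {
    v <- dataset[[f]]
    miss <- is.na(v) | v == ""
    data.frame(
      field = f,
      unique_values = length(unique(v[!miss])),
      missing_pct = 100 * mean(miss),
      discriminating_power = if (all(miss)) NA_real_ else discriminating_power(v)
    )
  })
  do.call(rbind, res)
}

#' Simple random sample of a dataset
#'
#' Draws `floor(fraction * N)` records without replacement; `fraction = 1`
#' returns the dataset unchanged (order preserved). Deterministic given the
#' seed.
#'
#' @param dataset data.frame.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return data.frame subset.
#' @export
sample_dataset <- function(dataset, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) {
    return(dataset)
  }
  n <- nrow(dataset)
  k <- floor(fraction * n)
  with_seed(seed, {
    idx <- sort(sample.int(n, k))
    out <- dataset[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
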
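STATE_LEVELS <- c("agree", "disagree", "missing")

# states matrix (0/1/2) -> combination code (base 3, first field least
# significant); works for up to 19 fields within double precision
state_codes <- function(states) {
  as.vector(states %*% 3^(seq_len(ncol(states)) - 1))
}

code_to_states <- function(codes, n_fields) {
  m <- matrix(0L, nrow = length(codes), ncol = n_fields)
  rest <- codes
  for (f in seq_len(n_fields)) {
    m[, f] <- as.integer(rest %% 3)
    rest <- rest %/% 3
  }
  m
}

new_field_state_table <- function(states, count, fields) {
  colnames(states) <- fields
  df <- as.data.frame(matrix(STATE_LEVELS[states + 1L],
    ncol = length(fields),
    dimnames = list(NULL, fields)
  ), stringsAsFactors = FALSE)
  df$count <- as.numeric(count)
  structure(df,
    states = states, fields = fields,
    class = c("field_state_table", "data.frame")
  )
}

#' @export
print.field_state_table <- function(x, ...) {
  cat(sprintf(
    "<field_state_table> %d combinations over %d fields, %s pairs\n",
    nrow(x), length(attr(x, "fields")), format(sum(x$count), big.mark = ",")
  ))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Tabulate field-state combinations over candidate pairs
#'
#' Counts, for every observed combination of per-field states
#' (agree/disagree/missing), how many candidate pairs fall in it. This table
#' is the sufficient statistic for the EM parameter estimation.
#'
#' @param comparisons a `pair_comparisons` object, or a list of state-code /
#'   count accumulators (internal use).
#' @return a `field_state_table`: one row per observed combination with a
#'   `count` column; counts sum to the number of pairs tabulated.
#' @export
tabulate_states <- function(comparisons) {
  stopifnot(inherits(comparisons, "pair_comparisons"))
  if (length(comparisons$ia) == 0) {
    stop("zero candidate pairs: nothing to tabulate", call. = FALSE)
  }
  fields <- colnames(comparisons$states)
  codes <- state_codes(comparisons$states)
  tab <- table_codes(codes, length(fields))
  new_field_state_table(code_to_states(tab$code, length(fields)), tab$count, fields)
}

table_codes <- function(codes, n_fields) {
  counts <- tabulate(codes + 1L, nbins = 3^n_fields)
  nz <- which(counts > 0L)
  list(code = nz - 1L, count = counts[nz])
}

#' Construct a parameter set for the extended Fellegi-Sunter model
#'
#' Per field: `m` (agreement probability among true matches), `u` (agreement
#' probability among non-matches), and the missing-state analogues `mm`,
#' `um`; globally `p`, the proportion of candidate pairs that are true
#' matches. The per-field disagreement probabilities are the complements
#' `1 - m - mm` and `1 - u - um`.
#'
#' @param fields character vector of field names.
#' @param m,u,mm,um numeric vectors (recycled) of per-field probabilities.
#' @param p global match proportion in (0, 1).
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(fields, m = 0.8, u = 0.1, mm = 0.1, um = 0.1,
                          p = 0.01) {
  nf <- length(fields)
  ps <- list(
    fields = fields,
    m = stats::setNames(rep_len(m, nf), fields),
    u = stats::setNames(rep_len(u, nf), fields),
    mm = stats::setNames(rep_len(mm, nf), fields),
    um = stats::setNames(rep_len(um, nf), fields),
    p = p, iterations = 0L, converged = NA, loglik = numeric(0)
  )
  validate_parameter_set(ps)
  structure(ps, class = "parameter_set")
}

validate_parameter_set <- function(ps) {
  probs <- c(ps$m, ps$u, ps$mm, ps$um, ps$p)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(ps$m + ps$mm > 1 + 1e-9) || any(ps$u + ps$um > 1 + 1e-9)) {
    stop("m + mm and u + um must not exceed 1", call. = FALSE)
  }
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set> p = %.4g, %d iterations, converged: %s\n",
    x$p, x$iterations, x$converged
  ))
  df <- data.frame(
    field = x$fields, m = x$m, u = signif(x$u, 4),
    mm = signif(x$mm, 4), um = signif(x$um, 4), row.names = NULL
  )
  print(df)
  invisible(x)
}

# per-combination products: states J x n (0/1/2), agree/disagree/missing
# probabilities per field
state_products <- function(states, pa, pd, pm) {
  out <- rep(1, nrow(states))
  for (f in seq_len(ncol(states))) {
    st <- states[, f]
    out <- out * ifelse(st == 0L, pa[f], ifelse(st == 1L, pd[f], pm[f]))
  }
  out
}

#' Recall and false-positive rate of one field-state combination
#'
#' `recall_j` is the probability that a true match presents this combination:
#' the product over fields of `m` for agreements, `1 - m - mm` for
#' disagreements, `mm` for missing. `fpr_j` is the analogous product for
#' non-matches using `u`, `um`.
#'
#' @param combination character vector of states (`agree`, `disagree`,
#'   `missing`), one per field, or an integer vector coded 0/1/2.
#' @param params a `parameter_set`.
#' @return named numeric vector `c(recall, fpr)`.
#' @export
combination_recall_fpr <- function(combination, params) {
  st <- combination_as_codes(combination, params$fields)
  states <- matrix(st, nrow = 1)
  c(
    recall = state_products(states, params$m, 1 - params$m - params$mm, params$mm),
    fpr = state_products(states, params$u, 1 - params$u - params$um, params$um)
  )
}

combination_as_codes <- function(combination, fields) {
  if (is.character(combination)) {
    st <- match(combination, STATE_LEVELS) - 1L
    if (anyNA(st)) stop("states must be agree/disagree/missing", call. = FALSE)
  } else {
    st <- as.integer(combination)
  }
  if (length(st) != length(fields)) {
    stop("combination length must equal the number of fields", call. = FALSE)
  }
  st
}

table_states_matrix <- function(table) {
  st <- attr(table, "states")
  if (is.null(st)) {
    fields <- setdiff(names(table), "count")
    st <- vapply(fields, function(f) match(table[[f]], STATE_LEVELS) - 1L,
      integer(nrow(table))
    )
    st <- matrix(st, nrow = nrow(table), dimnames = list(NULL, fields))
  }
  st
}

#' EM expectation step
#'
#' Computes, for every combination in the table, the posterior probability
#' that a pair presenting it is a true match:
#' `p_j = p recall_j / (p recall_j + (1 - p) fpr_j)`.
#'
#' @param table a `field_state_table`.
#' @param params a `parameter_set`.
#' @return data.frame with `recall`, `fpr`, `p_j` per combination (row order
#'   of `table`).
#' @export
em_expectation <- function(table, params) {
  states <- table_states_matrix(table)
  recall <- state_products(states, params$m, 1 - params$m - params$mm, params$mm)
  fpr <- state_products(states, params$u, 1 - params$u - params$um, params$um)
  num <- params$p * recall
  den <- num + (1 - params$p) * fpr
  p_j <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    warning("zero-likelihood combination(s): posterior set to 0", call. = FALSE)
  }
  data.frame(recall = recall, fpr = fpr, p_j = p_j)
}

#' EM maximisation step
#'
#' Re-estimates every parameter from the posterior match probabilities:
#' `m_f` is the match mass on combinations where field `f` agrees divided by
#' the total match mass (and `mm_f` likewise for the missing state); `u_f`,
#' `um_f` use the non-match mass; `p` is the match mass over all pairs.
#'
#' @param table a `field_state_table`.
#' @param stats output of [em_expectation()] (needs column `p_j`).
#' @return an updated `parameter_set`.
#' @export
em_maximisation <- function(table, stats) {
  states <- table_states_matrix(table)
  fields <- colnames(states)
  cj <- table$count
  pj <- stats$p_j
  match_mass <- sum(pj * cj)
  nonmatch_mass <- sum((1 - pj) * cj)
  if (match_mass <= 0 || nonmatch_mass <= 0) {
    stop("degenerate fit: all posterior probabilities are 0 or 1", call. = FALSE)
  }
  nf <- length(fields)
  m <- u <- mm <- um <- numeric(nf)
  for (f in seq_len(nf)) {
    ag <- states[, f] == 0L
    mi <- states[, f] == 2L
    m[f] <- sum(pj[ag] * cj[ag]) / match_mass
    mm[f] <- sum(pj[mi] * cj[mi]) / match_mass
    u[f] <- sum((1 - pj[ag]) * cj[ag]) / nonmatch_mass
    um[f] <- sum((1 - pj[mi]) * cj[mi]) / nonmatch_mass
  }
  ps <- structure(
    list(
      fields = fields,
      m = stats::setNames(m, fields), u = stats::setNames(u, fields),
      mm = stats::setNames(mm, fields), um = stats::setNames(um, fields),
      p = match_mass / sum(cj), iterations = 0L, converged = NA,
      loglik = numeric(0)
    ),
    class = "parameter_set"
  )
  clip_parameter_set(ps)
}

# clip to [eps, 1-eps] to prevent infinite weights on separable data, then
# restore m+mm <= 1 (and u+um <= 1) if clipping broke it
clip_parameter_set <- function(ps, eps = 1e-6) {
  cl <- function(x) pmin(pmax(x, eps), 1 - eps)
  ps$m <- cl(ps$m)
  ps$u <- cl(ps$u)
  ps$mm <- cl(ps$mm)
  ps$um <- cl(ps$um)
  ps$p <- min(max(ps$p, eps), 1 - eps)
  sm <- ps$m + ps$mm
  over <- sm > 1 - eps
  if (any(over)) {
    sc <- (1 - eps) / sm[over]
    ps$m[over] <- ps$m[over] * sc
    ps$mm[over] <- ps$mm[over] * sc
  }
  su <- ps$u + ps$um
  over <- su > 1 - eps
  if (any(over)) {
    sc <- (1 - eps) / su[over]
    ps$u[over] <- ps$u[over] * sc
    ps$um[over] <- ps$um[over] * sc
  }
  ps
}

observed_loglik <- function(table, params) {
  states <- table_states_matrix(table)
  recall <- state_products(states, params$m, 1 - params$m - params$mm, params$mm)
  fpr <- state_products(states, params$u, 1 - params$u - params$um, params$um)
  lik <- params$p * recall + (1 - params$p) * fpr
  sum(table$count * log(pmax(lik, .Machine$double.xmin)))
}

#' Fit the extended Fellegi-Sunter model by EM
#'
#' Alternates [em_expectation()] and [em_maximisation()] from the given
#' starting values until the largest absolute parameter change falls below
#' `tol` or `max_iter` is reached. The default starting values are `m = 0.8`,
#' `u = 0.1`, `mm = um = 0.1` (with `p = 0.01`). The observed-data
#' log-likelihood of every iteration is recorded in the result's `loglik`
#' element.
#'
#' @param table a `field_state_table`.
#' @param init starting `parameter_set`; defaults to the values above.
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_iter iteration cap.
#' @return a `parameter_set` with `iterations`, `converged` and `loglik`
#'   filled in.
#' @export
run_em <- function(table, init = NULL, tol = 1e-6, max_iter = 1000L) {
  fields <- attr(table, "fields") %||% setdiff(names(table), "count")
  if (is.null(init)) init <- parameter_set(fields)
  validate_parameter_set(init)
  params <- clip_parameter_set(init)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    stats <- em_expectation(table, params)
    new <- em_maximisation(table, stats)
    ll <- c(ll, observed_loglik(table, new))
    delta <- max(abs(c(
      new$m - params$m, new$u - params$u, new$mm - params$mm,
      new$um - params$um, new$p - params$p
    )))
    params <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d iterations", max_iter), call. = FALSE)
  }
  params$iterations <- iter
  params$converged <- converged
  params$loglik <- ll
  params
}

#' Frequency-based u-probability estimates on unblocked data
#'
#' Jaro's estimator: for each field, the probability that two randomly drawn
#' records agree is `sum_v c_v (c_v - 1) / (N_f (N_f - 1))` over the value
#' counts `c_v` of the `N_f` records non-missing on the field. The missing
#' u-probability is the unordered-pair probability that at least one of the
#' two values is missing: `um = 1 - N_f (N_f - 1) / (N (N - 1))`. Because it
#' uses all record pairs — not just blocked ones — this estimator avoids the
#' upward bias that blocking induces in EM's u estimates.
#'
#' For Bloom-encoded fields agreement is counted as exact filter equality
#' (identical plaintext implies identical filter), which slightly
#' underestimates u relative to near-match agreement.
#'
#' @param encoded an `encoded_dataset`.
#' @return data.frame with per-field `u` (conditional on both values
#'   present), `um`, and `n_nonmissing`; fields that are entirely missing get
#'   `NA` and a warning.
#' @export
estimate_u_frequencies <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  n <- encoded$n
  if (n < 2) stop("need at least 2 records", call. = FALSE)
  scheme <- encoded$scheme
  res <- lapply(seq_len(nrow(scheme)), function(i) {
    f <- scheme$field[i]
    enc <- encoded$fields[[f]]
    vals <- if (enc$type == "bloom") {
      cpp_column_hash(enc$bits, enc$missing)
    } else {
      enc$token
    }
    nm <- sum(!is.na(vals))
    if (nm < 2) {
      warning(sprintf("field '%s' is (almost) entirely missing: u undefined", f),
        call. = FALSE
      )
      return(data.frame(field = f, u = NA_real_, um = NA_real_, n_nonmissing = nm))
    }
    cv <- table(vals[!is.na(vals)])
    u <- sum(cv * (cv - 1)) / (nm * (nm - 1))
    um <- 1 - (nm * (nm - 1)) / (n * (n - 1))
    data.frame(field = f, u = u, um = um, n_nonmissing = nm)
  })
  do.call(rbind, res)
}

#' Agreement and disagreement weights from m and u
#'
#' `w_agree = log2(m / u)`, `w_disagree = log2((1 - m) / (1 - u))`. Base-2
#' logs put the weights on the entropy (bits) scale. Inputs are clipped to
#' `[1e-6, 1 - 1e-6]` with a warning, so separable fields yield large but
#' finite weights.
#'
#' @param m,u numeric vectors of probabilities.
#' @return data.frame with `w_agree`, `w_disagree` (plus `field` names if
#'   `m` is named).
#' @export
weights_from_parameters <- function(m, u) {
  eps <- 1e-6
  if (any(m <= eps | m >= 1 - eps | u <= eps | u >= 1 - eps, na.rm = TRUE)) {
    warning("m or u at clip boundary: weight saturated", call. = FALSE)
  }
  mc <- pmin(pmax(m, eps), 1 - eps)
  uc <- pmin(pmax(u, eps), 1 - eps)
  out <- data.frame(
    w_agree = log2(mc / uc),
    w_disagree = log2((1 - mc) / (1 - uc))
  )
  if (!is.null(names(m))) out <- cbind(field = names(m), out)
  out
}

#' Per-field weight table of a parameter set
#'
#' @param params a `parameter_set`.
#' @return data.frame with `field`, `w_agree`, `w_disagree`.
#' @export
weight_set <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  weights_from_parameters(params$m, params$u)
}

#' Adopt final linkage parameters: EM m with frequency-based u
#'
#' The EM fit runs on blocked candidate pairs, where non-matches are heavily
#' under-represented, so its u estimates are biased upward. The adopted
#' parameter set keeps EM's `m`/`mm` and global `p` but replaces `u`/`um`
#' with the unblocked frequency-based estimates. The conditional agreement
#' probability returned by [estimate_u_frequencies()] is rescaled by
#' `(1 - um)` so that agree/disagree/missing probabilities form a proper
#' trinary distribution, matching the EM model's unconditional convention.
#'
#' @param em_params `parameter_set` from [run_em()].
#' @param u_freq data.frame from [estimate_u_frequencies()].
#' @return a `parameter_set` to be used for weights, scoring and threshold
#'   estimation.
#' @export
adopt_parameters <- function(em_params, u_freq) {
  stopifnot(inherits(em_params, "parameter_set"))
  idx <- match(em_params$fields, u_freq$field)
  if (anyNA(idx)) stop("u_freq lacks some fields", call. = FALSE)
  u <- u_freq$u[idx]
  um <- u_freq$um[idx]
  keep <- is.na(u)
  u_uncond <- u * (1 - um)
  out <- em_params
  out$u <- stats::setNames(ifelse(keep, em_params$u, u_uncond), em_params$fields)
  out$um <- stats::setNames(ifelse(keep, em_params$um, um), em_params$fields)
  clip_parameter_set(out)
}

#' Write / read a parameter set as JSON
#'
#' @param params a `parameter_set`.
#' @param path JSON path.
#' @name parameters_json
#' @return `read_parameters_json()` returns a `parameter_set`.
#' @export
write_parameters_json <- function(params, path) {
  w <- weight_set(params)
  obj <- list(
    fields = lapply(stats::setNames(seq_along(params$fields), params$fields), function(i) {
      list(
        m = params$m[[i]], u = params$u[[i]], mm = params$mm[[i]],
        um = params$um[[i]], w_agree = w$w_agree[i], w_disagree = w$w_disagree[i]
      )
    }),
    p = params$p, iterations = params$iterations, converged = params$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname parameters_json
#' @export
read_parameters_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fields <- names(obj$fields)
  g <- function(nm) vapply(obj$fields, function(x) x[[nm]], numeric(1))
  ps <- parameter_set(fields,
    m = g("m"), u = g("u"), mm = g("mm"), um = g("um"),
    p = obj$p
  )
  ps$iterations <- obj$iterations
  ps$converged <- obj$converged
  ps
}
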
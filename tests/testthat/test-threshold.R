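test_that("the full state space enumerates 3^n combinations with unit mass", {
  tab2 <- state_table(rbind(c(0L, 0L)), 5)
  ps2 <- parameter_set(c("f1", "f2"), m = 0.9, u = 0.1, mm = 0.05, um = 0.05, p = 0.1)
  sp2 <- enumerate_full_space(tab2, ps2)
  expect_equal(nrow(sp2), 9)
  expect_equal(sum(sp2$recall), 1, tolerance = 1e-9)
  expect_equal(sum(sp2$fpr), 1, tolerance = 1e-9)
  expect_equal(sum(sp2$count), 5)

  ps4 <- parameter_set(paste0("f", 1:4), m = 0.9, u = 0.1, mm = 0.05, um = 0.05)
  sp4 <- enumerate_full_space(state_table(rbind(rep(0L, 4)), 1, paste0("f", 1:4)), ps4)
  expect_equal(nrow(sp4), 81)
  expect_equal(sum(sp4$recall), 1, tolerance = 1e-9)
  expect_equal(sum(sp4$fpr), 1, tolerance = 1e-9)

  # unseen combinations carry zero count but positive recall/fpr
  unseen <- sp2[sp2$count == 0, ]
  expect_equal(nrow(unseen), 8)
  expect_true(all(unseen$recall > 0))
  expect_true(all(unseen$fpr > 0))

  expect_error(
    enumerate_full_space(
      state_table(matrix(0L, 1, 13), 1, paste0("f", 1:13)),
      parameter_set(paste0("f", 1:13))
    ),
    "3\\^13"
  )
})

test_that("combination weights sum agreement, disagreement and zero", {
  w <- data.frame(field = c("f1", "f2"), w_agree = c(3, 4), w_disagree = c(-2, -5))
  expect_equal(combination_weight(c("missing", "missing"), w), 0)
  expect_equal(combination_weight(c("agree", "agree"), w), 7)
  expect_equal(combination_weight(c("agree", "missing"), w), 3)
  expect_equal(combination_weight(c("disagree", "agree"), w), 2)
})

test_that("match totals derive from the posterior mass and comparison space", {
  tab <- state_table(rbind(c(0L, 0L), c(1L, 1L)), c(3, 7))
  stats <- data.frame(p_j = c(0.8, 0.1))
  tot <- estimate_match_totals(tab, stats, n_records = 1000)
  expect_equal(tot$total_comparisons, 499500)
  expect_equal(tot$true_matches, 0.8 * 3 + 0.1 * 7)
  expect_equal(tot$false_matches, 499500 - tot$true_matches)

  one_pair <- state_table(rbind(c(0L, 0L)), 1)
  expect_equal(
    estimate_match_totals(one_pair, data.frame(p_j = 0.6), 2)$total_comparisons,
    1
  )

  zero <- estimate_match_totals(tab, data.frame(p_j = c(0, 0)), 100)
  expect_equal(zero$true_matches, 0)
  expect_equal(zero$false_matches, zero$total_comparisons)
  expect_error(quality_curve(
    enumerate_full_space(tab, parameter_set(c("f1", "f2"))), zero
  ), "undefined")
  expect_error(estimate_match_totals(tab, data.frame(p_j = c(1, 1)), 2), "exceed")
})

test_that("the quality curve matches a brute-force oracle on a 2-field space", {
  m <- c(0.9, 0.9)
  u <- c(0.1, 0.1)
  mm <- um <- c(0.05, 0.05)
  tm_tot <- 100
  fm_tot <- 9900

  # --- independent oracle: explicit enumeration of all 9 combinations ---
  wa <- log2(m / u)
  wd <- log2((1 - m) / (1 - u))
  oracle <- expand.grid(s1 = 0:2, s2 = 0:2)
  prob3 <- function(s, mv, mmv) {
    if (s == 0) mv else if (s == 1) 1 - mv - mmv else mmv
  }
  oracle$recall <- mapply(
    function(s1, s2) prob3(s1, m[1], mm[1]) * prob3(s2, m[2], mm[2]),
    oracle$s1, oracle$s2
  )
  oracle$fpr <- mapply(
    function(s1, s2) prob3(s1, u[1], um[1]) * prob3(s2, u[2], um[2]),
    oracle$s1, oracle$s2
  )
  wof <- function(s, i) if (s == 0) wa[i] else if (s == 1) wd[i] else 0
  oracle$weight <- mapply(
    function(s1, s2) wof(s1, 1) + wof(s2, 2),
    oracle$s1, oracle$s2
  )
  thresholds <- sort(unique(oracle$weight))
  oracle_curve <- do.call(rbind, lapply(thresholds, function(t) {
    # same tie tolerance as the package: with symmetric m and u the
    # (agree, disagree) weight is mathematically exactly zero, but floating
    # point leaves it a few ulp off
    sel <- oracle$weight >= t - 1e-9
    tp <- tm_tot * sum(oracle$recall[sel])
    fp <- fm_tot * sum(oracle$fpr[sel])
    pr <- tp / (tp + fp)
    rc <- tp / tm_tot
    data.frame(
      threshold = t, est_tp = tp, est_fp = fp, precision = pr,
      recall = rc, fmeasure = 2 * pr * rc / (pr + rc)
    )
  }))

  # --- package route ---
  ps <- parameter_set(c("f1", "f2"), m = m, u = u, mm = mm, um = um, p = 0.5)
  tab <- state_table(rbind(c(0L, 0L)), 1, c("f1", "f2"))
  space <- enumerate_full_space(tab, ps)
  curve <- quality_curve(space, list(
    true_matches = tm_tot, false_matches = fm_tot,
    total_comparisons = tm_tot + fm_tot
  ))

  expect_equal(curve$threshold, oracle_curve$threshold, tolerance = 1e-12)
  expect_equal(curve$est_tp, oracle_curve$est_tp, tolerance = 1e-9)
  expect_equal(curve$est_fp, oracle_curve$est_fp, tolerance = 1e-9)
  expect_equal(curve$precision, oracle_curve$precision, tolerance = 1e-9)
  expect_equal(curve$recall, oracle_curve$recall, tolerance = 1e-9)
  expect_equal(curve$fmeasure, oracle_curve$fmeasure, tolerance = 1e-9)

  # the chosen threshold maximises the oracle's F-measure too
  expect_equal(
    select_threshold(curve),
    min(oracle_curve$threshold[oracle_curve$fmeasure >= max(oracle_curve$fmeasure) - 1e-12])
  )
})

test_that("curve endpoints and monotonicity behave as predicted", {
  tab <- simulate_state_table(
    m = c(0.9, 0.85, 0.95), u = c(0.05, 0.1, 0.02), mm = rep(0.03, 3),
    um = rep(0.03, 3), p = 0.1, n_pairs = 10000, seed = 91
  )
  fit <- run_em(tab)
  stats <- em_expectation(tab, fit)
  totals <- estimate_match_totals(tab, stats, n_records = 500)
  space <- enumerate_full_space(tab, fit)
  curve <- quality_curve(space, totals)

  # at the minimum weight all recall mass is included
  expect_equal(curve$recall[1], 1, tolerance = 1e-9)
  # recall and estimated FP never increase with the threshold
  expect_true(all(diff(curve$recall) <= 1e-12))
  expect_true(all(diff(curve$est_fp) <= 1e-12))
  # mass conservation at the lowest threshold
  expect_equal(curve$est_tp[1], attr(curve, "true_matches"), tolerance = 1e-9)
  expect_equal(curve$est_fp[1], attr(curve, "false_matches"), tolerance = 1e-9)

  # integer grid includes a point above the top weight: empty selection
  icurve <- quality_curve(space, totals, integer_thresholds = TRUE)
  top <- icurve[nrow(icurve), ]
  if (top$threshold > max(space$weight)) {
    expect_equal(top$est_tp, 0)
    expect_equal(top$precision, 1)
    expect_equal(top$fmeasure, 0)
  }
})

test_that("threshold selection breaks ties toward the smaller threshold", {
  fake <- structure(
    data.frame(
      threshold = c(1, 2, 3), est_tp = c(3, 2, 1), est_fp = c(1, 1, 1),
      precision = c(.75, .66, .5), recall = c(1, .66, .33),
      fmeasure = c(0.5, 0.5, 0.2)
    ),
    class = c("quality_curve", "data.frame")
  )
  expect_equal(select_threshold(fake), 1)
  single <- fake[2, ]
  class(single) <- c("quality_curve", "data.frame")
  expect_equal(select_threshold(single), 2)
})
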
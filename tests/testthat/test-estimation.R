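test_that("state tabulation conserves pair counts", {
  d <- small_dataset(150, seed = 51)
  dc <- corrupt_dataset(d, corruption_config(0.1, seed = 52))
  enc <- encode_dataset(dc, bloom_params(secret_key = test_key))
  pairs <- candidate_pairs(enc)
  cmp <- compare_pairs(enc, pairs)
  tab <- tabulate_states(cmp)
  expect_s3_class(tab, "field_state_table")
  expect_equal(sum(tab$count), nrow(pairs))
  expect_lte(nrow(tab), 3^10)
  expect_equal(anyDuplicated(tab[pprlink:::LINKAGE_FIELDS]), 0)

  # a single identical pair lands in the all-agree combination
  d1 <- rbind(person_row("A1"), person_row("A2"))
  e1 <- encode_dataset(d1, bloom_params(secret_key = test_key))
  c1 <- compare_pairs(e1, data.frame(ia = 1, ib = 2))
  t1 <- tabulate_states(c1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$count, 1)
  expect_true(all(t1[1, pprlink:::LINKAGE_FIELDS] == "agree"))
})

test_that("recall and fpr of a combination are trinary products", {
  ps <- parameter_set(c("f1", "f2"), m = 0.8, u = 0.1, mm = 0.1, um = 0.1)
  rf <- combination_recall_fpr(c("agree", "missing"), ps)
  expect_equal(unname(rf["recall"]), 0.8 * 0.1)
  expect_equal(unname(rf["fpr"]), 0.1 * 0.1)

  ps4 <- parameter_set(paste0("f", 1:4), m = 0.8, u = 0.1, mm = 0.1, um = 0.1)
  rf4 <- combination_recall_fpr(rep("missing", 4), ps4)
  expect_equal(unname(rf4["recall"]), 1e-4)

  ps3 <- parameter_set(paste0("f", 1:3), m = 0.8, u = 0.1, mm = 0.1, um = 0.1)
  rf3 <- combination_recall_fpr(rep("agree", 3), ps3)
  expect_equal(unname(rf3["fpr"]), 1e-3)
})

test_that("the expectation step computes the posterior match proportion", {
  # recall = fpr with p = 0.5 -> posterior 0.5
  tab <- state_table(matrix(c(0L, 1L), nrow = 1), 10, c("f1", "f2"))
  ps <- parameter_set(c("f1", "f2"), m = 0.5, u = 0.5, mm = 0.25, um = 0.25, p = 0.5)
  st <- em_expectation(tab, ps)
  expect_equal(st$p_j, 0.5)

  # direct evaluation: recall .08, fpr .01, p .5 -> 8/9
  tab2 <- state_table(matrix(c(0L, 2L), nrow = 1), 5, c("f1", "f2"))
  ps2 <- parameter_set(c("f1", "f2"), m = c(0.8, 0.5), mm = c(0.1, 0.1), u = c(0.1, 0.5), um = c(0.1, 0.1), p = 0.5)
  # recall = 0.8 * 0.1 = 0.08 ; fpr = 0.1 * 0.1 = 0.01
  expect_equal(em_expectation(tab2, ps2)$p_j, 8 / 9)

  # fpr 0, recall > 0 -> posterior 1 (clipping keeps fpr positive, so build
  # the limit explicitly through the formula guard)
  ps3 <- parameter_set(c("f1", "f2"), m = 0.8, u = 1e-6, mm = 0.1, um = 1e-6, p = 0.5)
  expect_gt(em_expectation(tab2, ps3)$p_j, 0.999)
})

test_that("the maximisation step reproduces hand-computed ratios", {
  # rows: (agree, agree) count 10 p_j .9 ; (disagree, agree) count 10 p_j .1
  tab <- state_table(rbind(c(0L, 0L), c(1L, 0L)), c(10, 10), c("f1", "f2"))
  stats <- data.frame(p_j = c(0.9, 0.1))
  ps <- em_maximisation(tab, stats)
  # match mass = 10 ; m1 = 9/10, m2 = 10/10 (clipped just inside 1)
  expect_equal(unname(ps$m["f1"]), 0.9)
  expect_gt(unname(ps$m["f2"]), 1 - 5e-6)
  expect_equal(ps$p, 0.5)
  # u1 = (0.1*10)/10 = 0.1 ; u2 = 1
  expect_equal(unname(ps$u["f1"]), 0.1)

  # all p_j = 1 degenerates (no non-match mass)
  expect_error(em_maximisation(tab, data.frame(p_j = c(1, 1))), "degenerate")

  # with all pairs matched (p_j ~ 1), m is the raw agreement fraction
  tab3 <- state_table(rbind(c(0L, 0L), c(1L, 0L)), c(30, 10), c("f1", "f2"))
  ps3 <- em_maximisation(tab3, data.frame(p_j = c(1 - 1e-9, 1 - 1e-9)))
  expect_equal(unname(ps3$m["f1"]), 0.75, tolerance = 1e-6)

  # agree + disagree + missing shares of the match mass sum to one
  tab4 <- state_table(rbind(c(0L, 2L), c(1L, 0L), c(2L, 1L)), c(5, 7, 3))
  ps4 <- em_maximisation(tab4, data.frame(p_j = c(0.9, 0.5, 0.2)))
  agree_share <- ps4$m
  miss_share <- ps4$mm
  disagree_share <- 1 - ps4$m - ps4$mm
  expect_equal(unname(agree_share + miss_share + disagree_share), c(1, 1))
})

test_that("EM starts from the documented defaults and reaches a fixed point", {
  ps <- parameter_set(c("a", "b"))
  expect_equal(unname(ps$m), c(0.8, 0.8))
  expect_equal(unname(ps$u), c(0.1, 0.1))
  expect_equal(unname(ps$mm), c(0.1, 0.1))
  expect_equal(unname(ps$um), c(0.1, 0.1))

  tab <- simulate_state_table(
    m = c(0.9, 0.85), u = c(0.1, 0.2), mm = c(0.05, 0.05),
    um = c(0.05, 0.05), p = 0.2, n_pairs = 20000, seed = 61
  )
  fit <- run_em(tab, tol = 1e-8)
  expect_true(fit$converged)
  # one further EM sweep moves every parameter by less than tol
  stats <- em_expectation(tab, fit)
  nxt <- em_maximisation(tab, stats)
  delta <- max(abs(c(
    nxt$m - fit$m, nxt$u - fit$u, nxt$mm - fit$mm, nxt$um - fit$um,
    nxt$p - fit$p
  )))
  expect_lt(delta, 1e-6)
})

test_that("EM recovers known parameters from simulated tables", {
  m_true <- c(0.95, 0.90, 0.85, 0.92, 0.88, 0.93)
  u_true <- c(0.02, 0.05, 0.10, 0.03, 0.08, 0.04)
  mm_true <- um_true <- rep(0.05, 6)
  p_true <- 0.05
  fits <- lapply(1:10, function(s) {
    tab <- simulate_state_table(m_true, u_true, mm_true, um_true, p_true,
      n_pairs = 100000, seed = 700 + s
    )
    run_em(tab)
  })
  m_hat <- rowMeans(vapply(fits, function(f) unname(f$m), numeric(6)))
  mm_hat <- rowMeans(vapply(fits, function(f) unname(f$mm), numeric(6)))
  p_hat <- mean(vapply(fits, function(f) f$p, numeric(1)))
  expect_true(all(abs(m_hat - m_true) < 0.02))
  expect_true(all(abs(mm_hat - mm_true) < 0.02))
  expect_lt(abs(p_hat - p_true), 0.01)

  # the observed-data log-likelihood never decreases within a fit
  for (f in fits) expect_true(all(diff(f$loglik) >= -1e-8))
})

test_that("EM output is invariant to row order and equivariant to field swaps", {
  tab <- simulate_state_table(
    m = c(0.9, 0.8, 0.95), u = c(0.05, 0.1, 0.02), mm = rep(0.05, 3),
    um = rep(0.05, 3), p = 0.1, n_pairs = 30000, seed = 71
  )
  fit <- run_em(tab)

  perm <- sample(nrow(tab))
  tab_shuffled <- state_table(
    pprlink:::table_states_matrix(tab)[perm, ], tab$count[perm],
    attr(tab, "fields")
  )
  fit2 <- run_em(tab_shuffled)
  expect_equal(fit2$m, fit$m, tolerance = 1e-9)
  expect_equal(fit2$u, fit$u, tolerance = 1e-9)
  expect_equal(fit2$p, fit$p, tolerance = 1e-9)

  # swapping two field columns permutes the fitted parameters identically
  st <- pprlink:::table_states_matrix(tab)
  swapped <- state_table(st[, c(2, 1, 3)], tab$count, c("f2", "f1", "f3"))
  fit3 <- run_em(swapped)
  expect_equal(unname(fit3$m[c("f1", "f2", "f3")]), unname(fit$m), tolerance = 1e-9)
  expect_equal(unname(fit3$u[c("f1", "f2", "f3")]), unname(fit$u), tolerance = 1e-9)
})

test_that("frequency-based u estimates match Jaro's formulas and an exhaustive oracle", {
  mk <- function(postcodes) {
    n <- length(postcodes)
    d <- do.call(rbind, lapply(seq_len(n), function(i) {
      person_row(sprintf("R%03d", i),
        entity_id = sprintf("E%03d", i),
        postcode = postcodes[i]
      )
    }))
    encode_dataset(d, bloom_params(secret_key = test_key))
  }
  g <- function(enc, f) {
    uf <- estimate_u_frequencies(enc)
    uf[uf$field == f, ]
  }
  # constant field: every pair agrees
  expect_equal(g(mk(rep("6000", 6)), "postcode")$u, 1)
  # {A:2, B:2}: u = (2 + 2) / (4*3) = 1/3
  expect_equal(g(mk(c("6000", "6000", "6111", "6111")), "postcode")$u, 1 / 3)

  # uniform over V values approaches 1/V; equals the brute-force all-pairs rate
  set.seed(81)
  vals <- sample(sprintf("6%03d", 1:10), 1000, replace = TRUE)
  est <- g(mk(vals), "postcode")$u
  agree <- outer(vals, vals, "==")
  brute <- (sum(agree) - length(vals)) / (length(vals) * (length(vals) - 1))
  expect_equal(est, brute)
  expect_equal(est, 1 / 10, tolerance = 0.05)

  # missing u-probability is the unordered-pair missing rate
  withmiss <- mk(c("6000", "6000", NA, "6111", NA, "6111"))
  row <- g(withmiss, "postcode")
  expect_equal(row$um, 1 - (4 * 3) / (6 * 5))
  # conditional agreement unaffected by the missing rows
  expect_equal(row$u, (2 + 2) / (4 * 3))
})

test_that("Bloom fields count u over identical filters", {
  d <- rbind(
    person_row("R1", last_name = "Smith"),
    person_row("R2", last_name = "Smith"),
    person_row("R3", last_name = "Jones"),
    person_row("R4", last_name = "Walker")
  )
  enc <- encode_dataset(d, bloom_params(secret_key = test_key))
  uf <- estimate_u_frequencies(enc)
  expect_equal(uf$u[uf$field == "last_name"], 2 / 12) # only the Smith pair
})

test_that("weights follow the log2 probability ratios", {
  w <- weights_from_parameters(0.8, 0.1)
  expect_equal(w$w_agree, 3.0) # log2(8)
  expect_equal(w$w_disagree, log2(0.2 / 0.9))
  expect_equal(w$w_disagree, -2.169925, tolerance = 1e-6)

  same <- weights_from_parameters(0.3, 0.3)
  expect_equal(same$w_agree, 0)
  expect_equal(same$w_disagree, 0)

  expect_warning(weights_from_parameters(1, 0.1), "saturated")
  # m > u gives a positive agreement and negative disagreement weight
  set.seed(5)
  m <- runif(20, 0.5, 0.99)
  u <- runif(20, 0.01, 0.4)
  w2 <- weights_from_parameters(m, u)
  expect_true(all(w2$w_agree > 0))
  expect_true(all(w2$w_disagree < 0))
})

test_that("adopted parameters swap in unconditional frequency u", {
  em <- parameter_set(c("f1", "f2"), m = c(0.9, 0.8), u = 0.4, mm = 0.05, um = 0.05, p = 0.3)
  em$iterations <- 5L
  uf <- data.frame(field = c("f1", "f2"), u = c(0.2, 0.5), um = c(0.1, 0.4))
  ad <- adopt_parameters(em, uf)
  expect_equal(unname(ad$u), c(0.2 * 0.9, 0.5 * 0.6))
  expect_equal(unname(ad$um), c(0.1, 0.4))
  expect_equal(ad$m, em$m) # m untouched
  expect_true(all(ad$u + ad$um <= 1))
})

test_that("parameter sets round-trip through JSON", {
  ps <- parameter_set(c("a", "b"), m = c(0.9, 0.7), u = c(0.05, 0.2), p = 0.12)
  ps$iterations <- 17L
  ps$converged <- TRUE
  path <- tempfile(fileext = ".json")
  write_parameters_json(ps, path)
  back <- read_parameters_json(path)
  expect_equal(back$m, ps$m)
  expect_equal(back$u, ps$u)
  expect_equal(back$p, ps$p)
  expect_equal(back$iterations, 17L)
  expect_true(back$converged)
})
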
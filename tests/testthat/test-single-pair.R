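test_that("midrank AUC matches the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4),
                       c("control", "control", "case", "case"))$auc, 1)
  expect_equal(roc_auc(rep(2.5, 6), rep(c("case", "control"), 3))$auc, 0.5)

  v <- c(3, 1, 2, 4)
  lab <- c("control", "case", "control", "case")
  expect_equal(roc_auc(v, lab)$auc, brute_force_auc(v, lab))  # = 0.5 here

  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(2:10, 1)
    n0 <- sample(2:10, 1)
    vals <- sample(seq_len(8), n1 + n0, replace = TRUE)  # forces ties
    lab <- rep(c("case", "control"), c(n1, n0))
    expect_equal(roc_auc(vals, lab)$auc, brute_force_auc(vals, lab))
  }
})

test_that("ROC points are anchored and consistent with trapezoidal area", {
  set.seed(5)
  v <- rnorm(20)
  lab <- rep(c("case", "control"), 10)
  r <- roc_auc(v, lab)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  trap <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
  expect_equal(trap, r$auc)
  expect_error(roc_auc(v, rep("case", 20)), "control")
})

test_that("AUC equals U/(n1 n2) with midranks", {
  set.seed(6)
  v <- rnorm(10)  # tie-free
  lab <- rep(c("case", "control"), each = 5)
  m <- mann_whitney_auc(v, lab)
  expect_lt(abs(m$auc - m$U / 25), 1e-12)
  expect_equal(m$U, brute_force_U(v, lab))

  m2 <- mann_whitney_auc(c(1, 2, 3, 4, 5, 6), rep(c("control", "case"), each = 3))
  expect_equal(m2$U, 9)   # perfect separation 3 vs 3
  expect_equal(m2$auc, 1)

  m3 <- mann_whitney_auc(rep(7, 8), rep(c("case", "control"), 4))
  expect_equal(m3$U, 16 / 2)  # n1 n2 / 2 under all-ties
  expect_equal(m3$auc, 0.5)
})

test_that("AUC is invariant under monotone transforms and flips under swap", {
  set.seed(7)
  v <- rnorm(30)
  lab <- rep(c("case", "control"), 15)
  a <- roc_auc(v, lab)$auc
  expect_identical(roc_auc(2 ^ v, lab)$auc, a)    # log2 vs ratio scale
  expect_identical(roc_auc(rank(v), lab)$auc, a)
  expect_equal(roc_auc(-v, lab)$auc, 1 - a)       # orientation identity
})

test_that("pair classifier recovers a planted shift near its theoretical AUC", {
  ct <- make_gaussian_ct(n1 = 30, n0 = 30, n_assays = 2, delta = c(3, 0),
                         sigma = 1, tau = 1.5, seed = 7)
  f <- pair_feature(ct, ct$assays[1], ct$assays[2])
  fit <- fit_pair_classifier(f)
  theo <- pnorm(3 / sqrt(2 * (1 + 1)))
  expect_lt(abs(fit$auc - theo), 0.06)
  expect_gt(fit$accuracy, 0.7)
  expect_lt(fit$mw_p, 1e-4)
  expect_true(fit$auc_ci_low <= fit$auc && fit$auc <= fit$auc_ci_high)
})

test_that("accuracy is the class-size-weighted mean of sens/spec", {
  ct <- make_gaussian_ct(n1 = 12, n0 = 18, n_assays = 4, delta = c(2, 0, 1, 0),
                         seed = 9)
  s <- screen_pairs(ct)
  with(s$results, expect_equal(
    accuracy, (sensitivity * n_case + specificity * n_control) /
      (n_case + n_control)))
  expect_true(all(s$results$auc >= 0.5))
  expect_true(all(s$results$auc_ci_low <= s$results$auc + 1e-12 &
                    s$results$auc <= s$results$auc_ci_high + 1e-12))
})

test_that("degenerate constant feature is flagged with AUC 0.5", {
  fit <- fit_pair_classifier(rep(1.3, 20), rep(c("case", "control"), 10))
  expect_true(fit$degenerate)
  expect_equal(fit$auc, 0.5)
  expect_equal(fit$coefficients[["slope"]], 0)
  # balanced classes: fitted p = 0.5 -> everything classified case
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 0)
})

test_that("perfect separation falls back to a deterministic step rule", {
  v <- c(rnorm(10, 10), rnorm(10, -10))
  lab <- rep(c("case", "control"), each = 10)
  fit <- fit_pair_classifier(v, lab)
  expect_true(fit$separable)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  expect_equal(fit$auc, 1)
  # DeLong interval at AUC 1 is degenerate zero-width
  ci <- auc_ci(v, lab, method = "delong")
  expect_equal(as.numeric(ci), c(1, 1))
  expect_true(attr(ci, "degenerate"))
})

test_that("label permutation centres the AUC distribution at 0.5", {
  ct <- make_gaussian_ct(n1 = 30, n0 = 30, n_assays = 2, delta = c(3, 0),
                         seed = 7)
  f <- pair_feature(ct, ct$assays[1], ct$assays[2])
  set.seed(7)
  null_auc <- replicate(1000, {
    lab <- sample(as.character(f$cohort))
    a <- roc_auc(f$log2_ratio, lab)$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.03)
})

test_that("bootstrap CI is deterministic under a seed and brackets the AUC", {
  set.seed(12)
  v <- c(rnorm(15, 1), rnorm(15))
  lab <- rep(c("case", "control"), each = 15)
  c1 <- auc_ci(v, lab, method = "bootstrap", n_boot = 500, seed = 99)
  c2 <- auc_ci(v, lab, method = "bootstrap", n_boot = 500, seed = 99)
  expect_identical(c1, c2)
  expect_lte(c1[["low"]], attr(c1, "auc"))
  expect_gte(c1[["high"]], attr(c1, "auc"))
})

test_that("AUC gate is inclusive and sorts by AUC then pair id", {
  res <- data.frame(pair_id = c("p1", "p2", "p3"),
                    auc = c(0.79, 0.80, 0.93),
                    stringsAsFactors = FALSE)
  sel <- select_pairs(res, auc_min = 0.8)
  expect_equal(nrow(sel), 2)
  expect_identical(sel$pair_id, c("p3", "p2"))  # 0.80 kept: inclusive gate
  expect_equal(nrow(select_pairs(data.frame(pair_id = "p", auc = 0.5))), 0)
})

test_that("screening a planted cohort gates all strongly planted pairs", {
  h <- qnorm(0.95)
  cfg <- synthetic_config(
    seed = 11,
    effects = data.frame(assay = c(1, 6, 16, 37, 42, 47),
                         delta = c(h, rep(-h, 5))))
  sim <- simulate_cohort(cfg)
  planted <- with(sim$truth$pairs,
                  pair_id[abs(theoretical_auc - pnorm(h)) < 1e-9])
  expect_equal(length(planted), 5)
  s <- screen_pairs(sim$ct)
  sel <- select_pairs(s, auc_min = 0.8)
  expect_true(all(planted %in% sel$pair_id))
})
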
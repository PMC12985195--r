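test_that("a k=1 combination reproduces the single-pair AUC", {
  ct <- make_gaussian_ct(n1 = 15, n0 = 15, n_assays = 4, delta = c(2, 0, 0, 0),
                         seed = 3)
  fm <- pair_feature_matrix(ct)
  lab <- ct$samples$cohort
  id <- colnames(fm)[1]
  cb <- build_combo(fm, id, lab)
  expect_equal(cb$auc, roc_auc(fm[, id], lab)$auc)  # monotone transform

  # three identical copies of one member = the single standardized feature
  fm3 <- cbind(fm, `copy1` = fm[, id], `copy2` = fm[, id])
  cb3 <- build_combo(fm3, c(id, "copy1", "copy2"), lab)
  expect_equal(cb3$auc, cb$auc)
  expect_equal(cb3$score, cb$score)
})

test_that("samples at the class-mean midpoint score 0 and classify as case", {
  x <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40), ncol = 2,
              dimnames = list(NULL, c("pA", "pB")))
  lab <- c("control", "control", "case", "case")
  cb <- build_combo(x, c("pA", "pB"), lab)
  # midpoints: pA (1.5+3.5)/2 = 2.5; pB (15+35)/2 = 25
  mid <- matrix(c(2.5, 25), 1, 2, dimnames = list(NULL, c("pA", "pB")))
  expect_equal(predict(cb, mid, type = "score"), 0)
  expect_equal(predict(cb, mid, type = "probability"), 0.5)
  expect_identical(as.character(predict(cb, mid, type = "class")), "case")
})

test_that("perfectly separating members give perfect combo metrics", {
  x <- matrix(c(rnorm(10, 8), rnorm(10, -8),
                rnorm(10, 6), rnorm(10, -6)), ncol = 2,
              dimnames = list(NULL, c("pA", "pB")))
  lab <- rep(c("case", "control"), each = 10)
  cb <- build_combo(x, c("pA", "pB"), lab)
  expect_equal(cb$sensitivity, 1)
  expect_equal(cb$specificity, 1)
  expect_equal(cb$accuracy, 1)
  expect_equal(cb$auc, 1)
  expect_error(evaluate_combo(cb, rep("case", 20)), "both classes")
})

test_that("an anti-oriented member drags the combo below its best member", {
  set.seed(13)
  n <- 60
  lab <- rep(c("case", "control"), each = n / 2)
  d <- 2.3
  sig <- as.numeric(lab == "case") * d
  x <- cbind(p1 = sig + rnorm(n), p2 = sig + rnorm(n), p3 = -sig + rnorm(n))
  best <- max(apply(x[, 1:2], 2, function(v) roc_auc(v, lab)$auc))
  # orientation forced +1 on the anti member documents that equal weights
  # cannot down-weight a bad input
  cb <- build_combo(x, c("p1", "p2", "p3"), lab, orientations = c(1, 1, 1))
  expect_lt(cb$auc, best)
})

test_that("combining three independent planted pairs beats each member", {
  d <- qnorm(0.9)  # per-assay shift giving theoretical pair AUC 0.9
  cfg <- synthetic_config(n_assays = 12, use_panel_ids = FALSE, seed = 5,
                          effects = data.frame(assay = c(1, 2, 3, 4, 5, 6),
                                               delta = c(d, d, d, -d, -d, -d)))
  sim <- simulate_cohort(cfg)
  fm <- pair_feature_matrix(sim$ct)
  lab <- sim$ct$samples$cohort
  members <- c("SYN-mir-001/SYN-mir-004", "SYN-mir-002/SYN-mir-005",
               "SYN-mir-003/SYN-mir-006")  # disjoint assays -> independent
  member_auc <- vapply(members, function(m) roc_auc(fm[, m], lab)$auc,
                       numeric(1))
  cb <- build_combo(fm, members, lab)
  expect_true(all(cb$auc > member_auc))
})

test_that("raw_ratio mode classifies every sample as case (formula caveat)", {
  ct <- make_gaussian_ct(n1 = 10, n0 = 10, n_assays = 4, delta = c(2, 0, 0, 0),
                         seed = 17)
  fm <- pair_feature_matrix(ct)
  lab <- ct$samples$cohort
  cb <- build_combo(fm, colnames(fm)[1:3], lab, mode = "raw_ratio")
  expect_true(cb$caveat)
  expect_true(all(cb$probability > 0.5))  # positive ratios -> score > 0
  expect_equal(cb$sensitivity, 1)
  expect_equal(cb$specificity, 0)
})

test_that("build_combo validates members", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("pA", "pB")))
  lab <- rep(c("case", "control"), 5)
  expect_error(build_combo(x, character(), lab), "at least one")
  expect_error(build_combo(x, c("pA", "pA"), lab), "duplicate")
  expect_error(build_combo(x, c("pA", "pX"), lab), "pX")
})

test_that("exhaustive search evaluates every combination deterministically", {
  ct <- make_gaussian_ct(n1 = 12, n0 = 12, n_assays = 5,
                         delta = c(2, 1.5, 0, 0, 0), seed = 19)
  fm <- pair_feature_matrix(ct)
  lab <- ct$samples$cohort
  s <- screen_pairs(ct)
  gated <- select_pairs(s, auc_min = 0)  # all 10 pairs
  cs <- combo_search(gated, fm, lab, k = 3)
  expect_equal(cs$n_evaluated, choose(10, 3))
  expect_equal(nrow(cs$results), choose(10, 3))

  # exactly one combination when the gate matches k
  cs1 <- combo_search(gated[1:3, ], fm, lab, k = 3)
  expect_equal(cs1$n_evaluated, 1)
  expect_error(combo_search(gated[1:2, ], fm, lab, k = 3), "at least k")

  # invariance under input ordering of the gated list
  perm <- gated[sample(nrow(gated)), ]
  cs2 <- combo_search(perm, fm, lab, k = 3)
  expect_identical(cs$results, cs2$results)

  # rerun is bit-identical (the search has no randomness)
  cs3 <- combo_search(gated, fm, lab, k = 3)
  expect_identical(cs$results, cs3$results)
})

test_that("k=1 search reduces to single-pair ranking", {
  ct <- make_gaussian_ct(n1 = 15, n0 = 15, n_assays = 5,
                         delta = c(2.5, 1.5, 0.8, 0, 0), seed = 20)
  fm <- pair_feature_matrix(ct)
  s <- screen_pairs(ct)
  gated <- select_pairs(s, auc_min = 0)
  cs <- combo_search(gated, fm, ct$samples$cohort, k = 1)
  expect_equal(cs$results$member_1[1], gated$pair_id[1])
  expect_equal(cs$results$auc, sort(gated$auc, decreasing = TRUE))
})

test_that("search criteria floors are inclusive filters", {
  ct <- make_gaussian_ct(n1 = 12, n0 = 12, n_assays = 4,
                         delta = c(2, 1, 0, 0), seed = 25)
  fm <- pair_feature_matrix(ct)
  lab <- ct$samples$cohort
  gated <- select_pairs(screen_pairs(ct), auc_min = 0)
  all_cs <- combo_search(gated, fm, lab, k = 2)
  strict <- combo_search(gated, fm, lab, k = 2,
                         criteria = list(min_auc = 0.9))
  expect_true(all(strict$results$auc >= 0.9))
  expect_equal(strict$n_evaluated, all_cs$n_evaluated)  # still exhaustive
  expect_true(nrow(strict$results) <= nrow(all_cs$results))
})
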
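test_that("packaged panel has 48 unique assays with valid annotations", {
  p <- gbm_panel()
  expect_s3_class(p, "mirna_panel")
  expect_equal(nrow(p), 48)
  expect_false(anyDuplicated(p$mirna_id) > 0)
  expect_true(all(p$role %in% c("oncomiR", "tumor_suppressor",
                                "context_dependent")))
  expect_type(p$brain_enriched, "logical")
})

test_that("read_panel handles minimal files and rejects bad ones", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("mirna_id,role,brain_enriched", "miR-21-5p,oncomiR,+"), f)
  p <- read_panel(f)
  expect_equal(nrow(p), 1)
  expect_identical(p$mirna_id, "miR-21-5p")

  writeLines(c("mirna_id,role,brain_enriched",
               "miR-21-5p,oncomiR,+", "miR-7-5p,tumor_suppressor,+",
               "miR-21-5p,oncomiR,+"), f)
  expect_error(read_panel(f), "miR-21-5p")

  writeLines(c("mirna_id,role,brain_enriched", "miR-21-5p,driver,+"), f)
  expect_error(read_panel(f), "role")
})

test_that("synonym normalization resolves vendor aliases onto the panel", {
  expect_identical(normalize_mirna_id("miR-451a"), "miR-451a-5p")
  expect_identical(normalize_mirna_id(c("miR-451a", "miR-21-5p")),
                   c("miR-451a-5p", "miR-21-5p"))
  # a panel listing both spellings collapses to a duplicate -> error
  f <- tempfile(fileext = ".csv")
  writeLines(c("mirna_id,role,brain_enriched",
               "miR-451a,context_dependent,+",
               "miR-451a-5p,context_dependent,+"), f)
  expect_error(read_panel(f), "miR-451a-5p")
})

test_that("long Ct tables parse censoring, collapse replicates by median", {
  panel <- gbm_panel()
  df <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S2", "S2"),
    cohort = c("case", "case", "control", "control", "control", "control"),
    assay = c("miR-7-5p", "miR-21-5p", "miR-7-5p",
              "miR-21-5p", "miR-21-5p", "miR-21-5p"),
    ct = c("Undetermined", "24.5", "30.1", "24.0", "24.2", "30.0"),
    stringsAsFactors = FALSE
  )
  ct <- read_ct_table(write_long_ct(df), "long", panel)
  expect_equal(n_samples(ct), 2)
  expect_true(ct$censored["S1", "miR-7-5p"])
  expect_equal(ct$ct["S1", "miR-7-5p"], 40)
  expect_equal(ct$ct["S2", "miR-21-5p"], 24.2)  # median of triplicate
  expect_false(ct$censored["S2", "miR-21-5p"])

  # replicate collapse is permutation invariant
  df2 <- df[sample(nrow(df)), ]
  ct2 <- read_ct_table(write_long_ct(df2), "long", panel)
  expect_equal(ct2$ct[rownames(ct$ct), colnames(ct$ct)], ct$ct)

  # output sets are subsets of input sets
  expect_true(all(rownames(ct$ct) %in% df$sample_id))
  expect_true(all(colnames(ct$ct) %in% df$assay))
})

test_that("unknown assays and unparseable samples are hard errors", {
  panel <- gbm_panel()
  df <- data.frame(sample_id = "S1", cohort = "case",
                   assay = "miR-999-5p", ct = "25", stringsAsFactors = FALSE)
  expect_error(read_ct_table(write_long_ct(df), "long", panel), "miR-999-5p")

  df <- data.frame(sample_id = c("S1", "S2"), cohort = c("case", "control"),
                   assay = c("miR-7-5p", "miR-7-5p"),
                   ct = c("25", "garbage"), stringsAsFactors = FALSE)
  expect_error(suppressWarnings(read_ct_table(write_long_ct(df), "long", panel)),
               "S2")
})

test_that("wide Ct tables read one row per sample", {
  panel <- gbm_panel()
  set.seed(4)
  n <- 60
  vals <- matrix(round(runif(n * 48, 20, 35), 2), n, 48)
  df <- data.frame(sample_id = sprintf("S%02d", 1:n),
                   cohort = rep(c("case", "control"), each = 30),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(48)) df[[panel$mirna_id[j]]] <- vals[, j]
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  ct <- read_ct_table(f, "wide", panel)
  expect_equal(n_samples(ct), 60)
  expect_equal(n_assays(ct), 48)
  expect_equal(unname(ct$ct["S01", "miR-7-5p"]), vals[1, 1])
})

test_that("write/read round-trip is bit-exact and preserves censoring", {
  sim <- simulate_cohort(synthetic_config(n_case = 5, n_control = 5,
                                          n_assays = 10, seed = 42))
  # force a censored well through the round trip
  ct0 <- sim$ct
  ct0$ct[1, 1] <- ct0$max_cycles
  ct0$censored[1, 1] <- TRUE
  f <- tempfile(fileext = ".csv")
  write_ct_table(ct0, f)
  panel <- data.frame(mirna_id = ct0$assays, role = "oncomiR",
                      brain_enriched = TRUE)
  class(panel) <- c("mirna_panel", "data.frame")
  ct1 <- read_ct_table(f, "long", panel)
  expect_identical(ct1$ct[rownames(ct0$ct), colnames(ct0$ct)], ct0$ct)
  expect_identical(ct1$censored[rownames(ct0$ct), colnames(ct0$ct)],
                   ct0$censored)
  expect_identical(as.character(ct1$samples$cohort),
                   as.character(ct0$samples$cohort))
})

test_that("align_profiles restricts to shared assays in identical order", {
  a <- make_gaussian_ct(n1 = 3, n0 = 3, n_assays = 5, seed = 1)
  al <- align_profiles(a, a)
  expect_identical(al$a$ct, a$ct)
  expect_identical(al$b$assays, al$a$assays)

  b <- a
  colnames(b$ct) <- colnames(b$censored) <- paste0("other-", seq_len(5))
  b$assays <- colnames(b$ct)
  expect_error(align_profiles(a, b), "fewer than 2")

  c_ <- a[, c(3, 1, 5)]
  al2 <- align_profiles(a, c_)
  expect_identical(al2$a$assays, al2$b$assays)
  expect_equal(n_assays(al2$a), 3)
})
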
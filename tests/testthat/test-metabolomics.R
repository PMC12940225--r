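mk_metab <- function(values, batch = 1, sample_ids = NULL, aliquot = NULL,
                     aliquot_group = NULL) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%02d", seq_len(ncol(m)))
  n <- nrow(m)
  tibble::tibble(
    sample_id = sample_ids %||% sprintf("s%02d", seq_len(n)),
    aliquot = aliquot %||% rep("A", n),
    aliquot_group = aliquot_group %||% rep(NA_character_, n),
    batch = rep(batch, length.out = n)
  ) |> dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("batch normalization divides by the within-batch median", {
  t <- mk_metab(cbind(m1 = c(2, 4, 6)))
  out <- batch_normalize(t)
  expect_equal(out$m1, c(0.5, 1, 1.5))
  # a single value normalizes to 1
  expect_equal(batch_normalize(mk_metab(cbind(m1 = 9)))$m1, 1)
  # fully-missing compound in a batch stays missing, with a warning
  t2 <- mk_metab(cbind(m1 = c(NA, NA), m2 = c(1, 3)))
  expect_warning(out2 <- batch_normalize(t2), "fully missing")
  expect_true(all(is.na(out2$m1)))
})

test_that("planted batch scale factors vanish after normalization", {
  sim <- cached_sim(500, 42)
  out <- batch_normalize(sim$metabolomics)
  for (b in unique(out$batch)) {
    meds <- vapply(met_value_cols(out),
                   function(m) median(out[[m]][out$batch == b], na.rm = TRUE),
                   0)
    expect_equal(unname(meds), rep(1, length(meds)), tolerance = 1e-9)
  }
})

test_that("sample exclusion uses mean + k * SD of missing counts", {
  # counts (10,10,10,10,100): mean 28, SD 40.25 -> threshold 229, none drop
  vals <- matrix(1, 5, 200)
  for (i in 1:4) vals[i, 1:10] <- NA
  vals[5, 1:100] <- NA
  t <- mk_metab(vals)
  out <- exclude_samples_by_missingness(t)
  expect_equal(nrow(out), 5)
  expect_length(attr(out, "excluded_samples"), 0)
  # equal counts (SD 0): nobody drops
  vals2 <- matrix(1, 4, 50)
  vals2[, 1:5] <- NA
  expect_equal(nrow(exclude_samples_by_missingness(mk_metab(vals2))), 4)
  # a genuine outlier drops at k = 5
  vals3 <- matrix(1, 40, 100)
  vals3[cbind(seq_len(40), seq_len(40) %% 7 + 1)] <- NA
  vals3[40, 1:80] <- NA
  out3 <- exclude_samples_by_missingness(mk_metab(vals3))
  expect_equal(attr(out3, "excluded_samples"), "s40")
})

test_that("compound filters respect the 70% and 30% boundaries", {
  n <- 100
  m_drop <- c(rep(NA, 71), rnorm(29, 10))   # 71% missing -> dropped
  m_keep <- c(rep(NA, 70), rnorm(30, 10))   # 70% is not "over 70%"
  t <- mk_metab(cbind(drop71 = m_drop, keep70 = m_keep, ok = rnorm(n, 10)))
  out <- filter_metabolites(t)
  expect_setequal(met_value_cols(out), c("keep70", "ok"))
  expect_equal(attr(out, "removed_metabolites")$metabolite, "drop71")
  expect_equal(attr(out, "removed_metabolites")$reason, "missingness")
})

test_that("the between-aliquot CV filter removes irreproducible compounds", {
  # aliquot pair (10, 16.5): mean 13.25, SD 4.596, CV 0.347 -> dropped
  # aliquot pair (10, 10): CV 0 -> kept
  t <- mk_metab(cbind(cv35 = c(10, 16.5, 8), cv0 = c(10, 10, 9)),
                sample_ids = c("s1", "s1", "s2"),
                aliquot = c("A", "B", "A"),
                aliquot_group = c("s1", "s1", NA))
  out <- filter_metabolites(t)
  expect_equal(met_value_cols(out), "cv0")
  rem <- attr(out, "removed_metabolites")
  expect_equal(rem$metabolite, "cv35")
  expect_equal(rem$reason, "cv")
  # without replicate groups the CV filter is skipped with a warning
  t2 <- mk_metab(cbind(cv35 = c(10, 16.5, 8)))
  expect_warning(out2 <- filter_metabolites(t2), "CV filter skipped")
  expect_equal(met_value_cols(out2), "cv35")
})

test_that("log2 + imputation is the identity on complete tables", {
  t <- mk_metab(cbind(m1 = c(2, 4), m2 = c(8, 16)))
  out <- log2_and_impute(t)
  expect_equal(out$m1, c(1, 2))
  expect_equal(out$m2, c(3, 4))
})

test_that("a missing entry among identical samples imputes to the common value", {
  vals <- matrix(rep(c(4, 8, 16), each = 12), 12)
  colnames(vals) <- c("m1", "m2", "m3")
  vals[3, 2] <- NA
  out <- log2_and_impute(mk_metab(vals))
  expect_equal(out$m2[3], 3)
  expect_false(anyNA(out[, c("m1", "m2", "m3")]))
})

test_that("imputation error stays small on smooth correlated data", {
  set.seed(31)
  n <- 120
  latent <- rnorm(n)
  x <- 2^(10 + outer(latent, rep(1, 12)) * 0.8 +
            matrix(rnorm(n * 12, 0, 0.3), n))
  colnames(x) <- sprintf("m%02d", 1:12)
  truth <- log2(x)
  holes <- matrix(runif(n * 12) < 0.05, n)
  x[holes] <- NA
  out <- log2_and_impute(mk_metab(x))
  imp <- as.matrix(out[, sprintf("m%02d", 1:12)])
  rmse <- sqrt(mean((imp[holes] - truth[holes])^2))
  expect_lt(rmse, 0.5)
})

test_that("QC on a clean one-batch table is the identity up to log2", {
  vals <- matrix(2^rnorm(60, 10), 20)
  colnames(vals) <- c("m1", "m2", "m3")
  vals <- sweep(vals, 2, apply(vals, 2, median), "/")  # batch medians already 1
  t <- mk_metab(vals)
  out <- suppressWarnings(metabolomics_qc(t))
  expect_equal(as.matrix(out$table[, c("m1", "m2", "m3")]),
               log2(vals), ignore_attr = TRUE)
  expect_length(out$excluded_samples, 0)
  expect_equal(nrow(out$removed_metabolites), 0)
})

test_that("full QC removes exactly the planted targets on the fixture", {
  sim <- cached_sim(500, 42)
  qc <- metabolomics_qc(sim$metabolomics)
  man <- sim$manifest$qc_targets
  expect_equal(qc$excluded_samples, man$missingness_outlier_sample)
  expect_setequal(qc$removed_metabolites$metabolite,
                  c(man$high_missing_metabolite, man$high_cv_metabolite))
  expect_false(anyNA(qc$table[, met_value_cols(qc$table)]))
  expect_equal(nrow(qc$table),
               sim$manifest$n_samples - length(qc$excluded_samples))
})

test_that("QC results are invariant to row and column order", {
  sim <- cached_sim(30, 7)
  t <- sim$metabolomics
  perm_rows <- sample(nrow(t))
  perm_cols <- c(met_meta_cols, sample(met_value_cols(t)))
  t2 <- t[perm_rows, perm_cols]
  q1 <- suppressWarnings(metabolomics_qc(t))
  q2 <- suppressWarnings(metabolomics_qc(t2))
  expect_setequal(met_value_cols(q1$table), met_value_cols(q2$table))
  o1 <- q1$table[order(q1$table$sample_id), met_value_cols(q1$table)]
  o2 <- q2$table[order(q2$table$sample_id), met_value_cols(q1$table)]
  expect_equal(as.data.frame(o1), as.data.frame(o2), tolerance = 1e-9)
})
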
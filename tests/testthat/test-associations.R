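test_that("global cognition is the oriented first principal component", {
  set.seed(8)
  # two perfectly correlated subtests: PC1 carries all variance
  a <- rnorm(50)
  gc2 <- global_cognition(cbind(t1 = a, t2 = 2 * a + 3))
  expect_equal(gc2$variance_explained, 1)
  expect_gt(cor(gc2$score, a), 0.999)
  # orthogonal equal-variance subtests: PC1 tends to half the variance
  n <- 4000
  gc0 <- global_cognition(cbind(t1 = rnorm(n), t2 = rnorm(n)))
  expect_equal(gc0$variance_explained, 0.5, tolerance = 0.05)
  expect_error(global_cognition(cbind(t1 = rnorm(5), t2 = rep(1, 5))),
               "constant")
})

test_that("a one-factor battery with loading 0.69 explains about 47%", {
  set.seed(12)
  n <- 4000
  f <- rnorm(n)
  subtests <- sapply(1:5, function(j) 0.69 * f + rnorm(n))
  gc <- global_cognition(subtests)
  expect_equal(gc$variance_explained, 0.47, tolerance = 0.03)
  # the score tracks the latent factor, positively
  expect_gt(cor(gc$score, f), 0.8)
})

test_that("the polygenic score is the weighted dosage sum", {
  w <- c(snp_a = 0.5, snp_b = -0.2)
  expect_equal(compute_prs(cbind(snp_a = c(0, 2), snp_b = c(0, 0)), w),
               c(0, 1))
  set.seed(3)
  d <- matrix(rbinom(20 * 28, 2, 0.4), 20,
              dimnames = list(NULL, sprintf("s%02d", 1:28)))
  wts <- setNames(rnorm(28, 0, 0.2), colnames(d))
  # independent dot-product oracle
  oracle <- vapply(seq_len(20), function(i) sum(d[i, ] * wts), 0)
  expect_equal(compute_prs(d, wts), oracle)
  d2 <- d
  d2[1, 3] <- NA
  expect_true(is.na(compute_prs(d2, wts)[1]))
  expect_false(anyNA(compute_prs(d2, wts)[-1]))
  expect_error(compute_prs(d * 2, wts), "\\[0, 2\\]")
})

test_that("standardized regression recovers exact and null relations", {
  set.seed(21)
  d <- tibble::tibble(x = rnorm(100))
  d$y <- d$x
  r <- regress_outcome(d, "y", "x")
  expect_equal(r$estimate, 1, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-12)

  d0 <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(regress_outcome(d0, "y", "x")$estimate), 0.1)
})

test_that("a planted standardized slope of 0.3 is recovered on average", {
  set.seed(99)
  ests <- replicate(50, {
    x <- rnorm(500)
    y <- 0.3 * x + sqrt(1 - 0.09) * rnorm(500)
    regress_outcome(tibble::tibble(x = x, y = y), "y", "x")$estimate
  })
  expect_equal(mean(ests), 0.3, tolerance = 0.05)
})

test_that("rank-deficient designs fail loudly", {
  d <- tibble::tibble(y = rnorm(30), x = rnorm(30))
  d$z <- d$x
  expect_error(regress_outcome(d, "y", "x", "z"), "collinear")
})

test_that("Kruskal-Wallis agrees with first-principles rank computations", {
  groups <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  res <- kruskal_dunn(unlist(groups), rep(c("a", "b", "c"), each = 3))
  kw <- res[res$test == "kruskal_wallis", ]
  # the tie-corrected H equals an independent from-scratch computation
  expect_equal(kw$statistic, kw_H_oracle(groups), tolerance = 1e-9)
  # full separation: the exact permutation p is the smallest attainable
  # (3! of 1680 assignments) and the test flags the contrast like it does
  expect_equal(kw_exact_p(groups), 6 / 1680, tolerance = 1e-9)
  expect_lt(kw$p_value, 0.05)
  # with ties, the tie-corrected statistic still matches the oracle
  tied <- list(c(1, 1, 2), c(2, 3, 3), c(9, 9, 9))
  res_t <- kruskal_dunn(unlist(tied), rep(c("a", "b", "c"), each = 3))
  expect_equal(res_t$statistic[res_t$test == "kruskal_wallis"],
               kw_H_oracle(tied), tolerance = 1e-9)
})

test_that("with two groups Dunn's z-squared reproduces the KW statistic", {
  set.seed(5)
  y <- rnorm(24)
  g <- rep(c("a", "b"), each = 12)
  res <- kruskal_dunn(y, g)
  H <- res$statistic[res$test == "kruskal_wallis"]
  z <- res$statistic[res$test == "dunn"]
  expect_equal(z^2, H, tolerance = 1e-9)
})

test_that("small groups are dropped from the rank tests with a warning", {
  y <- c(1, 2, 3, 4, 9)
  g <- c("a", "a", "b", "b", "c")
  expect_warning(res <- kruskal_dunn(y, g), "dropped")
  expect_equal(res$n[res$test == "kruskal_wallis"], 4)
})

test_that("the Wilcoxon test matches exact enumeration and handles ties", {
  # fully separated 3 vs 3: two-sided exact p = 0.1
  expect_equal(wilcox_exact_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  w <- wilcoxon_sex(c(1, 2, 3, 10, 11, 12),
                    rep(c("female", "male"), each = 3))
  expect_equal(w$p_value, 0.1, tolerance = 1e-9)
  # identical values in both groups: p = 1 under the tie-corrected normal
  w2 <- wilcoxon_sex(rep(5, 10), rep(c("female", "male"), 5))
  expect_equal(w2$p_value, 1)
  expect_error(wilcoxon_sex(1:5, rep("female", 5)), "non-empty")
})

test_that("interaction analysis finds sex-specific slopes and stratifies", {
  set.seed(17)
  n <- 600
  sex <- rep(c("female", "male"), n / 2)
  flux <- rnorm(n)
  cog <- ifelse(sex == "male", -0.3, 0) * flux + rnorm(n, 0, 0.8)
  d <- tibble::tibble(cognition = cog, flux = flux, sex = sex,
                      age = rnorm(n, 60, 5), bmi = rnorm(n, 27, 4),
                      education = sample(1:4, n, TRUE))
  res <- interaction_analysis(d, "cognition", "flux")
  expect_lt(res$p_value[res$test == "interaction"], 0.05)
  male <- res[grepl("male\\)", res$predictor) & !grepl("female", res$predictor), ]
  female <- res[grepl("\\(female\\)", res$predictor), ]
  expect_lt(male$estimate, -0.1)
  expect_lt(abs(female$estimate), 0.15)

  d_eq <- d
  d_eq$cognition <- 0.2 * d_eq$flux + rnorm(n, 0, 0.8)
  res_eq <- interaction_analysis(d_eq, "cognition", "flux")
  expect_lt(abs(res_eq$estimate[res_eq$test == "interaction"]), 0.12)

  expect_error(interaction_analysis(d[d$sex == "male", ], "cognition", "flux"),
               "both sexes")
})

test_that("the exact Fisher r x c test matches hypergeometric oracles", {
  tb <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_rxc(tb), fisher_2x2_p(tb), tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(tb), 0.4857143, tolerance = 1e-6)
  # identical rows: p = 1
  expect_equal(fisher_exact_rxc(rbind(c(5, 5, 5), c(5, 5, 5))), 1)
  # random 2 x 3 tables against stats::fisher.test
  set.seed(61)
  for (i in 1:5) {
    tb <- matrix(rpois(6, 6), 2)
    expect_equal(fisher_exact_rxc(tb), fisher.test(tb)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_rxc(matrix(1, 3, 3)), "2 x C")
})

test_that("the Monte-Carlo fallback approximates the exact Fisher p", {
  tb <- matrix(c(12, 3, 2, 9, 5, 8), 2)
  exact <- fisher_exact_rxc(tb)
  mc <- fisher_exact_rxc(tb, max_tables = 1, mc_reps = 20000, mc_seed = 4)
  expect_equal(mc, exact, tolerance = 0.02)
})

test_that("two-sample t works from values and from summary statistics", {
  r <- t_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 0)
  # cohort-table style summaries: near-identical ages in two sexes
  r2 <- t_two_sample(c(mean = 61.66, sd = 5.38, n = 608),
                     c(mean = 61.64, sd = 5.48, n = 456))
  expect_lt(abs(r2$statistic - 0.06), 0.005)
  expect_lt(abs(r2$p_value - 0.95), 0.01)
  # agreement with stats::t.test on raw values
  set.seed(14)
  a <- rnorm(30, 1)
  b <- rnorm(40, 0.5, 2)
  r3 <- t_two_sample(a, b)
  tt <- t.test(a, b)
  expect_equal(r3$statistic, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r3$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("a one-SD shift at n=50 per group is reliably detected", {
  set.seed(26)
  hits <- replicate(200, {
    t_two_sample(rnorm(50, 1), rnorm(50, 0))$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("APOE grouping matches the declared allele logic", {
  g <- apoe_groups(c("E2/E2", "E2/E3", "E3/E3", "E3/E4", "E4/E4", "E2/E4"))
  expect_equal(as.character(g),
               c("E2", "E2", "E3", "E4", "E4", "excluded"))
  expect_error(apoe_groups("E5/E5"), "unknown")
})

test_that("driver attribution ranks the sole producer first with R2 = 1", {
  sim <- cached_sim(200, 13)
  ma <- mapped_abundances(sim)
  sex <- setNames(sim$cohort$sex, sim$cohort$sample_id)
  fm <- pipeline_fluxes(sim$pan_models, ma$table, sex, sim$hosts, sim$diet,
                        c("dca_like", "null_m1"))
  fm <- mask_zero_and_bound_limited(fm)
  res <- driver_attribution(fm, ma$table, sim$pan_models)
  dca <- res[res$metabolite == "dca_like", ]
  # only the producer is a candidate at all; bystanders are excluded by rule
  expect_equal(dca$species, "sp_dca")
  expect_equal(dca$r_squared, 1, tolerance = 1e-9)
  n1 <- res[res$metabolite == "null_m1", ]
  expect_equal(n1$species[n1$rank == 1], "sp_null1")
  expect_false("sp_bystander" %in% res$species)
})

test_that("precursor producers join the candidate set", {
  sim <- cached_sim(200, 13)
  ma <- mapped_abundances(sim)
  sex <- setNames(sim$cohort$sex, sim$cohort$sample_id)
  fm <- pipeline_fluxes(sim$pan_models, ma$table, sex, sim$hosts, sim$diet,
                        c("met_b"))
  res <- driver_attribution(fm, ma$table, sim$pan_models,
                            precursors = list(met_b = "met_a"))
  expect_true("sp_chain" %in% res$species)
})
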
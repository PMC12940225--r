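test_that("demand reactions are unbalanced sinks and idempotent", {
  m <- stoich_model(
    "blood",
    tibble::tibble(id = "make", lb = 0, ub = 3),
    tibble::tibble(reaction = "make", metabolite = "dchac[bc]", coef = 1))
  m2 <- add_demand_reaction(m, "dchac")
  st <- m2$stoich[m2$stoich$reaction == "DM_dchac[bc]", ]
  expect_equal(st$metabolite, "dchac[bc]")
  expect_equal(st$coef, -1)
  expect_equal(m2$reactions$lb[m2$reactions$id == "DM_dchac[bc]"], 0)
  expect_equal(m2$reactions$ub[m2$reactions$id == "DM_dchac[bc]"], 1e6)
  expect_identical(add_demand_reaction(m2, "dchac"), m2)
  expect_error(add_demand_reaction(m, "dchac", "[luLI]"), "not found")
})

test_that("fba_max finds the single bottleneck", {
  m <- add_demand_reaction(bottleneck_model(src_ub = 5), "A", "[c]")
  sol <- fba_max(m, "DM_A[c]")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5, tolerance = 1e-9)
  expect_error(fba_max(m, "nope"), "not in model")
})

test_that("solver status is propagated faithfully, never a fabricated zero", {
  # infeasible: forced production of a metabolite with no consumer
  m <- stoich_model(
    "inf",
    tibble::tibble(id = c("force", "snk"), lb = c(1, 0), ub = c(2, 1e6)),
    tibble::tibble(reaction = c("force", "snk"),
                   metabolite = c("A[c]", "B[c]"), coef = c(1, -1)))
  expect_equal(fba_max(m, "snk")$status, "infeasible")
  # unbounded: producer/consumer pair with no finite upper bounds
  res <- .simplex_lp(matrix(c(1, -1), 1, 2), 0, c(0, 0), c(Inf, Inf),
                     c(1, 0), TRUE)
  expect_equal(res$status, 2)
})

test_that("fba_max agrees with the basic-solution enumeration oracle", {
  set.seed(101)
  for (rep in 1:25) {
    lp <- random_toy_lp(n_rxns = sample(5:8, 1), n_mets = sample(2:4, 1))
    res <- .simplex_lp(lp$A, lp$b, lp$lb, lp$ub, lp$cc, TRUE)
    oracle <- enum_lp_max(lp$A, lp$b, lp$lb, lp$ub, lp$cc)
    expect_equal(res$status, 0)
    expect_equal(res$objective, oracle, tolerance = 1e-6)
  }
})

test_that("the multi-objective sweep equals one-shot solves", {
  sim <- cached_sim(30, 7)
  wbm <- sole_producer_wbm(0.25, sim = sim)
  for (met in c("met_a", "host_only")) wbm <- add_demand_reaction(wbm, met)
  lp <- compile_lp(wbm)
  cols <- lp$rxn_index[paste0("DM_", c("dca_like", "met_a", "host_only"),
                              "[bc]")]
  multi <- .simplex_lp_multi(lp$A, lp$b, lp$lb, lp$ub, as.integer(cols))
  single <- vapply(cols, function(j) solve_compiled(lp, j)$objective, 0)
  expect_equal(multi$status, c(0L, 0L, 0L))
  expect_equal(unname(multi$objective), unname(single), tolerance = 1e-9)
})

test_that("optimal solutions satisfy steady state, bounds, and coupling", {
  wbm <- sole_producer_wbm(0.5)
  lp <- compile_lp(wbm)
  sol <- fba_max(wbm, "DM_dca_like[bc]", retain_flux = TRUE)
  v <- sol$flux
  # S v = 0 on the metabolite rows
  S <- lp$A[seq_along(lp$met_index), seq_len(lp$n_rxns)]
  expect_lt(max(abs(S %*% v)), 1e-6)
  expect_true(all(v >= wbm$reactions$lb - 1e-6))
  expect_true(all(v <= wbm$reactions$ub + 1e-6))
  cp <- wbm$coupling
  expect_true(all(abs(v[cp$reaction]) <= cp$C * v[cp$biomass] + 1e-6))
})

test_that("widening a bound never decreases a maximal demand flux", {
  set.seed(55)
  wbm <- sole_producer_wbm(0.25)
  base <- fba_max(wbm, "DM_dca_like[bc]")$objective
  for (i in sample(nrow(wbm$reactions), 8)) {
    w2 <- wbm
    w2$reactions$ub[i] <- w2$reactions$ub[i] + 50
    expect_gte(fba_max(w2, "DM_dca_like[bc]")$objective, base - 1e-9)
  }
})

test_that("predict_blood_fluxes fills layers, rounds, and subtracts by sex", {
  sim <- cached_sim(30, 7)
  pans <- sim$pan_models
  hosts <- purrr::map(sim$hosts, apply_diet, diet = sim$diet)
  mk <- function(a_dca, sex) {
    comm <- build_community(pans[c("sp_dca", "sp_bystander")],
                            c(sp_dca = a_dca, sp_bystander = 1 - a_dca))
    join_host_microbiome(hosts[[sex]], comm)
  }
  models <- list(s1 = mk(0.1, "female"), s2 = mk(0.2, "male"),
                 s3 = mk(0.4, "female"))
  fm <- predict_blood_fluxes(models, hosts,
                             c("dca_like", "met_a", "host_only"))
  # no microbial route in any sample -> scaled exactly 0
  expect_equal(unname(fm$scaled[, "met_a"]), c(0, 0, 0))
  expect_equal(unname(fm$scaled[, "host_only"]), c(0, 0, 0))
  # coupling-bound producer: scaled linear in abundance (1 : 2 : 4)
  expect_equal(unname(fm$scaled[, "dca_like"]), c(40, 80, 160))
  # germ-free layer follows each sample's sex
  expect_equal(unname(fm$germfree[, "host_only"]), rep(50, 3))
  # scaled = raw - germfree wherever both defined
  expect_equal(fm$scaled, round(fm$raw - fm$germfree, 6))
})

test_that("the fast abundance sweep equals the naive per-sample route", {
  sim <- cached_sim(30, 7)
  ma <- mapped_abundances(sim)
  sex <- setNames(sim$cohort$sex, sim$cohort$sample_id)
  mets <- sim$manifest$flux_metabolites
  fm <- pipeline_fluxes(sim$pan_models, ma$table, sex, sim$hosts, sim$diet,
                        mets)
  hosts <- purrr::map(sim$hosts, apply_diet, diet = sim$diet)
  for (i in c(1, 9, 23)) {
    sid <- ma$table$sample_id[i]
    av <- unlist(ma$table[i, setdiff(names(ma$table), "sample_id")])
    comm <- build_community(sim$pan_models[names(av)[av > 0]], av[av > 0])
    wbm <- join_host_microbiome(hosts[[sex[sid]]], comm)
    gf <- hosts[[sex[sid]]]
    for (met in mets) {
      wbm_d <- add_demand_reaction(wbm, met)
      gf_d <- add_demand_reaction(gf, met)
      naive <- round(fba_max(wbm_d, paste0("DM_", met, "[bc]"))$objective, 6) -
        round(fba_max(gf_d, paste0("DM_", met, "[bc]"))$objective, 6)
      expect_equal(unname(fm$scaled[sid, met]), round(naive, 6),
                   tolerance = 1e-9)
    }
  }
})

test_that("tidy and glance expose the flux matrix layers", {
  fm <- flux_matrix(matrix(c(1, 2, 0, 3), 2,
                           dimnames = list(c("a", "b"), c("x", "y"))))
  td <- tidy(fm)
  expect_equal(nrow(td), 4)
  expect_equal(td$scaled[td$sample == "b" & td$metabolite == "y"], 3)
  expect_equal(glance(fm)$n_masked, 0)
})
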
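mini_strain <- function(id, rxns) {
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, function(r) r$lb %||% 0, 0),
    ub = vapply(rxns, function(r) r$ub %||% 1e6, 0)
  )
  stoich <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })
  stoich_model(id, reactions, stoich, biomass = "bio")
}

r_bio <- list(id = "bio", stoich = c("S[c]" = -1, "biomass[c]" = 1))
r_up <- list(id = "up", stoich = c("fiber[luM]" = -1, "S[c]" = 1))

test_that("pan model is the union of strain reactions", {
  s1 <- mini_strain("st1", list(r_bio, r_up,
                                list(id = "R1", stoich = c("S[c]" = -1,
                                                           "P[c]" = 1))))
  s2 <- mini_strain("st2", list(r_bio, r_up,
                                list(id = "R3", stoich = c("S[c]" = -1,
                                                           "Q[c]" = 1))))
  pan <- build_pan_species(list(s1, s2))
  expect_setequal(pan$reactions$id, c("bio", "up", "R1", "R3"))
  expect_identical(build_pan_species(list(s1)), s1)
})

test_that("duplicate reactions take the widest bounds; conflicts are named", {
  s1 <- mini_strain("st1", list(r_bio, modifyList(r_up, list(lb = 0, ub = 10))))
  s2 <- mini_strain("st2", list(r_bio, modifyList(r_up, list(lb = -5, ub = 8))))
  pan <- build_pan_species(list(s1, s2))
  up <- pan$reactions[pan$reactions$id == "up", ]
  # interval-union oracle over observed strain bounds
  expect_equal(c(up$lb, up$ub), c(min(0, -5), max(10, 8)))

  s3 <- mini_strain("st3", list(r_bio, list(id = "up",
                                            stoich = c("fiber[luM]" = -2,
                                                       "S[c]" = 1))))
  expect_error(build_pan_species(list(s1, s3)), "st1.*st3")
})

test_that("community construction validates abundances and builds communityBiomass", {
  pans <- cached_sim(30, 7)$pan_models
  expect_error(build_community(pans, c(sp_dca = 0.5, sp_chain = 0.4)),
               "sum to 1")
  comm <- build_community(pans, c(sp_dca = 0.25, sp_chain = 0.75,
                                  sp_cap = 0))
  expect_setequal(comm$members$species, c("sp_dca", "sp_chain"))
  cb <- comm$stoich[comm$stoich$reaction == "communityBiomass", ]
  expect_equal(
    cb$coef[match(c("sp_dca__biomass[c]", "sp_chain__biomass[c]",
                    "microbiota_LI_biomass[luM]"), cb$metabolite)],
    c(-0.25, -0.75, 1))
  # every member reaction except its biomass is coupled at C = 400
  expect_true(all(comm$coupling$C == 400))
  expect_setequal(
    comm$coupling$reaction,
    setdiff(grep("^sp_", comm$reactions$id, value = TRUE),
            c("sp_dca__bio", "sp_chain__bio")))
})

test_that("pinned community flux forces each biomass to its abundance", {
  sim <- cached_sim(30, 7)
  comm <- build_community(sim$pan_models[c("sp_dca", "sp_null1")],
                          c(sp_dca = 0.3, sp_null1 = 0.7))
  host <- apply_diet(toy_host_model("female"), sim$diet)
  wbm <- join_host_microbiome(host, comm)
  sol <- fba_max(wbm, "communityBiomass", retain_flux = TRUE)
  expect_equal(sol$status, "optimal")
  # excretion pinned at 1 -> communityBiomass flux 1 -> v_bio,k = a_k
  expect_equal(unname(sol$flux[["communityBiomass"]]), 1, tolerance = 1e-9)
  expect_equal(unname(sol$flux[["sp_dca__bio"]]), 0.3, tolerance = 1e-9)
  expect_equal(unname(sol$flux[["sp_null1__bio"]]), 0.7, tolerance = 1e-9)
})

test_that("sole-producer secretion is capped by coupling at C * a_k", {
  wbm <- sole_producer_wbm(0.25)
  expect_equal(fba_max(wbm, "DM_dca_like[bc]")$objective, 100,
               tolerance = 1e-9)
})

test_that("join preserves sex and pins the excretion and objective reactions", {
  sim <- cached_sim(30, 7)
  comm <- build_community(sim$pan_models["sp_dca"], c(sp_dca = 1))
  wbm <- join_host_microbiome(apply_diet(toy_host_model("male"), sim$diet),
                              comm)
  expect_equal(wbm$sex, "male")
  rx <- wbm$reactions
  for (rid in c("Excretion_EX_microbiota_LI_biomass[fe]",
                "Whole_body_objective_rxn")) {
    expect_equal(rx$lb[rx$id == rid], 1)
    expect_equal(rx$ub[rx$id == rid], 1)
  }
  expect_error(
    join_host_microbiome(bottleneck_model(), comm),
    "large-intestinal lumen")
})

test_that("removing the community restores the germ-free host exactly", {
  sim <- cached_sim(30, 7)
  host <- apply_diet(toy_host_model("female"), sim$diet)
  comm <- build_community(sim$pan_models[c("sp_dca", "sp_chain")],
                          c(sp_dca = 0.5, sp_chain = 0.5))
  back <- remove_community(join_host_microbiome(host, comm))
  expect_equal(back$reactions, host$reactions)
  expect_equal(back$stoich, host$stoich)
  expect_equal(back$sex, host$sex)
})

test_that("host-only metabolites see the same maximum with or without microbes", {
  sim <- cached_sim(30, 7)
  host <- apply_diet(toy_host_model("female"), sim$diet)
  gf <- add_demand_reaction(host, "host_only")
  wbm <- sole_producer_wbm(0.25)
  wbm <- add_demand_reaction(wbm, "host_only")
  expect_equal(fba_max(wbm, "DM_host_only[bc]")$objective,
               fba_max(gf, "DM_host_only[bc]")$objective,
               tolerance = 1e-9)
})

test_that("a species without a route to a metabolite never changes its maximum", {
  sim <- cached_sim(30, 7)
  pans <- sim$pan_models
  host <- apply_diet(toy_host_model("female"), sim$diet)
  with_by <- build_community(pans[c("sp_dca", "sp_bystander")],
                             c(sp_dca = 0.25, sp_bystander = 0.75))
  just_null <- build_community(pans[c("sp_dca", "sp_null1")],
                               c(sp_dca = 0.25, sp_null1 = 0.75))
  f1 <- fba_max(add_demand_reaction(join_host_microbiome(host, with_by),
                                    "dca_like"), "DM_dca_like[bc]")
  f2 <- fba_max(add_demand_reaction(join_host_microbiome(host, just_null),
                                    "dca_like"), "DM_dca_like[bc]")
  expect_equal(f1$objective, f2$objective, tolerance = 1e-9)
})

test_that("namespacing leaves no id collisions after joining", {
  sim <- cached_sim(30, 7)
  comm <- build_community(sim$pan_models,
                          setNames(rep(1 / 7, 7), names(sim$pan_models)))
  wbm <- join_host_microbiome(apply_diet(toy_host_model("female"), sim$diet),
                              comm)
  expect_false(anyDuplicated(wbm$reactions$id) > 0)
  expect_false(anyDuplicated(wbm$metabolites$id) > 0)
})

test_that("positive abundance without a biomass reaction is a hard error", {
  nobio <- stoich_model(
    "nobio",
    tibble::tibble(id = "up", lb = 0, ub = 1),
    tibble::tibble(reaction = "up", metabolite = c("fiber[luM]", "S[c]"),
                   coef = c(-1, 1)))
  expect_error(build_community(list(bad = nobio), c(bad = 1)),
               "no biomass reaction")
})
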
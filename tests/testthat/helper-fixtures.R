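# Shared fixtures. The moderately sized simulation is cached per test run:
# several files check different planted facts against the same draw.

tiny_config <- function(n = 30, seed = 7, ...) {
  effect_config(n_samples = n, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_sim <- function(n = 500, seed = 42) {
  key <- sprintf("sim_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cohort(effect_config(n_samples = n,
                                                           seed = seed))
  }
  .fixture_cache[[key]]
}

# map + renormalize a simulated cohort's abundances
mapped_abundances <- function(sim, threshold = 1e-6) {
  filt <- filter_species_level(sim$abundance, threshold = threshold)
  mp <- map_to_resource(filt, sim$manifest$resource_species,
                        threshold = threshold)
  list(table = renormalize_abundances(mp$table, threshold = threshold),
       report = mp$report)
}

# a minimal two-reaction model: source (bounded) -> A -> sink
bottleneck_model <- function(src_ub = 5) {
  stoich_model(
    "bottleneck",
    tibble::tibble(id = c("src", "snk"), lb = c(0, 0), ub = c(src_ub, 1e6)),
    tibble::tibble(reaction = c("src", "snk"),
                   metabolite = c("A[c]", "A[c]"), coef = c(1, -1))
  )
}

# host + single-producer community at abundance a, diet applied, demand added
sole_producer_wbm <- function(a, C = 400, sim = NULL) {
  sim <- sim %||% cached_sim(30, 7)
  pans <- sim$pan_models
  ab <- if (a < 1) c(sp_dca = a, sp_bystander = 1 - a) else c(sp_dca = 1)
  comm <- build_community(pans[names(ab)], ab, C = C)
  host <- apply_diet(toy_host_model("female"), sim$diet)
  wbm <- join_host_microbiome(host, comm)
  add_demand_reaction(wbm, "dca_like")
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
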
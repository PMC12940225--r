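#' Configuration for the synthetic cohort generator
#'
#' Defines every planted ground-truth effect the generator emits, so each
#' downstream stage can be tested against a known answer. Defaults emulate
#' the study conditions of an aging population cohort with 16S-derived
#' species abundances: cohort size, sex split, APOE genotype frequencies,
#' education distribution, per-sample read coverage at the species level and
#' after resource mapping, and a small planted effect battery (one driver
#' species whose abundance rises with age, an APOE-shifted species, a strict
#' two-step production chain, a bound-limited secretion, and metabolomics
#' batch/missingness/CV structure).
#'
#' @param n_samples cohort size (>= 2), default 500.
#' @param seed master seed; every output artifact draws from its own named
#'   substream derived from it.
#' @param age_slope planted standardized slope of the driver species'
#'   log-abundance on age, default 0.3.
#' @param apoe_multiplier per-risk-group abundance multiplier planted on the
#'   driver species (named E2/E3/E4).
#' @param sex_fraction proportion of female samples, default 608/1065.
#' @param species_coverage_mean,species_coverage_sd per-sample fraction of
#'   reads resolved at species rank (defaults 0.495 and 0.097).
#' @param mapped_share_mean,mapped_share_sd per-sample fraction of species
#'   reads that map to the reconstruction resource (defaults 0.6402, 0.1163).
#' @param abund_sdlog log-scale SD of species base abundances.
#' @param n_unmapped_species,n_higher_taxa counts of unmapped species-rank
#'   pseudo-taxa and of higher-rank (genus-level) taxa.
#' @param coupling_C community coupling factor, default 400.
#' @param n_mets number of ordinary metabolomics compounds (three planted
#'   special compounds are added on top).
#' @param n_batches,batch_scale metabolomics batch count and multiplicative
#'   scale factors.
#' @param missingness_rate missing-at-random entry rate; the planted
#'   missingness outlier sample gets 10x this rate, and all planted
#'   missingness is disabled when the rate is 0.
#' @param n_aliquot_groups number of samples measured as replicate aliquot
#'   pairs (for the CV filter).
#' @param met_shift_log2 planted log2 shift of compound `met_shift` in the
#'   APOE E4 risk group.
#' @param n_subtests,cognition_loading cognitive subtest count and their
#'   common loading on the latent factor (0.69 reproduces a first principal
#'   component explaining about 47% of subtest variance at 5 subtests).
#' @param n_snps number of risk SNPs for the polygenic score.
#' @param apoe_freqs named genotype frequencies (defaults match the cohort
#'   table: E2/E2, E2/E3, E2/E4, E3/E3, E3/E4, E4/E4).
#' @param education_probs probabilities of the four ordinal education levels.
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate marginals.
#' @return an `effect_config` list.
#' @export
effect_config <- function(n_samples = 500, seed = 1,
                          age_slope = 0.3,
                          apoe_multiplier = c(E2 = 0.8, E3 = 1, E4 = 1.25),
                          sex_fraction = 608 / 1065,
                          species_coverage_mean = 0.495,
                          species_coverage_sd = 0.097,
                          mapped_share_mean = 0.6402,
                          mapped_share_sd = 0.1163,
                          abund_sdlog = 1,
                          n_unmapped_species = 3, n_higher_taxa = 3,
                          coupling_C = 400,
                          n_mets = 30, n_batches = 2,
                          batch_scale = c(1, 2.5),
                          missingness_rate = 0.05,
                          n_aliquot_groups = 3,
                          met_shift_log2 = 1.0,
                          n_subtests = 5, cognition_loading = 0.69,
                          n_snps = 28,
                          apoe_freqs = c(`E2/E2` = 5, `E2/E3` = 121,
                                         `E2/E4` = 25, `E3/E3` = 644,
                                         `E3/E4` = 251, `E4/E4` = 19) / 1065,
                          education_probs = c(62, 348, 320, 332) / 1062,
                          age_mean = 61.65, age_sd = 5.4,
                          bmi_mean = 27.4, bmi_sd = 4.5) {
  cfg <- as.list(environment())
  if (n_samples < 2) abort_gf("n_samples must be >= 2", "config_error")
  props <- c(sex_fraction, missingness_rate, species_coverage_mean,
             mapped_share_mean)
  if (any(props < 0 | props > 1)) {
    abort_gf("proportions must lie in [0, 1]", "config_error")
  }
  if (length(batch_scale) != n_batches) {
    abort_gf("batch_scale must have one factor per batch", "config_error")
  }
  if (abs(sum(apoe_freqs) - 1) > 1e-6 || abs(sum(education_probs) - 1) > 1e-6) {
    abort_gf("apoe_freqs and education_probs must sum to 1", "config_error")
  }
  structure(cfg, class = "effect_config")
}

# the toy species universe: who produces what, at which yield, under which
# secretion cap; driver/chain/cap roles are fixed by name
species_spec <- function(config) {
  tibble::tribble(
    ~species,       ~mu,  ~role,
    "sp_dca",       0.0,  "driver",
    "sp_chain",     0.3,  "chain",
    "sp_null1",     0.0,  "null",
    "sp_null2",    -0.2,  "null",
    "sp_null3",     0.2,  "null",
    "sp_cap",       0.8,  "cap",
    "sp_bystander", 1.0,  "none"
  )
}

toy_products <- function() {
  list(
    sp_dca = list(list(met = "dca_like", yield = 1, sec_ub = 1e6)),
    sp_chain = list(list(met = "met_a", yield = 1, sec_ub = 1e6),
                    list(met = "met_b", yield = 0.5, sec_ub = 1e6,
                         from = "met_a")),
    sp_null1 = list(list(met = "null_m1", yield = 1, sec_ub = 1e6)),
    sp_null2 = list(list(met = "null_m2", yield = 1, sec_ub = 1e6)),
    sp_null3 = list(list(met = "null_m3", yield = 1, sec_ub = 1e6)),
    sp_cap = list(list(met = "cap_like", yield = 1, sec_ub = 10)),
    sp_bystander = list()
  )
}

# one strain model; variant 2 narrows a bound and adds a strain-unique
# dead-end storage reaction, so the pan union has real work to do
toy_strain_model <- function(species, products, variant) {
  up_ub <- if (variant == 2) 5e5 else 1e6
  rxns <- list(
    list(id = "up_bio", lb = 0, ub = up_ub,
         stoich = c("fiber[luM]" = -1, "bsub[c]" = 1)),
    list(id = "bio", lb = 0, ub = 1e6,
         stoich = c("bsub[c]" = -1, "biomass[c]" = 1))
  )
  for (p in products) {
    if (is.null(p$from)) {
      sub <- paste0("psub_", p$met, "[c]")
      rxns <- c(rxns, list(
        list(id = paste0("up_", p$met), lb = 0, ub = up_ub,
             stoich = setNames(c(-1, 1), c("fiber[luM]", sub))),
        list(id = paste0("conv_", p$met), lb = 0, ub = 1e6,
             stoich = setNames(c(-1, p$yield),
                               c(sub, paste0(p$met, "[c]"))))
      ))
    } else {
      rxns <- c(rxns, list(
        list(id = paste0("conv_", p$met), lb = 0, ub = 1e6,
             stoich = setNames(c(-1, p$yield),
                               c(paste0(p$from, "[c]"),
                                 paste0(p$met, "[c]"))))
      ))
    }
    rxns <- c(rxns, list(
      list(id = paste0("ex_", p$met), lb = 0, ub = p$sec_ub,
           stoich = setNames(c(-1, 1),
                             c(paste0(p$met, "[c]"),
                               paste0(p$met, "[luM]"))))
    ))
  }
  if (variant == 2) {
    rxns <- c(rxns, list(
      list(id = "store", lb = 0, ub = 1e6,
           stoich = c("bsub[c]" = -1, "store[c]" = 1))
    ))
  }
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub")
  )
  stoich <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })
  stoich_model(paste0(species, "_strain", variant), reactions, stoich,
               biomass = "bio")
}

#' Generate toy strain reconstructions with planted producers
#'
#' Emits two strain models per species of the default toy universe: a sole
#' producer of a secondary-bile-acid-like compound (`sp_dca` -> `dca_like`,
#' the single-driver ground truth), a species carrying a strict two-step
#' chain (`met_a` -> 0.5 `met_b`, the grouping ground truth), three null
#' producers, a producer whose secretion is capped at 10 mmol/day/person
#' (bound-limited ground truth), and a bystander without products. Each model
#' consumes a shared lumen substrate (`fiber[luM]`) through a dedicated
#' uptake per pathway and has a flagged biomass reaction. Output is fully
#' deterministic.
#'
#' @param config an [effect_config()].
#' @return named list: species -> list of strain `stoich_model`s, with a
#'   `manifest` attribute recording the planted facts.
#' @export
generate_toy_reconstructions <- function(config) {
  spp <- species_spec(config)
  prods <- toy_products()
  if (!all(names(prods) %in% spp$species)) {
    abort_gf("product map references undefined species", "config_error")
  }
  strains <- purrr::map(setNames(spp$species, spp$species), function(sp) {
    list(toy_strain_model(sp, prods[[sp]], 1),
         toy_strain_model(sp, prods[[sp]], 2))
  })
  producers <- purrr::imap(prods, function(ps, sp) {
    vapply(ps, `[[`, "", "met")
  })
  manifest <- list(
    species = spp$species,
    producers = purrr::map(
      setNames(unlist(producers), unlist(producers)),
      function(met) names(producers)[vapply(producers, function(x) met %in% x,
                                            TRUE)]),
    sole_producer = list(metabolite = "dca_like", species = "sp_dca"),
    chain = list(precursor = "met_a", product = "met_b", yield = 0.5,
                 species = "sp_chain"),
    bound_limited = list(metabolite = "cap_like", cap = 10),
    host_only_metabolite = "host_only",
    coupling_C = config$coupling_C
  )
  attr(strains, "manifest") <- manifest
  strains
}

#' Toy germ-free host whole-body model
#'
#' A minimal multi-compartment host: dietary exchanges on `[d]`, transports
#' into the large-intestinal lumen `[luLI]`, absorption of each microbial
#' product from `[luLI]` into blood `[bc]`, a host-only blood metabolite fed
#' by a dedicated dietary substrate that microbes cannot consume, and a
#' `Whole_body_objective_rxn` pinned to 1 mmol/day/person.
#'
#' @param sex `"female"` or `"male"` tag.
#' @param microbial_mets blood metabolites the microbiota may supply.
#' @return a `stoich_model`.
#' @export
toy_host_model <- function(sex = c("female", "male"),
                           microbial_mets = c("dca_like", "met_a", "met_b",
                                              "null_m1", "null_m2", "null_m3",
                                              "cap_like")) {
  sex <- match.arg(sex)
  rxns <- list(
    list(id = "EX_fiber[d]", lb = -1e6, ub = 0, stoich = c("fiber[d]" = -1)),
    list(id = "EX_hsub[d]", lb = -1e6, ub = 0, stoich = c("hsub[d]" = -1)),
    list(id = "EX_unused[d]", lb = -1e6, ub = 1e6,
         stoich = c("unused[d]" = -1)),
    list(id = "t_fiber", lb = 0, ub = 1e6,
         stoich = c("fiber[d]" = -1, "fiber[luLI]" = 1)),
    list(id = "t_hsub", lb = 0, ub = 1e6,
         stoich = c("hsub[d]" = -1, "hsub[luLI]" = 1)),
    list(id = "host_energy", lb = 0, ub = 1e6,
         stoich = c("fiber[luLI]" = -1, "energy[bc]" = 1)),
    list(id = "Whole_body_objective_rxn", lb = 1, ub = 1,
         stoich = c("energy[bc]" = -1)),
    list(id = "host_met", lb = 0, ub = 1e6,
         stoich = c("hsub[luLI]" = -1, "host_only[bc]" = 1))
  )
  for (met in microbial_mets) {
    rxns <- c(rxns, list(
      list(id = paste0("t_", met), lb = 0, ub = 1e6,
           stoich = setNames(c(-1, 1),
                             c(paste0(met, "[luLI]"), paste0(met, "[bc]"))))
    ))
  }
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub")
  )
  stoich <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })
  stoich_model(paste0("host_", sex), reactions, stoich, sex = sex)
}

#' Toy diet
#'
#' Dietary flux bounds (mmol/day/person) for the toy host: ample shared
#' substrate for the microbiota plus the host-only substrate.
#'
#' @return tibble with columns `metabolite` and `flux`.
#' @export
toy_diet <- function() {
  tibble::tibble(metabolite = c("fiber", "hsub"), flux = c(5000, 50))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# shared cohort draw: both the abundance and the metabolomics generators
# need the same covariates, so the cohort has its own substream
gen_cohort <- function(config) {
  with_substream(config$seed, "cohort", {
    n <- config$n_samples
    sex <- ifelse(runif(n) < config$sex_fraction, "female", "male")
    apoe <- sample(names(config$apoe_freqs), n, replace = TRUE,
                   prob = config$apoe_freqs)
    f <- rnorm(n)  # latent cognition factor
    subtests <- sapply(seq_len(config$n_subtests), function(j) {
      config$cognition_loading * f + rnorm(n)
    })
    colnames(subtests) <- sprintf("subtest_%d", seq_len(config$n_subtests))
    snp_p <- runif(config$n_snps, 0.1, 0.9)
    dosages <- sapply(seq_len(config$n_snps), function(j) {
      rbinom(n, 2, snp_p[j])
    })
    colnames(dosages) <- sprintf("snp_%02d", seq_len(config$n_snps))
    snp_weights <- rnorm(config$n_snps, 0, 0.15)

    cohort <- dplyr::bind_cols(
      tibble::tibble(
        sample_id = sprintf("S%04d", seq_len(n)),
        age = rnorm(n, config$age_mean, config$age_sd),
        sex = sex,
        bmi = rnorm(n, config$bmi_mean, config$bmi_sd),
        education = sample(1:4, n, replace = TRUE,
                           prob = config$education_probs),
        apoe_genotype = apoe
      ),
      tibble::as_tibble(subtests),
      tibble::as_tibble(dosages)
    )
    list(cohort = cohort,
         snp_weights = setNames(snp_weights,
                                sprintf("snp_%02d", seq_len(config$n_snps))),
         latent_cognition = f)
  })
}

#' Generate a raw relative-abundance table with planted effects
#'
#' Species base abundances are log-normal; the planted age effect adds
#' `age_slope * z(age)` and the APOE shift adds `log(multiplier)` to the
#' driver species on the log scale before closure to the simplex, so
#' monotone covariate-abundance links survive renormalization. Each sample
#' assigns a share of reads to higher-rank (genus-level) taxa and, within
#' species-rank reads, to unmapped pseudo-species, emulating read coverage
#' statistics of species filtering and resource mapping. Rows sum to one
#' exactly.
#'
#' @param config an [effect_config()].
#' @param models output of [generate_toy_reconstructions()] (defines the
#'   mapped species set).
#' @return tibble `sample_id` + taxon columns, with `taxa` (rank metadata)
#'   and `manifest` attributes.
#' @export
generate_abundance_table <- function(config, models) {
  spp <- species_spec(config)
  ch <- gen_cohort(config)$cohort
  n <- config$n_samples
  with_substream(config$seed, "abundance", {
    z_age <- zstd(ch$age)
    logw <- matrix(rnorm(n * nrow(spp), 0, config$abund_sdlog), n) +
      matrix(spp$mu, n, nrow(spp), byrow = TRUE)
    colnames(logw) <- spp$species
    logw[, "sp_dca"] <- logw[, "sp_dca"] + config$age_slope * z_age
    grp <- apoe_groups(ch$apoe_genotype)
    mult <- config$apoe_multiplier
    shift <- ifelse(grp %in% names(mult), log(mult[grp]), 0)
    logw[, "sp_dca"] <- logw[, "sp_dca"] + shift

    w <- exp(logw)
    w_un <- matrix(exp(rnorm(n * config$n_unmapped_species)), n)
    w_hi <- matrix(exp(rnorm(n * config$n_higher_taxa)), n)

    species_cov <- rtrunc_norm(n, config$species_coverage_mean,
                               config$species_coverage_sd, 0.05, 0.95)
    mapped_share <- rtrunc_norm(n, config$mapped_share_mean,
                                config$mapped_share_sd, 0.05, 0.95)

    mapped <- species_cov * mapped_share * w / rowSums(w)
    unmapped <- species_cov * (1 - mapped_share) * w_un / rowSums(w_un)
    higher <- (1 - species_cov) * w_hi / rowSums(w_hi)

    un_names <- sprintf("unmapped_sp%d", seq_len(config$n_unmapped_species))
    hi_names <- sprintf("genus_g%d", seq_len(config$n_higher_taxa))
    colnames(unmapped) <- un_names
    colnames(higher) <- hi_names

    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = ch$sample_id),
      tibble::as_tibble(mapped), tibble::as_tibble(unmapped),
      tibble::as_tibble(higher)
    )
    attr(out, "taxa") <- tibble::tibble(
      taxon = c(spp$species, un_names, hi_names),
      rank = c(rep("species", nrow(spp) + length(un_names)),
               rep("genus", length(hi_names)))
    )
    attr(out, "manifest") <- list(
      resource_species = spp$species,
      unmapped_species = un_names,
      higher_taxa = hi_names,
      species_coverage_mean = config$species_coverage_mean,
      mapped_share_mean = config$mapped_share_mean,
      age_effect = list(covariate = "age", species = "sp_dca",
                        slope = config$age_slope),
      apoe_shift = list(species = "sp_dca",
                        multiplier = as.list(config$apoe_multiplier))
    )
    out
  })
}

#' Generate cohort covariates and raw metabolomics with planted QC structure
#'
#' The cohort table carries age, sex, BMI, ordinal education, APOE genotype,
#' cognitive subtests loading on one latent factor, and per-SNP allelic
#' dosages in `[0,2]`. The metabolomics table carries positive peak
#' intensities with multiplicative batch scale factors, missing entries at
#' the configured rate, replicate-aliquot rows for CV computation, and three
#' planted QC targets: a sample with tenfold missingness, a compound missing
#' in 80% of samples, and a compound whose replicate aliquots differ by a
#' factor 1.65 (CV about 0.347). A log2 shift is planted on compound
#' `met_shift` in the APOE E4 risk group. All planted missingness scales
#' with `missingness_rate` and vanishes when it is zero.
#'
#' @param config an [effect_config()].
#' @return list with `cohort`, `metabolomics`, and `manifest`.
#' @export
generate_covariates_and_metabolomics <- function(config) {
  ch <- gen_cohort(config)
  cohort <- ch$cohort
  n <- config$n_samples

  met_names <- c(sprintf("met_%02d", seq_len(config$n_mets)),
                 "met_shift", "met_highmiss", "met_highcv")
  M <- length(met_names)

  metab <- with_substream(config$seed, "metabolomics", {
    base <- rnorm(M, 12, 1)
    x <- matrix(rnorm(n * M, 0, 0.7), n, M) +
      matrix(base, n, M, byrow = TRUE)
    colnames(x) <- met_names
    grp <- apoe_groups(cohort$apoe_genotype)
    x[grp == "E4", "met_shift"] <- x[grp == "E4", "met_shift"] +
      config$met_shift_log2

    batch <- sample(seq_len(config$n_batches), n, replace = TRUE)
    rep_ids <- cohort$sample_id[sample.int(n, config$n_aliquot_groups)]
    outlier_id <- setdiff(cohort$sample_id, rep_ids)[1]

    rows <- tibble::tibble(
      sample_id = cohort$sample_id, aliquot = "A",
      aliquot_group = ifelse(cohort$sample_id %in% rep_ids,
                             cohort$sample_id, NA_character_),
      batch = batch, idx = seq_len(n)
    )
    reps <- rows[rows$sample_id %in% rep_ids, ]
    reps$aliquot <- "B"
    rows <- dplyr::bind_rows(rows, reps)

    intens <- 2^x[rows$idx, , drop = FALSE]
    # replicate aliquots re-measure the same sample with small technical noise
    is_b <- rows$aliquot == "B"
    intens[is_b, ] <- intens[is_b, ] *
      exp(matrix(rnorm(sum(is_b) * M, 0, 0.02), sum(is_b), M))
    # planted high-CV compound: aliquot B reads 1.65x aliquot A
    intens[is_b, "met_highcv"] <- 2^x[rows$idx[is_b], "met_highcv"] * 1.65
    intens[!is_b & !is.na(rows$aliquot_group), "met_highcv"] <-
      2^x[rows$idx[!is_b & !is.na(rows$aliquot_group)], "met_highcv"]
    intens <- intens * config$batch_scale[rows$batch]

    rate <- config$missingness_rate
    miss <- matrix(runif(nrow(intens) * M) < rate, nrow(intens), M)
    if (rate > 0) {
      miss[rows$sample_id == outlier_id & rows$aliquot == "A", ] <-
        runif(M) < min(1, 10 * rate)
      miss[, met_names == "met_highmiss"] <- runif(nrow(intens)) < 0.8
    }
    intens[miss] <- NA_real_

    out <- dplyr::bind_cols(
      rows[, c("sample_id", "aliquot", "aliquot_group", "batch")],
      tibble::as_tibble(intens)
    )
    list(table = out, outlier_id = outlier_id, rep_ids = rep_ids)
  })

  manifest <- list(
    snp_weights = as.list(ch$snp_weights),
    cognition = list(n_subtests = config$n_subtests,
                     loading = config$cognition_loading),
    batch_scale = config$batch_scale,
    qc_targets = list(
      missingness_outlier_sample = if (config$missingness_rate > 0)
        metab$outlier_id else NULL,
      high_missing_metabolite = if (config$missingness_rate > 0)
        "met_highmiss" else NULL,
      high_cv_metabolite = "met_highcv",
      replicate_aliquot_samples = metab$rep_ids
    ),
    planted_group_difference = list(metabolite = "met_shift",
                                    group = "apoe_group", level = "E4",
                                    log2_shift = config$met_shift_log2)
  )
  list(cohort = cohort, metabolomics = metab$table, manifest = manifest)
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator under the master seed and assembles the
#' machine-readable manifest of planted ground truths used by the recovery
#' tests: producer identities, the chain coupling, planted covariate
#' effects, QC targets, and the resource species set.
#'
#' @param config an [effect_config()].
#' @return list of class `synthetic_cohort`: `strains`, `pan_models`,
#'   `abundance`, `cohort`, `metabolomics`, `hosts`, `diet`, `manifest`.
#' @export
simulate_cohort <- function(config = effect_config()) {
  strains <- generate_toy_reconstructions(config)
  pans <- purrr::imap(strains, function(ss, sp) build_pan_species(ss, id = sp))
  abundance <- generate_abundance_table(config, strains)
  cm <- generate_covariates_and_metabolomics(config)
  mets <- unique(unlist(purrr::map(toy_products(),
                                   ~ vapply(.x, `[[`, "", "met"))))
  hosts <- list(female = toy_host_model("female", mets),
                male = toy_host_model("male", mets))
  manifest <- c(attr(strains, "manifest"),
                attr(abundance, "manifest"),
                cm$manifest,
                list(flux_metabolites = c(mets, "host_only"),
                     seed = config$seed, n_samples = config$n_samples))
  structure(list(strains = strains, pan_models = pans, abundance = abundance,
                 cohort = cm$cohort, metabolomics = cm$metabolomics,
                 hosts = hosts, diet = toy_diet(), manifest = manifest),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Abundances, covariates, and metabolomics as TSV; models as COBRA-style
#' JSON; the ground-truth manifest as JSON.
#'
#' @param sim a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$abundance, file.path(dir, "abundances.tsv"))
  readr::write_tsv(attr(sim$abundance, "taxa"), file.path(dir, "taxa.tsv"))
  readr::write_tsv(sim$cohort, file.path(dir, "cohort.tsv"))
  readr::write_tsv(sim$metabolomics, file.path(dir, "metabolomics.tsv"))
  readr::write_tsv(sim$diet, file.path(dir, "diet.tsv"))
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  purrr::iwalk(sim$pan_models, function(m, sp) {
    write_model_json(m, file.path(mdir, paste0(sp, ".json")))
  })
  purrr::iwalk(sim$hosts, function(h, sx) {
    write_model_json(h, file.path(mdir, paste0("host_", sx, ".json")))
  })
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
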
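#' Pipeline configuration
#'
#'  Collects every stage threshold with its conventional default: the 1e-6
#'  abundance floor, coupling factor 400, six-decimal flux rounding with the
#'  1e-6 identity tolerance, the 90% zero/identical refinement fractions, the
#'  0.999 R-squared grouping threshold, the metabolomics 70% missingness and
#'  30% CV filters with mean + 5 SD sample exclusion and 10-neighbour KNN
#'  imputation, plus the synthetic-cohort effect configuration. Round-trips
#'  losslessly through JSON (see [write_pipeline_config()]).
#'
#' @param n_samples,seed cohort size and master seed (forwarded to
#'   [effect_config()] unless `effect` is supplied).
#' @param coupling_C community coupling factor.
#' @param abundance_floor relative-abundance floor.
#' @param zero_frac,ident_frac,flux_tol,r2_threshold flux refinement and
#'   grouping thresholds.
#' @param missing_frac,cv_max,k_sd,knn_k metabolomics QC thresholds.
#' @param diet_file optional path to a diet TSV (`metabolite`, `flux`);
#'   defaults to the built-in [toy_diet()].
#' @param effect an [effect_config()]; built from `n_samples`/`seed` when
#'   omitted.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_samples = 500, seed = 1, coupling_C = 400,
                            abundance_floor = 1e-6,
                            zero_frac = 0.9, ident_frac = 0.9,
                            flux_tol = 1e-6, r2_threshold = 0.999,
                            missing_frac = 0.7, cv_max = 0.30, k_sd = 5,
                            knn_k = 10, diet_file = NULL, effect = NULL) {
  effect <- effect %||% effect_config(n_samples = n_samples, seed = seed,
                                      coupling_C = coupling_C)
  structure(list(
    n_samples = effect$n_samples, seed = effect$seed,
    coupling_C = effect$coupling_C,
    abundance_floor = abundance_floor, zero_frac = zero_frac,
    ident_frac = ident_frac, flux_tol = flux_tol,
    r2_threshold = r2_threshold, missing_frac = missing_frac,
    cv_max = cv_max, k_sd = k_sd, knn_k = knn_k,
    diet_file = diet_file, effect = effect
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$effect <- unclass(obj$effect)
  # named vectors become JSON objects so their names survive the round trip
  for (fld in c("apoe_multiplier", "apoe_freqs")) {
    obj$effect[[fld]] <- as.list(obj$effect[[fld]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- obj$effect
  for (fld in c("apoe_multiplier", "apoe_freqs")) {
    eff[[fld]] <- unlist(eff[[fld]])
  }
  eff <- do.call(effect_config, eff[names(eff) %in% names(formals(effect_config))])
  obj$effect <- NULL
  obj$diet_file <- obj$diet_file %||% NULL
  do.call(pipeline_config, c(obj[names(obj) %in% names(formals(pipeline_config))],
                             list(effect = eff)))
}

#' Predict per-sample blood fluxes directly from abundances
#'
#' Equivalent to building each sample's community, joining it to the host,
#' and running [predict_blood_fluxes()], but exploits that the joined model
#' differs between samples only in the communityBiomass stoichiometric
#' coefficients (-a_k): the LP is compiled once per sex and that single
#' column is patched per sample. Results are identical to the per-sample
#' construction route.
#'
#' @param pan_models named list of pan `stoich_model`s.
#' @param abundances renormalized abundance tibble (`sample_id` + species
#'   columns summing to 1 per row).
#' @param sex named character vector (by sample id) of host sexes.
#' @param hosts list of germ-free hosts by sex.
#' @param diet diet tibble.
#' @param metabolites blood metabolite base names to maximise.
#' @param C coupling factor, default 400.
#' @return a `flux_matrix`.
#' @export
pipeline_fluxes <- function(pan_models, abundances, sex, hosts, diet,
                            metabolites, C = 400) {
  species <- setdiff(names(abundances), "sample_id")
  samples <- abundances$sample_id
  sexes <- sex[samples]
  amat <- as.matrix(abundances[, species, drop = FALSE])

  template <- build_community(
    pan_models, setNames(rep(1 / length(species), length(species)), species),
    C = C)
  bio_mets <- paste0(template$members$species, "__biomass[c]")

  lp_by_sex <- lapply(setNames(unique(sexes), unique(sexes)), function(sx) {
    wbm <- join_host_microbiome(apply_diet(hosts[[sx]], diet), template)
    for (met in metabolites) wbm <- add_demand_reaction(wbm, met)
    lp <- compile_lp(wbm)
    list(lp = lp,
         cb_col = lp$rxn_index[["communityBiomass"]],
         bio_rows = lp$met_index[bio_mets],
         dm_cols = lp$rxn_index[paste0("DM_", metabolites, "[bc]")])
  })
  order_species <- match(template$members$species, species)

  gf <- sapply(setNames(unique(sexes), unique(sexes)), function(sx) {
    h <- apply_diet(hosts[[sx]], diet)
    for (met in metabolites) h <- add_demand_reaction(h, met)
    lp <- compile_lp(h)
    vapply(metabolites, function(met) {
      sol <- solve_compiled(lp, lp$rxn_index[[paste0("DM_", met, "[bc]")]])
      if (sol$status != "optimal") {
        abort_gf(sprintf("germ-free model not optimal for %s", met),
                 "solver_error")
      }
      round6(sol$objective)
    }, 0)
  })
  gf <- matrix(gf, nrow = length(metabolites),
               dimnames = list(metabolites, unique(sexes)))

  raw <- matrix(NA_real_, length(samples), length(metabolites),
                dimnames = list(samples, metabolites))
  mask <- matrix(NA_character_, length(samples), length(metabolites),
                 dimnames = list(samples, metabolites))
  for (s in seq_along(samples)) {
    ctx <- lp_by_sex[[sexes[s]]]
    ctx$lp$A[cbind(ctx$bio_rows, ctx$cb_col)] <- -amat[s, order_species]
    res <- .simplex_lp_multi(ctx$lp$A, ctx$lp$b, ctx$lp$lb, ctx$lp$ub,
                             as.integer(ctx$dm_cols))
    if (any(res$status == 2)) {
      abort_gf(sprintf("unbounded demand flux in sample %s", samples[s]),
               "solver_error")
    }
    if (any(res$status != 0)) {
      mask[s, ] <- "infeasible"
    } else {
      raw[s, ] <- round6(res$objective)
    }
  }
  gf_layer <- t(gf)[sexes, , drop = FALSE]
  dimnames(gf_layer) <- dimnames(raw)
  scaled <- round6(raw - gf_layer)
  scaled[!is.na(mask)] <- NA_real_
  raw[!is.na(mask)] <- NA_real_
  new_flux_matrix(raw, gf_layer, scaled, mask, setNames(sexes, samples))
}

#' Association battery between fluxes and risk factors
#'
#' Runs the full statistical battery on a processed flux matrix: per
#' metabolite, (i) standardized linear regression of flux on age controlling
#' for sex, (ii) standardized regression of the global cognition score on
#' flux controlling for age, sex, BMI, and education, (iii) Wilcoxon
#' rank-sum between sexes, (iv) Kruskal-Wallis across APOE risk groups
#' (E2/E4 carriers excluded) with Dunn post-hoc pairs, and (v) the
#' flux-by-sex interaction model on global cognition. FDR adjustment is
#' applied per analysis family across metabolites (Kruskal-Wallis rows for
#' the APOE family; Dunn p-values stay unadjusted).
#'
#' @param fm a processed `flux_matrix`.
#' @param cohort cohort tibble (sample_id, age, sex, bmi, education,
#'   apoe_genotype, subtest columns).
#' @return named list of tidy association tibbles: `age`, `cognition`,
#'   `sex`, `apoe`, `interaction`.
#' @export
flux_association_battery <- function(fm, cohort) {
  sc <- masked_scaled(fm)
  cohort <- cohort[match(fm$samples, cohort$sample_id), ]
  subtests <- dplyr::select(cohort, dplyr::starts_with("subtest_"))
  cognition <- global_cognition(subtests)$score
  grp <- apoe_groups(cohort$apoe_genotype)

  per_met <- function(f) {
    purrr::map_dfr(seq_along(fm$metabolites), function(j) {
      res <- f(sc[, j])
      if (!is.null(res)) res$outcome_metabolite <- fm$metabolites[j]
      res
    })
  }
  fdr_by_family <- function(tb, tests = unique(tb$test)) {
    hit <- tb$test %in% tests
    tb$fdr[hit] <- bh_fdr(tb$p_value[hit])
    tb
  }

  age <- per_met(function(v) {
    d <- dplyr::mutate(cohort, flux = v)
    tryCatch(regress_outcome(d, "flux", "age", "sex"),
             error = function(e) NULL)
  }) |> fdr_by_family()

  cog <- per_met(function(v) {
    d <- dplyr::mutate(cohort, flux = v, cognition = cognition)
    tryCatch(regress_outcome(d, "cognition", "flux",
                             c("age", "sex", "bmi", "education")),
             error = function(e) NULL)
  }) |> fdr_by_family()

  sexw <- per_met(function(v) {
    tryCatch(wilcoxon_sex(v, cohort$sex), error = function(e) NULL)
  }) |> fdr_by_family()

  apoe <- per_met(function(v) {
    keep <- grp != "excluded"
    tryCatch(kruskal_dunn(v[keep], droplevels(grp[keep])),
             error = function(e) NULL)
  }) |> fdr_by_family(tests = "kruskal_wallis")

  inter <- per_met(function(v) {
    d <- dplyr::mutate(cohort, flux = v, cognition = cognition)
    tryCatch(interaction_analysis(d, "cognition", "flux"),
             error = function(e) NULL)
  }) |> fdr_by_family(tests = "interaction")

  list(age = age, cognition = cog, sex = sexw, apoe = apoe,
       interaction = inter)
}

stage_checksum <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  s <- if (is.data.frame(x)) {
    paste(unlist(lapply(x, function(col) {
      if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
    })), collapse = "|")
  } else {
    paste(deparse(x), collapse = "|")
  }
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1000000007
  h
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate, map, build+solve, flux processing, metabolomics QC,
#' and the association battery, returning all stage outputs plus a run
#' report (seed, thresholds, per-stage summary figures, and stage
#' checksums). A stage failure aborts with an error naming the stage;
#' upstream outputs computed so far are attached to the error condition.
#'
#' @param config a `pipeline_config` (or an `effect_config`, which is
#'   wrapped with default thresholds).
#' @param verbose print stage progress.
#' @return a `pipeline_result` list: `sim`, `mapping`, `abundances`, `fm`
#'   (raw flux matrix), `processed`, `groups`, `qc`, `associations`,
#'   `drivers`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  if (inherits(config, "effect_config")) {
    config <- pipeline_config(effect = config)
  }
  done <- list()
  stage <- function(name, code) {
    if (verbose) message("stage ", name)
    tryCatch(force(code), error = function(e) {
      abort_gf(sprintf("pipeline failed at stage '%s': %s", name,
                       conditionMessage(e)),
               paste0("stage_", name, "_error"))
    })
  }

  sim <- stage("simulate", simulate_cohort(config$effect))
  diet <- stage("build", {
    if (!is.null(config$diet_file)) {
      if (!file.exists(config$diet_file)) {
        stop("diet file not found: ", config$diet_file)
      }
      readr::read_tsv(config$diet_file, show_col_types = FALSE)
    } else sim$diet
  })

  mapping <- stage("map", {
    filt <- filter_species_level(sim$abundance,
                                 threshold = config$abundance_floor)
    mp <- map_to_resource(filt, sim$manifest$resource_species,
                          threshold = config$abundance_floor)
    ren <- renormalize_abundances(mp$table,
                                  threshold = config$abundance_floor)
    list(report = mp$report, abundances = ren)
  })

  fm <- stage("fba", {
    sex <- setNames(sim$cohort$sex, sim$cohort$sample_id)
    pipeline_fluxes(sim$pan_models, mapping$abundances, sex, sim$hosts,
                    diet, sim$manifest$flux_metabolites,
                    C = config$coupling_C)
  })

  processed <- stage("process", {
    process_flux_matrix(fm, zero_frac = config$zero_frac,
                        ident_frac = config$ident_frac,
                        tol = config$flux_tol,
                        r2_threshold = config$r2_threshold)
  })

  qc <- stage("qc", {
    metabolomics_qc(sim$metabolomics, k_sd = config$k_sd,
                    missing_frac = config$missing_frac,
                    cv_max = config$cv_max, k_neighbors = config$knn_k)
  })

  assoc <- stage("associate",
                 flux_association_battery(processed$fm, sim$cohort))
  drivers <- stage("associate",
                   driver_attribution(processed$fm, mapping$abundances,
                                      sim$pan_models,
                                      precursors =
                                        setNames(list(sim$manifest$chain$precursor),
                                                 sim$manifest$chain$product)))

  report <- list(
    seed = config$seed,
    thresholds = config[c("coupling_C", "abundance_floor", "zero_frac",
                          "ident_frac", "flux_tol", "r2_threshold",
                          "missing_frac", "cv_max", "k_sd", "knn_k")],
    mapping = glance(mapping$report),
    n_flux_metabolites = length(processed$fm$metabolites),
    n_groups = nrow(processed$groups),
    qc = tibble::tibble(
      n_excluded_samples = length(qc$excluded_samples),
      n_removed_metabolites = nrow(qc$removed_metabolites)),
    checksums = c(
      abundances = stage_checksum(mapping$abundances),
      flux = stage_checksum(round(processed$fm$scaled, 6)),
      associations = stage_checksum(assoc$age))
  )
  structure(list(sim = sim, mapping = mapping$report,
                 abundances = mapping$abundances, fm = fm,
                 processed = processed$fm, groups = processed$groups,
                 qc = qc, associations = assoc, drivers = drivers,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  seed %s; %d samples; %d flux metabolites after processing (%d groups)\n",
              format(x$report$seed), length(x$fm$samples),
              x$report$n_flux_metabolites, x$report$n_groups))
  cat(sprintf("  mapping: %.1f%% species reads, %.1f%% mapped reads\n",
              100 * x$report$mapping$mean_species_coverage,
              100 * x$report$mapping$mean_mapped_coverage))
  cat(sprintf("  QC: %d samples excluded, %d compounds removed\n",
              x$report$qc$n_excluded_samples,
              x$report$qc$n_removed_metabolites))
  invisible(x)
}
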
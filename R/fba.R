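#' Add a blood demand reaction
#'
#' Demand reactions are unbalanced left-sided sinks (e.g.
#' `DM_dchac[bc]: 1 dchac[bc] -> `) whose maximal flux measures the model's
#' capacity to accumulate a metabolite in a compartment. Bounds are
#' (0, 1,000,000) mmol/day/person. Calling twice is a no-op.
#'
#' @param model a `stoich_model`.
#' @param metabolite base metabolite name (without compartment tag).
#' @param compartment compartment tag, default `"[bc]"` (blood).
#' @return the model with the demand reaction, whose id is
#'   `DM_<metabolite><compartment>`.
#' @export
add_demand_reaction <- function(model, metabolite, compartment = "[bc]") {
  met <- paste0(metabolite, compartment)
  rid <- paste0("DM_", met)
  if (rid %in% model$reactions$id) return(model)
  if (!met %in% model$metabolites$id) {
    abort_gf(sprintf("metabolite '%s' not found in compartment %s",
                     metabolite, compartment), "lookup_error")
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions, tibble::tibble(id = rid, lb = 0, ub = 1e6))
  model$stoich <- dplyr::bind_rows(
    model$stoich, tibble::tibble(reaction = rid, metabolite = met, coef = -1))
  model
}

# Compile a model into the LP  max c'v  s.t. S v = 0, coupling rows, lb<=v<=ub.
# Coupling |v_j| <= C v_bio becomes two slack-completed equality rows, keeping
# S itself pristine. Returns dense matrices sized for the built-in simplex.
compile_lp <- function(model) {
  rxn <- model$reactions
  n <- nrow(rxn)
  mets <- model$metabolites$id
  m <- length(mets)
  ridx <- setNames(seq_len(n), rxn$id)
  midx <- setNames(seq_len(m), mets)

  k <- nrow(model$coupling)
  A <- matrix(0, m + 2L * k, n + 2L * k)
  st <- model$stoich
  A[cbind(midx[st$metabolite], ridx[st$reaction])] <- st$coef

  lb <- c(rxn$lb, rep(0, 2L * k))
  ub <- c(rxn$ub, rep(Inf, 2L * k))
  if (k > 0) {
    j <- ridx[model$coupling$reaction]
    bj <- ridx[model$coupling$biomass]
    C <- model$coupling$C
    r1 <- m + seq_len(k)          # v_j - C v_bio + s1 = 0
    r2 <- m + k + seq_len(k)      # v_j + C v_bio - s2 = 0
    A[cbind(r1, j)] <- 1;  A[cbind(r1, bj)] <- A[cbind(r1, bj)] - C
    A[cbind(r2, j)] <- 1;  A[cbind(r2, bj)] <- A[cbind(r2, bj)] + C
    A[cbind(r1, n + seq_len(k))] <- 1
    A[cbind(r2, n + k + seq_len(k))] <- -1
  }
  list(A = A, b = rep(0, nrow(A)), lb = lb, ub = ub,
       rxn_index = ridx, met_index = midx, n_rxns = n)
}

solve_compiled <- function(lp, objective_col, maximize = TRUE,
                           retain_flux = FALSE) {
  cc <- rep(0, ncol(lp$A))
  cc[objective_col] <- 1
  res <- .simplex_lp(lp$A, lp$b, lp$lb, lp$ub, cc, maximize)
  status <- c(`0` = "optimal", `1` = "infeasible", `2` = "unbounded",
              `3` = "iteration_limit")[[as.character(res$status)]]
  flux <- NULL
  if (status == "optimal" && retain_flux) {
    flux <- setNames(res$x[seq_len(lp$n_rxns)], names(lp$rxn_index))
  }
  structure(list(objective = res$objective, status = status, flux = flux),
            class = "flux_solution")
}

#' Maximise a reaction flux by flux balance analysis
#'
#' Solves the linear program max c'v subject to S v = 0, the model's coupling
#' constraints, and lb <= v <= ub, with c the indicator of the objective
#' reaction. A steady state is assumed. Solver failures are reported in the
#' `status` field, never silently turned into zeros.
#'
#' @param model a `stoich_model`.
#' @param objective_rxn reaction id to maximise.
#' @param retain_flux keep the full flux vector (default FALSE; only the
#'   objective value is normally of interest).
#' @return a `flux_solution`: `objective` (mmol/day/person), `status`
#'   (`"optimal"`, `"infeasible"`, or `"unbounded"`), and optionally `flux`.
#' @export
fba_max <- function(model, objective_rxn, retain_flux = FALSE) {
  lp <- compile_lp(model)
  if (!objective_rxn %in% names(lp$rxn_index)) {
    abort_gf(sprintf("objective reaction '%s' not in model", objective_rxn),
             "lookup_error")
  }
  solve_compiled(lp, lp$rxn_index[[objective_rxn]], retain_flux = retain_flux)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective=%s\n", x$status,
              format(x$objective)))
  invisible(x)
}

new_flux_matrix <- function(raw, germfree, scaled, mask, sex) {
  structure(list(raw = raw, germfree = germfree, scaled = scaled,
                 mask = mask, sex = sex,
                 samples = rownames(raw) %||% character(),
                 metabolites = colnames(raw) %||% character()),
            class = "flux_matrix")
}

#' Predict maximal blood metabolite fluxes for a set of samples
#'
#' For every (sample, metabolite) pair, adds a blood demand reaction and
#' maximises it by FBA on the sample's microbiome-WBM (`raw` layer). The
#' germ-free layer is computed once per sex per metabolite on the matching
#' germ-free host; the `scaled` layer is raw minus germ-free — the net
#' microbial contribution. All values are rounded to six decimals before
#' scaling. Samples whose model is infeasible are masked whole-row with
#' reason `infeasible` and the sweep continues. An unbounded demand is a
#' modeling error (every route must be capped by diet or coupling).
#'
#' @param models named list of `microbiome_wbm`s, one per sample.
#' @param germfree named list of diet-constrained germ-free hosts, by sex
#'   (`female`, `male`).
#' @param metabolites character vector of blood metabolite base names.
#' @return a `flux_matrix` with `raw`, `germfree`, `scaled` layers and a
#'   reason-coded mask.
#' @export
predict_blood_fluxes <- function(models, germfree, metabolites) {
  stopifnot(length(metabolites) > 0, length(models) > 0)
  samples <- names(models)
  sexes <- vapply(models, `[[`, "", "sex")

  gf_flux <- sapply(unique(sexes), function(sx) {
    gf <- germfree[[sx]]
    if (is.null(gf)) abort_gf(sprintf("no germ-free host for sex '%s'", sx),
                              "input_error")
    for (met in metabolites) gf <- add_demand_reaction(gf, met)
    lp <- compile_lp(gf)
    vapply(metabolites, function(met) {
      sol <- solve_compiled(lp, lp$rxn_index[[paste0("DM_", met, "[bc]")]])
      if (sol$status != "optimal") {
        abort_gf(sprintf("germ-free model not optimal for %s (%s)", met,
                         sol$status), "solver_error")
      }
      round6(sol$objective)
    }, 0)
  })
  gf_flux <- matrix(gf_flux, nrow = length(metabolites),
                    dimnames = list(metabolites, unique(sexes)))

  raw <- matrix(NA_real_, length(samples), length(metabolites),
                dimnames = list(samples, metabolites))
  mask <- matrix(NA_character_, length(samples), length(metabolites),
                 dimnames = list(samples, metabolites))
  for (s in seq_along(samples)) {
    mod <- models[[s]]
    for (met in metabolites) mod <- add_demand_reaction(mod, met)
    lp <- compile_lp(mod)
    for (met in metabolites) {
      sol <- solve_compiled(lp, lp$rxn_index[[paste0("DM_", met, "[bc]")]])
      if (sol$status == "unbounded") {
        abort_gf(sprintf("unbounded demand flux for %s in sample %s", met,
                         samples[s]), "solver_error")
      }
      if (sol$status != "optimal") {
        mask[s, ] <- "infeasible"
        break
      }
      raw[s, met] <- round6(sol$objective)
    }
  }

  gf_layer <- t(gf_flux)[sexes, , drop = FALSE]
  dimnames(gf_layer) <- dimnames(raw)
  scaled <- round6(raw - gf_layer)
  scaled[!is.na(mask)] <- NA_real_
  raw[!is.na(mask)] <- NA_real_
  new_flux_matrix(raw, gf_layer, scaled, mask, sexes)
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat(sprintf("<flux_matrix> %d samples x %d metabolites (%d masked entries)\n",
              length(x$samples), length(x$metabolites), sum(!is.na(x$mask))))
  invisible(x)
}

#' Tidy a flux matrix into long format
#'
#' @param x a `flux_matrix`.
#' @param ... unused.
#' @return tibble with columns sample, metabolite, raw, germfree, scaled,
#'   mask (NA when the value is usable).
#' @export
tidy.flux_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples, times = length(x$metabolites)),
    metabolite = rep(x$metabolites, each = length(x$samples)),
    raw = as.vector(x$raw),
    germfree = as.vector(x$germfree),
    scaled = as.vector(x$scaled),
    mask = as.vector(x$mask)
  )
}

#' @export
glance.flux_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples),
    n_metabolites = length(x$metabolites),
    n_masked = sum(!is.na(x$mask)),
    mask_reasons = paste(sort(unique(stats::na.omit(as.vector(x$mask)))),
                         collapse = ",")
  )
}

# scaled layer with the mask applied (masked entries NA)
masked_scaled <- function(fm) {
  out <- fm$scaled
  out[!is.na(fm$mask)] <- NA_real_
  out
}

#' Construct a flux matrix from plain layers
#'
#' Mostly useful for testing the post-processing rules on hand-crafted
#' values; [predict_blood_fluxes()] builds these during a normal run.
#'
#' @param scaled samples x metabolites matrix of scaled (net microbial)
#'   fluxes, with dimnames.
#' @param raw,germfree optional matching layers (default: raw = scaled on a
#'   zero germ-free background).
#' @param mask optional character matrix of mask reasons (NA = usable).
#' @param sex optional per-sample sex vector (default all female).
#' @return a `flux_matrix`.
#' @export
flux_matrix <- function(scaled, raw = NULL, germfree = NULL, mask = NULL,
                        sex = NULL) {
  scaled <- as.matrix(scaled)
  if (is.null(rownames(scaled))) {
    rownames(scaled) <- sprintf("S%03d", seq_len(nrow(scaled)))
  }
  if (is.null(colnames(scaled))) {
    colnames(scaled) <- sprintf("m%02d", seq_len(ncol(scaled)))
  }
  germfree <- germfree %||% (scaled * 0)
  raw <- raw %||% (scaled + germfree)
  mask <- mask %||% matrix(NA_character_, nrow(scaled), ncol(scaled),
                           dimnames = dimnames(scaled))
  sex <- sex %||% setNames(rep("female", nrow(scaled)), rownames(scaled))
  dimnames(raw) <- dimnames(germfree) <- dimnames(mask) <- dimnames(scaled)
  new_flux_matrix(raw, germfree, scaled, mask, sex)
}
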
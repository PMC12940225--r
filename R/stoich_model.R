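#' Create a stoichiometric metabolic model
#'
#' A minimal constraint-based model container: metabolites with bracketed
#' compartment tags (e.g. `glc[bc]` for blood, `fiber[luLI]` for the
#' large-intestinal lumen), reactions with flux bounds in mmol/day/person, and
#' a sparse stoichiometry in long (reaction, metabolite, coefficient) form.
#' Substrates carry negative coefficients, products positive ones; a steady
#' state (S v = 0) is assumed whenever the model is solved. Reactions with no
#' stated bounds default to the conventional unconstrained range of
#' -1,000,000 to 1,000,000 mmol/day/person.
#'
#' @param id model identifier.
#' @param reactions tibble with columns `id`, `lb`, `ub` (bounds optional,
#'   defaulting to the unconstrained range).
#' @param stoich tibble with columns `reaction`, `metabolite`, `coef`; all
#'   coefficients must be nonzero.
#' @param sex optional sex tag (`"female"` or `"male"`) for host models.
#' @param biomass optional id of the designated biomass reaction.
#' @param coupling optional tibble of flux-coupling constraints with columns
#'   `reaction`, `biomass`, `C`; each row enforces |v_rxn| <= C * v_biomass.
#' @return an object of class `stoich_model`.
#' @export
stoich_model <- function(id, reactions, stoich, sex = NA_character_,
                         biomass = NA_character_, coupling = NULL) {
  reactions <- tibble::as_tibble(reactions)
  if (!"lb" %in% names(reactions)) reactions$lb <- -1e6
  if (!"ub" %in% names(reactions)) reactions$ub <- 1e6
  reactions$lb[is.na(reactions$lb)] <- -1e6
  reactions$ub[is.na(reactions$ub)] <- 1e6
  stoich <- tibble::as_tibble(stoich)
  for (cl in names(reactions)) reactions[[cl]] <- unname(reactions[[cl]])
  for (cl in names(stoich)) stoich[[cl]] <- unname(stoich[[cl]])

  if (anyDuplicated(reactions$id)) {
    abort_gf("duplicate reaction ids", "model_error")
  }
  if (any(reactions$lb > reactions$ub)) {
    abort_gf("reaction with lb > ub", "model_error")
  }
  if (any(stoich$coef == 0)) {
    abort_gf("zero stoichiometric coefficients are not allowed", "model_error")
  }
  if (!all(stoich$reaction %in% reactions$id)) {
    abort_gf("stoichiometry references unknown reactions", "model_error")
  }
  if (anyDuplicated(paste(stoich$reaction, stoich$metabolite))) {
    abort_gf("duplicate (reaction, metabolite) stoichiometry entries", "model_error")
  }
  if (!is.na(biomass) && !biomass %in% reactions$id) {
    abort_gf("biomass reaction not in model", "model_error")
  }
  if (!is.null(coupling)) {
    coupling <- tibble::as_tibble(coupling)
    if (any(coupling$C <= 0)) abort_gf("coupling factor must be > 0", "model_error")
    bad <- !c(coupling$reaction, coupling$biomass) %in% reactions$id
    if (any(bad)) abort_gf("coupling references unknown reactions", "model_error")
  }

  mets <- sort(unique(stoich$metabolite))
  structure(
    list(
      id = id,
      reactions = reactions[, c("id", "lb", "ub")],
      stoich = stoich[, c("reaction", "metabolite", "coef")],
      metabolites = tibble::tibble(id = mets,
                                   compartment = met_compartment(mets)),
      sex = sex,
      biomass = biomass,
      coupling = coupling %||%
        tibble::tibble(reaction = character(), biomass = character(),
                       C = numeric())
    ),
    class = "stoich_model"
  )
}

# "dchac[bc]" -> "[bc]"; no bracket -> NA
met_compartment <- function(ids) {
  m <- regmatches(ids, regexpr("\\[[^]]+\\]$", ids))
  out <- rep(NA_character_, length(ids))
  out[grepl("\\[[^]]+\\]$", ids)] <- m
  out
}

met_base <- function(ids) sub("\\[[^]]+\\]$", "", ids)

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s: %d reactions, %d metabolites",
              x$id, nrow(x$reactions), nrow(x$metabolites)))
  if (!is.na(x$sex)) cat(sprintf(" [%s]", x$sex))
  if (nrow(x$coupling) > 0) {
    cat(sprintf(", %d coupling constraints", nrow(x$coupling)))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a stoichiometric model into its reaction table
#'
#' @param x a `stoich_model`.
#' @param ... unused.
#' @return tibble with one row per reaction: id, bounds, and a compact
#'   human-readable equation.
#' @export
tidy.stoich_model <- function(x, ...) {
  eqs <- x$stoich |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(equation = reaction_equation(.data$metabolite, .data$coef),
                     .groups = "drop")
  dplyr::left_join(x$reactions, eqs, by = c(id = "reaction"))
}

reaction_equation <- function(mets, coefs) {
  fmt <- function(m, k) {
    ifelse(abs(k) == 1, m, paste0(abs(k), " ", m))
  }
  lhs <- paste(fmt(mets[coefs < 0], coefs[coefs < 0]), collapse = " + ")
  rhs <- paste(fmt(mets[coefs > 0], coefs[coefs > 0]), collapse = " + ")
  paste(lhs, "->", rhs)
}

#' @export
glance.stoich_model <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_reactions = nrow(x$reactions),
    n_metabolites = nrow(x$metabolites),
    n_coupling = nrow(x$coupling),
    sex = x$sex
  )
}

# internal: append reactions given as list(id = list(stoich=c(...), lb, ub))
add_reactions <- function(model, rxns) {
  new_rxn <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, function(r) r$lb %||% -1e6, 0),
    ub = vapply(rxns, function(r) r$ub %||% 1e6, 0)
  )
  new_st <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })
  stoich_model(model$id,
               dplyr::bind_rows(model$reactions, new_rxn),
               dplyr::bind_rows(model$stoich, new_st),
               sex = model$sex, biomass = model$biomass,
               coupling = model$coupling)
}

#' Write a model to COBRA-style JSON
#'
#' The layout mirrors the community JSON schema used by constraint-based
#' toolkits: `metabolites` (id, compartment), `reactions` (id, bounds,
#' metabolite coefficient map, objective coefficient). Coupling constraints,
#' which plain COBRA JSON has no slot for, are stored under an extra
#' `coupling_constraints` key.
#'
#' @param model a `stoich_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  st <- split(model$stoich, model$stoich$reaction)
  rx <- purrr::pmap(model$reactions, function(id, lb, ub) {
    s <- st[[id]]
    list(id = id, lower_bound = lb, upper_bound = ub,
         metabolites = as.list(setNames(s$coef, s$metabolite)),
         objective_coefficient = 0)
  })
  obj <- list(
    id = model$id,
    sex = model$sex,
    biomass = model$biomass,
    metabolites = purrr::pmap(model$metabolites, function(id, compartment) {
      list(id = id, compartment = compartment)
    }),
    reactions = rx,
    coupling_constraints = purrr::pmap(model$coupling,
      function(reaction, biomass, C) list(reaction = reaction,
                                          biomass = biomass, C = C))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from COBRA-style JSON
#'
#' @param path file written by [write_model_json()] or any COBRA JSON file
#'   with `metabolites` and `reactions` arrays.
#' @return a `stoich_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rxns <- purrr::map(obj$reactions, function(r) {
    list(id = r$id, lb = r$lower_bound %||% -1e6, ub = r$upper_bound %||% 1e6,
         stoich = unlist(r$metabolites))
  })
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub")
  )
  stoich <- purrr::map_dfr(rxns, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })
  coupling <- NULL
  if (length(obj$coupling_constraints)) {
    coupling <- purrr::map_dfr(obj$coupling_constraints, function(cc) {
      tibble::tibble(reaction = cc$reaction, biomass = cc$biomass, C = cc$C)
    })
  }
  stoich_model(obj$id %||% "model", reactions, stoich,
               sex = obj$sex %||% NA_character_,
               biomass = obj$biomass %||% NA_character_,
               coupling = coupling)
}

#' Constrain dietary uptake
#'
#' Dietary exchange reactions (single-metabolite exchanges on the `[d]`
#' compartment) are bounded by the diet: a metabolite with dietary flux f gets
#' bounds (-f, 0) under the uptake-negative convention, and every dietary
#' exchange the diet does not name is closed to uptake (lb = 0). Diet fluxes
#' are in mmol/day/person. Diet entries without a matching dietary exchange
#' reaction are skipped with a warning.
#'
#' @param model a `stoich_model` (or `microbiome_wbm`).
#' @param diet tibble with columns `metabolite` (base name, no compartment
#'   tag) and `flux` (maximal uptake, mmol/day/person).
#' @return the constrained model.
#' @export
apply_diet <- function(model, diet) {
  diet <- tibble::as_tibble(diet)
  st_n <- dplyr::count(model$stoich, .data$reaction)
  single <- st_n$reaction[st_n$n == 1]
  dx <- model$stoich[model$stoich$reaction %in% single &
                       met_compartment(model$stoich$metabolite) %in% "[d]", ]
  diet_rxn <- setNames(dx$reaction, met_base(dx$metabolite))

  missing_ex <- setdiff(diet$metabolite, names(diet_rxn))
  if (length(missing_ex)) {
    warn_gf(paste0("diet metabolites without a dietary exchange, skipped: ",
                   paste(missing_ex, collapse = ", ")),
            "diet_warning")
    diet <- diet[!diet$metabolite %in% missing_ex, ]
  }

  rx <- model$reactions
  # close all dietary exchanges to uptake, then open the dieted ones
  rx$lb[rx$id %in% diet_rxn] <- 0
  idx <- match(diet_rxn[diet$metabolite], rx$id)
  rx$lb[idx] <- -diet$flux
  rx$ub[idx] <- 0
  model$reactions <- rx
  model
}
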
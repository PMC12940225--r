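#' Build a pan-species model from strain reconstructions
#'
#' Takes the union of all unique reactions and metabolites across the strain
#' models of one species. Reactions appearing in several strains must have
#' identical stoichiometry; their bounds are widened to the extremes observed
#' across strains (interval union), so the pan model can do whatever any
#' strain can. The designated biomass reaction is taken from the strains'
#' biomass flags.
#'
#' @param strain_models list of `stoich_model` objects for one species.
#' @param id id of the resulting pan model; defaults to the first strain's id
#'   with a `pan_` prefix.
#' @return a `stoich_model`.
#' @export
build_pan_species <- function(strain_models, id = NULL) {
  stopifnot(length(strain_models) >= 1)
  if (length(strain_models) == 1 && is.null(id)) return(strain_models[[1]])
  id <- id %||% paste0("pan_", strain_models[[1]]$id)

  key <- function(st) {
    st <- st[order(st$metabolite), ]
    paste(st$metabolite, format(st$coef, digits = 15), collapse = ";")
  }
  seen <- list()   # rxn id -> list(stoich_key, lb, ub, strain)
  for (m in strain_models) {
    st_by_rxn <- split(m$stoich, m$stoich$reaction)
    for (i in seq_len(nrow(m$reactions))) {
      rid <- m$reactions$id[i]
      k <- key(st_by_rxn[[rid]])
      if (is.null(seen[[rid]])) {
        seen[[rid]] <- list(key = k, lb = m$reactions$lb[i],
                            ub = m$reactions$ub[i], strain = m$id,
                            stoich = st_by_rxn[[rid]])
      } else {
        if (seen[[rid]]$key != k) {
          abort_gf(sprintf(
            "reaction '%s' has conflicting stoichiometry in strains '%s' and '%s'",
            rid, seen[[rid]]$strain, m$id), "assembly_error")
        }
        seen[[rid]]$lb <- min(seen[[rid]]$lb, m$reactions$lb[i])
        seen[[rid]]$ub <- max(seen[[rid]]$ub, m$reactions$ub[i])
      }
    }
  }
  reactions <- tibble::tibble(
    id = names(seen),
    lb = vapply(seen, `[[`, 0, "lb"),
    ub = vapply(seen, `[[`, 0, "ub")
  )
  stoich <- purrr::map_dfr(seen, `[[`, "stoich")
  biomass <- unique(stats::na.omit(
    vapply(strain_models, `[[`, "", "biomass")))
  if (length(biomass) != 1) {
    abort_gf("strains must designate exactly one biomass reaction id",
             "assembly_error")
  }
  stoich_model(id, reactions, stoich, biomass = biomass)
}

#' Assemble a microbial community model
#'
#' Each member species' pan model is namespaced (ids prefixed with the species
#' name) and connected through the shared microbiota lumen `[luM]`, whose
#' metabolites stay unprefixed. A `communityBiomass` reaction consumes each
#' species' biomass metabolite with its relative abundance a_k as the
#' stoichiometric coefficient and produces one unit of
#' `microbiota_LI_biomass[luM]`. Every microbial reaction j of species k is
#' flux-coupled to that species' biomass reaction, |v_j| <= C * v_bio(k), so
#' no flux can run through a taxon that is not growing.
#'
#' Species with zero abundance are excluded; the remaining abundances must
#' already sum to one (no silent renormalization here — use
#' [renormalize_abundances()] upstream).
#'
#' @param pan_models named list of pan `stoich_model`s (names = species).
#' @param abundances named numeric vector of relative abundances a_k.
#' @param C coupling factor (dimensionless), default 400.
#' @return a `community_model` (also a `stoich_model`) with a `members` field.
#' @export
build_community <- function(pan_models, abundances, C = 400) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0) {
    abort_gf("no species with positive abundance", "input_error")
  }
  if (abs(sum(abundances) - 1) > 1e-9) {
    abort_gf(sprintf("abundances must sum to 1 (got %.12f); renormalize first",
                     sum(abundances)), "input_error")
  }
  missing <- setdiff(names(abundances), names(pan_models))
  if (length(missing)) {
    abort_gf(paste0("no pan model for species: ",
                    paste(missing, collapse = ", ")), "input_error")
  }

  parts <- purrr::imap(pan_models[names(abundances)], function(m, sp) {
    if (is.na(m$biomass)) {
      abort_gf(sprintf("species '%s' has positive abundance but no biomass reaction",
                       sp), "assembly_error")
    }
    ns_met <- function(ids) {
      comp <- met_compartment(ids)
      ifelse(comp %in% "[luM]", ids, paste0(sp, "__", ids))
    }
    st <- m$stoich
    st$reaction <- paste0(sp, "__", st$reaction)
    st$metabolite <- ns_met(st$metabolite)
    rx <- m$reactions
    rx$id <- paste0(sp, "__", rx$id)
    bio <- paste0(sp, "__", m$biomass)
    list(reactions = rx, stoich = st, biomass = bio,
         coupling = tibble::tibble(
           reaction = setdiff(rx$id, bio), biomass = bio, C = C))
  })

  reactions <- purrr::map_dfr(parts, "reactions")
  stoich <- purrr::map_dfr(parts, "stoich")
  coupling <- purrr::map_dfr(parts, "coupling")
  members <- tibble::tibble(
    species = names(abundances),
    abundance = unname(abundances),
    biomass_rxn = vapply(parts, `[[`, "", "biomass")
  )

  # communityBiomass: sum_k a_k * biomass_met(k) -> 1 microbiota_LI_biomass
  bio_mets <- purrr::map_chr(parts, function(p) {
    st <- p$stoich[p$stoich$reaction == p$biomass & p$stoich$coef > 0, ]
    st$metabolite[1]
  })
  cb <- tibble::tibble(
    reaction = "communityBiomass",
    metabolite = c(unname(bio_mets), "microbiota_LI_biomass[luM]"),
    coef = c(-members$abundance, 1)
  )
  reactions <- dplyr::bind_rows(
    reactions, tibble::tibble(id = "communityBiomass", lb = 0, ub = 1e6))
  stoich <- dplyr::bind_rows(stoich, cb)

  out <- stoich_model("community", reactions, stoich, coupling = coupling)
  out$members <- members
  class(out) <- c("community_model", class(out))
  out
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d members, %d reactions, C coupling on %d reactions\n",
              nrow(x$members), nrow(x$reactions), nrow(x$coupling)))
  invisible(x)
}

#' Join a host whole-body model to a microbial community
#'
#' Connects the community's shared lumen `[luM]` to the host's
#' large-intestinal lumen `[luLI]` with reversible junction transports for
#' every metabolite the two sides share, routes the community biomass to feces
#' and pins its excretion (`Excretion_EX_microbiota_LI_biomass[fe]`) to
#' exactly 1 mmol/day/person, and pins `Whole_body_objective_rxn` to 1 so all
#' samples maintain the same host biomass turnover. The host's sex tag is
#' preserved; removing the community and junctions again (see
#' [remove_community()]) restores the germ-free host.
#'
#' @param host host `stoich_model` with a `[luLI]` compartment and a
#'   `Whole_body_objective_rxn`.
#' @param community a `community_model`.
#' @return a `microbiome_wbm` object (also a `stoich_model`).
#' @export
join_host_microbiome <- function(host, community) {
  if (!"[luLI]" %in% host$metabolites$compartment) {
    abort_gf("host model has no large-intestinal lumen ([luLI]) compartment",
             "structural_error")
  }
  host_li <- host$metabolites$id[host$metabolites$compartment %in% "[luLI]"]
  lumen <- community$metabolites$id[community$metabolites$compartment %in% "[luM]"]
  shared <- intersect(met_base(lumen), met_base(host_li))
  shared <- setdiff(shared, "microbiota_LI_biomass")

  junctions <- purrr::map(shared, function(b) {
    list(id = paste0("LUM_", b), lb = -1e6, ub = 1e6,
         stoich = setNames(c(-1, 1),
                           c(paste0(b, "[luM]"), paste0(b, "[luLI]"))))
  })
  junctions <- c(junctions, list(
    list(id = "LUM_microbiota_LI_biomass", lb = 0, ub = 1e6,
         stoich = c("microbiota_LI_biomass[luM]" = -1,
                    "microbiota_LI_biomass[fe]" = 1)),
    list(id = "Excretion_EX_microbiota_LI_biomass[fe]", lb = 1, ub = 1,
         stoich = c("microbiota_LI_biomass[fe]" = -1))
  ))
  jn_rxn <- tibble::tibble(
    id = vapply(junctions, `[[`, "", "id"),
    lb = vapply(junctions, `[[`, 0, "lb"),
    ub = vapply(junctions, `[[`, 0, "ub")
  )
  jn_st <- purrr::map_dfr(junctions, function(r) {
    tibble::tibble(reaction = r$id, metabolite = names(r$stoich),
                   coef = unname(r$stoich))
  })

  reactions <- dplyr::bind_rows(host$reactions, community$reactions, jn_rxn)
  stoich <- dplyr::bind_rows(host$stoich, community$stoich, jn_st)
  reactions$lb[reactions$id == "Whole_body_objective_rxn"] <- 1
  reactions$ub[reactions$id == "Whole_body_objective_rxn"] <- 1

  out <- stoich_model(paste0(host$id, "+microbiome"), reactions, stoich,
                      sex = host$sex, coupling = community$coupling)
  out$members <- community$members
  out$host_reactions <- host$reactions$id
  out$junction_reactions <- jn_rxn$id
  class(out) <- c("microbiome_wbm", class(out))
  out
}

#' Remove the microbial community from a joined model
#'
#' Inverse of [join_host_microbiome()]: drops community reactions and the
#' lumen junctions, restoring the germ-free host (the round trip is exact up
#' to reaction order).
#'
#' @param wbm a `microbiome_wbm`.
#' @return the germ-free host `stoich_model`.
#' @export
remove_community <- function(wbm) {
  stopifnot(inherits(wbm, "microbiome_wbm"))
  keep <- wbm$reactions$id %in% wbm$host_reactions
  reactions <- wbm$reactions[keep, ]
  stoich <- wbm$stoich[wbm$stoich$reaction %in% reactions$id, ]
  stoich_model(sub("\\+microbiome$", "", wbm$id), reactions, stoich,
               sex = wbm$sex)
}
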
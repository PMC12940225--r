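#' Mask zero and bound-limited flux predictions
#'
#' Two removal rules applied to the scaled (net microbial) layer, in order.
#' First, scaled values of exactly zero are masked (`zero_contribution`): they
#' indicate no microbial contribution. Second, for each metabolite, if the
#' maximal obtained flux (after six-decimal rounding) occurs in two or more
#' samples, those samples are masked (`bound_limited`): a shared maximum
#' means the prediction was capped by a host or dietary flux bound rather
#' than by the community, which would bias the downstream statistics.
#'
#' @param fm a `flux_matrix` with populated scaled layer.
#' @return the `flux_matrix` with an updated mask.
#' @export
mask_zero_and_bound_limited <- function(fm) {
  sc <- masked_scaled(fm)
  zero <- !is.na(sc) & sc == 0
  fm$mask[zero] <- "zero_contribution"
  sc[zero] <- NA_real_
  for (j in seq_along(fm$metabolites)) {
    col <- sc[, j]
    if (all(is.na(col))) next
    mx <- max(col, na.rm = TRUE)
    at_max <- !is.na(col) & col == mx
    if (sum(at_max) >= 2) fm$mask[at_max, j] <- "bound_limited"
  }
  fm
}

# largest run of values mutually reachable through steps <= tol (equivalence
# by chaining, i.e. union-find on |x_i - x_j| <= tol)
modal_bin_count <- function(x, tol) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0) return(0L)
  grp <- cumsum(c(1, diff(x) > tol))
  max(tabulate(grp))
}

#' Refine the metabolite selection
#'
#' Drops metabolites for which no informative flux distribution remains:
#' those with masked (zero or removed) entries in more than `zero_frac` of
#' samples, and those whose flux values are identical within `tol`
#' mmol/day/person (tolerance-binned modal value) for `ident_frac` of the
#' samples or more.
#'
#' @param fm a `flux_matrix`, already masked by
#'   [mask_zero_and_bound_limited()].
#' @param zero_frac masked-fraction threshold (strictly-greater-than), default 0.9.
#' @param ident_frac identical-fraction threshold (greater-or-equal), default 0.9.
#' @param tol equivalence tolerance for "identical", default 1e-6.
#' @return the `flux_matrix` restricted to surviving metabolites.
#' @export
refine_metabolites <- function(fm, zero_frac = 0.9, ident_frac = 0.9,
                               tol = 1e-6) {
  n <- length(fm$samples)
  sc <- masked_scaled(fm)
  drop <- vapply(seq_along(fm$metabolites), function(j) {
    n_masked <- sum(is.na(sc[, j]))
    if (n_masked > zero_frac * n) return(TRUE)
    modal_bin_count(sc[, j], tol) >= ident_frac * n
  }, TRUE)
  keep_flux_metabolites(fm, fm$metabolites[!drop])
}

keep_flux_metabolites <- function(fm, keep) {
  j <- match(keep, fm$metabolites)
  new_flux_matrix(fm$raw[, j, drop = FALSE], fm$germfree[, j, drop = FALSE],
                  fm$scaled[, j, drop = FALSE], fm$mask[, j, drop = FALSE],
                  fm$sex)
}

#' Group linearly dependent metabolites
#'
#' Metabolites whose maximal fluxes are stoichiometrically linked (e.g. a
#' strict precursor-product chain) carry the same information. Pairwise
#' simple linear regressions are computed over samples where both metabolites
#' are unmasked; pairs with R-squared above `r2_threshold` are connected, and
#' connected components of two or more metabolites become groups. Within a
#' group only the member with the smallest maximal possible flux is retained,
#' renamed to the concatenation of the member names (e.g. `"metA/metB"`).
#' Pairs sharing fewer than three unmasked samples are skipped.
#'
#' @param fm a refined `flux_matrix`.
#' @param r2_threshold R-squared threshold, default 0.999 (strictly greater).
#' @return list with `fm` (grouped flux matrix) and `groups` (tibble with
#'   group label, members, representative, and minimal pairwise R-squared).
#' @export
group_dependent_metabolites <- function(fm, r2_threshold = 0.999) {
  sc <- masked_scaled(fm)
  p <- length(fm$metabolites)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  r2 <- matrix(NA_real_, p, p, dimnames = list(fm$metabolites, fm$metabolites))
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        ok <- !is.na(sc[, i]) & !is.na(sc[, j])
        if (sum(ok) < 3) next
        if (sd(sc[ok, i]) == 0 || sd(sc[ok, j]) == 0) next
        r2[i, j] <- r2[j, i] <- cor(sc[ok, i], sc[ok, j])^2
        if (!is.na(r2[i, j]) && r2[i, j] > r2_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(p), find, 1L)
  comp <- split(seq_len(p), roots)
  comp <- comp[lengths(comp) >= 2]

  groups <- purrr::map_dfr(comp, function(idx) {
    mets <- fm$metabolites[idx]
    maxima <- vapply(idx, function(j) max(sc[, j], na.rm = TRUE), 0)
    rep_met <- mets[which.min(maxima)]
    tibble::tibble(
      group = paste(mets, collapse = "/"),
      members = paste(mets, collapse = ";"),
      representative = rep_met,
      r2_min = min(r2[idx, idx][upper.tri(r2[idx, idx])], na.rm = TRUE)
    )
  })

  drop <- unlist(purrr::map(comp, function(idx) {
    mets <- fm$metabolites[idx]
    maxima <- vapply(idx, function(j) max(sc[, j], na.rm = TRUE), 0)
    setdiff(mets, mets[which.min(maxima)])
  })) %||% character()
  fm <- keep_flux_metabolites(fm, setdiff(fm$metabolites, drop))
  if (nrow(groups) > 0) {
    ren <- setNames(groups$group, groups$representative)
    hit <- fm$metabolites %in% names(ren)
    fm$metabolites[hit] <- unname(ren[fm$metabolites[hit]])
    colnames(fm$raw) <- colnames(fm$germfree) <- colnames(fm$scaled) <-
      colnames(fm$mask) <- fm$metabolites
  }
  list(fm = fm, groups = groups)
}

#' Run the full flux post-processing chain
#'
#' Fixed order: six-decimal rounding and germ-free scaling happen at
#' prediction time; this applies zero masking, bound-limited masking,
#' refinement, and linear-dependence grouping, in that order.
#'
#' @param fm a `flux_matrix` from [predict_blood_fluxes()].
#' @inheritParams refine_metabolites
#' @inheritParams group_dependent_metabolites
#' @return list with `fm` (analysis-ready flux matrix) and `groups`.
#' @export
process_flux_matrix <- function(fm, zero_frac = 0.9, ident_frac = 0.9,
                                tol = 1e-6, r2_threshold = 0.999) {
  fm <- mask_zero_and_bound_limited(fm)
  fm <- refine_metabolites(fm, zero_frac, ident_frac, tol)
  group_dependent_metabolites(fm, r2_threshold)
}
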
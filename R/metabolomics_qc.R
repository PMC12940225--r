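# Metabolomics tables are tibbles with meta columns sample_id, aliquot,
# aliquot_group, batch followed by one column per compound (positive peak
# intensities or NA).

met_meta_cols <- c("sample_id", "aliquot", "aliquot_group", "batch")

met_value_cols <- function(t) setdiff(names(t), met_meta_cols)

#' Batch-normalize peak intensities
#'
#' Divides every intensity by the median value of its compound within its
#' batch (missing values ignored in the median), so batch medians become 1.
#' Compounds fully missing in a batch stay missing there, with a warning.
#'
#' @param t metabolomics tibble with a `batch` column.
#' @return the normalized table.
#' @export
batch_normalize <- function(t) {
  stopifnot("batch" %in% names(t))
  mets <- met_value_cols(t)
  fully_missing <- character()
  for (b in unique(t$batch)) {
    i <- t$batch == b
    med <- vapply(mets, function(m) median(t[[m]][i], na.rm = TRUE), 0)
    gone <- mets[is.na(med)]
    fully_missing <- union(fully_missing, gone)
    med[is.na(med)] <- 1
    t[i, mets] <- purrr::map2(t[i, mets], med, `/`)
  }
  if (length(fully_missing)) {
    warn_gf(paste0("compounds fully missing in some batch remain missing: ",
                   paste(fully_missing, collapse = ", ")), "qc_warning")
  }
  t
}

#' Exclude samples with extreme missingness
#'
#' Drops samples whose missing-value count exceeds the overall mean
#' missing-value count by more than `k` standard deviations (mean + k*SD of
#' the per-sample counts).
#'
#' @param t metabolomics tibble.
#' @param k SD multiplier, default 5.
#' @return the table without the excluded samples; their ids are recorded in
#'   the `excluded_samples` attribute.
#' @export
exclude_samples_by_missingness <- function(t, k = 5) {
  mets <- met_value_cols(t)
  counts <- rowSums(is.na(t[, mets]))
  thr <- mean(counts) + k * sd(counts)
  drop <- !is.na(thr) & counts > thr
  out <- t[!drop, ]
  attr(out, "excluded_samples") <- unique(t$sample_id[drop])
  out
}

# mean between-aliquot CV over replicate groups; NA when no replicate group
# has two or more present values
aliquot_cv <- function(values, groups) {
  ok <- !is.na(groups)
  if (!any(ok)) return(NA_real_)
  cvs <- tapply(values[ok], groups[ok], function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
  if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
}

#' Filter compounds by missingness and aliquot reproducibility
#'
#' Removes compounds missing in more than `missing_frac` of samples and
#' compounds whose between-aliquot coefficient of variation (SD/mean over
#' replicate aliquots, averaged across replicate groups) exceeds `cv_max`.
#' Without replicate groups the CV filter is skipped with a warning.
#'
#' @param t metabolomics tibble.
#' @param missing_frac missingness threshold, default 0.7 (strictly greater).
#' @param cv_max CV threshold, default 0.30 (strictly greater).
#' @return the filtered table; removed compounds are recorded in the
#'   `removed_metabolites` attribute.
#' @export
filter_metabolites <- function(t, missing_frac = 0.7, cv_max = 0.30) {
  mets <- met_value_cols(t)
  miss <- vapply(mets, function(m) mean(is.na(t[[m]])), 0)
  drop_miss <- mets[miss > missing_frac]

  has_reps <- "aliquot_group" %in% names(t) && any(!is.na(t$aliquot_group))
  drop_cv <- character()
  if (!has_reps) {
    warn_gf("no replicate aliquot groups; CV filter skipped", "qc_warning")
  } else {
    cv <- vapply(mets, function(m) aliquot_cv(t[[m]], t$aliquot_group), 0)
    drop_cv <- mets[!is.na(cv) & cv > cv_max]
  }
  removed <- tibble::tibble(
    metabolite = c(drop_miss, setdiff(drop_cv, drop_miss)),
    reason = c(rep("missingness", length(drop_miss)),
               rep("cv", length(setdiff(drop_cv, drop_miss))))
  )
  out <- t[, c(intersect(met_meta_cols, names(t)),
               setdiff(mets, removed$metabolite))]
  attr(out, "removed_metabolites") <- removed
  out
}

#' Log2-transform and impute missing intensities
#'
#' Applies log2 to all present values, then imputes missing entries by
#' k-nearest-neighbour imputation with samples as neighbours: distances are
#' Euclidean over co-present, z-standardized compounds, and each missing
#' entry is the mean of the `k_neighbors` nearest samples observed for that
#' compound. The output has no missing entries. A compound missing
#' everywhere cannot occur after filtering and raises an error.
#'
#' @param t filtered metabolomics tibble.
#' @param k_neighbors neighbours per imputation, default 10.
#' @return the log2, fully imputed table.
#' @export
log2_and_impute <- function(t, k_neighbors = 10) {
  mets <- met_value_cols(t)
  x <- log2(as.matrix(t[, mets]))
  if (any(colSums(!is.na(x)) == 0)) {
    abort_gf("compound with no observed values reached imputation",
             "qc_error")
  }
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    # mean squared difference over co-present compounds, all pairs at once:
    # with Z the zero-filled standardized matrix and P the presence mask,
    # sum_co (z_i - z_r)^2 = (Z^2 P')_ir + (Z^2 P')_ri - 2 (Z Z')_ir
    # (columns sorted by name so distances do not depend on column order
    # through floating-point summation order)
    z <- z[, order(colnames(z)), drop = FALSE]
    P <- (!is.na(z)) * 1
    Z0 <- z; Z0[is.na(Z0)] <- 0
    S2 <- (Z0^2) %*% t(P)
    CP <- Z0 %*% t(Z0)
    CO <- P %*% t(P)
    D <- (S2 + t(S2) - 2 * CP) / CO
    D[CO == 0] <- Inf
    diag(D) <- Inf
    # neighbours are always drawn from the observed values, never from
    # already-imputed entries, so the result is independent of row order
    x_obs <- x
    need <- which(rowSums(is.na(x_obs)) > 0)
    for (i in need) {
      ord <- order(D[i, ])
      ord <- ord[is.finite(D[i, ord])]
      for (j in which(is.na(x_obs[i, ]))) {
        cand <- ord[!is.na(x_obs[ord, j])]
        if (length(cand) == 0) next
        nn <- cand[seq_len(min(k_neighbors, length(cand)))]
        x[i, j] <- mean(x_obs[nn, j])
      }
    }
  }
  out <- dplyr::bind_cols(t[, intersect(met_meta_cols, names(t))],
                          tibble::as_tibble(x))
  attributes(out)$removed_metabolites <- attr(t, "removed_metabolites")
  out
}

#' Run the full metabolomics QC chain
#'
#' Batch-median normalization, sample exclusion by missingness (mean +
#' `k_sd` * SD), compound filters (missingness and between-aliquot CV), log2
#' transform, and KNN imputation, in that order. Replicate aliquot rows are
#' collapsed to the first aliquot after the CV filter so downstream analyses
#' see one row per sample.
#'
#' @param t raw metabolomics tibble.
#' @param k_sd SD multiplier for sample exclusion, default 5.
#' @param missing_frac,cv_max compound filter thresholds.
#' @param k_neighbors KNN imputation neighbours.
#' @return list: `table` (post-QC, one row per sample), `excluded_samples`,
#'   `removed_metabolites`.
#' @export
metabolomics_qc <- function(t, k_sd = 5, missing_frac = 0.7, cv_max = 0.30,
                            k_neighbors = 10) {
  t <- batch_normalize(t)
  t <- exclude_samples_by_missingness(t, k = k_sd)
  excluded <- attr(t, "excluded_samples")
  t <- filter_metabolites(t, missing_frac, cv_max)
  removed <- attr(t, "removed_metabolites")
  if ("aliquot" %in% names(t)) {
    t <- t[t$aliquot == "A" | is.na(t$aliquot), ]
  }
  t <- log2_and_impute(t, k_neighbors)
  list(table = t, excluded_samples = excluded,
       removed_metabolites = removed)
}
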
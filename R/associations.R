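# Every test returns rows of the same tidy shape so results bind into one
# table per analysis family.
assoc_row <- function(outcome, predictor, test, estimate, statistic, p,
                      n, covariates = character()) {
  tibble::tibble(outcome = outcome, predictor = predictor, test = test,
                 estimate = estimate, statistic = statistic, p_value = p,
                 fdr = NA_real_, n = n,
                 covariates = paste(covariates, collapse = ","))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone after sorting and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0,1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  p.adjust(pvals, method = "BH")
}

#' Map APOE genotypes to risk groups
#'
#' E2 = \{E2/E2, E2/E3\} (protective), E3 = \{E3/E3\} (reference),
#' E4 = \{E3/E4, E4/E4\} (risk); the ambiguous E2/E4 genotype is excluded
#' because its allelic effect is undefined.
#'
#' @param genotypes character vector of genotypes like `"E3/E4"`.
#' @return factor with levels E2, E3, E4, excluded.
#' @export
apoe_groups <- function(genotypes) {
  map <- c(`E2/E2` = "E2", `E2/E3` = "E2", `E3/E3` = "E3",
           `E3/E4` = "E4", `E4/E4` = "E4", `E2/E4` = "excluded")
  unknown <- setdiff(unique(genotypes), names(map))
  if (length(unknown)) {
    abort_gf(paste0("unknown APOE genotypes: ", paste(unknown, collapse = ", ")),
             "input_error")
  }
  factor(map[genotypes], levels = c("E2", "E3", "E4", "excluded"))
}

#' Global cognition score (first principal component)
#'
#' Standardizes the subtest scores and projects complete cases onto the
#' first principal component. The sign is oriented so the score correlates
#' positively with the mean standardized subtest, making "higher = better
#' cognition" reproducible. The proportion of subtest variance explained by
#' the component is reported alongside.
#'
#' @param subtests tibble or matrix of numeric subtest scores (>= 2 columns),
#'   complete cases only.
#' @return list: `score` (numeric, one per row), `variance_explained`.
#' @export
global_cognition <- function(subtests) {
  x <- as.matrix(subtests)
  stopifnot(ncol(x) >= 2, !anyNA(x))
  if (any(apply(x, 2, sd) == 0)) {
    abort_gf("constant subtest column", "input_error")
  }
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (cor(score, rowMeans(z)) < 0) score <- -score
  list(score = unname(score),
       variance_explained = unname(pc$sdev[1]^2 / sum(pc$sdev^2)))
}

#' Polygenic risk score
#'
#' Weighted allele count: PRS = sum over SNPs of dosage D_i times published
#' effect weight E_i. Samples with any missing dosage get a missing PRS (no
#' zero-filling).
#'
#' @param dosages tibble or matrix of allelic dosages in `[0,2]`, one column
#'   per SNP.
#' @param weights named numeric vector of per-SNP effect weights; names must
#'   match the dosage columns.
#' @return numeric PRS per sample.
#' @export
compute_prs <- function(dosages, weights) {
  d <- as.matrix(dosages)
  if (is.null(names(weights)) || !setequal(names(weights), colnames(d))) {
    abort_gf("weights must be named by the dosage SNP columns", "input_error")
  }
  d <- d[, names(weights), drop = FALSE]
  if (any(d < 0 | d > 2, na.rm = TRUE)) {
    abort_gf("dosages must lie in [0, 2]", "input_error")
  }
  as.vector(d %*% weights)
}

#' Linear regression of an outcome on a focal predictor
#'
#' Ordinary least squares of `outcome ~ predictor + covariates` on complete
#' cases, reporting the focal coefficient with its two-sided Wald p-value.
#' When `standardize` is TRUE (the default) the focal predictor and a
#' continuous outcome are z-standardized before fitting, so the estimate is
#' a standardized slope.
#'
#' @param data tibble containing all columns.
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names.
#' @param standardize z-standardize outcome and predictor first.
#' @return one-row association tibble.
#' @export
regress_outcome <- function(data, outcome, predictor,
                            covariates = character(), standardize = TRUE) {
  cols <- c(outcome, predictor, covariates)
  d <- data[complete.cases(data[, cols]), cols]
  if (nrow(d) < length(cols) + 2) {
    abort_gf("too few complete cases for regression", "input_error")
  }
  if (standardize) {
    d[[outcome]] <- zstd(d[[outcome]])
    if (is.numeric(d[[predictor]])) d[[predictor]] <- zstd(d[[predictor]])
  }
  f <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- lm(f, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort_gf(paste0("rank-deficient design; collinear terms: ",
                    paste(bad, collapse = ", ")), "input_error")
  }
  sm <- summary(fit)$coefficients
  focal <- rownames(sm)[startsWith(rownames(sm), predictor)][1]
  assoc_row(outcome, predictor, "linear", sm[focal, 1], sm[focal, 3],
            sm[focal, 4], nrow(d), covariates)
}

# tie-corrected Dunn z for one pair from pooled ranks
dunn_pair <- function(ranks, groups, N, tie_term, g1, g2) {
  r1 <- ranks[groups == g1]; r2 <- ranks[groups == g2]
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / length(r1) + 1 / length(r2)))
  z <- (mean(r1) - mean(r2)) / se
  c(z = z, p = 2 * pnorm(-abs(z)))
}

#' Kruskal-Wallis test with Dunn post-hoc pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H across groups, followed by Dunn's pairwise
#' z tests on the pooled ranks with the tie correction
#' sum(t^3 - t) / (12 (N - 1)). Dunn p-values are reported unadjusted (an
#' adjustment can be applied downstream). Groups with fewer than two members
#' are dropped with a warning.
#'
#' @param y numeric outcome.
#' @param groups group labels (factor or character).
#' @return association tibble: one `kruskal_wallis` row plus one `dunn` row
#'   per group pair, with `predictor` naming the pair.
#' @export
kruskal_dunn <- function(y, groups) {
  keep <- !is.na(y) & !is.na(groups)
  y <- y[keep]; groups <- factor(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn_gf(paste0("groups of size < 2 dropped: ",
                   paste(small, collapse = ", ")), "stats_warning")
    keep <- !groups %in% small
    y <- y[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) abort_gf("need >= 2 groups", "input_error")

  kw <- kruskal.test(y, groups)
  out <- assoc_row("y", "groups", "kruskal_wallis", NA_real_,
                   unname(kw$statistic), kw$p.value, length(y))

  ranks <- rank(y)
  N <- length(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(groups), 2, simplify = FALSE)
  dunn <- purrr::map_dfr(pairs, function(pr) {
    res <- dunn_pair(ranks, groups, N, tie_term, pr[1], pr[2])
    assoc_row("y", paste(pr, collapse = " vs "), "dunn",
              NA_real_, res[["z"]], res[["p"]],
              sum(groups %in% pr))
  })
  dplyr::bind_rows(out, dunn)
}

#' Wilcoxon rank-sum test between sexes
#'
#' Two-sided rank-sum test of an outcome between female and male samples,
#' with the normal approximation and tie correction.
#'
#' @param y numeric outcome.
#' @param sex vector with two levels (e.g. female/male).
#' @return one-row association tibble.
#' @export
wilcoxon_sex <- function(y, sex) {
  keep <- !is.na(y) & !is.na(sex)
  y <- y[keep]; sex <- factor(sex[keep])
  if (nlevels(sex) != 2 || any(table(sex) == 0)) {
    abort_gf("both groups must be non-empty", "input_error")
  }
  # exact for small tie-free samples, tie-corrected normal otherwise; fully
  # tied data degenerates to z = 0/0, reported as p = 1 by convention
  wt <- suppressWarnings(wilcox.test(y ~ sex, correct = FALSE))
  p <- if (is.finite(wt$p.value)) wt$p.value else 1
  assoc_row("y", "sex", "wilcoxon", NA_real_, unname(wt$statistic),
            p, length(y))
}

#' Sex-interaction analysis with stratified follow-up
#'
#' Fits `y ~ flux + sex + flux:sex + covariates`; when the interaction term
#' is significant at `alpha`, per-sex models with the stratified covariate
#' set are fitted as follow-ups. All fitted results are reported.
#'
#' @param data tibble with outcome, flux, sex, and covariates.
#' @param outcome,flux column names.
#' @param covariates covariates of the interaction model (default age, bmi,
#'   education).
#' @param strat_covariates covariates of the stratified models (default bmi,
#'   education).
#' @param alpha significance gate for the follow-up, default 0.05.
#' @return association tibble: `interaction` row, plus stratified `linear`
#'   rows when triggered.
#' @export
interaction_analysis <- function(data, outcome, flux,
                                 covariates = c("age", "bmi", "education"),
                                 strat_covariates = c("bmi", "education"),
                                 alpha = 0.05) {
  if (length(unique(stats::na.omit(data$sex))) < 2) {
    abort_gf("both sexes required for the interaction model", "input_error")
  }
  cols <- c(outcome, flux, "sex", covariates)
  d <- data[complete.cases(data[, cols]), cols]
  d[[outcome]] <- zstd(d[[outcome]])
  d[[flux]] <- zstd(d[[flux]])
  f <- stats::as.formula(paste(
    outcome, "~", flux, "* sex +",
    paste(covariates, collapse = " + ")))
  fit <- lm(f, data = d)
  sm <- summary(fit)$coefficients
  inter <- grep(":", rownames(sm), value = TRUE)[1]
  out <- assoc_row(outcome, paste0(flux, ":sex"), "interaction",
                   sm[inter, 1], sm[inter, 3], sm[inter, 4], nrow(d),
                   covariates)
  if (sm[inter, 4] < alpha) {
    strat <- purrr::map_dfr(unique(d$sex), function(sx) {
      res <- regress_outcome(d[d$sex == sx, ], outcome, flux,
                             strat_covariates, standardize = FALSE)
      res$predictor <- paste0(flux, " (", sx, ")")
      res
    })
    out <- dplyr::bind_rows(out, strat)
  }
  out
}

#' Exact Fisher test of independence for a 2 x C table
#'
#' Full enumeration of all tables with the observed margins: the two-sided
#' p-value is the total multivariate hypergeometric probability of tables no
#' more likely than the observed one (with the conventional 1 + 1e-7
#' relative slack). Enumeration runs over the C-1 free cells of the first
#' row; when the enumeration size exceeds `max_tables` a seeded Monte-Carlo
#' estimate over `mc_reps` margin-preserving draws is used instead.
#'
#' @param table 2 x C matrix of non-negative integer counts.
#' @param max_tables enumeration cap, default 2e7.
#' @param mc_reps Monte-Carlo replicates past the cap.
#' @param mc_seed seed for the Monte-Carlo fallback.
#' @return the two-sided p-value.
#' @export
fisher_exact_rxc <- function(table, max_tables = 2e7, mc_reps = 1e5,
                             mc_seed = 1) {
  x <- as.matrix(table)
  if (nrow(x) != 2 || any(x < 0) || any(x != round(x))) {
    abort_gf("need a 2 x C table of non-negative integer counts", "input_error")
  }
  cs <- colSums(x); r1 <- sum(x[1, ]); N <- sum(x)
  C <- ncol(x)
  logp_obs <- sum(lchoose(cs, x[1, ])) - lchoose(N, r1)
  slack <- log1p(1e-7)

  n_tables <- prod(cs[-C] + 1)
  if (n_tables > max_tables) {
    set.seed(mc_seed)
    hits <- 0L
    for (r in seq_len(mc_reps)) {
      # draw first row from the multivariate hypergeometric by sequential
      # conditional hypergeometric sampling
      rem <- r1; left <- N
      row1 <- integer(C)
      for (j in seq_len(C)) {
        left <- left - cs[j]
        row1[j] <- if (j == C) rem else
          stats::rhyper(1, cs[j], left, rem)
        rem <- rem - row1[j]
      }
      lp <- sum(lchoose(cs, row1)) - lchoose(N, r1)
      if (lp <= logp_obs + slack) hits <- hits + 1L
    }
    return(hits / mc_reps)
  }

  # vectorised enumeration: loop the first free cell, vectorise the rest
  free <- seq_len(C - 1)
  lch <- lapply(free, function(j) lchoose(cs[j], 0:cs[j]))
  if (C == 2) {
    gsum <- 0; glog <- 0
  } else {
    grids <- expand.grid(lapply(free[-1], function(j) 0:cs[j]))
    gsum <- Reduce(`+`, grids)
    glog <- Reduce(`+`, Map(function(col, j) lch[[j]][col + 1],
                            grids, free[-1]))
  }
  total <- 0
  for (v in 0:cs[1]) {
    last <- r1 - v - gsum
    ok <- last >= 0 & last <= cs[C]
    if (!any(ok)) next
    lp <- lch[[1]][v + 1] + glog[ok] + lchoose(cs[C], last[ok]) -
      lchoose(N, r1)
    total <- total + sum(exp(lp[lp <= logp_obs + slack]))
  }
  min(1, total)
}

#' Two-sample t-test from values or summary statistics
#'
#' Welch's unequal-variance t-test (two-sided). Accepts either raw value
#' vectors or summary triplets `(mean, sd, n)`, mirroring how cohort
#' characteristic tables report groups. Zero variance in both groups with
#' equal means returns p = 1 by convention.
#'
#' @param a,b numeric vectors, or lists/vectors with elements `mean`, `sd`,
#'   `n`.
#' @param var_equal use the pooled-variance Student variant instead.
#' @return one-row association tibble (estimate = mean difference).
#' @export
t_two_sample <- function(a, b, var_equal = FALSE) {
  summarize_arg <- function(v) {
    if (is.list(v) || !is.null(names(v))) {
      list(mean = v[["mean"]], sd = v[["sd"]], n = v[["n"]])
    } else {
      list(mean = mean(v), sd = sd(v), n = length(v))
    }
  }
  sa <- summarize_arg(a); sb <- summarize_arg(b)
  if (sa$n < 2 || sb$n < 2) abort_gf("need n >= 2 per group", "input_error")
  est <- sa$mean - sb$mean
  if (sa$sd == 0 && sb$sd == 0) {
    p <- if (est == 0) 1 else 0
    return(assoc_row("a", "b", "t_two_sample", est, if (est == 0) 0 else Inf,
                     p, sa$n + sb$n))
  }
  if (var_equal) {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  } else {
    va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  tstat <- est / se
  assoc_row("a", "b", "t_two_sample", est, tstat,
            2 * pt(-abs(tstat), df), sa$n + sb$n)
}

#' Attribute flux variation to candidate driver species
#'
#' For each metabolite, candidate species are those whose pan model can
#' exchange the metabolite (or a declared precursor) with the shared lumen.
#' Each candidate's abundance is regressed against the metabolite's flux in
#' a simple linear regression and candidates are ranked by R-squared. By
#' default abundances enter on the identity scale, where a sole
#' coupling-bound producer yields R-squared of exactly 1; set
#' `log2_abundance` to mirror the log2 + z preprocessing of the association
#' battery.
#'
#' @param fm a processed `flux_matrix`.
#' @param abundances renormalized abundance tibble (`sample_id` + species).
#' @param models named list of pan `stoich_model`s.
#' @param precursors optional named list: metabolite -> precursor
#'   metabolites, extending the candidate sets.
#' @param log2_abundance use log2 + z-standardized abundances.
#' @return tibble: metabolite, species, r_squared, rank.
#' @export
driver_attribution <- function(fm, abundances, models, precursors = list(),
                               log2_abundance = FALSE) {
  sc <- masked_scaled(fm)
  rows <- match(abundances$sample_id, fm$samples)
  if (anyNA(rows)) abort_gf("flux and abundance samples differ", "input_error")

  secretes <- function(model, met) {
    lum <- paste0(met, "[luM]")
    any(model$stoich$metabolite == lum & model$stoich$coef > 0)
  }
  purrr::map_dfr(fm$metabolites, function(met) {
    base_mets <- unique(c(strsplit(met, "/", fixed = TRUE)[[1]]))
    targets <- unique(c(base_mets, unlist(precursors[base_mets])))
    cand <- names(models)[vapply(models, function(m) {
      any(vapply(targets, function(tm) secretes(m, tm), TRUE))
    }, TRUE)]
    cand <- intersect(cand, names(abundances))
    if (length(cand) == 0) {
      warn_gf(paste0("no candidate species for ", met), "attribution_warning")
      return(tibble::tibble(metabolite = character(), species = character(),
                            r_squared = numeric(), rank = integer()))
    }
    flux <- sc[rows, match(met, fm$metabolites)]
    res <- purrr::map_dbl(cand, function(sp) {
      a <- abundances[[sp]]
      if (log2_abundance) a <- zstd(log2(a + 1e-12))
      ok <- !is.na(flux) & !is.na(a)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(flux[ok]) == 0) return(NA_real_)
      cor(a[ok], flux[ok])^2
    })
    ord <- order(-res, na.last = TRUE)
    tibble::tibble(metabolite = met, species = cand[ord],
                   r_squared = res[ord],
                   rank = seq_along(cand))
  })
}
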